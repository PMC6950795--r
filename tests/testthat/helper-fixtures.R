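# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except where a reader is under test.

# A minimal manifest data frame with the class the readers attach.
make_manifest <- function(probe_id, chrom = "chr1", pos = seq_along(probe_id),
                          genes = "GENEA", tags = "Body", cgi = "None",
                          in_sparse = TRUE, in_dense = TRUE) {
  df <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                   gene_symbols = genes, region_tags = tags,
                   cgi_relation = cgi, in_sparse = in_sparse,
                   in_dense = in_dense, stringsAsFactors = FALSE)
  class(df) <- c("methexpr_manifest", "data.frame")
  df
}

# A differential-result table shaped like run_cohort() output.
make_diff <- function(probe_id, call, delta = ifelse(call == "HYPER", 0.3,
                                                     ifelse(call == "HYPO", -0.3, 0.01)),
                      p = ifelse(call == "NS", 0.5, 0.001), cohort = "c1") {
  data.frame(probe_id = probe_id, cohort = cohort, delta_beta = delta,
             t = NA_real_, p_value = p, adj_p = p, call = call,
             n_cancer = 10, n_normal = 10, stringsAsFactors = FALSE)
}

# Gene models built directly from exon coordinates (1-based closed).
make_models <- function(...) {
  methexpr:::new_gene_models(list(...))
}

make_tx <- function(gene, chrom, strand, exons, cds = NULL) {
  methexpr:::build_transcript(gene = gene, chrom = chrom, strand = strand,
                              exons = exons, cds = cds)
}

# Small three-cohort simulation used by several pipeline-level tests.
small_config <- function(seed = 42, n_genes = 80, ...) {
  sim_config(seed = seed, n_genes = n_genes, probes_per_gene_sparse = 2,
             probes_per_gene_dense = 5,
             cohorts = data.frame(name = c("a", "b", "c"),
                                  n_cancer = c(20, 20, 30),
                                  n_normal = c(20, 20, 15),
                                  platform = c("sparse", "dense", "dense"),
                                  stringsAsFactors = FALSE),
             ...)
}

# Brute-force TSS-window membership: is any TSS offset within w?
brute_window <- function(pos, tsss, strand, w) {
  d <- if (strand == "+") pos - tsss else tsss - pos
  any(abs(d) <= w)
}

# Brute-force signed nearest distance with the upstream tie rule.
brute_nearest <- function(pos, tsss, strand) {
  d <- if (strand == "+") pos - tsss else tsss - pos
  cand <- d[abs(d) == min(abs(d))]
  if (any(cand < 0)) min(cand) else cand[1]
}
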