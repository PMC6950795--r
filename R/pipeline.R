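#' End-to-end pipeline run
#'
#' Orchestrates the full analysis on a simulated study (or on a pre-built
#' study list of the same shape): per-cohort differential methylation,
#' cross-cohort probe consensus, regulation-group assignment against the
#' expression status table, dense-manifest "-only" refinement, top-gene
#' ranking, methylation-expression correlation of the "-only" hyperprobes on
#' matched samples, and genomic context (TSS windows, distance histogram,
#' CGI summary, region fractions). Stage outputs are pure functions of the
#' configuration and seed: rerunning with the same config reproduces every
#' table byte for byte.
#'
#' @param config A [sim_config()] describing the synthetic study.
#' @param test_cfg A [test_config()] for the per-probe tests.
#' @param outdir Optional directory; when given, every stage table is
#'   written as TSV plus a machine-readable `run_summary.json`.
#' @param required_cohorts Cohorts required for consensus (default: all).
#' @param fc_split Fold-change magnitude split for the distance histogram
#'   (default 0.2).
#' @param rank_k Number of top genes to rank per group (default 10).
#' @param study Optional pre-generated [simulate_study()] result; when
#'   supplied, `config` is ignored for generation.
#' @return Object of class \code{methexpr_run}: a list with the stage
#'   outputs (\code{diff}, \code{consensus}, \code{groups}, \code{only},
#'   \code{ranked}, \code{correlation}, \code{context}) and a
#'   \code{summary} list of per-stage counts.
#' @export
run_pipeline <- function(config = sim_config(), test_cfg = test_config(),
                         outdir = NULL, required_cohorts = NULL,
                         fc_split = 0.2, rank_k = 10, study = NULL) {
  t0 <- proc.time()[["elapsed"]]
  study <- study %||% simulate_study(config)
  config <- study$config
  required_cohorts <- required_cohorts %||% config$cohorts$name

  diff <- lapply(names(study$cohorts), function(nm)
    run_cohort(study$cohorts[[nm]]$beta, study$cohorts[[nm]]$samples,
               test_cfg, cohort = nm))
  names(diff) <- names(study$cohorts)

  cons <- probe_consensus(diff, required_cohorts)
  groups <- assign_groups(cons, study$manifest, study$expr_status)

  dense_diff <- diff[[config$matched_cohort]]
  only <- filter_only_groups(groups, dense_diff, study$manifest)

  ranked <- list()
  for (grp in c("UPUP", "UPDOWN")) {
    n_only <- sum(only$group == grp & only$category == "only")
    if (n_only > 0) {
      ranked[[grp]] <- rank_genes(dense_diff, study$manifest, only,
                                  group = grp, k = min(rank_k, n_only))
    }
  }

  correlation <- list()
  context <- list()
  for (grp in c("UPUP", "UPDOWN")) {
    only_genes <- only$gene[only$group == grp & only$category == "only"]
    if (!length(only_genes)) next
    hyper_probes <- dense_diff$probe_id[dense_diff$call == "HYPER"]
    correlation[[grp]] <- correlate_group(
      study$cohorts[[config$matched_cohort]]$beta, study$expr,
      study$manifest, only_genes, probes = hyper_probes)
    dist <- tss_distances(study$manifest, study$models, genes = only_genes,
                          probes = hyper_probes)
    context[[grp]] <- list(
      distances = dist,
      windows = window_counts(dist),
      histogram = bin_distances(dist, dense_diff, fc_split = fc_split),
      upstream_fraction = mean(dist$nearest_d < 0),
      cgi = cgi_summary(study$manifest, only_genes, probes = hyper_probes),
      regions = region_fractions(study$manifest, dense_diff, study$models,
                                 only_genes))
  }

  memb <- strsplit(groups$memberships, ",", fixed = TRUE)
  group_counts <- vapply(membership_levels, function(l)
    sum(vapply(memb, function(m) l %in% m, logical(1))), integer(1))
  summary <- list(
    seed = config$seed,
    n_genes = config$n_genes,
    n_probes_dense = nrow(study$truth$probes),
    n_probes_consensus_input = nrow(cons),
    n_consensus_hyper = sum(cons$consensus == "HYPER"),
    n_consensus_hypo = sum(cons$consensus == "HYPO"),
    group_counts = as.list(group_counts),
    n_inconsistent = sum(groups$inconsistent),
    only_counts = lapply(c(UPUP = "UPUP", UPDOWN = "UPDOWN"), function(g)
      as.list(table(factor(only$category[only$group == g],
                           levels = c("only", "excluded_hypo",
                                      "excluded_no_hyper", "no_dense_probe"))))),
    elapsed_sec = NA_real_)

  res <- structure(list(study = study, diff = diff, consensus = cons,
                        groups = groups, only = only, ranked = ranked,
                        correlation = correlation, context = context,
                        summary = summary),
                   class = "methexpr_run")
  if (!is.null(outdir)) write_run(res, outdir)
  res$summary$elapsed_sec <- proc.time()[["elapsed"]] - t0
  res
}

# Write every stage table of a run; tables are timestamp-free so reruns with
# the same seed are byte-identical.
write_run <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$diff)) {
    write_tsv(res$diff[[nm]], file.path(outdir, paste0("diffmeth_", nm, ".tsv")))
  }
  write_tsv(res$consensus, file.path(outdir, "consensus.tsv"))
  write_tsv(res$groups, file.path(outdir, "groups.tsv"))
  write_tsv(res$only, file.path(outdir, "only_groups.tsv"))
  for (grp in names(res$ranked)) {
    write_tsv(res$ranked[[grp]],
              file.path(outdir, paste0("top_genes_", grp, ".tsv")))
  }
  for (grp in names(res$correlation)) {
    write_tsv(res$correlation[[grp]]$records,
              file.path(outdir, paste0("correlation_records_", grp, ".tsv")))
    write_tsv(res$correlation[[grp]]$summary,
              file.path(outdir, paste0("correlation_bins_", grp, ".tsv")))
  }
  for (grp in names(res$context)) {
    ctx <- res$context[[grp]]
    write_tsv(ctx$windows, file.path(outdir, paste0("tss_windows_", grp, ".tsv")))
    write_tsv(ctx$histogram, file.path(outdir, paste0("tss_histogram_", grp, ".tsv")))
    write_tsv(ctx$cgi$per_relation, file.path(outdir, paste0("cgi_", grp, ".tsv")))
    write_tsv(ctx$regions, file.path(outdir, paste0("region_fractions_", grp, ".tsv")))
  }
  jsonlite::write_json(res$summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.methexpr_run <- function(x, ...) {
  s <- x$summary
  cat("methexpr pipeline run (seed ", s$seed, ")\n", sep = "")
  cat("  probes: ", s$n_probes_consensus_input, " tested across cohorts; ",
      s$n_consensus_hyper, " consensus HYPER, ",
      s$n_consensus_hypo, " consensus HYPO\n", sep = "")
  cat("  regulation groups: ",
      paste(sprintf("%s=%d", names(s$group_counts), unlist(s$group_counts)),
            collapse = ", "),
      " (", s$n_inconsistent, " inconsistent)\n", sep = "")
  for (g in names(s$only_counts)) {
    oc <- s$only_counts[[g]]
    cat("  ", g, ": ", sum(unlist(oc)), " -> ", oc$only, " ", g, "-only",
        " (", oc$excluded_hypo, " with a hypomethylated probe, ",
        oc$excluded_no_hyper, " without a hypermethylated probe, ",
        oc$no_dense_probe, " without dense probes)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.methexpr_run <- function(object, ...) object$summary
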