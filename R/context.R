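#' TSS windows and distance bins
#'
#' `tss_windows()` returns the symmetric window half-widths (bp) used for
#' counting probes surrounding the TSS; `distance_bin_breaks()` the
#' boundaries of the signed-distance histogram bins, half-open `[lo, hi)`,
#' partitioning the whole line from below -1500 to beyond +2000.
#'
#' @return Numeric vector of window sizes / bin boundaries.
#' @export
tss_windows <- function() c(50, 100, 200, 300, 400, 500, 1000, 1500, 2000)

#' @rdname tss_windows
#' @export
distance_bin_breaks <- function() {
  c(-1500, -1000, -500, -400, -300, -200, -100, -50, 0,
    50, 100, 200, 300, 400, 500, 1000, 1500, 2000)
}

distance_bin_labels <- function() {
  br <- distance_bin_breaks()
  c(paste0("(-Inf,", br[1], ")"),
    paste0("[", br[-length(br)], ",", br[-1], ")"),
    paste0("[", br[length(br)], ",Inf)"))
}

#' Signed probe-to-TSS distances
#'
#' For every (probe, gene) association, computes the strand-aware signed
#' offset of the probe position to each TSS of the gene (positive =
#' downstream of the TSS in transcription direction, negative = upstream; a
#' probe exactly at the TSS has d = 0, counted downstream). The nearest
#' distance minimises |offset|, ties resolved to the upstream (negative)
#' offset. Window membership is evaluated against ANY TSS of the gene:
#' a pair is in window w when some TSS offset satisfies |d| <= w, so
#' membership is monotone in w. Probe/gene chromosome mismatches yield no
#' distance and are reported in the \code{"skipped"} attribute.
#'
#' @param annotation Manifest with probe positions.
#' @param models Gene models ([read_gene_models_bed12()]).
#' @param genes Gene symbols to analyse (default: all annotated genes with a
#'   model).
#' @param probes Optional probe-id subset.
#' @return Data frame with columns \code{probe_id}, \code{gene},
#'   \code{nearest_d} (signed bp), \code{n_tss}, and logical
#'   \code{win_<w>} columns for each window of [tss_windows()].
#' @export
tss_distances <- function(annotation, models, genes = NULL, probes = NULL) {
  map <- probe_gene_map(annotation)
  if (!is.null(genes)) map <- map[map$gene %in% genes, , drop = FALSE]
  if (!is.null(probes)) map <- map[map$probe_id %in% probes, , drop = FALSE]
  map <- map[map$gene %in% names(models$by_gene), , drop = FALSE]
  pos <- annotation$pos[match(map$probe_id, annotation$probe_id)]
  chrom <- annotation$chrom[match(map$probe_id, annotation$probe_id)]
  wins <- tss_windows()
  n <- nrow(map)
  nearest <- rep(NA_real_, n)
  n_tss <- integer(n)
  winm <- matrix(FALSE, n, length(wins),
                 dimnames = list(NULL, paste0("win_", wins)))
  skipped <- logical(n)
  for (i in seq_len(n)) {
    idx <- models$by_gene[[map$gene[i]]]
    tx1 <- models$transcripts[[idx[1]]]
    if (tx1$chrom != chrom[i]) { skipped[i] <- TRUE; next }
    tsss <- gene_tss(models, map$gene[i])
    n_tss[i] <- length(tsss)
    d <- if (tx1$strand == "+") pos[i] - tsss else tsss - pos[i]
    best <- abs(d) == min(abs(d))
    cand <- d[best]
    nearest[i] <- if (any(cand < 0)) min(cand) else cand[1]
    winm[i, ] <- vapply(wins, function(w) any(abs(d) <= w), logical(1))
  }
  out <- data.frame(probe_id = map$probe_id, gene = map$gene,
                    nearest_d = nearest, n_tss = n_tss,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(winm))
  out <- out[!skipped, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- map$probe_id[skipped]
  out
}

#' Count probes and genes per TSS window
#'
#' @param distances Output of [tss_distances()].
#' @return Data frame \code{window}, \code{n_probes} ((probe, gene) pairs in
#'   the window), \code{n_genes} (distinct genes with such a pair).
#' @export
window_counts <- function(distances) {
  wins <- tss_windows()
  data.frame(window = wins,
             n_probes = vapply(wins, function(w)
               sum(distances[[paste0("win_", w)]]), integer(1)),
             n_genes = vapply(wins, function(w)
               length(unique(distances$gene[distances[[paste0("win_", w)]]])),
               integer(1)))
}

#' Histogram of nearest-TSS distances split by fold-change magnitude
#'
#' Assigns each (probe, gene) pair's nearest signed TSS distance to exactly
#' one half-open distance bin and counts pairs with high (|delta-beta| >=
#' `fc_split`) versus low fold change.
#'
#' @param distances Output of [tss_distances()].
#' @param diff [run_cohort()] result supplying each probe's delta-beta.
#' @param fc_split Fold-change magnitude threshold separating high from low
#'   (default 0.2, the conventional beta-scale cut; high fold changes range
#'   up to 0.5).
#' @return Data frame \code{bin}, \code{high_count}, \code{low_count}.
#' @export
bin_distances <- function(distances, diff, fc_split = 0.2) {
  delta <- diff$delta_beta[match(distances$probe_id, diff$probe_id)]
  ok <- !is.na(distances$nearest_d) & !is.na(delta)
  d <- distances$nearest_d[ok]
  high <- abs(delta[ok]) >= fc_split
  idx <- findInterval(d, distance_bin_breaks()) + 1L  # 1 = (-Inf, -1500)
  labs <- distance_bin_labels()
  f <- factor(labs[idx], levels = labs)
  data.frame(bin = labs,
             high_count = as.integer(table(f[high])),
             low_count = as.integer(table(f[!high])),
             stringsAsFactors = FALSE)
}

#' CpG-island context summary
#'
#' Counts (probe, gene) pairs and distinct genes per CGI relation (Island,
#' N/S shore, N/S shelf, None), pools shores and shelves across their N/S
#' sides, and reports the fraction of genes having at least one probe in any
#' of island, shore or shelf.
#'
#' @param annotation Manifest carrying \code{cgi_relation}.
#' @param genes Gene symbols of the set to summarise.
#' @param probes Optional probe-id subset (e.g. hypermethylated probes only).
#' @return List with \code{per_relation} (six levels), \code{pooled}
#'   (island / shore / shelf / None) and \code{any_gene_fraction}.
#' @export
cgi_summary <- function(annotation, genes, probes = NULL) {
  map <- probe_gene_map(annotation)
  map <- map[map$gene %in% genes, , drop = FALSE]
  if (!is.null(probes)) map <- map[map$probe_id %in% probes, , drop = FALSE]
  rel <- annotation$cgi_relation[match(map$probe_id, annotation$probe_id)]
  per <- data.frame(cgi_relation = cgi_levels,
                    n_probes = vapply(cgi_levels, function(l)
                      sum(rel == l), integer(1)),
                    n_genes = vapply(cgi_levels, function(l)
                      length(unique(map$gene[rel == l])), integer(1)),
                    stringsAsFactors = FALSE)
  pooled_of <- c(Island = "island", N_Shore = "shore", S_Shore = "shore",
                 N_Shelf = "shelf", S_Shelf = "shelf", None = "None")
  pooled_levels <- c("island", "shore", "shelf", "None")
  prel <- pooled_of[rel]
  pooled <- data.frame(region = pooled_levels,
                       n_probes = vapply(pooled_levels, function(l)
                         sum(prel == l), integer(1)),
                       n_genes = vapply(pooled_levels, function(l)
                         length(unique(map$gene[prel == l])), integer(1)),
                       stringsAsFactors = FALSE)
  genes_present <- unique(map$gene)
  any_genes <- unique(map$gene[rel != "None"])
  frac <- if (length(genes_present)) length(any_genes) / length(genes_present) else NA_real_
  rownames(per) <- rownames(pooled) <- NULL
  list(per_relation = per, pooled = pooled, any_gene_fraction = frac)
}

#' Gene-region overlap fractions
#'
#' Overlaps each probe position with the gene-region geometry of its
#' ASSOCIATED gene (union of intervals over the gene's transcripts): 3'UTR,
#' 5'UTR, coding exons, exons, introns. Probes are split by their dense
#' differential call into hypermethylated (HYPER) and non-differentially
#' methylated (NS); HYPO probes are not tabulated. A probe may count in
#' several region types. Fractions use all pairs of the given status as
#' denominator. For first exon / first coding exon / first intron the
#' denominator is instead the pairs overlapping any exon / coding exon /
#' intron, and a probe is "first" when it lies in the strand-aware first
#' such region of ANY transcript.
#'
#' @param annotation Manifest with probe positions.
#' @param diff [run_cohort()] table supplying per-probe calls.
#' @param models Gene models.
#' @param genes Gene symbols of the set.
#' @return Data frame with columns \code{region}, \code{status} (hyper /
#'   nondiff), \code{count}, \code{denominator}, \code{fraction}; the three
#'   first-region rows use the any-region counts as denominator. Genes
#'   without a model are skipped (attribute \code{n_skipped_pairs}).
#' @export
region_fractions <- function(annotation, diff, models, genes) {
  map <- probe_gene_map(annotation)
  map <- map[map$gene %in% genes, , drop = FALSE]
  map$call <- diff$call[match(map$probe_id, diff$probe_id)]
  map <- map[!is.na(map$call) & map$call %in% c("HYPER", "NS"), , drop = FALSE]
  has_model <- map$gene %in% names(models$by_gene)
  n_skipped <- sum(!has_model)
  map <- map[has_model, , drop = FALSE]
  pos <- annotation$pos[match(map$probe_id, annotation$probe_id)]
  status <- ifelse(map$call == "HYPER", "hyper", "nondiff")
  in_region <- matrix(FALSE, nrow(map), length(region_types),
                      dimnames = list(NULL, region_types))
  in_first <- matrix(FALSE, nrow(map), length(first_region_of),
                     dimnames = list(NULL, unname(first_region_of)))
  for (g in unique(map$gene)) {
    sel <- which(map$gene == g)
    for (rt in region_types) {
      ivls <- gene_region_union(models, g, rt)
      in_region[sel, rt] <- point_in_ivls(pos[sel], ivls)
    }
    for (rt in names(first_region_of)) {
      fr <- first_region_of[[rt]]
      ivls <- gene_first_intervals(models, g, fr)
      in_first[sel, fr] <- point_in_ivls(pos[sel], ivls)
    }
  }
  rows <- list()
  pretty <- c(utr3 = "3'UTR", utr5 = "5'UTR", coding_exons = "coding exons",
              exons = "exons", introns = "introns")
  for (st in c("hyper", "nondiff")) {
    sel <- status == st
    denom <- sum(sel)
    for (rt in region_types) {
      cnt <- sum(in_region[sel, rt])
      rows[[paste(st, rt)]] <- data.frame(
        region = pretty[[rt]], status = st, count = cnt, denominator = denom,
        fraction = if (denom > 0) cnt / denom else NA_real_)
    }
    for (rt in names(first_region_of)) {
      fr <- first_region_of[[rt]]
      denom_f <- sum(in_region[sel, rt])
      cnt <- sum(in_first[sel, fr] & in_region[sel, rt])
      rows[[paste(st, fr)]] <- data.frame(
        region = gsub("_", " ", fr), status = st, count = cnt,
        denominator = denom_f,
        fraction = if (denom_f > 0) cnt / denom_f else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped_pairs") <- n_skipped
  out
}
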