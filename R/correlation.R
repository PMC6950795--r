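#' Correlation bin labels
#'
#' The eleven named methylation-expression correlation groups, ordered from
#' "very strong negative" through "no correlation" to "very strong positive".
#' On the magnitude scale the boundaries are 0.1, 0.2, 0.4 and 0.5: |r| in
#' (0, 0.1] is very weak, (0.1, 0.2] weak, (0.2, 0.4] intermediate,
#' (0.4, 0.5] strong and (0.5, 1] very strong; r = 0 is its own
#' "no correlation" bin. Bins are half-open on |r| with the boundary
#' belonging to the weaker-magnitude bin (|r| = 0.4 is intermediate,
#' |r| = 0.5 is strong).
#'
#' @return Character vector of the 11 ordered labels.
#' @export
correlation_bin_levels <- function() {
  mags <- c("very strong", "strong", "intermediate", "weak", "very weak")
  c(paste(mags, "negative"), "no correlation", paste(rev(mags), "positive"))
}

#' Bin Pearson correlations into the 11 named groups
#'
#' @param r Numeric vector of correlation values in \[-1, 1\]; values beyond
#'   1 in magnitude by more than 1e-12 are an error, within tolerance they
#'   are clamped.
#' @return Factor with the levels of [correlation_bin_levels()]; NA in, NA
#'   out.
#' @examples
#' bin_correlation(c(0.3, -0.45, 0))
#' @export
bin_correlation <- function(r) {
  bad <- !is.na(r) & abs(r) > 1 + 1e-12
  if (any(bad)) stop_data("correlation magnitude above 1: ", r[which(bad)[1]])
  r <- pmin(pmax(r, -1), 1)
  mags <- c("very weak", "weak", "intermediate", "strong", "very strong")
  idx <- findInterval(abs(r), c(0, 0.1, 0.2, 0.4, 0.5), left.open = TRUE)
  lab <- ifelse(is.na(r), NA_character_,
         ifelse(r == 0, "no correlation",
                paste(mags[pmax(idx, 1)], ifelse(r > 0, "positive", "negative"))))
  factor(lab, levels = correlation_bin_levels())
}

#' Correlate probe methylation with gene expression on matched samples
#'
#' For every (probe, gene) association of the given gene set, computes the
#' Pearson correlation between the probe's beta-value profile and the gene's
#' expression profile across the samples shared by both matrices (pooled
#' cancer and normal), then bins it into the 11 named correlation groups.
#' Correlations are undefined (and excluded from the summary percentages)
#' when fewer than three complete pairs remain or either profile is
#' constant.
#'
#' @param meth Probes-by-samples beta matrix.
#' @param expr Genes-by-samples expression matrix.
#' @param annotation Manifest mapping probes to genes.
#' @param genes Gene symbols to analyse.
#' @param probes Optional probe-id subset (e.g. only significantly
#'   hypermethylated probes); default: all probes of the gene set.
#' @return List with \code{records} (probe, gene, r, n, bin, defined) and
#'   \code{summary} (per-bin probe counts, percentage of defined records and
#'   distinct gene counts).
#' @export
correlate_group <- function(meth, expr, annotation, genes, probes = NULL) {
  shared <- intersect(colnames(meth), colnames(expr))
  if (!length(shared)) stop_data("no shared samples between methylation and expression")
  map <- probe_gene_map(annotation)
  map <- map[map$gene %in% genes & map$probe_id %in% rownames(meth) &
               map$gene %in% rownames(expr), , drop = FALSE]
  if (!is.null(probes)) map <- map[map$probe_id %in% probes, , drop = FALSE]
  n_rec <- nrow(map)
  r <- n <- numeric(n_rec)
  defined <- logical(n_rec)
  M <- meth[, shared, drop = FALSE]
  E <- expr[, shared, drop = FALSE]
  for (i in seq_len(n_rec)) {
    x <- M[map$probe_id[i], ]
    y <- E[map$gene[i], ]
    ok <- !is.na(x) & !is.na(y)
    n[i] <- sum(ok)
    if (n[i] >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      r[i] <- stats::cor(x[ok], y[ok])
      defined[i] <- TRUE
    } else {
      r[i] <- NA_real_
    }
  }
  records <- data.frame(probe_id = map$probe_id, gene = map$gene, r = r,
                        n = n, bin = bin_correlation(r), defined = defined,
                        stringsAsFactors = FALSE)
  def <- records[records$defined, , drop = FALSE]
  counts <- table(factor(def$bin, levels = correlation_bin_levels()))
  gene_counts <- vapply(correlation_bin_levels(), function(b) {
    length(unique(def$gene[as.character(def$bin) == b]))
  }, integer(1))
  summary <- data.frame(bin = correlation_bin_levels(),
                        n_probes = as.integer(counts),
                        pct_probes = if (nrow(def)) 100 * as.integer(counts) / nrow(def) else rep(NA_real_, 11),
                        n_genes = unname(gene_counts),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
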