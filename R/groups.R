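#' Cross-cohort probe consensus
#'
#' A probe reaches HYPER (HYPO) consensus when it is testable in every
#' required cohort and called HYPER (HYPO) in all of them; any other pattern
#' - a disagreeing call, an NS call, or missing/untestable in a required
#' cohort - yields NONE. The mean delta-beta is averaged over all cohorts in
#' which the probe was testable.
#'
#' @param results_by_cohort Named list of [run_cohort()] result tables.
#' @param required_cohorts Cohort names required for consensus (default: all
#'   names of `results_by_cohort`).
#' @return Data frame with columns \code{probe_id}, \code{consensus} (HYPER /
#'   HYPO / NONE), \code{mean_delta_beta}, \code{n_testable}, plus per-cohort
#'   \code{call.<cohort>} and \code{delta.<cohort>} columns.
#' @export
probe_consensus <- function(results_by_cohort,
                            required_cohorts = names(results_by_cohort)) {
  if (!length(results_by_cohort)) stop_data("need at least one cohort result table")
  if (is.null(names(results_by_cohort)) || any(!nzchar(names(results_by_cohort)))) {
    stop_data("results_by_cohort must be a named list")
  }
  miss <- setdiff(required_cohorts, names(results_by_cohort))
  if (length(miss)) stop_data("required cohort(s) without results: ",
                              paste(miss, collapse = ", "))
  probes <- sort(unique(unlist(lapply(results_by_cohort, `[[`, "probe_id"))))
  if (!length(probes)) {
    warning("no probes in any cohort result", call. = FALSE)
  }
  calls <- matrix(NA_character_, length(probes), length(results_by_cohort),
                  dimnames = list(probes, names(results_by_cohort)))
  deltas <- matrix(NA_real_, length(probes), length(results_by_cohort),
                   dimnames = list(probes, names(results_by_cohort)))
  for (nm in names(results_by_cohort)) {
    tab <- results_by_cohort[[nm]]
    idx <- match(tab$probe_id, probes)
    calls[idx, nm] <- tab$call
    deltas[idx, nm] <- tab$delta_beta
  }
  req_calls <- calls[, required_cohorts, drop = FALSE]
  all_hyper <- rowSums(req_calls == "HYPER", na.rm = TRUE) == length(required_cohorts) &
    rowSums(is.na(req_calls)) == 0
  all_hypo <- rowSums(req_calls == "HYPO", na.rm = TRUE) == length(required_cohorts) &
    rowSums(is.na(req_calls)) == 0
  consensus <- ifelse(all_hyper, "HYPER", ifelse(all_hypo, "HYPO", "NONE"))
  n_testable <- rowSums(!is.na(calls))
  mean_delta <- rowMeans(deltas, na.rm = TRUE)
  mean_delta[n_testable == 0] <- NA_real_
  out <- data.frame(probe_id = probes, consensus = unname(consensus),
                    mean_delta_beta = unname(mean_delta),
                    n_testable = unname(n_testable),
                    stringsAsFactors = FALSE)
  for (nm in names(results_by_cohort)) {
    out[[paste0("call.", nm)]] <- unname(calls[, nm])
    out[[paste0("delta.", nm)]] <- unname(deltas[, nm])
  }
  attr(out, "required_cohorts") <- required_cohorts
  out
}

membership_levels <- c("UPUP", "UPDOWN", "DOWNUP", "DOWNDOWN")

#' Assign genes to regulation-pattern groups
#'
#' Crosses each gene's methylation consensus status with its expression
#' status. A gene is methylation-UP when it has at least one HYPER-consensus
#' probe and no HYPO-consensus probe, DOWN in the mirror case, BOTH when it
#' has probes of both consensus directions (flagged inconsistent), and NONE
#' otherwise. Group membership crosses direction with expression: UPUP =
#' methylation gain with upregulated expression, UPDOWN = gain with
#' downregulation, DOWNUP / DOWNDOWN the hypomethylated counterparts. BOTH
#' genes join both direction-compatible groups. Genes with expression status
#' NS, or without an expression record, receive no membership.
#'
#' @param consensus Output of [probe_consensus()].
#' @param annotation Manifest (see [read_manifest()]) mapping probes to genes.
#' @param expr Expression status table (see [read_expression_status()]).
#' @return Data frame with one row per gene having at least one mapped probe
#'   in the consensus: \code{gene}, \code{meth_status} (UP / DOWN / BOTH /
#'   NONE), \code{expr_status}, \code{memberships} (comma-separated),
#'   \code{inconsistent}, \code{avg_delta_beta} (mean delta-beta over all
#'   mapped testable (probe, cohort) pairs), \code{n_hyper}, \code{n_hypo},
#'   \code{n_nondiff} probe tallies. Attribute \code{n_no_expression} counts
#'   genes with probes but no expression record.
#' @export
assign_groups <- function(consensus, annotation, expr) {
  map <- probe_gene_map(annotation)
  map <- map[map$probe_id %in% consensus$probe_id, , drop = FALSE]
  cons <- consensus$consensus[match(map$probe_id, consensus$probe_id)]
  genes <- sort(unique(map$gene))
  n_hyper <- tapply(cons == "HYPER", map$gene, sum)[genes]
  n_hypo <- tapply(cons == "HYPO", map$gene, sum)[genes]
  n_nondiff <- tapply(cons == "NONE", map$gene, sum)[genes]
  meth_status <- ifelse(n_hyper > 0 & n_hypo > 0, "BOTH",
                 ifelse(n_hyper > 0, "UP",
                 ifelse(n_hypo > 0, "DOWN", "NONE")))
  expr_status <- expr$status[match(genes, expr$gene)]
  avg <- average_gene_fold_change(consensus, annotation)
  memberships <- character(length(genes))
  for (i in seq_along(genes)) {
    m <- character(0)
    if (!is.na(expr_status[i]) && expr_status[i] != "NS") {
      up_m <- meth_status[i] %in% c("UP", "BOTH")
      down_m <- meth_status[i] %in% c("DOWN", "BOTH")
      if (up_m && expr_status[i] == "UP") m <- c(m, "UPUP")
      if (up_m && expr_status[i] == "DOWN") m <- c(m, "UPDOWN")
      if (down_m && expr_status[i] == "UP") m <- c(m, "DOWNUP")
      if (down_m && expr_status[i] == "DOWN") m <- c(m, "DOWNDOWN")
    }
    memberships[i] <- paste(m, collapse = ",")
  }
  out <- data.frame(gene = genes,
                    meth_status = unname(meth_status),
                    expr_status = unname(expr_status),
                    memberships = memberships,
                    inconsistent = unname(meth_status == "BOTH"),
                    avg_delta_beta = unname(avg$avg_delta_beta[match(genes, avg$gene)]),
                    n_hyper = unname(n_hyper), n_hypo = unname(n_hypo),
                    n_nondiff = unname(n_nondiff),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_no_expression") <- sum(is.na(expr_status))
  out
}

# Genes carrying a given membership label.
genes_in_group <- function(groups, label) {
  groups$gene[vapply(strsplit(groups$memberships, ",", fixed = TRUE),
                     function(m) label %in% m, logical(1))]
}

#' Gene-level average methylation fold change
#'
#' Unweighted mean of the per-(probe, cohort) delta-beta values over all
#' mapped probes that were testable, significant or not - the gene-level
#' "average methylation fold change" used for fold-change rankings.
#'
#' @param consensus Output of [probe_consensus()] (carries the per-cohort
#'   delta-beta columns).
#' @param annotation Manifest mapping probes to genes.
#' @return Data frame with columns \code{gene}, \code{avg_delta_beta},
#'   \code{n_pairs}; genes without any testable mapped probe are absent.
#' @export
average_gene_fold_change <- function(consensus, annotation) {
  map <- probe_gene_map(annotation)
  map <- map[map$probe_id %in% consensus$probe_id, , drop = FALSE]
  delta_cols <- grep("^delta\\.", colnames(consensus), value = TRUE)
  dmat <- as.matrix(consensus[match(map$probe_id, consensus$probe_id),
                              delta_cols, drop = FALSE])
  sums <- rowSums(dmat, na.rm = TRUE)
  counts <- rowSums(!is.na(dmat))
  tot <- tapply(sums, map$gene, sum)
  n <- tapply(counts, map$gene, sum)
  genes <- sort(names(tot))
  out <- data.frame(gene = genes,
                    avg_delta_beta = unname(tot[genes] / n[genes]),
                    n_pairs = unname(n[genes]), stringsAsFactors = FALSE)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine groups on the dense manifest ("-only" filtering)
#'
#' For each gene of a regulation group, tallies its dense-manifest probes by
#' their differential call in a single dense cohort. A gene stays in the
#' "-only" group when it has at least one significantly hypermethylated dense
#' probe and no significantly hypomethylated one (i.e. only hypermethylated
#' or non-differentially methylated probes); genes with any HYPO dense probe
#' are excluded, as are genes with no HYPER probe or with no testable dense
#' probe at all, each in its own category so the partition accounting
#' (#only + #excluded_hypo + #excluded_no_hyper + #no_dense_probe = #group)
#' holds exactly.
#'
#' @param groups Output of [assign_groups()].
#' @param dense_results [run_cohort()] table for the dense cohort.
#' @param annotation Manifest with \code{in_dense} flags.
#' @param directions Group labels to refine (default UPUP and UPDOWN; the
#'   hypomethylated groups are symmetric and can be requested explicitly).
#' @return Data frame with one row per (gene, group): \code{gene},
#'   \code{group}, \code{category} (\code{only}, \code{excluded_hypo},
#'   \code{excluded_no_hyper}, \code{no_dense_probe}), dense tallies
#'   \code{n_dense_hyper}, \code{n_dense_hypo}, \code{n_dense_nondiff},
#'   \code{n_dense}, and \code{frac_hyper} = hyper / all dense probes.
#' @export
filter_only_groups <- function(groups, dense_results, annotation,
                               directions = c("UPUP", "UPDOWN")) {
  map <- probe_gene_map(annotation)
  dense_probes <- annotation$probe_id[annotation$in_dense]
  map <- map[map$probe_id %in% dense_probes, , drop = FALSE]
  map$call <- dense_results$call[match(map$probe_id, dense_results$probe_id)]
  map <- map[!is.na(map$call), , drop = FALSE]  # untestable dense probes drop out
  rows <- list()
  for (grp in directions) {
    genes <- genes_in_group(groups, grp)
    if (!length(genes)) next
    sub <- map[map$gene %in% genes, , drop = FALSE]
    n_hyper <- tapply(sub$call == "HYPER", sub$gene, sum)
    n_hypo <- tapply(sub$call == "HYPO", sub$gene, sum)
    n_ns <- tapply(sub$call == "NS", sub$gene, sum)
    hy <- ifelse(is.na(n_hyper[genes]), 0, n_hyper[genes])
    ho <- ifelse(is.na(n_hypo[genes]), 0, n_hypo[genes])
    ns <- ifelse(is.na(n_ns[genes]), 0, n_ns[genes])
    tot <- hy + ho + ns
    category <- ifelse(tot == 0, "no_dense_probe",
                ifelse(ho > 0, "excluded_hypo",
                ifelse(hy == 0, "excluded_no_hyper", "only")))
    rows[[grp]] <- data.frame(gene = genes, group = grp,
                              category = unname(category),
                              n_dense_hyper = unname(hy),
                              n_dense_hypo = unname(ho),
                              n_dense_nondiff = unname(ns),
                              n_dense = unname(tot),
                              frac_hyper = unname(ifelse(tot > 0, hy / tot, NA_real_)),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), group = character(),
                      category = character(), n_dense_hyper = integer(),
                      n_dense_hypo = integer(), n_dense_nondiff = integer(),
                      n_dense = integer(), frac_hyper = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Rank "-only" genes by average hypermethylation significance
#'
#' For each gene in the requested "-only" group, averages the raw p-values of
#' its significantly hypermethylated dense probes and returns the `k` genes
#' with the smallest mean p (most significantly hypermethylated), ties broken
#' lexicographically by gene symbol for reproducibility.
#'
#' @param dense_results [run_cohort()] table for the dense cohort.
#' @param annotation Manifest with \code{in_dense} flags.
#' @param only_table Output of [filter_only_groups()].
#' @param group Group label to rank within (default `"UPUP"`).
#' @param k Number of genes to return (default 10).
#' @return Data frame \code{gene}, \code{mean_p}, \code{n_hyper_probes},
#'   ordered ascending by \code{mean_p}.
#' @export
rank_genes <- function(dense_results, annotation, only_table, group = "UPUP",
                       k = 10) {
  genes <- only_table$gene[only_table$group == group &
                             only_table$category == "only"]
  if (!length(genes)) stop_data("no '", group, "' -only genes to rank")
  map <- probe_gene_map(annotation)
  map <- map[map$gene %in% genes &
               map$probe_id %in% annotation$probe_id[annotation$in_dense], ,
             drop = FALSE]
  idx <- match(map$probe_id, dense_results$probe_id)
  map$call <- dense_results$call[idx]
  map$p <- dense_results$p_value[idx]
  map <- map[!is.na(map$call) & map$call == "HYPER", , drop = FALSE]
  mean_p <- tapply(map$p, map$gene, mean)
  n_probes <- tapply(map$p, map$gene, length)
  out <- data.frame(gene = names(mean_p), mean_p = unname(mean_p),
                    n_hyper_probes = unname(n_probes), stringsAsFactors = FALSE)
  out <- out[order(out$mean_p, out$gene), , drop = FALSE]
  if (k > nrow(out)) {
    warning("k = ", k, " exceeds group size ", nrow(out), "; returning all",
            call. = FALSE)
    k <- nrow(out)
  }
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}
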