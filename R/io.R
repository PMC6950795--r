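#' Read a beta-value matrix
#'
#' Reads a probes-by-samples TSV of methylation beta values (fractions in
#' \[0,1\]). The first column holds probe identifiers; the header holds sample
#' identifiers. Empty cells and \code{"NA"} become missing values. Every
#' column must be described by the sample sheet.
#'
#' @param path Path to the TSV file.
#' @param sample_sheet Data frame with columns \code{sample_id},
#'   \code{condition} (\code{"cancer"} or \code{"normal"}) and \code{cohort};
#'   see [read_sample_sheet()].
#' @return Numeric matrix with probe-id rownames and sample-id colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\ts1\ts2", "cg01\t0.5\t0.7", "cg02\tNA\t0.1"), tf)
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     condition = c("cancer", "normal"), cohort = "demo")
#' read_beta_matrix(tf, sheet)
#' @export
read_beta_matrix <- function(path, sample_sheet) {
  df <- read_tsv(path, colClasses = "character")
  if (ncol(df) < 2) stop_data("beta matrix must have a probe-id column and >=1 sample column")
  probes <- df[[1]]
  if (anyDuplicated(probes)) {
    stop_data("duplicate probe id(s): ",
              paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  missing_sheet <- setdiff(samples, sample_sheet$sample_id)
  if (length(missing_sheet)) {
    stop_data("sample column(s) without sample-sheet entry: ",
              paste(missing_sheet, collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
                dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad_parse <- !is.na(df[[j + 1]]) & is.na(v)
    if (any(bad_parse)) {
      stop_data("non-numeric beta value for probe ", probes[which(bad_parse)[1]],
                ", sample ", samples[j])
    }
    out_of_range <- !is.na(v) & (v < 0 | v > 1)
    if (any(out_of_range)) {
      stop_data("beta value outside [0,1] for probe ",
                probes[which(out_of_range)[1]], ", sample ", samples[j])
    }
    mat[, j] <- v
  }
  mat
}

#' Write a beta-value matrix
#'
#' @param mat Numeric probes-by-samples matrix with dimnames.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_beta_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Read or write a sample sheet
#'
#' A sample sheet maps each sample id to its condition (\code{cancer} or
#' \code{normal}) and cohort name.
#'
#' @param path TSV path with columns \code{sample_id}, \code{condition},
#'   \code{cohort}.
#' @return Data frame with those three character columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  req <- c("sample_id", "condition", "cohort")
  if (!all(req %in% colnames(df))) {
    stop_data("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop_data("duplicate sample id in sample sheet")
  bad <- setdiff(unique(df$condition), c("cancer", "normal"))
  if (length(bad)) stop_data("unknown condition(s): ", paste(bad, collapse = ", "))
  df[req]
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) write_tsv(sheet, path)

cgi_levels <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "None")

#' Read an Illumina-style probe manifest
#'
#' Parses a CSV with columns \code{probe_id}, \code{chrom}, \code{pos}
#' (1-based coordinate as in Illumina manifests), \code{gene_symbols} and
#' \code{region_tags} (semicolon-separated, parallel lists),
#' \code{cgi_relation} (one of Island, N_Shore, S_Shore, N_Shelf, S_Shelf,
#' None; empty maps to None) and optional logical columns \code{in_sparse}
#' and \code{in_dense} flagging platform membership (27k-like sparse vs
#' 450k-like dense). When the length of the gene and region lists disagree a
#' warning is raised and tags are paired best-effort.
#'
#' @param path CSV path.
#' @return Data frame of class \code{methexpr_manifest}, one row per probe.
#' @seealso [probe_gene_map()] for the expanded per-association table.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA"))
  req <- c("probe_id", "chrom", "pos", "gene_symbols", "region_tags",
           "cgi_relation")
  if (!all(req %in% colnames(df))) {
    stop_data("manifest must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) stop_data("duplicate probe id in manifest")
  pos <- suppressWarnings(as.numeric(df$pos))
  if (any(is.na(pos) | pos < 1 | pos != floor(pos))) {
    stop_data("malformed position for probe ",
              df$probe_id[which(is.na(pos) | pos < 1 | pos != floor(pos))[1]])
  }
  df$pos <- as.integer(pos)
  df$gene_symbols[is.na(df$gene_symbols)] <- ""
  df$region_tags[is.na(df$region_tags)] <- ""
  df$cgi_relation[is.na(df$cgi_relation) | df$cgi_relation == ""] <- "None"
  bad <- setdiff(unique(df$cgi_relation), cgi_levels)
  if (length(bad)) stop_data("unknown CGI relation(s): ", paste(bad, collapse = ", "))
  if (!"in_sparse" %in% colnames(df)) df$in_sparse <- FALSE
  if (!"in_dense" %in% colnames(df)) df$in_dense <- TRUE
  df$in_sparse <- as.logical(df$in_sparse)
  df$in_dense <- as.logical(df$in_dense)
  class(df) <- c("methexpr_manifest", "data.frame")
  df
}

#' Write a probe manifest CSV
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand a manifest into per-(probe, gene) associations
#'
#' Each probe row may list several genes separated by semicolons; this
#' expands to one row per distinct (probe, gene) pair (duplicated symbols
#' within one probe are collapsed), carrying along the paired manifest region
#' tag where available. Probes with an empty gene field contribute no rows.
#'
#' @param manifest Manifest from [read_manifest()].
#' @return Data frame with columns \code{probe_id}, \code{gene},
#'   \code{region_tag}.
#' @export
probe_gene_map <- function(manifest) {
  genes <- strsplit(manifest$gene_symbols, ";", fixed = TRUE)
  tags <- strsplit(manifest$region_tags, ";", fixed = TRUE)
  rows <- vector("list", nrow(manifest))
  warned <- FALSE
  for (i in seq_len(nrow(manifest))) {
    g <- genes[[i]][nzchar(genes[[i]])]
    if (!length(g)) next
    tg <- tags[[i]]
    if (length(tg) != length(genes[[i]]) && length(tg) > 0 && !warned) {
      warning("gene/region tag lists differ in length for probe ",
              manifest$probe_id[i], "; pairing best-effort", call. = FALSE)
      warned <- TRUE
    }
    tg <- rep_len(if (length(tg)) tg else NA_character_, length(genes[[i]]))
    tg <- tg[nzchar(genes[[i]])]
    keep <- !duplicated(g)
    rows[[i]] <- data.frame(probe_id = manifest$probe_id[i], gene = g[keep],
                            region_tag = tg[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(probe_id = character(), gene = character(),
                      region_tag = character())
  }
  rownames(out) <- NULL
  out
}

#' Read or write a gene expression status table
#'
#' The table gives, per gene symbol, a log2 fold change, a p-value and a
#' status call in \code{UP}, \code{DOWN}, \code{NS} (the shape of a
#' meta-analysis differential-expression result consumed as input).
#'
#' @param path TSV path with columns \code{gene}, \code{logFC}, \code{p},
#'   \code{status}.
#' @return Data frame with those columns.
#' @export
read_expression_status <- function(path) {
  df <- read_tsv(path)
  req <- c("gene", "logFC", "p", "status")
  if (!all(req %in% colnames(df))) {
    stop_data("expression status table must have columns: ",
              paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(df$status), c("UP", "DOWN", "NS"))
  if (length(bad)) stop_data("unknown expression status: ", paste(bad, collapse = ", "))
  if (any(df$status == "UP" & df$logFC <= 0) ||
      any(df$status == "DOWN" & df$logFC >= 0)) {
    stop_data("expression status inconsistent with logFC sign")
  }
  df[req]
}

#' @rdname read_expression_status
#' @param tab Expression status data frame.
#' @export
write_expression_status <- function(tab, path) write_tsv(tab, path)
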