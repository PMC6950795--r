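#' Read gene models from a BED12 file
#'
#' Imports BED12 transcripts (via \pkg{rtracklayer}) and derives, per
#' transcript, the interval geometry used for probe characterisation: exons,
#' introns, coding exons, 5'/3' UTRs (all 1-based closed, as in
#' Bioconductor), the strand-aware transcription start site and the
#' strand-aware first exon / first coding exon / first intron. The BED name
#' field is taken as the gene symbol; a gene may have several transcripts and
#' therefore several TSSs. Records whose block arithmetic is inconsistent
#' with the record end are dropped with a warning.
#'
#' @param path BED12 file path.
#' @return Object of class \code{gene_models}: a list with element
#'   \code{transcripts} (list of per-transcript geometries) and
#'   \code{by_gene} (gene symbol to transcript indices).
#' @export
read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  txs <- vector("list", length(gr))
  keep <- rep(TRUE, length(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  thick <- gr$thick
  blocks <- gr$blocks
  for (i in seq_along(gr)) {
    b <- blocks[[i]]
    ex <- cbind(starts[i] - 1L + S4Vectors::start(b),
                starts[i] - 1L + S4Vectors::end(b))
    if (max(ex[, 2]) != ends[i] || min(ex[, 1]) != starts[i]) {
      warning("dropping BED12 record ", gr$name[i],
              ": block arithmetic inconsistent with record span", call. = FALSE)
      keep[i] <- FALSE
      next
    }
    cds <- c(S4Vectors::start(thick)[i], S4Vectors::end(thick)[i])
    if (cds[2] < cds[1]) cds <- NULL  # zero-width thick: non-coding
    txs[[i]] <- build_transcript(gene = gr$name[i], chrom = chroms[i],
                                 strand = strands[i], exons = ex, cds = cds)
  }
  txs <- txs[keep]
  new_gene_models(txs)
}

# Assemble a gene_models object from a list of transcripts.
new_gene_models <- function(transcripts) {
  genes <- vapply(transcripts, function(t) t$gene, character(1))
  by_gene <- split(seq_along(transcripts), genes)
  structure(list(transcripts = transcripts, by_gene = by_gene),
            class = "gene_models")
}

# Derive the per-transcript geometry from exons (2-col 1-based closed
# matrix, sorted ascending) and an optional coding span c(start, end).
build_transcript <- function(gene, chrom, strand, exons, cds = NULL) {
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    stop_data("overlapping exons in transcript of gene ", gene)
  }
  n <- nrow(exons)
  introns <- if (n > 1) {
    cbind(exons[-n, 2] + 1, exons[-1, 1] - 1)
  } else matrix(numeric(0), ncol = 2)
  tx_start <- exons[1, 1]
  tx_end <- exons[n, 2]
  tss <- if (strand == "+") tx_start else tx_end
  coding_exons <- utr5 <- utr3 <- matrix(numeric(0), ncol = 2)
  if (!is.null(cds)) {
    coding_exons <- ivl_intersect1(exons, cds[1], cds[2])
    left_utr <- ivl_intersect1(exons, tx_start, cds[1] - 1)
    right_utr <- ivl_intersect1(exons, cds[2] + 1, tx_end)
    if (strand == "+") {
      utr5 <- left_utr; utr3 <- right_utr
    } else {
      utr5 <- right_utr; utr3 <- left_utr
    }
  }
  # strand-aware ordinals: genomic-leftmost is first on +, last on -
  first_exon <- if (strand == "+") exons[1, , drop = FALSE] else exons[n, , drop = FALSE]
  first_intron <- if (nrow(introns)) {
    if (strand == "+") introns[1, , drop = FALSE] else introns[nrow(introns), , drop = FALSE]
  } else matrix(numeric(0), ncol = 2)
  first_coding_exon <- if (nrow(coding_exons)) {
    if (strand == "+") coding_exons[1, , drop = FALSE] else coding_exons[nrow(coding_exons), , drop = FALSE]
  } else matrix(numeric(0), ncol = 2)
  list(gene = gene, chrom = chrom, strand = strand,
       tx_start = tx_start, tx_end = tx_end, tss = tss,
       exons = exons, introns = introns, cds = cds,
       coding_exons = coding_exons, utr5 = utr5, utr3 = utr3,
       first_exon = first_exon, first_intron = first_intron,
       first_coding_exon = first_coding_exon)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x$transcripts), "transcript(s),",
      length(x$by_gene), "gene(s)\n")
  invisible(x)
}

#' Transcription start sites of a gene
#'
#' @param models A \code{gene_models} object.
#' @param gene Gene symbol.
#' @return Sorted unique vector of 1-based TSS coordinates (empty if the gene
#'   has no model).
#' @export
gene_tss <- function(models, gene) {
  idx <- models$by_gene[[gene]]
  if (is.null(idx)) return(numeric(0))
  sort(unique(vapply(models$transcripts[idx], function(t) t$tss, numeric(1))))
}

region_types <- c("utr3", "utr5", "coding_exons", "exons", "introns")
first_region_of <- c(coding_exons = "first_coding_exon", exons = "first_exon",
                     introns = "first_intron")

# Union of a region type's intervals over all transcripts of a gene.
gene_region_union <- function(models, gene, region) {
  idx <- models$by_gene[[gene]]
  if (is.null(idx)) return(matrix(numeric(0), ncol = 2))
  parts <- lapply(models$transcripts[idx], function(t) t[[region]])
  ivl_union(do.call(rbind, parts))
}

# Per-transcript "first" intervals of a gene (a probe is first-X if it lies
# in the first X of ANY transcript).
gene_first_intervals <- function(models, gene, first_region) {
  idx <- models$by_gene[[gene]]
  if (is.null(idx)) return(matrix(numeric(0), ncol = 2))
  parts <- lapply(models$transcripts[idx], function(t) t[[first_region]])
  m <- do.call(rbind, parts)
  if (is.null(m)) matrix(numeric(0), ncol = 2) else m
}

#' Write gene models as BED12
#'
#' @param models A \code{gene_models} object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  lines <- vapply(models$transcripts, function(t) {
    n <- nrow(t$exons)
    chrom_start <- t$tx_start - 1  # BED is 0-based half-open
    sizes <- t$exons[, 2] - t$exons[, 1] + 1
    offs <- t$exons[, 1] - t$tx_start
    thick <- if (is.null(t$cds)) c(chrom_start, chrom_start) else c(t$cds[1] - 1, t$cds[2])
    paste(t$chrom, chrom_start, t$tx_end, t$gene, 0, t$strand,
          thick[1], thick[2], 0, n,
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
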