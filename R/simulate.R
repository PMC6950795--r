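#' Simulation configuration
#'
#' Describes a synthetic multi-cohort methylation/expression study with
#' planted regulation-group structure. Defaults emulate the published study
#' design this generator stands in for: three cohorts with the cohort sizes
#' of the real series (95/86 and 73/63 cancer/normal on top of a 503/50
#' cohort whose 497/35 matched subset carries expression), a sparse
#' promoter-focused manifest inside a dense one, beta-scale effect sizes of
#' 0.2 and probes scattered within +/-2000 bp of the TSS.
#'
#' @param seed Master RNG seed; every derived stream is a deterministic
#'   function of it.
#' @param n_genes Number of genes.
#' @param probes_per_gene_sparse Probes per gene on the sparse (27k-like)
#'   manifest.
#' @param probes_per_gene_dense Probes per gene on the dense (450k-like)
#'   manifest; must be >= the sparse count.
#' @param cohorts Data frame with columns \code{name}, \code{n_cancer},
#'   \code{n_normal}, \code{platform} (\code{"sparse"} or \code{"dense"}).
#' @param group_fractions Named fractions over \code{UPUP}, \code{UPDOWN},
#'   \code{DOWNUP}, \code{DOWNDOWN}, \code{NULL} summing to 1.
#' @param delta_beta_effect Planted methylation effect in beta units, in
#'   (0, 0.5].
#' @param beta_noise_sd Within-group noise standard deviation on the logit
#'   scale.
#' @param expr_coupling Absolute Pearson correlation in \[0, 1) targeted
#'   between a coupled gene's mean probe methylation and its expression.
#' @param frac_inconsistent Fraction of non-NULL genes given exactly one
#'   opposite-direction probe (planted among the dense-only probes when the
#'   dense manifest is larger, so the ambiguity surfaces on the dense
#'   expansion).
#' @param tss_span Probes are placed uniformly within +/- `tss_span` bp of
#'   the gene TSS.
#' @param baseline_shapes List of two Beta-distribution shape pairs for the
#'   bimodal baseline methylation mixture (defaults Beta(2,10) and
#'   Beta(10,2), mimicking the characteristic two-mode array beta
#'   distribution).
#' @param matched_cohort Cohort whose samples carry matched expression
#'   (default: the last dense cohort).
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 500,
                       probes_per_gene_sparse = 2,
                       probes_per_gene_dense = 16,
                       cohorts = data.frame(
                         name = c("cohortA", "cohortB", "cohortC"),
                         n_cancer = c(95, 73, 497),
                         n_normal = c(86, 63, 35),
                         platform = c("sparse", "dense", "dense"),
                         stringsAsFactors = FALSE),
                       group_fractions = c(UPUP = 0.15, UPDOWN = 0.30,
                                           DOWNUP = 0.05, DOWNDOWN = 0.10,
                                           "NULL" = 0.40),
                       delta_beta_effect = 0.2,
                       beta_noise_sd = 0.4,
                       expr_coupling = 0.5,
                       frac_inconsistent = 0.02,
                       tss_span = 2000,
                       baseline_shapes = list(c(2, 10), c(10, 2)),
                       matched_cohort = NULL) {
  labels <- c("UPUP", "UPDOWN", "DOWNUP", "DOWNDOWN", "NULL")
  if (!all(labels %in% names(group_fractions))) {
    stop_config("group_fractions must name ", paste(labels, collapse = ", "))
  }
  group_fractions <- group_fractions[labels]
  if (abs(sum(group_fractions) - 1) > 1e-9) {
    stop_config("group_fractions must sum to 1")
  }
  if (any(group_fractions < 0)) stop_config("group_fractions must be non-negative")
  if (delta_beta_effect <= 0 || delta_beta_effect > 0.5) {
    stop_config("delta_beta_effect must be in (0, 0.5]")
  }
  if (probes_per_gene_dense < probes_per_gene_sparse) {
    stop_config("probes_per_gene_dense must be >= probes_per_gene_sparse")
  }
  if (n_genes < 1 || probes_per_gene_sparse < 1) {
    stop_config("counts must be >= 1")
  }
  if (expr_coupling < 0 || expr_coupling >= 1) {
    stop_config("expr_coupling must be in [0, 1)")
  }
  if (frac_inconsistent < 0 || frac_inconsistent > 1) {
    stop_config("frac_inconsistent must be in [0, 1]")
  }
  if (anyDuplicated(cohorts$name)) stop_config("cohort names must be unique")
  if (!all(cohorts$platform %in% c("sparse", "dense"))) {
    stop_config("cohort platform must be 'sparse' or 'dense'")
  }
  if (is.null(matched_cohort)) {
    dense <- cohorts$name[cohorts$platform == "dense"]
    matched_cohort <- if (length(dense)) dense[length(dense)] else
      cohorts$name[nrow(cohorts)]
  }
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 probes_per_gene_sparse = probes_per_gene_sparse,
                 probes_per_gene_dense = probes_per_gene_dense,
                 cohorts = cohorts, group_fractions = group_fractions,
                 delta_beta_effect = delta_beta_effect,
                 beta_noise_sd = beta_noise_sd,
                 expr_coupling = expr_coupling,
                 frac_inconsistent = frac_inconsistent,
                 tss_span = tss_span, baseline_shapes = baseline_shapes,
                 matched_cohort = matched_cohort),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,",
      x$probes_per_gene_dense, "dense /", x$probes_per_gene_sparse,
      "sparse probes per gene,", nrow(x$cohorts), "cohort(s)\n")
  cat("  planted delta-beta:", x$delta_beta_effect,
      " coupling:", x$expr_coupling, " seed:", x$seed, "\n")
  invisible(x)
}

#' Plant the ground truth of a synthetic study
#'
#' Draws a regulation-group label per gene from the configured fractions,
#' gives each probe of a non-NULL gene the group's methylation direction
#' (HYPER for UPUP/UPDOWN, HYPO for DOWNUP/DOWNDOWN) with the configured
#' delta-beta, leaves NULL genes' probes at zero effect, and flips exactly
#' one probe of a `frac_inconsistent` share of non-NULL genes to the
#' opposite direction (preferring a dense-only probe). Baseline methylation
#' per probe is drawn from the bimodal Beta mixture and shared by all
#' cohorts.
#'
#' @param config A [sim_config()].
#' @return List of class \code{truth_table} with \code{genes} (gene, group,
#'   expr_status), \code{probes} (probe_id, gene, direction, planted_delta,
#'   baseline, in_sparse, in_dense).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "truth"))
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  labels <- names(config$group_fractions)
  group <- sample(labels, config$n_genes, replace = TRUE,
                  prob = config$group_fractions)
  expr_status <- c(UPUP = "UP", UPDOWN = "DOWN", DOWNUP = "UP",
                   DOWNDOWN = "DOWN", "NULL" = "NS")[group]
  ppg <- config$probes_per_gene_dense
  probe_gene <- rep(genes, each = ppg)
  probe_rank <- rep(seq_len(ppg), times = config$n_genes)
  probes <- sprintf("cg%07d", seq_along(probe_gene))
  dir_of <- c(UPUP = "HYPER", UPDOWN = "HYPER", DOWNUP = "HYPO",
              DOWNDOWN = "HYPO", "NULL" = "NONE")
  direction <- dir_of[rep(group, each = ppg)]
  in_sparse <- probe_rank <= config$probes_per_gene_sparse
  non_null <- which(group != "NULL")
  n_inc <- round(config$frac_inconsistent * length(non_null))
  inconsistent_genes <- if (n_inc > 0) {
    sort(sample(non_null, n_inc))
  } else integer(0)
  for (gi in inconsistent_genes) {
    idx <- which(probe_gene == genes[gi])
    # prefer a dense-only probe so the ambiguity appears on the dense manifest
    cand <- idx[!in_sparse[idx]]
    flip <- if (length(cand)) cand[length(cand)] else idx[length(idx)]
    direction[flip] <- ifelse(direction[flip] == "HYPER", "HYPO", "HYPER")
  }
  planted_delta <- ifelse(direction == "HYPER", config$delta_beta_effect,
                   ifelse(direction == "HYPO", -config$delta_beta_effect, 0))
  comp <- sample.int(2, length(probes), replace = TRUE)
  sh <- config$baseline_shapes
  baseline <- stats::rbeta(length(probes),
                           ifelse(comp == 1, sh[[1]][1], sh[[2]][1]),
                           ifelse(comp == 1, sh[[1]][2], sh[[2]][2]))
  # keep baselines off the clip boundaries so a planted delta always moves
  # the group mean (worst case a ~2.3 logit-unit shift after clipping)
  baseline <- clamp_beta(baseline, 0.01, 0.99)
  structure(list(
    genes = data.frame(gene = genes, group = group,
                       expr_status = unname(expr_status),
                       stringsAsFactors = FALSE),
    probes = data.frame(probe_id = probes, gene = probe_gene,
                        direction = unname(direction),
                        planted_delta = unname(planted_delta),
                        baseline = baseline,
                        in_sparse = in_sparse, in_dense = TRUE,
                        stringsAsFactors = FALSE)),
    class = "truth_table")
}

#' Synthetic probe manifest and gene models
#'
#' Places each gene on a chromosome with a strand and a primary TSS, scatters
#' its probes uniformly within the configured span of the TSS, samples a CGI
#' relation per probe, assigns an Illumina-style region tag from the TSS
#' offset (carried but not used for region geometry), and builds one or two
#' transcripts per gene (a 20% share gets an alternative-TSS transcript)
#' with three exons and a coding span.
#'
#' @param config A [sim_config()].
#' @param truth Output of [generate_truth()].
#' @return List with \code{manifest} (see [read_manifest()]) and
#'   \code{models} (a \code{gene_models} object).
#' @export
generate_annotation <- function(config, truth) {
  set.seed(derive_seed(config$seed, "annotation"))
  genes <- truth$genes$gene
  n <- length(genes)
  chrom <- paste0("chr", ((seq_len(n) - 1) %% 22) + 1)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # space genes 1 Mb apart along each chromosome
  tss <- 100000 + ((seq_len(n) - 1) %/% 22) * 1000000 +
    sample.int(1000, n, replace = TRUE)
  gene_tab <- data.frame(gene = genes, chrom = chrom, strand = strand,
                         tss = tss, stringsAsFactors = FALSE)
  # transcripts: 3 exons downstream of the TSS; 20% get a second transcript
  # whose TSS sits 600 bp further downstream
  txs <- list()
  alt <- stats::runif(n) < 0.2
  exon_lens <- c(300, 200, 500)
  intron_lens <- c(800, 1200)
  for (i in seq_len(n)) {
    for (shift in if (alt[i]) c(0, 600) else 0) {
      if (strand[i] == "+") {
        s1 <- tss[i] + shift
        e_starts <- s1 + c(0, exon_lens[1] + intron_lens[1],
                           exon_lens[1] + intron_lens[1] + exon_lens[2] + intron_lens[2])
        exons <- cbind(e_starts, e_starts + exon_lens - 1)
        cds <- c(s1 + 150, exons[3, 1] + 250)
      } else {
        e1 <- tss[i] - shift
        e_ends <- e1 - c(0, exon_lens[1] + intron_lens[1],
                         exon_lens[1] + intron_lens[1] + exon_lens[2] + intron_lens[2])
        exons <- cbind(e_ends - exon_lens + 1, e_ends)
        exons <- exons[order(exons[, 1]), , drop = FALSE]
        cds <- c(exons[1, 1] + 250, e1 - 150)
      }
      txs[[length(txs) + 1]] <- build_transcript(
        gene = genes[i], chrom = chrom[i], strand = strand[i],
        exons = exons, cds = cds)
    }
  }
  models <- new_gene_models(txs)
  # probes scattered around the primary TSS
  pr <- truth$probes
  gi <- match(pr$gene, genes)
  offset <- sample.int(2 * config$tss_span + 1, nrow(pr), replace = TRUE) -
    config$tss_span - 1
  pos <- pmax(tss[gi] + offset, 1)
  cgi <- sample(cgi_levels, nrow(pr), replace = TRUE,
                prob = c(0.35, 0.12, 0.12, 0.06, 0.06, 0.29))
  signed <- ifelse(strand[gi] == "+", pos - tss[gi], tss[gi] - pos)
  tag <- ifelse(abs(signed) <= 200 & signed <= 0, "TSS200",
         ifelse(abs(signed) <= 1500 & signed <= 0, "TSS1500", "Body"))
  manifest <- data.frame(probe_id = pr$probe_id, chrom = chrom[gi], pos = pos,
                         gene_symbols = pr$gene, region_tags = tag,
                         cgi_relation = cgi, in_sparse = pr$in_sparse,
                         in_dense = pr$in_dense, stringsAsFactors = FALSE)
  class(manifest) <- c("methexpr_manifest", "data.frame")
  list(manifest = manifest, models = models, gene_tab = gene_tab)
}

#' Simulate one cohort's beta matrix
#'
#' Draws beta values for every probe and sample of a cohort. The group mean
#' for normals is the probe baseline; cancer samples get the planted
#' delta-beta applied to the baseline (clipped to \[0.001, 0.999\]) and both
#' means are perturbed with Gaussian noise on the logit scale, keeping
#' values inside the unit interval before a final clip. Sparse-platform
#' cohorts expose only the sparse probe subset. Each cohort draws from its
#' own RNG stream derived from the master seed and the cohort name, so
#' cohorts are stable under reordering.
#'
#' @param config A [sim_config()].
#' @param truth Output of [generate_truth()].
#' @param cohort_name Name of a configured cohort.
#' @return List with \code{beta} (probes-by-samples matrix) and
#'   \code{samples} (sample sheet).
#' @export
generate_cohort <- function(config, truth, cohort_name) {
  row <- which(config$cohorts$name == cohort_name)
  if (!length(row)) stop_config("unknown cohort: ", cohort_name)
  set.seed(derive_seed(config$seed, paste0("cohort:", cohort_name)))
  pr <- truth$probes
  if (config$cohorts$platform[row] == "sparse") {
    pr <- pr[pr$in_sparse, , drop = FALSE]
  }
  n_c <- config$cohorts$n_cancer[row]
  n_n <- config$cohorts$n_normal[row]
  ids_c <- sprintf("%s_C%04d", cohort_name, seq_len(n_c))
  ids_n <- sprintf("%s_N%04d", cohort_name, seq_len(n_n))
  mu_normal <- stats::qlogis(pr$baseline)
  mu_cancer <- stats::qlogis(clamp_beta(pr$baseline + pr$planted_delta))
  np <- nrow(pr)
  noise <- matrix(stats::rnorm(np * (n_c + n_n), sd = config$beta_noise_sd),
                  nrow = np)
  logits <- cbind(mu_cancer + noise[, seq_len(n_c), drop = FALSE],
                  mu_normal + noise[, n_c + seq_len(n_n), drop = FALSE])
  beta <- clamp_beta(stats::plogis(logits))
  dimnames(beta) <- list(pr$probe_id, c(ids_c, ids_n))
  samples <- data.frame(sample_id = c(ids_c, ids_n),
                        condition = rep(c("cancer", "normal"), c(n_c, n_n)),
                        cohort = cohort_name, stringsAsFactors = FALSE)
  list(beta = beta, samples = samples)
}

#' Simulate matched gene expression
#'
#' Builds, for the matched cohort's samples, a gene-by-sample expression
#' matrix on a continuous log2-like scale: expression = baseline + sign *
#' slope * (mean dense-probe methylation of the gene in that sample) +
#' Gaussian noise, with sign +1 for UPUP/DOWNDOWN genes, -1 for
#' UPDOWN/DOWNUP and 0 for NULL. The slope is calibrated per gene against
#' the empirical spread of its mean methylation so the population |Pearson
#' r| between methylation and expression approximates `expr_coupling`. Also
#' returns the gene-level expression status table implied by the planted
#' labels.
#'
#' @param config A [sim_config()].
#' @param truth Output of [generate_truth()].
#' @param cohort Output of [generate_cohort()] for the matched cohort.
#' @return List with \code{expr} (genes-by-samples matrix) and \code{status}
#'   (gene, logFC, p, status).
#' @export
generate_expression <- function(config, truth, cohort) {
  set.seed(derive_seed(config$seed, "expression"))
  beta <- cohort$beta
  pr <- truth$probes[truth$probes$probe_id %in% rownames(beta), , drop = FALSE]
  genes <- truth$genes$gene
  n_s <- ncol(beta)
  # per-gene mean methylation per sample
  gsplit <- split(pr$probe_id, pr$gene)
  meanmeth <- t(vapply(genes, function(g) {
    colMeans(beta[gsplit[[g]], , drop = FALSE])
  }, numeric(n_s)))
  sign_of <- c(UPUP = 1, DOWNDOWN = 1, UPDOWN = -1, DOWNUP = -1, "NULL" = 0)
  sgn <- sign_of[truth$genes$group]
  sd_e <- 1
  sd_m <- apply(meanmeth, 1, stats::sd)
  rho <- config$expr_coupling
  slope <- ifelse(sd_m > 0 & sgn != 0 & rho > 0,
                  rho / sqrt(1 - rho^2) * sd_e / sd_m, 0)
  base_expr <- stats::rnorm(length(genes), mean = 8, sd = 2)
  noise <- matrix(stats::rnorm(length(genes) * n_s, sd = sd_e),
                  nrow = length(genes))
  expr <- base_expr + sgn * slope * meanmeth + noise
  dimnames(expr) <- list(genes, colnames(beta))
  status <- truth$genes$expr_status
  logfc <- ifelse(status == "UP", abs(stats::rnorm(length(genes), 1.5, 0.5)),
           ifelse(status == "DOWN", -abs(stats::rnorm(length(genes), 1.5, 0.5)),
                  stats::rnorm(length(genes), 0, 0.05)))
  p <- ifelse(status == "NS", stats::runif(length(genes), 0.2, 1),
              stats::runif(length(genes), 0, 1e-4))
  list(expr = expr,
       status = data.frame(gene = genes, logFC = logfc, p = p,
                           status = status, stringsAsFactors = FALSE))
}

#' Simulate a complete study
#'
#' Runs [generate_truth()], [generate_annotation()], [generate_cohort()] for
#' every configured cohort and [generate_expression()] for the matched
#' cohort, optionally writing every artifact (beta matrices, sample sheets,
#' manifest CSV, BED12 gene models, expression TSVs, truth JSON) to a
#' directory.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @return List with \code{truth}, \code{manifest}, \code{models},
#'   \code{cohorts} (named list of beta/samples), \code{expr},
#'   \code{expr_status}, \code{config}.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL) {
  truth <- generate_truth(config)
  ann <- generate_annotation(config, truth)
  cohorts <- lapply(config$cohorts$name, function(nm)
    generate_cohort(config, truth, nm))
  names(cohorts) <- config$cohorts$name
  ex <- generate_expression(config, truth, cohorts[[config$matched_cohort]])
  out <- list(truth = truth, manifest = ann$manifest, models = ann$models,
              cohorts = cohorts, expr = ex$expr, expr_status = ex$status,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(cohorts)) {
      write_beta_matrix(cohorts[[nm]]$beta,
                        file.path(outdir, paste0("beta_", nm, ".tsv")))
      write_sample_sheet(cohorts[[nm]]$samples,
                         file.path(outdir, paste0("samples_", nm, ".tsv")))
    }
    write_manifest(ann$manifest, file.path(outdir, "manifest.csv"))
    write_gene_models_bed12(ann$models, file.path(outdir, "gene_models.bed"))
    write_tsv(data.frame(gene = rownames(ex$expr),
                         as.data.frame(ex$expr), check.names = FALSE),
              file.path(outdir, "expression.tsv"))
    write_expression_status(ex$status, file.path(outdir, "expression_status.tsv"))
    jsonlite::write_json(list(genes = truth$genes, probes = truth$probes),
                         file.path(outdir, "truth.json"), dataframe = "columns",
                         digits = NA)
  }
  out
}
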