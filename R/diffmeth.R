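#' Differential-methylation test configuration
#'
#' @param alpha Significance threshold on the (by default raw) p-value;
#'   probes with p below `alpha` and a positive (negative) beta-value
#'   difference are called HYPER (HYPO).
#' @param test `"welch"` (default, unequal-variance two-sample t) or
#'   `"pooled"` (pooled-variance t).
#' @param adjust `"none"` (default; the threshold applies to raw p-values) or
#'   `"BH"` for Benjamini-Hochberg adjustment across a cohort's testable
#'   probes, in which case `alpha` applies to the adjusted values.
#' @return A list of class \code{test_config}.
#' @export
test_config <- function(alpha = 0.05, test = c("welch", "pooled"),
                        adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_config("alpha must be a single number in (0,1)")
  }
  structure(list(alpha = alpha, test = test, adjust = adjust),
            class = "test_config")
}

# Vectorised two-sample t over matrix rows. X1, X2: numeric matrices
# (probes x samples), NAs allowed. Returns delta (mean1 - mean2), t, df, p,
# n1, n2. Zero variance in both groups => t NA, p 1 (logged by callers).
row_two_sample_t <- function(X1, X2, test = "welch") {
  n1 <- rowSums(!is.na(X1))
  n2 <- rowSums(!is.na(X2))
  m1 <- rowSums(X1, na.rm = TRUE) / n1
  m2 <- rowSums(X2, na.rm = TRUE) / n2
  v1 <- rowSums((X1 - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2, na.rm = TRUE) / (n2 - 1)
  delta <- m1 - m2
  if (test == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  tstat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  tstat[degenerate] <- NA_real_
  p[degenerate] <- 1
  list(delta = delta, t = tstat, df = df, p = p, n1 = n1, n2 = n2,
       degenerate = degenerate)
}

#' Test a single probe for differential methylation
#'
#' Two-sample test (Welch by default) of cancer versus normal beta values.
#' The effect size is the delta-beta: mean(cancer) - mean(normal), in beta
#' units (the beta-scale "methylation fold change"). Probes with fewer than
#' three non-missing values in either group are untestable (not NS) and are
#' excluded from cross-cohort consensus.
#'
#' @param values_cancer,values_normal Numeric beta-value vectors, NAs allowed.
#' @param config A [test_config()].
#' @param probe_id,cohort Optional identifiers carried into the result.
#' @return One-row data frame with columns \code{probe_id}, \code{cohort},
#'   \code{delta_beta}, \code{t}, \code{p_value}, \code{call} (HYPER / HYPO /
#'   NS), \code{testable}, \code{n_cancer}, \code{n_normal}.
#' @examples
#' test_probe(c(0.80, 0.82, 0.78, 0.81), c(0.50, 0.52, 0.49, 0.51))
#' @export
test_probe <- function(values_cancer, values_normal, config = test_config(),
                       probe_id = "probe", cohort = NA_character_) {
  n1 <- sum(!is.na(values_cancer))
  n2 <- sum(!is.na(values_normal))
  if (n1 < 3 || n2 < 3) {
    return(data.frame(probe_id = probe_id, cohort = cohort,
                      delta_beta = NA_real_, t = NA_real_, p_value = NA_real_,
                      call = NA_character_, testable = FALSE,
                      n_cancer = n1, n_normal = n2,
                      stringsAsFactors = FALSE))
  }
  r <- row_two_sample_t(matrix(values_cancer, nrow = 1),
                        matrix(values_normal, nrow = 1), config$test)
  call <- call_from(r$delta, r$p, config$alpha)
  data.frame(probe_id = probe_id, cohort = cohort, delta_beta = r$delta,
             t = r$t, p_value = r$p, call = call, testable = TRUE,
             n_cancer = n1, n_normal = n2, stringsAsFactors = FALSE)
}

call_from <- function(delta, p, alpha) {
  ifelse(p < alpha & delta > 0, "HYPER",
         ifelse(p < alpha & delta < 0, "HYPO", "NS"))
}

#' Per-probe differential methylation across a cohort
#'
#' Runs the configured two-sample test on every row of a beta matrix,
#' splitting columns into cancer and normal by the sample sheet. Probes with
#' fewer than three non-missing values in either condition are excluded and
#' reported in the \code{"untestable"} attribute. With \code{adjust = "BH"}
#' the Benjamini-Hochberg adjustment is computed over all testable probes of
#' the cohort and the HYPER/HYPO threshold applies to the adjusted values.
#'
#' @param mat Probes-by-samples beta matrix (see [read_beta_matrix()]).
#' @param sheet Sample sheet covering the matrix columns.
#' @param config A [test_config()].
#' @param cohort Cohort label stored in the result (default: the sheet's
#'   cohort value).
#' @return Data frame with one row per testable probe: \code{probe_id},
#'   \code{cohort}, \code{delta_beta}, \code{t}, \code{p_value},
#'   \code{adj_p}, \code{call}, \code{n_cancer}, \code{n_normal}. Attribute
#'   \code{untestable} holds excluded probe ids.
#' @export
run_cohort <- function(mat, sheet, config = test_config(), cohort = NULL) {
  miss <- setdiff(colnames(mat), sheet$sample_id)
  if (length(miss)) {
    stop_data("matrix column(s) not in sample sheet: ", paste(miss, collapse = ", "))
  }
  cond <- sheet$condition[match(colnames(mat), sheet$sample_id)]
  cohort <- cohort %||% unique(sheet$cohort[match(colnames(mat), sheet$sample_id)])[1]
  X1 <- mat[, cond == "cancer", drop = FALSE]
  X2 <- mat[, cond == "normal", drop = FALSE]
  if (ncol(X1) < 3 || ncol(X2) < 3) {
    stop_data("cohort ", cohort, " has fewer than 3 samples in a condition")
  }
  r <- row_two_sample_t(X1, X2, config$test)
  testable <- r$n1 >= 3 & r$n2 >= 3
  if (any(r$degenerate & testable)) {
    message(sum(r$degenerate & testable),
            " probe(s) with zero variance in both groups called NS (p = 1)")
  }
  out <- data.frame(probe_id = rownames(mat), cohort = cohort,
                    delta_beta = r$delta, t = r$t, p_value = r$p,
                    adj_p = NA_real_, call = NA_character_,
                    n_cancer = r$n1, n_normal = r$n2,
                    stringsAsFactors = FALSE)[testable, , drop = FALSE]
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  p_for_call <- if (config$adjust == "BH") out$adj_p else out$p_value
  out$call <- call_from(out$delta_beta, p_for_call, config$alpha)
  rownames(out) <- NULL
  untestable <- rownames(mat)[!testable]
  if (length(untestable)) {
    message(length(untestable), " untestable probe(s) excluded in cohort ", cohort)
  }
  attr(out, "untestable") <- untestable
  out
}
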