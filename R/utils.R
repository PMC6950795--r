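# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
clamp_beta <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

# Deterministic per-label RNG seed derived from a master seed; stable under
# reordering of labels and kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(as.character(label))
  h <- sum(as.double(codes) * seq_along(codes) * 131)
  as.integer((abs(as.double(seed)) * 7919 + h * 104729 + 17) %% 2147483629)
}

# TSV writer that round-trips doubles exactly (17 significant digits).
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), ...)
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("methexpr_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("methexpr_config_error", "error")))
}

# Union of 1-based closed intervals given as a 2-column matrix (start, end).
ivl_union <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(numeric(0), ncol = 2))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1] <= out[k, 2] + 1) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  out
}

# Intersect interval matrix a with a single interval c(lo, hi); 1-based closed.
ivl_intersect1 <- function(a, lo, hi) {
  if (is.null(a) || nrow(a) == 0 || hi < lo) return(matrix(numeric(0), ncol = 2))
  s <- pmax(a[, 1], lo)
  e <- pmin(a[, 2], hi)
  keep <- s <= e
  cbind(s[keep], e[keep])
}

# Is each position inside any interval of m (1-based closed)?
point_in_ivls <- function(pos, m) {
  if (is.null(m) || nrow(m) == 0) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= m[, 1] & p <= m[, 2]), logical(1))
}
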