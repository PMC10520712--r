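#' Global Moran's I with randomization inference
#'
#' Computes `I = sum_ij w_ij (x_i - xbar)(x_j - xbar) / (S2 * sum_ij w_ij)`
#' with `S2 = (1/n) sum_i (x_i - xbar)^2`, its expectation `-1/(n-1)` and the
#' variance under the randomization (permutation) assumption, and reports a
#' one-sided upper-tail z/p (the positive-autocorrelation alternative). The
#' matrix is used exactly as given — the statistic self-normalizes by the
#' total weight, so binary adjacency is the natural input; row-standardized
#' input is accepted for cross-checking.
#'
#' @param x numeric vector over regions (not constant, `n >= 3`).
#' @param W a `spatial_weights` object or bare nonnegative matrix with zero
#'   diagonal and positive total weight.
#' @param permutations if > 0, additionally compute an empirical one-sided
#'   p-value from that many random permutations of `x`.
#' @return list of class `moran_test`: `I`, `expected`, `variance`, `z`, `p`,
#'   `n`, and `p_perm` when requested. The randomization variance needs
#'   `n >= 4`; for `n = 3` the statistic is returned with `NA` inference.
#' @export
global_moran <- function(x, W, permutations = 0) {
  w <- as_weights_matrix(W)
  n <- length(x)
  if (n < 3L) stop_gc("need at least 3 regions")
  if (nrow(w) != n || ncol(w) != n) stop_gc("weights dimension does not match x")
  if (any(diag(w) != 0)) stop_gc("weights must have a zero diagonal")
  if (any(w < 0)) stop_gc("weights must be nonnegative")
  S0 <- sum(w)
  if (S0 <= 0) stop_gc("all-zero weights matrix")
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  if (m2 == 0) stop_gc("zero variance: x is constant")
  I <- as.numeric(t(z) %*% w %*% z) / (m2 * S0)
  EI <- -1 / (n - 1)
  if (n >= 4L) {
    S1 <- 0.5 * sum((w + t(w))^2)
    S2 <- sum((rowSums(w) + colSums(w))^2)
    b2 <- (n * sum(z^4)) / (sum(z^2)^2)
    EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
              b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2)
    VI <- EI2 - EI^2
    zscore <- (I - EI) / sqrt(VI)
    p <- stats::pnorm(zscore, lower.tail = FALSE)
  } else {
    VI <- NA_real_; zscore <- NA_real_; p <- NA_real_
    warn_gc("randomization variance undefined for n = 3; returning NA inference")
  }
  out <- list(I = I, expected = EI, variance = VI, z = zscore, p = p, n = n)
  if (permutations > 0) {
    Iperm <- replicate(permutations, {
      zp <- z[sample.int(n)]
      as.numeric(t(zp) %*% w %*% zp) / (m2 * S0)
    })
    out$p_perm <- (1 + sum(Iperm >= I)) / (permutations + 1)
    out$permutations <- permutations
  }
  structure(out, class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), z = %.3f, one-sided p = %.4g, n = %d\n",
              x$I, x$expected, x$z, x$p, x$n))
  if (!is.null(x$p_perm)) {
    cat(sprintf("  permutation p (%d perms) = %.4g\n", x$permutations, x$p_perm))
  }
  invisible(x)
}

#' Local Moran's I with LISA quadrant classification
#'
#' `I_i = ((x_i - xbar) / S2) * sum_j w_ij (x_j - xbar)` per region, with the
#' quadrant read from the signs of the own deviation and the weighted
#' neighbour deviation (spatial lag): HH (high-high), LH, LL, HL. Zero
#' deviations classify as "low" (strict positivity defines "high"). The local
#' values satisfy `sum_i I_i = I_global * sum_ij w_ij`.
#'
#' @inheritParams global_moran
#' @return data.frame of class `local_moran` with columns `region`, `I_i`,
#'   `deviation` (x_i - xbar), `lag` (weighted neighbour deviation),
#'   `quadrant`.
#' @export
local_moran <- function(x, W) {
  w <- as_weights_matrix(W)
  n <- length(x)
  if (n < 3L) stop_gc("need at least 3 regions")
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  if (m2 == 0) stop_gc("zero variance: x is constant")
  lag <- as.vector(w %*% z)
  Ii <- z * lag / m2
  quadrant <- ifelse(z > 0 & lag > 0, "HH",
              ifelse(z <= 0 & lag > 0, "LH",
              ifelse(z <= 0 & lag <= 0, "LL", "HL")))
  structure(data.frame(region = rownames(w) %||% as.character(seq_len(n)),
                       I_i = Ii, deviation = z, lag = lag,
                       quadrant = quadrant, stringsAsFactors = FALSE),
            class = c("local_moran", "data.frame"))
}

#' Yearly global Moran's I over a panel variable
#'
#' One `global_moran` per year; yearly errors (e.g. a constant cross-section)
#' propagate with the offending year in the message.
#'
#' @param panel balanced long data.frame with `region`, `year` and the
#'   variable column.
#' @param variable name of the variable to test.
#' @param W spatial weights (binary adjacency recommended).
#' @param permutations forwarded to [global_moran()].
#' @return data.frame with one row per year: `year`, `I`, `expected`,
#'   `variance`, `z`, `p`.
#' @export
moran_by_year <- function(panel, variable, W, permutations = 0) {
  mats <- panel_matrices(panel, variable,
                         region_order = if (inherits(W, "spatial_weights")) W$region_order else NULL)
  M <- mats[[variable]]
  years <- attr(mats, "years")
  rows <- lapply(seq_along(years), function(t) {
    res <- tryCatch(global_moran(M[, t], W, permutations = permutations),
                    error = function(e) stop_gc("year %s: %s", years[t], conditionMessage(e)))
    data.frame(year = years[t], I = res$I, expected = res$expected,
               variance = res$variance, z = res$z, p = res$p)
  })
  do.call(rbind, rows)
}
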