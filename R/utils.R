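# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
#' @noRd
stop_gc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_gc <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check a long panel (region, year, value columns) is balanced; returns
# region and year orderings.
check_balanced <- function(panel) {
  if (!all(c("region", "year") %in% names(panel))) {
    stop_gc("panel must have 'region' and 'year' columns")
  }
  tab <- table(panel$region, panel$year)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1L, ]
    stop_gc("unbalanced panel: region '%s' x year '%s' appears %d times",
            rownames(tab)[bad[1L]], colnames(tab)[bad[2L]],
            tab[bad[1L], bad[2L]])
  }
  list(regions = rownames(tab), years = colnames(tab))
}

# Extract named n x T matrices (regions ordered as `region_order`) from a
# balanced long panel.
panel_matrices <- function(panel, vars, region_order = NULL) {
  bal <- check_balanced(panel)
  region_order <- region_order %||% bal$regions
  if (!setequal(region_order, bal$regions)) {
    stop_gc("panel regions do not match requested region order")
  }
  years <- sort(unique(panel$year))
  out <- lapply(vars, function(v) {
    if (!v %in% names(panel)) stop_gc("variable '%s' not found in panel", v)
    m <- matrix(NA_real_, nrow = length(region_order), ncol = length(years),
                dimnames = list(region_order, as.character(years)))
    idx <- cbind(match(as.character(panel$region), region_order),
                 match(as.character(panel$year), as.character(years)))
    m[idx] <- panel[[v]]
    if (anyNA(m)) {
      cell <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop_gc("missing value for variable '%s' at region '%s', year %s",
              v, region_order[cell[1L]], years[cell[2L]])
    }
    m
  })
  names(out) <- vars
  structure(out, years = years, regions = region_order)
}

# Moment-matched log-normal parameters for a positive variable.
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Symmetrize then clip eigenvalues at zero to repair a near-PSD matrix.
nearest_psd <- function(V, warn = TRUE) {
  V <- (V + t(V)) / 2
  ee <- eigen(V, symmetric = TRUE)
  if (min(ee$values) < -1e-8 * max(abs(ee$values))) {
    if (warn) warn_gc("covariance matrix not positive semidefinite; eigenvalues clipped at zero")
    V <- ee$vectors %*% (pmax(ee$values, 0) * t(ee$vectors))
    dimnames(V) <- dimnames(ee$vectors)
  }
  V
}

# Draw `n` multivariate normal rows with mean `mu` and covariance `V`.
rmvnorm_psd <- function(n, mu, V) {
  V <- nearest_psd(V, warn = FALSE)
  ee <- eigen(V, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), nrow = length(mu))
  z <- matrix(stats::rnorm(n * length(mu)), nrow = n)
  sweep(z %*% t(L), 2L, mu, "+")
}

# Numerical central-difference Hessian; used only as a cross-check oracle in
# tests, kept internal so both routes live behind one surface.
num_hessian <- function(f, x, h = 1e-5) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  hs <- pmax(abs(x), 1) * h
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- hs[i]; ej[j] <- hs[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hs[i] * hs[j])
    }
  }
  H
}
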