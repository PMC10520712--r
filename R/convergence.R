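#' Development level of one industry
#'
#' Summarizes an industry's region-year development from its two input
#' indicators (employment, fixed-asset investment) and one output indicator
#' (GDP or persons served): all three are treated as positive indicators,
#' min-max standardized over the pooled panel, and aggregated with entropy
#' weights into a single level `U` in \[0, 1\].
#'
#' @param industry_panel long data.frame with columns `region`, `year`,
#'   `industry` and the indicator columns.
#' @param industry label of the industry to score (e.g. `"H0"`).
#' @param indicators indicator column names (default employment, investment,
#'   output).
#' @return data.frame (region, year, U).
#' @export
development_level <- function(industry_panel, industry,
                              indicators = c("employment", "investment", "output")) {
  if (!all(c("region", "year", "industry") %in% names(industry_panel))) {
    stop_gc("industry panel needs region, year and industry columns")
  }
  sub <- industry_panel[industry_panel$industry == industry, , drop = FALSE]
  if (!nrow(sub)) stop_gc("industry '%s' absent from panel", industry)
  missing_cols <- setdiff(indicators, names(sub))
  if (length(missing_cols)) {
    stop_gc("indicator column(s) missing: %s", paste(missing_cols, collapse = ", "))
  }
  if (any(vapply(sub[indicators], function(x) any(x < 0), logical(1L)))) {
    stop_gc("industry indicators must be nonnegative")
  }
  specs <- lapply(indicators, indicator_spec, polarity = "positive")
  std <- standardize_indicators(sub[c("region", "year", indicators)], specs,
                                scope = "pooled")
  w <- entropy_weights(std)
  out <- composite_index(std, w, index_name = "U")
  out[order(out$year, out$region), , drop = FALSE]
}

#' Coupling coordination degree of two subsystems
#'
#' The two-system coupling degree `C = 2*sqrt(U1*U2) / (U1 + U2)` measures how
#' balanced the two development levels are (1 iff equal and positive, 0 when
#' either subsystem is absent); the coordination level `T = alpha*U1 +
#' (1-alpha)*U2` measures the joint level; the coupling coordination degree is
#' `D = sqrt(C*T)`, in \[0, 1\].
#'
#' @param U1,U2 numeric vectors of development levels in \[0, 1\].
#' @param alpha contribution weight of the first subsystem, in \[0, 1\]
#'   (default 0.5, equal contribution).
#' @return numeric vector `D`.
#' @seealso [coupling_components()] for the intermediate `C` and `T`.
#' @export
coupling_coordination <- function(U1, U2, alpha = 0.5) {
  coupling_components(U1, U2, alpha)$D
}

#' @rdname coupling_coordination
#' @return for `coupling_components`, a data.frame with columns `C`, `T`, `D`.
#' @export
coupling_components <- function(U1, U2, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) stop_gc("alpha must lie in [0, 1]")
  tol <- 1e-9
  if (min(U1, U2) < -tol || max(U1, U2) > 1 + tol) {
    stop_gc("development levels must lie in [0, 1]")
  }
  U1 <- clamp(U1, 0, 1); U2 <- clamp(U2, 0, 1)
  s <- U1 + U2
  C <- ifelse(s > 0, 2 * sqrt(U1 * U2) / s, 0)
  Tl <- alpha * U1 + (1 - alpha) * U2
  data.frame(C = C, T = Tl, D = sqrt(C * Tl))
}

#' Synthesize pairwise convergence degrees into one overall degree
#'
#' Treats the per-partner coupling-coordination columns as positive \[0, 1\]
#' indicators. With `method = "entropy"` the partner columns are
#' entropy-weighted (weights from their cross-observation proportions) and the
#' overall degree is the weighted sum of the raw D values, so identical
#' columns synthesize to the common value; with `method = "mean"` partners are
#' averaged equally. If every column is constant the entropy method falls back
#' to equal weights with a warning.
#'
#' @param pairwise long data.frame (region, year, partner, D) or a numeric
#'   matrix with one column per partner.
#' @param method `"entropy"` (default) or `"mean"`.
#' @return list with `hicd` (data.frame region, year, hicd — or plain vector
#'   for matrix input) and `weights` (per-partner synthesis weights, sum 1).
#' @export
synthesize_hicd <- function(pairwise, method = c("entropy", "mean")) {
  method <- match.arg(method)
  if (is.data.frame(pairwise)) {
    needed <- c("region", "year", "partner", "D")
    if (!all(needed %in% names(pairwise))) {
      stop_gc("pairwise data.frame needs columns %s", paste(needed, collapse = ", "))
    }
    partners <- sort(unique(pairwise$partner))
    key <- interaction(pairwise$region, pairwise$year, drop = TRUE)
    Dmat <- matrix(NA_real_, nlevels(key), length(partners),
                   dimnames = list(levels(key), partners))
    Dmat[cbind(as.integer(key), match(pairwise$partner, partners))] <- pairwise$D
    if (anyNA(Dmat)) stop_gc("pairwise block is not balanced over region-year x partner")
    meta <- pairwise[!duplicated(key), c("region", "year")]
    meta <- meta[order(unique(as.integer(key))), , drop = FALSE]
  } else {
    Dmat <- as.matrix(pairwise)
    meta <- NULL
  }
  if (!ncol(Dmat)) stop_gc("empty pairwise block")
  w <- if (ncol(Dmat) == 1L) {
    stats::setNames(1, colnames(Dmat))
  } else if (method == "mean") {
    stats::setNames(rep(1 / ncol(Dmat), ncol(Dmat)), colnames(Dmat))
  } else {
    ew <- tryCatch(entropy_weights(Dmat), error = function(e) NULL)
    if (is.null(ew)) {
      warn_gc("all pairwise-D columns constant; falling back to equal synthesis weights")
      stats::setNames(rep(1 / ncol(Dmat), ncol(Dmat)), colnames(Dmat))
    } else ew$weights
  }
  overall <- as.vector(Dmat %*% w)
  if (is.null(meta)) return(list(hicd = overall, weights = w))
  out <- data.frame(meta, hicd = overall, row.names = NULL)
  list(hicd = out[order(out$year, out$region), , drop = FALSE], weights = w)
}

#' Healthcare-industry convergence degrees for a whole panel
#'
#' Full convergence scoring: computes the development level of the focal
#' industry and of every partner industry separately (entropy-weighted
#' input/output composites), the pairwise coupling-coordination degree
#' `D(H0, Hk)` per region-year, and the synthesized overall degree (HICD).
#'
#' @param industry_panel long data.frame (region, year, industry, employment,
#'   investment, output).
#' @param focal focal industry label (default `"H0"`).
#' @param partners partner labels; default all other industries in the panel.
#' @param alpha contribution weight of the focal industry in `T`.
#' @param synthesis `"entropy"` or `"mean"` synthesis of partner degrees.
#' @param indicators indicator columns used for the development levels.
#' @return object of class `convergence_result`: list with `pairwise` (long
#'   data.frame region, year, partner, D), `hicd` (region, year, hicd),
#'   `development` (region, year, industry, U), `synthesis_weights`, `alpha`,
#'   `synthesis`.
#' @export
convergence_degrees <- function(industry_panel, focal = "H0", partners = NULL,
                                alpha = 0.5, synthesis = c("entropy", "mean"),
                                indicators = c("employment", "investment", "output")) {
  synthesis <- match.arg(synthesis)
  industries <- unique(industry_panel$industry)
  if (!focal %in% industries) stop_gc("focal industry '%s' absent from panel", focal)
  partners <- partners %||% setdiff(sort(industries), focal)
  if (!length(partners)) stop_gc("no partner industries")
  absent <- setdiff(partners, industries)
  if (length(absent)) stop_gc("partner industr(ies) absent: %s", paste(absent, collapse = ", "))
  U <- lapply(c(focal, partners), function(ind) {
    u <- development_level(industry_panel, ind, indicators)
    u$industry <- ind
    u
  })
  names(U) <- c(focal, partners)
  u0 <- U[[focal]]
  pw <- do.call(rbind, lapply(partners, function(p) {
    uk <- U[[p]]
    stopifnot(identical(uk$region, u0$region), identical(uk$year, u0$year))
    data.frame(region = u0$region, year = u0$year, partner = p,
               D = coupling_coordination(u0$U, uk$U, alpha),
               stringsAsFactors = FALSE)
  }))
  syn <- synthesize_hicd(pw, method = synthesis)
  structure(list(pairwise = pw, hicd = syn$hicd,
                 development = do.call(rbind, U),
                 synthesis_weights = syn$weights,
                 alpha = alpha, synthesis = synthesis, focal = focal),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("convergence_result: focal %s vs %d partners, %d region-years\n",
              x$focal, length(x$synthesis_weights), nrow(x$hicd)))
  cat(sprintf("  HICD range: [%.3f, %.3f], synthesis: %s (alpha = %.2f)\n",
              min(x$hicd$hicd), max(x$hicd$hicd), x$synthesis, x$alpha))
  invisible(x)
}

#' Average pairwise convergence by region and partner
#'
#' Region-by-partner table of time-averaged pairwise coupling-coordination
#' degrees (the layout used to report average convergence per province and
#' partner industry).
#'
#' @param cr a `convergence_result`.
#' @return data.frame, one row per region, one column per partner.
#' @export
pairwise_mean_table <- function(cr) {
  stopifnot(inherits(cr, "convergence_result"))
  agg <- stats::aggregate(D ~ region + partner, data = cr$pairwise, FUN = mean)
  partners <- sort(unique(agg$partner))
  regions <- sort(unique(agg$region))
  m <- matrix(NA_real_, length(regions), length(partners),
              dimnames = list(regions, partners))
  m[cbind(match(agg$region, regions), match(agg$partner, partners))] <- agg$D
  data.frame(region = regions, m, check.names = FALSE, row.names = NULL)
}

#' Overall convergence degree time series with totals and ranks
#'
#' Wide region-by-year table of the synthesized convergence degree, plus each
#' region's period mean (`total_hicd`) and its rank (1 = highest).
#'
#' @param cr a `convergence_result`.
#' @return data.frame with one row per region.
#' @export
hicd_table <- function(cr) {
  stopifnot(inherits(cr, "convergence_result"))
  h <- cr$hicd
  years <- sort(unique(h$year))
  regions <- sort(unique(h$region))
  m <- matrix(NA_real_, length(regions), length(years),
              dimnames = list(regions, as.character(years)))
  m[cbind(match(h$region, regions), match(as.character(h$year), as.character(years)))] <- h$hicd
  tot <- rowMeans(m)
  out <- data.frame(region = regions, m, total_hicd = tot,
                    rank = rank(-tot, ties.method = "min"),
                    check.names = FALSE, row.names = NULL)
  out[order(out$rank), , drop = FALSE]
}
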