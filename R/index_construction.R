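#' Declare an indicator's name, polarity and units
#'
#' @param name column name of the indicator in the raw panel.
#' @param polarity `"positive"` (more is better, min-max mapped min->0,
#'   max->1) or `"negative"` (less is better, mapped max->0, min->1).
#' @param units free-text units, carried through to reports.
#' @return list of class `indicator_spec`.
#' @export
indicator_spec <- function(name, polarity = c("positive", "negative"), units = "") {
  polarity <- match.arg(polarity)
  structure(list(name = name, polarity = polarity, units = units),
            class = "indicator_spec")
}

#' Default specs for the three public-health indicators
#'
#' Life expectancy at birth is a positive indicator; perinatal and maternal
#' mortality are negative indicators.
#'
#' @return list of [indicator_spec()]s.
#' @export
health_indicator_specs <- function() {
  list(indicator_spec("life_expectancy", "positive", "years"),
       indicator_spec("perinatal_mortality", "negative", "per 1,000 births"),
       indicator_spec("maternal_mortality", "negative", "per 100,000 live births"))
}

#' Polarity-aware min-max standardization of an indicator panel
#'
#' Positive indicators are mapped by `(y - min) / (max - min)`, negative ones
#' by `(max - y) / (max - min)`, with the min/max taken across regions within
#' each year (`scope = "per_year"`, the default) or over the whole pooled
#' panel (`scope = "pooled"`). A degenerate group (max equal to min) maps to
#' the constant 0.5 with a warning; any constant indicator later receives
#' entropy weight zero, so the choice of constant cannot bias the index.
#'
#' @param panel balanced long data.frame with columns `region`, `year` and one
#'   column per indicator; no missing values allowed.
#' @param specs list of [indicator_spec()]s.
#' @param scope `"per_year"` or `"pooled"` min-max scope.
#' @return data.frame (region, year, standardized indicator columns) of class
#'   `standardized_panel`, with attributes `specs`, `scope` and `provenance`
#'   (which formula applied per indicator).
#' @export
standardize_indicators <- function(panel, specs, scope = c("per_year", "pooled")) {
  scope <- match.arg(scope)
  if (inherits(specs, "indicator_spec")) specs <- list(specs)
  check_balanced(panel)
  out <- panel[c("region", "year")]
  prov <- character(0)
  for (sp in specs) {
    if (!inherits(sp, "indicator_spec")) stop_gc("specs must be indicator_spec objects")
    v <- sp$name
    if (!v %in% names(panel)) stop_gc("indicator '%s' not found in panel", v)
    y <- panel[[v]]
    if (anyNA(y)) {
      i <- which(is.na(y))[1L]
      stop_gc("missing value in indicator '%s' at region '%s', year %s",
              v, panel$region[i], panel$year[i])
    }
    grp <- if (scope == "per_year") as.character(panel$year) else rep("all", length(y))
    p <- numeric(length(y))
    for (gval in unique(grp)) {
      sel <- grp == gval
      lo <- min(y[sel]); hi <- max(y[sel])
      if (hi == lo) {
        warn_gc("indicator '%s' is constant within group '%s'; standardized to 0.5", v, gval)
        p[sel] <- 0.5
      } else if (sp$polarity == "positive") {
        p[sel] <- (y[sel] - lo) / (hi - lo)
      } else {
        p[sel] <- (hi - y[sel]) / (hi - lo)
      }
    }
    out[[v]] <- p
    prov[v] <- if (sp$polarity == "positive") "minmax_positive" else "minmax_negative"
  }
  structure(out, specs = specs, scope = scope, provenance = prov,
            class = c("standardized_panel", "data.frame"))
}

std_matrix <- function(std) {
  if (inherits(std, "standardized_panel") || is.data.frame(std)) {
    cols <- setdiff(names(std), c("region", "year"))
    as.matrix(as.data.frame(std)[cols])
  } else {
    as.matrix(std)
  }
}

#' Entropy weights for standardized indicators
#'
#' Implements the canonical entropy-weight method over all N observations
#' (pooled region-years): per indicator j, proportions
#' `q_ij = p_ij / sum_i p_ij`, Shannon entropy
#' `e_j = -(1/ln N) * sum_i q_ij ln q_ij` (with `0 ln 0 := 0`), information
#' divergence `d_j = 1 - e_j`, and weight `w_j = d_j / sum_j d_j`. An
#' indicator constant across all observations carries no information and gets
#' weight zero; if every indicator is constant the method fails.
#'
#' @param std a `standardized_panel`, or a numeric matrix of values in
#'   \[0, 1\] (rows = observations, columns = indicators).
#' @param shift optional epsilon added to every standardized value before the
#'   proportions are formed (the common `p + eps` variant); default 0.
#' @return list of class `entropy_weights` with `weights` (sums to 1),
#'   `entropies`, `divergences`, `n_obs`.
#' @export
entropy_weights <- function(std, shift = 0) {
  P <- std_matrix(std)
  if (nrow(P) < 2L) stop_gc("need at least 2 observations")
  if (min(P) < -1e-9 || max(P) > 1 + 1e-9) {
    stop_gc("standardized values must lie in [0, 1]")
  }
  if (shift < 0) stop_gc("shift must be >= 0")
  P <- P + shift
  N <- nrow(P)
  e <- apply(P, 2L, function(col) {
    tot <- sum(col)
    if (tot <= 0) return(1)            # all-zero column: no information
    q <- col / tot
    ql <- ifelse(q > 0, q * log(q), 0) # 0 * ln 0 := 0
    -sum(ql) / log(N)
  })
  d <- pmax(1 - e, 0)
  if (all(d < 1e-12)) stop_gc("no discriminating information: all indicators constant")
  w <- d / sum(d)
  structure(list(weights = w, entropies = e, divergences = d,
                 n_obs = N, shift = shift),
            class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("entropy weights (N =", x$n_obs, "):\n")
  print(round(rbind(weight = x$weights, entropy = x$entropies,
                    divergence = x$divergences), 4))
  invisible(x)
}

#' Composite index as the entropy-weighted sum of standardized indicators
#'
#' `Health_it = sum_j w_j p_itj`; a convex combination of \[0, 1\] values, so
#' the index is bounded in \[0, 1\].
#'
#' @param std a `standardized_panel`.
#' @param w an `entropy_weights` object (or bare named weight vector) whose
#'   indicators match the standardized columns.
#' @param index_name name of the output column (default `"health"`).
#' @return data.frame (region, year, index column).
#' @export
composite_index <- function(std, w, index_name = "health") {
  P <- std_matrix(std)
  wv <- if (inherits(w, "entropy_weights")) w$weights else w
  if (length(wv) != ncol(P)) {
    stop_gc("dimension mismatch: %d weights for %d indicators", length(wv), ncol(P))
  }
  if (!is.null(names(wv)) && !is.null(colnames(P))) {
    if (!setequal(names(wv), colnames(P))) stop_gc("weight names do not match indicator columns")
    wv <- wv[colnames(P)]
  }
  val <- as.vector(P %*% wv)
  out <- if (is.data.frame(std)) std[c("region", "year")] else data.frame(obs = seq_len(nrow(P)))
  out[[index_name]] <- clamp(val, 0, 1)  # guard fp residue at the bounds
  out
}
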