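#' Likelihood-ratio test between nested panel fits
#'
#' `statistic = 2 * (loglik_full - loglik_restricted)`, clipped at zero, with
#' a chi-square reference on `df` restrictions. Recognized nestings: SDM vs
#' SLM (theta = 0), SDM vs SEM (common-factor restriction), SLM/SEM/SDM vs FE
#' (spatial parameter zero), and the same family under richer vs poorer
#' fixed-effects modes (the fixed-effects LR test). Both fits must use the
#' same outcome and covariates.
#'
#' @param full,restricted `spfit` objects from [fit_spatial_panel()].
#' @param df number of restrictions; by default the difference in parameter
#'   counts.
#' @return data.frame of class `sp_test` with `name`, `statistic`, `df`, `p`.
#' @export
lr_test <- function(full, restricted, df = NULL) {
  stopifnot(inherits(full, "spfit"), inherits(restricted, "spfit"))
  if (!identical(full$y_var, restricted$y_var) ||
      !identical(full$x_vars, restricted$x_vars)) {
    stop_gc("fits use different variables; not nested")
  }
  same_effects <- identical(full$effects, restricted$effects)
  fam_ok <- list(SDM = c("SLM", "SEM", "FE"), SLM = "FE", SEM = "FE")
  nested_family <- same_effects &&
    restricted$family %in% (fam_ok[[full$family]] %||% character(0))
  nested_effects <- identical(full$family, restricted$family) &&
    full$n_params > restricted$n_params
  identical_spec <- identical(full$family, restricted$family) &&
    same_effects && full$n_params == restricted$n_params
  if (!nested_family && !nested_effects && !identical_spec) {
    stop_gc("'%s' (%s effects) does not nest '%s' (%s effects)",
            full$family, full$effects, restricted$family, restricted$effects)
  }
  df <- df %||% (full$n_params - restricted$n_params)
  if (df < 0L || (df < 1L && !identical_spec)) stop_gc("nonpositive degrees of freedom")
  stat <- max(0, 2 * (full$loglik - restricted$loglik))
  if (identical_spec) {
    return(structure(data.frame(name = sprintf("LR_%s_identical", full$family),
                                statistic = stat, df = df, p = 1),
                     class = c("sp_test", "data.frame")))
  }
  name <- if (nested_family) {
    sprintf("LR_%s_vs_%s", full$family, restricted$family)
  } else {
    sprintf("LR_%s_effects_%s_vs_%s", full$family, full$effects, restricted$effects)
  }
  structure(data.frame(name = name, statistic = stat, df = df,
                       p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = c("sp_test", "data.frame"))
}

#' Hausman specification test (fixed vs random effects)
#'
#' `H = (b_FE - b_RE)' [V_FE - V_RE]^-1 (b_FE - b_RE)` on the slope
#' coefficients common to both fits (intercept and spatial-lag terms
#' excluded), referred to chi-square with as many degrees of freedom as
#' common slopes. When the variance difference is not positive definite a
#' pseudo-inverse is used with a warning.
#'
#' @param fe_fit fixed-effects fit (e.g. `fit_spatial_panel(..., family = "FE")`).
#' @param re_fit random-effects fit from [fit_random_effects()].
#' @return data.frame of class `sp_test` with `name = "Hausman"`.
#' @export
hausman_test <- function(fe_fit, re_fit) {
  stopifnot(inherits(fe_fit, "spfit"), inherits(re_fit, "spfit"))
  common <- intersect(fe_fit$x_vars, re_fit$x_vars)
  common <- intersect(common, intersect(names(fe_fit$coefficients),
                                        names(re_fit$coefficients)))
  if (!length(common)) stop_gc("no common slope parameters")
  d <- fe_fit$coefficients[common] - re_fit$coefficients[common]
  Vd <- fe_fit$vcov[common, common, drop = FALSE] -
    re_fit$vcov[common, common, drop = FALSE]
  Vi <- tryCatch({
    ee <- eigen((Vd + t(Vd)) / 2, symmetric = TRUE)
    if (min(ee$values) <= 1e-12 * max(abs(ee$values))) {
      warn_gc("variance difference not positive definite; using pseudo-inverse")
      pos <- ee$values > max(abs(ee$values)) * 1e-10
      ee$vectors[, pos, drop = FALSE] %*%
        (t(ee$vectors[, pos, drop = FALSE]) / ee$values[pos])
    } else {
      solve(Vd)
    }
  }, error = function(e) stop_gc("cannot invert variance difference: %s", conditionMessage(e)))
  stat <- max(0, as.numeric(t(d) %*% Vi %*% d))
  df <- length(common)
  structure(data.frame(name = "Hausman", statistic = stat, df = df,
                       p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = c("sp_test", "data.frame"))
}
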