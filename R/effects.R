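#' Direct, indirect and total effect decomposition
#'
#' For each covariate r of a spatial-lag or spatial-Durbin fit, the
#' marginal-effect matrix is `S_r(W) = (I - rho*W)^-1 (I*beta_r + W*theta_r)`
#' (`theta_r = 0` for SLM). The direct effect is the average diagonal
#' element, the total effect the average row sum, and the indirect
#' (spillover) effect their difference — so `total = direct + indirect`
#' exactly.
#'
#' @param fit an `spfit` with family `"SLM"` or `"SDM"` and an interior
#'   spatial parameter.
#' @param W the row-standardized `spatial_weights` used in the fit.
#' @return data.frame with columns `term`, `direct`, `indirect`, `total`.
#' @export
decompose_effects <- function(fit, W) {
  stopifnot(inherits(fit, "spfit"))
  if (!fit$family %in% c("SLM", "SDM")) {
    stop_gc("effect decomposition is defined for SLM/SDM fits, not %s", fit$family)
  }
  if (isTRUE(fit$boundary)) warn_gc("spatial parameter at interval boundary; effects unreliable")
  Wm <- as_weights_matrix(W)
  n <- nrow(Wm)
  eff <- effect_points(fit$coefficients, fit$rho, fit$x_vars, Wm,
                       sdm = fit$family == "SDM")
  data.frame(term = fit$x_vars,
             direct = eff$direct, indirect = eff$indirect, total = eff$total,
             row.names = NULL)
}

# Shared kernel: effects for one (coefficients, rho) draw.
effect_points <- function(coefs, rho, x_vars, Wm, sdm) {
  n <- nrow(Wm)
  Ainv <- solve(diag(n) - rho * Wm)
  direct <- total <- numeric(length(x_vars))
  for (j in seq_along(x_vars)) {
    br <- coefs[[x_vars[j]]]
    thr <- if (sdm) coefs[[paste0("W.", x_vars[j])]] else 0
    S <- Ainv %*% (diag(br, n) + thr * Wm)
    direct[j] <- mean(diag(S))
    total[j] <- sum(S) / n
  }
  list(direct = direct, total = total, indirect = total - direct)
}

#' Monte-Carlo inference for effect decompositions
#'
#' Simulates `(beta, theta, rho)` jointly from the asymptotic normal
#' distribution implied by the fit's covariance (draws with the spatial
#' parameter outside its admissible interval are rejected), recomputes the
#' direct/indirect/total decomposition per draw, and reports the draw
#' standard deviation as the standard error, `t = point / SE`, and two-sided
#' normal p-values. Reproducible under `seed`.
#'
#' @inheritParams decompose_effects
#' @param n_draws number of accepted parameter draws (>= 100).
#' @param seed integer RNG seed.
#' @return data.frame of class `effects_table`: per covariate the point
#'   estimates and their simulated `*_se`, `*_t`, `*_p`; attributes `n_draws`,
#'   `seed`, `method`.
#' @export
effects_inference <- function(fit, W, n_draws = 1000L, seed = 1L) {
  if (n_draws < 100L) stop_gc("n_draws must be >= 100")
  pts <- decompose_effects(fit, W)
  Wm <- as_weights_matrix(W)
  par_names <- c(names(fit$coefficients), "rho")
  V <- fit$vcov[par_names, par_names, drop = FALSE]
  V <- nearest_psd(V)
  mu <- c(fit$coefficients, rho = fit$rho)
  set.seed(seed %% .Machine$integer.max)
  iv <- fit$interval
  draws <- matrix(NA_real_, 0L, length(mu))
  tries <- 0L
  while (nrow(draws) < n_draws && tries < 50L) {
    need <- n_draws - nrow(draws)
    cand <- rmvnorm_psd(ceiling(need * 1.2) + 8L, mu, V)
    ok <- cand[, length(mu)] > iv[1L] & cand[, length(mu)] < iv[2L]
    draws <- rbind(draws, cand[ok, , drop = FALSE])
    tries <- tries + 1L
  }
  if (nrow(draws) < n_draws) stop_gc("could not obtain %d admissible draws", n_draws)
  draws <- draws[seq_len(n_draws), , drop = FALSE]
  colnames(draws) <- par_names
  k <- length(fit$x_vars)
  dmat <- imat <- tmat <- matrix(NA_real_, n_draws, k)
  sdm <- fit$family == "SDM"
  for (i in seq_len(n_draws)) {
    co <- as.list(draws[i, seq_len(length(fit$coefficients))])
    names(co) <- names(fit$coefficients)
    e <- effect_points(co, draws[i, "rho"], fit$x_vars, Wm, sdm)
    dmat[i, ] <- e$direct; imat[i, ] <- e$indirect; tmat[i, ] <- e$total
  }
  mk <- function(point, sims, prefix) {
    se <- apply(sims, 2L, stats::sd)
    t <- point / se
    out <- data.frame(point, se, t, 2 * stats::pnorm(-abs(t)))
    names(out) <- paste0(prefix, c("", "_se", "_t", "_p"))
    out
  }
  out <- cbind(data.frame(term = pts$term),
               mk(pts$direct, dmat, "direct"),
               mk(pts$indirect, imat, "indirect"),
               mk(pts$total, tmat, "total"))
  names(out)[names(out) == "direct"] <- "direct"
  structure(out, n_draws = n_draws, seed = seed,
            method = "parameter simulation from asymptotic covariance",
            class = c("effects_table", "data.frame"))
}

#' Effect decomposition by regional subset
#'
#' Refits the model on each regional subgroup with the corresponding
#' principal submatrix of W (re-standardized) and runs [effects_inference()]
#' per region. A subset whose weights develop islands aborts with a clear
#' message naming the subset; other subsets are unaffected.
#'
#' @param panel balanced long data.frame covering all regions.
#' @param W full row-standardized `spatial_weights`.
#' @param groups named character vector region -> group (as in a
#'   [region_map()]).
#' @param y_var,x_vars,effects,log_transform passed to [fit_spatial_panel()].
#' @param family model family (default `"SDM"`).
#' @param n_draws,seed passed to [effects_inference()]; the seed is offset by
#'   the group index for independent draws.
#' @return named list per group: `list(fit, effects)`; a failed group holds a
#'   `condition` describing the failure instead.
#' @export
regional_effects <- function(panel, W, groups, y_var, x_vars,
                             family = "SDM", effects = "twoway",
                             log_transform = FALSE, n_draws = 1000L, seed = 1L) {
  out <- list()
  gnames <- unique(groups)
  for (gi in seq_along(gnames)) {
    g <- gnames[gi]
    regions <- names(groups)[groups == g]
    res <- tryCatch({
      Wsub <- subset_weights(W, regions)
      if (length(Wsub$islands)) {
        stop_gc("subset '%s' creates island(s): %s — edit the grouping or edges",
                g, paste(Wsub$islands, collapse = ", "))
      }
      sub <- panel[panel$region %in% regions, , drop = FALSE]
      fit <- fit_spatial_panel(sub, y_var, x_vars, Wsub, family = family,
                               effects = effects, log_transform = log_transform)
      list(fit = fit, effects = effects_inference(fit, Wsub, n_draws = n_draws,
                                                  seed = seed + gi))
    }, error = function(e) list(condition = conditionMessage(e)))
    out[[g]] <- res
  }
  out
}
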