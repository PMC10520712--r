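#' Within (demeaning) transformation of a balanced panel matrix
#'
#' Removes individual means (rows), time means (columns), or both (adding
#' back the grand mean) from an n x T region-by-year matrix, absorbing the
#' corresponding fixed effects. Attribute `dims_eff` records the effective
#' dimensions left after demeaning: time demeaning costs one cross-sectional
#' degree of freedom per period, individual demeaning one period.
#'
#' @param x n x T numeric matrix (regions x years), or a balanced long
#'   data.frame with `region`/`year` columns (then `vars` selects columns and
#'   a list of transformed matrices is returned).
#' @param effects one of `"none"`, `"individual"`, `"time"`, `"twoway"`.
#' @param vars variable names when `x` is a data.frame.
#' @return transformed matrix (or list of matrices) with attribute
#'   `dims_eff = c(N_eff, T_eff)`.
#' @export
within_transform <- function(x, effects = c("twoway", "individual", "time", "none"),
                             vars = NULL) {
  effects <- match.arg(effects)
  if (is.data.frame(x)) {
    if (is.null(vars)) stop_gc("vars must name the panel columns to transform")
    mats <- panel_matrices(x, vars)
    return(lapply(mats, within_transform, effects = effects))
  }
  m <- as.matrix(x)
  n <- nrow(m); Tt <- ncol(m)
  ind <- effects %in% c("individual", "twoway")
  tim <- effects %in% c("time", "twoway")
  out <- m
  if (ind) out <- out - rowMeans(m)
  if (tim) out <- sweep(out, 2L, colMeans(m))
  if (ind && tim) out <- out + mean(m)  # row+col removal double-subtracts the grand mean
  attr(out, "dims_eff") <- c(N_eff = n - as.integer(tim), T_eff = Tt - as.integer(ind))
  out
}

log_panel_mats <- function(mats, vars, log_transform) {
  if (!log_transform) return(mats)
  for (v in vars) {
    m <- mats[[v]]
    if (any(m <= 0)) {
      cell <- which(m <= 0, arr.ind = TRUE)[1L, ]
      stop_gc("log transform requires strictly positive values; variable '%s' is %g at region '%s', year %s",
              v, m[cell[1L], cell[2L]], rownames(m)[cell[1L]], colnames(m)[cell[2L]])
    }
    mats[[v]] <- log(m)
  }
  mats
}

fe_decompose <- function(q, effects) {
  n <- nrow(q); Tt <- ncol(q)
  g <- 0; mu <- numeric(n); v <- numeric(Tt)
  if (effects == "individual") {
    mu <- rowMeans(q)
  } else if (effects == "time") {
    v <- colMeans(q)
  } else if (effects == "twoway") {
    g <- mean(q)
    mu <- rowMeans(q) - g
    v <- colMeans(q) - g
  }
  list(mu = mu, v = v, grand = g,
       fitted = outer(mu, rep(1, Tt)) + outer(rep(1, n), v) + g)
}

#' Maximum-likelihood spatial panel estimation
#'
#' Fits one of four panel specifications to a balanced region-year panel with
#' fixed effects absorbed by demeaning:
#' \describe{
#'   \item{FE}{non-spatial least squares on the demeaned data;}
#'   \item{SLM}{spatial lag model, `y = rho*W*y + X*beta + fe + eps`;}
#'   \item{SEM}{spatial error model, `y = X*beta + u`, `u = lambda*W*u + eps`;}
#'   \item{SDM}{spatial Durbin model, `y = rho*W*y + X*beta + W*X*theta + fe + eps`.}
#' }
#' Spatial families are estimated by concentrated maximum likelihood over the
#' scalar spatial parameter on its admissible interval
#' `(1/omega_min + delta, 1/omega_max - delta)` (omega the eigenvalues of the
#' row-standardized W), with the log-Jacobian computed from the eigenvalues as
#' `sum_k log(1 - rho*omega_k)` per effective period. With
#' `bias_correct = TRUE` (default) the likelihood uses the exact transformed
#' dimensions — `T - 1` effective periods when individual effects are
#' demeaned, `n - 1` effective regions and one unit eigenvalue of W dropped
#' when time effects are demeaned — which removes the incidental-parameter
#' bias in the variance estimate. The parameter covariance comes from the
#' analytic expected information matrix.
#'
#' @param panel balanced long data.frame.
#' @param y_var outcome column name.
#' @param x_vars covariate column names.
#' @param W row-standardized `spatial_weights` with no islands (any W is
#'   accepted for `family = "FE"`).
#' @param family `"SDM"`, `"SLM"`, `"SEM"` or `"FE"`.
#' @param effects fixed-effects mode: `"twoway"`, `"individual"`, `"time"`,
#'   `"none"` (an intercept is added automatically for `"none"`).
#' @param log_transform natural-log all model variables (requires strictly
#'   positive inputs).
#' @param bias_correct use effective-dimension (transformed) likelihood.
#' @param delta inset from the spatial-parameter interval boundaries.
#' @param fix_spatial optionally fix rho (SLM/SDM) or lambda (SEM) at a value
#'   instead of estimating it (used for nested comparisons).
#' @param theta_zero for `family = "SDM"`, constrain all spatial-lag
#'   coefficients theta to zero (the model then coincides with the SLM; used
#'   to verify the reduction chain).
#' @return object of class `spfit`: coefficients (`beta`, and `theta` for
#'   SDM), spatial parameter `rho`/`lambda`, `sigma2`, `loglik`, `vcov`
#'   (coefficients + spatial parameter + sigma2), coefficient table with
#'   standard errors / t / p, `r2_naive` and `r2_within`, recovered fixed
#'   effects, panel dimensions and bookkeeping.
#' @export
fit_spatial_panel <- function(panel, y_var, x_vars, W,
                              family = c("SDM", "SLM", "SEM", "FE"),
                              effects = c("twoway", "individual", "time", "none"),
                              log_transform = FALSE, bias_correct = TRUE,
                              delta = 1e-5, fix_spatial = NULL,
                              theta_zero = FALSE) {
  family <- match.arg(family)
  effects <- match.arg(effects)
  stopifnot(inherits(W, "spatial_weights"))
  spatial <- family != "FE"
  if (spatial) {
    if (!W$standardized) stop_gc("spatial families require a row-standardized W")
    if (length(W$islands)) stop_gc("spatial families require no islands; found: %s",
                                   paste(W$islands, collapse = ", "))
  }
  Wm <- W$W
  mats <- panel_matrices(panel, c(y_var, x_vars), region_order = W$region_order)
  mats <- log_panel_mats(mats, c(y_var, x_vars), log_transform)
  years <- attr(mats, "years")
  Yl <- mats[[y_var]]
  n <- nrow(Yl); Tt <- ncol(Yl)
  k0 <- length(x_vars)
  ind <- effects %in% c("individual", "twoway")
  tim <- effects %in% c("time", "twoway")

  WY <- Wm %*% Yl
  WXl <- lapply(mats[x_vars], function(m) Wm %*% m)

  dm <- function(m) within_transform(m, effects)
  Yd <- dm(Yl); WYd <- dm(WY)
  Xd <- lapply(mats[x_vars], dm)
  WXd <- lapply(WXl, dm)

  yv <- as.vector(Yd)
  Zl <- lapply(Xd, as.vector)
  names(Zl) <- x_vars
  if (family == "SDM" && !theta_zero) {
    for (v in x_vars) Zl[[paste0("W.", v)]] <- as.vector(WXd[[v]])
  }
  if (effects == "none") Zl <- c(list(`(Intercept)` = rep(1, n * Tt)), Zl)
  Zm <- do.call(cbind, Zl)
  colnames(Zm) <- names(Zl)
  k <- ncol(Zm)

  bias_correct <- isTRUE(bias_correct) && effects != "none"
  N_eff <- if (bias_correct && tim) n - 1L else n
  T_eff <- if (bias_correct && ind) Tt - 1L else Tt
  NTe <- N_eff * T_eff

  ev <- NULL; ev_use <- NULL; iv <- c(NA_real_, NA_real_)
  if (spatial) {
    ev <- weights_eigen(W)
    iv <- rho_interval(W, ev)
    ev_use <- ev
    if (bias_correct && tim) {
      # drop one unit eigenvalue: the component along 1 removed by
      # cross-sectional demeaning (requires a connected graph)
      unit <- which(abs(ev - max(ev)) < 1e-9)
      if (length(unit) > 1L) {
        warn_gc("W appears disconnected (%d maximal eigenvalues); time demeaning removes only one",
                length(unit))
      }
      ev_use <- ev[-which.max(ev)]
    }
  }

  ols <- function(y, X) {
    qrX <- qr(X)
    b <- qr.coef(qrX, y)
    b[is.na(b)] <- 0
    list(b = b, e = y - X %*% b)
  }

  conc <- NULL; opt_par <- NULL
  if (family == "FE") {
    f0 <- ols(yv, Zm)
    b <- drop(f0$b)
    RSS <- sum(f0$e^2)
    sigma2 <- RSS / NTe
    loglik <- -NTe / 2 * (log(2 * pi * sigma2) + 1)
    dfv <- max(NTe - k, 1L)
    Vb <- (RSS / dfv) * solve(crossprod(Zm))
    vc <- matrix(0, k + 1L, k + 1L,
                 dimnames = list(c(colnames(Zm), "sigma2"), c(colnames(Zm), "sigma2")))
    vc[seq_len(k), seq_len(k)] <- Vb
    vc["sigma2", "sigma2"] <- 2 * sigma2^2 / NTe
    spar <- NULL; spar_name <- NULL
  } else if (family %in% c("SLM", "SDM")) {
    Wyv <- as.vector(WYd)
    f0 <- ols(yv, Zm); f1 <- ols(Wyv, Zm)
    a0 <- sum(f0$e^2); a1 <- sum(f0$e * f1$e); a2 <- sum(f1$e^2)
    conc <- function(rho) {
      RSS <- a0 - 2 * rho * a1 + rho^2 * a2
      T_eff * sum(log(1 - rho * ev_use)) - NTe / 2 * log(RSS / NTe) -
        NTe / 2 * (log(2 * pi) + 1)
    }
    if (is.null(fix_spatial)) {
      op <- stats::optimize(conc, c(iv[1L] + delta, iv[2L] - delta),
                            maximum = TRUE, tol = .Machine$double.eps^0.5)
      spar <- op$maximum
    } else spar <- fix_spatial
    opt_par <- spar
    b <- drop(f0$b - spar * f1$b)
    RSS <- a0 - 2 * spar * a1 + spar^2 * a2
    sigma2 <- RSS / NTe
    loglik <- conc(spar)
    spar_name <- "rho"
  } else { # SEM
    Wyv <- as.vector(WYd)
    WZ <- do.call(cbind, lapply(x_vars, function(v) as.vector(WXd[[v]])))
    Zx <- Zm
    if (effects == "none") {
      # intercept filters to (1 - lambda) * 1 under row-standardized W
      WZ <- cbind(rep(1, n * Tt), WZ)
    }
    conc <- function(lambda) {
      ys <- yv - lambda * Wyv
      Xs <- Zx - lambda * WZ
      fo <- ols(ys, Xs)
      RSS <- sum(fo$e^2)
      T_eff * sum(log(1 - lambda * ev_use)) - NTe / 2 * log(RSS / NTe) -
        NTe / 2 * (log(2 * pi) + 1)
    }
    if (is.null(fix_spatial)) {
      op <- stats::optimize(conc, c(iv[1L] + delta, iv[2L] - delta),
                            maximum = TRUE, tol = .Machine$double.eps^0.5)
      spar <- op$maximum
    } else spar <- fix_spatial
    opt_par <- spar
    ys <- yv - spar * Wyv
    Xs <- Zx - spar * WZ
    fo <- ols(ys, Xs)
    b <- drop(fo$b)
    RSS <- sum(fo$e^2)
    sigma2 <- RSS / NTe
    loglik <- conc(spar)
    spar_name <- "lambda"
  }
  names(b) <- colnames(Zm)

  boundary <- FALSE
  if (spatial && is.null(fix_spatial)) {
    boundary <- min(abs(spar - iv)) < 1e-4
    if (boundary) warn_gc("spatial parameter estimate %.4f is within 1e-4 of the interval boundary", spar)
  }

  # --- analytic expected information -> vcov ------------------------------
  if (spatial) {
    Mc <- if (bias_correct && tim) diag(n) - 1 / n else diag(n)
    if (family %in% c("SLM", "SDM")) {
      A <- diag(n) - spar * Wm
      Cmat <- Wm %*% solve(A)
      Cm <- Mc %*% Cmat %*% Mc
      P <- matrix(Zm %*% b, n, Tt)
      CP <- Cm %*% P
      trC <- T_eff * sum(diag(Cm))
      trCC <- T_eff * (sum(Cm * t(Cm)) + sum(Cm * Cm))
      Ibb <- crossprod(Zm) / sigma2
      Ibr <- crossprod(Zm, as.vector(CP)) / sigma2
      Irr <- trCC + sum(CP^2) / sigma2
      Irs <- trC / sigma2
      Iss <- NTe / (2 * sigma2^2)
      Info <- rbind(cbind(Ibb, Ibr, 0),
                    cbind(t(Ibr), Irr, Irs),
                    cbind(matrix(0, 1, k), Irs, Iss))
    } else {
      B <- diag(n) - spar * Wm
      G <- Wm %*% solve(B)
      Gm <- Mc %*% G %*% Mc
      trG <- T_eff * sum(diag(Gm))
      trGG <- T_eff * (sum(Gm * t(Gm)) + sum(Gm * Gm))
      Ibb <- crossprod(Xs) / sigma2
      Info <- rbind(cbind(Ibb, matrix(0, k, 2)),
                    cbind(matrix(0, 1, k), trGG, trG / sigma2),
                    cbind(matrix(0, 1, k), trG / sigma2, NTe / (2 * sigma2^2)))
    }
    pn <- c(colnames(Zm), spar_name, "sigma2")
    dimnames(Info) <- list(pn, pn)
    vc <- tryCatch(solve(Info), error = function(e) {
      warn_gc("information matrix singular; using pseudo-inverse")
      ee <- eigen((Info + t(Info)) / 2, symmetric = TRUE)
      pos <- ee$values > max(ee$values) * 1e-12
      V <- ee$vectors[, pos, drop = FALSE] %*%
        (t(ee$vectors[, pos, drop = FALSE]) / ee$values[pos])
      dimnames(V) <- dimnames(Info); V
    })
    vc <- (vc + t(vc)) / 2
  }

  # --- fitted values, fixed-effect recovery, goodness of fit --------------
  signal <- matrix(Zm %*% b, n, Tt)   # demeaned-scale systematic part
  if (family %in% c("SLM", "SDM")) {
    fit_d <- spar * WYd + signal
    sig_raw <- {
      Zraw <- do.call(cbind, c(
        if (effects == "none") list(rep(1, n * Tt)) else NULL,
        lapply(mats[x_vars], as.vector),
        if (family == "SDM" && !theta_zero) lapply(WXl[x_vars], as.vector) else NULL))
      matrix(Zraw %*% b, n, Tt) + spar * WY
    }
  } else {
    fit_d <- signal
    Zraw <- do.call(cbind, c(
      if (effects == "none") list(rep(1, n * Tt)) else NULL,
      lapply(mats[x_vars], as.vector),
      if (family == "SDM" && !theta_zero) lapply(WXl[x_vars], as.vector) else NULL))
    sig_raw <- matrix(Zraw %*% b, n, Tt)
  }
  fe <- fe_decompose(Yl - sig_raw, effects)
  fitted_raw <- sig_raw + fe$fitted
  r2_within <- stats::cor(as.vector(fit_d), yv)^2
  r2_naive <- stats::cor(as.vector(fitted_raw), as.vector(Yl))^2

  est <- if (spatial) c(b, stats::setNames(spar, spar_name)) else b
  se <- sqrt(pmax(diag(vc)[seq_along(est)], 0))
  tstat <- est / se
  pval <- 2 * stats::pnorm(-abs(tstat))
  coeftab <- data.frame(term = names(est), estimate = est, se = se,
                        t = tstat, p = pval, row.names = NULL)

  fe_count <- if (effects == "none") 0L else (ind * (n - 1L) + tim * (Tt - 1L) + 1L)
  theta <- if (family == "SDM") {
    if (theta_zero) stats::setNames(rep(0, length(x_vars)), x_vars)
    else stats::setNames(b[paste0("W.", x_vars)], x_vars)
  } else NULL

  structure(list(
    family = family, effects = effects,
    coefficients = b,
    beta = b[intersect(names(b), x_vars)],
    theta = theta,
    rho = if (spatial && spar_name == "rho") spar else NULL,
    lambda = if (spatial && spar_name == "lambda") spar else NULL,
    sigma2 = sigma2, loglik = loglik, vcov = vc,
    coef_table = coeftab,
    r2_naive = r2_naive, r2_within = r2_within,
    fe_individual = stats::setNames(fe$mu, rownames(Yl)),
    fe_time = stats::setNames(fe$v, colnames(Yl)),
    fe_grand = fe$grand,
    n = n, T = Tt, N_eff = N_eff, T_eff = T_eff,
    n_params = k + as.integer(spatial) + 1L + fe_count,
    y_var = y_var, x_vars = x_vars, log_transform = log_transform,
    bias_correct = bias_correct, interval = iv, boundary = boundary,
    eigenvalues = ev, conc_loglik = conc,
    region_order = W$region_order, years = years
  ), class = "spfit")
}

#' @export
print.spfit <- function(x, ...) {
  cat(sprintf("%s panel model (%s effects%s), n = %d, T = %d\n",
              x$family, x$effects,
              if (x$log_transform) ", log scale" else "", x$n, x$T))
  print(transform(x$coef_table, estimate = round(estimate, 4), se = round(se, 4),
                  t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("sigma2 = %.5f, log-likelihood = %.4f, R2 (naive) = %.4f, R2 (within) = %.4f\n",
              x$sigma2, x$loglik, x$r2_naive, x$r2_within))
  invisible(x)
}

#' @export
coef.spfit <- function(object, ...) object$coefficients

#' @export
logLik.spfit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' @export
vcov.spfit <- function(object, ...) object$vcov

#' Random-effects (error-components) panel estimation by feasible GLS
#'
#' Non-spatial individual random-effects comparator for the Hausman test:
#' variance components from the within and between regressions, then GLS by
#' quasi-demeaning with `theta_q = 1 - sqrt(sigma2_e / (sigma2_e + T*sigma2_mu))`.
#'
#' @inheritParams fit_spatial_panel
#' @return an `spfit`-like object with `family = "RE"` (intercept plus
#'   slopes, FGLS covariance).
#' @export
fit_random_effects <- function(panel, y_var, x_vars, log_transform = FALSE) {
  mats <- panel_matrices(panel, c(y_var, x_vars))
  mats <- log_panel_mats(mats, c(y_var, x_vars), log_transform)
  Y <- mats[[y_var]]
  n <- nrow(Y); Tt <- ncol(Y); k <- length(x_vars)
  Xm <- lapply(mats[x_vars], identity)
  # within (individual) regression
  yw <- as.vector(within_transform(Y, "individual"))
  Xw <- do.call(cbind, lapply(Xm, function(m) as.vector(within_transform(m, "individual"))))
  bw <- qr.coef(qr(Xw), yw); bw[is.na(bw)] <- 0
  rss_w <- sum((yw - Xw %*% bw)^2)
  sigma2_e <- rss_w / (n * (Tt - 1) - k)
  # between regression
  yb <- rowMeans(Y)
  Xb <- cbind(1, do.call(cbind, lapply(Xm, rowMeans)))
  bb <- qr.coef(qr(Xb), yb); bb[is.na(bb)] <- 0
  rss_b <- sum((yb - Xb %*% bb)^2)
  sigma2_between <- rss_b / max(n - k - 1, 1)
  sigma2_mu <- max(0, sigma2_between - sigma2_e / Tt)
  theta_q <- 1 - sqrt(sigma2_e / (sigma2_e + Tt * sigma2_mu))
  ybar <- rowMeans(Y)
  ys <- as.vector(Y - theta_q * ybar)
  Xs <- do.call(cbind, lapply(Xm, function(m) as.vector(m - theta_q * rowMeans(m))))
  Xs <- cbind(`(Intercept)` = rep(1 - theta_q, n * Tt), Xs)
  colnames(Xs) <- c("(Intercept)", x_vars)
  bre <- qr.coef(qr(Xs), ys); bre[is.na(bre)] <- 0
  e <- ys - Xs %*% bre
  Vb <- sigma2_e * solve(crossprod(Xs))
  dimnames(Vb) <- list(colnames(Xs), colnames(Xs))
  est <- drop(bre); names(est) <- colnames(Xs)
  se <- sqrt(diag(Vb))
  structure(list(
    family = "RE", effects = "individual",
    coefficients = est, beta = est[x_vars], theta = NULL,
    rho = NULL, lambda = NULL,
    sigma2 = sigma2_e, sigma2_mu = sigma2_mu, theta_q = theta_q,
    loglik = NA_real_, vcov = Vb,
    coef_table = data.frame(term = names(est), estimate = est, se = se,
                            t = est / se, p = 2 * stats::pnorm(-abs(est / se)),
                            row.names = NULL),
    r2_naive = stats::cor(as.vector(Xs %*% bre), ys)^2, r2_within = NA_real_,
    n = n, T = Tt, n_params = k + 3L,
    y_var = y_var, x_vars = x_vars, log_transform = log_transform
  ), class = "spfit")
}
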