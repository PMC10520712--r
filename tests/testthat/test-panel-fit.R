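# Spatial panel maximum likelihood: transforms, fits, specification tests.

test_that("within transformation demeans as specified", {
  m <- rbind(c(1, 2), c(3, 4))
  expect_equal(unname(within_transform(m, "none")), m, ignore_attr = TRUE)
  expect_equal(unname(within_transform(m, "twoway")), matrix(0, 2, 2),
               ignore_attr = TRUE)                       # perfectly additive panel
  cst <- matrix(5, 3, 4)
  expect_equal(unname(within_transform(cst, "individual")), matrix(0, 3, 4),
               ignore_attr = TRUE)
  mi <- within_transform(m, "individual")
  expect_equal(unname(rowMeans(mi)), c(0, 0), ignore_attr = TRUE)
  expect_equal(attr(within_transform(m, "twoway"), "dims_eff"),
               c(N_eff = 1L, T_eff = 1L))

  unb <- data.frame(region = c("a", "a", "b"), year = c(1, 2, 1), v = 1:3)
  expect_error(within_transform(unb, "individual", vars = "v"), "unbalanced")
})

test_that("noiseless SDM data are recovered exactly", {
  # with literally zero noise the SDM likelihood is degenerate (RSS = 0 for
  # every rho); vanishing noise tests the same identity in a well-posed way
  map <- make_lattice_map(3, 3)
  W <- row_standardize(weights_from_edges(map))
  d <- dgp_config(n_regions = 9, n_years = 6, rho_true = 0,
                  beta_true = c(x1 = 1.5, x2 = -0.7), theta_true = c(x1 = 0, x2 = 0),
                  sigma2_true = 1e-16, fe_individual_sd = 0.5, fe_time_sd = 0.3, seed = 2)
  spec <- list(x1 = list(mean = 0, sd = 1), x2 = list(mean = 0, sd = 1))
  sim <- simulate_sdm_panel(map, d, covariate_spec = spec)
  # near-zero noise makes the information matrix ill-scaled; warnings expected
  f <- suppressWarnings(
    fit_spatial_panel(sim, "y", c("x1", "x2"), W, family = "SDM", effects = "twoway"))
  # beta is recovered exactly; (rho, theta) are identified only up to the
  # common-factor ridge theta = -rho * beta, on which the fit must lie
  expect_equal(unname(f$beta), c(1.5, -0.7), tolerance = 1e-6)
  expect_equal(unname(f$theta), unname(-f$rho * f$beta), tolerance = 1e-5)

  # with the spatial parameter pinned at truth the lag coefficients vanish
  f0 <- suppressWarnings(
    fit_spatial_panel(sim, "y", c("x1", "x2"), W, family = "SDM",
                      effects = "twoway", fix_spatial = 0))
  expect_equal(unname(f0$beta), c(1.5, -0.7), tolerance = 1e-6)
  expect_equal(unname(f0$theta), c(0, 0), tolerance = 1e-6)

  # the SLM (no lagged X soaking up W y) pins rho itself at zero
  fs <- suppressWarnings(
    fit_spatial_panel(sim, "y", c("x1", "x2"), W, family = "SLM",
                      effects = "twoway"))
  expect_lt(abs(fs$rho), 1e-6)
  expect_equal(unname(fs$beta), c(1.5, -0.7), tolerance = 1e-6)
})

test_that("reduction chain: SDM(theta=0) = SLM and SLM(rho=0) = FE", {
  for (s in 1:5) {
    rp <- random_small_panel(600 + s)
    slm <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SLM")
    sdm0 <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SDM",
                              theta_zero = TRUE)
    expect_equal(slm$coefficients, sdm0$coefficients[names(slm$coefficients)],
                 tolerance = 1e-8)
    expect_equal(slm$rho, sdm0$rho, tolerance = 1e-8)
    expect_equal(slm$loglik, sdm0$loglik, tolerance = 1e-8)

    fe <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "FE")
    slm0 <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SLM",
                              fix_spatial = 0)
    expect_equal(slm0$coefficients, fe$coefficients, tolerance = 1e-8)
  }
})

test_that("optimizer attains the likelihood-grid maximum", {
  for (s in 1:8) {
    rp <- random_small_panel(700 + s)
    for (fam in c("SLM", "SEM", "SDM")) {
      f <- suppressWarnings(
        fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = fam))
      iv <- f$interval
      grid <- seq(iv[1] + 1e-4, iv[2] - 1e-4, length.out = 201)
      gl <- vapply(grid, f$conc_loglik, numeric(1))
      expect_gte(f$loglik, max(gl) - 1e-6)
      expect_false(any(!is.finite(gl)))      # smooth, no NaN on the interval
    }
  }
})

test_that("eigenvalue log-determinant identity holds", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    w <- random_binary_w(n)
    rownames(w) <- colnames(w) <- sprintf("r%d", 1:n)
    sw <- row_standardize(geoconverge:::new_spatial_weights(w, FALSE))
    ev <- geoconverge:::weights_eigen(sw)
    rho <- stats::runif(1, 1 / min(ev) + 0.05, 0.95)
    expect_equal(sum(log(1 - rho * ev)),
                 determinant(diag(n) - rho * sw$W, logarithm = TRUE)$modulus[1],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("analytic information matrix agrees with a numerical Hessian", {
  rp <- random_small_panel(801, n_side = 4, Tt = 8)
  f <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SDM",
                         effects = "twoway")
  n <- f$n; Tt <- f$T
  mats <- geoconverge:::panel_matrices(rp$panel, c("y", rp$vars),
                                       region_order = rp$W$region_order)
  dm <- function(m) within_transform(m, "twoway")
  yv <- as.vector(dm(mats$y))
  Wyv <- as.vector(dm(rp$W$W %*% mats$y))
  Z <- do.call(cbind, c(lapply(rp$vars, function(v) as.vector(dm(mats[[v]]))),
                        lapply(rp$vars, function(v) as.vector(dm(rp$W$W %*% mats[[v]])))))
  NTe <- (n - 1) * (Tt - 1)
  ev_use <- f$eigenvalues[-which.max(f$eigenvalues)]
  ll <- function(p) {
    k <- ncol(Z)
    e <- yv - p[k + 1] * Wyv - Z %*% p[1:k]
    s2 <- exp(p[k + 2])
    (Tt - 1) * sum(log(1 - p[k + 1] * ev_use)) - NTe / 2 * log(2 * pi * s2) -
      sum(e^2) / (2 * s2)
  }
  H <- geoconverge:::num_hessian(ll, c(f$coefficients, f$rho, log(f$sigma2)))
  se_num <- sqrt(diag(solve(-H)))
  k <- length(f$coefficients)
  se_ana <- sqrt(diag(f$vcov))[1:(k + 1)]
  expect_equal(unname(se_ana), unname(se_num[1:(k + 1)]), tolerance = 0.1)
})

test_that("SDM recovers DGP parameters on the study-sized panel", {
  map <- make_lattice_map(5, 6)
  W <- row_standardize(weights_from_edges(map))
  d <- dgp_config(seed = 314)
  rhos <- betas <- numeric(20)
  for (i in 1:20) {
    sim <- simulate_sdm_panel(map, d, seed = 2000 + i)
    f <- fit_spatial_panel(sim, "y", names(d$beta_true), W, family = "SDM",
                           effects = "twoway")
    rhos[i] <- f$rho; betas[i] <- f$beta["HICD"]
  }
  expect_lt(abs(mean(rhos) - d$rho_true), 0.05)
  expect_lt(abs(mean(betas) - d$beta_true["HICD"]), 0.05)
})

test_that("SEM recovers a spatial-error process", {
  # SEM truth: y = X b + (I - lam W)^-1 eps + fe
  map <- make_lattice_map(5, 6)
  W <- row_standardize(weights_from_edges(map))
  set.seed(77)
  n <- 30; Tt <- 18; lam <- 0.4; b <- 1.2
  Binv <- solve(diag(n) - lam * W$W)
  lams <- betas <- numeric(10)
  for (i in 1:10) {
    X <- matrix(stats::rnorm(n * Tt), n, Tt)
    E <- Binv %*% matrix(stats::rnorm(n * Tt, 0, 0.3), n, Tt)
    Y <- b * X + E + stats::rnorm(n, 0, 0.5)          # individual effects
    pan <- data.frame(region = rep(W$region_order, Tt),
                      year = rep(1:Tt, each = n),
                      x = as.vector(X), y = as.vector(Y))
    f <- fit_spatial_panel(pan, "y", "x", W, family = "SEM", effects = "individual")
    lams[i] <- f$lambda; betas[i] <- f$beta["x"]
  }
  expect_lt(abs(mean(lams) - lam), 0.1)
  expect_lt(abs(mean(betas) - b), 0.02)
})

test_that("LR tests behave under null, power, and degenerate inputs", {
  rp <- random_small_panel(900, n_side = 3, Tt = 6)
  sdm <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SDM")
  slm <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SLM")
  lr <- lr_test(sdm, slm, df = length(rp$vars))
  expect_gte(lr$statistic, 0)
  expect_true(lr$p >= 0 && lr$p <= 1)

  same <- lr_test(sdm, sdm)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  fe2 <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "FE")
  expect_error(lr_test(fe2, sdm), "does not nest")

  # power: strong spatial-lag covariates are detected at study scale
  map <- make_lattice_map(5, 6)
  W <- row_standardize(weights_from_edges(map))
  dp <- dgp_config(n_regions = 30, n_years = 18, rho_true = 0.24,
                   beta_true = c(x = 0.6), theta_true = c(x = 0.5),
                   sigma2_true = 0.01, seed = 1)
  hits <- sapply(1:20, function(i) {
    sim <- simulate_sdm_panel(map, dp, covariate_spec = list(x = list(mean = 0, sd = 0.3)),
                              seed = 3000 + i)
    f1 <- fit_spatial_panel(sim, "y", "x", W, family = "SDM", effects = "twoway")
    f0 <- fit_spatial_panel(sim, "y", "x", W, family = "SLM", effects = "twoway")
    lr_test(f1, f0, df = 1)$p < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("Hausman test has size under RE-consistent DGP and power under correlation", {
  gen <- function(seed, corr) {
    set.seed(seed)
    n <- 30; Tt <- 10
    x <- matrix(stats::rnorm(n * Tt), n, Tt)
    mu <- if (corr) 0.8 * rowMeans(x) + stats::rnorm(n, 0, 0.3) else stats::rnorm(n, 0, 0.5)
    y <- 1 + 2 * x + mu + matrix(stats::rnorm(n * Tt, 0, 1), n, Tt)
    data.frame(region = rep(sprintf("r%02d", 1:n), Tt), year = rep(1:Tt, each = n),
               x = as.vector(x), y = as.vector(y))
  }
  run <- function(seed, corr) {
    pan <- gen(seed, corr)
    fe <- fit_spatial_panel(pan, "y", "x",
                            geoconverge:::new_spatial_weights(
                              { w <- matrix(0, 30, 30)
                                rownames(w) <- colnames(w) <- sprintf("r%02d", 1:30); w },
                              FALSE),
                            family = "FE", effects = "individual")
    re <- fit_random_effects(pan, "y", "x")
    suppressWarnings(hausman_test(fe, re)$p < 0.05)
  }
  size <- mean(sapply(1:40, function(s) run(4000 + s, FALSE)))
  power <- mean(sapply(1:40, function(s) run(5000 + s, TRUE)))
  expect_lte(size, 0.2)
  expect_gt(power, 0.5)
  expect_gt(power, size)
})

test_that("hausman degenerate and error cases", {
  pan <- random_small_panel(1100)$panel
  fe <- fit_spatial_panel(pan, "y", c("x1", "x2"),
                          random_small_panel(1100)$W, family = "FE",
                          effects = "individual")
  suppressWarnings(h0 <- hausman_test(fe, fe))
  expect_equal(h0$statistic, 0)
  re <- fit_random_effects(pan, "y", c("x1", "x2"))
  h <- suppressWarnings(hausman_test(fe, re))
  expect_equal(h$df, 2)
  expect_true(h$p >= 0 && h$p <= 1)
})

test_that("log transform demands positive data and is otherwise exact", {
  rp <- random_small_panel(1200)
  pan <- rp$panel
  pan$y <- exp(pan$y); pan$x1 <- exp(pan$x1); pan$x2 <- exp(pan$x2)
  f_log <- fit_spatial_panel(pan, "y", c("x1", "x2"), rp$W, family = "SDM",
                             log_transform = TRUE)
  f_raw <- fit_spatial_panel(rp$panel, "y", c("x1", "x2"), rp$W, family = "SDM")
  expect_equal(f_log$coefficients, f_raw$coefficients, tolerance = 1e-10)
  pan$x1[3] <- -1
  expect_error(fit_spatial_panel(pan, "y", c("x1", "x2"), rp$W, family = "SDM",
                                 log_transform = TRUE), "strictly positive")
})
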