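# Direct / indirect / total effect decomposition and its inference.

fake_fit <- function(coefs, rho, x_vars, family = "SDM", vcov = NULL, iv = c(-1.5, 1)) {
  structure(list(family = family, coefficients = coefs, rho = rho,
                 x_vars = x_vars, boundary = FALSE, interval = iv,
                 vcov = vcov), class = "spfit")
}

test_that("closed forms: rho = 0 and the SLM row-sum identity", {
  W <- row_standardize(weights_from_edges(path_map(4)))
  # SDM at rho = 0: direct = beta, indirect = theta (zero-diagonal W, rows sum 1)
  f <- fake_fit(c(x = 0.7, W.x = 0.3), rho = 0, x_vars = "x")
  e <- decompose_effects(f, W)
  expect_equal(e$direct, 0.7, tolerance = 1e-12)
  expect_equal(e$indirect, 0.3, tolerance = 1e-12)
  expect_equal(e$total, 1.0, tolerance = 1e-12)

  # SLM: total = beta / (1 - rho) on connected row-standardized W
  for (rho in c(-0.5, 0.2, 0.6)) {
    fs <- fake_fit(c(x = 1.3), rho = rho, x_vars = "x", family = "SLM")
    es <- decompose_effects(fs, W)
    expect_equal(es$total, 1.3 / (1 - rho), tolerance = 1e-10)
    expect_equal(es$total, es$direct + es$indirect, tolerance = 1e-14)
  }
})

test_that("4-node path decomposition matches the dense-inverse oracle", {
  W <- row_standardize(weights_from_edges(path_map(4)))
  f <- fake_fit(c(x = 1, W.x = 0.2), rho = 0.3, x_vars = "x")
  e <- decompose_effects(f, W)
  S <- solve(diag(4) - 0.3 * W$W) %*% (diag(4) * 1 + 0.2 * W$W)
  expect_equal(e$direct, mean(diag(S)), tolerance = 1e-12)
  expect_equal(e$total, mean(rowSums(S)), tolerance = 1e-12)
  expect_equal(e$indirect, mean(rowSums(S)) - mean(diag(S)), tolerance = 1e-12)
})

test_that("additivity holds to machine precision on random draws", {
  set.seed(61)
  W <- row_standardize(weights_from_edges(make_lattice_map(3, 3)))
  for (rep in 1:20) {
    f <- fake_fit(c(a = stats::rnorm(1), b = stats::rnorm(1),
                    W.a = stats::rnorm(1), W.b = stats::rnorm(1)),
                  rho = stats::runif(1, -0.5, 0.8), x_vars = c("a", "b"))
    e <- decompose_effects(f, W)
    expect_equal(e$total, e$direct + e$indirect, tolerance = 1e-14)
  }
})

test_that("noiseless DGP effects equal the analytic decomposition of truth", {
  map <- make_lattice_map(3, 3)
  W <- row_standardize(weights_from_edges(map))
  d <- dgp_config(n_regions = 9, n_years = 8, rho_true = 0.35,
                  beta_true = c(x = 1.1), theta_true = c(x = -0.4),
                  sigma2_true = 1e-12, fe_individual_sd = 0, fe_time_sd = 0, seed = 3)
  sim <- simulate_sdm_panel(map, d, covariate_spec = list(x = list(mean = 0, sd = 1)))
  f <- suppressWarnings(   # near-zero noise makes the information ill-scaled
    fit_spatial_panel(sim, "y", "x", W, family = "SDM", effects = "twoway"))
  e <- decompose_effects(f, W)
  S <- solve(diag(9) - 0.35 * W$W) %*% (diag(9) * 1.1 - 0.4 * W$W)
  expect_equal(e$direct, mean(diag(S)), tolerance = 1e-5)
  expect_equal(e$total, mean(rowSums(S)), tolerance = 1e-5)
})

test_that("simulation inference is seed-deterministic with sane limits", {
  rp <- random_small_panel(1300)
  f <- fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SDM")
  e1 <- effects_inference(f, rp$W, n_draws = 200, seed = 9)
  e2 <- effects_inference(f, rp$W, n_draws = 200, seed = 9)
  expect_identical(e1, e2)
  expect_true(all(e1$direct_se >= 0))
  expect_error(effects_inference(f, rp$W, n_draws = 50), "n_draws")

  # vanishing parameter uncertainty drives t to +/- infinity, sign-consistent
  ftiny <- f
  ftiny$vcov <- f$vcov * 1e-12
  et <- effects_inference(ftiny, rp$W, n_draws = 200, seed = 9)
  expect_true(all(abs(et$direct_t) > abs(e1$direct_t)))
  expect_equal(sign(et$direct_t), sign(et$direct))

  expect_error(decompose_effects(
    fit_spatial_panel(rp$panel, "y", rp$vars, rp$W, family = "SEM"), rp$W),
    "SLM/SDM")
})

test_that("effect confidence intervals cover the DGP truth", {
  map <- make_lattice_map(5, 6)
  W <- row_standardize(weights_from_edges(map))
  d <- dgp_config(n_regions = 30, n_years = 18, rho_true = 0.24,
                  beta_true = c(x = 0.58), theta_true = c(x = -0.12),
                  sigma2_true = 0.01, seed = 12)
  S <- solve(diag(30) - 0.24 * W$W) %*% (diag(30) * 0.58 - 0.12 * W$W)
  truth <- c(direct = mean(diag(S)), indirect = mean(rowSums(S)) - mean(diag(S)))
  nrep <- 60
  cov_d <- cov_i <- logical(nrep)
  for (i in seq_len(nrep)) {
    sim <- simulate_sdm_panel(map, d, covariate_spec = list(x = list(mean = 0, sd = 0.5)),
                              seed = 7000 + i)
    f <- fit_spatial_panel(sim, "y", "x", W, family = "SDM", effects = "twoway")
    e <- effects_inference(f, W, n_draws = 200, seed = i)
    cov_d[i] <- abs(e$direct - truth["direct"]) <= 1.96 * e$direct_se
    cov_i[i] <- abs(e$indirect - truth["indirect"]) <= 1.96 * e$indirect_se
  }
  expect_gte(mean(cov_d), 0.85)
  expect_gte(mean(cov_i), 0.85)
})

test_that("regional effect runs isolate failing subsets", {
  map <- make_lattice_map(4, 4)
  W <- row_standardize(weights_from_edges(map))
  d <- dgp_config(n_regions = 16, n_years = 8, beta_true = c(x = 0.5),
                  theta_true = c(x = 0.1), seed = 4)
  sim <- simulate_sdm_panel(map, d, covariate_spec = list(x = list(mean = 0, sd = 1)))
  # a scattered group with no internal adjacency must fail alone
  groups <- map$groups
  groups[] <- "a"
  groups[c("R01", "R16")] <- "b"   # opposite corners: islands after subsetting
  groups[c("R02", "R03", "R04", "R08")] <- "c"
  res <- suppressWarnings(
    regional_effects(sim, W, groups, "y", "x", n_draws = 150, seed = 2))
  expect_null(res$a$condition)
  expect_s3_class(res$a$effects, "effects_table")
  expect_match(res$b$condition, "island")
  expect_null(res$c$condition)
})
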