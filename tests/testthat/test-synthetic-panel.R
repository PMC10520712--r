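# Synthetic region maps and the SDM data-generating process.

test_that("lattice maps have the expected rook structure and groupings", {
  m <- make_lattice_map(2, 2)
  expect_length(m$region_ids, 4)
  expect_equal(nrow(m$edges), 4)            # rook edges of a 2x2 grid

  m2 <- make_lattice_map(5, 6)
  expect_length(m2$region_ids, 30)
  expect_equal(nrow(m2$edges), 49)          # rows*(cols-1) + cols*(rows-1)
  expect_setequal(names(m2$groups), m2$region_ids)
  expect_equal(unname(table(m2$groups)[c("east", "central", "west")]),
               c(10L, 10L, 10L), ignore_attr = TRUE)

  expect_error(make_lattice_map(1, 1), "degenerate")
  expect_error(region_map(c("a", "b"), data.frame(from = "a", to = "z")), "not in region set")
  expect_error(region_map(c("a", "b"), data.frame(from = "a", to = "a")), "self-loop")
})

test_that("noiseless DGP reduces to the closed-form solve", {
  m <- grid2()
  W <- row_standardize(weights_from_edges(m))$W

  # rho = 0, theta = 0: plain linear model, y = X beta exactly
  d0 <- dgp_config(n_regions = 4, n_years = 3, rho_true = 0,
                   beta_true = c(x = 2), theta_true = c(x = 0),
                   sigma2_true = 0, fe_individual_sd = 0, fe_time_sd = 0, seed = 5)
  s0 <- simulate_sdm_panel(m, d0, covariate_spec = list(x = list(mean = 1, sd = 1)))
  expect_equal(s0$y, 2 * s0$x, tolerance = 1e-12)

  # rho = 0.5 on the 2x2 grid: y = (I - 0.5 W)^-1 x, checked by direct solve
  d1 <- dgp_config(n_regions = 4, n_years = 2, rho_true = 0.5,
                   beta_true = c(x = 1), theta_true = c(x = 0),
                   sigma2_true = 0, fe_individual_sd = 0, fe_time_sd = 0, seed = 6)
  s1 <- simulate_sdm_panel(m, d1, covariate_spec = list(x = list(mean = 0, sd = 1)))
  X <- matrix(s1$x, 4); Y <- matrix(s1$y, 4)
  expect_equal(Y, solve(diag(4) - 0.5 * W) %*% X, tolerance = 1e-12,
               ignore_attr = TRUE)

  # general noiseless case: closed form (I - rho W)^-1 (X b + W X t) per year
  d2 <- dgp_config(n_regions = 4, n_years = 3, rho_true = 0.3,
                   beta_true = c(x = 1.5), theta_true = c(x = -0.4),
                   sigma2_true = 0, fe_individual_sd = 0, fe_time_sd = 0, seed = 7)
  s2 <- simulate_sdm_panel(m, d2, covariate_spec = list(x = list(mean = 0, sd = 1)))
  X <- matrix(s2$x, 4); Y <- matrix(s2$y, 4)
  for (t in 1:3) {
    expect_equal(Y[, t],
                 drop(solve(diag(4) - 0.3 * W, X[, t] * 1.5 - 0.4 * W %*% X[, t])),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("generator is seed-deterministic and guards stationarity", {
  m <- make_lattice_map(3, 3)
  d <- dgp_config(n_regions = 9, n_years = 4, beta_true = c(x = 1),
                  theta_true = c(x = 0.2), seed = 42)
  spec <- list(x = list(mean = 0, sd = 1))
  a <- simulate_sdm_panel(m, d, covariate_spec = spec)
  b <- simulate_sdm_panel(m, d, covariate_spec = spec)
  expect_identical(serialize(as.data.frame(a), NULL),
                   serialize(as.data.frame(b), NULL))

  dbad <- dgp_config(n_regions = 9, n_years = 4, rho_true = 1.2,
                     beta_true = c(x = 1), theta_true = c(x = 0), seed = 1)
  expect_error(simulate_sdm_panel(m, dbad, covariate_spec = spec), "stationarity")
  expect_error(dgp_config(n_regions = 3), "n_regions")
  expect_error(dgp_config(n_years = 1), "n_years")

  # fixed effects held across replications when redraw_fe = FALSE
  dfix <- dgp_config(n_regions = 9, n_years = 4, beta_true = c(x = 1),
                     theta_true = c(x = 0), seed = 9, redraw_fe = FALSE)
  f1 <- attr(simulate_sdm_panel(m, dfix, covariate_spec = spec, seed = 101), "truth")$fe
  f2 <- attr(simulate_sdm_panel(m, dfix, covariate_spec = spec, seed = 202), "truth")$fe
  expect_identical(f1, f2)
})

test_that("indicator tables respect declared ranges and are reproducible", {
  m <- make_lattice_map(5, 6)
  tb <- simulate_indicator_tables(m, n_years = 18, seed = 3)
  h <- tb$health
  expect_true(all(h$life_expectancy >= 65 & h$life_expectancy <= 85))
  expect_true(all(h$perinatal_mortality >= 1.8 & h$perinatal_mortality <= 25))
  expect_true(all(h$maternal_mortality >= 1 & h$maternal_mortality <= 161))
  expect_true(all(tb$industry$employment > 0))
  expect_true(all(tb$industry$investment > 0))
  expect_true(all(tb$industry$output > 0))
  expect_setequal(unique(tb$industry$industry), c("H0", sprintf("H%d", 1:12)))

  tb2 <- simulate_indicator_tables(m, n_years = 18, seed = 3)
  expect_identical(serialize(tb$health, NULL), serialize(tb2$health, NULL))
  expect_identical(serialize(tb$industry, NULL), serialize(tb2$industry, NULL))
  expect_error(simulate_indicator_tables(m, n_years = 1), "n_years")
})
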