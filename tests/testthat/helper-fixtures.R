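# Shared fixtures and independent oracles, all built in code.

path_map <- function(n = 4) {
  ids <- as.character(seq_len(n))
  region_map(ids, data.frame(from = ids[-n], to = ids[-1]))
}

grid2 <- function() make_lattice_map(2, 2)

# Independent O(n^2) brute-force Moran's I: explicit double loop over all
# ordered pairs, no matrix algebra shared with the implementation.
moran_brute <- function(x, w) {
  n <- length(x)
  xb <- sum(x) / n
  s2 <- sum((x - xb)^2) / n
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
    }
  }
  num / (s2 * sum(w))
}

local_moran_brute <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  s2 <- sum((x - xb)^2) / n
  sapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + w[i, j] * (x[j] - xb)
    (x[i] - xb) / s2 * acc
  })
}

# Random connected-ish symmetric binary weights for small n (retry until no
# island).
random_binary_w <- function(n, p = 0.45) {
  repeat {
    w <- matrix(0, n, n)
    up <- which(upper.tri(w))
    w[up] <- stats::rbinom(length(up), 1, p)
    w <- w + t(w)
    if (all(rowSums(w) > 0)) return(w)
  }
}

# Small random panel + weights for estimator stress tests.
random_small_panel <- function(seed, n_side = 3, Tt = 5, k = 2) {
  set.seed(seed)
  map <- make_lattice_map(n_side, n_side)
  vars <- paste0("x", seq_len(k))
  dg <- dgp_config(n_regions = n_side^2, n_years = Tt,
                   rho_true = stats::runif(1, -0.3, 0.6),
                   beta_true = stats::setNames(stats::rnorm(k), vars),
                   theta_true = stats::setNames(stats::rnorm(k, 0, 0.3), vars),
                   sigma2_true = 0.05, fe_individual_sd = 0.2, fe_time_sd = 0.1,
                   seed = seed)
  spec <- stats::setNames(rep(list(list(mean = 0, sd = 1)), k), vars)
  panel <- simulate_sdm_panel(map, dg, covariate_spec = spec)
  list(map = map, dgp = dg, panel = panel, vars = vars,
       W = row_standardize(weights_from_edges(map)))
}
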