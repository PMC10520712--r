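#' Study configuration
#'
#' One object drives the whole pipeline: either a synthetic mode (a
#' [dgp_config()] plus a [region_map()], so every downstream stage runs on
#' generated data with known truth) or a data mode (in-memory tables or CSV
#' paths for health indicators, industry input/output tables, covariates and
#' an adjacency edge list).
#'
#' @param map a [region_map()] (synthetic mode default: 5 x 6 rook lattice,
#'   30 regions).
#' @param dgp a [dgp_config()] for synthetic mode, or `NULL` for data mode.
#' @param data for data mode, a list with elements `health`
#'   (region/year/indicator data.frame or CSV path), `industry`, `covariates`
#'   (region/year/covariate levels), and optionally `edges` when `map` is not
#'   given.
#' @param y_var outcome column name used in models (default `"health"`).
#' @param x_vars model covariate columns, as level variables; all model
#'   variables are natural-logged inside the fits. Default the convergence
#'   degree plus the five controls.
#' @param indicator_specs specs for the health index (default
#'   [health_indicator_specs()]).
#' @param focal,partners focal industry and partner labels (`NULL` partners =
#'   all others present).
#' @param alpha coupling contribution weight.
#' @param synthesis `"entropy"` or `"mean"` HICD synthesis.
#' @param effects fixed-effects mode for all model fits.
#' @param n_draws Monte-Carlo draws for effect inference.
#' @param seed master seed; all stage seeds derive from it.
#' @param years year labels of the panel.
#' @return list of class `study_config`.
#' @export
study_config <- function(map = make_lattice_map(5, 6),
                         dgp = dgp_config(),
                         data = NULL,
                         y_var = "health",
                         x_vars = c("HICD", "Age", "Edu", "RGDP", "URB", "GOV"),
                         indicator_specs = health_indicator_specs(),
                         focal = "H0", partners = NULL,
                         alpha = 0.5, synthesis = "entropy",
                         effects = "twoway", n_draws = 1000L, seed = 20020L,
                         years = NULL) {
  if (is.null(dgp) && is.null(data)) stop_gc("exactly one of dgp / data must be given")
  if (!is.null(dgp) && !is.null(data)) stop_gc("exactly one of dgp / data must be given")
  if (!is.null(dgp)) {
    stopifnot(inherits(dgp, "dgp_config"))
    years <- years %||% (2001L + seq_len(dgp$n_years))
    if (length(map$region_ids) != dgp$n_regions) {
      stop_gc("map regions (%d) and dgp n_regions (%d) disagree",
              length(map$region_ids), dgp$n_regions)
    }
  }
  structure(list(map = map, dgp = dgp, data = data, y_var = y_var,
                 x_vars = x_vars, indicator_specs = indicator_specs,
                 focal = focal, partners = partners, alpha = alpha,
                 synthesis = synthesis, effects = effects,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 years = years),
            class = "study_config")
}

#' Descriptive statistics table
#'
#' Mean, sample (n-1) standard deviation, min and max per variable, with
#' units when supplied.
#'
#' @param panel data.frame; the `region`/`year` columns are ignored.
#' @param vars variables to summarize (default all numeric, non-key columns).
#' @param units optional named character vector of units.
#' @return data.frame with columns `variable`, `unit`, `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
descriptive_stats <- function(panel, vars = NULL, units = NULL) {
  if (!nrow(panel)) stop_gc("empty panel")
  vars <- vars %||% setdiff(names(panel)[vapply(panel, is.numeric, logical(1L))],
                            c("region", "year"))
  rows <- lapply(vars, function(v) {
    x <- panel[[v]]
    data.frame(variable = v,
               unit = unname(units[v] %||% NA_character_),
               mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               min = min(x), max = max(x), n = length(x))
  })
  do.call(rbind, rows)
}

read_or_df <- function(x) {
  if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
}

#' Run the full convergence-and-health study
#'
#' Executes the stages in order: composite health index construction,
#' industry convergence scoring, variable merge, yearly Moran diagnostics,
#' model fits (FE, SLM, SEM, SDM), LR / Hausman specification tests, national
#' effect decomposition, and regional effect decomposition. A failing later
#' stage is recorded in `errors` and leaves earlier outputs intact. The
#' entire run is deterministic under the configured seed.
#'
#' In synthetic mode the health outcome is generated from the known
#' spatial-Durbin process using the convergence degree computed from the
#' simulated industry tables plus simulated log-scale controls, so estimated
#' coefficients can be compared with the generator's truth.
#'
#' @param config a [study_config()].
#' @return object of class `study_report`: list with `descriptives`,
#'   `moran`, `model_comparison`, `fits`, `tests`, `effects_national`,
#'   `effects_regional`, `convergence` tables, `panel`, `weights`,
#'   `metadata`, `errors`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  report <- list(errors = list())
  t0 <- proc.time()[["elapsed"]]
  decisions <- c(
    "index standardization scope: per_year (pooled available)",
    "entropy weighting pooled over all region-years; 0*ln0 := 0, no shift",
    "coupling degree: two-system C = 2*sqrt(U1*U2)/(U1+U2), alpha = 0.5 default",
    sprintf("HICD synthesis: %s weighting of pairwise degrees", config$synthesis),
    "Moran's I on raw binary adjacency W; randomization inference, one-sided",
    "models on row-standardized W; effective-dimension (bias-corrected) ML",
    "descriptive sd convention: sample (n-1)",
    "variable merge: inner join on (region, year), dropped keys logged")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  map <- config$map
  Wb <- weights_from_edges(map)
  Wr <- suppressWarnings(row_standardize(Wb))
  synthetic <- !is.null(config$dgp)
  seed <- config$seed

  # --- stage: input tables ------------------------------------------------
  if (synthetic) {
    tables <- simulate_indicator_tables(map, config$dgp$n_years,
                                        seed = seed + 1L,
                                        years = config$years)
    health_raw <- tables$health
    industry <- tables$industry
  } else {
    health_raw <- read_or_df(config$data$health)
    industry <- read_or_df(config$data$industry)
  }

  # --- stage: composite health index -------------------------------------
  index <- stage("index", {
    std <- standardize_indicators(health_raw, config$indicator_specs, scope = "per_year")
    w <- entropy_weights(std)
    list(std = std, weights = w, index = composite_index(std, w))
  })

  # --- stage: convergence -------------------------------------------------
  convergence <- stage("convergence", {
    convergence_degrees(industry, focal = config$focal,
                        partners = config$partners, alpha = config$alpha,
                        synthesis = config$synthesis)
  })

  # --- stage: merge / outcome construction --------------------------------
  panel <- stage("merge", {
    if (is.null(convergence)) stop_gc("convergence stage failed upstream")
    hicd <- convergence$hicd
    if (any(hicd$hicd <= 0)) {
      stop_gc("nonpositive convergence degree; cannot log-transform")
    }
    if (synthetic) {
      # the outcome is generated on the log scale from the known SDM process,
      # with ln(HICD) taken from the convergence stage and the controls drawn
      # on the log scale; the panel stores level variables, which the model
      # stage logs back — so estimated coefficients are comparable to truth
      dgp <- config$dgp
      n <- length(map$region_ids); Tt <- dgp$n_years
      cov_spec <- default_covariate_spec(include_hicd = FALSE)
      extra <- setdiff(config$x_vars, c("HICD", names(cov_spec)))
      if (length(extra)) stop_gc("no covariate spec for: %s", paste(extra, collapse = ", "))
      set.seed((seed + 2L) %% .Machine$integer.max)
      Xmats <- lapply(cov_spec[setdiff(config$x_vars, "HICD")],
                      draw_covariate, n = n, Tt = Tt, Wm = Wr$W)
      hm <- panel_matrices(transform(hicd, lnHICD = log(hicd)), "lnHICD",
                           region_order = map$region_ids)
      Xmats <- c(list(HICD = hm$lnHICD), Xmats)[config$x_vars]
      dgp2 <- dgp
      names(dgp2$beta_true) <- names(dgp2$theta_true) <- names(dgp$beta_true)
      sim <- simulate_sdm_panel(map, dgp2, X = Xmats, seed = seed + 3L,
                                years = config$years, y_name = "lnHealth")
      out <- sim[c("region", "year")]
      for (v in config$x_vars) out[[v]] <- exp(sim[[v]])
      out[[config$y_var]] <- exp(sim$lnHealth)
      out
    } else {
      cov <- read_or_df(config$data$covariates)
      idx <- index$index
      m1 <- merge(idx, hicd, by = c("region", "year"))
      merged <- merge(m1, cov, by = c("region", "year"))
      if (nrow(merged) < nrow(idx)) {
        warn_gc("inner join dropped %d region-year row(s)", nrow(idx) - nrow(merged))
      }
      if (!"HICD" %in% names(merged)) merged$HICD <- merged$hicd
      absent <- setdiff(config$x_vars, names(merged))
      if (length(absent)) stop_gc("model covariate(s) not found after merge: %s",
                                  paste(absent, collapse = ", "))
      merged
    }
  })

  # --- stage: descriptives ------------------------------------------------
  descr <- stage("descriptives", {
    units <- c(health = "index",
               life_expectancy = "years", perinatal_mortality = "per 1,000 births",
               maternal_mortality = "per 100,000 live births",
               hicd = "index [0,1]", HICD = "index [0,1]",
               Age = "% aged 65+", Edu = "years", RGDP = "yuan per person",
               URB = "% urban", GOV = "% of budget")
    parts <- list()
    if (!is.null(index)) {
      parts$health_ind <- merge(index$index, health_raw, by = c("region", "year"))
    }
    main <- if (!is.null(panel)) panel else parts$health_ind
    if (!is.null(convergence) && !("HICD" %in% names(main %||% data.frame()))) {
      parts$hicd <- convergence$hicd
    }
    tabs <- c(
      if (!is.null(main)) list(descriptive_stats(main, units = units)),
      if (!is.null(parts$health_ind))
        list(descriptive_stats(parts$health_ind,
                               vars = c("health", "life_expectancy",
                                        "perinatal_mortality", "maternal_mortality"),
                               units = units)),
      if (!is.null(parts$hicd)) list(descriptive_stats(parts$hicd, vars = "hicd", units = units)))
    out <- do.call(rbind, tabs)
    out[!duplicated(out$variable), , drop = FALSE]
  })

  # --- stage: Moran diagnostics ------------------------------------------
  moran <- stage("moran", {
    if (is.null(panel)) stop_gc("merge stage failed upstream")
    moran_by_year(panel, config$y_var, Wb)
  })

  # --- stage: model fits --------------------------------------------------
  fits <- stage("fits", {
    if (is.null(panel)) stop_gc("merge stage failed upstream")
    fams <- c("FE", "SLM", "SEM", "SDM")
    out <- lapply(fams, function(f) {
      fit_spatial_panel(panel, config$y_var, config$x_vars, Wr, family = f,
                        effects = config$effects, log_transform = TRUE)
    })
    names(out) <- fams
    out
  })

  model_comparison <- stage("model_comparison", {
    if (is.null(fits)) stop_gc("fits stage failed upstream")
    rows <- lapply(names(fits), function(f) {
      ct <- fits[[f]]$coef_table
      ct$model <- f
      ct
    })
    tab <- do.call(rbind, rows)[, c("model", "term", "estimate", "se", "t", "p")]
    gof <- do.call(rbind, lapply(names(fits), function(f) {
      data.frame(model = f, term = c("log-likelihood", "R2_naive", "R2_within", "sigma2"),
                 estimate = c(fits[[f]]$loglik, fits[[f]]$r2_naive,
                              fits[[f]]$r2_within, fits[[f]]$sigma2),
                 se = NA_real_, t = NA_real_, p = NA_real_)
    }))
    rbind(tab, gof)
  })

  # --- stage: specification tests ----------------------------------------
  tests <- stage("tests", {
    if (is.null(fits)) stop_gc("fits stage failed upstream")
    k <- length(config$x_vars)
    res <- list(
      lr_test(fits$SDM, fits$SLM, df = k),
      lr_test(fits$SDM, fits$SEM, df = k))
    pooled <- tryCatch(
      fit_spatial_panel(panel, config$y_var, config$x_vars, Wr, family = "SDM",
                        effects = "none", log_transform = TRUE),
      error = function(e) NULL)
    if (!is.null(pooled)) res <- c(res, list(lr_test(fits$SDM, pooled)))
    fe_ns <- fit_spatial_panel(panel, config$y_var, config$x_vars, Wr,
                               family = "FE", effects = "individual",
                               log_transform = TRUE)
    re_ns <- fit_random_effects(panel, config$y_var, config$x_vars,
                                log_transform = TRUE)
    res <- c(res, list(hausman_test(fe_ns, re_ns)))
    do.call(rbind, res)
  })

  # --- stage: national effects -------------------------------------------
  effects_national <- stage("effects_national", {
    if (is.null(fits)) stop_gc("fits stage failed upstream")
    effects_inference(fits$SDM, Wr, n_draws = config$n_draws, seed = seed + 4L)
  })

  # --- stage: regional effects -------------------------------------------
  effects_regional <- stage("effects_regional", {
    if (is.null(panel)) stop_gc("merge stage failed upstream")
    regional_effects(panel, Wr, map$groups, config$y_var, config$x_vars,
                     family = "SDM", effects = config$effects,
                     log_transform = TRUE, n_draws = config$n_draws,
                     seed = seed + 5L)
  })

  meta <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("geoconverge")),
    mode = if (synthetic) "synthetic" else "data",
    n_regions = length(map$region_ids),
    n_years = length(unique(if (!is.null(panel)) panel$year else config$years)),
    effects = config$effects, n_draws = config$n_draws,
    decisions = decisions,
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 2))
  if (synthetic) {
    meta$dgp_truth <- list(rho = config$dgp$rho_true,
                           beta = as.list(config$dgp$beta_true),
                           theta = as.list(config$dgp$theta_true),
                           sigma2 = config$dgp$sigma2_true)
  }

  structure(list(
    descriptives = descr, moran = moran, model_comparison = model_comparison,
    fits = fits, tests = tests, effects_national = effects_national,
    effects_regional = effects_regional,
    convergence = list(
      pairwise_means = if (!is.null(convergence)) pairwise_mean_table(convergence),
      hicd = if (!is.null(convergence)) hicd_table(convergence),
      synthesis_weights = if (!is.null(convergence)) convergence$synthesis_weights),
    index_weights = if (!is.null(index)) index$weights,
    panel = panel, weights = list(binary = Wb, standardized = Wr),
    metadata = meta, errors = report$errors
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", x$metadata$mode, "mode,",
      x$metadata$n_regions, "regions x", x$metadata$n_years, "years\n")
  ok <- c("descriptives", "moran", "model_comparison", "tests",
          "effects_national", "effects_regional")
  for (s in ok) cat(sprintf("  %-18s %s\n", s,
                            if (is.null(x[[s]])) "FAILED" else "ok"))
  if (length(x$errors)) {
    cat("errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

# Flatten one regional-effects entry into a data.frame block.
regional_effects_table <- function(effects_regional) {
  rows <- lapply(names(effects_regional), function(g) {
    e <- effects_regional[[g]]
    if (!is.null(e$condition)) {
      return(data.frame(group = g, term = NA_character_, error = e$condition))
    }
    cbind(data.frame(group = g), as.data.frame(e$effects))
  })
  do.call(rbind, lapply(rows, function(r) {
    # align columns across failed/ok groups
    r
  }))
}

#' Write a study report's tables to a directory
#'
#' Emits deterministic CSVs (descriptives, yearly Moran, model comparison,
#' specification tests, national and regional effects, convergence tables)
#' plus a `metadata.json` run record. Only `metadata.json` contains timing,
#' so the table files are byte-identical across same-seed reruns.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(obj, name) {
    if (is.null(obj)) return()
    path <- file.path(dir, name)
    utils::write.csv(format(as.data.frame(obj), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit(report$descriptives, "descriptives.csv")
  emit(report$moran, "moran_by_year.csv")
  emit(report$model_comparison, "model_comparison.csv")
  emit(report$tests, "tests.csv")
  emit(report$effects_national, "effects_national.csv")
  if (!is.null(report$effects_regional)) {
    ok <- !vapply(report$effects_regional, function(e) is.null(e$effects), logical(1L))
    if (any(ok)) {
      tab <- do.call(rbind, lapply(names(report$effects_regional)[ok], function(g) {
        cbind(data.frame(group = g), as.data.frame(report$effects_regional[[g]]$effects))
      }))
      emit(tab, "effects_regional.csv")
    }
  }
  emit(report$convergence$pairwise_means, "convergence_pairwise.csv")
  emit(report$convergence$hicd, "hicd_by_year.csv")
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(report$metadata, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(files, meta_path))
}
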