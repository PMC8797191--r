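# Tiny FNV-1a hash of an R object's deparsed form, for cache keys.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Experiment configuration
#'
#' Desk-scale defaults keep every preset runnable on one CPU in minutes;
#' `paper_scale = TRUE` switches to the production problem sizes (20000
#' trials, 25 us / 1 um grids) intended for cluster execution.
#'
#' @param preset Preset name; see [run_experiment()].
#' @param overrides Named list of parameter overrides (e.g. `x_na`, `ka`,
#'   `gbar_mult`, `tau`, `ra`, `soma_size`, `reset_voltage`).
#' @param scale Named list overriding the scale defaults (`n_trials`, `dt`,
#'   `dx`, `soma_dx`, `n_surrogates`, `n_resamples`, `pilot_duration`,
#'   `verify_duration`).
#' @param seed Root seed; every random stage derives its seed from it.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param paper_scale Use production problem sizes.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(preset, overrides = list(), scale = list(),
                              seed = 1, out_dir = NULL,
                              paper_scale = FALSE) {
  base <- if (paper_scale) {
    list(n_trials = 20000, dt = 0.025, dx = 1, soma_dx = 1,
         n_surrogates = 500, n_resamples = 1000,
         pilot_duration = 200000, verify_duration = 500000)
  } else {
    list(n_trials = 60, dt = 0.05, dx = 2, soma_dx = 5,
         n_surrogates = 200, n_resamples = 400,
         pilot_duration = 60000, verify_duration = 150000)
  }
  base[names(scale)] <- scale
  structure(list(preset = preset, overrides = overrides, scale = base,
                 seed = seed, out_dir = out_dir,
                 paper_scale = paper_scale),
            class = "experiment_config")
}

# Apply named overrides to the three spec records.
apply_overrides <- function(morph, passive, sodium, ov) {
  if (!is.null(ov$x_na)) morph$x_na <- ov$x_na
  if (!is.null(ov$soma_size)) {
    morph$soma_diameter <- ov$soma_size
    morph$soma_length <- ov$soma_size
    if (ov$soma_size > 1000) morph$soma_dx <- ov$soma_size / 20
  }
  if (!is.null(ov$ra)) passive$axial_resistivity <- ov$ra
  if (!is.null(ov$ka)) sodium$slope <- ov$ka
  if (!is.null(ov$gbar_mult))
    sodium$peak_conductance <- sodium$peak_conductance * ov$gbar_mult
  list(morph = do.call(morphology_spec, unclass(morph)),
       passive = do.call(passive_spec, unclass(passive)),
       sodium = do.call(sodium_spec, unclass(sodium)))
}

# Calibrate one model condition and run the gain pipeline; results cached
# by a hash of (condition, scale, seed) when cache_dir is given.
condition_gain <- function(ov, tau, wp, scale, seed, cache_dir = NULL) {
  key <- config_hash(list(ov, tau, unclass(wp), scale, seed))
  if (!is.null(cache_dir)) {
    fp <- file.path(cache_dir, paste0(key, ".rds"))
    if (file.exists(fp)) return(readRDS(fp))
  }
  sp <- apply_overrides(morphology_spec(dx = scale$dx,
                                        soma_dx = scale$soma_dx),
                        passive_spec(), sodium_spec(), ov)
  cell <- build_cell(sp$morph, sp$passive, sp$sodium)
  rv <- ov$reset_voltage %||% sp$passive$leak_reversal
  cal <- calibrate_thresholds(cell, target_rate = wp$target_rate,
                              dt = scale$dt, reset_voltage = rv)
  op <- find_operating_point(cell, cal$policy, wp, tau = tau, dt = scale$dt,
                             seed = mix_seed(seed, 17),
                             pilot_duration = scale$pilot_duration,
                             verify_duration = scale$verify_duration)
  cfg <- gain_config(n_trials = scale$n_trials, dt = scale$dt,
                     n_surrogates = scale$n_surrogates,
                     n_resamples = scale$n_resamples)
  curve <- run_gain_pipeline(cell, cal$policy, op$mu, op$sigma, tau,
                             config = cfg, seed = mix_seed(seed, 29))
  out <- list(curve = curve, op = op, cal = cal, cell = cell,
              overrides = ov, tau = tau)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(out, file.path(cache_dir, paste0(key, ".rds")))
  }
  out
}

#' Cutoff-frequency surface over a two-parameter grid
#'
#' For each grid point the model is rebuilt, thresholds recalibrated, the
#' operating point re-found (fixed rate and CV, or fixed rate and stimulus
#' standard deviation), the gain pipeline run and the factor-2 cutoff
#' extracted. Per-point failures are flagged, not fatal; no interpolation is
#' applied to the stored grid.
#'
#' @param axis1,axis2 Lists `list(name = , values = )`; names as in the
#'   `overrides` of [experiment_config()] plus `"tau"`.
#' @param wp A [working_point()].
#' @param tau OU correlation time (ms) unless scanned by an axis.
#' @param scale Scale list as in [experiment_config()].
#' @param seed Root seed.
#' @param cache_dir Optional cache directory.
#' @return An object of class `cutoff_surface` with `axis1`, `axis2`,
#'   `cutoff` (matrix, Hz) and `ok` (logical matrix).
#' @export
cutoff_surface <- function(axis1, axis2, wp = working_point(), tau = 5,
                           scale = experiment_config("x")$scale, seed = 1,
                           cache_dir = NULL) {
  n1 <- length(axis1$values)
  n2 <- length(axis2$values)
  cutoff <- matrix(NA_real_, n1, n2)
  ok <- matrix(FALSE, n1, n2)
  details <- vector("list", n1 * n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    ov <- list()
    tau_ij <- tau
    for (ax in list(list(a = axis1, v = axis1$values[i]),
                    list(a = axis2, v = axis2$values[j]))) {
      if (ax$a$name == "tau") tau_ij <- ax$v else ov[[ax$a$name]] <- ax$v
    }
    res <- tryCatch(
      condition_gain(ov, tau_ij, wp, scale, mix_seed(seed, i * 211 + j),
                     cache_dir = cache_dir),
      error = function(e) e)
    k <- (i - 1) * n2 + j
    if (inherits(res, "error")) {
      details[[k]] <- conditionMessage(res)
    } else {
      cutoff[i, j] <- res$curve$cutoff_frequency
      ok[i, j] <- TRUE
      details[[k]] <- list(op = res$op[c("mu", "sigma", "rate", "cv")],
                           cutoff = res$curve$cutoff_frequency)
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, cutoff = cutoff, ok = ok,
                 wp = wp, tau = tau, details = details),
            class = "cutoff_surface")
}

#' Run a figure-level experiment preset
#'
#' Presets reproduce the study's figure-level computations at configurable
#' (desk-scale by default) trial counts:
#' \describe{
#'   \item{`fig1`}{Steady-state bifurcation analysis: equilibrium branches
#'     over `x_na`, critical distance, voltage-clamp sweep and discontinuity
#'     at `x_na = 40`, current-clamp ramp comparison.}
#'   \item{`fig2`}{Dynamic gain versus sodium position (`x_na` list).}
#'   \item{`fig3`}{Axonal phase plots and soma-to-axon transfer impedance
#'     versus `x_na`.}
#'   \item{`fig4`}{F-I curves and gain for sodium conductance multipliers
#'     (with the -90 mV reset variant).}
#'   \item{`fig6`}{Gain versus input correlation time (`tau` 5 vs 50 ms).}
#'   \item{`fig7`}{Current-clamp decoupling and gain for standard versus
#'     steep sodium activation (`ka` 6 vs 0.1 mV).}
#'   \item{`fig9`}{Cutoff surface over `ka` and `gbar_mult`.}
#'   \item{`fig10`}{Gain versus soma size.}
#' }
#' All seeds derive from the config's root seed, so reruns with the same
#' config reproduce identical outputs; gain conditions are cached under
#' `out_dir/cache` when an output directory is set.
#'
#' @param config An [experiment_config()].
#' @return A named list of outputs (invisible when written to disk).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cache_dir <- if (!is.null(config$out_dir))
    file.path(config$out_dir, "cache")
  runner <- switch(config$preset,
    fig1 = preset_fig1, fig2 = preset_gain_scan, fig3 = preset_fig3,
    fig4 = preset_fig4, fig6 = preset_fig6, fig7 = preset_fig7,
    fig9 = preset_fig9, fig10 = preset_fig10,
    stop("unknown preset: ", config$preset))
  bundle <- runner(config, cache_dir)
  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  invisible(bundle)
}

preset_fig1 <- function(config, cache_dir) {
  ov <- config$overrides
  scan <- bifurcation_scan(x_na_values = ov$x_na %||% seq(10, 60, by = 5))
  cell40 <- build_cell(morphology_spec(x_na = 40))
  sweep <- vclamp_sweep(cell40, seq(-60, -50, by = 0.25))
  ramp <- slow_ramp(0, 0.05, 4000, dt = 0.05)
  cc <- cclamp_ramp(build_cell(morphology_spec(x_na = 40, dx = 2,
                                               soma_dx = 5)),
                    ramp, detection_threshold = -30)
  list(branches = scan$branches,
       summary = list(critical_distance_um = scan$critical_distance,
                      jump_voltage_mv = sweep_jump_voltage(sweep)),
       vclamp = sweep, cclamp = cc)
}

gain_scan <- function(config, cache_dir, conditions, taus = NULL) {
  out <- list()
  for (k in seq_along(conditions)) {
    ov <- conditions[[k]]
    tau <- if (is.null(taus)) config$overrides$tau %||% 5 else taus[[k]]
    res <- condition_gain(ov, tau, working_point(), config$scale,
                          mix_seed(config$seed, k), cache_dir)
    nm <- paste0(names(conditions)[k] %||% paste0("cond", k))
    out[[nm]] <- res
  }
  out
}

preset_gain_scan <- function(config, cache_dir) {
  xs <- config$overrides$x_na %||% c(0, 20, 40)
  conds <- lapply(xs, function(x) list(x_na = x))
  names(conds) <- paste0("x_na_", xs)
  res <- gain_scan(config, cache_dir, conds)
  list(curves = lapply(res, function(r) as.data.frame(r$curve)),
       summary = list(cutoffs = lapply(res, function(r)
         r$curve$cutoff_frequency)))
}

preset_fig3 <- function(config, cache_dir) {
  xs <- config$overrides$x_na %||% c(20, 40, 80)
  cell_dense <- function(x) build_cell(morphology_spec(
    x_na = x, dx = config$scale$dx, soma_dx = config$scale$soma_dx))
  phase <- list()
  imped <- list()
  for (x in xs) {
    cell <- cell_dense(x)
    cal <- calibrate_thresholds(cell, dt = config$scale$dt)
    phase[[paste0("x_na_", x)]] <-
      ap_phase_plot(cell, cal$policy, cal$pilot_current,
                    dt = config$scale$dt)
    pcell <- build_cell(morphology_spec(x_na = x, dx = config$scale$dx,
                                        soma_dx = config$scale$soma_dx),
                        sodium = sodium_spec(peak_conductance = 0))
    imped[[paste0("x_na_", x)]] <- transfer_impedance_sine(
      pcell, c(1, 2, 5, 10, 20, 50, 100, 200, 500), probe = max(x, 1),
      dt = config$scale$dt)
  }
  list(phase_plots = phase, impedance = imped)
}

preset_fig4 <- function(config, cache_dir) {
  mults <- config$overrides$gbar_mult %||% c(1, 5, 10)
  fi <- list()
  for (g in mults) {
    sp <- apply_overrides(morphology_spec(x_na = 40, dx = config$scale$dx,
                                          soma_dx = config$scale$soma_dx),
                          passive_spec(), sodium_spec(),
                          list(gbar_mult = g))
    cell <- build_cell(sp$morph, sp$passive, sp$sodium)
    cal <- calibrate_thresholds(cell, dt = config$scale$dt,
                                reset_voltage = -90)
    mus <- cal$pilot_current * seq(0.6, 1.8, by = 0.2)
    fi[[paste0("gbar_", g)]] <- fi_curve(cell, cal$policy, mus,
                                         dt = config$scale$dt)
  }
  list(fi_curves = fi)
}

preset_fig6 <- function(config, cache_dir) {
  xs <- config$overrides$x_na %||% 40
  conds <- list()
  taus <- list()
  for (x in xs) for (tau in c(5, 50)) {
    conds[[paste0("x_na_", x, "_tau_", tau)]] <- list(x_na = x)
    taus[[paste0("x_na_", x, "_tau_", tau)]] <- tau
  }
  res <- gain_scan(config, cache_dir, conds, taus)
  list(curves = lapply(res, function(r) as.data.frame(r$curve)))
}

preset_fig7 <- function(config, cache_dir) {
  kas <- config$overrides$ka %||% c(6, 0.1)
  dec <- list()
  for (ka in kas) {
    sp <- apply_overrides(morphology_spec(x_na = 40, dx = config$scale$dx,
                                          soma_dx = config$scale$soma_dx),
                          passive_spec(), sodium_spec(), list(ka = ka))
    cell <- build_cell(sp$morph, sp$passive, sp$sodium)
    ramp <- slow_ramp(0, 0.05, 4000, dt = config$scale$dt)
    dec[[paste0("ka_", ka)]] <- cclamp_ramp(cell, ramp,
                                            detection_threshold = -20)
  }
  conds <- lapply(kas, function(k) list(ka = k))
  names(conds) <- paste0("ka_", kas)
  res <- gain_scan(config, cache_dir, conds)
  list(decoupling = dec,
       curves = lapply(res, function(r) as.data.frame(r$curve)))
}

preset_fig9 <- function(config, cache_dir) {
  cutoff_surface(
    axis1 = list(name = "ka",
                 values = config$overrides$ka %||% c(0.1, 1, 6)),
    axis2 = list(name = "gbar_mult",
                 values = config$overrides$gbar_mult %||% c(1, 5, 20)),
    tau = config$overrides$tau %||% 50, scale = config$scale,
    seed = config$seed, cache_dir = cache_dir)
}

preset_fig10 <- function(config, cache_dir) {
  sizes <- config$overrides$soma_size %||% c(50, 200)
  conds <- lapply(sizes, function(s) list(soma_size = s))
  names(conds) <- paste0("soma_", sizes)
  res <- gain_scan(config, cache_dir, conds)
  list(curves = lapply(res, function(r) as.data.frame(r$curve)))
}

# Write a bundle's data.frames as CSV and everything scalar as JSON.
write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(x, prefix) {
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(config$out_dir,
                                    paste0(prefix, ".csv")),
                       row.names = FALSE)
      return(NULL)
    }
    if (is.list(x) && !is.null(names(x))) {
      kept <- lapply(names(x), function(nm)
        flat(x[[nm]], paste0(prefix, "_", nm)))
      names(kept) <- names(x)
      kept <- kept[!vapply(kept, is.null, TRUE)]
      if (length(kept)) return(kept)
      return(NULL)
    }
    x
  }
  summary <- flat(bundle, config$preset)
  jsonlite::write_json(
    list(preset = config$preset, seed = config$seed,
         overrides = config$overrides, scale = config$scale,
         config_hash = config_hash(unclass(config)), summary = summary),
    file.path(config$out_dir, paste0(config$preset, "_summary.json")),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(NULL)
}

#' Write spike trains to CSV
#'
#' @param spikes A list of [spike_train()] objects.
#' @param path Output CSV path (`trial_id`, `spike_time_ms`).
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(spikes, path) {
  df <- do.call(rbind, lapply(seq_along(spikes), function(i)
    data.frame(trial_id = rep(i, length(spikes[[i]]$spike_times)),
               spike_time_ms = spikes[[i]]$spike_times)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
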