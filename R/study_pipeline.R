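#' Run a complete synthetic cutting study end to end
#'
#' Generates a worker population, simulates two-pass force traces for
#' every worker on every substrate (material x thickness), processes the
#' traces through steady-state detection and pass decomposition, joins the
#' blade geometry, computes model predictions and normalized forces, fits
#' the allometric scalings and the parameter-recovery regression, and
#' returns tidy tables mirroring the structure of the study's results.
#'
#' Sheet thickness and (optionally) the trial's true tearing energy are
#' drawn per trial from the configured dispersions; normalized forces and
#' lower-bound bands use the nominal (characterized) material properties,
#' as an experimenter would. Thickness correction is not applied to
#' pseudoleaf substrates (their thickness variation is within 5%); plant
#' profiles go through [thickness_correct()] in [process_trial()].
#'
#' @param config a [synthetic_study_config()].
#' @return An object of class `study_summary`: list with `per_trial`
#'   (data frame, one row per worker x substrate), `summary` (group x
#'   substrate cells), `fits` (allometric and parameter-recovery fits),
#'   `population`, `excluded` and `config`.
#' @export
run_study <- function(config = synthetic_study_config()) {
  stopifnot(inherits(config, "synthetic_study_config"))
  population <- generate_worker_population(config)

  substrates <- expand.grid(material = names(config$materials),
                            thickness = config$thicknesses,
                            stringsAsFactors = FALSE)
  substrates$label <- sprintf("%s %.0fum", substrates$material,
                              substrates$thickness * 1e6)

  set.seed(config$seed + 1L)
  rows <- vector("list", nrow(population) * nrow(substrates))
  k <- 0L
  for (i in seq_len(nrow(population))) {
    worker <- population[i, ]
    for (j in seq_len(nrow(substrates))) {
      k <- k + 1L
      nominal <- config$materials[[substrates$material[j]]]
      t_nom <- substrates$thickness[j]
      t_true <- max(stats::rnorm(1L, t_nom,
                                 config$thickness_rel_sd * t_nom),
                    t_nom / 2)
      Gc_true <- if (config$material_scatter) {
        max(stats::rnorm(1L, nominal$Gc, nominal$Gc_sd), nominal$Gc / 10)
      } else nominal$Gc
      trial_material <- material_properties(nominal$name, Gc = Gc_true,
                                            sigma_c = nominal$sigma_c,
                                            E = nominal$E)
      sheet <- sheet_spec(t_true, substrate_label = substrates$label[j])
      sim <- generate_force_trace(worker, trial_material, sheet, config)

      meas <- tryCatch(process_trial(sim$first, sim$second),
                       error = function(e) e)
      if (inherits(meas, "error")) {
        rows[[k]] <- data.frame(
          sample_id = worker$sample_id, group = worker$group,
          mass_mg = worker$mass_mg, substrate = substrates$label[j],
          material = substrates$material[j], thickness_nominal_m = t_nom,
          thickness_m = t_true, R_m = worker$edge_radius_m,
          Fc_N = NA_real_, Fs_N = NA_real_, Ff_N = NA_real_,
          omega = NA_real_, F_min_N = NA_real_, normalized_force = NA_real_,
          Ff_true_N = sim$truth$Ff, Gc_true = sim$truth$Gc,
          flag = "short_steady_state", stringsAsFactors = FALSE)
        next
      }
      pred <- predict_cutting_force(config$model, nominal,
                                    blade_geometry(worker$edge_radius_m),
                                    sheet_spec(t_nom))
      rows[[k]] <- data.frame(
        sample_id = worker$sample_id, group = worker$group,
        mass_mg = worker$mass_mg, substrate = substrates$label[j],
        material = substrates$material[j], thickness_nominal_m = t_nom,
        thickness_m = t_true, R_m = worker$edge_radius_m,
        Fc_N = meas$Fc, Fs_N = meas$Fs, Ff_N = meas$Ff,
        omega = pred$omega, F_min_N = nominal$Gc * t_true,
        normalized_force = meas$Ff / (nominal$Gc * t_true),
        Ff_true_N = sim$truth$Ff, Gc_true = sim$truth$Gc,
        flag = if (is.na(meas$flag)) NA_character_ else meas$flag,
        stringsAsFactors = FALSE)
    }
  }
  per_trial <- do.call(rbind, rows)

  filtered <- validity_filter(per_trial)
  retained <- filtered$retained

  summary_df <- if (nrow(retained) == 0L) data.frame() else
    do.call(rbind, lapply(
    split(retained, list(retained$group, retained$substrate), drop = TRUE),
    function(cell) {
      nominal <- config$materials[[cell$material[1L]]]
      band <- lower_bound_force(
        nominal, sheet_spec(cell$thickness_nominal_m[1L],
                            config$thickness_rel_sd *
                              cell$thickness_nominal_m[1L]))
      data.frame(
        group = cell$group[1L], substrate = cell$substrate[1L],
        n = nrow(cell),
        Fc_mean_N = mean(cell$Fc_N), Fc_sd_N = stats::sd(cell$Fc_N),
        Fs_mean_N = mean(cell$Fs_N), Fs_sd_N = stats::sd(cell$Fs_N),
        Ff_mean_N = mean(cell$Ff_N), Ff_sd_N = stats::sd(cell$Ff_N),
        F_min_N = unname(band[["F_min"]]),
        F_min_sd_N = unname(band[["F_min_sd"]]),
        normalized_mean = mean(cell$normalized_force),
        normalized_sd = stats::sd(cell$normalized_force),
        omega_mean = mean(cell$omega), omega_max = max(cell$omega),
        stringsAsFactors = FALSE)
    }))
  rownames(summary_df) <- NULL

  # degenerate inputs (zero radii, all-excluded cells) yield NULL fits
  try_fit <- function(expr) tryCatch(expr, error = function(e) NULL)
  fits <- list(
    radius_vs_mass = lapply(split(population, population$group),
                            function(g) try_fit(
                              fit_power_law(g$mass_mg, g$edge_radius_m))),
    force_vs_mass = lapply(
      split(retained, list(retained$group, retained$substrate),
            drop = TRUE),
      function(cell) try_fit(fit_power_law(cell$mass_mg, cell$Ff_N))),
    parameter_recovery = lapply(
      split(retained, retained$material),
      function(cell) try_fit(recover_cutting_parameters(cell)))
  )

  structure(list(per_trial = per_trial, summary = summary_df, fits = fits,
                 population = population, excluded = filtered$excluded,
                 config = config),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Synthetic cutting study: %d trials (%d excluded), seed %d\n",
              nrow(x$per_trial), nrow(x$excluded), x$config$seed))
  df <- x$summary
  cat(sprintf("%-8s %-16s %5s %9s %9s %11s\n", "group", "substrate", "n",
              "Ff (mN)", "Gc*t (mN)", "Ff/(Gc*t)"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("%-8s %-16s %5d %9.1f %9.1f %11.3f\n",
                df$group[i], df$substrate[i], df$n[i],
                df$Ff_mean_N[i] * 1e3, df$F_min_N[i] * 1e3,
                df$normalized_mean[i]))
  }
  invisible(x)
}

#' Process one two-pass trial into a cut measurement
#'
#' Runs steady-state detection on the first pass, aligns the second-pass
#' window to the same displacement interval, decomposes the passes, and
#' optionally applies the lamina thickness correction (for biological
#' substrates).
#'
#' @param first,second [force_trace()]s of the two passes.
#' @param window_length,settle_fraction passed to [detect_steady_state()].
#' @param sample_thickness,reference_thickness when both are given, the
#'   measurement is corrected to the reference thickness.
#' @return A `cut_measurement`.
#' @export
process_trial <- function(first, second, window_length = 2e-3,
                          settle_fraction = 0.1,
                          sample_thickness = NULL,
                          reference_thickness = NULL) {
  w1 <- detect_steady_state(first, window_length, settle_fraction)
  w2 <- detect_steady_state(second, window_length, settle_fraction,
                            start_displacement = w1$start_displacement)
  meas <- decompose_passes(w1, w2)
  if (!is.null(sample_thickness) && !is.null(reference_thickness)) {
    meas <- thickness_correct(meas, sample_thickness, reference_thickness)
  }
  meas
}

#' Apply the trial validity rules
#'
#' Excludes trials flagged for head/epoxy contact, fixation failure, blade
#' damage or a steady-state region shorter than the averaging window, and
#' reports counts per reason. Trials flagged only with a warning (e.g.
#' negative fracture force) are retained.
#'
#' @param trials data frame with a `flag` column (`NA` = clean).
#' @param exclude_flags flags that invalidate a trial.
#' @return List with `retained`, `excluded` (both data frames) and
#'   `counts` (table of exclusion reasons).
#' @export
validity_filter <- function(trials,
                            exclude_flags = c("head_contact",
                                              "fixation_failure",
                                              "blade_damage",
                                              "short_steady_state")) {
  stopifnot(is.data.frame(trials), "flag" %in% names(trials))
  drop <- !is.na(trials$flag) & trials$flag %in% exclude_flags
  excluded <- trials[drop, , drop = FALSE]
  retained <- trials[!drop, , drop = FALSE]
  if (nrow(retained) == 0L) {
    warning("all trials excluded by the validity rules")
  }
  list(retained = retained, excluded = excluded,
       counts = table(excluded$flag))
}

#' Recover Gc and C*sigma_c from measured forces and edge radii
#'
#' Under the cutting model, `Ff / t = Gc + (C * sigma_c) * R`: regressing
#' the thickness-normalized fracture force on the edge radius across wear
#' levels recovers the material's tearing energy as the intercept and the
#' near-tip stress term as the slope.
#'
#' @param trials per-trial data frame with columns `Ff_N`, `thickness_m`
#'   and `R_m` (one material).
#' @return List with `Gc_hat` (J m^-2), `Csigma_hat` (Pa) and the
#'   underlying `lm` fit.
#' @export
recover_cutting_parameters <- function(trials) {
  stopifnot(all(c("Ff_N", "thickness_m", "R_m") %in% names(trials)))
  ok <- stats::complete.cases(trials[, c("Ff_N", "thickness_m", "R_m")])
  trials <- trials[ok, , drop = FALSE]
  fit <- stats::lm(I(Ff_N / thickness_m) ~ R_m, data = trials)
  list(Gc_hat = unname(stats::coef(fit)[1L]),
       Csigma_hat = unname(stats::coef(fit)[2L]),
       fit = fit)
}
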