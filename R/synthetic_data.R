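#' Configuration of a synthetic cutting study
#'
#' Collects every parameter of the synthetic study: worker population,
#' blade wear model, substrate materials and thicknesses, force-trace
#' shape and noise, and the cutting-model constants. The defaults are the
#' study conditions: two worker groups of 15 spanning roughly 2-55 mg,
#' pristine edge radii of 162 +/- 120 nm independent of size, forager
#' radii scaling as mass^-0.87 over 89-11712 nm, 4:1 and 10:1 PDMS
#' pseudoleaves of 200 and 400 um with 5% thickness dispersion, two passes
#' at 0.3 mm/s over 5 mm, and spacing forces of 12-22% of the total.
#'
#' @param seed integer seed making every generated artefact reproducible.
#' @param n_per_group workers per group; default 15.
#' @param materials named list of [material_properties()]; defaults to the
#'   two PDMS pseudoleaf formulations.
#' @param thicknesses sheet thicknesses in metres; default 200 and 400 um.
#' @param thickness_rel_sd relative sheet-to-sheet thickness dispersion;
#'   default 0.05.
#' @param material_scatter draw each trial's true Gc from a normal with
#'   the material's stated sd (specimen-level heterogeneity)? Default TRUE.
#' @param callow_mass_range,forager_mass_range body-mass ranges in mg.
#' @param pristine_radius_mean,pristine_radius_sd truncated-normal
#'   parameters (m) for size-invariant pristine edge radii.
#' @param pristine_radius_min lower truncation bound (m).
#' @param wear_exponent allometric exponent of forager edge radius against
#'   body mass; default -0.87.
#' @param wear_radius_range attainable forager radii (m); draws are clamped
#'   to this range. Default 89-11712 nm.
#' @param wear_sdlog lognormal scatter (sd of log radius) about the wear
#'   power law; default 0.5.
#' @param callow_wedge,forager_wedge mean/sd wedge angles (degrees).
#' @param spacing_fraction_range spacing force as a fraction of the total
#'   cutting force; default 0.12-0.22 (pseudoleaf profile; use 0.09-0.14
#'   for plant substrates).
#' @param trace_noise_sd additive Gaussian noise on the force signal (N);
#'   default 1 mN.
#' @param peak_overshoot initiation peak height as a multiple of the
#'   steady-state total force; default 1.3.
#' @param settle_length exponential settling length after the peak (m);
#'   default 0.05 mm.
#' @param peak_position displacement of the initiation peak (m);
#'   default 0.8 mm.
#' @param stage_speed stage speed (m/s); default 0.3 mm/s.
#' @param travel total travel per pass (m); default 5 mm.
#' @param sampling_rate force sampling rate (Hz); default 300.
#' @param model a [cut_model_config()].
#' @return An object of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(
    seed = 1L,
    n_per_group = 15L,
    materials = list("4:1 PDMS" = pdms_4to1(), "10:1 PDMS" = pdms_10to1()),
    thicknesses = c(200e-6, 400e-6),
    thickness_rel_sd = 0.05,
    material_scatter = TRUE,
    callow_mass_range = c(1.9, 55.5),
    forager_mass_range = c(2.3, 54.8),
    pristine_radius_mean = 162e-9,
    pristine_radius_sd = 120e-9,
    pristine_radius_min = 10e-9,
    wear_exponent = -0.87,
    wear_radius_range = c(89e-9, 11712e-9),
    wear_sdlog = 0.5,
    callow_wedge = c(mean = 77, sd = 15),
    forager_wedge = c(mean = 93, sd = 9),
    spacing_fraction_range = c(0.12, 0.22),
    trace_noise_sd = 1e-3,
    peak_overshoot = 1.3,
    settle_length = 0.05e-3,
    peak_position = 0.8e-3,
    stage_speed = 0.3e-3,
    travel = 5e-3,
    sampling_rate = 300,
    model = cut_model_config()) {
  stopifnot(all(vapply(materials, inherits, TRUE, "material_properties")),
            all(thicknesses > 0), thickness_rel_sd >= 0,
            pristine_radius_mean >= 0, pristine_radius_sd >= 0,
            wear_radius_range[1L] > 0,
            wear_radius_range[2L] >= wear_radius_range[1L],
            wear_sdlog >= 0, trace_noise_sd >= 0,
            spacing_fraction_range[1L] >= 0,
            spacing_fraction_range[2L] < 1,
            stage_speed > 0, travel > 0, sampling_rate > 0,
            peak_overshoot >= 1,
            inherits(model, "cut_model_config"))
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_study_config"
  cfg
}

# Truncated-normal draws by rejection (lower bound only).
.rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Generate a worker population with known blade geometry
#'
#' Body masses are evenly spaced in log10-space within each group's range.
#' Pristine (callow) edge radii are size-invariant truncated-normal draws;
#' forager radii follow the wear power law `R = a * m^wear_exponent` with
#' lognormal scatter, clamped to the configured attainable range. The
#' prefactor `a` maps the geometric mid-mass onto the geometric centre of
#' that range. Fully deterministic for a fixed `config$seed`.
#'
#' @param config a [synthetic_study_config()].
#' @return A data frame with one row per worker: `sample_id`, `group`,
#'   `mass_mg`, `edge_radius_m`, `wedge_angle_deg`.
#' @export
generate_worker_population <- function(config) {
  stopifnot(inherits(config, "synthetic_study_config"))
  set.seed(config$seed)
  n <- config$n_per_group

  masses <- function(range) 10^seq(log10(range[1L]), log10(range[2L]),
                                   length.out = n)
  m_cal <- masses(config$callow_mass_range)
  m_for <- masses(config$forager_mass_range)

  r_cal <- .rtruncnorm_lower(n, config$pristine_radius_mean,
                             config$pristine_radius_sd,
                             config$pristine_radius_min)

  # prefactor: geometric mid-mass -> geometric centre of the radius range
  gm_mass <- sqrt(prod(config$forager_mass_range))
  gm_R <- sqrt(prod(config$wear_radius_range))
  a <- gm_R / gm_mass^config$wear_exponent
  r_for <- a * m_for^config$wear_exponent *
    exp(stats::rnorm(n, 0, config$wear_sdlog))
  r_for <- pmin(pmax(r_for, config$wear_radius_range[1L]),
                config$wear_radius_range[2L])

  wedge <- function(par) pmin(pmax(stats::rnorm(n, par[["mean"]],
                                                par[["sd"]]), 10), 170)
  data.frame(
    sample_id = c(sprintf("callow_%02d", seq_len(n)),
                  sprintf("forager_%02d", seq_len(n))),
    group = rep(c("callow", "forager"), each = n),
    mass_mg = c(m_cal, m_for),
    edge_radius_m = c(r_cal, r_for),
    wedge_angle_deg = c(wedge(config$callow_wedge),
                        wedge(config$forager_wedge)),
    stringsAsFactors = FALSE
  )
}

#' Generate a two-pass force trace with known ground truth
#'
#' The first pass ramps linearly to an initiation peak (`peak_overshoot`
#' times the steady-state total force) at `peak_position`, settles
#' exponentially onto a plateau at `Fc = Gc*t*(1 + Omega) + Fs`, and the
#' second pass is a plateau at the spacing force `Fs` alone; both carry
#' additive Gaussian noise. `Fs` is drawn so that `Fs/Fc` lies in the
#' configured spacing-fraction range.
#'
#' @param worker one row of [generate_worker_population()] (or a list with
#'   `edge_radius_m` and `sample_id`).
#' @param material a [material_properties()] giving this trial's true
#'   `Gc` and the nominal `sigma_c`.
#' @param sheet a [sheet_spec()] with this trial's true thickness.
#' @param config a [synthetic_study_config()].
#' @param seed optional integer; when given, the RNG is seeded so the
#'   trace is reproducible in isolation.
#' @return A list with elements `first` and `second` ([force_trace()]s)
#'   and `truth` (list of true `Fc`, `Fs`, `Ff`, `omega`, `R`, `Gc`,
#'   `thickness`, `spacing_fraction`).
#' @export
generate_force_trace <- function(worker, material, sheet, config,
                                 seed = NULL) {
  stopifnot(inherits(material, "material_properties"),
            inherits(sheet, "sheet_spec"),
            inherits(config, "synthetic_study_config"))
  if (!is.null(seed)) set.seed(seed)

  blade <- blade_geometry(worker$edge_radius_m)
  omega <- sharpness_number(config$model, material, blade)
  Ff <- material$Gc * sheet$thickness * (1 + omega)
  f <- stats::runif(1L, config$spacing_fraction_range[1L],
                    config$spacing_fraction_range[2L])
  Fs <- f / (1 - f) * Ff
  Fc <- Ff + Fs

  t_grid <- seq(0, config$travel / config$stage_speed,
                by = 1 / config$sampling_rate)
  x <- t_grid * config$stage_speed
  peak <- config$peak_overshoot * Fc

  first <- ifelse(
    x <= config$peak_position,
    peak * x / config$peak_position,
    Fc + (peak - Fc) * exp(-(x - config$peak_position) /
                             config$settle_length)
  )
  second <- rep(Fs, length(x))
  if (config$trace_noise_sd > 0) {
    first <- first + stats::rnorm(length(x), 0, config$trace_noise_sd)
    second <- second + stats::rnorm(length(x), 0, config$trace_noise_sd)
  }
  trial_id <- if (!is.null(worker$sample_id)) worker$sample_id else "trial"
  list(
    first = force_trace(t_grid, first, config$stage_speed, "first",
                        trial_id),
    second = force_trace(t_grid, second, config$stage_speed, "second",
                         trial_id),
    truth = list(Fc = Fc, Fs = Fs, Ff = Ff, omega = omega,
                 R = worker$edge_radius_m, Gc = material$Gc,
                 thickness = sheet$thickness, spacing_fraction = f)
  )
}

#' Generate a wedge-plus-arc tip cross-section contour
#'
#' The contour is two straight flanks at the given wedge angle joined by a
#' circular arc of the given radius, tangent to both flanks - the exact
#' geometry the edge-radius estimator assumes. The apex of the ideal wedge
#' sits at the origin with the interior bisector along +y; optional
#' rotation, translation and point jitter produce transformed or noisy
#' copies.
#'
#' @param radius tip arc radius in metres; `>= 0` (0 gives a sharp wedge).
#' @param wedge_angle_deg interior wedge angle in degrees, in (0, 180).
#' @param scale metres per pixel.
#' @param noise_px Gaussian jitter sd on both pixel coordinates; default 0.
#' @param seed optional integer seed for the jitter.
#' @param flank_length_px flank length in pixels; default
#'   `max(4 * radius_px, 50)`.
#' @param spacing_px point spacing along the outline in pixels;
#'   default 0.5 (arc) and `2 * spacing_px` (flanks).
#' @param rotation_deg,offset_px rigid transform applied to the contour.
#' @param specimen_id label.
#' @return A [cross_section_contour()].
#' @export
generate_cross_section <- function(radius, wedge_angle_deg, scale,
                                   noise_px = 0, seed = NULL,
                                   flank_length_px = NULL,
                                   spacing_px = 0.5,
                                   rotation_deg = 0, offset_px = c(0, 0),
                                   specimen_id = "synthetic") {
  stopifnot(radius >= 0, wedge_angle_deg > 0, wedge_angle_deg < 180,
            scale > 0)
  if (!is.null(seed)) set.seed(seed)
  r <- radius / scale
  beta <- wedge_angle_deg / 2 * pi / 180
  if (is.null(flank_length_px)) flank_length_px <- max(4 * r, 50)

  # tangent points at distance l = r/tan(beta) from the apex along flanks
  l <- if (r > 0) r / tan(beta) else 0
  d <- if (r > 0) r / sin(beta) else 0        # arc centre (0, d)
  flank_pts <- function(side) {
    s <- seq(l, l + flank_length_px, by = 2 * spacing_px)
    cbind(side * s * sin(beta), s * cos(beta))
  }
  left <- flank_pts(-1)
  right <- flank_pts(+1)

  arc <- NULL
  if (r > 0) {
    # left tangent point sits at angle beta - pi on the arc circle, the
    # right one at -beta; the arc between them runs through the bottom
    th1 <- beta - pi
    th2 <- -beta
    n_arc <- max(8L, ceiling(r * (th2 - th1) / spacing_px))
    th <- seq(th1, th2, length.out = n_arc + 1L)
    th <- th[-c(1L, length(th))]              # tangent pts are on flanks
    arc <- cbind(r * cos(th), d + r * sin(th))
  }

  P <- rbind(left[rev(seq_len(nrow(left))), , drop = FALSE], arc, right)
  dup <- c(FALSE, rowSums((P[-1L, , drop = FALSE] -
                           P[-nrow(P), , drop = FALSE])^2) == 0)
  P <- P[!dup, , drop = FALSE]                # r = 0: flanks share the apex
  if (noise_px > 0) {
    P <- P + matrix(stats::rnorm(length(P), 0, noise_px), ncol = 2L)
  }
  if (rotation_deg != 0) {
    a <- rotation_deg * pi / 180
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    P <- P %*% t(Rm)
  }
  P <- sweep(P, 2L, -as.numeric(offset_px))
  cross_section_contour(P, scale = scale, specimen_id = specimen_id)
}

#' Generate a synthetic stress-strain record or pure-shear pair
#'
#' Tensile curves are linear with slope `E` up to half the strength, rise
#' smoothly (monotone cubic) to a peak at exactly `sigma_c`, then soften
#' linearly. For a pure-shear pair, the critical stretch of the notional
#' notched twin is solved (to machine precision) so that the trapezoidal
#' strain energy density of the unnotched curve times the specimen height
#' reproduces the material's `Gc` exactly.
#'
#' @param material a [material_properties()]; its `E`, `sigma_c` and `Gc`
#'   are the ground truth.
#' @param test_type `"dogbone_tension"` or `"pure_shear"`.
#' @param noise relative additive noise (fraction of `sigma_c`);
#'   default 0.
#' @param seed optional integer seed.
#' @param n_points samples along the strain axis; default 200.
#' @param specimen_height pure-shear specimen height (m); default 10 mm.
#' @return A [stress_strain_curve()] or, for `"pure_shear"`, a
#'   [pure_shear_pair()].
#' @export
generate_stress_strain <- function(material,
                                   test_type = c("dogbone_tension",
                                                 "pure_shear"),
                                   noise = 0, seed = NULL,
                                   n_points = 200L,
                                   specimen_height = 10e-3) {
  stopifnot(inherits(material, "material_properties"))
  test_type <- match.arg(test_type)
  if (!is.null(seed)) set.seed(seed)
  E <- material$E
  sc <- material$sigma_c

  eps_l <- 0.5 * sc / E       # end of the linear region
  eps_p <- 1.5 * sc / E       # strain at peak stress
  eps_f <- eps_p + 0.3 * sc / E

  n1 <- max(20L, ceiling(n_points * eps_l / eps_f))
  n2 <- max(10L, ceiling(n_points * (eps_p - eps_l) / eps_f))
  n3 <- max(3L, n_points - n1 - n2)
  eps <- c(seq(0, eps_l, length.out = n1 + 1L),
           seq(eps_l, eps_p, length.out = n2 + 1L)[-1L],
           seq(eps_p, eps_f, length.out = n3 + 1L)[-1L])
  # keep the modulus-fit window (low strains) well resolved
  lin <- min(0.05, eps_l)
  eps <- sort(unique(c(seq(0, lin, length.out = 12L), eps)))

  hermite <- function(e) {
    # monotone cubic on [eps_l, eps_p]: value/slope (E*eps_l, E) -> (sc, 0)
    h <- eps_p - eps_l
    u <- (e - eps_l) / h
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h00 * (E * eps_l) + h10 * h * E + h01 * sc
  }
  sig <- ifelse(eps <= eps_l, E * eps,
                ifelse(eps <= eps_p, hermite(eps),
                       sc - 0.2 * sc * (eps - eps_p) / (eps_f - eps_p)))
  if (noise > 0) {
    sig <- sig + stats::rnorm(length(sig), 0, noise * sc)
  }

  if (test_type == "dogbone_tension") {
    return(stress_strain_curve(eps, sig, test_type = "dogbone_tension"))
  }

  target <- material$Gc / specimen_height
  # stiff-but-tough materials need more stretch to store Gc/h0: extend the
  # record at the post-softening stress until the energy target is passed
  W_end <- function(e, s) sum(diff(e) * (s[-1L] + s[-length(s)])) / 2
  while (W_end(eps, sig) < 1.05 * target) {
    deps <- eps[length(eps)] - eps[length(eps) - 1L]
    eps <- c(eps, eps[length(eps)] + deps)
    sig <- c(sig, 0.8 * sc)
  }
  curve <- stress_strain_curve(eps, sig, test_type = "pure_shear_unnotched")
  lam_c <- stats::uniroot(
    function(lam) strain_energy_density(curve, lam) - target,
    lower = 1 + eps[2L], upper = 1 + eps[length(eps)],
    tol = .Machine$double.eps^0.75
  )$root
  pure_shear_pair(curve, critical_stretch = lam_c,
                  specimen_height = specimen_height)
}

#' Generate a batch of replicate material-test specimens
#'
#' Draws per-specimen true properties from the material's stated normal
#' dispersions (truncated to stay positive), generates one tensile curve
#' and one pure-shear pair per specimen, and returns them with the
#' per-specimen ground truth. Feeding the batch through [young_modulus()],
#' [ultimate_tensile_strength()], [tearing_energy_pure_shear()] and
#' [summarize_material()] emulates the characterization campaign.
#'
#' @param material a [material_properties()] giving means and sds.
#' @param n replicate specimens; default 8.
#' @param noise relative stress noise passed to [generate_stress_strain()].
#' @param seed integer seed.
#' @return A list with `specimens` (list of `tensile` / `pure_shear`
#'   pairs) and `truth` (data frame of per-specimen E, sigma_c, Gc).
#' @export
generate_material_batch <- function(material, n = 8L, noise = 0,
                                    seed = 1L) {
  stopifnot(inherits(material, "material_properties"))
  set.seed(seed)
  truth <- data.frame(
    E = .rtruncnorm_lower(n, material$E, material$E_sd, material$E / 10),
    sigma_c = .rtruncnorm_lower(n, material$sigma_c, material$sigma_c_sd,
                                material$sigma_c / 10),
    Gc = .rtruncnorm_lower(n, material$Gc, material$Gc_sd, material$Gc / 10)
  )
  specimens <- lapply(seq_len(n), function(i) {
    m_i <- material_properties(sprintf("%s rep %d", material$name, i),
                               Gc = truth$Gc[i], sigma_c = truth$sigma_c[i],
                               E = truth$E[i])
    list(tensile = generate_stress_strain(m_i, "dogbone_tension",
                                          noise = noise),
         pure_shear = generate_stress_strain(m_i, "pure_shear",
                                             noise = noise))
  })
  list(specimens = specimens, truth = truth)
}
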