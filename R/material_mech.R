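#' Stress-strain curve from a uniaxial test
#'
#' Engineering stress and strain throughout: stress is force over the
#' initial cross-sectional area, strain the elongation over the initial
#' gauge length.
#'
#' @param strain engineering strain, dimensionless, non-decreasing from 0.
#' @param stress engineering stress in Pa, finite.
#' @param gauge_length,width,thickness specimen geometry in metres
#'   (optional metadata; must be positive when given).
#' @param test_type `"dogbone_tension"`, `"pure_shear_notched"` or
#'   `"pure_shear_unnotched"`.
#' @return An object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress,
                                gauge_length = NA_real_, width = NA_real_,
                                thickness = NA_real_,
                                test_type = c("dogbone_tension",
                                              "pure_shear_notched",
                                              "pure_shear_unnotched")) {
  test_type <- match.arg(test_type)
  if (length(strain) != length(stress) || length(strain) < 2L) {
    stop("'strain' and 'stress' must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(stress)) || any(!is.finite(strain))) {
    stop("'strain' and 'stress' must be finite", call. = FALSE)
  }
  if (strain[1L] < 0 || any(diff(strain) < 0)) {
    stop("'strain' must be non-decreasing and start at >= 0", call. = FALSE)
  }
  for (g in c(gauge_length, width, thickness)) {
    if (!is.na(g) && g <= 0) stop("specimen geometry must be positive",
                                  call. = FALSE)
  }
  structure(list(strain = as.numeric(strain), stress = as.numeric(stress),
                 gauge_length = gauge_length, width = width,
                 thickness = thickness, test_type = test_type),
            class = "stress_strain_curve")
}

#' Pure-shear test pair
#'
#' An unnotched pure-shear specimen provides the strain energy density as a
#' function of stretch; its notched twin provides the stretch at which the
#' pre-crack starts to propagate. Together they yield the tearing energy.
#'
#' @param unnotched a [stress_strain_curve()] for the unnotched specimen.
#' @param critical_stretch stretch at crack propagation in the notched
#'   twin; `> 1`.
#' @param specimen_height unstrained specimen height in the loading
#'   direction, metres; `> 0`.
#' @return An object of class `pure_shear_pair`.
#' @export
pure_shear_pair <- function(unnotched, critical_stretch, specimen_height) {
  stopifnot(inherits(unnotched, "stress_strain_curve"))
  if (!is.numeric(critical_stretch) || length(critical_stretch) != 1L ||
      critical_stretch <= 1) {
    stop("'critical_stretch' must be a single number > 1", call. = FALSE)
  }
  if (!is.numeric(specimen_height) || length(specimen_height) != 1L ||
      specimen_height <= 0) {
    stop("'specimen_height' must be a single positive number (m)",
         call. = FALSE)
  }
  structure(list(unnotched = unnotched, critical_stretch = critical_stretch,
                 specimen_height = specimen_height),
            class = "pure_shear_pair")
}

#' Young's modulus from the initial linear region
#'
#' Least-squares slope of stress against strain over a fixed strain window
#' (default 0-5%). On an exactly affine record the slope is recovered
#' exactly.
#'
#' @param curve a [stress_strain_curve()].
#' @param strain_window two-element numeric window of strains to fit over.
#' @return Modulus in Pa.
#' @export
young_modulus <- function(curve, strain_window = c(0, 0.05)) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  sel <- curve$strain >= strain_window[1L] & curve$strain <= strain_window[2L]
  if (sum(sel) < 5L) {
    stop("fewer than 5 samples in the linear-fit strain window",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(curve$stress[sel] ~ curve$strain[sel]))[2L])
}

#' Ultimate tensile strength
#'
#' @param curve a [stress_strain_curve()].
#' @return Maximum stress in Pa.
#' @export
ultimate_tensile_strength <- function(curve) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  max(curve$stress)
}

#' Strain energy density up to a given stretch
#'
#' Trapezoidal integral of the stress-strain record from zero strain to
#' `stretch - 1`, with the final partial segment evaluated at linearly
#' interpolated stress. Units J m^-3.
#'
#' @param curve a [stress_strain_curve()].
#' @param stretch stretch ratio (`1 + strain`) up to which to integrate.
#' @return Energy density in J m^-3.
#' @export
strain_energy_density <- function(curve, stretch) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  eps_c <- stretch - 1
  eps <- curve$strain
  sig <- curve$stress
  if (eps_c < eps[1L] - 1e-12 || eps_c > eps[length(eps)] + 1e-12) {
    stop("curve does not span the requested stretch", call. = FALSE)
  }
  full <- which(eps <= eps_c)
  W <- 0
  if (length(full) > 1L) {
    W <- sum(diff(eps[full]) * (sig[full][-1L] + sig[full][-length(full)])) / 2
  }
  i <- full[length(full)]
  if (i < length(eps) && eps_c > eps[i]) {
    sig_c <- sig[i] + (sig[i + 1L] - sig[i]) *
      (eps_c - eps[i]) / (eps[i + 1L] - eps[i])
    W <- W + (eps_c - eps[i]) * (sig[i] + sig_c) / 2
  }
  W
}

#' Tearing energy from a pure-shear test pair
#'
#' For the pure-shear (wide, short sheet) geometry the energy release rate
#' is independent of crack length and equals `Gc = W(lambda_c) * h0`, with
#' `W` the strain energy density of the unnotched specimen at the critical
#' stretch `lambda_c` of the notched twin and `h0` the unstrained specimen
#' height.
#'
#' @param pair a [pure_shear_pair()].
#' @return Tearing energy in J m^-2.
#' @export
tearing_energy_pure_shear <- function(pair) {
  stopifnot(inherits(pair, "pure_shear_pair"))
  W <- strain_energy_density(pair$unnotched, pair$critical_stretch)
  W * pair$specimen_height
}

#' Summarize replicate estimates into material properties
#'
#' Per-quantity mean and sample standard deviation across replicate
#' specimens. With fewer than two replicates the sd is reported as 0 with
#' a warning.
#'
#' @param name material label.
#' @param Gc,sigma_c,E numeric vectors of replicate estimates (J m^-2, Pa,
#'   Pa).
#' @return A [material_properties()] object.
#' @examples
#' summarize_material("demo", Gc = c(90, 98, 106),
#'                    sigma_c = rep(6e6, 3), E = rep(4.1e6, 3))
#' @export
summarize_material <- function(name, Gc, sigma_c, E) {
  stat <- function(v, what) {
    if (length(v) < 2L) {
      warning(sprintf("fewer than 2 replicates for %s: sd reported as 0",
                      what))
      return(c(mean(v), 0))
    }
    c(mean(v), stats::sd(v))
  }
  g <- stat(Gc, "Gc"); s <- stat(sigma_c, "sigma_c"); e <- stat(E, "E")
  material_properties(name, Gc = g[1L], Gc_sd = g[2L],
                      sigma_c = s[1L], sigma_c_sd = s[2L],
                      E = e[1L], E_sd = e[2L])
}
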