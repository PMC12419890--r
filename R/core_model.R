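#' Blade geometry
#'
#' Geometry of a cutting tool reduced to the two quantities the cutting
#' model uses: the cutting-edge radius `R` (the radius of the smallest
#' circle tangent to both flanks that fits inside the tip cross-section)
#' and the wedge angle between the flanks.
#'
#' @param edge_radius cutting-edge radius in metres; `>= 0`.
#' @param wedge_angle interior angle between the flanks in degrees,
#'   in (0, 180). Not used by the force model itself but carried as part
#'   of the tool description.
#' @param label one of `"pristine"`, `"forager"`, `"scalpel"`, `"custom"`.
#' @return An object of class `blade_geometry`.
#' @export
blade_geometry <- function(edge_radius, wedge_angle = 90,
                           label = c("custom", "pristine", "forager",
                                     "scalpel")) {
  label <- match.arg(label)
  if (!is.numeric(edge_radius) || length(edge_radius) != 1L ||
      !is.finite(edge_radius) || edge_radius < 0) {
    stop("'edge_radius' must be a single non-negative number (m)",
         call. = FALSE)
  }
  if (!is.numeric(wedge_angle) || length(wedge_angle) != 1L ||
      !is.finite(wedge_angle) || wedge_angle <= 0 || wedge_angle >= 180) {
    stop("'wedge_angle' must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  structure(list(edge_radius = edge_radius, wedge_angle = wedge_angle,
                 label = label),
            class = "blade_geometry")
}

#' Sheet specification
#'
#' @param thickness sheet thickness in metres; `> 0`.
#' @param thickness_sd standard deviation of the thickness in metres; `>= 0`.
#' @param substrate_label free-text substrate label.
#' @return An object of class `sheet_spec`.
#' @export
sheet_spec <- function(thickness, thickness_sd = 0,
                       substrate_label = "substrate") {
  if (!is.numeric(thickness) || length(thickness) != 1L ||
      !is.finite(thickness) || thickness <= 0) {
    stop("'thickness' must be a single positive number (m)", call. = FALSE)
  }
  if (!is.numeric(thickness_sd) || length(thickness_sd) != 1L ||
      !is.finite(thickness_sd) || thickness_sd < 0) {
    stop("'thickness_sd' must be a single non-negative number (m)",
         call. = FALSE)
  }
  structure(list(thickness = thickness, thickness_sd = thickness_sd,
                 substrate_label = substrate_label),
            class = "sheet_spec")
}

#' Cutting-model configuration
#'
#' @param C dimensionless contact constant of order unity, multiplying the
#'   near-tip dissipation term. Default 2, following prior work on mandible
#'   cutting; it subsumes contact area, friction and strain stiffening.
#' @param omega_sharp_threshold sharpness cut-off: a blade with
#'   Omega strictly below this value is classed as ideally sharp. Default
#'   0.05, the empirical condition under which measured fracture forces are
#'   indistinguishable from the lower bound.
#' @return An object of class `cut_model_config`.
#' @export
cut_model_config <- function(C = 2, omega_sharp_threshold = 0.05) {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("'C' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(omega_sharp_threshold) ||
      length(omega_sharp_threshold) != 1L ||
      !is.finite(omega_sharp_threshold) || omega_sharp_threshold <= 0) {
    stop("'omega_sharp_threshold' must be a single positive number",
         call. = FALSE)
  }
  structure(list(C = C, omega_sharp_threshold = omega_sharp_threshold),
            class = "cut_model_config")
}

#' Lower-bound cutting force Gc * t
#'
#' The energetic cost of creating new crack surface bounds the steady-state
#' cutting force from below by the product of tearing energy and sheet
#' thickness, independent of tool geometry. The uncertainty is first-order
#' Gaussian propagation assuming independent errors on `Gc` and `t`:
#' `sqrt((t*Gc_sd)^2 + (Gc*t_sd)^2)`.
#'
#' @param material a [material_properties()] object.
#' @param sheet a [sheet_spec()] object.
#' @return Named numeric vector `c(F_min =, F_min_sd =)` in newtons.
#' @examples
#' lower_bound_force(pdms_10to1(), sheet_spec(200e-6))  # ~39.4 mN
#' @export
lower_bound_force <- function(material, sheet) {
  stopifnot(inherits(material, "material_properties"),
            inherits(sheet, "sheet_spec"))
  F_min <- material$Gc * sheet$thickness
  F_min_sd <- sqrt((sheet$thickness * material$Gc_sd)^2 +
                   (material$Gc * sheet$thickness_sd)^2)
  c(F_min = F_min, F_min_sd = F_min_sd)
}

#' Dimensionless sharpness number Omega = C * sigma_c * R / Gc
#'
#' Ratio of the blade's edge radius to the material length scale
#' `Gc/sigma_c`, scaled by the contact constant `C`. Omega measures the
#' relative contribution of near-tip dissipation to the cutting force:
#' for Omega << 1 the force is set by the material alone; for Omega of
#' order 1 or larger, tool geometry dominates.
#'
#' @param config a [cut_model_config()].
#' @param material a [material_properties()].
#' @param blade a [blade_geometry()].
#' @return A single dimensionless number, `>= 0`.
#' @examples
#' sharpness_number(cut_model_config(), pdms_4to1(),
#'                  blade_geometry(162e-9, label = "pristine"))  # ~0.02
#' @export
sharpness_number <- function(config, material, blade) {
  stopifnot(inherits(config, "cut_model_config"),
            inherits(material, "material_properties"),
            inherits(blade, "blade_geometry"))
  config$C * material$sigma_c * blade$edge_radius / material$Gc
}

#' Classify a blade's sharpness regime
#'
#' @param omega_value dimensionless sharpness number(s); `>= 0`.
#' @param config a [cut_model_config()] supplying the threshold.
#' @return Character vector: `"ideally_sharp"` if `omega <` the threshold
#'   (strict, so a value exactly at the threshold is transitional),
#'   `"geometry_dominated"` if `omega >= 1`, `"transitional"` otherwise.
#' @export
classify_sharpness <- function(omega_value, config = cut_model_config()) {
  stopifnot(inherits(config, "cut_model_config"))
  if (!is.numeric(omega_value) || any(!is.finite(omega_value)) ||
      any(omega_value < 0)) {
    stop("'omega_value' must be non-negative and finite", call. = FALSE)
  }
  ifelse(omega_value < config$omega_sharp_threshold, "ideally_sharp",
         ifelse(omega_value >= 1, "geometry_dominated", "transitional"))
}

#' Predict the steady-state fracture force for a blade and sheet
#'
#' Combines the lower bound with the geometric penalty:
#' `F_pred = Gc * t * (1 + Omega)`. The normalized force `F_pred/(Gc*t)`
#' equals `1 + Omega` identically; the regime label comes from
#' [classify_sharpness()].
#'
#' @inheritParams sharpness_number
#' @param sheet a [sheet_spec()].
#' @return An object of class `cut_force_prediction` with fields `F_min`,
#'   `F_min_sd`, `omega`, `F_pred`, `normalized_force`, `regime` (forces
#'   in newtons).
#' @examples
#' worn <- blade_geometry(11712e-9, label = "forager")
#' predict_cutting_force(cut_model_config(), pdms_4to1(), worn,
#'                       sheet_spec(400e-6))  # ~95 mN
#' @export
predict_cutting_force <- function(config, material, blade, sheet) {
  lb <- lower_bound_force(material, sheet)
  omega <- sharpness_number(config, material, blade)
  F_pred <- unname(lb[["F_min"]]) * (1 + omega)
  structure(
    list(F_min = unname(lb[["F_min"]]), F_min_sd = unname(lb[["F_min_sd"]]),
         omega = omega, F_pred = F_pred, normalized_force = 1 + omega,
         regime = classify_sharpness(omega, config)),
    class = "cut_force_prediction"
  )
}

#' @export
print.cut_force_prediction <- function(x, ...) {
  cat(sprintf("Cutting-force prediction (%s regime)\n", x$regime))
  cat(sprintf("  lower bound Gc*t : %.3g +/- %.2g mN\n",
              x$F_min * 1e3, x$F_min_sd * 1e3))
  cat(sprintf("  Omega            : %.3g\n", x$omega))
  cat(sprintf("  predicted force  : %.3g mN (%.3g x lower bound)\n",
              x$F_pred * 1e3, x$normalized_force))
  invisible(x)
}

#' Critical edge radius for a tolerable force elevation
#'
#' Inverts the sharpness number: the largest edge radius whose predicted
#' force exceeds the lower bound by at most a relative `tolerance` is
#' `R_crit = tolerance * Gc / (C * sigma_c)`.
#'
#' @inheritParams sharpness_number
#' @param tolerance relative force elevation deemed acceptable; `>= 0`.
#' @return Critical radius in metres.
#' @examples
#' critical_radius(cut_model_config(), pdms_4to1(), 0.05)  # ~408 nm
#' @export
critical_radius <- function(config, material, tolerance) {
  stopifnot(inherits(config, "cut_model_config"),
            inherits(material, "material_properties"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      !is.finite(tolerance) || tolerance < 0) {
    stop("'tolerance' must be a single non-negative number", call. = FALSE)
  }
  tolerance * material$Gc / (config$C * material$sigma_c)
}
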