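#' Material properties of a thin cut substrate
#'
#' Bundles the three mechanical properties that control thin-sheet cutting:
#' the tearing energy (fracture toughness) `Gc`, the characteristic stress
#' `sigma_c` (identified with the ultimate tensile strength by default) and
#' the Young's modulus `E`, each with a standard deviation describing
#' specimen-to-specimen dispersion. All values are SI: J m^-2 for `Gc`,
#' Pa for stresses and moduli.
#'
#' @param name label for the material (e.g. `"4:1 PDMS"`).
#' @param Gc tearing energy in J m^-2; must be positive.
#' @param sigma_c characteristic stress (UTS) in Pa; must be positive.
#' @param E Young's modulus in Pa; must be positive.
#' @param Gc_sd,sigma_c_sd,E_sd standard deviations (same units); `>= 0`.
#'
#' @return An object of class `material_properties`.
#' @seealso [material_length_scale()], [pdms_4to1()], [pdms_10to1()],
#'   [japanese_laurel()]
#' @export
material_properties <- function(name, Gc, sigma_c, E,
                                Gc_sd = 0, sigma_c_sd = 0, E_sd = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in list(Gc = Gc, sigma_c = sigma_c, E = E)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'Gc', 'sigma_c' and 'E' must be single positive finite numbers",
           call. = FALSE)
    }
  }
  for (v in list(Gc_sd = Gc_sd, sigma_c_sd = sigma_c_sd, E_sd = E_sd)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("standard deviations must be single non-negative numbers",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, Gc = Gc, Gc_sd = Gc_sd,
         sigma_c = sigma_c, sigma_c_sd = sigma_c_sd,
         E = E, E_sd = E_sd),
    class = "material_properties"
  )
}

#' @export
print.material_properties <- function(x, ...) {
  ls <- material_length_scale(x)
  cat(sprintf("Material: %s\n", x$name))
  cat(sprintf("  Gc      = %.4g +/- %.2g J m^-2\n", x$Gc, x$Gc_sd))
  cat(sprintf("  sigma_c = %.4g +/- %.2g MPa\n",
              x$sigma_c / 1e6, x$sigma_c_sd / 1e6))
  cat(sprintf("  E       = %.4g +/- %.2g MPa\n", x$E / 1e6, x$E_sd / 1e6))
  cat(sprintf("  length scale Gc/sigma_c = %.3g +/- %.2g um\n",
              ls[["value"]] * 1e6, ls[["sd"]] * 1e6))
  invisible(x)
}

#' Material length scale Gc / sigma_c
#'
#' The ratio of tearing energy to characteristic stress has dimensions of
#' length and sets the scale against which a blade's edge radius is judged:
#' an edge much finer than `Gc/sigma_c` cuts at the physical minimum force.
#' The uncertainty is first-order Gaussian propagation with independent
#' errors.
#'
#' @param material a [material_properties()] object.
#' @return Named numeric vector with elements `value` and `sd`, in metres.
#' @examples
#' material_length_scale(pdms_4to1())   # ~16.3 um
#' @export
material_length_scale <- function(material) {
  stopifnot(inherits(material, "material_properties"))
  value <- material$Gc / material$sigma_c
  sd <- sqrt((material$Gc_sd / material$sigma_c)^2 +
             (material$Gc * material$sigma_c_sd / material$sigma_c^2)^2)
  c(value = value, sd = sd)
}

#' Reference substrate materials
#'
#' Characterized properties of the three study substrates: two
#' polydimethylsiloxane (PDMS) elastomer "pseudoleaf" formulations
#' (base:curing-agent mixing ratios 4:1 and 10:1, which differ roughly
#' twofold in material length scale) and Japanese laurel leaf lamina.
#' Means and standard deviations are from tensile (E, UTS) and pure-shear
#' (Gc) testing of replicate specimens.
#'
#' @return A [material_properties()] object.
#' @name reference_materials
NULL

#' @rdname reference_materials
#' @export
pdms_4to1 <- function() {
  material_properties("4:1 PDMS", Gc = 98, Gc_sd = 9,
                      sigma_c = 6.0e6, sigma_c_sd = 2e6,
                      E = 4.1e6, E_sd = 0.3e6)
}

#' @rdname reference_materials
#' @export
pdms_10to1 <- function() {
  material_properties("10:1 PDMS", Gc = 197, Gc_sd = 25,
                      sigma_c = 5.5e6, sigma_c_sd = 2e6,
                      E = 1.6e6, E_sd = 0.3e6)
}

#' @rdname reference_materials
#' @export
japanese_laurel <- function() {
  material_properties("Japanese laurel", Gc = 746, Gc_sd = 210,
                      sigma_c = 1.63e6, sigma_c_sd = 0.3e6,
                      E = 31e6, E_sd = 4e6)
}
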