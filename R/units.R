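#' Stiffness unit conversions
#'
#' Conversions among Young's modulus E (kPa), shear modulus mu (kPa), and
#' shear-wave velocity c (m/s) under the standard soft-tissue assumptions of
#' incompressibility and local homogeneity/isotropy:
#' `E = 3 * mu` and `mu = rho * c^2`, so `c = sqrt(E / (3 * rho))` with E in
#' Pa. Tissue density `rho` defaults to 1000 kg/m3; with that value the kPa
#' forms simplify to `c = sqrt(E_kPa / 3)`. All conversions are strictly
#' increasing and mutually consistent. Devices report Young's modulus, but
#' for anisotropic muscle tissue SWV is the recommended reporting unit, so
#' results are emitted in both.
#'
#' @param E Young's modulus in kPa, `>= 0`.
#' @param mu Shear modulus in kPa, `>= 0`.
#' @param c_ms Shear-wave velocity in m/s, `>= 0`.
#' @param rho Tissue density in kg/m3, `> 0`.
#' @return Converted values (vectorized).
#' @name unit_conversion
NULL

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be finite numeric")
  }
  if (any(x < 0)) stop(what, " must be >= 0")
  as.numeric(x)
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop("rho must be a single positive density in kg/m3")
  }
  rho
}

#' @rdname unit_conversion
#' @export
young_to_shear <- function(E) check_nonneg(E, "E") / 3

#' @rdname unit_conversion
#' @export
shear_to_young <- function(mu) 3 * check_nonneg(mu, "mu")

#' @rdname unit_conversion
#' @export
young_to_swv <- function(E, rho = 1000) {
  sqrt(1000 * check_nonneg(E, "E") / (3 * check_rho(rho)))
}

#' @rdname unit_conversion
#' @export
swv_to_young <- function(c_ms, rho = 1000) {
  3 * check_rho(rho) * check_nonneg(c_ms, "c_ms")^2 / 1000
}

#' @rdname unit_conversion
#' @export
shear_to_swv <- function(mu, rho = 1000) {
  sqrt(1000 * check_nonneg(mu, "mu") / check_rho(rho))
}

#' @rdname unit_conversion
#' @export
swv_to_shear <- function(c_ms, rho = 1000) {
  check_rho(rho) * check_nonneg(c_ms, "c_ms")^2 / 1000
}
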