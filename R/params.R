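#' Parameter set for the outer hair cell composite membrane
#'
#' Constructs and validates the full parameter set describing the orthotropic
#' composite wall of a cylindrical outer hair cell (OHC). All quantities are
#' SI: moduli in N/m, times in seconds, capacitance in F/m^2, radius in m.
#' The electromechanical coupling coefficients enter the constitutive
#' equations only through the products `alpha_i * C_sp` (units 1/V, i.e.
#' strain per volt), so those products are what is stored.
#'
#' @param C11,C12,C22 Elastic moduli of the orthotropic wall (N/m). The
#'   elastic matrix `[[C11, C12], [C12, C22]]` must be positive definite.
#' @param eta Viscoelastic coefficient of the springpot (power-law) element,
#'   N s^nu / m. `eta = 0` gives the purely elastic limit.
#' @param nu Power-law exponent, in (0, 1). `nu = 1` is reserved for the
#'   Kelvin-Voigt comparison mode of [isometric_force()] and is rejected here
#'   for time-domain kernels (the t^-1 relaxation term is a delta function).
#' @param tau_e Prestin charge-transfer (RC) time constant, s.
#' @param C_sp Specific membrane capacitance, F/m^2.
#' @param alpha1_Csp,alpha2_Csp Products alpha_i * C_sp coupling transferred
#'   charge to active longitudinal (1) and circumferential (2) strain, 1/V.
#' @param r_c Cell radius, m.
#' @return An object of class `c("ohc_params", "membrane_params")`.
#' @seealso [default_ohc_params()], [sphere_params()], [load_params()]
#' @export
ohc_params <- function(C11, C12, C22, eta, nu, tau_e, C_sp,
                       alpha1_Csp, alpha2_Csp, r_c) {
  p <- structure(
    list(C11 = C11, C12 = C12, C22 = C22, eta = eta, nu = nu,
         tau_e = tau_e, C_sp = C_sp,
         alpha1_Csp = alpha1_Csp, alpha2_Csp = alpha2_Csp, r_c = r_c),
    class = c("ohc_params", "membrane_params"))
  validate_params(p)
}

#' Parameter set for an isotropic spherical prestin-transfected cell
#'
#' As [ohc_params()], for the isotropic spherical membrane of a cell
#' transfected with prestin (e.g. HEK): a single area modulus `K` replaces
#' the orthotropic matrix and a single coupling product `alpha_Csp` replaces
#' the pair.
#'
#' @param K Area modulus of the isotropic membrane, N/m.
#' @param alpha_Csp Product alpha * C_sp, 1/V.
#' @inheritParams ohc_params
#' @return An object of class `c("sphere_params", "membrane_params")`.
#' @export
sphere_params <- function(K, eta, nu, tau_e, C_sp, alpha_Csp, r_c) {
  p <- structure(
    list(K = K, eta = eta, nu = nu, tau_e = tau_e, C_sp = C_sp,
         alpha_Csp = alpha_Csp, r_c = r_c),
    class = c("sphere_params", "membrane_params"))
  validate_params(p)
}

#' Validate a membrane parameter object
#'
#' Checks all type invariants: positive-definite elastic matrix (or K > 0),
#' 0 < nu < 1, eta >= 0, tau_e > 0, C_sp > 0, r_c > 0, finite numeric
#' scalars throughout. Called by every constructor and by [load_params()].
#'
#' @param p A `membrane_params` object.
#' @return `p`, invisibly unchanged, or an error naming the offending field.
#' @export
validate_params <- function(p) {
  num1 <- function(field) {
    x <- p[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("field '", field, "' must be a finite numeric scalar", call. = FALSE)
    x
  }
  pos <- function(field) {
    if (num1(field) <= 0)
      stop("field '", field, "' must be > 0", call. = FALSE)
  }
  if (inherits(p, "ohc_params")) {
    pos("C11"); pos("C22"); num1("C12")
    if (p$C11 * p$C22 - p$C12^2 <= 0)
      stop("elastic matrix [C11 C12; C12 C22] is not positive definite ",
           "(C11*C22 - C12^2 <= 0)", call. = FALSE)
    num1("alpha1_Csp"); num1("alpha2_Csp")
  } else if (inherits(p, "sphere_params")) {
    pos("K"); num1("alpha_Csp")
  } else {
    stop("not a membrane_params object", call. = FALSE)
  }
  if (num1("eta") < 0) stop("field 'eta' must be >= 0", call. = FALSE)
  if (num1("nu") <= 0 || p$nu >= 1)
    stop("field 'nu' must lie in (0, 1); nu = 1 is only available as the ",
         "Kelvin-Voigt mode of isometric_force()/complex_modulus()",
         call. = FALSE)
  pos("tau_e"); pos("C_sp"); pos("r_c")
  invisible(p)
}

# Default values, each with a citation string to the primary literature.
# The power-law exponent and the prestin time are the optimal values obtained
# by fitting this model class to broadband OHC data (see the methods
# vignette); moduli and couplings are representative published estimates.
.ohc_defaults <- list(
  C11 = 0.06, C12 = 0.04, C22 = 0.08,
  eta = 6.5e-6, nu = 0.7, tau_e = 5e-6, C_sp = 0.01,
  alpha1_Csp = -0.08, alpha2_Csp = 0.03, r_c = 5e-6)

.ohc_citations <- c(
  C11 = "representative orthotropic OHC wall modulus; scale from area-modulus estimates ~0.07 N/m (Iwasa 2001; Tolomeo & Steele 1995; Spector et al. 1998)",
  C12 = "representative cross modulus of the orthotropic OHC wall (Tolomeo & Steele 1995; Spector et al. 1998)",
  C22 = "representative circumferential modulus; circumferential actin filaments make the wall stiffer in direction 2 (Tolomeo & Steele 1995)",
  eta = "package default: least-squares fit of the isometric-force amplitude model (nu fixed at 0.7) to a flat broadband force target, 1-80 kHz, emulating microchamber data (Frank et al. 1999); see methods vignette",
  nu = "optimal power-law exponent for broadband OHC force data; upper end of published cell-rheology exponents (cf. Deng et al. 2006; Hoffman & Crocker 2009)",
  tau_e = "RC time of prestin charge transfer from the filter approximation of the Fokker-Planck charge-transfer model (Sun et al. 2009)",
  C_sp = "canonical specific membrane capacitance, 1 uF/cm^2",
  alpha1_Csp = "longitudinal active strain per volt from electromotile length changes in the microchamber experiment (Dallos et al. 1991; Hallworth et al. 1993; Tolomeo & Steele 1995)",
  alpha2_Csp = "circumferential active strain per volt, opposite sign and roughly 0.4x the longitudinal coupling (Dallos et al. 1991; Hallworth et al. 1993)",
  r_c = "typical OHC radius, 5 um")

.sphere_defaults <- list(
  K = 0.24, eta = 6.5e-6, nu = 0.7, tau_e = 5e-6, C_sp = 0.01,
  alpha_Csp = -0.05, r_c = 5e-6)

.sphere_citations <- c(
  K = "area modulus of the plasma membrane, K = 0.24 N/m (Rawicz et al. 2000)",
  eta = .ohc_citations[["eta"]],
  nu = .ohc_citations[["nu"]],
  tau_e = .ohc_citations[["tau_e"]],
  C_sp = .ohc_citations[["C_sp"]],
  alpha_Csp = "from HEK electromotility: ~0.4 V potential change gives ~-0.1 um displacement at ~5 um radius (Zheng et al. 2000); computed by alpha_csp_from_displacement()",
  r_c = "HEK cell radius, about 5 um (Zheng et al. 2000)")

#' Default outer hair cell parameter set
#'
#' Returns the package's default OHC parameter set. Every numeric default
#' carries a citation string retrievable with [param_citations()]; the
#' derivation of the viscoelastic defaults (eta, nu) and of the coupling
#' products is documented in the methods vignette.
#'
#' @return An `ohc_params` object with a `"citations"` attribute.
#' @examples
#' p <- default_ohc_params()
#' p$nu      # 0.7
#' p$tau_e   # 5e-6 s
#' @export
default_ohc_params <- function() {
  p <- do.call(ohc_params, .ohc_defaults)
  attr(p, "citations") <- .ohc_citations
  p
}

#' Default spherical (prestin-transfected cell) parameter set
#'
#' @return A `sphere_params` object with a `"citations"` attribute. The
#'   coupling default equals
#'   `alpha_csp_from_displacement(-0.1e-6, 5e-6, 0.4)` = -0.05 1/V.
#' @export
default_sphere_params <- function() {
  p <- do.call(sphere_params, .sphere_defaults)
  stopifnot(isTRUE(all.equal(p$alpha_Csp,
                             alpha_csp_from_displacement(-0.1e-6, 5e-6, 0.4))))
  attr(p, "citations") <- .sphere_citations
  p
}

#' Electromechanical coupling product from an electromotility measurement
#'
#' For a spherical cell, a steady potential change `delta_V` produces a
#' steady radial displacement `displacement` at radius `radius`; the steady
#' active strain per volt is then `(displacement / radius) / delta_V`, which
#' equals the coupling product alpha * C_sp of the charge-strain coupling
#' (at steady state the transferred charge is C_sp * V per unit area).
#'
#' @param displacement Radial displacement, m (signed).
#' @param radius Cell radius, m (> 0).
#' @param delta_V Change in transmembrane potential, V (nonzero).
#' @return alpha * C_sp in 1/V.
#' @examples
#' alpha_csp_from_displacement(-0.1e-6, 5e-6, 0.4)  # -0.05
#' @export
alpha_csp_from_displacement <- function(displacement, radius, delta_V) {
  stopifnot(is.numeric(displacement), is.numeric(radius), is.numeric(delta_V),
            radius > 0, delta_V != 0)
  (displacement / radius) / delta_V
}

#' Citations attached to a default parameter set
#'
#' @param p A `membrane_params` object carrying a `"citations"` attribute
#'   (as returned by [default_ohc_params()] / [default_sphere_params()]).
#' @return A data.frame with columns `field`, `value`, `citation`.
#' @export
param_citations <- function(p) {
  cit <- attr(p, "citations")
  if (is.null(cit)) stop("parameter object carries no citations", call. = FALSE)
  data.frame(field = names(cit),
             value = unlist(p[names(cit)], use.names = FALSE),
             citation = unname(cit),
             stringsAsFactors = FALSE)
}

#' @export
print.membrane_params <- function(x, ...) {
  geom <- if (inherits(x, "ohc_params")) "cylinder (outer hair cell)"
          else "sphere (prestin-transfected cell)"
  cat("<membrane_params>", geom, "\n")
  for (f in names(x)) cat(sprintf("  %-11s %g\n", f, x[[f]]))
  invisible(x)
}

# ---- config file I/O --------------------------------------------------------

.time_scale <- c(s = 1, ms = 1e-3, us = 1e-6)

#' Read a membrane parameter set from a JSON config file
#'
#' The config schema (shipped as `inst/extdata/config-schema.md`) has
#' top-level sections `geometry` ("cylinder" or "sphere"), `mechanical`,
#' `electrical`, `coupling` and `cell`, plus an optional `units` section.
#' All values are SI unless `units` declares otherwise; currently
#' `units$tau_e` may be "s", "ms" or "us". The returned object passes
#' [validate_params()].
#'
#' @param path Path to a JSON file.
#' @return An `ohc_params` or `sphere_params` object.
#' @seealso [write_params()]
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- function(section, field) {
    v <- cfg[[section]][[field]]
    if (is.null(v)) stop("config is missing field '", section, "$", field, "'",
                         call. = FALSE)
    v
  }
  geom <- cfg$geometry
  if (is.null(geom) || !geom %in% c("cylinder", "sphere"))
    stop("config field 'geometry' must be \"cylinder\" or \"sphere\"",
         call. = FALSE)
  tau_e <- need("electrical", "tau_e")
  if (!is.null(cfg$units$tau_e)) {
    u <- cfg$units$tau_e
    if (!u %in% names(.time_scale))
      stop("units$tau_e must be one of ", paste(names(.time_scale),
           collapse = ", "), call. = FALSE)
    tau_e <- tau_e * .time_scale[[u]]
  }
  if (geom == "cylinder") {
    ohc_params(C11 = need("mechanical", "C11"),
               C12 = need("mechanical", "C12"),
               C22 = need("mechanical", "C22"),
               eta = need("mechanical", "eta"),
               nu  = need("mechanical", "nu"),
               tau_e = tau_e,
               C_sp  = need("electrical", "C_sp"),
               alpha1_Csp = need("coupling", "alpha1_Csp"),
               alpha2_Csp = need("coupling", "alpha2_Csp"),
               r_c = need("cell", "r_c"))
  } else {
    sphere_params(K  = need("mechanical", "K"),
                  eta = need("mechanical", "eta"),
                  nu  = need("mechanical", "nu"),
                  tau_e = tau_e,
                  C_sp  = need("electrical", "C_sp"),
                  alpha_Csp = need("coupling", "alpha_Csp"),
                  r_c = need("cell", "r_c"))
  }
}

#' Write a membrane parameter set to a JSON config file
#'
#' Values are written in SI units; the written file round-trips through
#' [load_params()] field-for-field.
#'
#' @param p A validated `membrane_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  cfg <- if (inherits(p, "ohc_params")) {
    list(geometry = "cylinder",
         mechanical = p[c("C11", "C12", "C22", "eta", "nu")],
         electrical = p[c("tau_e", "C_sp")],
         coupling   = p[c("alpha1_Csp", "alpha2_Csp")],
         cell       = p["r_c"])
  } else {
    list(geometry = "sphere",
         mechanical = p[c("K", "eta", "nu")],
         electrical = p[c("tau_e", "C_sp")],
         coupling   = p["alpha_Csp"],
         cell       = p["r_c"])
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
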