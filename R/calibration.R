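#' Oxyphor calibration constants
#'
#' Stern-Volmer calibration for a phosphorescent oxygen probe: the lifetime in
#' a zero-oxygen environment `tau0_s` and the quenching constant `kq`, so that
#' \eqn{1/\tau = 1/\tau_0 + k_q \cdot PO_2}. R0 (Pd-meso-tetra(4-carboxyphenyl)
#' porphyrin) is confined to the blood plasma after intravenous injection; G2
#' (Pd-tetra(4-carboxyphenyl)benzoporphyrin dendrimer) labels the retinal
#' tissue after intravitreal injection.
#'
#' Calibration constants are instrument- and environment-specific and should be
#' supplied explicitly. When omitted, literature placeholder values are used
#' (R0: tau0 = 637 us, kq = 381 /mmHg/s; G2: tau0 = 251 us, kq = 281 /mmHg/s)
#' and a warning is emitted.
#'
#' @param name Probe name, `"R0"` (vascular) or `"G2"` (tissue).
#' @param tau0_s Zero-oxygen lifetime in seconds.
#' @param kq Quenching constant in mmHg^-1 s^-1.
#' @param source Optional citation string for the constants.
#' @return An object of class `oxyphor_calibration`.
#' @examples
#' cal <- oxyphor_calibration("G2", tau0_s = 251e-6, kq = 281)
#' @export
oxyphor_calibration <- function(name = c("R0", "G2"), tau0_s = NULL, kq = NULL,
                                source = NULL) {
  name <- match.arg(name)
  defaults <- list(
    R0 = list(tau0_s = 637e-6, kq = 381),
    G2 = list(tau0_s = 251e-6, kq = 281)
  )[[name]]
  used_default <- is.null(tau0_s) || is.null(kq)
  if (is.null(tau0_s)) tau0_s <- defaults$tau0_s
  if (is.null(kq)) kq <- defaults$kq
  if (used_default) {
    warning(sprintf(
      paste0("using literature placeholder calibration for %s ",
             "(tau0 = %.0f us, kq = %.0f /mmHg/s); supply instrument-specific ",
             "constants for quantitative use"),
      name, tau0_s * 1e6, kq), call. = FALSE)
  }
  stopifnot(is.numeric(tau0_s), length(tau0_s) == 1L, tau0_s > 0,
            is.numeric(kq), length(kq) == 1L, kq > 0)
  structure(
    list(name = name, tau0_s = tau0_s, kq = kq,
         source = source %||% if (used_default) "literature placeholder" else NA_character_),
    class = "oxyphor_calibration")
}

#' @export
print.oxyphor_calibration <- function(x, ...) {
  cat(sprintf("<oxyphor_calibration> %s: tau0 = %.1f us, kq = %.1f /mmHg/s (%s)\n",
              x$name, x$tau0_s * 1e6, x$kq, x$source))
  invisible(x)
}

#' Oxyhemoglobin dissociation curve (Hill form)
#'
#' Hill model of hemoglobin oxygen saturation,
#' \eqn{S(PO_2) = PO_2^n / (PO_2^n + P_{50}^n)}, plus the constants needed to
#' convert saturation to blood oxygen content:
#' \eqn{C = c_{Hb} S(PO_2) + \alpha \cdot PO_2}.
#'
#' Defaults are literature placeholder values for rat blood (P50 = 36 mmHg,
#' n = 2.7, Hb capacity 0.2 mL O2/mL blood, solubility 3e-5 mL O2/mL/mmHg);
#' a warning is emitted when any of them is filled in.
#'
#' @param p50_mmHg Half-saturation oxygen tension, mmHg.
#' @param hill_n Hill cooperativity exponent (dimensionless).
#' @param hb_capacity Oxygen-carrying capacity at full saturation, mL O2 per mL
#'   blood.
#' @param solubility Physically dissolved oxygen, mL O2 per mL blood per mmHg.
#'   Set to 0 to ignore dissolved oxygen.
#' @param source Optional citation string.
#' @return An object of class `dissociation_curve`.
#' @examples
#' curve <- dissociation_curve(p50_mmHg = 36, hill_n = 2.7,
#'                             hb_capacity = 0.2, solubility = 3e-5)
#' @export
dissociation_curve <- function(p50_mmHg = NULL, hill_n = NULL,
                               hb_capacity = NULL, solubility = NULL,
                               source = NULL) {
  used_default <- is.null(p50_mmHg) || is.null(hill_n) ||
    is.null(hb_capacity) || is.null(solubility)
  if (is.null(p50_mmHg)) p50_mmHg <- 36
  if (is.null(hill_n)) hill_n <- 2.7
  if (is.null(hb_capacity)) hb_capacity <- 0.2
  if (is.null(solubility)) solubility <- 3e-5
  if (used_default) {
    warning("using literature placeholder rat dissociation-curve constants; ",
            "supply study-specific values for quantitative use", call. = FALSE)
  }
  stopifnot(p50_mmHg > 0, hill_n > 0, hb_capacity > 0, solubility >= 0)
  structure(
    list(p50_mmHg = p50_mmHg, hill_n = hill_n, hb_capacity = hb_capacity,
         solubility = solubility,
         source = source %||% if (used_default) "literature placeholder" else NA_character_),
    class = "dissociation_curve")
}

#' @export
print.dissociation_curve <- function(x, ...) {
  cat(sprintf(
    "<dissociation_curve> P50 = %.1f mmHg, n = %.2f, Hb capacity = %.3f, alpha = %.2g\n",
    x$p50_mmHg, x$hill_n, x$hb_capacity, x$solubility))
  invisible(x)
}

#' Default oxygen diffusivity-solubility product for retinal tissue
#'
#' Returns the literature placeholder Dk (oxygen diffusion coefficient times
#' solubility) of 1.97e-10 mL O2 cm^-1 s^-1 mmHg^-1, converted to per-minute
#' units (1.182e-8 mL O2 cm^-1 min^-1 mmHg^-1) as used by the three-layer
#' diffusion model. Emits a warning: Dk is tissue- and temperature-specific and
#' should be configured explicitly.
#'
#' @return Dk in mL O2 cm^-1 min^-1 mmHg^-1.
#' @export
default_dk <- function() {
  warning("using literature placeholder Dk = 1.97e-10 mL O2/cm/s/mmHg; ",
          "supply a study-specific value for quantitative use", call. = FALSE)
  1.97e-10 * 60
}

`%||%` <- function(a, b) if (is.null(a)) b else a
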