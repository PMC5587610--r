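#' Hemoglobin oxygen saturation (Hill equation)
#'
#' \eqn{S(PO_2) = PO_2^n / (PO_2^n + P_{50}^n)}.
#'
#' @param po2_mmHg Oxygen tension, mmHg (vectorized, must be >= 0).
#' @param curve A [dissociation_curve()].
#' @return Saturation in [0, 1).
#' @export
hill_saturation <- function(po2_mmHg, curve) {
  if (any(po2_mmHg < 0, na.rm = TRUE)) {
    stop("oxygen tension must be non-negative")
  }
  p <- po2_mmHg^curve$hill_n
  p / (p + curve$p50_mmHg^curve$hill_n)
}

#' Blood oxygen content
#'
#' Hemoglobin-bound plus physically dissolved oxygen:
#' \eqn{C = c_{Hb} S(PO_2) + \alpha PO_2} in mL O2 per mL blood.
#'
#' @inheritParams hill_saturation
#' @return Oxygen content, mL O2 per mL blood.
#' @export
o2_content <- function(po2_mmHg, curve) {
  curve$hb_capacity * hill_saturation(po2_mmHg, curve) +
    curve$solubility * po2_mmHg
}

#' Inner retinal oxygen extraction fraction
#'
#' The fraction of the oxygen delivered by the retinal circulation that the
#' inner retina extracts: \eqn{OEF = (C_a - C_v)/C_a} with arterial and venous
#' contents from [o2_content()]. Computed per animal from that animal's mean
#' arterial and venous tensions.
#'
#' @param po2a,po2v Mean arterial and venous oxygen tension, mmHg
#'   (`po2a > 0`).
#' @param curve A [dissociation_curve()].
#' @return A one-row tibble: `po2a_mmHg`, `po2v_mmHg`, `sa`, `sv`, `ca`, `cv`,
#'   `oef`.
#' @examples
#' crv <- dissociation_curve(36, 2.7, 0.2, 3e-5)
#' oef(41, 25, crv)$oef
#' @export
oef <- function(po2a, po2v, curve) {
  stopifnot(is.numeric(po2a), length(po2a) == 1, po2a > 0,
            is.numeric(po2v), length(po2v) == 1, po2v >= 0)
  sa <- hill_saturation(po2a, curve)
  sv <- hill_saturation(po2v, curve)
  ca <- o2_content(po2a, curve)
  cv <- o2_content(po2v, curve)
  if (ca <= 0) stop("arterial oxygen content is zero; OEF undefined")
  tibble::tibble(po2a_mmHg = po2a, po2v_mmHg = po2v,
                 sa = sa, sv = sv, ca = ca, cv = cv,
                 oef = (ca - cv) / ca)
}

#' Cohort summary statistics
#'
#' Mean and SD per measured quantity, paired two-sided t tests for
#' (arterial vs venous tension) and (venous tension vs mean inner tissue
#' tension), and ordinary least-squares regressions of QO2 on maximum outer
#' tissue tension and of OEF on mean inner tissue tension.
#'
#' @param per_animal A data frame with one row per animal and (any subset of)
#'   columns `po2a`, `po2v`, `inner_tpo2`, `max_outer_tpo2`, `min_outer_tpo2`,
#'   `oef`, `qo2`. At least 3 animals.
#' @return A list of tibbles: `summary` (variable, mean, sd, n), `paired`
#'   (comparison, mean_diff, t, df, p), `regressions` (response, predictor,
#'   slope, intercept, r2, p). Statistics that are undefined for the data
#'   (degenerate variance, missing columns) come back as `NA` rows.
#' @export
cohort_stats <- function(per_animal) {
  stopifnot(is.data.frame(per_animal), nrow(per_animal) >= 3)
  vars <- intersect(c("po2a", "po2v", "inner_tpo2", "max_outer_tpo2",
                      "min_outer_tpo2", "oef", "qo2"), names(per_animal))
  summary_tbl <- purrr::map_dfr(vars, function(v) {
    x <- per_animal[[v]]
    tibble::tibble(variable = v, mean = mean(x, na.rm = TRUE),
                   sd = stats::sd(x, na.rm = TRUE), n = sum(is.finite(x)))
  })

  paired_test <- function(a, b, label) {
    if (!all(c(a, b) %in% names(per_animal))) {
      return(tibble::tibble(comparison = label, mean_diff = NA_real_,
                            t = NA_real_, df = NA_real_, p = NA_real_))
    }
    x <- per_animal[[a]]; y <- per_animal[[b]]
    ok <- is.finite(x) & is.finite(y)
    res <- tryCatch(stats::t.test(x[ok], y[ok], paired = TRUE),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$statistic)) {
      # zero-variance differences: t undefined unless the difference is 0
      d <- x[ok] - y[ok]
      t_val <- if (stats::sd(d) == 0 && mean(d) == 0) 0 else NA_real_
      return(tibble::tibble(comparison = label, mean_diff = mean(d),
                            t = t_val, df = length(d) - 1, p = NA_real_))
    }
    tibble::tibble(comparison = label,
                   mean_diff = unname(res$estimate),
                   t = unname(res$statistic), df = unname(res$parameter),
                   p = res$p.value)
  }
  paired_tbl <- dplyr::bind_rows(
    paired_test("po2a", "po2v", "po2a - po2v"),
    paired_test("po2v", "inner_tpo2", "po2v - inner_tpo2"))

  regress <- function(yv, xv) {
    if (!all(c(yv, xv) %in% names(per_animal))) {
      return(tibble::tibble(response = yv, predictor = xv, slope = NA_real_,
                            intercept = NA_real_, r2 = NA_real_,
                            p = NA_real_))
    }
    d <- data.frame(y = per_animal[[yv]], x = per_animal[[xv]])
    d <- d[is.finite(d$y) & is.finite(d$x), ]
    if (nrow(d) < 3 || stats::sd(d$x) == 0) {
      return(tibble::tibble(response = yv, predictor = xv, slope = NA_real_,
                            intercept = NA_real_, r2 = NA_real_,
                            p = NA_real_))
    }
    fit <- stats::lm(y ~ x, data = d)
    sm <- summary(fit)
    p_val <- if (sm$sigma == 0) NA_real_ else
      stats::coef(sm)["x", "Pr(>|t|)"]
    tibble::tibble(response = yv, predictor = xv,
                   slope = stats::coef(fit)[["x"]],
                   intercept = stats::coef(fit)[["(Intercept)"]],
                   r2 = sm$r.squared, p = p_val)
  }
  reg_tbl <- dplyr::bind_rows(
    regress("qo2", "max_outer_tpo2"),
    regress("oef", "inner_tpo2"))

  list(summary = summary_tbl, paired = paired_tbl, regressions = reg_tbl)
}
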