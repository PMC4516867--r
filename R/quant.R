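# Isotope-dilution quantification: unit conversion, sample-preparation
# arithmetic, calibration fitting, LOD, and the end-to-end per-run pipeline.

#' Average molecular weight of a formula
#'
#' Uses conventional (average) atomic weights, the scale on which weighed
#' material is specified; deuterium counts at the 2H mass.
#'
#' @param f A [parse_formula()] result.
#' @return Molecular weight in g/mol.
#' @export
average_mw <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  sum(vapply(names(f$counts), function(sym) {
    w <- .AVERAGE_WEIGHTS[[sym]]
    if (is.null(w) || is.na(w)) stop("no average weight for '", sym, "'",
                                     call. = FALSE)
    w * f$counts[[sym]]
  }, numeric(1)))
}

#' Convert nanograms to picomoles
#'
#' `mass_ng / MW * 1000` with the average molecular weight of the (salt)
#' formula. For denatonium benzoate (C28H34N2O3, MW ~446.6 g/mol), 0.68 ng
#' is 1.52 pmol.
#'
#' @param mass_ng Mass in ng (>= 0).
#' @param f Formula of the weighed species, e.g.
#'   `parse_formula("C28H34N2O3")` for the benzoate salt.
#' @return Amount in pmol.
#' @export
ng_to_pmol <- function(mass_ng, f = parse_formula("C28H34N2O3")) {
  stopifnot(mass_ng >= 0)
  mass_ng / average_mw(f) * 1000
}

#' @rdname ng_to_pmol
#' @param amount_pmol Amount in pmol (>= 0).
#' @export
pmol_to_ng <- function(amount_pmol, f = parse_formula("C28H34N2O3")) {
  stopifnot(amount_pmol >= 0)
  amount_pmol * average_mw(f) / 1000
}

#' Sample-preparation scheme
#'
#' Volumes and concentrations of the dilution chain: a sample volume is
#' evaporated and reconstituted, an aliquot is diluted and spiked with the
#' labeled standard, and a fixed volume is injected. The default values
#' mirror a 20 uL aliquot of a 200 uL reconstitution diluted with 123 uL
#' water plus 2 uL of 0.5 mg/mL standard (final 145 uL).
#'
#' @param sample_volume_uL Volume of original sample taken.
#' @param reconstitution_volume_uL Volume the evaporated residue is dissolved
#'   in.
#' @param aliquot_uL Aliquot of the reconstituted solution carried forward.
#' @param diluent_uL Diluent added to the aliquot.
#' @param standard_volume_uL Volume of standard solution spiked in.
#' @param standard_conc_mg_per_mL Concentration of the standard solution.
#' @param injection_volume_uL Volume injected on column.
#' @return A `prep_scheme` list.
#' @export
prep_scheme <- function(sample_volume_uL = 1300,
                        reconstitution_volume_uL = 200,
                        aliquot_uL = 20, diluent_uL = 123,
                        standard_volume_uL = 2,
                        standard_conc_mg_per_mL = 0.5,
                        injection_volume_uL = 5) {
  vals <- c(sample_volume_uL, reconstitution_volume_uL, aliquot_uL,
            diluent_uL, standard_volume_uL, standard_conc_mg_per_mL,
            injection_volume_uL)
  if (any(vals <= 0)) stop("all scheme quantities must be > 0", call. = FALSE)
  if (aliquot_uL > reconstitution_volume_uL) {
    stop("aliquot cannot exceed the reconstitution volume", call. = FALSE)
  }
  structure(list(sample_volume_uL = sample_volume_uL,
                 reconstitution_volume_uL = reconstitution_volume_uL,
                 aliquot_uL = aliquot_uL, diluent_uL = diluent_uL,
                 standard_volume_uL = standard_volume_uL,
                 standard_conc_mg_per_mL = standard_conc_mg_per_mL,
                 injection_volume_uL = injection_volume_uL),
            class = "prep_scheme")
}

#' On-column amounts implied by a preparation scheme
#'
#' Chains concentration x volume through the scheme: evaporation carries all
#' analyte from the sample volume into the reconstitution volume; the
#' aliquot, diluent and standard spike define the final vial; the injection
#' volume then gives on-column masses for both species.
#'
#' @param scheme A [prep_scheme()].
#' @param analyte_conc_ug_per_mL Analyte concentration in the original
#'   sample (ug/mL; >= 0).
#' @return List with `analyte_ng` and `standard_ng` on column, plus
#'   `analyte_ng_vial`, `standard_ng_vial` and `final_volume_uL`.
#' @export
prep_amounts <- function(scheme, analyte_conc_ug_per_mL) {
  stopifnot(inherits(scheme, "prep_scheme"), analyte_conc_ug_per_mL >= 0)
  analyte_ug <- analyte_conc_ug_per_mL * scheme$sample_volume_uL / 1000
  aliquot_frac <- scheme$aliquot_uL / scheme$reconstitution_volume_uL
  analyte_ng_vial <- analyte_ug * aliquot_frac * 1000
  standard_ng_vial <- scheme$standard_volume_uL *
    scheme$standard_conc_mg_per_mL * 1e3  # uL * mg/mL = ug -> ng
  final_volume <- scheme$aliquot_uL + scheme$diluent_uL +
    scheme$standard_volume_uL
  inj_frac <- scheme$injection_volume_uL / final_volume
  list(analyte_ng = analyte_ng_vial * inj_frac,
       standard_ng = standard_ng_vial * inj_frac,
       analyte_ng_vial = analyte_ng_vial,
       standard_ng_vial = standard_ng_vial,
       final_volume_uL = final_volume)
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of response against amount; R-squared is the
#' squared Pearson correlation and the residual standard deviation comes
#' from the fit.
#'
#' @param amount_ng Calibration amounts (>= 3 points, >= 2 distinct).
#' @param response Measured responses (same length).
#' @return A `calibration_result`: `slope`, `intercept`, `r_squared`,
#'   `residual_sd`, `n`, plus `lod_ng`/`lod_pmol` slots filled by
#'   [estimate_lod()].
#' @export
fit_calibration <- function(amount_ng, response) {
  stopifnot(length(amount_ng) == length(response))
  if (length(amount_ng) < 3) stop("need at least 3 points", call. = FALSE)
  if (length(unique(amount_ng)) < 2) {
    stop("degenerate design: all amounts identical", call. = FALSE)
  }
  fit <- stats::lm(response ~ amount_ng)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 n = length(amount_ng),
                 lod_ng = NA_real_, lod_pmol = NA_real_),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> slope %.4g, intercept %.4g, R^2 %.6f\n",
              x$slope, x$intercept, x$r_squared))
  if (!is.na(x$lod_ng)) {
    cat(sprintf("  LOD %.3g ng (%.3g pmol)\n", x$lod_ng, x$lod_pmol))
  }
  invisible(x)
}

#' Limit of detection from a calibration fit
#'
#' ICH-style estimator: `lod_ng = 3.3 * residual_sd / slope`, converted to
#' pmol via the average molecular weight of the salt formula. A residual sd
#' of zero yields a zero LOD flagged as below the simulation floor.
#'
#' @param cal A [fit_calibration()] result with positive slope.
#' @param salt_formula Formula used for the ng -> pmol conversion.
#' @return The `calibration_result` with `lod_ng`, `lod_pmol` and
#'   `lod_below_floor` filled in.
#' @export
estimate_lod <- function(cal, salt_formula = parse_formula("C28H34N2O3")) {
  stopifnot(inherits(cal, "calibration_result"))
  if (cal$slope <= 0) stop("slope must be positive for LOD", call. = FALSE)
  cal$lod_ng <- 3.3 * cal$residual_sd / cal$slope
  cal$lod_pmol <- ng_to_pmol(cal$lod_ng, salt_formula)
  cal$lod_below_floor <- cal$lod_ng < 1e-9
  cal
}

#' Quantify one LC-MS run by isotope dilution
#'
#' End-to-end pipeline for a single run: extract the XIC spanning the full
#' light+heavy envelope, detect the chromatographic peak, sum the spectra
#' across the peak bounds, project the summed spectrum onto the basis grid,
#' estimate light/heavy fractions by NNLS, and scale the spiked standard
#' amount by the light/heavy ratio. When a [prep_scheme()] is given, the
#' on-column amount is back-calculated to a concentration in the original
#' sample. All intermediates are returned.
#'
#' @param run A `centroid_run`.
#' @param basis An [build_basis()] result.
#' @param standard_pmol Spiked internal-standard amount on column (pmol).
#' @param scheme Optional [prep_scheme()] for back-calculation.
#' @param mz_tol Matching tolerance for [match_envelope()].
#' @param min_snr Passed to [find_peak()].
#' @param salt_formula Formula for pmol -> ng conversion in the report.
#' @return A `quant_result` list: `analyte_pmol`, `analyte_ng`, `fractions`
#'   (the [estimate_fractions()] record), `peak` (the [find_peak()] region),
#'   `light_area`, `heavy_area`, `response` (light/heavy area ratio),
#'   `detected`, and `sample_conc_ug_per_mL` when a scheme is supplied.
#' @export
quantify_run <- function(run, basis, standard_pmol, scheme = NULL,
                         mz_tol = 0.01, min_snr = 5,
                         salt_formula = parse_formula("C28H34N2O3")) {
  stopifnot(inherits(run, "centroid_run"), inherits(basis, "envelope_basis"),
            standard_pmol > 0)
  grid <- basis$mz_grid
  center <- mean(range(grid))
  half <- diff(range(grid)) / 2 + 0.5
  x <- extract_xic(run, center, half)
  pk <- find_peak(x, min_snr)
  if (is.null(pk)) {
    return(structure(list(analyte_pmol = 0, analyte_ng = 0, fractions = NULL,
                          peak = NULL, detected = FALSE,
                          stage = "find_peak: no peak above threshold"),
                     class = "quant_result"))
  }
  idx <- pk$start_index:pk$end_index
  peaks <- do.call(rbind, lapply(run$scans[idx], function(s) s$peaks))
  mt <- match_envelope(peaks, basis, mz_tol)
  est <- tryCatch(estimate_fractions(mt$observed, basis),
                  error = function(e) stop("estimate_fractions: ",
                                           conditionMessage(e), call. = FALSE))
  amount <- tryCatch(ratio_and_amount(est, standard_pmol),
                     error = function(e) stop("ratio_and_amount: ",
                                              conditionMessage(e), call. = FALSE))
  total <- sum(mt$observed)
  light_area <- total * est$light_fraction
  heavy_area <- total * est$heavy_fraction
  out <- list(analyte_pmol = amount,
              analyte_ng = pmol_to_ng(amount, salt_formula),
              fractions = est, peak = pk,
              light_area = light_area, heavy_area = heavy_area,
              response = light_area / heavy_area,
              foreign_intensity = mt$foreign_intensity,
              detected = TRUE)
  if (!is.null(scheme)) {
    # invert the prep chain: on-column ng -> vial -> reconstitution -> sample
    unit <- prep_amounts(scheme, 1)  # ng on column per 1 ug/mL in sample
    out$sample_conc_ug_per_mL <- out$analyte_ng / unit$analyte_ng
  }
  structure(out, class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  if (!x$detected) {
    cat("<quant_result> non-detect (", x$stage, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<quant_result> %.4g pmol (%.4g ng) analyte on column\n",
              x$analyte_pmol, x$analyte_ng))
  cat(sprintf("  light/heavy = %.4f/%.4f, residual %.3g\n",
              x$fractions$light_fraction, x$fractions$heavy_fraction,
              x$fractions$residual_norm))
  if (!is.null(x$sample_conc_ug_per_mL)) {
    cat(sprintf("  back-calculated sample conc: %.4g ug/mL\n",
                x$sample_conc_ug_per_mL))
  }
  invisible(x)
}
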