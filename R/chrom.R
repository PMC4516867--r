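# Extracted ion chromatograms, peak detection, co-elution and peak purity.

#' Extract an ion chromatogram
#'
#' Per-scan summed intensity of centroid peaks within `[mz - tol, mz + tol]`;
#' zero where no peak matches.
#'
#' @param run A `centroid_run`.
#' @param mz Target m/z (Da).
#' @param tol Half-width of the extraction window (Da, > 0).
#' @return An `xic`: data frame with `rt` (minutes) and `intensity`, plus
#'   attributes `target_mz` and `tol`.
#' @export
extract_xic <- function(run, mz, tol) {
  stopifnot(inherits(run, "centroid_run"), tol > 0)
  rt <- vapply(run$scans, function(s) s$rt, numeric(1))
  intensity <- vapply(run$scans, function(s) {
    p <- s$peaks
    sum(p$intensity[abs(p$mz - mz) <= tol])
  }, numeric(1))
  structure(data.frame(rt = rt, intensity = intensity),
            target_mz = mz, tol = tol, class = c("xic", "data.frame"))
}

#' Detect the chromatographic peak in an XIC
#'
#' The apex is the maximum point. A baseline and noise scale are estimated
#' robustly (median and MAD of the trace); the peak exists only if the apex
#' exceeds `baseline + min_snr * noise`. Bounds are where the trace falls
#' below `max(baseline + min_snr * noise, 5%% of apex)`, padded by two scans
#' on each side so the integrated tails cover >99%% of a Gaussian peak; the
#' area is trapezoidal over the bounded region. Disjoint above-threshold
#' segments are counted as peak candidates and the tallest is returned.
#'
#' @param x An [extract_xic()] result.
#' @param min_snr Signal-to-noise multiple required above baseline.
#' @return A `peak_region` list: `rt_apex`, `rt_start`, `rt_end`, `area`,
#'   `apex_index`, `start_index`, `end_index`, `n_candidates`; or `NULL`
#'   (no-peak) when nothing exceeds the threshold.
#' @export
find_peak <- function(x, min_snr = 5) {
  stopifnot(inherits(x, "xic"), nrow(x) > 0)
  it <- x$intensity
  base <- stats::median(it)
  noise <- stats::mad(it)
  apex <- which.max(it)
  if (it[apex] <= 0 || it[apex] <= base + min_snr * noise) return(NULL)
  thr <- max(base + min_snr * noise, 0.05 * it[apex])
  above <- it > thr
  segs <- rle(above)
  n_candidates <- sum(segs$values)
  i0 <- apex
  while (i0 > 1 && it[i0 - 1] > thr) i0 <- i0 - 1
  i1 <- apex
  while (i1 < length(it) && it[i1 + 1] > thr) i1 <- i1 + 1
  i0 <- max(1, i0 - 2)
  i1 <- min(length(it), i1 + 2)
  area <- pracma::trapz(x$rt[i0:i1], it[i0:i1])
  structure(list(rt_apex = x$rt[apex], rt_start = x$rt[i0], rt_end = x$rt[i1],
                 area = area, apex_index = apex, start_index = i0,
                 end_index = i1, n_candidates = n_candidates),
            class = "peak_region")
}

#' Retention-time difference between the light and heavy channels
#'
#' Extracts one XIC per channel, detects both peaks, and reports the
#' absolute apex difference in scan units (sub-scan precision is not
#' implied; multiply by the scan interval for minutes).
#'
#' @param run A `centroid_run`.
#' @param light_mz,heavy_mz Monoisotopic m/z of the two channels.
#' @param tol Extraction half-width in Da.
#' @param min_snr Passed to [find_peak()].
#' @return Absolute apex index difference in scans.
#' @export
coelution_delta <- function(run, light_mz, heavy_mz, tol = 0.01,
                            min_snr = 5) {
  pk_l <- find_peak(extract_xic(run, light_mz, tol), min_snr)
  pk_h <- find_peak(extract_xic(run, heavy_mz, tol), min_snr)
  if (is.null(pk_l) || is.null(pk_h)) {
    stop("no peak detected in one of the channels", call. = FALSE)
  }
  abs(pk_l$apex_index - pk_h$apex_index)
}

#' Peak purity across a chromatographic peak
#'
#' Deconvolves every scan inside the region independently and reports the
#' series of per-scan light fractions together with its standard deviation.
#' A pure, co-eluting peak has a constant fraction (sd 0 without noise);
#' composition drift across the peak — e.g. a shifted heavy profile — shows
#' up as dispersion.
#'
#' @param run A `centroid_run`.
#' @param region A [find_peak()] result with at least 3 scans.
#' @param basis An [build_basis()] result.
#' @param mz_tol Matching tolerance for [match_envelope()].
#' @return List with `rt`, `light_fraction` (per-scan series) and `sd`.
#' @export
peak_purity <- function(run, region, basis, mz_tol = 0.01) {
  stopifnot(inherits(region, "peak_region"))
  idx <- region$start_index:region$end_index
  if (length(idx) < 3) stop("region must contain at least 3 scans", call. = FALSE)
  rt <- numeric(0); lf <- numeric(0)
  for (i in idx) {
    s <- run$scans[[i]]
    mt <- suppressWarnings(match_envelope(s$peaks, basis, mz_tol))
    if (all(mt$observed == 0)) next
    est <- estimate_fractions(mt$observed, basis)
    rt <- c(rt, s$rt)
    lf <- c(lf, est$light_fraction)
  }
  if (length(lf) < 3) stop("fewer than 3 scans carried envelope signal",
                           call. = FALSE)
  list(rt = rt, light_fraction = lf, sd = stats::sd(lf))
}
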