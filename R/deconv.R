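# Envelope deconvolution: decompose an observed isotopic envelope into
# light (analyte) and heavy (labeled standard) contributions by non-negative
# least squares over theoretical basis envelopes. With exactly two species
# and complete labeling this reduces to the classical overlap-corrected peak
# ratio; the NNLS form additionally handles partial labeling states and uses
# the whole envelope rather than two peaks.

#' Build the light/heavy envelope basis
#'
#' The reference m/z grid is the union of the centroids of the light pattern
#' and the labeling-state mixture pattern of the standard, merged at
#' `merge_tol` so that overlapping centroids — notably the light M+2 and the
#' alpha-d2 monoisotopic peak, ~6 mDa apart — share one grid position. Each
#' column is the species' abundance vector on that grid (columns sum to 1).
#'
#' @param light A [parse_formula()] result for the unlabeled ion.
#' @param standard_states A [state_distribution()] for the standard; each
#'   labeled formula must carry the same charge as `light` (guaranteed by
#'   [labeled_formula()]).
#' @param merge_tol Grid merge tolerance in Da. The default 0.01 is below the
#'   1-Da isotopic spacing but above the light-M+2 / heavy-M+0 split.
#' @param pattern_tol Centroid merge tolerance used when computing each
#'   species' pattern before aggregation onto the grid; kept at the
#'   fine-pattern default so basis columns and generated spectra share one
#'   pattern computation.
#' @return An `envelope_basis`: list with `mz_grid`, `light`, `heavy`
#'   (abundance vectors), and `charge`.
#' @export
build_basis <- function(light, standard_states, merge_tol = 0.01,
                        pattern_tol = 1e-3) {
  stopifnot(inherits(light, "molecular_formula"))
  lp <- isotope_pattern(light, merge_tol = pattern_tol)
  hp <- mixture_pattern(light, standard_states, merge_tol = pattern_tol)
  allmz <- c(lp$mz, hp$mz)
  allab <- c(lp$abundance, hp$abundance)
  grid <- merge_centroids(allmz, allab, merge_tol)$mz
  assign_col <- function(p) {
    v <- numeric(length(grid))
    idx <- vapply(p$mz, function(m) which.min(abs(grid - m)), integer(1))
    for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + p$abundance[i]
    v
  }
  structure(list(mz_grid = grid, light = assign_col(lp),
                 heavy = assign_col(hp), charge = light$charge),
            class = "envelope_basis")
}

#' Project observed peaks onto the basis grid
#'
#' Each grid centroid receives the summed intensity of observed peaks within
#' `mz_tol`; observed peaks inside the envelope's m/z span that match no grid
#' point are reported as foreign intensity (interference accounting).
#'
#' @param peaks Data frame with `mz`, `intensity` (one spectrum).
#' @param basis An [build_basis()] result.
#' @param mz_tol Matching tolerance in Da (~30 ppm at m/z 325 by default).
#' @return List with `observed` (vector on the grid) and
#'   `foreign_intensity`. An empty match yields a zero vector with a warning.
#' @export
match_envelope <- function(peaks, basis, mz_tol = 0.01) {
  stopifnot(inherits(basis, "envelope_basis"), mz_tol > 0)
  grid <- basis$mz_grid
  obs <- numeric(length(grid))
  foreign <- 0
  if (nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      d <- abs(grid - peaks$mz[i])
      j <- which.min(d)
      if (d[j] <= mz_tol) {
        obs[j] <- obs[j] + peaks$intensity[i]
      } else if (peaks$mz[i] >= min(grid) - 1 && peaks$mz[i] <= max(grid) + 1) {
        foreign <- foreign + peaks$intensity[i]
      }
    }
  }
  if (all(obs == 0)) {
    warning("no observed peaks matched the envelope grid", call. = FALSE)
  }
  list(observed = obs, foreign_intensity = foreign)
}

#' Estimate light and heavy fractions
#'
#' Non-negative least squares of `observed ~ a * light + b * heavy`; the
#' reported fractions are `a/(a+b)` and `b/(a+b)` (normalized after the
#' solve so the residual stays interpretable), with the L1 residual as a
#' fraction of total observed intensity.
#'
#' @param observed Non-negative vector on the basis grid (from
#'   [match_envelope()]), not all zero.
#' @param basis An [build_basis()] result.
#' @return A `fraction_estimate`: list with `light_fraction`,
#'   `heavy_fraction`, `residual_norm`.
#' @export
estimate_fractions <- function(observed, basis) {
  stopifnot(inherits(basis, "envelope_basis"))
  if (any(observed < 0)) stop("observed intensities must be >= 0", call. = FALSE)
  if (all(observed == 0)) stop("observed vector is all zero", call. = FALSE)
  A <- cbind(light = basis$light, heavy = basis$heavy)
  ata <- crossprod(A)
  cnd <- kappa(ata, exact = TRUE)
  if (!is.finite(cnd) || cnd > 1e8) {
    stop("basis columns are collinear (condition ", format(cnd, digits = 3),
         "); light and heavy envelopes are indistinguishable", call. = FALSE)
  }
  fit <- pracma::lsqnonneg(A, observed)
  x <- fit$x
  if (sum(x) == 0) stop("degenerate fit: both coefficients zero", call. = FALSE)
  res <- observed - A %*% x
  structure(list(light_fraction = x[1] / sum(x),
                 heavy_fraction = x[2] / sum(x),
                 residual_norm = sum(abs(res)) / sum(abs(observed))),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf("<fraction_estimate> light %.4f / heavy %.4f (residual %.3g)\n",
              x$light_fraction, x$heavy_fraction, x$residual_norm))
  invisible(x)
}

#' Analyte amount from the fraction estimate
#'
#' Isotope dilution: the analyte amount is the spiked standard amount scaled
#' by the light/heavy ratio.
#'
#' @param est A [estimate_fractions()] result.
#' @param standard_amount Standard amount on column (any unit; the result is
#'   in the same unit).
#' @return Analyte amount.
#' @export
ratio_and_amount <- function(est, standard_amount) {
  stopifnot(inherits(est, "fraction_estimate"), standard_amount >= 0)
  if (est$heavy_fraction <= 0) {
    stop("no internal standard detected (heavy fraction is zero)",
         call. = FALSE)
  }
  standard_amount * est$light_fraction / est$heavy_fraction
}
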