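# Seeded synthetic centroid LC-MS runs: two co-eluting isotopologue
# envelopes on a shared Gaussian elution profile, ESI-TOF-like centroid
# merging, multiplicative lognormal noise and an optional flat baseline.
# Absolute intensities are arbitrary units; only ratios carry meaning.

#' Acquisition model for the synthetic generator
#'
#' @param resolving_power FWHM-based resolving power; rendered centroids
#'   closer than one FWHM (mz / resolving_power) are merged. Default 30000,
#'   typical of a benchtop ESI-TOF.
#' @param scan_interval Seconds between scans.
#' @param rt_window Length-2 numeric, acquisition window in minutes.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise (0 disables noise).
#' @param baseline_level Mean intensity of additive baseline peaks (0
#'   disables the baseline).
#' @param intensity_per_pmol Response factor: total XIC ion current per pmol
#'   on column, shared by light and heavy species (equal ionization
#'   efficiency of isotopologues).
#' @param seed Integer seed; the same seed reproduces the run bit for bit.
#' @return An `acquisition_model` list.
#' @export
acquisition_model <- function(resolving_power = 30000, scan_interval = 1,
                              rt_window = c(17.5, 20), noise_cv = 0.01,
                              baseline_level = 0, intensity_per_pmol = 1e4,
                              seed = 1L) {
  stopifnot(resolving_power > 0, scan_interval > 0,
            length(rt_window) == 2, rt_window[2] > rt_window[1],
            noise_cv >= 0, baseline_level >= 0, intensity_per_pmol > 0)
  structure(list(resolving_power = resolving_power,
                 scan_interval = scan_interval, rt_window = rt_window,
                 noise_cv = noise_cv, baseline_level = baseline_level,
                 intensity_per_pmol = intensity_per_pmol,
                 seed = as.integer(seed)),
            class = "acquisition_model")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render one centroid spectrum
#'
#' Superposes weighted isotope patterns, merges centroids closer than one
#' FWHM at the model's resolving power (intensity-weighted mean m/z), applies
#' multiplicative lognormal noise with CV `noise_cv`, and adds flat baseline
#' peaks when `baseline_level > 0`. Uses the current RNG stream; callers that
#' need reproducibility seed it themselves (as [simulate_run()] does).
#'
#' @param components List of `list(pattern = <isotope_pattern>, weight =
#'   <total ion current>)`.
#' @param model An [acquisition_model()].
#' @return Data frame with `mz`, `intensity`.
#' @export
render_spectrum <- function(components, model) {
  if (length(components) == 0) stop("no components to render", call. = FALSE)
  mz <- unlist(lapply(components, function(cp) cp$pattern$mz))
  it <- unlist(lapply(components, function(cp) {
    if (cp$weight < 0) stop("component weights must be >= 0", call. = FALSE)
    cp$weight * cp$pattern$abundance
  }))
  keep <- it > 0
  if (!any(keep)) return(data.frame(mz = numeric(0), intensity = numeric(0)))
  fwhm <- mean(mz[keep]) / model$resolving_power
  m <- merge_centroids(mz[keep], it[keep], fwhm)
  intensity <- m$abundance
  if (model$noise_cv > 0) {
    s <- sqrt(log(1 + model$noise_cv^2))
    intensity <- intensity *
      stats::rlnorm(length(intensity), meanlog = -s^2 / 2, sdlog = s)
  }
  out <- data.frame(mz = m$mz, intensity = intensity)
  if (model$baseline_level > 0) {
    nb <- 10L
    bmz <- stats::runif(nb, min(out$mz) - 5, max(out$mz) + 5)
    bint <- stats::rexp(nb, 1 / model$baseline_level)
    out <- rbind(out, data.frame(mz = bmz, intensity = bint))
    out <- out[order(out$mz), ]
    rownames(out) <- NULL
  }
  out
}

#' Simulate a centroid LC-MS run
#'
#' Light (analyte) and heavy (labeled standard) envelopes share one Gaussian
#' elution profile exactly — co-elution is the generative assumption — with
#' per-scan component weights scaled so each species' summed ion current
#' equals `amount * intensity_per_pmol`. Deterministic given `model$seed`.
#'
#' @param analyte_pmol,standard_pmol Amounts on column (>= 0).
#' @param standard_states A [state_distribution()] describing the labeling of
#'   the standard; its heavy envelope is the state-probability-weighted
#'   mixture of labeled patterns.
#' @param rt_apex Elution apex in minutes (inside the model's rt window).
#' @param rt_sigma Gaussian elution sigma in minutes.
#' @param model An [acquisition_model()].
#' @param light_formula Formula of the unlabeled analyte ion.
#' @return A `centroid_run`: list of scans, each `list(rt, peaks)` with
#'   `peaks` a data frame of `mz`, `intensity`; rt strictly increasing.
#' @export
simulate_run <- function(analyte_pmol, standard_pmol, standard_states,
                         rt_apex = 18.83, rt_sigma = 0.1,
                         model = acquisition_model(),
                         light_formula = parse_formula("C21H29N2O", 1)) {
  stopifnot(analyte_pmol >= 0, standard_pmol >= 0, rt_sigma > 0)
  if (rt_apex < model$rt_window[1] || rt_apex > model$rt_window[2]) {
    stop("rt_apex must lie inside the acquisition window", call. = FALSE)
  }
  light <- isotope_pattern(light_formula)
  heavy <- mixture_pattern(light_formula, standard_states)
  rts <- seq(model$rt_window[1], model$rt_window[2],
             by = model$scan_interval / 60)
  profile <- exp(-(rts - rt_apex)^2 / (2 * rt_sigma^2))
  profile <- profile / sum(profile)
  with_seed(model$seed, {
    scans <- lapply(seq_along(rts), function(i) {
      comps <- list(
        list(pattern = light,
             weight = analyte_pmol * model$intensity_per_pmol * profile[i]),
        list(pattern = heavy,
             weight = standard_pmol * model$intensity_per_pmol * profile[i]))
      list(rt = rts[i], peaks = render_spectrum(comps, model))
    })
    structure(list(scans = scans), class = "centroid_run")
  })
}

# State-probability-weighted mixture of labeled isotope patterns, merged on
# a common instrument-level grid.
mixture_pattern <- function(light_formula, states, merge_tol = 1e-3) {
  stopifnot(inherits(states, "label_state_distribution"))
  mz <- numeric(0); ab <- numeric(0)
  for (i in seq_len(nrow(states))) {
    f <- labeled_formula(light_formula, states$n_alpha_d[i], states$amide_d[i])
    p <- isotope_pattern(f, merge_tol = merge_tol)
    mz <- c(mz, p$mz)
    ab <- c(ab, states$prob[i] * p$abundance)
  }
  m <- merge_centroids(mz, ab, merge_tol)
  new_pattern(m$mz, m$abundance / sum(m$abundance))
}

#' Simulate a calibration series
#'
#' One run per analyte amount against a shared standard amount; each run gets
#' a distinct seed derived from the model's seed so replicates differ only by
#' noise.
#'
#' @param amounts_pmol Analyte amounts (>= 2 distinct values unless a single
#'   repeated amount is intended for replicate studies).
#' @param standard_pmol Shared internal-standard amount.
#' @param standard_states Labeling of the standard, as in [simulate_run()].
#' @param model An [acquisition_model()]; run i uses `seed + i`.
#' @param ... Passed on to [simulate_run()] (rt_apex, rt_sigma, formula).
#' @return List of `centroid_run` objects, one per amount.
#' @export
simulate_calibration_series <- function(amounts_pmol, standard_pmol,
                                        standard_states,
                                        model = acquisition_model(), ...) {
  if (length(amounts_pmol) == 0) stop("empty amount list", call. = FALSE)
  lapply(seq_along(amounts_pmol), function(i) {
    mi <- model
    mi$seed <- model$seed + i
    simulate_run(amounts_pmol[i], standard_pmol, standard_states,
                 model = mi, ...)
  })
}

#' @export
print.centroid_run <- function(x, ...) {
  n <- length(x$scans)
  rts <- vapply(x$scans, function(s) s$rt, numeric(1))
  cat(sprintf("<centroid_run> %d scans, rt %.2f-%.2f min\n",
              n, min(rts), max(rts)))
  invisible(x)
}

#' Write / read a centroid run as CSV
#'
#' The documented CSV dialect has columns `scan` (1-based index), `rt_min`,
#' `mz`, `intensity`, one row per centroid peak; scans with no peaks are
#' represented by their absence. Output is bit-stable for a fixed seed.
#'
#' @param run A `centroid_run`.
#' @param path File path.
#' @return `write_run_csv` returns `path` invisibly; `read_run_csv` returns a
#'   `centroid_run`.
#' @export
write_run_csv <- function(run, path) {
  stopifnot(inherits(run, "centroid_run"))
  rows <- lapply(seq_along(run$scans), function(i) {
    s <- run$scans[[i]]
    if (nrow(s$peaks) == 0) return(NULL)
    data.frame(scan = i, rt_min = s$rt, mz = s$peaks$mz,
               intensity = s$peaks$intensity)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_csv
#' @export
read_run_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("scan", "rt_min", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  scans <- lapply(split(df, df$scan), function(g) {
    list(rt = g$rt_min[1],
         peaks = data.frame(mz = g$mz, intensity = g$intensity))
  })
  scans <- scans[order(vapply(scans, function(s) s$rt, numeric(1)))]
  structure(list(scans = unname(scans)), class = "centroid_run")
}
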