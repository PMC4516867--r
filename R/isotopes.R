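# Molecular formulas and aggregated isotope patterns.
#
# Patterns are computed by per-element multinomial convolution: the isotope
# distribution of E_n is the n-fold convolution of the single-atom
# distribution, and the molecular pattern is the convolution across elements.
# Centroids closer than `merge_tol` are merged by abundance-weighted mean, so
# the result is an aggregated (instrument-level) envelope, not fine structure.

#' Parse a molecular formula string
#'
#' Parses Hill-like element-count strings such as `"C21H29N2O"`. The symbol
#' `"D"` denotes deuterium and is kept distinct from `"H"` throughout.
#'
#' @param text Formula string; one-or-two-letter element symbols each followed
#'   by an optional positive count.
#' @param charge Integer charge of the species (sign included); 0 for a
#'   neutral molecule.
#' @return A `molecular_formula` object: a list with `counts` (named integer
#'   vector) and `charge`.
#' @export
#' @examples
#' parse_formula("C21H29N2O", charge = 1)   # denatonium cation
#' parse_formula("C21H27D2N2O", charge = 1) # alpha-dideuterated analogue
parse_formula <- function(text, charge = 0) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || nchar(text) == 0) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nchar(num) == 0) 1L else as.integer(num)
    if (is.na(n) || n <= 0) stop("malformed count in '", tok, "'", call. = FALSE)
    if (is.null(.ISOTOPE_TABLE[[sym]])) {
      stop("unknown element symbol: '", sym, "'", call. = FALSE)
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  new_formula(counts, charge)
}

new_formula <- function(counts, charge) {
  stopifnot(all(counts >= 0), sum(counts) > 0)
  counts <- counts[counts > 0]
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "molecular_formula")
}

#' @export
format.molecular_formula <- function(x, ...) {
  first <- c("C", "H", "D")
  syms <- c(intersect(first, names(x$counts)),
            sort(setdiff(names(x$counts), first)))
  counts <- x$counts[syms]
  body <- paste0(syms, ifelse(counts > 1, counts, ""), collapse = "")
  z <- x$charge
  suffix <- if (z == 0) "" else paste0(" [", abs(z), if (z > 0) "+" else "-", "]")
  paste0(body, suffix)
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format(x), "\n")
  invisible(x)
}

#' Monoisotopic m/z of a formula
#'
#' Sums the lightest-isotope mass of every atom (deuterium contributes the
#' full 2H mass), subtracts one electron mass per positive charge (adds per
#' negative charge), and divides by `|charge|`. With charge 0 the neutral
#' monoisotopic mass is returned.
#'
#' @param f A [parse_formula()] result.
#' @return m/z in Da per unit charge (Da for neutrals).
#' @export
#' @examples
#' monoisotopic_mz(parse_formula("C21H29N2O", 1)) # ~325.227
monoisotopic_mz <- function(f) {
  stopifnot(inherits(f, "molecular_formula"))
  mass <- sum(vapply(names(f$counts), function(sym) {
    .ISOTOPE_TABLE[[sym]]$mass[1] * f$counts[[sym]]
  }, numeric(1)))
  z <- f$charge
  if (z == 0) return(mass)
  (mass - z * .ELECTRON_MASS) / abs(z)
}

new_pattern <- function(mz, abundance) {
  o <- order(mz)
  structure(data.frame(mz = mz[o], abundance = abundance[o]),
            class = c("isotope_pattern", "data.frame"))
}

# Merge centroids closer than tol: sorted single pass, abundance-weighted mz.
merge_centroids <- function(mz, ab, tol) {
  o <- order(mz)
  mz <- mz[o]; ab <- ab[o]
  grp <- cumsum(c(1, diff(mz) > tol))
  tot <- rowsum(ab, grp, reorder = FALSE)[, 1]
  wmz <- rowsum(mz * ab, grp, reorder = FALSE)[, 1] / tot
  bad <- !is.finite(wmz)
  if (any(bad)) wmz[bad] <- rowsum(mz, grp, reorder = FALSE)[bad, 1] /
      tabulate(grp)[bad]
  list(mz = unname(wmz), abundance = unname(tot))
}

# Exact-collision tolerance for intermediate convolutions: far below any real
# fine-structure splitting, so it only deduplicates floating-point-identical
# mass sums. User-facing merging happens once, at the end.
.EXACT_TOL <- 1e-9

# Distribution of n atoms of one element, by binary-exponentiation convolution.
element_pattern <- function(sym, n) {
  iso <- .ISOTOPE_TABLE[[sym]]
  acc <- list(mz = 0, abundance = 1)
  base <- list(mz = iso$mass, abundance = iso$abundance)
  while (n > 0) {
    if (n %% 2 == 1) acc <- convolve_raw(acc, base, .EXACT_TOL)
    n <- n %/% 2
    if (n > 0) base <- convolve_raw(base, base, .EXACT_TOL)
  }
  acc
}

convolve_raw <- function(a, b, tol, floor_ab = 1e-15) {
  mz <- outer(a$mz, b$mz, "+")
  ab <- outer(a$abundance, b$abundance, "*")
  keep <- ab > floor_ab
  merge_centroids(mz[keep], ab[keep], tol)
}

#' Theoretical isotope pattern of a formula
#'
#' Convolves the per-element multinomial isotope distributions of the
#' formula, merges centroids closer than `merge_tol` by abundance-weighted
#' mean, drops peaks below `abundance_floor`, and renormalizes to sum 1.
#' Masses are converted to m/z using the formula's charge (electron-mass
#' corrected).
#'
#' @param f A [parse_formula()] result.
#' @param abundance_floor Relative abundance below which peaks are dropped,
#'   in (0, 0.01].
#' @param merge_tol Centroid merge tolerance in Da (> 0).
#' @return An `isotope_pattern` data frame with columns `mz`, `abundance`.
#' @export
#' @examples
#' isotope_pattern(parse_formula("C21H29N2O", 1))
isotope_pattern <- function(f, abundance_floor = 1e-5, merge_tol = 1e-3) {
  stopifnot(inherits(f, "molecular_formula"))
  if (!(abundance_floor > 0 && abundance_floor <= 0.01)) {
    stop("abundance_floor must be in (0, 0.01]", call. = FALSE)
  }
  if (merge_tol <= 0) stop("merge_tol must be > 0", call. = FALSE)
  acc <- list(mz = 0, abundance = 1)
  for (sym in names(f$counts)) {
    acc <- convolve_raw(acc, element_pattern(sym, f$counts[[sym]]), .EXACT_TOL)
  }
  acc <- merge_centroids(acc$mz, acc$abundance, merge_tol)
  ab <- acc$abundance / sum(acc$abundance)
  keep <- ab >= abundance_floor
  mz <- acc$mz[keep]
  ab <- ab[keep] / sum(ab[keep])
  z <- f$charge
  if (z != 0) mz <- (mz - z * .ELECTRON_MASS) / abs(z)
  new_pattern(mz, ab)
}

#' Convolve two isotope patterns
#'
#' Forms all pairwise (mass-sum, abundance-product) centroids of two
#' normalized patterns, merges within `merge_tol`, and renormalizes. This is
#' the pattern of the combined species when both inputs are on the mass
#' (uncharged) scale.
#'
#' @param a,b `isotope_pattern` objects (abundances summing to 1).
#' @param merge_tol Centroid merge tolerance in Da.
#' @return An `isotope_pattern`.
#' @export
convolve_patterns <- function(a, b, merge_tol = 1e-3) {
  stopifnot(inherits(a, "isotope_pattern"), inherits(b, "isotope_pattern"))
  for (p in list(a, b)) {
    if (abs(sum(p$abundance) - 1) > 1e-9) {
      stop("patterns must be normalized before convolution", call. = FALSE)
    }
  }
  m <- convolve_raw(list(mz = a$mz, abundance = a$abundance),
                    list(mz = b$mz, abundance = b$abundance), merge_tol,
                    floor_ab = 0)
  new_pattern(m$mz, m$abundance / sum(m$abundance))
}
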