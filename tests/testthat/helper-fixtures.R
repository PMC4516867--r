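# Shared fixtures and an independent isotope-pattern oracle.

denatonium <- function() parse_formula("C21H29N2O", 1)
benzoate_salt <- function() parse_formula("C28H34N2O3")
full_d2 <- function() state_distribution(1, amide_d = FALSE, n_alpha = 2L)

noiseless_model <- function(seed = 1L, ...) {
  acquisition_model(noise_cv = 0, seed = seed, ...)
}

# Exhaustive isotopologue oracle, independent of the convolution code path:
# enumerate per-element isotope compositions (multinomial probabilities),
# take the cross product over elements, then aggregate masses with the same
# sorted-gap grouping rule, floor and renormalization the package documents.
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- NULL
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1)
    out <- rbind(out, cbind(i, sub))
  }
  out
}

oracle_pattern <- function(f, abundance_floor = 1e-5, merge_tol = 1e-3) {
  per_elem <- lapply(names(f$counts), function(sym) {
    iso <- element_isotopes(sym)
    n <- f$counts[[sym]]
    comps <- compositions(n, length(iso$mass))
    data.frame(
      mass = as.vector(comps %*% iso$mass),
      prob = apply(comps, 1, function(k) dmultinom(k, prob = iso$abundance)))
  })
  acc <- data.frame(mass = 0, prob = 1)
  for (e in per_elem) {
    acc <- data.frame(mass = as.vector(outer(acc$mass, e$mass, "+")),
                      prob = as.vector(outer(acc$prob, e$prob, "*")))
    acc <- acc[acc$prob > 1e-15, ]
  }
  o <- order(acc$mass)
  mass <- acc$mass[o]; prob <- acc$prob[o]
  grp <- cumsum(c(1, diff(mass) > merge_tol))
  mz <- tapply(mass * prob, grp, sum) / tapply(prob, grp, sum)
  ab <- tapply(prob, grp, sum)
  ab <- ab / sum(ab)
  keep <- ab >= abundance_floor
  mz <- mz[keep]; ab <- ab[keep] / sum(ab[keep])
  z <- f$charge
  if (z != 0) mz <- (mz - z * 0.000548579909) / abs(z)
  data.frame(mz = as.numeric(mz), abundance = as.numeric(ab))
}

# A random small formula (<= max_atoms atoms) for property tests.
random_formula <- function(max_atoms = 12) {
  syms <- c("C", "H", "N", "O", "S", "Cl")
  n_elem <- sample(1:3, 1)
  chosen <- sample(syms, n_elem)
  counts <- integer(0)
  left <- max_atoms
  for (s in chosen) {
    n <- sample(1:max(1, left - (length(chosen) - length(counts) - 1)), 1)
    counts[s] <- n
    left <- left - n
  }
  parse_formula(paste0(names(counts), counts, collapse = ""), 0)
}

# Merge two runs, offsetting the second one's scans by `shift` scan indices
# (used to impose a retention-time shift on the heavy channel).
combine_shifted <- function(run_a, run_b, shift = 0L) {
  n <- length(run_a$scans)
  scans <- lapply(seq_len(n), function(i) {
    j <- i - shift
    pk <- run_a$scans[[i]]$peaks
    if (j >= 1 && j <= n) pk <- rbind(pk, run_b$scans[[j]]$peaks)
    pk <- pk[order(pk$mz), , drop = FALSE]
    list(rt = run_a$scans[[i]]$rt, peaks = pk)
  })
  structure(list(scans = scans), class = "centroid_run")
}
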