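# Independent oracles and fixture builders shared across the suite.

# Full-matrix DTW dynamic program in plain R (symmetric steps, |a-b| cost),
# with path length recovered by backtracking. Used as the reference the
# compiled kernel is checked against on short sequences.
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n, m)
  D[1, 1] <- abs(a[1] - b[1])
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (i == 1 && j == 1) next
    prev <- c(if (i > 1) D[i - 1, j] else Inf,
              if (j > 1) D[i, j - 1] else Inf,
              if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
    D[i, j] <- abs(a[i] - b[j]) + min(prev)
  }
  i <- n; j <- m; len <- 1L
  while (i > 1 || j > 1) {
    dd <- if (i > 1 && j > 1) D[i - 1, j - 1] else Inf
    du <- if (i > 1) D[i - 1, j] else Inf
    dl <- if (j > 1) D[i, j - 1] else Inf
    if (dd <= du && dd <= dl) { i <- i - 1; j <- j - 1 }
    else if (du <= dl) i <- i - 1
    else j <- j - 1
    len <- len + 1L
  }
  list(distance = D[n, m], path_length = len)
}

# All-pairs brute-force table matcher: for each entry, count distinct
# charge states whose ladder value is within tol of any observed m/z.
table_match_oracle <- function(obs_mz, ladders, tol, min_charge_states = 2) {
  counts <- integer(0)
  for (e in unique(ladders$entry_id)) {
    sub <- ladders[ladders$entry_id == e, ]
    matched_z <- unique(sub$z[vapply(sub$mz, function(m) {
      any(abs(obs_mz - m) <= tol)
    }, logical(1))])
    counts[as.character(e)] <- length(matched_z)
  }
  list(counts = counts, passed = any(counts >= min_charge_states))
}

# Synthetic gradient run: Gaussian chromatographic peaks carrying stick
# spectra, no noise unless asked for.
make_gradient_run <- function(species, run_length = 2.5,
                              scan_interval = 0.01) {
  times <- seq(scan_interval, run_length, by = scan_interval)
  scans <- lapply(times, function(tt) {
    mz <- numeric(0); inten <- numeric(0)
    for (sp in species) {
      env <- exp(-(tt - sp$rt)^2 / (2 * sp$width^2))
      if (env < 1e-8) next
      mz <- c(mz, sp$sticks$mz)
      inten <- c(inten, sp$response * env * sp$sticks$rel)
    }
    if (length(mz)) {
      o <- order(mz)
      mass_spectrum(mz[o], inten[o])
    } else {
      mass_spectrum(numeric(0), numeric(0))
    }
  })
  lcms_run("gradient", times, scans)
}

# Noiseless spectrum of Lorentzian singlets on the standard grid.
make_lorentz_spectrum <- function(positions, heights = NULL, fwhm_hz = 2,
                                  field = 80, grid = default_nmr_grid()) {
  if (is.null(heights)) heights <- rep(1, length(positions))
  y <- numeric(length(grid))
  gam <- (fwhm_hz / field) / 2
  for (i in seq_along(positions)) {
    y <- y + heights[i] * gam^2 / ((grid - positions[i])^2 + gam^2)
  }
  nmr_spectrum(grid, y, field = field)
}

# Small periodic-table oracle used to hand-sum masses in tests.
mono_mass <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207117, Br = 78.9183376,
               F = 18.9984032, Zn = 63.92914201, Cu = 62.92959772)

random_formula <- function() {
  els <- sample(names(mono_mass), sample(2:5, 1))
  counts <- sample(1:12, length(els), replace = TRUE)
  chem_formula(stats::setNames(counts, els))
}
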