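#' 1H NMR spectrum objects
#'
#' A frequency-domain spectrum: a strictly increasing ppm axis, a real
#' intensity vector of the same length, the spectrometer field strength in
#' MHz (needed to convert line-broadening values between Hz and ppm) and an
#' optional list of masked ppm intervals (solvent / suppression zones that
#' all downstream comparisons must ignore).
#'
#' @param ppm Strictly increasing numeric ppm axis.
#' @param intensity Finite numeric vector, same length as `ppm`.
#' @param field Spectrometer frequency in MHz (default 80, benchtop).
#' @param masks List of length-2 numeric vectors `c(lo, hi)` in ppm.
#' @return An `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, field = 80, masks = list()) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have equal length")
  }
  if (length(ppm) < 2L) stop("a spectrum needs at least two points")
  if (any(diff(ppm) <= 0)) stop("ppm axis must be strictly increasing")
  if (!all(is.finite(intensity))) stop("intensities must be finite")
  for (mk in masks) {
    if (length(mk) != 2L || mk[1] >= mk[2]) {
      stop("each mask must be c(lo, hi) with lo < hi")
    }
    if (mk[2] < ppm[1] || mk[1] > ppm[length(ppm)]) {
      stop("mask [", mk[1], ", ", mk[2], "] lies outside the ppm axis")
    }
  }
  structure(list(ppm = ppm, intensity = intensity, field = field,
                 masks = masks),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<1H NMR spectrum> %d points, %.3f-%.3f ppm, %g MHz, %d mask(s)\n",
              length(x$ppm), min(x$ppm), max(x$ppm), x$field,
              length(x$masks)))
  invisible(x)
}

#' Default comparison grid
#'
#' The common ppm axis all spectra are interpolated onto before comparison:
#' 0 to 12 ppm at 0.002 ppm spacing (6001 points), commensurate with the
#' digital resolution of an 80 MHz benchtop instrument.
#'
#' @param from,to,by Grid bounds and spacing in ppm.
#' @return Numeric vector.
#' @export
default_nmr_grid <- function(from = 0, to = 12, by = 0.002) {
  seq(from, to, by = by)
}

#' Preprocess a spectrum onto a common grid
#'
#' Linear interpolation onto the target grid, zeroing of masked regions, and
#' normalization (max = 1 by default, or unit area). All cross-spectrum
#' operations (DTW, peak picking, binding tests) assume preprocessed input.
#' Preprocessing an already gridded, normalized spectrum is idempotent, and
#' the output is invariant to the input's overall intensity scale.
#'
#' @param spec An `nmr_spectrum`.
#' @param grid Target ppm axis; must lie within the source axis range.
#' @param normalization `"max"` or `"area"`.
#' @return An `nmr_spectrum` on `grid`.
#' @export
nmr_preprocess <- function(spec, grid = default_nmr_grid(),
                           normalization = c("max", "area")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (min(grid) < min(spec$ppm) - 1e-9 || max(grid) > max(spec$ppm) + 1e-9) {
    stop("target grid extends outside the source ppm range")
  }
  y <- stats::approx(spec$ppm, spec$intensity, xout = grid, rule = 2)$y
  for (mk in spec$masks) y[grid >= mk[1] & grid <= mk[2]] <- 0
  if (normalization == "max") {
    top <- max(abs(y))
    if (top > 0) y <- y / top
  } else {
    area <- sum(y) * mean(diff(grid))
    if (abs(area) > 0) y <- y / area
  }
  nmr_spectrum(grid, y, field = spec$field, masks = spec$masks)
}

#' Combine starting-material reference spectra
#'
#' Weighted pointwise sum of spectra on a common grid, renormalized to
#' max = 1: the "sum of starting materials" reference that reaction spectra
#' are compared against.
#'
#' @param specs List of `nmr_spectrum`s on an identical ppm grid.
#' @param weights Positive weights, one per spectrum (default equal).
#' @return An `nmr_spectrum`.
#' @export
combine_references <- function(specs, weights = NULL) {
  if (!length(specs)) stop("need at least one spectrum")
  grid <- specs[[1]]$ppm
  for (s in specs) {
    if (length(s$ppm) != length(grid) || any(abs(s$ppm - grid) > 1e-9)) {
      stop("all spectra must share a common ppm grid")
    }
  }
  if (is.null(weights)) weights <- rep(1, length(specs))
  if (length(weights) != length(specs) || any(weights < 0)) {
    stop("weights must be non-negative, one per spectrum")
  }
  y <- Reduce(`+`, Map(function(s, w) w * s$intensity, specs, weights))
  top <- max(abs(y))
  if (top > 0) y <- y / top
  masks <- unique(do.call(c, lapply(specs, `[[`, "masks")))
  nmr_spectrum(grid, y, field = specs[[1]]$field, masks = masks)
}

#' Dynamic time warping distance between two spectra
#'
#' Classic DTW with absolute-difference local cost and the symmetric step
#' pattern, optionally constrained to a Sakoe-Chiba band. The normalized
#' distance (total distance divided by warping-path length) is what all
#' decision thresholds operate on, making them independent of grid length.
#'
#' @param a,b `nmr_spectrum`s on a common grid (or bare numeric vectors).
#' @param band Sakoe-Chiba radius in points; `NULL` (default) uses 5% of the
#'   sequence length; a negative value disables the constraint.
#' @return A `dtw_result`: list with `distance`, `normalized_distance`,
#'   `path_length`.
#' @examples
#' dtw_distance(c(2), c(5))$distance # 3
#' @export
dtw_distance <- function(a, b, band = NULL) {
  av <- if (inherits(a, "nmr_spectrum")) a$intensity else as.numeric(a)
  bv <- if (inherits(b, "nmr_spectrum")) b$intensity else as.numeric(b)
  if (!length(av) || !length(bv)) stop("empty spectra passed to DTW")
  if (is.null(band)) band <- max(1L, as.integer(0.05 * max(length(av),
                                                           length(bv))))
  res <- .dtw_core(av, bv, as.integer(band))
  structure(
    list(distance = res$distance,
         normalized_distance = res$distance / res$path_length,
         path_length = as.integer(res$path_length)),
    class = "dtw_result"
  )
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<DTW> distance %.6g, normalized %.6g (path %d)\n",
              x$distance, x$normalized_distance, x$path_length))
  invisible(x)
}

#' Has a chemical change occurred?
#'
#' Compares a reaction spectrum against the combined starting-material
#' reference by DTW; a normalized distance above the threshold is read as
#' evidence that the starting materials have been transformed.
#'
#' @param reaction,sm_sum Preprocessed `nmr_spectrum`s on a common grid.
#' @param threshold Normalized-distance threshold (default 0.009).
#' @param band Passed to [dtw_distance()].
#' @return List with `passed` (logical) and `dtw` (`dtw_result`).
#' @export
chemical_change <- function(reaction, sm_sum, threshold = 0.009, band = NULL) {
  d <- dtw_distance(reaction, sm_sum, band = band)
  list(passed = d$normalized_distance > threshold, dtw = d,
       threshold = threshold)
}

#' Scale-up parity check
#'
#' A scaled-up reaction passes when its spectrum matches the screening-scale
#' spectrum within a parity threshold that must be strictly tighter than the
#' chemical-change threshold (the two thresholds answer opposite questions:
#' "different enough?" versus "same enough?").
#'
#' @param screen,scaleup Preprocessed `nmr_spectrum`s on a common grid.
#' @param parity_threshold Normalized-distance threshold (default 0.006).
#' @param change_threshold The chemical-change threshold this must undercut.
#' @param band Passed to [dtw_distance()].
#' @return List with `passed` and `dtw`.
#' @export
parity_check <- function(screen, scaleup, parity_threshold = 0.006,
                         change_threshold = 0.009, band = NULL) {
  if (parity_threshold >= change_threshold) {
    stop("parity_threshold (", parity_threshold,
         ") must be smaller than the chemical-change threshold (",
         change_threshold, ")")
  }
  d <- dtw_distance(screen, scaleup, band = band)
  list(passed = d$normalized_distance <= parity_threshold, dtw = d,
       threshold = parity_threshold)
}

#' Pick peaks in a spectrum
#'
#' Local maxima above a height floor (as a fraction of the spectrum maximum),
#' outside all masked regions, with maxima closer than `min_separation`
#' merged (keeping the taller).
#'
#' @param spec Preprocessed `nmr_spectrum`.
#' @param height_min Minimum height as a fraction of the maximum intensity
#'   (default 0.1).
#' @param min_separation Merge radius in ppm (default 0.05).
#' @return A `peak_set`: data.frame with columns `position` (ppm) and
#'   `height`, sorted by position.
#' @export
pick_peaks <- function(spec, height_min = 0.1, min_separation = 0.05) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  y <- spec$intensity; x <- spec$ppm
  n <- length(y)
  floor_h <- height_min * max(y)
  if (max(y) <= 0) {
    return(structure(data.frame(position = numeric(0), height = numeric(0)),
                     class = c("peak_set", "data.frame")))
  }
  i <- 2:(n - 1)
  is_max <- y[i] >= y[i - 1] & y[i] > y[i + 1] & y[i] >= floor_h
  cand <- i[is_max]
  for (mk in spec$masks) cand <- cand[x[cand] < mk[1] | x[cand] > mk[2]]
  # merge close maxima, tallest first
  keep <- integer(0)
  for (j in cand[order(-y[cand])]) {
    if (!length(keep) || all(abs(x[j] - x[keep]) >= min_separation)) {
      keep <- c(keep, j)
    }
  }
  keep <- sort(keep)
  structure(data.frame(position = x[keep], height = y[keep]),
            class = c("peak_set", "data.frame"))
}

#' Symmetric-product heuristic
#'
#' A single, symmetric self-assembled architecture is expected to show about
#' as many 1H resonances as the sum of its starting materials' resonances,
#' but at different chemical shifts. The test passes iff (a) the reaction
#' peak count is within `count_tolerance` of the summed starting-material
#' counts and (b) at least `min_shifted_frac` of the reaction peaks lie at
#' least `shift_min` ppm away from every starting-material peak. Complex
#' mixtures (oligomers, polymers) fail on (a); unreacted mixtures fail on
#' (b).
#'
#' @param reaction_peaks `peak_set` of the reaction spectrum.
#' @param sm_peaks List of `peak_set`s, one per starting material, picked
#'   with the same parameters.
#' @param count_tolerance Allowed absolute count difference (default 2).
#' @param shift_min Minimum shift in ppm for a peak to count as moved
#'   (default 0.02).
#' @param min_shifted_frac Minimum fraction of moved reaction peaks
#'   (default 0.5).
#' @return List with `passed`, `count_ok`, `shift_ok`, `n_reaction`,
#'   `n_sm_total`, `frac_shifted`.
#' @export
symmetric_product_test <- function(reaction_peaks, sm_peaks,
                                   count_tolerance = 2, shift_min = 0.02,
                                   min_shifted_frac = 0.5) {
  n_rxn <- nrow(reaction_peaks)
  n_sm <- sum(vapply(sm_peaks, nrow, integer(1)))
  count_ok <- abs(n_rxn - n_sm) <= count_tolerance
  sm_pos <- unlist(lapply(sm_peaks, `[[`, "position"))
  if (n_rxn == 0L) {
    frac <- 0
  } else if (!length(sm_pos)) {
    frac <- 1
  } else {
    moved <- vapply(reaction_peaks$position,
                    function(p) min(abs(p - sm_pos)) >= shift_min,
                    logical(1))
    frac <- mean(moved)
  }
  shift_ok <- n_rxn > 0L && frac >= min_shifted_frac
  list(passed = count_ok && shift_ok, count_ok = count_ok,
       shift_ok = shift_ok, n_reaction = n_rxn, n_sm_total = n_sm,
       frac_shifted = frac)
}

#' Apply Lorentzian line broadening
#'
#' Convolves the spectrum with a unit-area Lorentzian kernel of full width at
#' half maximum `lb` Hz (converted to ppm through the field strength),
#' emulating exponential apodization in the frequency domain. Total area is
#' preserved. Used to blur away slow-exchange fine structure before
#' host-guest shift-perturbation analysis.
#'
#' @param spec Preprocessed `nmr_spectrum` on a uniform grid.
#' @param lb Line broadening in Hz (>= 0; 0 returns the input unchanged).
#' @return An `nmr_spectrum`.
#' @export
apply_line_broadening <- function(spec, lb) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (lb < 0) stop("line broadening must be >= 0 Hz")
  if (lb == 0) return(spec)
  dppm <- diff(spec$ppm)
  if (diff(range(dppm)) > 1e-9) stop("line broadening needs a uniform grid")
  step <- mean(dppm)
  fwhm_ppm <- lb / spec$field
  # Lorentzian tails are heavy: truncating at k x FWHM leaves ~1/(pi k) of
  # the kernel mass outside, so the window is wide (40 x FWHM) and the
  # result is rescaled to conserve the total integral exactly.
  half_width <- max(3L, ceiling(40 * fwhm_ppm / step))
  k_x <- seq(-half_width, half_width) * step
  gam <- fwhm_ppm / 2
  kern <- gam / (pi * (k_x^2 + gam^2))
  kern <- kern / sum(kern)
  n <- length(spec$intensity)
  padded <- c(rep(0, half_width), spec$intensity, rep(0, half_width))
  sm <- stats::convolve(padded, rev(kern), type = "open")
  y <- sm[(2 * half_width + 1):(2 * half_width + n)]
  total_in <- sum(spec$intensity)
  total_out <- sum(y)
  if (abs(total_out) > 1e-12 && abs(total_in) > 1e-12) {
    y <- y * (total_in / total_out)
  }
  y[abs(y) < 1e-15] <- 0
  nmr_spectrum(spec$ppm, y, field = spec$field, masks = spec$masks)
}

#' Host-guest binding test by chemical-shift perturbation
#'
#' Both spectra are line-broadened (emulating fast exchange), peaks are
#' picked inside the aromatic window, and the host is called "bound" if any
#' aromatic host peak's nearest counterpart in the host-plus-guest spectrum
#' has moved by at least `shift_min` ppm, or if aromatic peaks appeared or
#' disappeared.
#'
#' @param host,host_plus_guest Preprocessed `nmr_spectrum`s on a common grid.
#' @param window Aromatic ppm window, default `c(6.0, 9.5)`.
#' @param lb Line broadening in Hz (default 10).
#' @param shift_min Minimum shift in ppm to call a peak moved (default 0.02).
#' @param height_min,min_separation Passed to [pick_peaks()].
#' @return List with `passed`, `shifts` (data.frame: host peak position,
#'   nearest counterpart, shift), `n_host`, `n_mix`.
#' @export
guest_binding_test <- function(host, host_plus_guest, window = c(6.0, 9.5),
                               lb = 10, shift_min = 0.02, height_min = 0.1,
                               min_separation = 0.05) {
  if (length(window) != 2L || window[1] >= window[2]) {
    stop("aromatic window must be c(lo, hi) with lo < hi")
  }
  in_window <- function(pk) pk[pk$position >= window[1] &
                               pk$position <= window[2], , drop = FALSE]
  hp <- in_window(pick_peaks(apply_line_broadening(host, lb),
                             height_min, min_separation))
  gp <- in_window(pick_peaks(apply_line_broadening(host_plus_guest, lb),
                             height_min, min_separation))
  if (nrow(hp) == 0L && nrow(gp) == 0L) {
    return(list(passed = FALSE,
                shifts = data.frame(host = numeric(0), mix = numeric(0),
                                    shift = numeric(0)),
                n_host = 0L, n_mix = 0L))
  }
  shifts <- data.frame(host = hp$position, mix = NA_real_, shift = NA_real_)
  if (nrow(hp) && nrow(gp)) {
    for (i in seq_len(nrow(hp))) {
      j <- which.min(abs(gp$position - hp$position[i]))
      shifts$mix[i] <- gp$position[j]
      shifts$shift[i] <- abs(gp$position[j] - hp$position[i])
    }
  }
  moved <- nrow(hp) && nrow(gp) && any(shifts$shift >= shift_min)
  appeared <- nrow(gp) > 0L &&
    any(vapply(gp$position, function(p) {
      !nrow(hp) || min(abs(p - hp$position)) >= shift_min
    }, logical(1)))
  disappeared <- nrow(hp) > 0L &&
    (nrow(gp) == 0L ||
       any(vapply(hp$position, function(p) {
         min(abs(p - gp$position)) >= shift_min
       }, logical(1))))
  list(passed = isTRUE(moved || appeared || disappeared), shifts = shifts,
       n_host = nrow(hp), n_mix = nrow(gp))
}
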