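#' Mass spectrum objects
#'
#' A centroided mass spectrum: ascending positive m/z values and
#' non-negative intensities. Values closer than 1e-6 Da are considered
#' duplicates and rejected.
#'
#' @param mz Ascending positive numeric m/z values.
#' @param intensity Non-negative numeric, same length.
#' @return A `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length")
  }
  if (length(mz)) {
    o <- order(mz); mz <- mz[o]; intensity <- intensity[o]
    if (any(mz <= 0)) stop("m/z values must be positive")
    if (any(diff(mz) < 1e-6)) stop("duplicate m/z values (within 1e-6)")
    if (any(intensity < 0)) stop("intensities must be non-negative")
  }
  structure(list(mz = mz, intensity = intensity), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass spectrum> %d peaks%s\n", length(x$mz),
              if (length(x$mz)) sprintf(", m/z %.2f-%.2f", min(x$mz),
                                        max(x$mz)) else ""))
  invisible(x)
}

#' LC-MS run objects
#'
#' A gradient UPLC-MS run (chromatogram plus time-ordered scans) or a
#' direct-injection run (column bypassed; all matching operates on the
#' time-averaged spectrum). The chromatogram defaults to the total ion
#' current computed from the scans.
#'
#' @param mode `"gradient"` or `"direct_injection"`.
#' @param times Strictly increasing scan times in minutes.
#' @param scans List of `mass_spectrum`s, one per time point.
#' @param tic Optional total-ion-current vector; computed from scans if
#'   omitted.
#' @return An `lcms_run`.
#' @export
lcms_run <- function(mode = c("gradient", "direct_injection"), times, scans,
                     tic = NULL) {
  mode <- match.arg(mode)
  times <- as.numeric(times)
  if (length(times) != length(scans)) {
    stop("one scan per time point is required")
  }
  if (length(times) && any(diff(times) <= 0)) {
    stop("scan times must be strictly increasing")
  }
  for (s in scans) stopifnot(inherits(s, "mass_spectrum"))
  if (is.null(tic)) {
    tic <- vapply(scans, function(s) sum(s$intensity), numeric(1))
  }
  if (length(tic) != length(times)) stop("tic length must match times")
  structure(list(mode = mode, times = times, scans = scans, tic = tic),
            class = "lcms_run")
}

#' @export
print.lcms_run <- function(x, ...) {
  cat(sprintf("<LC-MS run> %s, %d scans over %.2f-%.2f min\n", x$mode,
              length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Time-averaged spectrum of a run
#'
#' Averages all scans (equal scan weights, intensities divided by the scan
#' count) after binning m/z values at `bin_width`; bin centroids are
#' intensity-weighted mean m/z. This is the spectrum that direct-injection
#' matching operates on.
#'
#' @param run An `lcms_run`.
#' @param scan_idx Indices of scans to average (default all).
#' @param bin_width m/z bin width in daltons (default 0.05).
#' @return A `mass_spectrum`.
#' @export
average_spectrum <- function(run, scan_idx = seq_along(run$scans),
                             bin_width = 0.05) {
  scans <- run$scans[scan_idx]
  if (!length(scans)) stop("no scans to average")
  mz <- unlist(lapply(scans, `[[`, "mz"))
  if (!length(mz)) return(mass_spectrum(numeric(0), numeric(0)))
  inten <- unlist(lapply(scans, `[[`, "intensity")) / length(scans)
  bin <- round(mz / bin_width)
  agg_i <- tapply(inten, bin, sum)
  agg_m <- tapply(mz * inten, bin, sum) / pmax(agg_i, .Machine$double.xmin)
  zero <- agg_i == 0
  if (any(zero)) { # all-zero bins: plain mean position
    agg_m[zero] <- tapply(mz, bin, mean)[zero]
  }
  mass_spectrum(as.numeric(agg_m), as.numeric(agg_i))
}

#' Detect chromatographic peaks in the TIC
#'
#' Prominence-based local-maxima detection on the moving-average-smoothed
#' total ion current: maxima whose topographic prominence exceeds
#' `min_prominence` times the trace maximum are kept, maxima closer than
#' `min_separation` minutes are merged (keeping the taller), and each peak
#' is integrated trapezoidally between valley bounds (the TIC minima towards
#' the neighbouring peaks, or the trace ends).
#'
#' @param run A gradient-mode `lcms_run`.
#' @param min_prominence Prominence floor as a fraction of the TIC maximum
#'   (default 0.05).
#' @param min_separation Merge radius in minutes (default 0.05).
#' @param smooth Moving-average window in points (default 5).
#' @return A `chrom_peaks` data.frame: apex, start, end (minutes), area,
#'   relative_area (fractions summing to 1 over detected peaks).
#' @export
detect_chrom_peaks <- function(run, min_prominence = 0.05,
                               min_separation = 0.05, smooth = 5L) {
  stopifnot(inherits(run, "lcms_run"))
  if (run$mode != "gradient") {
    stop("peak detection requires a gradient run; for direct injection ",
         "match against average_spectrum() instead")
  }
  t <- run$times; y <- run$tic
  if (length(t) < 2L) stop("need at least two time points")
  ys <- .moving_average(y, smooth)
  empty <- data.frame(apex = numeric(0), start = numeric(0),
                      end = numeric(0), area = numeric(0),
                      relative_area = numeric(0))
  if (max(ys) <= 0) return(structure(empty, class = c("chrom_peaks",
                                                      "data.frame")))
  n <- length(ys)
  i <- 2:(n - 1)
  cand <- i[ys[i] >= ys[i - 1] & ys[i] > ys[i + 1]]
  prom <- vapply(cand, function(j) .prominence(ys, j), numeric(1))
  cand <- cand[prom >= min_prominence * max(ys)]
  if (!length(cand)) return(structure(empty, class = c("chrom_peaks",
                                                       "data.frame")))
  keep <- integer(0)
  for (j in cand[order(-ys[cand])]) {
    if (!length(keep) || all(abs(t[j] - t[keep]) >= min_separation)) {
      keep <- c(keep, j)
    }
  }
  keep <- sort(keep)
  # valley bounds between adjacent kept peaks, trace ends outside
  starts <- ends <- integer(length(keep))
  for (k in seq_along(keep)) {
    lo <- if (k == 1L) 1L else {
      between <- keep[k - 1L]:keep[k]
      between[which.min(ys[between])]
    }
    hi <- if (k == length(keep)) n else {
      between <- keep[k]:keep[k + 1L]
      between[which.min(ys[between])]
    }
    starts[k] <- lo; ends[k] <- hi
  }
  area <- vapply(seq_along(keep), function(k) {
    idx <- starts[k]:ends[k]
    .trapz(t[idx], y[idx])
  }, numeric(1))
  out <- data.frame(apex = t[keep], start = t[starts], end = t[ends],
                    area = area,
                    relative_area = if (sum(area) > 0) area / sum(area)
                                    else rep(0, length(area)))
  structure(out, class = c("chrom_peaks", "data.frame"))
}

.moving_average <- function(y, w) {
  w <- max(1L, min(as.integer(w), length(y)))
  if (w == 1L) return(y)
  kern <- rep(1 / w, w)
  ys <- as.numeric(stats::filter(y, kern, sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)] # edges: fall back to raw values
  ys
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Topographic prominence of the local maximum at index j: height minus the
# higher of the two key saddles (minimum between the peak and the nearest
# strictly higher ground on each side; trace end counts as ground level 0
# reference, i.e. the side minimum itself).
.prominence <- function(y, j) {
  h <- y[j]
  left <- if (j == 1L) h else {
    seg <- y[seq_len(j - 1L)]
    higher <- which(seg > h)
    if (length(higher)) min(y[(max(higher)):(j - 1L)]) else min(seg)
  }
  right <- if (j == length(y)) h else {
    seg <- y[(j + 1L):length(y)]
    higher <- which(seg > h)
    if (length(higher)) min(seg[seq_len(min(higher))]) else min(seg)
  }
  h - max(left, right)
}

#' Extract the mass spectrum of a chromatographic peak
#'
#' Averages all scans falling within the peak's start/end window (equal
#' scan weights) and re-centroids by m/z binning.
#'
#' @param run A gradient `lcms_run`.
#' @param peak One row of a `chrom_peaks` data.frame.
#' @param bin_width m/z bin width in daltons (default 0.05).
#' @return A `mass_spectrum`.
#' @export
extract_peak_spectrum <- function(run, peak, bin_width = 0.05) {
  idx <- which(run$times >= peak$start - 1e-12 &
               run$times <= peak$end + 1e-12)
  if (!length(idx)) {
    stop("no scans within peak window [", peak$start, ", ", peak$end, "] min")
  }
  average_spectrum(run, idx, bin_width)
}

#' Main chromatographic peaks
#'
#' The subset of detected peaks whose relative area is at least
#' `rel_area_min` (default 0.10), preserving elution order.
#'
#' @param peaks A `chrom_peaks` data.frame.
#' @param rel_area_min Relative-area floor.
#' @return A `chrom_peaks` data.frame.
#' @export
main_peaks <- function(peaks, rel_area_min = 0.10) {
  out <- peaks[peaks$relative_area >= rel_area_min, , drop = FALSE]
  structure(out, class = c("chrom_peaks", "data.frame"))
}

# Spectrum peaks above a relative-intensity floor.
.spectrum_peaks <- function(spectrum, rel_intensity_min = 0.02) {
  if (!length(spectrum$mz)) return(spectrum)
  floor_i <- rel_intensity_min * max(spectrum$intensity)
  keep <- spectrum$intensity >= floor_i & spectrum$intensity > 0
  mass_spectrum(spectrum$mz[keep], spectrum$intensity[keep])
}

#' Targeted m/z matching against main UPLC peaks
#'
#' The gradient-mode screening question: is the anticipated product mass
#' among the main peaks of the UPLC trace? Chromatographic peaks are
#' detected, the main ones (relative area >= `rel_area_min`) retained, each
#' main peak's averaged mass spectrum extracted, and every expected m/z
#' compared against its spectrum peaks (above a relative-intensity floor)
#' within `tol`. The result passes if at least one expected value matches in
#' at least one main peak.
#'
#' @param run A gradient `lcms_run`.
#' @param expected data.frame with columns `label` and `mz` (e.g. from
#'   [adduct_mz()]).
#' @param tol Matching tolerance in daltons (default 0.5, unit resolution).
#' @param rel_area_min Main-peak relative-area floor (default 0.10).
#' @param rel_intensity_min Spectrum-peak relative-intensity floor
#'   (default 0.02).
#' @param ... Passed to [detect_chrom_peaks()].
#' @return An `ms_match`: list with `passed`, `matches` (data.frame: label,
#'   expected_mz, observed_mz, apex), `n_main_peaks`.
#' @export
match_targeted <- function(run, expected, tol = 0.5, rel_area_min = 0.10,
                           rel_intensity_min = 0.02, ...) {
  if (is.null(expected) || !nrow(expected)) {
    stop("expected m/z list must not be empty")
  }
  if (!all(c("label", "mz") %in% names(expected))) {
    names(expected)[1:2] <- c("label", "mz")
  }
  peaks <- main_peaks(detect_chrom_peaks(run, ...), rel_area_min)
  matches <- list()
  if (nrow(peaks)) {
    for (k in seq_len(nrow(peaks))) {
      spec <- .spectrum_peaks(extract_peak_spectrum(run, peaks[k, ]),
                              rel_intensity_min)
      if (!length(spec$mz)) next
      for (e in seq_len(nrow(expected))) {
        d <- abs(spec$mz - expected$mz[e])
        hit <- which(d <= tol)
        if (length(hit)) {
          best <- hit[which.min(d[hit])]
          matches[[length(matches) + 1L]] <- data.frame(
            label = expected$label[e], expected_mz = expected$mz[e],
            observed_mz = spec$mz[best], apex = peaks$apex[k],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(label = character(0), expected_mz = numeric(0),
               observed_mz = numeric(0), apex = numeric(0))
  structure(list(passed = nrow(matches) > 0L, matches = matches,
                 n_main_peaks = nrow(peaks)),
            class = "ms_match")
}

#' Table-based assembly matching for direct-injection spectra
#'
#' The supramolecular screening question: does the spectrum contain at least
#' `min_charge_states` distinct rungs of the counterion charge ladder of any
#' precalculated assembly? For each lookup-table entry the distinct (z, n)
#' ladder values matched within `tol` against spectrum peaks (above a
#' relative-intensity floor) are counted; the result passes if any entry
#' reaches the minimum. Requiring two charge combinations suppresses the
#' false positives a single accidental match would produce against a large
#' table.
#'
#' @param spectrum A `mass_spectrum` (typically [average_spectrum()] of a
#'   direct-injection run).
#' @param table An `mz_table` from [build_lookup_table()].
#' @param tol Matching tolerance in daltons (default: the table's own).
#' @param min_charge_states Minimum distinct matched charge states
#'   (default 2).
#' @param rel_intensity_min Spectrum-peak relative-intensity floor
#'   (default 0.02).
#' @return An `ms_match`: `passed`, `matches` (data.frame: entry_id,
#'   combination, z, n, expected mz, observed_mz), `charge_state_counts`
#'   (named integer per matched entry).
#' @export
match_assembly_table <- function(spectrum, table, tol = NULL,
                                 min_charge_states = 2L,
                                 rel_intensity_min = 0.02) {
  stopifnot(inherits(table, "mz_table"))
  if (!nrow(table$ladders)) stop("empty m/z lookup table")
  if (is.null(tol)) tol <- table$tol
  obs <- .spectrum_peaks(spectrum, rel_intensity_min)
  lad <- table$ladders
  if (length(obs$mz)) {
    nearest <- vapply(lad$mz, function(m) {
      j <- which.min(abs(obs$mz - m)); obs$mz[j]
    }, numeric(1))
    hit <- abs(nearest - lad$mz) <= tol
  } else {
    nearest <- rep(NA_real_, nrow(lad)); hit <- rep(FALSE, nrow(lad))
  }
  matches <- lad[hit, c("entry_id", "combination", "m", "l", "Q", "z", "n",
                        "mz")]
  matches$observed_mz <- nearest[hit]
  counts <- if (nrow(matches)) {
    tab <- tapply(matches$z, matches$entry_id, function(z) length(unique(z)))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  structure(list(passed = any(counts >= min_charge_states),
                 matches = matches, charge_state_counts = counts,
                 min_charge_states = as.integer(min_charge_states)),
            class = "ms_match")
}

#' @export
print.ms_match <- function(x, ...) {
  cat("<MS match> ", if (x$passed) "PASS" else "FAIL", "; ",
      nrow(x$matches), " matched value(s)\n", sep = "")
  invisible(x)
}
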