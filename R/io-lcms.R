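#' Read an LC-MS run
#'
#' Two dialects. `"mzml"` reads centroided MS1 scans from an mzML file
#' through the mzR package (retention times converted from seconds to
#' minutes). `"csv"` reads the package's CSV dialect: comment header lines
#' starting with `#` (carrying `mode: gradient|direct_injection`), a header
#' row `scan_time,mz,intensity`, then one row per (scan time, m/z,
#' intensity) triple. Rows sharing a scan time form one mass spectrum; scan
#' times must be non-decreasing in the file and strictly increasing across
#' scans.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"mzml"` (default: by file extension).
#' @param mode Run mode for mzML input, where the file itself does not say
#'   whether the column was bypassed (default `"gradient"`).
#' @return An `lcms_run`.
#' @export
read_lcms <- function(path, dialect = NULL, mode = "gradient") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.mzml$", tolower(path))) "mzml" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "mzml"))
  if (dialect == "mzml") {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package")
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle))
    hdr <- mzR::header(handle)
    ms1 <- which(hdr$msLevel == 1L)
    if (!length(ms1)) stop("no MS1 scans in ", path)
    scans <- lapply(ms1, function(i) {
      pk <- mzR::peaks(handle, i)
      keep <- pk[, 2] > 0
      mass_spectrum(pk[keep, 1], pk[keep, 2])
    })
    return(lcms_run(mode, hdr$retentionTime[ms1] / 60, scans))
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  mode <- "gradient"
  for (h in hdr) {
    if (grepl("mode:", h)) mode <- trimws(sub(".*mode:\\s*", "", h))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L || !grepl("^\\s*scan_time\\s*,", body[1])) {
    stop("expected 'scan_time,mz,intensity' header in ", path)
  }
  dat <- utils::read.csv(textConnection(body), header = TRUE)
  for (col in c("scan_time", "mz", "intensity")) {
    dat[[col]] <- suppressWarnings(as.numeric(dat[[col]]))
  }
  # NA m/z with zero intensity is the sentinel for an empty scan
  sentinel <- is.na(dat$mz) & !is.na(dat$intensity) & dat$intensity == 0
  if (anyNA(dat$scan_time) || anyNA(dat$intensity) ||
      any(is.na(dat$mz) & !sentinel)) {
    stop("malformed rows in ", path)
  }
  if (is.unsorted(dat$scan_time)) {
    stop("scans out of time order in ", path)
  }
  times <- unique(dat$scan_time)
  scans <- lapply(times, function(tt) {
    rows <- dat[dat$scan_time == tt & dat$intensity > 0, , drop = FALSE]
    mass_spectrum(rows$mz, rows$intensity)
  })
  lcms_run(mode, times, scans)
}

#' Write an LC-MS run to the CSV dialect
#'
#' Empty scans are written as a single zero-intensity sentinel row (m/z 0 is
#' invalid, so an `mz` of `NA` with zero intensity marks them); they round-
#' trip to empty spectra.
#'
#' @param run An `lcms_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lcms <- function(run, path) {
  stopifnot(inherits(run, "lcms_run"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mode: %s", run$mode), con)
  writeLines("scan_time,mz,intensity", con)
  for (i in seq_along(run$times)) {
    s <- run$scans[[i]]
    if (length(s$mz)) {
      writeLines(sprintf("%.12g,%.12g,%.12g", run$times[i], s$mz,
                         s$intensity), con)
    } else {
      writeLines(sprintf("%.12g,NA,0", run$times[i]), con)
    }
  }
  invisible(path)
}
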