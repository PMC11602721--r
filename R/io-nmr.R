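#' Read a 1H NMR spectrum
#'
#' Two dialects are supported. `"jcamp"` reads JCAMP-DX files containing
#' either an `##XYDATA=(X++(Y..Y))` block (AFFN, equidistant abscissa) or an
#' NTUPLES `##DATA TABLE= (X++(R..R))` block (the real part); unknown
#' records are skipped with a warning. `"csv"` reads the package's CSV
#' dialect: comment header lines starting with `#` carrying
#' `field_mhz:` and zero or more `mask: lo,hi` entries, then a header row
#' `ppm,intensity` and the data. Descending-ppm files are normalized to an
#' ascending axis.
#'
#' @param path File path.
#' @param dialect `"jcamp"` or `"csv"` (default: by file extension,
#'   `.jdx`/`.dx` vs anything else).
#' @return An `nmr_spectrum`.
#' @export
read_nmr <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp"
               else "csv"
  }
  dialect <- match.arg(dialect, c("jcamp", "csv"))
  if (dialect == "jcamp") .read_jcamp(path) else .read_nmr_csv(path)
}

#' Write a 1H NMR spectrum
#'
#' @param spec An `nmr_spectrum`.
#' @param path Output path.
#' @param dialect `"jcamp"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_nmr <- function(spec, path, dialect = c("csv", "jcamp")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spec, "nmr_spectrum"))
  if (dialect == "csv") .write_nmr_csv(spec, path) else
    .write_jcamp(spec, path)
  invisible(path)
}

.write_nmr_csv <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_mhz: %.8g", spec$field), con)
  for (mk in spec$masks) {
    writeLines(sprintf("# mask: %.8g,%.8g", mk[1], mk[2]), con)
  }
  writeLines("ppm,intensity", con)
  writeLines(sprintf("%.12g,%.12g", spec$ppm, spec$intensity), con)
}

.read_nmr_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- 80
  masks <- list()
  for (h in hdr) {
    if (grepl("field_mhz:", h)) {
      field <- as.numeric(sub(".*field_mhz:\\s*", "", h))
    } else if (grepl("mask:", h)) {
      mk <- as.numeric(strsplit(sub(".*mask:\\s*", "", h), ",")[[1]])
      masks[[length(masks) + 1L]] <- mk
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path)
  if (!grepl("^\\s*ppm\\s*,", body[1])) {
    stop("expected 'ppm,intensity' header in ", path)
  }
  dat <- utils::read.csv(textConnection(body), header = TRUE)
  dat$ppm <- suppressWarnings(as.numeric(dat$ppm))
  dat$intensity <- suppressWarnings(as.numeric(dat$intensity))
  if (anyNA(dat$ppm) || anyNA(dat$intensity)) {
    stop("malformed ppm/intensity values in ", path)
  }
  o <- order(dat$ppm) # normalize descending axes
  nmr_spectrum(dat$ppm[o], dat$intensity[o], field = field, masks = masks)
}

.write_jcamp <- function(spec, path) {
  # uniform-grid check: XYDATA (X++(Y..Y)) assumes equidistant abscissa
  d <- diff(spec$ppm)
  if (diff(range(d)) > 1e-9) {
    stop("JCAMP XYDATA output requires a uniform ppm grid")
  }
  yfac <- max(abs(spec$intensity), 1e-300) / 1e6
  yint <- round(spec$intensity / yfac)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("##TITLE= chemtriage spectrum")
  w("##JCAMP-DX= 5.00")
  w("##DATA TYPE= NMR SPECTRUM")
  w("##DATA CLASS= XYDATA")
  w("##.OBSERVE FREQUENCY= ", sprintf("%.8g", spec$field))
  w("##XUNITS= PPM")
  w("##YUNITS= ARBITRARY UNITS")
  w("##XFACTOR= 1")
  w("##YFACTOR= ", sprintf("%.12g", yfac))
  w("##FIRSTX= ", sprintf("%.12g", spec$ppm[1]))
  w("##LASTX= ", sprintf("%.12g", spec$ppm[length(spec$ppm)]))
  w("##NPOINTS= ", length(spec$ppm))
  w("##XYDATA= (X++(Y..Y))")
  # AFFN: one X value then up to 8 Y values per line
  idx <- seq(1, length(yint), by = 8L)
  for (i in idx) {
    j <- min(i + 7L, length(yint))
    w(sprintf("%.6f", spec$ppm[i]), " ",
      paste(format(yint[i:j], scientific = FALSE, trim = TRUE),
            collapse = " "))
  }
  w("##END=")
}

.read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  get_field <- function(key, default = NA_real_) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", key, "=\\s*"), "", hit[1]))
  }
  freq <- get_field("\\.OBSERVE FREQUENCY", 80)
  xfac <- get_field("XFACTOR", 1)
  yfac <- get_field("YFACTOR", 1)
  npoints <- get_field("NPOINTS")
  firstx <- get_field("FIRSTX")
  lastx <- get_field("LASTX")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) {
    start <- grep("^##DATA TABLE=\\s*\\(X\\+\\+\\(R\\.\\.R\\)\\)", lines)
    if (!length(start)) {
      stop("no XYDATA or (X++(R..R)) DATA TABLE block in ", path)
    }
  }
  known <- c("TITLE", "JCAMP-DX", "DATA TYPE", "DATA CLASS", "XUNITS",
             "YUNITS", "XFACTOR", "YFACTOR", "FIRSTX", "LASTX", "NPOINTS",
             "XYDATA", "DATA TABLE", "END", ".OBSERVE FREQUENCY")
  labels <- sub("=.*$", "", grep("^##", lines, value = TRUE))
  unknown <- setdiff(unique(sub("^##", "", labels)), known)
  if (length(unknown)) {
    warning("skipping unrecognized JCAMP record(s): ",
            paste(unknown, collapse = ", "))
  }
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start[1]]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  body <- lines[(start[1] + 1L):end]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty data block in ", path)
  ys <- numeric(0)
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln),
                                                 "[ \t,]+")[[1]]))
    if (anyNA(vals) || length(vals) < 2L) {
      stop("malformed JCAMP data line in ", path, ": ", sQuote(ln))
    }
    ys <- c(ys, vals[-1]) # first token is the line's X value
  }
  if (!is.na(npoints) && length(ys) != npoints) {
    stop("NPOINTS=", npoints, " but ", length(ys), " ordinates in ", path)
  }
  n <- length(ys)
  x <- if (!is.na(firstx) && !is.na(lastx)) {
    seq(firstx, lastx, length.out = n) * xfac
  } else {
    stop("FIRSTX/LASTX missing in ", path)
  }
  o <- order(x)
  nmr_spectrum(x[o], (ys * yfac)[o], field = freq)
}
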