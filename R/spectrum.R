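#' Construct a Raman spectrum
#'
#' A spectrum is a tibble with columns `wavenumber` (Raman shift, cm^-1,
#' strictly increasing) and `intensity` (counts per second, cps), carrying
#' free-form metadata in the `"meta"` attribute. It is the currency every
#' pipeline stage consumes and returns.
#'
#' Negative intensities are physically meaningless on raw spectra and are
#' rejected unless `allow_negative = TRUE` (used internally for
#' background-subtracted and residual spectra, which are flagged in `meta`).
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1.
#' @param intensity Numeric vector of intensities in cps, same length.
#' @param meta Named list of metadata (source file, acquisition label, flags).
#' @param allow_negative Permit negative intensities (background-free /
#'   residual spectra). When `TRUE` the spectrum is flagged via
#'   `meta$negative_values`.
#' @return A `raman_spectrum` tibble.
#' @examples
#' s <- raman_spectrum(1000:1010, rep(5, 11))
#' s
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list(),
                           allow_negative = FALSE) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    rlang::abort("`wavenumber` and `intensity` must have equal length.",
                 class = "ramanbca_format_error")
  }
  if (length(wavenumber) < 2) {
    rlang::abort("A spectrum needs at least 2 points.",
                 class = "ramanbca_format_error")
  }
  if (anyNA(wavenumber) || any(!is.finite(wavenumber))) {
    rlang::abort("Non-finite wavenumbers.", class = "ramanbca_format_error")
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    rlang::abort("Non-finite intensities (NaN/Inf).",
                 class = "ramanbca_format_error")
  }
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    dup <- anyDuplicated(wavenumber)
    if (dup) {
      rlang::abort(
        sprintf("Duplicate wavenumber %.6g.", wavenumber[dup]),
        class = "ramanbca_format_error"
      )
    }
    rlang::abort("Wavenumbers must be strictly increasing.",
                 class = "ramanbca_format_error")
  }
  if (any(intensity < 0)) {
    if (!allow_negative) {
      rlang::abort(
        "Negative intensities on a raw spectrum; use `allow_negative = TRUE` for background-subtracted or residual spectra.",
        class = "ramanbca_format_error"
      )
    }
    meta$negative_values <- TRUE
  }
  out <- tibble::tibble(wavenumber = wavenumber, intensity = intensity)
  class(out) <- c("raman_spectrum", class(out))
  attr(out, "meta") <- meta
  out
}

#' @export
#' @rdname raman_spectrum
is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

#' Spectrum metadata
#'
#' @param s A `raman_spectrum`.
#' @return The metadata list.
#' @export
spec_meta <- function(s) attr(s, "meta") %||% list()

#' @param value Replacement metadata list.
#' @export
#' @rdname spec_meta
`spec_meta<-` <- function(s, value) {
  attr(s, "meta") <- value
  s
}

# rebuild a spectrum from an existing one, preserving/extending meta
spec_update <- function(s, intensity = NULL, wavenumber = NULL, meta = list()) {
  raman_spectrum(
    wavenumber %||% s$wavenumber,
    intensity %||% s$intensity,
    meta = utils::modifyList(spec_meta(s), meta),
    allow_negative = TRUE
  )
}

#' Regular spectral grid
#'
#' The default spans the instrument range, 50-1900 cm^-1, sampled at
#' 1 cm^-1 (about twice the 2 cm^-1 FWHM optical resolution).
#'
#' @param start,stop Range in cm^-1 (`start < stop`).
#' @param step Sampling step in cm^-1 (> 0).
#' @return A `spectral_grid` object.
#' @export
spectral_grid <- function(start = 50, stop = 1900, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) {
    rlang::abort("`start` must be < `stop`.", class = "ramanbca_param_error")
  }
  if (step <= 0) {
    rlang::abort("`step` must be > 0.", class = "ramanbca_param_error")
  }
  structure(list(start = start, stop = stop, step = step),
            class = "spectral_grid")
}

#' @export
#' @rdname spectral_grid
grid_axis <- function(grid) {
  n <- floor((grid$stop - grid$start) / grid$step) + 1
  grid$start + grid$step * (seq_len(n) - 1)
}

#' @export
format.spectral_grid <- function(x, ...) {
  sprintf("<spectral_grid %g-%g cm-1, step %g>", x$start, x$stop, x$step)
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV files carry two numeric columns (wavenumber cm^-1, intensity cps)
#' with an optional single header line, auto-detected by a non-numeric
#' first row. JCAMP-DX support covers single-block AFFN
#' `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)` files.
#'
#' Descending axes are re-sorted ascending and noted in
#' `spec_meta(s)$reversed`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension: `.jdx`/`.dx` is JCAMP), `"csv"`,
#'   or `"jcamp"`.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
                 class = "ramanbca_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", path, ignore.case = TRUE)) {
      "jcamp"
    } else {
      "csv"
    }
  }
  xy <- switch(format,
    csv = read_xy_csv(path),
    jcamp = read_xy_jcamp(path)
  )
  meta <- list(source = path, format = format)
  if (is.unsorted(xy$x, strictly = TRUE)) {
    if (all(diff(xy$x) < 0)) {
      xy$y <- rev(xy$y)
      xy$x <- rev(xy$x)
      meta$reversed <- TRUE
    }
  }
  raman_spectrum(xy$x, xy$y, meta = meta, allow_negative = TRUE)
}

read_xy_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    rlang::abort(sprintf("%s: empty file.", path),
                 class = "ramanbca_format_error")
  }
  first_fields <- strsplit(trimws(lines[[1]]), ",")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first_fields)))
  start <- if (has_header) 2L else 1L
  if (length(lines) < start + 1L) {
    rlang::abort(sprintf("%s: fewer than 2 data points.", path),
                 class = "ramanbca_format_error")
  }
  rows <- strsplit(trimws(lines[start:length(lines)]), ",")
  x <- numeric(length(rows))
  y <- numeric(length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    vals <- suppressWarnings(as.numeric(f))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      rlang::abort(
        sprintf("%s: non-numeric row at line %d: '%s'",
                path, i + start - 1L, lines[i + start - 1L]),
        class = "ramanbca_format_error"
      )
    }
    x[i] <- vals[1]
    y[i] <- vals[2]
  }
  if (anyDuplicated(x)) {
    rlang::abort(
      sprintf("%s: duplicate wavenumber %.6g.", path, x[anyDuplicated(x)]),
      class = "ramanbca_format_error"
    )
  }
  list(x = x, y = y)
}

jcamp_field <- function(lines, key) {
  hit <- grep(sprintf("^##%s=", key), lines, ignore.case = TRUE, value = TRUE)
  if (length(hit) == 0) return(NULL)
  trimws(sub("^##[^=]*=", "", hit[[1]]))
}

read_xy_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  xf <- as.numeric(jcamp_field(lines, "XFACTOR") %||% "1")
  yf <- as.numeric(jcamp_field(lines, "YFACTOR") %||% "1")
  data_start <- grep("^##(XYDATA|XYPOINTS)=", lines, ignore.case = TRUE)
  if (length(data_start) == 0) {
    rlang::abort(sprintf("%s: no ##XYDATA or ##XYPOINTS block.", path),
                 class = "ramanbca_format_error")
  }
  data_start <- data_start[[1]]
  mode <- if (grepl("XYPOINTS", lines[data_start], ignore.case = TRUE)) {
    "xypoints"
  } else {
    "xydata"
  }
  data_end <- grep("^##", lines)
  data_end <- data_end[data_end > data_start]
  data_end <- if (length(data_end)) min(data_end) - 1L else length(lines)
  body <- lines[seq(data_start + 1L, data_end)]
  body <- body[nzchar(trimws(body))]
  if (mode == "xypoints") {
    toks <- unlist(strsplit(trimws(body), "[,;[:space:]]+"))
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) || length(vals) %% 2 != 0) {
      rlang::abort(sprintf("%s: malformed XYPOINTS block.", path),
                   class = "ramanbca_format_error")
    }
    x <- vals[seq(1, length(vals), by = 2)] * xf
    y <- vals[seq(2, length(vals), by = 2)] * yf
    return(list(x = x, y = y))
  }
  # (X++(Y..Y)): each line starts with the x of its first y; spacing from
  # FIRSTX/LASTX/NPOINTS
  firstx <- as.numeric(jcamp_field(lines, "FIRSTX"))
  lastx <- as.numeric(jcamp_field(lines, "LASTX"))
  np <- as.numeric(jcamp_field(lines, "NPOINTS"))
  if (anyNA(c(firstx, lastx, np)) || np < 2) {
    rlang::abort(sprintf("%s: XYDATA needs FIRSTX/LASTX/NPOINTS.", path),
                 class = "ramanbca_format_error")
  }
  dx <- (lastx - firstx) / (np - 1)
  ys <- numeric(0)
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (anyNA(vals) || length(vals) < 2) {
      rlang::abort(sprintf("%s: malformed XYDATA line: '%s'", path, ln),
                   class = "ramanbca_format_error")
    }
    ys <- c(ys, vals[-1])
  }
  if (length(ys) != np) {
    rlang::abort(sprintf("%s: NPOINTS=%d but %d Y values found.",
                         path, np, length(ys)),
                 class = "ramanbca_format_error")
  }
  list(x = (firstx + dx * (seq_len(np) - 1)) * xf, y = ys * yf)
}

#' Write a spectrum to CSV or JCAMP-DX
#'
#' Round-trips through [read_spectrum()] reproduce both axes to better
#' than 1e-6 relative error. JCAMP output uses `(X++(Y..Y))` when the axis
#' is uniform and `XYPOINTS` otherwise.
#'
#' @inheritParams read_spectrum
#' @param s A `raman_spectrum`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "csv", "jcamp")) {
  stopifnot(is_raman_spectrum(s))
  format <- rlang::arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", path, ignore.case = TRUE)) {
      "jcamp"
    } else {
      "csv"
    }
  }
  ok <- tryCatch({
    con <- file(path, "w")
    on.exit(close(con))
    if (format == "csv") {
      writeLines("wavenumber,intensity", con)
      writeLines(sprintf("%.10g,%.10g", s$wavenumber, s$intensity), con)
    } else {
      write_jcamp(s, con)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    rlang::abort(sprintf("Cannot write %s: %s", path, conditionMessage(ok)),
                 class = "ramanbca_io_error")
  }
  invisible(path)
}

write_jcamp <- function(s, con) {
  x <- s$wavenumber
  y <- s$intensity
  title <- spec_meta(s)$label %||% "ramanbca spectrum"
  hdr <- c(
    sprintf("##TITLE=%s", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", x[1]),
    sprintf("##LASTX=%.10g", x[length(x)]),
    sprintf("##NPOINTS=%d", length(x))
  )
  writeLines(hdr, con)
  dx <- diff(x)
  uniform <- max(abs(dx - dx[1])) <= 1e-9 * max(abs(x))
  if (uniform) {
    writeLines("##XYDATA=(X++(Y..Y))", con)
    idx <- split(seq_along(y), ceiling(seq_along(y) / 6))
    for (ii in idx) {
      writeLines(paste(c(sprintf("%.10g", x[ii[1]]),
                         sprintf("%.10g", y[ii])), collapse = " "), con)
    }
  } else {
    writeLines("##XYPOINTS=(XY..XY)", con)
    writeLines(sprintf("%.10g, %.10g", x, y), con)
  }
  writeLines("##END=", con)
}

#' Resample a spectrum onto a regular grid
#'
#' Linear interpolation; grid points outside the spectrum's support are
#' zero-filled and flagged in `spec_meta(s)$extrapolated`. Resampling a
#' spectrum already on the grid is the identity.
#'
#' @param s A `raman_spectrum`.
#' @param grid A [spectral_grid()].
#' @return A `raman_spectrum` on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(is_raman_spectrum(s), inherits(grid, "spectral_grid"))
  ax <- grid_axis(grid)
  rng <- range(s$wavenumber)
  if (rng[2] < ax[1] || rng[1] > ax[length(ax)]) {
    rlang::abort("Grid does not overlap the spectrum's support.",
                 class = "ramanbca_domain_error")
  }
  y <- stats::approx(s$wavenumber, s$intensity, xout = ax,
                     method = "linear", rule = 1)$y
  outside <- is.na(y)
  y[outside] <- 0
  meta <- list(resampled = TRUE)
  if (any(outside)) meta$extrapolated <- TRUE
  spec_update(s, wavenumber = ax, intensity = y, meta = meta)
}

#' Savitzky-Golay smoothing
#'
#' Polynomial-filter smoothing on a uniform axis. Polynomials of degree
#' `<= order` pass through unchanged (the filter's exactness property), so
#' band areas of smooth spectra are preserved.
#'
#' @param s A `raman_spectrum` on a uniform axis.
#' @param window Odd filter length in points (> `order`).
#' @param order Polynomial order (>= 1).
#' @return The smoothed `raman_spectrum`.
#' @export
smooth_spectrum <- function(s, window = 11, order = 3) {
  stopifnot(is_raman_spectrum(s))
  if (window %% 2 != 1 || window <= order || order < 1) {
    rlang::abort("Need odd `window` > `order` >= 1.",
                 class = "ramanbca_param_error")
  }
  dx <- diff(s$wavenumber)
  if (max(abs(dx - dx[1])) > 1e-6 * abs(dx[1])) {
    rlang::abort("Savitzky-Golay smoothing needs a uniform axis; resample first.",
                 class = "ramanbca_param_error")
  }
  y <- signal::sgolayfilt(s$intensity, p = order, n = window)
  spec_update(s, intensity = y, meta = list(smoothed = c(window, order)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' @param object A `raman_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raman_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavenumber, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (cps)")
}

#' @importFrom rlang %||% .data
NULL
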