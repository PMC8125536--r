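#' Field-swept EPR spectrum
#'
#' The universal currency of the pipeline: a uniform ascending field axis in
#' Gauss, the (first-derivative, arbitrary-unit) intensity, and acquisition
#' metadata.
#'
#' @param field_G field axis in Gauss, uniform ascending, length >= 2.
#' @param intensity intensity values, same length as `field_G`.
#' @param frequency_GHz microwave frequency in GHz (> 0).
#' @param temperature_K sample temperature in K (optional).
#' @param modulation_amplitude_G field-modulation amplitude in G (metadata
#'   only; not convolved into simulations).
#' @param metadata free-form named list (labels, provenance).
#' @return an object of class `epr_spectrum`.
#' @export
epr_spectrum <- function(field_G, intensity, frequency_GHz,
                         temperature_K = NA_real_,
                         modulation_amplitude_G = NA_real_,
                         metadata = list()) {
  field_G <- as.numeric(field_G)
  intensity <- as.numeric(intensity)
  if (length(field_G) < 2) stop("field axis needs at least 2 points")
  if (length(field_G) != length(intensity)) {
    stop("`field_G` and `intensity` lengths differ")
  }
  .check_uniform(field_G)
  if (!is.numeric(frequency_GHz) || frequency_GHz <= 0) {
    stop("`frequency_GHz` must be > 0")
  }
  structure(list(field_G = field_G, intensity = intensity,
                 frequency_GHz = frequency_GHz,
                 temperature_K = temperature_K,
                 modulation_amplitude_G = modulation_amplitude_G,
                 metadata = metadata),
            class = "epr_spectrum")
}

.check_uniform <- function(field_G, rel_tol = 1e-6) {
  d <- diff(field_G)
  if (any(d <= 0)) stop("field axis must be strictly increasing")
  step <- mean(d)
  if (max(abs(d - step)) > rel_tol * step) {
    stop("field axis must be uniform to within 1e-6 relative")
  }
  invisible(step)
}

field_step <- function(spec) mean(diff(spec$field_G))

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<epr_spectrum> %d points, %.6g-%.6g G, %.6f GHz%s\n",
    length(x$field_G), min(x$field_G), max(x$field_G), x$frequency_GHz,
    if (is.na(x$temperature_K)) "" else sprintf(", %g K", x$temperature_K)))
  invisible(x)
}

#' @export
plot.epr_spectrum <- function(x, ..., xlab = "Field (G)",
                              ylab = "dA/dB (a.u.)") {
  plot(x$field_G, x$intensity, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read / write a two-column ASCII spectrum
#'
#' The on-disk dialect used throughout: `#`-prefixed `key: value` header
#' lines carrying `frequency_GHz`, `temperature_K` and
#' `modulation_amplitude_G` (plus free-form metadata), then two
#' whitespace-separated numeric columns (field in Gauss, intensity).
#' The reader tolerates blank lines and missing metadata (with a warning
#' for a missing frequency); a non-numeric data row is an error naming the
#' offending line.
#'
#' @param path file path.
#' @param spec an [epr_spectrum()].
#' @return `read_spectrum` returns an `epr_spectrum`; `write_spectrum`
#'   returns `path` invisibly.  The round trip is lossless to the 15
#'   significant digits written.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- list()
  field <- numeric(0)
  inten <- numeric(0)
  nrow <- 0L
  for (li in seq_along(lines)) {
    ln <- trimws(lines[[li]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      if (grepl(":", body, fixed = TRUE)) {
        key <- trimws(sub(":.*$", "", body))
        val <- trimws(sub("^[^:]*:", "", body))
        num <- suppressWarnings(as.numeric(val))
        meta[[key]] <- if (is.na(num)) val else num
      }
      next
    }
    parts <- strsplit(ln, "[ \t,]+")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("line %d of '%s' does not hold two columns", li, path))
    }
    vals <- suppressWarnings(as.numeric(parts[1:2]))
    if (any(is.na(vals))) {
      stop(sprintf("non-numeric data on line %d of '%s'", li, path))
    }
    nrow <- nrow + 1L
    field[nrow] <- vals[1]
    inten[nrow] <- vals[2]
  }
  if (nrow < 2) stop("'", path, "' holds fewer than 2 data rows")
  freq <- meta[["frequency_GHz"]]
  if (is.null(freq)) {
    warning("'", path, "' has no frequency_GHz header; assuming 9.4 GHz")
    freq <- 9.4
  }
  known <- c("frequency_GHz", "temperature_K", "modulation_amplitude_G")
  epr_spectrum(field, inten, frequency_GHz = freq,
               temperature_K = meta[["temperature_K"]] %||% NA_real_,
               modulation_amplitude_G =
                 meta[["modulation_amplitude_G"]] %||% NA_real_,
               metadata = meta[setdiff(names(meta), known)])
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "epr_spectrum"))
  hdr <- c(sprintf("# frequency_GHz: %.15g", spec$frequency_GHz))
  if (!is.na(spec$temperature_K)) {
    hdr <- c(hdr, sprintf("# temperature_K: %.15g", spec$temperature_K))
  }
  if (!is.na(spec$modulation_amplitude_G)) {
    hdr <- c(hdr, sprintf("# modulation_amplitude_G: %.15g",
                          spec$modulation_amplitude_G))
  }
  for (k in names(spec$metadata)) {
    v <- spec$metadata[[k]]
    if (is.numeric(v) && length(v) == 1) {
      hdr <- c(hdr, sprintf("# %s: %.15g", k, v))
    } else if (is.character(v) && length(v) == 1) {
      hdr <- c(hdr, sprintf("# %s: %s", k, v))
    }
  }
  rows <- sprintf("%.15g\t%.15g", spec$field_G, spec$intensity)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Resample spectra onto a common field axis
#'
#' Restricts all spectra to the intersection of their field ranges and
#' linearly interpolates onto a common uniform axis (the finest step among
#' the inputs).  Disjoint field ranges are an error.  Resampling is noted
#' in each spectrum's metadata.
#'
#' @param specs list of [epr_spectrum()] objects.
#' @return list of spectra sharing one field axis.
#' @export
align_spectra <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1)
  lapply(specs, function(s) stopifnot(inherits(s, "epr_spectrum")))
  lo <- max(vapply(specs, function(s) min(s$field_G), numeric(1)))
  hi <- min(vapply(specs, function(s) max(s$field_G), numeric(1)))
  if (hi <= lo) stop("spectra have disjoint field ranges; cannot align")
  step <- min(vapply(specs, field_step, numeric(1)))
  axis <- seq(lo, hi, by = step)
  already <- all(vapply(specs, function(s) {
    length(s$field_G) == length(axis) && max(abs(s$field_G - axis)) < 1e-9 * step
  }, logical(1)))
  if (already) return(specs)
  lapply(specs, function(s) {
    y <- stats::approx(s$field_G, s$intensity, xout = axis)$y
    s$field_G <- axis
    s$intensity <- y
    s$metadata$resampled <- "linear interpolation onto common axis"
    s
  })
}

# shared-axis check used by the arithmetic operations
.same_axis <- function(a, b) {
  length(a$field_G) == length(b$field_G) &&
    max(abs(a$field_G - b$field_G)) <= 1e-9 * field_step(a)
}

# index set of a field window (two-vector, Gauss), optionally minus an
# excluded interval
.window_idx <- function(spec, window, exclude = NULL) {
  stopifnot(length(window) == 2)
  idx <- which(spec$field_G >= min(window) & spec$field_G <= max(window))
  if (!length(idx)) stop("window lies outside the field axis")
  if (!is.null(exclude)) {
    idx <- setdiff(idx, which(spec$field_G >= min(exclude) &
                                spec$field_G <= max(exclude)))
  }
  idx
}
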