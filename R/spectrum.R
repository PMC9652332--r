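#' Construct a sampled spectrum
#'
#' A spectrum is a tibble with columns `wavelength_nm` (strictly increasing)
#' and `value` (non-negative, arbitrary units). It represents any sampled
#' wavelength-indexed curve: an LED emission spectrum, a photosensitizer
#' absorption spectrum, or a power-meter responsivity curve.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param value Numeric vector of the same length; all values >= 0 and at
#'   least one value > 0.
#' @return A tibble of class `pdt_spectrum` with columns `wavelength_nm`,
#'   `value`.
#' @examples
#' s <- spectrum_tbl(c(680, 690, 700), c(0, 1, 0))
#' @export
spectrum_tbl <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2L) {
    abort("a spectrum needs at least 2 samples")
  }
  if (length(value) != length(wavelength_nm)) {
    abort("wavelength_nm and value must have the same length")
  }
  if (anyNA(wavelength_nm) || anyNA(value)) {
    abort("spectrum samples must not contain NA")
  }
  if (any(diff(wavelength_nm) <= 0)) {
    abort("wavelengths must be strictly increasing")
  }
  if (any(value < 0)) {
    abort("spectrum values must be non-negative")
  }
  if (all(value == 0)) {
    abort("at least one spectrum value must be positive")
  }
  out <- tibble(wavelength_nm = wavelength_nm, value = value)
  class(out) <- c("pdt_spectrum", class(out))
  out
}

#' @export
print.pdt_spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum: %d samples, %.6g-%.6g nm, peak %.6g at %.6g nm>\n",
    nrow(x), min(x$wavelength_nm), max(x$wavelength_nm),
    max(x$value), x$wavelength_nm[which.max(x$value)]
  ))
  NextMethod()
}

is_spectrum <- function(x) {
  is.data.frame(x) && all(c("wavelength_nm", "value") %in% names(x))
}

as_spectrum <- function(x, arg = "spectrum") {
  if (!is_spectrum(x)) {
    abort(sprintf("`%s` must have columns wavelength_nm and value", arg))
  }
  if (inherits(x, "pdt_spectrum")) x else spectrum_tbl(x$wavelength_nm, x$value)
}

#' Read and write two-column spectrum CSV files
#'
#' The on-disk format is a two-column CSV (`wavelength_nm`, `value`) with
#' optional `#`-prefixed comment lines before the header. The writer always
#' emits wavelengths sorted in increasing order.
#'
#' @param path File path.
#' @param comments For the writer, optional character vector written as
#'   `#`-prefixed comment lines.
#' @return `read_spectrum_csv()` returns a `pdt_spectrum` tibble;
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2) abort("spectrum CSV needs two columns")
  names(df)[1:2] <- c("wavelength_nm", "value")
  df <- dplyr::arrange(df, .data$wavelength_nm)
  spectrum_tbl(df$wavelength_nm, df$value)
}

#' @rdname read_spectrum_csv
#' @param spectrum A spectrum (any data frame with `wavelength_nm`, `value`).
#' @export
write_spectrum_csv <- function(spectrum, path, comments = NULL) {
  spectrum <- as_spectrum(spectrum)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.10g,%.10g", spectrum$wavelength_nm, spectrum$value),
             con)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation inside the spectrum's support; exactly zero outside
#' (emission and absorption are physically bounded, so no extrapolation).
#'
#' @param spectrum A spectrum.
#' @param grid_nm Strictly increasing numeric vector of target wavelengths.
#' @return A tibble with columns `wavelength_nm` (== `grid_nm`) and `value`.
#'   Not a `pdt_spectrum` when all interpolated values are zero.
#' @examples
#' s <- spectrum_tbl(c(690, 700), c(0, 10))
#' resample_spectrum(s, 695)$value  # 5
#' @export
resample_spectrum <- function(spectrum, grid_nm) {
  spectrum <- as_spectrum(spectrum)
  grid_nm <- as.numeric(grid_nm)
  if (length(grid_nm) == 0L) abort("resampling grid is empty")
  if (length(grid_nm) > 1L && any(diff(grid_nm) <= 0)) {
    abort("resampling grid must be strictly increasing")
  }
  v <- approx(spectrum$wavelength_nm, spectrum$value, xout = grid_nm,
              method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  out <- tibble(wavelength_nm = grid_nm, value = v)
  if (length(grid_nm) >= 2L && any(v > 0)) {
    class(out) <- c("pdt_spectrum", class(out))
  }
  out
}

#' Value of a spectrum at a single wavelength
#'
#' @inheritParams resample_spectrum
#' @param at_nm Wavelength in nm.
#' @return Interpolated value (0 outside support).
#' @export
spectrum_value_at <- function(spectrum, at_nm) {
  resample_spectrum(spectrum, at_nm)$value
}

#' Full width at half maximum of a single-peaked spectrum
#'
#' Finds the lowest and highest wavelengths at which the curve crosses half
#' of its peak value, linearly interpolating between samples. The spectrum
#' must be unimodal up to measurement ripple: secondary maxima below
#' `ripple_tol` of the peak are ignored; anything larger is an error, as is
#' a flat spectrum or one that never falls below half maximum on either side.
#'
#' @param spectrum A spectrum.
#' @param ripple_tol Secondary-maximum tolerance as a fraction of the peak
#'   (default 0.05): LED spectra carry measurement ripple.
#' @return Named numeric vector `c(low_nm, high_nm)`.
#' @examples
#' g <- gaussian_spectrum(689, fwhm_nm = 26)
#' fwhm_interval(g)  # ~ c(676, 702)
#' @export
fwhm_interval <- function(spectrum, ripple_tol = 0.05) {
  spectrum <- as_spectrum(spectrum)
  w <- spectrum$wavelength_nm
  v <- spectrum$value
  peak <- max(v)
  if (peak <= 0 || all(v == peak)) {
    abort("fwhm undefined: spectrum is flat")
  }
  i_peak <- which.max(v)
  half <- peak / 2
  # unimodality check: local maxima other than the global peak must stay
  # below ripple_tol * peak
  dv <- diff(v)
  is_locmax <- c(FALSE, dv[-length(dv)] > 0 & dv[-1] < 0, FALSE)
  sec <- v[is_locmax & seq_along(v) != i_peak]
  if (length(sec) > 0 && max(sec) > ripple_tol * peak) {
    abort(sprintf(
      "fwhm undefined: spectrum is multimodal (secondary maximum %.3g of peak exceeds tolerance %.3g)",
      max(sec) / peak, ripple_tol
    ))
  }
  # lowest crossing: scan from the left edge toward the peak
  cross_down <- function() {
    for (i in seq_len(i_peak - 1)) {
      if (v[i] <= half && v[i + 1] > half) {
        return(w[i] + (half - v[i]) / (v[i + 1] - v[i]) * (w[i + 1] - w[i]))
      }
    }
    abort("fwhm undefined: spectrum never falls to half maximum on the low side")
  }
  # highest crossing: scan from the right edge toward the peak
  cross_up <- function() {
    if (i_peak >= length(v)) {
      abort("fwhm undefined: spectrum never falls to half maximum on the high side")
    }
    for (i in seq(length(v) - 1, i_peak)) {
      if (v[i] > half && v[i + 1] <= half) {
        return(w[i] + (v[i] - half) / (v[i] - v[i + 1]) * (w[i + 1] - w[i]))
      }
    }
    abort("fwhm undefined: spectrum never falls to half maximum on the high side")
  }
  c(low_nm = cross_down(), high_nm = cross_up())
}

#' Gaussian spectrum generator
#'
#' Convenience constructor for Gaussian-shaped spectra (LED emission lines,
#' photosensitizer Q-bands) on a regular grid.
#'
#' @param center_nm Peak wavelength (nm).
#' @param fwhm_nm Full width at half maximum (nm). Exactly one of `fwhm_nm`
#'   and `sigma_nm` must be given.
#' @param sigma_nm Standard deviation (nm).
#' @param peak Peak value (default 1).
#' @param range_nm Wavelength range; defaults to center +/- 4 sigma.
#' @param step_nm Grid step (default 0.02 nm).
#' @return A `pdt_spectrum`.
#' @export
gaussian_spectrum <- function(center_nm, fwhm_nm = NULL, sigma_nm = NULL,
                              peak = 1, range_nm = NULL, step_nm = 0.02) {
  if (is.null(sigma_nm) == is.null(fwhm_nm)) {
    abort("give exactly one of fwhm_nm and sigma_nm")
  }
  if (is.null(sigma_nm)) sigma_nm <- fwhm_nm / (2 * sqrt(2 * log(2)))
  if (is.null(range_nm)) {
    range_nm <- center_nm + c(-4, 4) * sigma_nm
  }
  w <- seq(range_nm[1], range_nm[2], by = step_nm)
  spectrum_tbl(w, peak * exp(-((w - center_nm)^2) / (2 * sigma_nm^2)))
}

#' Overlay spectra for inspection
#'
#' @param ... Named spectra (`led = s1, absorber = s2, ...`).
#' @param normalize Scale each spectrum to unit peak before plotting
#'   (default TRUE; the curves carry arbitrary units).
#' @return A ggplot.
#' @export
plot_spectra <- function(..., normalize = TRUE) {
  specs <- list(...)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- paste0("spectrum_", seq_along(specs))
  }
  df <- purrr::imap_dfr(specs, function(s, nm) {
    s <- as_spectrum(s, nm)
    v <- if (normalize) s$value / max(s$value) else s$value
    tibble(which = nm, wavelength_nm = s$wavelength_nm, value = v)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = if (normalize) "value (peak-normalized)" else "value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
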