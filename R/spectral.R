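#' Construct a spectrometer readout
#'
#' A 288-channel micro-spectrometer spectrum covering roughly 340-850 nm.
#' Counts come from a 10-bit converter; wavelengths are integer nm from the
#' factory channel-to-wavelength calibration.
#'
#' @param wavelengths_nm Integer wavelengths per channel (nondecreasing).
#' @param counts Nonnegative counts per channel.
#' @param integration_time_ms Integration time (default 300, the fluorescence
#'   setting).
#' @param kind One of `"dark"`, `"fluorescence"`, `"reflectance"`.
#' @return Object of class `spectrum`.
#' @export
spectrum <- function(wavelengths_nm, counts, integration_time_ms = 300,
                     kind = c("fluorescence", "dark", "reflectance")) {
  kind <- match.arg(kind)
  stopifnot(length(wavelengths_nm) == length(counts),
            integration_time_ms > 0)
  if (is.unsorted(wavelengths_nm)) stop("wavelengths must be nondecreasing")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  structure(list(wavelengths_nm = as.integer(wavelengths_nm),
                 counts = as.numeric(counts),
                 integration_time_ms = integration_time_ms,
                 kind = kind,
                 masked = rep(FALSE, length(counts))),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d channels %d-%d nm, %g ms integration\n",
              x$kind, length(x$counts), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$integration_time_ms))
  invisible(x)
}

#' Map spectrometer channel indices to integer wavelengths
#'
#' Fifth-degree polynomial in the 0-based channel index with device-specific
#' factory coefficients `c0..c5`, rounded half-up to integer nanometres. A
#' non-monotone mapping (possible with corrupt coefficients) is flagged via a
#' warning.
#'
#' @param channel_indices 0-based channel indices (default 0:287).
#' @param coefficients Numeric vector of 6 polynomial coefficients, constant
#'   term first. The default is a documented synthetic linear map spanning
#'   340-850 nm over 288 channels (true factory coefficients are per-device).
#' @return Integer wavelengths (nm).
#' @examples
#' map_wavelengths(0:287)[c(1, 288)]
#' @export
map_wavelengths <- function(channel_indices = 0:287,
                            coefficients = c(340, 1.7726, 0, 0, 0, 0)) {
  stopifnot(length(coefficients) == 6)
  wl <- drop(outer(channel_indices, 0:5, `^`) %*% coefficients)
  wl <- as.integer(round_half_up(wl))
  if (length(wl) > 1 && any(diff(wl) <= 0))
    warning("wavelength mapping is not monotone; check calibration coefficients")
  wl
}

#' Mean dark-current spectrum
#'
#' Channel-wise arithmetic mean of dark readouts (captured at night with the
#' excitation light off); the estimate subtracted from fluorescence spectra.
#'
#' @param darks Nonempty list of `spectrum` objects of kind `"dark"`.
#' @return A `spectrum` of kind `"dark"`.
#' @export
mean_dark <- function(darks) {
  if (length(darks) == 0) stop("need at least one dark spectrum")
  stopifnot(all(vapply(darks, inherits, logical(1), "spectrum")))
  wl <- darks[[1]]$wavelengths_nm
  for (d in darks)
    if (!identical(d$wavelengths_nm, wl))
      stop("dark spectra have mismatched wavelength axes")
  counts <- rowMeans(vapply(darks, `[[`, numeric(length(wl)), "counts"))
  spectrum(wl, counts, darks[[1]]$integration_time_ms, kind = "dark")
}

#' Subtract the mean dark spectrum from a measurement
#'
#' Channel-wise subtraction with negative results clipped to zero (counts are
#' physical).
#'
#' @param spec Measured `spectrum`.
#' @param dark Mean dark `spectrum` on the same wavelength axis.
#' @return Dark-corrected `spectrum`.
#' @export
subtract_dark <- function(spec, dark) {
  stopifnot(inherits(spec, "spectrum"), inherits(dark, "spectrum"))
  if (!identical(spec$wavelengths_nm, dark$wavelengths_nm))
    stop("spectra have mismatched wavelength axes")
  out <- spec
  out$counts <- pmax(spec$counts - dark$counts, 0)
  out
}

#' Mask a wavelength band
#'
#' Flags channels inside `[lo, hi]` nm as masked so downstream peak and index
#' extraction ignores them. The default band 400-660 nm carries residual
#' culture-room light and imperfectly blocked excitation light. Idempotent.
#'
#' @param spec A `spectrum`.
#' @param lo,hi Band limits in nm (`lo <= hi`).
#' @return The spectrum with an updated `masked` flag vector.
#' @export
mask_band <- function(spec, lo = 400, hi = 660) {
  stopifnot(inherits(spec, "spectrum"))
  if (lo > hi) stop("lo must be <= hi")
  spec$masked <- spec$masked | (spec$wavelengths_nm >= lo & spec$wavelengths_nm <= hi)
  spec
}

#' Chlorophyll fluorescence summary
#'
#' Reads the fluorescence emission intensities near the two chlorophyll
#' maxima: F690 (mostly photosystem II) and F730/F740 (PSII and PSI), using
#' the channel nearest each nominal wavelength (no interpolation; the sensor
#' resolution is ~15 nm). The chlorophyll-content index F690/F740 is
#' reported, and each band is checked for being a local maximum within
#' +-10 nm as a quality flag.
#'
#' @param spec A dark-corrected `spectrum` (masked channels are ignored for
#'   the local-maximum check).
#' @return List of class `fluorescence_result`: `F690`, `F730`, `F740`,
#'   `ratio_F690_F740` (`NA` when F740 is 0), and logical quality flags
#'   `local_max_690`, `local_max_740`.
#' @export
fluorescence_summary <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  wl <- spec$wavelengths_nm
  value_at <- function(target) {
    i <- which.min(abs(wl - target))
    spec$counts[i]
  }
  # quality flag: the band hosts a peak if the nominal channel is within 5%
  # of the window maximum (the sampled apex may sit one channel off)
  local_max <- function(target) {
    i <- which.min(abs(wl - target))
    win <- which(abs(wl - wl[i]) <= 10 & !spec$masked)
    length(win) > 0 && spec$counts[i] >= 0.95 * max(spec$counts[win])
  }
  f690 <- value_at(690); f730 <- value_at(730); f740 <- value_at(740)
  structure(list(F690 = f690, F730 = f730, F740 = f740,
                 ratio_F690_F740 = if (f740 > 0) f690 / f740 else NA_real_,
                 local_max_690 = local_max(690),
                 local_max_740 = local_max(740)),
            class = "fluorescence_result")
}

#' Read and write spectra as CSV
#'
#' Plain CSV with columns `wavelength_nm`, `counts` and a `#`-prefixed
#' metadata header (`integration_time_ms`, `kind`).
#'
#' @param spec A `spectrum`.
#' @param path File path.
#' @return `write_spectrum_csv` returns `path` invisibly; `read_spectrum_csv`
#'   a `spectrum`.
#' @export
write_spectrum_csv <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# integration_time_ms=%g", spec$integration_time_ms),
               sprintf("# kind=%s", spec$kind)), con)
  utils::write.csv(data.frame(wavelength_nm = spec$wavelengths_nm,
                              counts = spec$counts),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^# *", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# *", key, "="), "", m[1]) else default
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, invert = TRUE,
                                            value = TRUE)))
  spectrum(df$wavelength_nm, df$counts,
           integration_time_ms = as.numeric(get("integration_time_ms", "300")),
           kind = get("kind", "fluorescence"))
}
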