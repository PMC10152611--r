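#' Haze index of a vessel sealing material
#'
#' Ratio of diffuse to total transmittance, expressed in percent after
#' subtracting the instrument's own relative scattered transmittance
#' (ASTM D1003 convention). High haze means strong light scattering and a
#' blurred view of the cultures through the sealing.
#'
#' @param total_pct Total transmittance in percent (> 0).
#' @param diffuse_pct Diffuse transmittance in percent (>= 0).
#' @param system_scatter_fraction Relative scattered transmittance of the
#'   measuring system itself (fraction, default 0; instrument-specific).
#' @return Haze index in percent, clipped below at 0. Vectorised.
#' @examples
#' haze_index(92.6, 1.4)  # PVC foil
#' haze_index(91.2, 0.5)  # polystyrene Petri dish
#' @export
haze_index <- function(total_pct, diffuse_pct, system_scatter_fraction = 0) {
  if (any(!is.finite(total_pct)) || any(total_pct <= 0))
    stop("total transmittance must be positive")
  if (any(diffuse_pct < 0, na.rm = TRUE))
    stop("diffuse transmittance must be nonnegative")
  pmax((diffuse_pct / total_pct - system_scatter_fraction) * 100, 0)
}

#' Band-averaged total transmittance
#'
#' Arithmetic mean of the total transmittance over all sampled wavelengths
#' inside a band, e.g. VIS 380-780 nm or the thermal window 8000-14000 nm.
#'
#' @param spec Data frame with columns `wavelength_nm` and `total_pct`
#'   (a transmittance spectrum; `diffuse_pct` optional).
#' @param lo_nm,hi_nm Band limits (inclusive).
#' @return Mean transmittance in percent.
#' @export
band_mean_transmittance <- function(spec, lo_nm, hi_nm) {
  stopifnot(is.data.frame(spec),
            all(c("wavelength_nm", "total_pct") %in% names(spec)),
            lo_nm <= hi_nm)
  sel <- spec$wavelength_nm >= lo_nm & spec$wavelength_nm <= hi_nm
  if (!any(sel)) stop("band contains no sampled wavelengths")
  mean(spec$total_pct[sel])
}

#' Read a transmittance spectrum from CSV
#'
#' Expects columns `wavelength_nm`, `total_pct` and optionally `diffuse_pct`;
#' rows where diffuse exceeds total are physically impossible and flagged.
#'
#' @param path CSV file path.
#' @return Data frame with an added logical column `flag_diffuse_gt_total`
#'   when diffuse transmittance is present.
#' @export
read_transmittance_csv <- function(path) {
  spec <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "total_pct") %in% names(spec)))
  if (is.unsorted(spec$wavelength_nm)) spec <- spec[order(spec$wavelength_nm), ]
  if ("diffuse_pct" %in% names(spec))
    spec$flag_diffuse_gt_total <- spec$diffuse_pct > spec$total_pct
  spec
}
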