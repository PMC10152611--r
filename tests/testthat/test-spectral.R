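test_that("wavelength mapping spans 340-850 nm and rounds half-up", {
  wl <- map_wavelengths(0:287)
  expect_equal(wl[1], 340)
  expect_equal(wl[288], 849)
  expect_true(!is.unsorted(wl))
  # rounding convention: .5 goes up
  expect_equal(map_wavelengths(0, c(689.5, 0, 0, 0, 0, 0)), 690)
  # quadratic term exercises the full polynomial
  expect_equal(map_wavelengths(10, c(340, 1.7, 0.001, 0, 0, 0)),
               round(340 + 17 + 0.1))
  # a constant map cannot be a wavelength axis
  expect_warning(map_wavelengths(0:10, c(500, 0, 0, 0, 0, 0)), "monotone")
  expect_warning(map_wavelengths(0:10, c(500, -1, 0, 0, 0, 0)), "monotone")
})

test_that("dark averaging and subtraction behave channel-wise with clipping", {
  wl <- map_wavelengths(0:287)
  d1 <- spectrum(wl, rep(10, 288), kind = "dark")
  d2 <- spectrum(wl, rep(20, 288), kind = "dark")
  md <- mean_dark(list(d1, d2))
  expect_equal(md$counts, rep(15, 288))
  expect_equal(mean_dark(list(d1))$counts, d1$counts)
  expect_error(mean_dark(list()), "at least one")
  # spectrum equal to its dark: zeros
  expect_equal(subtract_dark(md, md)$counts, rep(0, 288))
  # clip: dark larger than signal
  lo <- spectrum(wl, rep(12, 288))
  expect_equal(subtract_dark(lo, md)$counts, rep(0, 288))
  # peak + dark recovered
  peak <- 100 * exp(-(wl - 690)^2 / 450)
  sp <- spectrum(wl, peak + 15)
  expect_equal(subtract_dark(sp, md)$counts, peak, tolerance = 1e-12)
})

test_that("band masking is idempotent and guards its limits", {
  sp <- spectrum(map_wavelengths(0:287), rep(5, 288))
  m1 <- mask_band(sp)
  expect_true(all(m1$masked[m1$wavelengths_nm >= 400 & m1$wavelengths_nm <= 660]))
  expect_false(any(m1$masked[m1$wavelengths_nm > 660]))
  expect_identical(mask_band(m1)$masked, m1$masked)
  expect_error(mask_band(sp, 700, 500), "lo")
})

test_that("fluorescence summary reads the chlorophyll peaks and their ratio", {
  wl <- map_wavelengths(0:287)
  mk <- function(a690, a735) {
    spectrum(wl, a690 * exp(-(wl - 690)^2 / (2 * 15^2)) +
                 a735 * exp(-(wl - 735)^2 / (2 * 15^2)))
  }
  fl <- fluorescence_summary(mk(100, 100))
  # equal amplitudes: F740 sits 5 nm off the 735 peak, so the ratio is
  # slightly above 1 by the Gaussian falloff
  expect_equal(fl$ratio_F690_F740, 1, tolerance = 0.1)
  expect_true(fl$local_max_690)
  # zero spectrum: everything zero, ratio undefined
  fl0 <- fluorescence_summary(spectrum(wl, rep(0, 288)))
  expect_equal(fl0$F690, 0)
  expect_true(is.na(fl0$ratio_F690_F740))
  # lone 690 peak: huge ratio, 740 not a local maximum
  fl1 <- fluorescence_summary(mk(200, 0))
  expect_gt(fl1$ratio_F690_F740, 5)
  expect_false(fl1$local_max_740)
})

test_that("summary is invariant to an offset removed by dark subtraction", {
  wl <- map_wavelengths(0:287)
  base <- 120 * exp(-(wl - 690)^2 / 450) + 90 * exp(-(wl - 735)^2 / 450)
  dark <- spectrum(wl, rep(40, 288), kind = "dark")
  sp_raw <- spectrum(wl, base + 40)
  fl_a <- fluorescence_summary(subtract_dark(sp_raw, dark))
  fl_b <- fluorescence_summary(spectrum(wl, base))
  expect_equal(fl_a$ratio_F690_F740, fl_b$ratio_F690_F740, tolerance = 1e-9)
})

test_that("spectra survive a CSV round trip with metadata", {
  sp <- spectrum(map_wavelengths(0:287), round(stats::runif(288, 0, 500)),
                 integration_time_ms = 300, kind = "fluorescence")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$counts, sp$counts)
  expect_equal(back$wavelengths_nm, sp$wavelengths_nm)
  expect_equal(back$integration_time_ms, 300)
  expect_equal(back$kind, "fluorescence")
})
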