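test_that("spectra_set enforces grid and metadata invariants", {
  expect_error(spectra_set(matrix(0.5, 1, 2), c(600, 600)), "increasing")
  expect_error(spectra_set(matrix(0.5, 1, 1), 300), "\\[350, 2500\\]")
  expect_error(spectra_set(matrix(1.7, 1, 1), 500), "out of \\[0, 1\\]")
  expect_error(
    spectra_set(matrix(0.5, 1, 1), 500,
                data.frame(sample_id = "a", treatment = "w9")),
    "treatment")
  expect_error(
    spectra_set(matrix(0.5, 1, 1), 500,
                data.frame(sample_id = "a", lwc = 120)),
    "lwc")
})

test_that("CSV round trip preserves order, metadata and reflectance", {
  ss <- toy_spectra(n = 3L, lwc = c(70, 75, 80))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ss, path)
  back <- read_spectra_csv(path)
  expect_identical(back$wavelengths, ss$wavelengths)
  expect_identical(back$meta$sample_id, ss$meta$sample_id)
  expect_equal(back$reflectance, ss$reflectance, tolerance = 1e-9)

  # percent-scale output: stored 0.4345 is written as 43.45
  one <- spectra_set(matrix(0.4345, 1, 1), 820)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(one, p2, reflectance_scale = "percent")
  expect_match(readLines(p2)[2], "43.45")
  expect_equal(unname(read_spectra_csv(p2, "percent")$reflectance[1, 1]),
               0.4345)
})

test_that("reading shuffled wavelength columns matches the sorted file", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,wl_352,wl_350,wl_351",
               "a,0.3,0.1,0.2",
               "b,0.6,0.4,0.5"), path)
  ss <- read_spectra_csv(path)
  expect_identical(ss$wavelengths, 350:352)
  expect_equal(ss$reflectance[1, ], c(wl_350 = 0.1, wl_351 = 0.2,
                                      wl_352 = 0.3))
})

test_that("CSV reader flags bad files", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,x", "a,1"), p)
  expect_error(read_spectra_csv(p), "wavelength columns")
  writeLines(c("sample_id,wl_500", "a,1.7"), p)
  expect_error(read_spectra_csv(p), "out of \\[0, 1\\]")
})

test_that("empty spectra set survives a round trip", {
  ss <- spectra_set(matrix(numeric(0), 0, 3), c(500, 501, 502))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ss, path)
  back <- read_spectra_csv(path)
  expect_identical(back$wavelengths, ss$wavelengths)
  expect_equal(n_samples(back), 0L)
})

test_that("atmospheric mask retains 1901 of 2151 bands and is idempotent", {
  refl <- matrix(0.5, 2, 2151)
  ss <- spectra_set(refl, default_grid())
  masked <- apply_atmospheric_mask(ss)
  expect_length(masked$wavelengths, 1901L)
  # lower endpoints retained, interiors dropped
  expect_true(all(c(1350L, 1800L, 2450L) %in% masked$wavelengths))
  expect_false(any(c(1351L, 1400L, 1950L, 2500L) %in% masked$wavelengths))
  again <- apply_atmospheric_mask(masked)
  expect_identical(again$wavelengths, masked$wavelengths)
  expect_identical(again$reflectance, masked$reflectance)
})

test_that("masking preserves retained reflectance exactly and can degenerate", {
  ss <- toy_spectra(n = 2L)
  masked <- apply_atmospheric_mask(ss, band_mask(list(c(550, 650))))
  kept <- setdiff(ss$wavelengths, c(600L))
  expect_identical(masked$wavelengths, kept)
  expect_identical(masked$reflectance,
                   ss$reflectance[, paste0("wl_", kept)])
  expect_identical(ss$wavelengths, c(500L, 600L, 700L, 800L, 900L)) # untouched
  expect_error(apply_atmospheric_mask(ss, band_mask(list(c(349, 2500)))),
               "every band")
  empty <- band_mask(list())
  expect_identical(apply_atmospheric_mask(ss, empty)$wavelengths,
                   ss$wavelengths)
})

test_that("lwc_from_mass follows the drying-method formula", {
  expect_equal(lwc_from_mass(5.00, 1.06), 78.8)
  expect_equal(lwc_from_mass(2.0, 0.5), 75.0)
  expect_equal(lwc_from_mass(3.3, 3.3), 0)
  expect_error(lwc_from_mass(1, 2), "exceed")
  expect_error(lwc_from_mass(-1, 0.5), "positive")
  # strictly decreasing in dry mass at fixed fresh mass
  dm <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(lwc_from_mass(5, dm)) < 0))
})

test_that("first derivative matches closed forms", {
  wl <- 500:520
  # constant spectrum -> zero everywhere
  ss <- spectra_set(matrix(0.3, 1, length(wl)), wl)
  expect_true(all(first_derivative(ss)$derivative == 0))
  # linear ramp R = a*wl + b -> derivative a at every band (incl. one-sided)
  a <- 4e-4
  ramp <- a * wl + 0.01
  ss <- spectra_set(matrix(ramp, 1), wl)
  expect_equal(unname(first_derivative(ss)$derivative[1, ]),
               rep(a, length(wl)))
  # sin(wl/100)/4 + 0.5 sampled at 1 nm vs the analytic derivative
  wl2 <- 350:2500
  ss2 <- spectra_set(matrix(sin(wl2 / 100) / 4 + 0.5, 1), wl2)
  d <- first_derivative(ss2)$derivative[1, ]
  analytic <- cos(wl2 / 100) / 400
  interior <- 2:(length(wl2) - 1L)
  expect_lt(max(abs(d[interior] - analytic[interior])), 1e-4)
})

test_that("derivative differences never span a mask gap", {
  ss <- spectra_set(matrix(seq(0.1, 0.9, length.out = 21), 1), 500:520)
  masked <- apply_atmospheric_mask(ss, band_mask(list(c(505, 510))))
  d <- first_derivative(masked)
  # bands adjacent to the gap use one-sided differences within their segment
  expect_false(anyNA(d$derivative))
  seg <- lwcspectra:::grid_segments(masked$wavelengths)
  expect_equal(length(unique(seg)), 2L)
})

test_that("thin_bands keeps every k-th band", {
  ss <- toy_spectra()
  th <- thin_bands(ss, 2L)
  expect_identical(th$wavelengths, ss$wavelengths[c(1, 3, 5)])
  expect_identical(th$reflectance, ss$reflectance[, c(1, 3, 5)])
})
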