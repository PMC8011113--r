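test_that("correlation curve matches a per-band oracle loop", {
  wl <- c(500L, 600L, 700L, 800L)
  refl <- withr::with_seed(51, matrix(runif(40, 0.1, 0.9), nrow = 10))
  lwc <- withr::with_seed(52, runif(10, 55, 90))
  # tie two bands to lwc exactly (affine, opposite signs)
  refl[, 1] <- (lwc - 50) / 100
  refl[, 2] <- (140 - lwc) / 100
  ss <- spectra_set(refl, wl)
  cc <- correlation_curve(ss, lwc)
  expect_equal(cc$r[1], 1.0)
  expect_equal(cc$r[2], -1.0)
  oracle <- vapply(seq_along(wl),
                   function(j) cor(refl[, j], lwc), 0)
  expect_equal(cc$r, oracle, tolerance = 1e-12)
  # zero-variance band is flagged missing
  refl2 <- refl; refl2[, 3] <- 0.5
  cc2 <- correlation_curve(spectra_set(refl2, wl), lwc)
  expect_true(is.na(cc2$r[3]))
})

test_that("local extrema detect canonical shapes", {
  ex <- local_extrema(c(0, 1, 0), window = 1L)
  expect_equal(ex$peaks, 2L)
  expect_length(ex$troughs, 0L)
  mono <- local_extrema(seq(0, 1, length.out = 20), window = 3L)
  expect_length(mono$peaks, 0L)
  expect_length(mono$troughs, 0L)
  # plateaus report their leftmost index
  plat <- local_extrema(c(0, 1, 1, 0, 0), window = 1L)
  expect_equal(plat$peaks, 2L)
})

test_that("extrema of two Gaussians on a trend land within one index", {
  x <- seq_len(300)
  f <- function(x) exp(-(x - 90)^2 / 200) + 0.8 * exp(-(x - 210)^2 / 300) +
    0.0005 * x
  v <- f(x)
  # numerically located maxima of the closed form on a fine grid
  fine <- seq(1, 300, by = 0.01)
  vf <- f(fine)
  peaks_true <- c(fine[which.max(vf[fine < 150])],
                  fine[fine >= 150][which.max(vf[fine >= 150])])
  ex <- local_extrema(v, window = 10L)
  expect_length(ex$peaks, 2L)
  expect_true(all(abs(ex$peaks - peaks_true) <= 1))
})

test_that("extrema are shift-invariant and sign-symmetric", {
  v <- withr::with_seed(61, cumsum(rnorm(120))) # smooth-ish random walk
  w <- 5L
  ex <- local_extrema(v, window = w)
  ex_shift <- local_extrema(v + 100, window = w)
  expect_identical(ex, ex_shift)
  ex_neg <- local_extrema(-v, window = w)
  expect_identical(ex$peaks, ex_neg$troughs)
  expect_identical(ex$troughs, ex_neg$peaks)
})

test_that("extrema never straddle a mask gap", {
  wl <- c(500:540, 600:640)
  # ramp up to the gap, ramp down after: without segmenting, index 41
  # would be a peak of the concatenated vector
  v <- c(seq(0, 1, length.out = 41), seq(0.9, 0, length.out = 41))
  ex <- local_extrema(v, wavelengths = wl, window = 10L)
  expect_length(ex$peaks, 0L)
  expect_length(ex$troughs, 0L)
})

test_that("CA selection seeds from |r| extrema and hits the target count", {
  # two bumps and the saddle between them: exactly three interior extrema
  wl <- 400:499
  r <- exp(-(wl - 430)^2 / (2 * 10^2)) + exp(-(wl - 470)^2 / (2 * 10^2))
  curve <- structure(list(wavelengths = wl, r = r),
                     class = "correlation_curve")
  ex <- local_extrema(abs(r), wl, window = 5L)
  expect_length(c(ex$peaks, ex$troughs), 3L)
  sel3 <- select_bands_ca(curve, n_target = 3L, window = 5L)
  expect_setequal(sel3$wavelengths, wl[sort(c(ex$peaks, ex$troughs))])
  # top-up path: more bands than extrema, respecting separation
  sel10 <- select_bands_ca(curve, n_target = 10L, window = 5L,
                           min_separation = 2L)
  expect_length(sel10$wavelengths, 10L)
  expect_false(is.unsorted(sel10$wavelengths))
  expect_true(all(sel3$wavelengths %in% sel10$wavelengths))
  # determinism
  expect_identical(sel10, select_bands_ca(curve, n_target = 10L,
                                          window = 5L, min_separation = 2L))
  expect_error(select_bands_ca(curve, n_target = 200L), "exceeds")
})

test_that("PLS1 recovers a rank-1 signal and matches OLS at full rank", {
  # rank-1: y is a noise-free linear function of one spectral direction
  n <- 30L; p <- 40L
  dir <- withr::with_seed(71, rnorm(p))
  scores <- withr::with_seed(72, rnorm(n))
  X <- outer(scores, dir) + 0.3
  y <- 2 * scores + 70
  fit <- lwcspectra:::pls1_fit(X, y, 3L)
  w1 <- fit$weights[, 1]
  cosim <- abs(sum(w1 * dir)) / sqrt(sum(w1^2) * sum(dir^2))
  expect_gt(cosim, 0.999)
  expect_lt(rmse(y, lwcspectra:::pls1_predict(fit, X, 1L)), 1e-6)
  rmsep <- lwcspectra:::pls1_rmsep(X, y, 3L, cv = "loo")
  expect_lt(rmsep[1], 1e-6)

  # full rank: all components reproduce OLS predictions
  X2 <- withr::with_seed(73, matrix(rnorm(20 * 8), 20))
  y2 <- withr::with_seed(74, rnorm(20, 75, 5))
  fit2 <- lwcspectra:::pls1_fit(X2, y2, 8L)
  ols <- unname(fitted(lm(y2 ~ X2)))
  expect_equal(lwcspectra:::pls1_predict(fit2, X2, 8L), ols,
               tolerance = 1e-8)
})

test_that("loading curves report a sane variance partition", {
  d <- default_sim_thinned()
  cal <- year_split(d$thinned)$calibration
  ld <- fit_pls_loadings(cal, max_components = 6L)
  expect_true(all(ld$explained_pct >= 0))
  expect_lte(sum(ld$explained_pct), 100 + 1e-8)
  expect_equal(nrow(ld$weights), length(ld$wavelengths))
  expect_length(ld$rmsep_by_components, ld$ncomp)
  # sign convention: largest-magnitude weight of each component positive
  for (a in seq_len(ld$ncomp)) {
    w <- ld$weights[, a]
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("x-Lw selects the union of loading-weight extrema", {
  wl <- 400:699
  bump <- exp(-(wl - 550)^2 / (2 * 20^2))
  lc1 <- structure(list(wavelengths = wl,
                        weights = cbind(bump),
                        explained_pct = 90, rmsep_by_components = 1,
                        ncomp = 1L),
                   class = "loading_curves")
  sel <- select_bands_xlw(lc1, n_components = 1L, window = 10L)
  expect_identical(sel$wavelengths, 550L)

  # two components with disjoint extrema sets (peaks plus the saddles
  # between neighbouring bumps) of sizes 3 and 5
  tri <- function(centers) {
    rowSums(vapply(centers,
                   function(c0) exp(-(wl - c0)^2 / (2 * 12^2)),
                   numeric(length(wl))))
  }
  lc2 <- lc1
  lc2$weights <- cbind(tri(c(430, 480)), tri(c(560, 610, 660)))
  lc2$ncomp <- 2L
  sel2 <- select_bands_xlw(lc2, n_components = 2L, window = 10L)
  expect_length(sel2$wavelengths, 8L)
  expect_setequal(sel2$wavelengths,
                  c(430L, 455L, 480L, 560L, 585L, 610L, 635L, 660L))
})

test_that("screening methods are deterministic and stay on the grid", {
  d <- default_sim_thinned()
  cal <- year_split(d$thinned)$calibration
  curve <- correlation_curve(cal)
  ca <- select_bands_ca(curve, n_target = 100L)
  expect_length(ca$wavelengths, 100L)
  ld <- fit_pls_loadings(cal, max_components = 10L)
  xlw <- select_bands_xlw(ld, n_components = 3L)
  expect_true(all(ca$wavelengths %in% d$thinned$wavelengths))
  expect_true(all(xlw$wavelengths %in% d$thinned$wavelengths))
  expect_identical(xlw$wavelengths,
                   select_bands_xlw(ld, n_components = 3L)$wavelengths)
  # the compact x-Lw set is smaller than the CA set
  expect_lt(length(xlw$wavelengths), length(ca$wavelengths))
})

test_that("top CA band coincides with the brute-force |r| maximum", {
  cfg <- synthetic_config(noise_sd = 0, residual_sd = 0)
  sim <- simulate_dataset(cfg)
  masked <- thin_bands(apply_atmospheric_mask(sim$spectra), 4L)
  curve <- correlation_curve(masked)
  ca <- select_bands_ca(curve, n_target = 50L)
  brute_best <- masked$wavelengths[which.max(abs(curve$r))]
  sel_r <- abs(curve$r[match(ca$wavelengths, masked$wavelengths)])
  expect_equal(ca$wavelengths[which.max(sel_r)], brute_best)
  expect_equal(band_reduction_percent(100, 28), 72)
})
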