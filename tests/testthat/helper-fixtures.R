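# Shared fixtures: all built in code, no files on disk.

# random spectra set on an arbitrary small grid
toy_spectra <- function(n = 6L, wavelengths = c(500L, 600L, 700L, 800L, 900L),
                        seed = 42L, lwc = NULL) {
  refl <- withr::with_seed(seed,
    matrix(runif(n * length(wavelengths), 0.05, 0.95), nrow = n))
  meta <- data.frame(sample_id = paste0("s", seq_len(n)),
                     stringsAsFactors = FALSE)
  if (!is.null(lwc)) meta$lwc <- lwc
  spectra_set(refl, wavelengths, meta)
}

# naive per-pair oracle for the two-band R2 map: recomputes every index and
# every correlation independently of the vectorized implementation
brute_force_pair_r2 <- function(spectra, lwc, kind) {
  wl <- spectra$wavelengths
  p <- length(wl)
  M <- matrix(NA_real_, p, p, dimnames = list(wl, wl))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      r1 <- spectra$reflectance[, i]
      r2 <- spectra$reflectance[, j]
      v <- switch(kind,
                  normalized = ifelse(r1 + r2 == 0, NA, (r1 - r2) / (r1 + r2)),
                  ratio = ifelse(r2 == 0, NA, r1 / r2),
                  difference = r1 - r2)
      ok <- !is.na(v) & is.finite(lwc)
      if (sum(ok) < 3L) next
      if (stats::var(v[ok]) == 0) next
      M[i, j] <- stats::cor(v[ok], lwc[ok])^2
    }
  }
  M
}

# small default-design simulation shared by slower tests (thinned grid)
default_sim_thinned <- local({
  cache <- NULL
  function(stride = 4L) {
    if (is.null(cache)) {
      sim <- simulate_dataset(synthetic_config())
      cache <<- list(sim = sim,
                     masked = apply_atmospheric_mask(sim$spectra))
    }
    list(sim = cache$sim, thinned = thin_bands(cache$masked, stride))
  }
})
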