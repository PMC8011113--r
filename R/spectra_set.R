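#' Construct a spectra set
#'
#' A `spectra_set` bundles a samples-by-wavelengths reflectance matrix with
#' per-sample metadata. Reflectance is always stored as a unitless fraction
#' in \[0, 1\]; percent appears only at I/O boundaries, so difference-type
#' indices and derivatives are never exposed to a silent factor-of-100
#' inconsistency.
#'
#' @param reflectance numeric matrix, `n_samples x n_bands`, values in
#'   \[0, 1\].
#' @param wavelengths integer wavelengths in nanometres, strictly increasing,
#'   all within \[350, 2500\]; length must equal `ncol(reflectance)`.
#' @param meta data frame with one row per sample. Recognised columns:
#'   `sample_id`, `year`, `cultivar`, `treatment` (one of `"w0"`, `"w1"`,
#'   `"w2"`), `date_index` (1-6) and `lwc` (percent in (0, 100\], may be
#'   `NA`). Missing columns are filled with `NA`.
#' @return An object of class `spectra_set`: a list with elements
#'   `wavelengths`, `reflectance` and `meta`.
#' @examples
#' wl <- 350:360
#' refl <- matrix(runif(2 * length(wl), 0.1, 0.5), nrow = 2)
#' ss <- spectra_set(refl, wl, data.frame(sample_id = c("a", "b")))
#' ss
#' @export
spectra_set <- function(reflectance, wavelengths,
                        meta = data.frame(sample_id = character(0))) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  wavelengths <- as.integer(wavelengths)
  validate_wavelength_grid(wavelengths)
  if (ncol(reflectance) != length(wavelengths)) {
    stop("reflectance has ", ncol(reflectance),
         " columns but the wavelength grid has ", length(wavelengths),
         " entries", call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) == 0L && nrow(reflectance) > 0L) {
    meta <- data.frame(sample_id = paste0("s", seq_len(nrow(reflectance))),
                       stringsAsFactors = FALSE)
  }
  if (nrow(meta) != nrow(reflectance)) {
    stop("meta has ", nrow(meta), " rows but reflectance has ",
         nrow(reflectance), call. = FALSE)
  }
  for (col in setdiff(meta_columns(), names(meta))) {
    meta[[col]] <- rep(NA, nrow(meta))
  }
  meta <- meta[meta_columns()]
  validate_meta(meta)
  check_reflectance_range(reflectance, wavelengths, meta$sample_id)
  dimnames(reflectance) <- list(NULL, paste0("wl_", wavelengths))
  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 meta = meta),
            class = "spectra_set")
}

meta_columns <- function() {
  c("sample_id", "year", "cultivar", "treatment", "date_index", "lwc")
}

validate_wavelength_grid <- function(wavelengths) {
  if (length(wavelengths) == 0L) {
    stop("wavelength grid is empty", call. = FALSE)
  }
  if (anyNA(wavelengths)) stop("wavelengths contain NA", call. = FALSE)
  if (any(diff(wavelengths) <= 0L)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (min(wavelengths) < 350L || max(wavelengths) > 2500L) {
    stop("wavelengths must lie within [350, 2500] nm", call. = FALSE)
  }
  invisible(wavelengths)
}

validate_meta <- function(meta) {
  tr <- meta$treatment[!is.na(meta$treatment)]
  if (length(tr) && !all(tr %in% c("w0", "w1", "w2"))) {
    stop("treatment must be one of w0, w1, w2; got: ",
         paste(unique(setdiff(tr, c("w0", "w1", "w2"))), collapse = ", "),
         call. = FALSE)
  }
  di <- meta$date_index[!is.na(meta$date_index)]
  if (length(di) && !all(di %in% 1:6)) {
    stop("date_index must be in 1..6", call. = FALSE)
  }
  lwc <- meta$lwc[!is.na(meta$lwc)]
  if (length(lwc) && (any(lwc <= 0) || any(lwc > 100))) {
    stop("lwc must be a percent in (0, 100]", call. = FALSE)
  }
  invisible(meta)
}

check_reflectance_range <- function(reflectance, wavelengths, ids) {
  bad <- which(reflectance < 0 | reflectance > 1 | is.na(reflectance),
               arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    id <- if (length(ids) >= i && !is.na(ids[i])) ids[i] else paste0("row ", i)
    stop("reflectance out of [0, 1] for sample '", id, "' at ",
         wavelengths[j], " nm (value ", format(reflectance[i, j]), ")",
         call. = FALSE)
  }
  invisible(reflectance)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", nrow(x$reflectance), "samples x",
      length(x$wavelengths), "bands (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm )\n")
  n_lwc <- sum(!is.na(x$meta$lwc))
  cat("  LWC available for", n_lwc, "samples\n")
  invisible(x)
}

#' Default 1-nm wavelength grid
#'
#' The full-resolution grid of a field spectroradiometer resampled to 1 nm:
#' 350 to 2500 nm, 2151 bands.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
default_grid <- function() 350:2500

#' Number of samples in a spectra set
#' @param spectra a [spectra_set()].
#' @return Integer sample count.
#' @export
n_samples <- function(spectra) nrow(spectra$reflectance)

#' Extract reflectance at given wavelengths
#'
#' Lookup is by exact integer match on the grid; the package never
#' interpolates between bands.
#'
#' @param spectra a [spectra_set()].
#' @param wavelengths integer wavelengths (nm) to extract.
#' @return Numeric matrix `n_samples x length(wavelengths)`.
#' @export
band <- function(spectra, wavelengths) {
  idx <- match(as.integer(wavelengths), spectra$wavelengths)
  if (anyNA(idx)) {
    stop("wavelength(s) not on the grid (masked or absent): ",
         paste(wavelengths[is.na(idx)], collapse = ", "), " nm",
         call. = FALSE)
  }
  spectra$reflectance[, idx, drop = FALSE]
}

#' Thin a spectra set to every k-th band
#'
#' Coarse-grid subsampling for exploratory runs; keeps the first band of
#' the grid and every `stride`-th band after it.
#'
#' @param spectra a [spectra_set()].
#' @param stride keep every `stride`-th band (default 4).
#' @return A `spectra_set` on the thinned grid.
#' @export
thin_bands <- function(spectra, stride = 4L) {
  stopifnot(inherits(spectra, "spectra_set"), stride >= 1L)
  keep <- seq(1L, length(spectra$wavelengths), by = as.integer(stride))
  out <- spectra
  out$wavelengths <- spectra$wavelengths[keep]
  out$reflectance <- spectra$reflectance[, keep, drop = FALSE]
  out
}

#' Leaf water content from fresh and dry mass
#'
#' LWC is the water mass fraction of fresh leaf mass, determined by the
#' oven-drying method: `(m_f - m_d) / m_f * 100`.
#'
#' @param fresh_mass fresh leaf mass in grams, > 0.
#' @param dry_mass oven-dry leaf mass in grams, in (0, `fresh_mass`\].
#' @return LWC in percent. Vectorised over both arguments.
#' @examples
#' lwc_from_mass(5.00, 1.06) # 78.8
#' @export
lwc_from_mass <- function(fresh_mass, dry_mass) {
  if (any(fresh_mass <= 0) || any(dry_mass <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  if (any(dry_mass > fresh_mass)) {
    stop("dry_mass cannot exceed fresh_mass", call. = FALSE)
  }
  (fresh_mass - dry_mass) / fresh_mass * 100
}
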