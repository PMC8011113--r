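#' Atmospheric exclusion windows
#'
#' Field reflectance near the strong atmospheric water-vapour bands is too
#' noisy to use. The default mask excludes 1350-1400, 1800-1950 and
#' 2450-2500 nm. An excluded interval `(a, b]` drops wavelengths `a < w <= b`
#' (the lower endpoint is retained); with the three default windows on the
#' 2151-band grid this leaves exactly 1901 bands.
#'
#' @param intervals numeric matrix or list of `c(low, high)` pairs in nm.
#' @return A `band_mask` object.
#' @examples
#' default_band_mask()
#' @export
band_mask <- function(intervals) {
  if (is.matrix(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  }
  intervals <- lapply(intervals, as.numeric)
  for (iv in intervals) {
    if (length(iv) != 2L || iv[1] >= iv[2]) {
      stop("each interval must be c(low, high) with low < high", call. = FALSE)
    }
  }
  if (length(intervals) > 1L) {
    o <- order(vapply(intervals, `[`, 0, 1L))
    intervals <- intervals[o]
    lows <- vapply(intervals, `[`, 0, 1L)
    highs <- vapply(intervals, `[`, 0, 2L)
    if (any(lows[-1L] < highs[-length(highs)])) {
      stop("mask intervals must not overlap", call. = FALSE)
    }
  }
  structure(list(excluded = intervals), class = "band_mask")
}

#' @rdname band_mask
#' @export
default_band_mask <- function() {
  band_mask(list(c(1350, 1400), c(1800, 1950), c(2450, 2500)))
}

#' @export
print.band_mask <- function(x, ...) {
  cat("band_mask with", length(x$excluded), "excluded window(s):\n")
  for (iv in x$excluded) cat("  (", iv[1], ",", iv[2], "] nm\n")
  invisible(x)
}

#' Drop atmospheric-window bands from a spectra set
#'
#' Removes every wavelength falling inside an excluded interval under the
#' half-open convention `(low, high]`. Masking is idempotent and the
#' reflectance of retained bands is untouched.
#'
#' @param spectra a [spectra_set()].
#' @param mask a [band_mask()]; defaults to the three atmospheric windows.
#' @return A new `spectra_set` on the reduced grid.
#' @examples
#' ss <- simulate_dataset(synthetic_config(seed = 1))$spectra
#' length(apply_atmospheric_mask(ss)$wavelengths) # 1901
#' @export
apply_atmospheric_mask <- function(spectra, mask = default_band_mask()) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(mask, "band_mask"))
  keep <- rep(TRUE, length(spectra$wavelengths))
  for (iv in mask$excluded) {
    keep <- keep & !(spectra$wavelengths > iv[1] & spectra$wavelengths <= iv[2])
  }
  if (!any(keep)) {
    stop("mask removes every band on the grid", call. = FALSE)
  }
  out <- spectra
  out$wavelengths <- spectra$wavelengths[keep]
  out$reflectance <- spectra$reflectance[, keep, drop = FALSE]
  out
}

#' Contiguous segments of a (possibly masked) grid
#'
#' Splits the wavelength grid at every gap larger than its native step
#' (the smallest spacing present, 1 nm on the full grid). Extremum
#' detection and derivatives never cross these gaps.
#'
#' @param wavelengths integer wavelengths in nm, strictly increasing.
#' @return Integer vector of segment ids, one per wavelength.
#' @keywords internal
grid_segments <- function(wavelengths) {
  if (length(wavelengths) == 0L) return(integer(0))
  if (length(wavelengths) == 1L) return(1L)
  step <- min(diff(wavelengths))
  c(0L, cumsum(diff(wavelengths) > step)) + 1L
}

#' First-derivative spectra
#'
#' Central differences `(R(w + d) - R(w - d)) / (2 d)` on the local grid step
#' `d`, with one-sided differences at segment endpoints. Mask gaps split the
#' grid into independent segments, so no difference spans an exclusion
#' window. Units: reflectance fraction per nm.
#'
#' @param spectra a [spectra_set()].
#' @return A list with `wavelengths` and `derivative`
#'   (`n_samples x n_bands`, same grid as the input).
#' @export
first_derivative <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  wl <- as.numeric(spectra$wavelengths)
  R <- spectra$reflectance
  seg <- grid_segments(spectra$wavelengths)
  D <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  for (s in unique(seg)) {
    j <- which(seg == s)
    if (length(j) < 2L) next # an isolated band has no derivative
    w <- wl[j]
    X <- R[, j, drop = FALSE]
    m <- length(j)
    Dj <- matrix(NA_real_, nrow(X), m)
    if (m >= 3L) {
      interior <- 2:(m - 1L)
      Dj[, interior] <- (X[, interior + 1L, drop = FALSE] -
                           X[, interior - 1L, drop = FALSE]) /
        rep(w[interior + 1L] - w[interior - 1L], each = nrow(X))
    }
    Dj[, 1L] <- (X[, 2L] - X[, 1L]) / (w[2L] - w[1L])
    Dj[, m] <- (X[, m] - X[, m - 1L]) / (w[m] - w[m - 1L])
    D[, j] <- Dj
  }
  list(wavelengths = spectra$wavelengths, derivative = D)
}

#' Read spectra from CSV
#'
#' Expects one row per sample, metadata columns (`sample_id`, `year`,
#' `cultivar`, `treatment`, `date_index`, `lwc`) and one reflectance column
#' per wavelength named `wl_<nm>`. Wavelength columns may appear in any
#' order; they are sorted on read.
#'
#' @param path CSV file path.
#' @param reflectance_scale `"fraction"` (values already in \[0, 1\]) or
#'   `"percent"` (divided by 100 on read).
#' @return A [spectra_set()] on the fraction scale.
#' @export
read_spectra_csv <- function(path, reflectance_scale = c("fraction", "percent")) {
  reflectance_scale <- match.arg(reflectance_scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  wl_cols <- grep("^wl_\\d+$", names(dt), value = TRUE)
  if (length(wl_cols) == 0L) {
    stop("no wavelength columns (wl_<nm>) found in ", path, call. = FALSE)
  }
  wl <- as.integer(sub("^wl_", "", wl_cols))
  if (anyDuplicated(wl)) {
    stop("duplicated wavelength columns: ",
         paste(wl[duplicated(wl)], collapse = ", "), call. = FALSE)
  }
  o <- order(wl)
  refl <- as.matrix(dt[wl_cols[o]])
  if (reflectance_scale == "percent") refl <- refl / 100
  meta_cols <- intersect(meta_columns(), names(dt))
  meta <- if (nrow(dt)) dt[meta_cols] else
    data.frame(sample_id = character(0))
  spectra_set(refl, wl[o], meta)
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra_csv()]: metadata columns followed by `wl_<nm>`
#' reflectance columns in ascending wavelength order.
#'
#' @param spectra a [spectra_set()].
#' @param path output file path.
#' @param reflectance_scale write as `"fraction"` or `"percent"`.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path,
                              reflectance_scale = c("fraction", "percent")) {
  reflectance_scale <- match.arg(reflectance_scale)
  stopifnot(inherits(spectra, "spectra_set"))
  refl <- spectra$reflectance
  if (reflectance_scale == "percent") refl <- refl * 100
  out <- cbind(spectra$meta, as.data.frame(refl))
  data.table::fwrite(out, path, sep = ",", na = "NA")
  invisible(path)
}
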