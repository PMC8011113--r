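#' Per-band correlation with LWC
#'
#' Pearson correlation between reflectance at each retained band and leaf
#' water content — the diagnostic curve of the correlation-extremum (CA)
#' screening method.
#'
#' @param spectra a [spectra_set()], already masked.
#' @param lwc LWC vector (percent); defaults to `spectra$meta$lwc`.
#' @return A `correlation_curve`: `wavelengths` and `r` (in \[-1, 1\],
#'   `NA` for zero-variance bands).
#' @export
correlation_curve <- function(spectra, lwc = spectra$meta$lwc) {
  stopifnot(inherits(spectra, "spectra_set"))
  ok <- is.finite(lwc)
  if (sum(ok) < 3L) stop("need at least 3 samples with finite LWC",
                         call. = FALSE)
  R <- spectra$reflectance[ok, , drop = FALSE]
  y <- lwc[ok]
  yc <- y - mean(y)
  Rc <- sweep(R, 2L, colMeans(R))
  sx <- sqrt(colSums(Rc^2))
  r <- drop(crossprod(Rc, yc)) / (sx * sqrt(sum(yc^2)))
  r[sx <= .Machine$double.eps^0.5 * nrow(R)] <- NA_real_
  structure(list(wavelengths = spectra$wavelengths, r = unname(r)),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("correlation_curve over", length(x$wavelengths), "bands; r in [",
      format(min(x$r, na.rm = TRUE), digits = 3), ",",
      format(max(x$r, na.rm = TRUE), digits = 3), "]\n")
  invisible(x)
}

#' Local peaks and troughs of a curve on the retained grid
#'
#' Index `i` is a peak if `values[i]` strictly exceeds every value within
#' `window` grid positions on both sides *inside the same contiguous
#' segment* (mask gaps split segments, so no extremum straddles an
#' exclusion window); troughs symmetric. Plateaus report their leftmost
#' index. Segment endpoints are never extrema (they lack a two-sided
#' neighbourhood).
#'
#' @param values numeric vector on the grid.
#' @param wavelengths matching wavelengths (used to find mask gaps);
#'   default assumes one contiguous segment.
#' @param window neighbourhood half-width in bands (>= 1).
#' @return List with integer index vectors `peaks` and `troughs`.
#' @export
local_extrema <- function(values, wavelengths = NULL, window = 10L) {
  stopifnot(window >= 1L, length(values) > 2L * window)
  seg <- if (is.null(wavelengths)) rep(1L, length(values)) else
    grid_segments(as.integer(wavelengths))
  peaks <- integer(0); troughs <- integer(0)
  for (s in unique(seg)) {
    j <- which(seg == s)
    v <- values[j]
    m <- length(v)
    if (m < 3L) next
    for (i in 2:(m - 1L)) {
      lo <- max(1L, i - window); hi <- min(m, i + window)
      nb <- v[setdiff(lo:hi, i)]
      if (anyNA(nb) || is.na(v[i])) next
      if (all(v[i] > nb)) peaks <- c(peaks, j[i])
      else if (all(v[i] < nb)) troughs <- c(troughs, j[i])
      else if (all(v[i] >= nb) && v[i] > v[i - 1L]) {
        # leftmost point of a plateau that dominates its neighbourhood
        peaks <- c(peaks, j[i])
      } else if (all(v[i] <= nb) && v[i] < v[i - 1L]) {
        troughs <- c(troughs, j[i])
      }
    }
  }
  list(peaks = peaks, troughs = troughs)
}

#' Correlation-extremum (CA) band selection
#'
#' Seeds the selection with the local extrema of `|r|` — the wavelengths
#' where the correlation magnitude between reflectance and LWC crests or
#' troughs — then adjusts to exactly `n_target` bands: excess seeds are
#' pruned to the `n_target` largest `|r|`; a shortfall is topped up from
#' the remaining bands ranked by `|r|`, subject to a minimum separation
#' from bands already selected. Fully deterministic; ties break towards
#' the smaller wavelength.
#'
#' @param curve a [correlation_curve()].
#' @param n_target number of bands to select (default 100).
#' @param window extremum neighbourhood half-width in bands (default 10).
#' @param min_separation minimum distance (bands) between a topped-up band
#'   and any already-selected band (default 2).
#' @return A `selected_bands` object: `method`, `wavelengths` (sorted),
#'   `diagnostics`.
#' @export
select_bands_ca <- function(curve, n_target = 100L, window = 10L,
                            min_separation = 2L) {
  stopifnot(inherits(curve, "correlation_curve"))
  p <- length(curve$wavelengths)
  if (n_target > p) stop("n_target exceeds available bands", call. = FALSE)
  absr <- abs(curve$r)
  ex <- local_extrema(absr, curve$wavelengths, window = window)
  seeds <- sort(unique(c(ex$peaks, ex$troughs)))
  if (length(seeds) > n_target) {
    o <- order(-absr[seeds], curve$wavelengths[seeds])
    sel <- sort(seeds[o[seq_len(n_target)]])
  } else {
    sel <- seeds
    pool <- setdiff(order(-absr, curve$wavelengths), sel)
    pool <- pool[!is.na(absr[pool])]
    for (cand in pool) {
      if (length(sel) >= n_target) break
      if (length(sel) == 0L || min(abs(cand - sel)) >= min_separation) {
        sel <- c(sel, cand)
      }
    }
    if (length(sel) < n_target) {
      # separation constraint exhausted the pool; relax it for the rest
      rest <- setdiff(pool, sel)
      sel <- c(sel, rest[seq_len(n_target - length(sel))])
    }
    sel <- sort(sel)
  }
  structure(list(method = "CA", wavelengths = curve$wavelengths[sel],
                 diagnostics = list(curve = curve, seeds = seeds,
                                    r = curve$r[sel])),
            class = "selected_bands")
}

#' @export
print.selected_bands <- function(x, ...) {
  cat("selected_bands (", x$method, "):", length(x$wavelengths),
      "wavelengths,", min(x$wavelengths), "-", max(x$wavelengths), "nm\n")
  invisible(x)
}

#' PLS loading-weight curves for band screening
#'
#' Fits a PLS1 model of LWC on the full retained spectrum and returns the
#' per-component x-loading-weight curves, the percent of response
#' variance each component explains, and the cross-validated RMSEP for
#' 1..`max_components` components (used to choose how many components to
#' mine for extrema).
#'
#' @param spectra a [spectra_set()], already masked.
#' @param lwc LWC vector (percent); defaults to `spectra$meta$lwc`.
#' @param max_components largest component count (default 10).
#' @param cv `"loo"` or `"kfold"` for the RMSEP curve.
#' @return A `loading_curves` object: `wavelengths`, `weights`
#'   (`p x ncomp`), `explained_pct`, `rmsep_by_components`, `ncomp`.
#' @export
fit_pls_loadings <- function(spectra, lwc = spectra$meta$lwc,
                             max_components = 10L, cv = c("loo", "kfold")) {
  cv <- match.arg(cv)
  stopifnot(inherits(spectra, "spectra_set"))
  ok <- is.finite(lwc)
  X <- spectra$reflectance[ok, , drop = FALSE]
  y <- lwc[ok]
  if (nrow(X) < max_components + 2L) {
    stop("need at least max_components + 2 samples", call. = FALSE)
  }
  fit <- pls1_fit(X, y, max_components)
  rmsep <- pls1_rmsep(X, y, fit$ncomp, cv = cv)
  structure(list(wavelengths = spectra$wavelengths,
                 weights = fit$weights,
                 explained_pct = fit$y_explained_pct,
                 rmsep_by_components = rmsep,
                 ncomp = fit$ncomp, fit = fit),
            class = "loading_curves")
}

#' @export
print.loading_curves <- function(x, ...) {
  cat("loading_curves:", x$ncomp, "components over",
      length(x$wavelengths), "bands\n")
  cat("  response variance explained (%):",
      paste(format(x$explained_pct, digits = 3), collapse = ", "), "\n")
  cat("  RMSEP by components:",
      paste(format(x$rmsep_by_components, digits = 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' x-loading-weight (x-Lw) band selection
#'
#' For each of the first `n_components` loading-weight curves, finds the
#' local peaks and troughs (via [local_extrema()]) and returns the sorted
#' union of their wavelengths. Typically selects far fewer bands than the
#' CA method.
#'
#' @param loadings a [fit_pls_loadings()] result.
#' @param n_components how many components to mine (default 3).
#' @param window extremum neighbourhood half-width in bands (default 10).
#' @return A `selected_bands` object.
#' @export
select_bands_xlw <- function(loadings, n_components = 3L, window = 10L) {
  stopifnot(inherits(loadings, "loading_curves"),
            n_components <= loadings$ncomp)
  idx <- integer(0)
  for (a in seq_len(n_components)) {
    ex <- local_extrema(loadings$weights[, a], loadings$wavelengths,
                        window = window)
    idx <- union(idx, c(ex$peaks, ex$troughs))
  }
  idx <- sort(idx)
  structure(list(method = "x-Lw", wavelengths = loadings$wavelengths[idx],
                 diagnostics = list(loadings = loadings,
                                    n_components = n_components)),
            class = "selected_bands")
}

#' Percent reduction in band count between two selections
#'
#' @param n_from band count of the larger selection.
#' @param n_to band count of the smaller selection.
#' @return `(n_from - n_to) / n_from * 100`.
#' @examples
#' band_reduction_percent(100, 28) # 72
#' @export
band_reduction_percent <- function(n_from, n_to) {
  stopifnot(n_from > 0, n_to >= 0)
  (n_from - n_to) / n_from * 100
}
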