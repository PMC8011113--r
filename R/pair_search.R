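#' Exhaustive two-band R-squared map
#'
#' For every pair of retained wavelengths, computes the squared Pearson
#' correlation between a generic two-band index (normalized, ratio or
#' difference form) and LWC. This is the contour-map statistic used to
#' find the best two-band combination: for a single-index linear model the
#' squared correlation equals the regression coefficient of determination.
#'
#' The difference form is computed in closed form from the band covariance
#' matrix (`cov(Ri - Rj, y) = cov(Ri, y) - cov(Rj, y)` and
#' `var(Ri - Rj) = var(Ri) + var(Rj) - 2 cov(Ri, Rj)`), so the full grid
#' costs one `p x p` crossproduct. The nonlinear normalized and ratio
#' forms stream one reference band at a time against all others.
#'
#' Cells where the index has zero variance (both diagonals) or fewer than
#' 3 defined samples are `NA`.
#'
#' @param spectra a [spectra_set()], already masked.
#' @param lwc numeric LWC vector (percent), one per sample; defaults to
#'   `spectra$meta$lwc`.
#' @param kind `"normalized"`, `"ratio"` or `"difference"`.
#' @param stride optional coarse-search stride in bands (default 1 =
#'   exhaustive over the retained grid).
#' @return A `pair_search_result`: `kind`, `wavelengths`, `r2_matrix`
#'   (`p x p`, rows = lambda1, cols = lambda2), `n_valid` per cell.
#' @export
pair_r2_map <- function(spectra, lwc = spectra$meta$lwc,
                        kind = c("normalized", "ratio", "difference"),
                        stride = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(spectra, "spectra_set"), stride >= 1L)
  keep_samp <- is.finite(lwc)
  if (sum(keep_samp) < 3L) {
    stop("need at least 3 samples with finite LWC", call. = FALSE)
  }
  sel <- seq(1L, length(spectra$wavelengths), by = as.integer(stride))
  wl <- spectra$wavelengths[sel]
  R <- spectra$reflectance[keep_samp, sel, drop = FALSE]
  y <- lwc[keep_samp]
  n <- length(y)
  p <- length(wl)
  yc <- y - mean(y)
  ssy <- sum(yc^2)

  if (kind == "difference") {
    Rc <- sweep(R, 2L, colMeans(R))
    C <- crossprod(Rc)                       # p x p band cross-products
    cy <- drop(crossprod(Rc, yc))            # band-vs-LWC cross-products
    v <- diag(C)
    num <- outer(cy, cy, "-")
    den <- outer(v, v, "+") - 2 * C
    den[den < 0] <- 0                        # numerical guard
    r2 <- num^2 / (den * ssy)
    r2[den <= .Machine$double.eps * max(v, 1)] <- NA_real_
    nv <- matrix(n, p, p)
  } else {
    r2 <- matrix(NA_real_, p, p)
    nv <- matrix(n, p, p)
    jmax <- if (kind == "normalized") p - 1L else p
    for (i in seq_len(if (kind == "normalized") p - 1L else p)) {
      cols <- if (kind == "normalized") (i + 1L):p else seq_len(p)
      ri <- R[, i]
      Rj <- R[, cols, drop = FALSE]
      V <- if (kind == "normalized") {
        den <- ri + Rj
        ifelse(den == 0, NA_real_, (ri - Rj) / den)
      } else {
        ifelse(Rj == 0, NA_real_, ri / Rj)
      }
      cr <- column_r2(V, y)
      r2[i, cols] <- cr$r2
      nv[i, cols] <- cr$n
    }
    if (kind == "normalized") {           # mirror: correlation is sign-blind
      low <- lower.tri(r2)
      r2[low] <- t(r2)[low]
      nv[low] <- t(nv)[low]
      diag(nv) <- n
    } else {
      diag(r2) <- NA_real_                # RVI diagonal is constant 1
    }
  }
  dimnames(r2) <- dimnames(nv) <- list(wl, wl)
  structure(list(kind = kind, wavelengths = wl, r2_matrix = r2,
                 n_valid = nv),
            class = "pair_search_result")
}

# squared Pearson correlation of each column of V with y, pairwise-complete
column_r2 <- function(V, y) {
  n <- length(y)
  has_na <- anyNA(V)
  if (!has_na) {
    yc <- y - mean(y)
    Vc <- sweep(V, 2L, colMeans(V))
    num <- drop(crossprod(Vc, yc))
    den <- colSums(Vc^2) * sum(yc^2)
    r2 <- ifelse(den > 0, num^2 / den, NA_real_)
    zero_var <- colSums(Vc^2) <= .Machine$double.eps^0.5 * n
    r2[zero_var] <- NA_real_
    return(list(r2 = r2, n = rep(n, ncol(V))))
  }
  r2 <- numeric(ncol(V))
  nv <- integer(ncol(V))
  for (j in seq_len(ncol(V))) {
    ok <- !is.na(V[, j])
    nv[j] <- sum(ok)
    if (nv[j] < 3L || stats::var(V[ok, j]) == 0 || stats::var(y[ok]) == 0) {
      r2[j] <- NA_real_
    } else {
      r2[j] <- stats::cor(V[ok, j], y[ok])^2
    }
  }
  list(r2 = r2, n = nv)
}

#' @export
print.pair_search_result <- function(x, ...) {
  cat("pair_search_result (", x$kind, "):",
      length(x$wavelengths), "bands,",
      sum(!is.na(x$r2_matrix)), "defined cells, max R2 =",
      format(max(x$r2_matrix, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Extract the top band pairs from an R-squared map
#'
#' The "hot spot" extraction: the `top_k` cells ranked by R-squared. For
#' the symmetric normalized and difference forms each unordered pair is
#' reported once with `lambda1 < lambda2`. Ties break towards the smaller
#' `lambda1`, then the smaller `lambda2`.
#'
#' @param result a [pair_r2_map()] result.
#' @param top_k number of pairs to return.
#' @return Data frame: `rank`, `lambda1`, `lambda2`, `r2`.
#' @export
best_pair <- function(result, top_k = 1L) {
  stopifnot(inherits(result, "pair_search_result"))
  M <- result$r2_matrix
  if (result$kind %in% c("normalized", "difference")) {
    M[lower.tri(M, diag = TRUE)] <- NA_real_
  }
  idx <- which(!is.na(M), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no defined cells in the R2 map", call. = FALSE)
  wl <- result$wavelengths
  df <- data.frame(lambda1 = wl[idx[, 1L]], lambda2 = wl[idx[, 2L]],
                   r2 = M[idx])
  o <- order(-df$r2, df$lambda1, df$lambda2)
  df <- df[o[seq_len(min(top_k, nrow(df)))], , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Export an R-squared map as CSV
#'
#' Wavelengths as row and column headers; undefined cells are written
#' empty.
#'
#' @param result a [pair_r2_map()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_contour <- function(result, path) {
  stopifnot(inherits(result, "pair_search_result"))
  df <- data.frame(wavelength = result$wavelengths,
                   result$r2_matrix, check.names = FALSE)
  data.table::fwrite(df, path, sep = ",", na = "")
  invisible(path)
}

#' Re-import an exported R-squared map
#'
#' @param path CSV written by [export_contour()].
#' @param kind index kind label to attach.
#' @return A `pair_search_result` (without per-cell sample counts).
#' @export
read_contour <- function(path, kind = "difference") {
  df <- data.table::fread(path, sep = ",", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  wl <- as.integer(df$wavelength)
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(wl, wl)
  structure(list(kind = kind, wavelengths = wl, r2_matrix = M,
                 n_valid = NULL),
            class = "pair_search_result")
}
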