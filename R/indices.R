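#' Generic two-band vegetation index
#'
#' The three index forms searched exhaustively over band pairs:
#' normalized `(R1 - R2)/(R1 + R2)`, ratio `R1/R2` and difference
#' `R1 - R2`. Samples with a zero denominator get `NA` (flagged, never
#' silently dropped).
#'
#' @param kind `"normalized"`, `"ratio"` or `"difference"`.
#' @param lambda1,lambda2 wavelengths in nm; must be on the (masked) grid.
#' @param spectra a [spectra_set()].
#' @return A list of class `index_values`: `name`, `values` (per-sample
#'   numeric, `NA` where undefined) and `n_undefined`.
#' @examples
#' ss <- spectra_set(matrix(c(0.4345, 0.3227), 1), c(820, 970))
#' generic_index("difference", 820, 970, ss)$values # 0.1118
#' @export
generic_index <- function(kind = c("normalized", "ratio", "difference"),
                          lambda1, lambda2, spectra) {
  kind <- match.arg(kind)
  r1 <- band(spectra, lambda1)[, 1L]
  r2 <- band(spectra, lambda2)[, 1L]
  v <- switch(kind,
    normalized = {
      den <- r1 + r2
      ifelse(den == 0, NA_real_, (r1 - r2) / den)
    },
    ratio = ifelse(r2 == 0, NA_real_, r1 / r2),
    difference = r1 - r2
  )
  name <- switch(kind,
                 normalized = sprintf("NDVI(R%d,R%d)", lambda1, lambda2),
                 ratio = sprintf("RVI(R%d,R%d)", lambda1, lambda2),
                 difference = sprintf("DVI(R%d,R%d)", lambda1, lambda2))
  index_values(name, v)
}

index_values <- function(name, values) {
  values <- unname(values)
  structure(list(name = name, values = values,
                 n_undefined = sum(is.na(values))),
            class = "index_values")
}

#' @export
print.index_values <- function(x, ...) {
  cat("index", x$name, ":", length(x$values), "values,",
      x$n_undefined, "undefined\n")
  invisible(x)
}

literature_index_names <- function() {
  c("RatioIndex", "NDWI", "MSI", "MDWI", "hNDVI", "WI", "SRWI", "NDII",
    "WI/hNDVI", "FD730-955")
}

#' Literature water indices
#'
#' Ten published water-status indices. Several are commonly printed with
#' typographical corruption in secondary sources; this catalogue follows
#' the original citations: NDWI = (R860 - R1240)/(R860 + R1240) (Gao),
#' hNDVI = (R900 - R680)/(R900 + R680) (the Rouse normalized-difference
#' form), NDII = (R820 - R1649)/(R820 + R1649) (Hardisky). MDWI uses the
#' max and min reflectance over the retained 1500-1750 nm window, and
#' FD730-955 the ratio of first-derivative values at 730 and 955 nm.
#'
#' @param name one of `"RatioIndex"` (R1650/R2220), `"NDWI"`, `"MSI"`
#'   (R1600/R820), `"MDWI"`, `"hNDVI"`, `"WI"` (R900/R970), `"SRWI"`
#'   (R820/R1200), `"NDII"`, `"WI/hNDVI"`, `"FD730-955"`.
#' @param spectra a [spectra_set()]; required bands must be on the grid.
#' @return An `index_values` object.
#' @export
literature_index <- function(name, spectra) {
  nd <- function(a, b) {
    den <- a + b
    ifelse(den == 0, NA_real_, (a - b) / den)
  }
  rt <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  v <- switch(name,
    "RatioIndex" = rt(band(spectra, 1650)[, 1], band(spectra, 2220)[, 1]),
    "NDWI" = nd(band(spectra, 860)[, 1], band(spectra, 1240)[, 1]),
    "MSI" = rt(band(spectra, 1600)[, 1], band(spectra, 820)[, 1]),
    "MDWI" = {
      win <- spectra$wavelengths >= 1500 & spectra$wavelengths <= 1750
      if (!any(win)) stop("MDWI needs bands in 1500-1750 nm", call. = FALSE)
      R <- spectra$reflectance[, win, drop = FALSE]
      mx <- apply(R, 1L, max); mn <- apply(R, 1L, min)
      nd(mx, mn)
    },
    "hNDVI" = nd(band(spectra, 900)[, 1], band(spectra, 680)[, 1]),
    "WI" = rt(band(spectra, 900)[, 1], band(spectra, 970)[, 1]),
    "SRWI" = rt(band(spectra, 820)[, 1], band(spectra, 1200)[, 1]),
    "NDII" = nd(band(spectra, 820)[, 1], band(spectra, 1649)[, 1]),
    "WI/hNDVI" = {
      wi <- literature_index("WI", spectra)$values
      hn <- literature_index("hNDVI", spectra)$values
      ifelse(is.na(hn) | hn == 0, NA_real_, wi / hn)
    },
    "FD730-955" = {
      fd <- first_derivative(spectra)
      j1 <- match(730L, fd$wavelengths); j2 <- match(955L, fd$wavelengths)
      if (is.na(j1) || is.na(j2)) {
        stop("FD730-955 needs bands 730 and 955 nm on the grid",
             call. = FALSE)
      }
      d1 <- fd$derivative[, j1]; d2 <- fd$derivative[, j2]
      ifelse(is.na(d2) | d2 == 0, NA_real_, d1 / d2)
    },
    stop("unknown index name: ", name, call. = FALSE)
  )
  index_values(name, v)
}

#' Catalogue of the 13 water indices
#'
#' The ten literature indices plus the three optimized two-band forms
#' parameterized at their best-performing pair (1185, 1307) nm.
#'
#' @return A data frame with columns `name`, `kind` and `wavelengths`
#'   (list column of nm vectors; window bounds for MDWI).
#' @export
index_catalog <- function() {
  lit <- data.frame(
    name = literature_index_names(),
    kind = c("ratio", "normalized", "ratio", "window_normalized",
             "normalized", "ratio", "ratio", "normalized", "composite",
             "derivative_ratio"),
    stringsAsFactors = FALSE)
  lit$wavelengths <- list(
    c(1650, 2220), c(860, 1240), c(1600, 820), c(1500, 1750),
    c(900, 680), c(900, 970), c(820, 1200), c(820, 1649),
    c(900, 970, 680), c(730, 955))
  opt <- data.frame(
    name = c("NDVI(R1185,R1307)", "RVI(R1185,R1307)", "DVI(R1185,R1307)"),
    kind = c("normalized", "ratio", "difference"),
    stringsAsFactors = FALSE)
  opt$wavelengths <- rep(list(c(1185, 1307)), 3L)
  rbind(lit, opt)
}

#' Evaluate catalogue indices on a spectra set
#'
#' @param spectra a [spectra_set()].
#' @param which character vector of catalogue names, or `"all"`.
#' @return Data frame, one column per index, one row per sample.
#' @export
compute_indices <- function(spectra, which = "all") {
  cat_df <- index_catalog()
  if (identical(which, "all")) which <- cat_df$name
  bad <- setdiff(which, cat_df$name)
  if (length(bad)) stop("not in catalogue: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- lapply(which, function(nm) {
    row <- cat_df[cat_df$name == nm, ]
    if (nm %in% literature_index_names()) {
      literature_index(nm, spectra)$values
    } else {
      kind <- row$kind
      wl <- row$wavelengths[[1L]]
      generic_index(kind, wl[1L], wl[2L], spectra)$values
    }
  })
  names(out) <- which
  as.data.frame(out, check.names = FALSE)
}
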