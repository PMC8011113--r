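#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. Out of sample this is not the squared
#' correlation and may be negative for models worse than the mean
#' predictor.
#'
#' @param y measured values; `yhat` predictions, same length >= 2.
#' @param yhat predicted values.
#' @return Unitless R-squared.
#' @export
r2_score <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("y has zero variance; R2 undefined", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Root mean squared error
#'
#' @inheritParams r2_score
#' @return RMSE in the units of `y` (LWC percent).
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1L)
  sqrt(mean((y - yhat)^2))
}

#' Ratio of performance to deviation
#'
#' `RPD = SD(y) / RMSE(y, yhat)`, with the sample (n - 1) SD by default.
#' Values above 1.4 flag a model whose predictions are usable.
#'
#' @inheritParams r2_score
#' @param sd_type `"sample"` (n - 1 denominator) or `"population"`.
#' @return List: `rpd` (Inf when RMSE is 0) and `adequate`
#'   (`rpd > 1.4`).
#' @export
rpd <- function(y, yhat, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  s <- stats::sd(y)
  if (sd_type == "population") s <- s * sqrt((length(y) - 1) / length(y))
  e <- rmse(y, yhat)
  val <- if (e == 0) Inf else s / e
  list(rpd = val, adequate = val > 1.4)
}

#' Descriptive statistics of LWC splits
#'
#' Max, min, mean, SD (n - 1) and CV% = SD / mean x 100 per split, the
#' standard sample-set summary table.
#'
#' @param splits named list of LWC vectors (each length >= 2).
#' @return Data frame with one row per split; values at full precision,
#'   printed to two decimals.
#' @examples
#' describe_lwc(list(toy = c(70, 75, 80, 85)))
#' @export
describe_lwc <- function(splits) {
  stopifnot(is.list(splits), length(splits) >= 1L)
  rows <- lapply(names(splits), function(nm) {
    v <- splits[[nm]]
    if (length(v) < 2L) {
      stop("split '", nm, "' needs >= 2 values for an SD", call. = FALSE)
    }
    s <- stats::sd(v)
    data.frame(split = nm, n = length(v), max = max(v), min = min(v),
               mean = mean(v), sd = s, cv_pct = s / mean(v) * 100,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split a dataset by season for calibration and validation
#'
#' The earliest year label becomes the calibration set, the latest the
#' validation set; any middle years are dropped with a warning.
#'
#' @param spectra a [spectra_set()] whose metadata carries >= 2 distinct
#'   `year` labels.
#' @return List with `calibration` and `validation` spectra sets.
#' @export
year_split <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  yrs <- sort(unique(spectra$meta$year))
  if (length(yrs) < 2L) {
    stop("year_split needs at least two distinct year labels", call. = FALSE)
  }
  if (length(yrs) > 2L) {
    warning("years ", paste(yrs[-c(1L, length(yrs))], collapse = ", "),
            " are neither earliest nor latest and were left unused",
            call. = FALSE)
  }
  subset_rows <- function(x, rows) {
    x$reflectance <- x$reflectance[rows, , drop = FALSE]
    x$meta <- x$meta[rows, , drop = FALSE]
    rownames(x$meta) <- NULL
    x
  }
  list(calibration = subset_rows(spectra, spectra$meta$year == yrs[1L]),
       validation = subset_rows(spectra, spectra$meta$year == yrs[length(yrs)]))
}

eval_report <- function(name, y, yhat) {
  rp <- rpd(y, yhat)
  data.frame(split = name, n = length(y), r2 = r2_score(y, yhat),
             rmse = rmse(y, yhat), rpd = rp$rpd, adequate = rp$adequate,
             stringsAsFactors = FALSE)
}

#' Band-set x model comparison table
#'
#' Runs the full comparison workflow: the dataset is split by year into
#' calibration and validation sets, characteristic bands are screened on
#' the calibration set only (no validation leakage, unless
#' `pooled_selection = TRUE` is requested explicitly), each model is
#' trained on the calibration set over each band set, and both splits are
#' scored by R-squared, RMSE and RPD.
#'
#' @param spectra a [spectra_set()] with LWC and two year labels; masked
#'   with [apply_atmospheric_mask()] beforehand (or pass `mask`).
#' @param band_set_methods subset of `c("full", "CA", "x-Lw")`.
#' @param model_methods subset of `c("PLSR", "RFR", "ERT", "KNN")`.
#' @param mask optional [band_mask()] applied before anything else.
#' @param ca_n_target CA band count (default 100, reduced automatically
#'   to the available band count).
#' @param window extremum window for both screening methods.
#' @param xlw_components loading-weight components to mine (default 3).
#' @param max_pls_components PLSR component cap.
#' @param seed seed for the stochastic models.
#' @param pooled_selection when `TRUE`, band screening sees both years
#'   (the leakage-prone variant, off by default).
#' @return A data frame of class `comparison_table`: one row per model x
#'   band set x split with `n_bands`, `n`, `r2`, `rmse`, `rpd`.
#' @export
run_comparison <- function(spectra,
                           band_set_methods = c("full", "CA", "x-Lw"),
                           model_methods = c("PLSR", "RFR", "ERT", "KNN"),
                           mask = NULL,
                           ca_n_target = 100L, window = 10L,
                           xlw_components = 3L, max_pls_components = 20L,
                           seed = 20180101L,
                           pooled_selection = FALSE) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!is.null(mask)) spectra <- apply_atmospheric_mask(spectra, mask)
  sp <- year_split(spectra)
  cal <- sp$calibration; val <- sp$validation
  sel_source <- if (pooled_selection) spectra else cal

  band_sets <- list()
  for (m in band_set_methods) {
    band_sets[[m]] <- switch(m,
      full = structure(list(method = "full",
                            wavelengths = spectra$wavelengths,
                            diagnostics = NULL),
                       class = "selected_bands"),
      CA = {
        curve <- correlation_curve(sel_source)
        select_bands_ca(curve,
                        n_target = min(ca_n_target,
                                       length(curve$wavelengths)),
                        window = window)
      },
      "x-Lw" = {
        ld <- fit_pls_loadings(sel_source, max_components =
                                 min(10L, n_samples(sel_source) - 2L))
        select_bands_xlw(ld, n_components = min(xlw_components, ld$ncomp),
                         window = window)
      },
      stop("unknown band set method: ", m, call. = FALSE))
  }

  rows <- list()
  for (bm in band_set_methods) {
    bands <- band_sets[[bm]]
    for (mm in model_methods) {
      spec <- switch(mm,
        PLSR = model_spec("PLSR", max_components = max_pls_components),
        RFR = model_spec("RFR", seed = seed),
        ERT = model_spec("ERT", seed = seed),
        KNN = model_spec("KNN", seed = seed))
      fit <- fit_lwc_model(spec, cal, bands = bands)
      rep_cal <- eval_report("calibration", cal$meta$lwc, predict(fit, cal))
      rep_val <- eval_report("validation", val$meta$lwc, predict(fit, val))
      rep <- rbind(rep_cal, rep_val)
      rep <- cbind(data.frame(model = mm, band_set = bm,
                              n_bands = length(bands$wavelengths),
                              stringsAsFactors = FALSE), rep)
      rows[[paste(mm, bm)]] <- rep
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", class(out))
  attr(out, "band_sets") <- band_sets
  attr(out, "seed") <- seed
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$r2 <- round(y$r2, 2); y$rmse <- round(y$rmse, 2)
  y$rpd <- round(y$rpd, 2)
  print(y)
  invisible(x)
}
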