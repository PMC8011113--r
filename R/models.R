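#' Model specification for LWC regression
#'
#' @param method one of `"PLSR"`, `"RFR"` (random forest), `"ERT"`
#'   (extremely randomized trees), `"KNN"`, `"INDEX_SLR"` (univariate
#'   linear model on one spectral index).
#' @param ... method hyperparameters overriding the defaults:
#'   * PLSR: `max_components` (cap, default `min(20, n - 2)` at fit time),
#'     `cv` (`"loo"` or `"kfold"`, default `"loo"`).
#'   * RFR / ERT: `n_trees` (500), `mtry_rule` (`"sqrt"`), `seed`.
#'   * KNN: `k` (3), `select_k` (`FALSE`; when `TRUE`, k chosen over 1..15
#'     by seeded 5-fold CV).
#'   * INDEX_SLR: `index_name` and `index_kind`/`index_wavelengths`, or a
#'     precomputed index via `fit(..., index_values = )`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(method = c("PLSR", "RFR", "ERT", "KNN", "INDEX_SLR"),
                       ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    PLSR = list(max_components = 20L, cv = "loo"),
    RFR = list(n_trees = 500L, mtry_rule = "sqrt", seed = 20180101L),
    ERT = list(n_trees = 500L, mtry_rule = "sqrt", seed = 20180101L),
    KNN = list(k = 3L, select_k = FALSE, k_grid = 1:15, cv_folds = 5L,
               seed = 20180101L),
    INDEX_SLR = list(index_kind = "difference",
                     index_wavelengths = c(1185L, 1307L)))
  hp <- utils::modifyList(defaults, list(...))
  if (method %in% c("RFR", "ERT") && hp$n_trees < 1L) {
    stop("n_trees must be >= 1", call. = FALSE)
  }
  if (method == "KNN" && hp$k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(list(method = method, hyper = hp), class = "model_spec")
}

feature_matrix <- function(spectra, bands) {
  wl <- if (inherits(bands, "selected_bands")) bands$wavelengths
        else if (identical(bands, "full")) spectra$wavelengths
        else as.integer(bands)
  wl <- sort(wl)
  X <- band(spectra, wl)
  colnames(X) <- paste0("wl_", wl)
  list(X = X, wavelengths = wl)
}

#' Fit an LWC regression model
#'
#' The four multivariate methods with their standard settings: PLSR with
#' the component count chosen by minimum leave-one-out RMSEP (capped at
#' `min(20, n - 2)`), random forest regression (500 trees, sqrt feature
#' subsampling, bootstrap resampling), extremely randomized trees (500
#' trees, sqrt feature subsampling, no bootstrap — every tree sees the
#' whole training set — and fully random split thresholds), and KNN with
#' Euclidean distance (fixed k = 3 by default). Predictors enter in
#' ascending wavelength order; tree and KNN models see raw reflectance,
#' PLSR centres it.
#'
#' @param spec a [model_spec()].
#' @param spectra training [spectra_set()].
#' @param bands a `selected_bands` object, an integer wavelength vector,
#'   or `"full"` for every retained band.
#' @param lwc training LWC (percent); defaults to `spectra$meta$lwc`.
#' @param index_values optional precomputed per-sample index vector for
#'   `INDEX_SLR`.
#' @return A `fitted_lwc_model`.
#' @export
fit_lwc_model <- function(spec, spectra, bands = "full",
                          lwc = spectra$meta$lwc, index_values = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(spectra, "spectra_set"))
  ok <- is.finite(lwc)
  if (sum(ok) < 10L) stop("need at least 10 training samples", call. = FALSE)
  hp <- spec$hyper
  if (spec$method == "INDEX_SLR") {
    v <- if (!is.null(index_values)) index_values else
      generic_index(hp$index_kind, hp$index_wavelengths[1L],
                    hp$index_wavelengths[2L], spectra)$values
    d <- data.frame(y = lwc[ok], x = v[ok])
    m <- stats::lm(y ~ x, data = d)
    return(structure(list(spec = spec, wavelengths = hp$index_wavelengths,
                          model = m,
                          summary = list(n = sum(ok),
                                         coef = stats::coef(m))),
                     class = "fitted_lwc_model"))
  }
  fm <- feature_matrix(spectra, bands)
  X <- fm$X[ok, , drop = FALSE]
  y <- lwc[ok]
  n <- nrow(X); p <- ncol(X)
  trained <- switch(spec$method,
    PLSR = {
      amax <- min(hp$max_components, n - 2L, p)
      rmsep <- pls1_rmsep(X, y, amax, cv = hp$cv)
      a_opt <- which.min(rmsep)
      fit <- suppressWarnings(pls1_fit(X, y, a_opt))
      list(fit = fit, ncomp = fit$ncomp, rmsep = rmsep)
    },
    RFR = {
      mtry <- max(1L, floor(sqrt(p)))
      ranger::ranger(x = X, y = y, num.trees = hp$n_trees, mtry = mtry,
                     seed = hp$seed, num.threads = 1L)
    },
    ERT = {
      mtry <- max(1L, floor(sqrt(p)))
      ranger::ranger(x = X, y = y, num.trees = hp$n_trees, mtry = mtry,
                     splitrule = "extratrees", num.random.splits = 1L,
                     replace = FALSE, sample.fraction = 1,
                     seed = hp$seed, num.threads = 1L)
    },
    KNN = {
      k <- hp$k
      if (isTRUE(hp$select_k)) k <- select_knn_k(X, y, hp)
      list(fit = caret::knnreg(X, y, k = k), k = k)
    })
  summary <- list(n = n, p = p,
                  ncomp = if (spec$method == "PLSR") trained$ncomp else NULL,
                  k = if (spec$method == "KNN") trained$k else NULL,
                  seed = hp$seed)
  structure(list(spec = spec, wavelengths = fm$wavelengths,
                 model = trained, summary = summary),
            class = "fitted_lwc_model")
}

select_knn_k <- function(X, y, hp) {
  n <- nrow(X)
  perm <- withr::with_seed(hp$seed, sample.int(n))
  folds <- split(perm, rep_len(seq_len(hp$cv_folds), n))
  rmse_k <- vapply(hp$k_grid, function(k) {
    err <- vapply(folds, function(te) {
      m <- caret::knnreg(X[-te, , drop = FALSE], y[-te], k = k)
      sum((y[te] - stats::predict(m, X[te, , drop = FALSE]))^2)
    }, 0)
    sqrt(sum(err) / n)
  }, 0)
  hp$k_grid[which.min(rmse_k)]
}

#' @export
print.fitted_lwc_model <- function(x, ...) {
  cat("fitted_lwc_model:", x$spec$method, "on", length(x$wavelengths),
      "wavelength(s)\n")
  if (!is.null(x$summary$ncomp)) cat("  PLS components:", x$summary$ncomp, "\n")
  if (!is.null(x$summary$k)) cat("  k:", x$summary$k, "\n")
  invisible(x)
}

#' Predict LWC from spectra
#'
#' Selects the model's stored feature wavelengths from the supplied
#' spectra (which may carry a superset of bands) and predicts one LWC
#' value per sample. Deterministic given the fitted model.
#'
#' @param object a `fitted_lwc_model`.
#' @param spectra a [spectra_set()] containing every stored wavelength.
#' @param ... ignored.
#' @return Numeric vector of predicted LWC (percent).
#' @export
predict.fitted_lwc_model <- function(object, spectra, ...) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (object$spec$method == "INDEX_SLR") {
    hp <- object$spec$hyper
    v <- generic_index(hp$index_kind, hp$index_wavelengths[1L],
                       hp$index_wavelengths[2L], spectra)$values
    return(unname(stats::predict(object$model, data.frame(x = v))))
  }
  X <- band(spectra, object$wavelengths)
  colnames(X) <- paste0("wl_", object$wavelengths)
  switch(object$spec$method,
    PLSR = pls1_predict(object$model$fit, X),
    RFR = ,
    ERT = stats::predict(object$model, data = X,
                         num.threads = 1L)$predictions,
    KNN = stats::predict(object$model$fit, X))
}
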