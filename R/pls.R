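#' PLS1 regression by NIPALS
#'
#' Partial least squares with a single response, computed by the classical
#' NIPALS deflation. Predictors and response are mean-centred only (no
#' unit-variance scaling), the common convention for reflectance spectra.
#' Each component's loading-weight vector is sign-oriented so that its
#' largest-magnitude element is positive, making the peak/trough geometry
#' of the weights reproducible across runs and libraries.
#'
#' @param X numeric predictor matrix `n x p`.
#' @param y numeric response vector, length `n`.
#' @param ncomp number of latent components.
#' @return A list of class `pls1_fit`: `weights` (`p x a` loading
#'   weights), `loadings` (`p x a` x-loadings), `scores` (`n x a`),
#'   `y_loadings` (length `a`), `coefficients` (`p x a`, regression
#'   vector using 1..a components), `intercepts`, `x_mean`, `y_mean`,
#'   `y_explained_pct` (percent of response variance captured per
#'   component), `ncomp`.
#' @keywords internal
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp_max <- min(n - 1L, p)
  if (ncomp > ncomp_max) {
    warning("ncomp truncated from ", ncomp, " to data rank bound ",
            ncomp_max, call. = FALSE)
    ncomp <- ncomp_max
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean)
  f <- y - y_mean
  ssy <- sum(f^2)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  expl <- numeric(ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < .Machine$double.eps^0.75) break  # residual orthogonal to X
    w <- w / wn
    j <- which.max(abs(w))
    if (w[j] < 0) w <- -w
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < .Machine$double.eps^0.75) break
    pv <- drop(crossprod(E, t)) / tt
    qa <- sum(t * f) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    expl[a] <- if (ssy > 0) qa^2 * tt / ssy * 100 else 0
    a_used <- a
  }
  if (a_used == 0L) stop("PLS found no usable component", call. = FALSE)
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  expl <- expl[seq_len(a_used)]
  # regression vectors for every truncation 1..a_used
  coefs <- matrix(0, p, a_used)
  R <- W %*% solve(crossprod(P, W))   # transformed weights: X b = T q
  for (a in seq_len(a_used)) {
    coefs[, a] <- R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]
  }
  intercepts <- y_mean - drop(crossprod(coefs, x_mean))
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = q,
                 coefficients = coefs, intercepts = intercepts,
                 x_mean = x_mean, y_mean = y_mean,
                 y_explained_pct = expl, ncomp = a_used),
            class = "pls1_fit")
}

#' @keywords internal
pls1_predict <- function(fit, X, ncomp = fit$ncomp) {
  X <- as.matrix(X)
  drop(X %*% fit$coefficients[, ncomp]) + fit$intercepts[ncomp]
}

#' Cross-validated RMSEP per component count
#'
#' @param X predictors `n x p`; `y` response.
#' @param max_components largest component count to evaluate.
#' @param cv `"loo"` (leave-one-out) or `"kfold"`.
#' @param k folds when `cv = "kfold"`.
#' @param seed seed for the k-fold shuffle.
#' @return Numeric vector of RMSEP (response units) for 1..max components.
#' @keywords internal
pls1_rmsep <- function(X, y, max_components, cv = c("loo", "kfold"),
                       k = 5L, seed = 20180101L) {
  cv <- match.arg(cv)
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- if (cv == "loo") {
    as.list(seq_len(n))
  } else {
    perm <- withr::with_seed(seed, sample.int(n))
    split(perm, rep_len(seq_len(k), n))
  }
  press <- matrix(NA_real_, length(folds), max_components)
  for (fi in seq_along(folds)) {
    te <- folds[[fi]]
    fit <- suppressWarnings(
      pls1_fit(X[-te, , drop = FALSE], y[-te], max_components))
    for (a in seq_len(max_components)) {
      ae <- min(a, fit$ncomp)
      pred <- pls1_predict(fit, X[te, , drop = FALSE], ae)
      press[fi, a] <- sum((y[te] - pred)^2)
    }
  }
  sqrt(colSums(press) / n)
}
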