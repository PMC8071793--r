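#' Partial-least-squares functional mode analysis (PLS1, NIPALS)
#'
#' Fits a single-response PLS regression of an observable on per-frame
#' feature vectors (here: per-residue punctual stress).  Components are
#' extracted by the NIPALS recursion: each weight vector is proportional to
#' the covariance of the current feature residuals with the observable
#' residuals, so the basis maximizes covariance with the observable rather
#' than feature variance (contrast PCA).  Features are mean-centered but not
#' variance-scaled, keeping coefficients comparable across residues in
#' physical force units.
#'
#' @param X frames x p feature matrix.
#' @param y length-frames observable vector.
#' @param n_components number of components K, `1 <= K < nrow(X)`.  If the
#'   residual feature matrix is exhausted earlier, K is reduced to the rank
#'   actually available, with a warning.
#' @return object of class `pls_fma`: list with `x_mean`, `y_mean`,
#'   `weights` (p x K), `loadings` (p x K), `y_loadings` (length K),
#'   `scores` (n x K training scores), `coef_path` (p x K cumulative
#'   regression vectors), `coefficients` (length-p regression vector using
#'   all K components) and `n_components`.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y disagree on the number of frames",
                           call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  if (n_components < 1 || n_components >= n) {
    stop("need frames > n_components >= 1", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("degenerate target: y has zero variance", call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  tol <- 1e-12 * max(abs(E))

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  b <- numeric(n_components)
  k_eff <- 0L
  for (k in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw <= tol) break
    w <- w / nw
    t_k <- E %*% w
    tt <- sum(t_k^2)
    if (tt <= tol^2) break
    p_k <- crossprod(E, t_k) / tt
    b_k <- sum(t_k * f) / tt
    E <- E - t_k %*% t(p_k)
    f <- f - b_k * t_k
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k; b[k] <- b_k
    k_eff <- k
  }
  if (k_eff == 0L) stop("degenerate target: no covariance between X and y",
                        call. = FALSE)
  if (k_eff < n_components) {
    warning("feature rank exhausted: n_components reduced to ", k_eff)
    W <- W[, seq_len(k_eff), drop = FALSE]
    P <- P[, seq_len(k_eff), drop = FALSE]
    Tm <- Tm[, seq_len(k_eff), drop = FALSE]
    b <- b[seq_len(k_eff)]
  }
  coef_path <- matrix(0, p, k_eff)
  for (k in seq_len(k_eff)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    coef_path[, k] <- Wk %*% solve(crossprod(Pk, Wk), b[seq_len(k)])
  }
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W,
                 loadings = P, y_loadings = b, scores = Tm,
                 coef_path = coef_path,
                 coefficients = coef_path[, k_eff],
                 n_components = k_eff),
            class = "pls_fma")
}

#' Predict the observable from a fitted PLS-FMA model
#'
#' `y_hat = y_mean + (X - x_mean) . coefficients`, optionally truncated to
#' the first `ncomp` components.
#'
#' @param object a [fit_pls()] model.
#' @param newdata frames x p feature matrix.
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predicted observable values.
#' @export
predict.pls_fma <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_mean), call. = FALSE)
  }
  if (is.null(ncomp)) ncomp <- object$n_components
  if (ncomp < 1 || ncomp > object$n_components) {
    stop("ncomp out of range", call. = FALSE)
  }
  beta <- object$coef_path[, ncomp]
  drop(object$y_mean + sweep(newdata, 2, object$x_mean) %*% beta)
}

#' @export
print.pls_fma <- function(x, ...) {
  cat("PLS-FMA model:", length(x$x_mean), "features,", x$n_components,
      "components\n")
  cat("  |coefficients| range:", signif(min(abs(x$coefficients)), 3), "-",
      signif(max(abs(x$coefficients)), 3), "\n")
  invisible(x)
}

#' Per-component contribution to model quality
#'
#' Contribution of component k is defined as the R-squared of the model
#' truncated to its first k components divided by the R-squared of the full
#' K-component model, both evaluated on the supplied data.  The first entry
#' quantifies how much of the model a single collective mode (the
#' ensemble-weighted first PLS component) explains.
#'
#' @param model a [fit_pls()] model.
#' @param X,y data on which to evaluate (typically the training set).
#' @return numeric length-K vector of contribution fractions; the last
#'   entry is 1 by construction.
#' @export
component_contribution <- function(model, X, y) {
  y <- as.numeric(y)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- vapply(seq_len(model$n_components), function(k) {
    1 - sum((y - predict(model, X, ncomp = k))^2) / ss_tot
  }, numeric(1))
  if (r2[model$n_components] <= 0) {
    stop("undefined contribution: full model has non-positive R-squared",
         call. = FALSE)
  }
  r2 / r2[model$n_components]
}

#' Sign-aligned ensemble average of coefficient vectors
#'
#' Averages the per-fold PLS coefficient vectors obtained under
#' cross-validation.  Vectors whose dot product with the first vector is
#' negative are flipped before averaging, so antiparallel duplicates do not
#' cancel.  The pairwise cosine-similarity matrix (computed before sign
#' alignment) is returned as a consistency diagnostic.
#'
#' @param vectors list of equal-length numeric vectors.
#' @return list with `average` (length-p vector) and `similarity`
#'   (m x m cosine matrix).
#' @export
ensemble_average_vectors <- function(vectors) {
  if (!is.list(vectors) || length(vectors) == 0L) {
    stop("need at least one vector", call. = FALSE)
  }
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1L) stop("vectors differ in length",
                                       call. = FALSE)
  V <- do.call(cbind, vectors)
  norms <- sqrt(colSums(V^2))
  Vn <- sweep(V, 2, pmax(norms, 1e-300), "/")
  similarity <- crossprod(Vn)
  flip <- ifelse(crossprod(Vn, Vn[, 1]) < 0, -1, 1)
  avg <- rowMeans(sweep(V, 2, drop(flip), "*"))
  list(average = avg, similarity = similarity)
}

#' Serialize a PLS-FMA model to JSON
#'
#' @param model a [fit_pls()] model.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_pls_model <- function(model, file) {
  obj <- list(x_mean = model$x_mean, y_mean = model$y_mean,
              weights = model$weights, loadings = model$loadings,
              y_loadings = model$y_loadings,
              coefficients = model$coefficients,
              n_components = model$n_components)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read a PLS-FMA model written by [write_pls_model()]
#'
#' The coefficient path is reconstructed from the stored weights and
#' loadings, so predictions (including truncated ones) are available.
#'
#' @param file path to the JSON file.
#' @return a `pls_fma` model (without training scores).
#' @export
read_pls_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  W <- as.matrix(obj$weights); P <- as.matrix(obj$loadings)
  K <- obj$n_components
  coef_path <- matrix(0, nrow(W), K)
  for (k in seq_len(K)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    coef_path[, k] <- Wk %*% solve(crossprod(Pk, Wk),
                                   obj$y_loadings[seq_len(k)])
  }
  structure(list(x_mean = obj$x_mean, y_mean = obj$y_mean, weights = W,
                 loadings = P, y_loadings = obj$y_loadings, scores = NULL,
                 coef_path = coef_path, coefficients = obj$coefficients,
                 n_components = K),
            class = "pls_fma")
}
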