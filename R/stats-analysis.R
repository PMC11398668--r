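#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used for all
#' structure-duration associations.
#'
#' @param x,y Numeric vectors of equal length (>= 3); pairs with missing
#'   values are dropped.
#' @returns Correlation in `[-1, 1]`; `NA` with a warning if either rank
#'   vector is constant.
#' @examples
#' spearman_rho(1:10, (1:10)^3)  # 1: monotone
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least three complete pairs")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    warn("constant ranks; Spearman correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Log transform of working-memory durations
#'
#' `ln(duration + offset)`; the offset keeps zero durations (silent
#' trials) finite. Censored durations enter at the delay length.
#'
#' @param durations Durations, ms (>= 0).
#' @param offset Offset, ms.
#' @returns Transformed vector.
#' @export
log_duration_transform <- function(durations, offset = 1) {
  if (any(durations < 0, na.rm = TRUE)) abort("durations must be >= 0")
  if (offset <= 0) abort("offset must be > 0")
  log(durations + offset)
}

standardize_cols <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) abort("constant feature column; cannot standardize")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}

#' Ridge regression of log duration on structural features
#'
#' Closed-form ridge fit of the cost
#' `(1/n) sum (y_i - b0 - b' x_i)^2 + lambda ||b||^2` with the intercept
#' unpenalized. Features are z-scored column-wise before fitting (so that
#' coefficient magnitudes are comparable across features); coefficients are
#' reported on the standardized scale. Missing feature values are imputed
#' with the column median (count recorded in the result).
#'
#' @param X Feature matrix or data frame (n x p).
#' @param y Response (already transformed, see
#'   [log_duration_transform()]).
#' @param lambda Regularization weight (>= 0).
#' @returns An object of class `wm_ridge`: list with `beta` (named),
#'   `beta0`, `lambda`, `r_squared`, `n`, `n_imputed`, `center`, `scale`,
#'   `fitted`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4)
#' y <- X %*% c(1, -2, 0, 0.5) + rnorm(50, sd = 0.1)
#' coef(ridge_fit(X, y, lambda = 0.01))
#' @export
ridge_fit <- function(X, y, lambda = 0) {
  X <- as.matrix(as.data.frame(X))
  if (!is.numeric(lambda) || lambda < 0) abort("lambda must be >= 0")
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) abort("X and y sizes disagree")
  if (n <= 2) abort("need more than two observations")
  n_imputed <- 0L
  if (anyNA(X)) {
    for (j in seq_len(p)) {
      miss <- is.na(X[, j])
      if (any(miss)) {
        X[miss, j] <- median(X[, j], na.rm = TRUE)
        n_imputed <- n_imputed + sum(miss)
      }
    }
  }
  std <- standardize_cols(X)
  Xs <- std$X
  yc <- y - mean(y)
  A <- crossprod(Xs) / n + diag(lambda, p)
  b <- tryCatch(solve(A, crossprod(Xs, yc) / n),
                error = function(e)
                  abort(paste0("singular system; use lambda > 0 (",
                               conditionMessage(e), ")")))
  beta <- setNames(as.numeric(b),
                   colnames(X) %||% paste0("x", seq_len(p)))
  fitted <- as.numeric(mean(y) + Xs %*% b)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum(yc^2)
  structure(list(beta = beta, beta0 = mean(y), lambda = lambda,
                 r_squared = 1 - ss_res / ss_tot, n = n,
                 n_imputed = n_imputed, center = std$center,
                 scale = std$scale, fitted = fitted),
            class = "wm_ridge")
}

#' @export
coef.wm_ridge <- function(object, ...) {
  c("(Intercept)" = object$beta0, object$beta)
}

#' @export
print.wm_ridge <- function(x, ...) {
  cat("<wm_ridge> lambda = ", x$lambda, ", n = ", x$n, ", R^2 = ",
      round(x$r_squared, 3), "\n", sep = "")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
tidy.wm_ridge <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         abs_estimate = abs(unname(x$beta)))
}

#' @export
glance.wm_ridge <- function(x, ...) {
  tibble(lambda = x$lambda, r.squared = x$r_squared, nobs = x$n,
         n_features = length(x$beta), n_imputed = x$n_imputed)
}

#' Cross-validated choice of the ridge weight
#'
#' k-fold cross-validation over a lambda grid with a seeded fold
#' assignment; standardization is re-estimated inside each training fold.
#'
#' @inheritParams ridge_fit
#' @param lambda_grid Candidate weights.
#' @param k Number of folds (>= 2).
#' @param seed Fold-assignment seed.
#' @returns The grid value with the smallest mean held-out squared error,
#'   with the full CV trace in the `"cv"` attribute (tibble `lambda`,
#'   `mse`).
#' @export
cv_lambda <- function(X, y, lambda_grid = 10^seq(-3, 3, length.out = 13),
                      k = 5, seed = NULL) {
  X <- as.matrix(as.data.frame(X))
  if (k < 2) abort("k must be >= 2")
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  mse <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- ridge_fit(X[tr, , drop = FALSE], y[tr], lam)
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, fit$center), 2,
                   fit$scale, "/")
      pred <- fit$beta0 + as.numeric(Xte %*% fit$beta)
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- lambda_grid[which.min(mse)]
  structure(best, cv = tibble(lambda = lambda_grid, mse = mse))
}

#' Feature importance ranking
#'
#' Features ordered by decreasing coefficient magnitude (the sign of a
#' ridge coefficient can be unreliable under collinearity; its magnitude
#' still ranks importance). Ties keep the original feature order (stable
#' sort).
#'
#' @param fit A [ridge_fit()] result.
#' @returns Tibble with columns `rank`, `term`, `estimate`, `abs_estimate`.
#' @export
importance_ranking <- function(fit) {
  stopifnot(inherits(fit, "wm_ridge"))
  ord <- order(-abs(fit$beta))  # radix/stable for ties
  tibble(rank = seq_along(ord), term = names(fit$beta)[ord],
         estimate = unname(fit$beta)[ord],
         abs_estimate = abs(unname(fit$beta))[ord])
}
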