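#' Build the lagged regression problem for VAR identification
#'
#' Returns the predicted-value matrix `y` (`(N-p) x M`, rows `p+1..N` of the
#' data) and the regressor matrix `yp` (`(N-p) x M*p`) whose row for time
#' `n` stacks `[row n-1, ..., row n-p]`; column block `k` (columns
#' `(k-1)*M+1 .. k*M`) is the data delayed by `k` steps.
#'
#' @param data numeric `N x M` matrix, rows = time steps.
#' @param p model order; requires `N > p`.
#' @return list with `y`, `yp`, `p`, `labels`.
#' @export
build_regression <- function(data, p) {
  data <- as.matrix(data)
  N <- nrow(data); M <- ncol(data)
  stopifnot(is_count(p))
  if (N <= p) stop(sprintf("need more rows (%d) than the order (%d)", N, p))
  if (anyNA(data)) stop("`data` contains missing values")
  idx <- (p + 1):N
  yp <- do.call(cbind, lapply(seq_len(p), function(k) data[idx - k, , drop = FALSE]))
  colnames(yp) <- paste0(rep(colnames(data) %||% default_labels(M), p),
                         ".l", rep(seq_len(p), each = M))
  list(y = data[idx, , drop = FALSE], yp = yp, p = p,
       labels = colnames(data) %||% default_labels(M))
}

# stacked (Mp x M) coefficient matrix -> list of p (M x M) lag matrices in
# the package's row = source, column = target orientation
unstack_coeffs <- function(A_stacked, M, p) {
  lapply(seq_len(p), function(k)
    A_stacked[((k - 1) * M + 1):(k * M), , drop = FALSE])
}

#' Ordinary least squares VAR identification
#'
#' Closed-form minimizer of the residual sum of squares of the lagged
#' regression; the innovation covariance is the residual covariance with the
#' unbiased divisor `N - p - M*p`. When the regressor Gram matrix is
#' numerically singular (the regime where the number of usable rows does not
#' exceed the number of coefficients per equation) a `singular_regression`
#' error is raised.
#'
#' @param data numeric `N x M` matrix.
#' @param p model order.
#' @param rcond_tol reciprocal-condition threshold below which the Gram
#'   matrix is treated as singular.
#' @return a [var_model()].
#' @export
identify_ols <- function(data, p, rcond_tol = 1e-12) {
  reg <- build_regression(data, p)
  M <- ncol(reg$y); NR <- nrow(reg$y)
  G <- crossprod(reg$yp)
  rc <- rcond(G)
  if (!is.finite(rc) || rc < rcond_tol)
    stop_with("singular_regression",
              sprintf(paste0("regressor Gram matrix is numerically singular ",
                             "(rcond %.3e); %d rows for %d coefficients per ",
                             "equation"), rc, NR, M * p))
  A_hat <- solve(G, crossprod(reg$yp, reg$y))
  resid <- reg$y - reg$yp %*% A_hat
  dof <- NR - M * p
  if (dof < 1)
    stop_with("singular_regression",
              "no residual degrees of freedom for the innovation covariance")
  sigma <- crossprod(resid) / dof
  var_model(unstack_coeffs(A_hat, M, p), sigma, labels = reg$labels)
}

#' LASSO VAR identification with hold-out selection of the penalty
#'
#' Fits the l1-penalized regression over a descending grid of penalty
#' values whose largest element zeroes every coefficient. The single global
#' penalty (shared across all target channels, equivalent to an element-wise
#' l1 norm on the whole coefficient matrix) is selected by repeated random
#' hold-out: on each repeat, 90% of the regression rows (drawn uniformly
#' without replacement) form the training set and the remainder the test
#' set; both are standardized to zero mean and unit variance per column; the
#' model is fit on the training rows for every grid value, and the test
#' residual sum of squares and the number of non-zero coefficients are
#' recorded. The selected penalty is, by default, the largest grid value
#' whose mean test RSS lies within one standard error (across repeats) of
#' the minimum — the classical sparsity-favoring one-standard-error rule,
#' under which the selected penalty grows as data become scarce.
#' `selection = "min"` takes the RSS minimizer, and `selection = "ratio"`
#' minimizes mean(test RSS) / mean(non-zero count) (grid values with empty
#' mean support excluded); the ratio rule tends to select dense solutions
#' and is provided for comparison. The final model is refit on all rows at
#' the selected penalty
#' and its coefficients are rescaled to the original units; coefficients
#' below `zero_tol` in magnitude after rescaling are set to exact zero. The
#' innovation covariance is the residual covariance of the final sparse fit
#' on the full data (divisor `N - p`).
#'
#' @param data numeric `N x M` matrix.
#' @param p model order.
#' @param grid_size number of penalty values.
#' @param repeats hold-out repetitions.
#' @param test_fraction fraction of rows held out for testing.
#' @param seed optional integer controlling the hold-out splits.
#' @param selection penalty-selection rule; see Details above.
#' @param lambda optional fixed penalty (on the standardized scale used by
#'   the grid); when given, cross-validation is skipped.
#' @param zero_tol magnitude below which a rescaled coefficient counts as
#'   zero.
#' @param thresh,maxit coordinate-descent convergence threshold and
#'   iteration cap for the final fit (tighten for near-zero penalties on
#'   ill-conditioned data).
#' @return list with `model` (a [var_model()]; a fully disconnected model is
#'   possible and valid) and `cv` (class `lasso_cv`: `lambda_grid`,
#'   `mean_test_rss`, `mean_nonzero`, `chosen_lambda`, `repeats`; `NULL`
#'   when `lambda` was fixed).
#' @export
identify_lasso <- function(data, p, grid_size = 300L, repeats = 10L,
                           test_fraction = 0.10, seed = NULL,
                           selection = c("1se", "min", "ratio"),
                           lambda = NULL, zero_tol = 1e-12,
                           thresh = 1e-10, maxit = 1e6) {
  selection <- match.arg(selection)
  reg <- build_regression(data, p)
  M <- ncol(reg$y); NR <- nrow(reg$y)
  zscore <- function(x) {
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    list(x = sweep(sweep(x, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
  }
  full_x <- zscore(reg$yp); full_y <- zscore(reg$y)
  # largest penalty that zeroes all coefficients of every target, on the
  # standardized data and glmnet's 1/(2n) loss scale
  lam_max <- max(abs(crossprod(full_x$x, full_y$x))) / NR
  grid <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = grid_size))

  fit_targets <- function(x, y, lam, thresh, maxit = 1e5) {
    lapply(seq_len(M), function(j)
      # a path truncated by the solver at the dense end is expected under
      # data paucity and handled by the accumulation below, so the solver's
      # convergence warnings are muffled
      withCallingHandlers(
        glmnet::glmnet(x, y[, j], family = "gaussian", lambda = lam,
                       standardize = FALSE, intercept = FALSE,
                       thresh = thresh, maxit = maxit),
        warning = function(w) {
          if (grepl("glmnet C\\+\\+ code", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }))
  }

  cv <- NULL
  if (is.null(lambda)) {
    n_test <- max(1L, round(test_fraction * NR))
    rss <- matrix(0, repeats, grid_size)
    nnz <- matrix(0, repeats, grid_size)
    cnt <- matrix(0L, repeats, grid_size)
    for (r in seq_len(repeats)) {
      test_idx <- with_seed(derive_seed(seed, r),
                            sample.int(NR, n_test))
      tr_x <- zscore(reg$yp[-test_idx, , drop = FALSE])
      tr_y <- zscore(reg$y[-test_idx, , drop = FALSE])
      te_x <- zscore(reg$yp[test_idx, , drop = FALSE])
      te_y <- zscore(reg$y[test_idx, , drop = FALSE])
      fits <- fit_targets(tr_x$x, tr_y$x, grid, thresh = 1e-8)
      for (j in seq_len(M)) {
        # fits carry the full supplied grid, so predict over the fitted
        # sequence directly (no per-lambda interpolation)
        pred <- stats::predict(fits[[j]], newx = te_x$x)
        cols <- match(round(fits[[j]]$lambda, 12), round(grid, 12))
        rss[r, cols] <- rss[r, cols] + colSums((te_y$x[, j] - pred)^2)
        nnz[r, cols] <- nnz[r, cols] + fits[[j]]$df
        cnt[r, cols] <- cnt[r, cols] + 1L
      }
      # a truncated path (solver gave up at the dense end) leaves some grid
      # values without all M target fits; those cells are not comparable
      rss[r, cnt[r, ] < M] <- NA
      nnz[r, cnt[r, ] < M] <- NA
    }
    mean_rss <- colMeans(rss, na.rm = TRUE)
    mean_nnz <- colMeans(nnz, na.rm = TRUE)
    n_ok <- colSums(!is.na(rss))
    se_rss <- apply(rss, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
    mean_rss[n_ok == 0] <- Inf  # never selectable
    i_min <- which.min(mean_rss)
    i_sel <- switch(selection,
      # largest penalty whose mean hold-out RSS is within one standard
      # error of the minimum (sparsity-favoring; the default)
      "1se" = min(which(mean_rss <= mean_rss[i_min] +
                          (if (is.finite(se_rss[i_min])) se_rss[i_min] else 0))),
      "min" = i_min,
      # literal ratio of mean test RSS to mean support size; penalties with
      # an empty mean support are excluded
      "ratio" = which.min(ifelse(mean_nnz > 0, mean_rss / mean_nnz, Inf)))
    lambda <- grid[i_sel]
    cv <- structure(
      list(lambda_grid = grid, mean_test_rss = mean_rss,
           se_test_rss = se_rss, mean_nonzero = mean_nnz,
           chosen_lambda = lambda, selection = selection,
           repeats = repeats),
      class = "lasso_cv"
    )
  }

  # refit along the grid down to the chosen penalty (warm-started path fits
  # are more accurate than a cold single-penalty fit), then extract there
  fit_grid <- if (any(grid == lambda)) grid[grid >= lambda] else
    sort(unique(c(grid[grid >= lambda], lambda)), decreasing = TRUE)
  fits <- fit_targets(full_x$x, full_y$x, fit_grid, thresh = thresh,
                      maxit = maxit)
  A_std <- vapply(fits, function(f)
    as.numeric(stats::coef(f, s = lambda, exact = FALSE)[-1, 1]),
    numeric(M * p))
  # back-transform to original units: b = b_std * sd_y[j] / sd_x[c]
  A_hat <- A_std * outer(1 / full_x$sd, full_y$sd)
  A_hat[abs(A_hat) < zero_tol] <- 0
  resid <- reg$y - reg$yp %*% A_hat
  resid <- sweep(resid, 2, colMeans(resid))
  sigma <- crossprod(resid) / NR
  list(model = var_model(unstack_coeffs(A_hat, M, p), sigma,
                         labels = reg$labels),
       cv = cv)
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf("LASSO hold-out selection: %d penalty values, %d repeats\n",
              length(x$lambda_grid), x$repeats))
  i <- which(x$lambda_grid == x$chosen_lambda)[1]
  cat(sprintf("  chosen lambda %.4g (mean test RSS %.4g, mean support %.1f)\n",
              x$chosen_lambda, x$mean_test_rss[i], x$mean_nonzero[i]))
  invisible(x)
}

#' Select the VAR order by the Bayesian Information Criterion
#'
#' Fits OLS models of order `1..p_max` on a common set of predicted rows
#' (the last `N - p_max`, held fixed across candidates so criteria are
#' comparable) and returns the order minimizing
#' `N' * ln det(Sigma_p) + ln(N') * p * M^2`, where `Sigma_p` is the
#' maximum-likelihood residual covariance and `N' = N - p_max`. Orders at
#' which the regression is singular are skipped with a warning.
#'
#' @param data numeric `N x M` matrix.
#' @param p_max largest candidate order.
#' @return the selected order (integer).
#' @export
select_order_bic <- function(data, p_max) {
  data <- as.matrix(data)
  N <- nrow(data); M <- ncol(data)
  stopifnot(is_count(p_max), N > p_max * M + p_max)
  Np <- N - p_max
  idx <- (p_max + 1):N
  bic <- rep(NA_real_, p_max)
  for (p in seq_len(p_max)) {
    yp <- do.call(cbind, lapply(seq_len(p), function(k)
      data[idx - k, , drop = FALSE]))
    y <- data[idx, , drop = FALSE]
    G <- crossprod(yp)
    rc <- rcond(G)
    if (!is.finite(rc) || rc < 1e-12) {
      warning(sprintf("order %d skipped: singular regression", p))
      next
    }
    resid <- y - yp %*% solve(G, crossprod(yp, y))
    S <- crossprod(resid) / Np
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) {
      warning(sprintf("order %d skipped: degenerate residual covariance", p))
      next
    }
    bic[p] <- Np * as.numeric(d$modulus) + log(Np) * p * M^2
  }
  if (all(is.na(bic))) stop("BIC selection failed at every candidate order")
  which.min(bic)
}
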