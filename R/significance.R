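#' Iterative amplitude-adjusted Fourier transform (IAAFT) surrogate
#'
#' Generates a randomized series that preserves the original amplitude
#' distribution exactly (the multiset of values is identical) and the power
#' spectrum approximately, by alternating spectrum matching (replace Fourier
#' amplitudes with the original ones, keep phases) and rank remapping
#' (replace values by the sorted originals in rank order), starting from a
#' random permutation. Iteration stops when the rank ordering reaches a
#' fixed point or `max_iter` is hit. Applied to a matrix, each column is
#' surrogated independently — preserving every channel's spectrum while
#' destroying all cross-channel coupling.
#'
#' @param x numeric vector (one channel) or `N x M` matrix.
#' @param seed optional integer.
#' @param max_iter iteration cap.
#' @return surrogate of the same shape as `x`.
#' @export
iaaft_surrogate <- function(x, seed = NULL, max_iter = 100L) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x)))
      out[, j] <- iaaft_surrogate(x[, j], seed = derive_seed(seed, j),
                                  max_iter = max_iter)
    return(out)
  }
  N <- length(x)
  stopifnot(N >= 16)
  amp <- Mod(stats::fft(x))
  sorted_x <- sort(x)
  ranks <- with_seed(seed, sample.int(N))
  s <- x[ranks]
  prev_order <- NULL
  for (it in seq_len(max_iter)) {
    # spectrum step: impose original amplitudes, keep current phases
    ft <- stats::fft(s)
    mod <- Mod(ft)
    mod[mod == 0] <- 1
    s2 <- Re(stats::fft(ft * (amp / mod), inverse = TRUE)) / N
    # amplitude step: remap to the original value multiset by rank
    ord <- rank(s2, ties.method = "first")
    s <- sorted_x[ord]
    if (!is.null(prev_order) && identical(ord, prev_order)) break
    prev_order <- ord
  }
  s
}

new_significance_mask <- function(mask, method, threshold = NULL,
                                  n_surrogates = NA_integer_) {
  diag(mask) <- FALSE
  structure(
    list(mask = mask, method = method, threshold = threshold,
         n_surrogates = n_surrogates),
    class = "significance_mask"
  )
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf("Significance mask (%s): %d of %d directed links significant\n",
              x$method, sum(x$mask), nrow(x$mask) * (nrow(x$mask) - 1)))
  invisible(x)
}

#' Surrogate-data significance test for the conditional TE network
#'
#' Estimates the conditional transfer entropy matrix from an OLS fit of the
#' data, then builds a per-link null distribution from `n_surrogates`
#' surrogate datasets in which every channel is independently IAAFT-
#' randomized (same spectra, no cross-coupling), each refit by OLS with the
#' cTE matrix recomputed. A link is significant when the observed cTE
#' strictly exceeds the stated percentile of its surrogate distribution
#' (ties count as not significant). Surrogates on which identification or
#' the Riccati solve fails are dropped with a warning; at least half must
#' survive.
#'
#' @param data numeric `N x M` matrix.
#' @param p VAR order for identification.
#' @param n_surrogates surrogate datasets generated.
#' @param percentile threshold percentile of the per-link null.
#' @param seed optional integer.
#' @return An object of class `significance_mask` with fields `mask` (`M x
#'   M` logical, diagonal `FALSE`), `method = "surrogate"`, `threshold`
#'   (per-link percentile values), `n_surrogates` (usable count); the
#'   observed cTE matrix is attached as attribute `observed`.
#' @export
surrogate_significance_cte <- function(data, p, n_surrogates = 100L,
                                       percentile = 95, seed = NULL) {
  data <- as.matrix(data)
  M <- ncol(data)
  observed <- cte_matrix(identify_ols(data, p))
  surr <- array(NA_real_, c(M, M, n_surrogates))
  usable <- 0L
  for (s in seq_len(n_surrogates)) {
    cte_s <- tryCatch({
      sd_ <- iaaft_surrogate(data, seed = derive_seed(seed, 7919L + s))
      suppressWarnings(cte_matrix(identify_ols(sd_, p)))
    }, error = function(e) {
      warning(sprintf("surrogate %d dropped: %s", s, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(cte_s)) {
      usable <- usable + 1L
      surr[, , usable] <- cte_s
    }
  }
  if (usable < ceiling(n_surrogates / 2))
    stop(sprintf("only %d of %d surrogates usable", usable, n_surrogates))
  thr <- apply(surr[, , seq_len(usable), drop = FALSE], c(1, 2),
               stats::quantile, probs = percentile / 100, na.rm = TRUE)
  diag(thr) <- NA_real_
  mask <- !is.na(observed) & !is.na(thr) & observed > thr
  out <- new_significance_mask(mask, "surrogate", threshold = thr,
                               n_surrogates = usable)
  attr(out, "observed") <- observed
  out
}

#' Sparsity-based significance for a LASSO-identified model
#'
#' For a sparse model, the conditional transfer entropy along a direction is
#' exactly zero precisely when every lag coefficient on that direction is
#' zero; a directed link is therefore declared significant when at least one
#' of its lag coefficients is non-zero. Purely deterministic in the model.
#'
#' @param model a [var_model()] (typically from [identify_lasso()]).
#' @param tol coefficient magnitude treated as zero.
#' @return An object of class `significance_mask` with `method = "sparsity"`.
#' @export
sparsity_significance_cte <- function(model, tol = 1e-12) {
  new_significance_mask(coefficient_support(model, tol), "sparsity")
}
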