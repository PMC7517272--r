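# Information measures for jointly Gaussian VAR processes. All are log
# ratios of partial variances (natural log, nats) obtained from the ISS
# representation via DARE submodels.

pv <- function(iss, target, a, tol, max_iter) {
  submodel_partial_variance(iss, target, a, tol = tol, max_iter = max_iter)$value
}

#' Transfer entropy from a source (set) to a target channel
#'
#' \eqn{T_{i \to j} = \frac{1}{2}\ln(\lambda_{j|j} / \lambda_{j|ij})}: the
#' information the past of the source channels adds about the target's
#' present beyond the target's own past. Multi-channel source sets are
#' supported (the set is treated jointly).
#'
#' @param model a [var_model()] or [var_to_iss()] result.
#' @param source source channel index or index set, disjoint from `target`.
#' @param target target channel index `j`.
#' @param tol,max_iter DARE iteration control.
#' @return transfer entropy in nats.
#' @export
#' @examples
#' transfer_entropy(build_simulation1_model(), 2, 4)
transfer_entropy <- function(model, source, target, tol = 1e-12,
                             max_iter = 10000L) {
  iss <- as_iss(model)
  check_disjoint(source = source, target = target)
  l_own <- pv(iss, target, target, tol, max_iter)
  l_full <- pv(iss, target, c(source, target), tol, max_iter)
  0.5 * log(l_own / l_full)
}

#' Joint transfer entropy from two source sets to a target
#'
#' \eqn{T_{ik \to j} = \frac{1}{2}\ln(\lambda_{j|j} / \lambda_{j|ijk})}: the
#' information the two source sets taken together add about the target's
#' present beyond the target's own past.
#'
#' @param model a [var_model()] or [var_to_iss()] result.
#' @param source_i,source_k disjoint source index sets.
#' @param target target channel index.
#' @param tol,max_iter DARE iteration control.
#' @return joint transfer entropy in nats.
#' @export
joint_transfer_entropy <- function(model, source_i, source_k, target,
                                   tol = 1e-12, max_iter = 10000L) {
  iss <- as_iss(model)
  check_disjoint(source_i = source_i, source_k = source_k, target = target)
  l_own <- pv(iss, target, target, tol, max_iter)
  l_full <- pv(iss, target, c(source_i, source_k, target), tol, max_iter)
  0.5 * log(l_own / l_full)
}

#' Conditional transfer entropy
#'
#' \eqn{T_{i \to j | s} = \frac{1}{2}\ln(\lambda_{j|js} / \lambda_{j|ijs})}:
#' the information the source's past adds about the target's present beyond
#' the past of the target *and* of the conditioning channels. With an empty
#' conditioning set this reduces exactly to [transfer_entropy()]. A non-zero
#' value marks a direct coupling (conditional Granger causality in the
#' Gaussian case).
#'
#' @param model a [var_model()] or [var_to_iss()] result.
#' @param source source index set.
#' @param target target channel index.
#' @param conditioning index set `s` (may be empty); `source`, `target`,
#'   `conditioning` must be pairwise disjoint.
#' @param tol,max_iter DARE iteration control.
#' @return conditional transfer entropy in nats.
#' @export
conditional_transfer_entropy <- function(model, source, target,
                                         conditioning = integer(0),
                                         tol = 1e-12, max_iter = 10000L) {
  iss <- as_iss(model)
  check_disjoint(source = source, target = target, conditioning = conditioning)
  l_red <- pv(iss, target, c(target, conditioning), tol, max_iter)
  l_full <- pv(iss, target, c(source, target, conditioning), tol, max_iter)
  0.5 * log(l_red / l_full)
}

#' Partial information decomposition of the joint transfer entropy
#'
#' Splits the joint transfer entropy from two source sets into unique,
#' redundant and synergistic components under the minimum-mutual-information
#' rule for Gaussian systems: the redundancy is the minimum of the two
#' individual transfer entropies, and
#' \deqn{T_{ik\to j} = U_{i\to j} + U_{k\to j} + R_{ik\to j} + S_{ik\to j}}
#' holds exactly by construction, as do \eqn{T_{i\to j} = U_{i\to j} +
#' R_{ik\to j}} and \eqn{T_{k\to j} = U_{k\to j} + R_{ik\to j}}.
#'
#' @param model a [var_model()] or [var_to_iss()] result.
#' @param source_i,source_k disjoint source index sets.
#' @param target target channel index.
#' @param tol,max_iter DARE iteration control.
#' @return An object of class `pid_result`: list with `joint`, `t_i`, `t_k`,
#'   `unique_i`, `unique_k`, `redundant`, `synergistic` (all in nats, raw
#'   floating-point values; tiny negatives are not clamped here).
#' @export
#' @examples
#' pid_decompose(build_simulation1_model(), 2, 3, 4)
pid_decompose <- function(model, source_i, source_k, target,
                          tol = 1e-12, max_iter = 10000L) {
  iss <- as_iss(model)
  check_disjoint(source_i = source_i, source_k = source_k, target = target)
  l_own <- pv(iss, target, target, tol, max_iter)
  t_i <- 0.5 * log(l_own / pv(iss, target, c(source_i, target), tol, max_iter))
  t_k <- 0.5 * log(l_own / pv(iss, target, c(source_k, target), tol, max_iter))
  joint <- 0.5 * log(l_own /
    pv(iss, target, c(source_i, source_k, target), tol, max_iter))
  redundant <- min(t_i, t_k)
  structure(
    list(joint = joint, t_i = t_i, t_k = t_k,
         unique_i = t_i - redundant, unique_k = t_k - redundant,
         redundant = redundant,
         synergistic = joint - t_i - t_k + redundant,
         target = target, source_i = source_i, source_k = source_k),
    class = "pid_result"
  )
}

#' @export
print.pid_result <- function(x, digits = 4, ...) {
  fmt <- function(v) formatC(max(v, 0), digits = digits, format = "f")
  cat(sprintf("PID of transfer to channel %s from {%s} and {%s} (nats):\n",
              paste(x$target, collapse = ","),
              paste(x$source_i, collapse = ","),
              paste(x$source_k, collapse = ",")))
  cat("  joint:      ", fmt(x$joint), "\n")
  cat("  T_i, T_k:   ", fmt(x$t_i), ", ", fmt(x$t_k), "\n", sep = "")
  cat("  unique:     ", fmt(x$unique_i), ", ", fmt(x$unique_k), "\n", sep = "")
  cat("  redundant:  ", fmt(x$redundant), "\n")
  cat("  synergistic:", fmt(x$synergistic), "\n")
  invisible(x)
}

#' Conditional transfer entropy between every pair of channels
#'
#' Entry `(i, j)` is the conditional transfer entropy from channel `i` to
#' channel `j` given all remaining channels; the diagonal is `NA`. One DARE
#' solve per excluded source yields the whole column set at once. A DARE
#' failure on an entry is recorded as `NA` with a warning rather than
#' aborting the matrix.
#'
#' @param model a [var_model()] or [var_to_iss()] result.
#' @param tol,max_iter DARE iteration control.
#' @return `M x M` numeric matrix (row = source, column = target).
#' @export
cte_matrix <- function(model, tol = 1e-12, max_iter = 10000L) {
  iss <- as_iss(model)
  M <- iss$M
  if (M < 2) stop("cte_matrix requires at least 2 channels")
  out <- matrix(NA_real_, M, M, dimnames = list(iss$labels, iss$labels))
  # lambda_{j | all} is exactly phi[j, j] (full observation set)
  l_full <- diag(iss$phi)
  for (i in seq_len(M)) {
    a <- setdiff(seq_len(M), i)
    phi_a <- tryCatch(
      submodel_innovation_cov(iss, a, tol = tol, max_iter = max_iter)$phi,
      dare_error = function(e) {
        warning(sprintf("cTE from channel %d: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(phi_a)) next
    for (j in a)
      out[i, j] <- 0.5 * log(phi_a[match(j, a), match(j, a)] / l_full[j])
  }
  out
}

check_disjoint <- function(...) {
  sets <- list(...)
  idx <- unlist(sets)
  if (anyDuplicated(idx))
    stop(sprintf("index sets must be pairwise disjoint (%s)",
                 paste(names(sets), collapse = ", ")))
  invisible(TRUE)
}
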