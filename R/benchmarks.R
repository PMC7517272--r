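# End-to-end simulation benchmarks: per-K bias/variance of PID estimates on
# the four-variate oscillator network, and cTE bias + link-classification
# performance on random ten-variate sparse networks.

#' Absolute and normalized bias of an estimated cTE matrix
#'
#' Per directed link, the absolute error `|T - That|` is evaluated on null
#' links (no true coupling, theoretical cTE zero) and the normalized error
#' `|(T - That)/T|` on non-null links; `BIAS` and `BIASN` are their means
#' over the respective link sets. The normalized form is only ever evaluated
#' where the theoretical value is positive.
#'
#' @param theoretical,estimated `M x M` cTE matrices (diagonal ignored).
#' @param adjacency `M x M` logical ground-truth adjacency.
#' @return list with `BIAS` (mean absolute error, null links) and `BIASN`
#'   (mean normalized error, non-null links).
#' @export
bias_metrics <- function(theoretical, estimated, adjacency) {
  stopifnot(all(dim(theoretical) == dim(estimated)),
            all(dim(theoretical) == dim(adjacency)))
  off <- !diag(nrow(adjacency))
  null_links <- off & !adjacency
  true_links <- off & adjacency & theoretical > 0
  err <- abs(theoretical - estimated)
  list(BIAS = mean(err[null_links], na.rm = TRUE),
       BIASN = mean((err / theoretical)[true_links], na.rm = TRUE))
}

#' Link-classification performance against a ground-truth network
#'
#' Treats detection of each off-diagonal directed link as a binary
#' classification: `FPR` is the fraction of null links detected, `FNR` the
#' fraction of true links missed, and `ACC` the fraction of all off-diagonal
#' links classified correctly. A class with no members yields `NA` for its
#' rate.
#'
#' @param truth `M x M` logical adjacency.
#' @param detected a `significance_mask` or `M x M` logical matrix.
#' @return list with `FPR`, `FNR`, `ACC`.
#' @export
classification_metrics <- function(truth, detected) {
  if (inherits(detected, "significance_mask")) detected <- detected$mask
  stopifnot(all(dim(truth) == dim(detected)))
  off <- !diag(nrow(truth))
  n_null <- sum(off & !truth); n_true <- sum(off & truth)
  fp <- sum(off & !truth & detected)
  fn <- sum(off & truth & !detected)
  list(FPR = if (n_null > 0) fp / n_null else NA_real_,
       FNR = if (n_true > 0) fn / n_true else NA_real_,
       ACC = 1 - (fp + fn) / sum(off))
}

#' Weighted in-strength of network nodes
#'
#' Sum of the weights of all significant links pointing into each node
#' (weights oriented row = source, column = target). With `nodes` given, the
#' node set is treated as a single super-node and only links entering it
#' from outside the set are counted, returning one number.
#'
#' @param weights `M x M` numeric link weights.
#' @param mask a `significance_mask` or `M x M` logical matrix.
#' @param nodes optional index set to treat as one grouped super-node.
#' @return named numeric vector of per-node in-strengths, or a single value
#'   when `nodes` is given.
#' @export
in_strength <- function(weights, mask, nodes = NULL) {
  if (inherits(mask, "significance_mask")) mask <- mask$mask
  stopifnot(all(dim(weights) == dim(mask)))
  w <- weights
  w[!mask | is.na(weights)] <- 0
  diag(w) <- 0
  if (is.null(nodes)) {
    out <- colSums(w)
    names(out) <- colnames(weights) %||% default_labels(ncol(weights))
    return(out)
  }
  outside <- setdiff(seq_len(nrow(w)), nodes)
  sum(w[outside, nodes, drop = FALSE])
}

sim1_measure_names <- c("T2", "T3", "R23", "S23", "U2", "U3", "joint")

sim1_pid_vector <- function(model, target) {
  pid <- pid_decompose(model, 2, 3, target)
  c(T2 = pid$t_i, T3 = pid$t_k, R23 = pid$redundant, S23 = pid$synergistic,
    U2 = pid$unique_i, U3 = pid$unique_k, joint = pid$joint)
}

#' Benchmark I: bias and variance of PID estimates on the oscillator network
#'
#' For each value of the data-paucity ratio `K = N / (M*p)` and each
#' realization, simulates `N = K * 8` samples of the four-variate VAR(2)
#' oscillator benchmark, identifies a VAR(2) by each requested method, and
#' computes the full PID (sources {2} and {3}) for targets 4 and 1.
#' Estimates are summarized per (K, method, target, measure) as bias
#' (absolute difference between the mean estimate and the theoretical value
#' from the true parameters) and sample variance across realizations.
#' Identification or Riccati failures on individual realizations (expected
#' for OLS at `K = 1`) are counted, not fatal.
#'
#' @param k_values ratios of sample count to coefficients per equation.
#' @param n_realizations realizations per K.
#' @param base_seed integer; per-realization seeds derive from it, so
#'   results are reproducible and independent of evaluation order.
#' @param methods subset of `c("ols", "lasso")`.
#' @param lasso_repeats,lasso_grid_size hold-out settings passed through.
#' @return An object of class `benchmark_report`: list with `results`
#'   (tidy data frame: K, realization, method, target, measure, value),
#'   `summary` (bias/variance per cell), `theoretical` (named values per
#'   target), and `failures`.
#' @export
run_simulation1 <- function(k_values = c(1, 2, 5, 10, 30),
                            n_realizations = 100L, base_seed = 1L,
                            methods = c("ols", "lasso"),
                            lasso_repeats = 10L, lasso_grid_size = 300L) {
  methods <- match.arg(methods, several.ok = TRUE)
  true_model <- build_simulation1_model()
  theoretical <- list("4" = sim1_pid_vector(true_model, 4),
                      "1" = sim1_pid_vector(true_model, 1))
  rows <- list(); failures <- list()
  for (K in k_values) {
    N <- K * true_model$M * true_model$p
    for (r in seq_len(n_realizations)) {
      sim_seed <- derive_seed(base_seed, K * 100000L + r)
      y <- simulate_var(true_model, N, seed = sim_seed)
      for (method in methods) {
        fit <- tryCatch(
          switch(method,
                 ols = identify_ols(y, 2),
                 lasso = identify_lasso(y, 2, grid_size = lasso_grid_size,
                                        repeats = lasso_repeats,
                                        seed = derive_seed(sim_seed, 17L))$model),
          error = function(e) NULL)
        vals <- if (is.null(fit)) NULL else tryCatch(
          list("4" = sim1_pid_vector(fit, 4), "1" = sim1_pid_vector(fit, 1)),
          error = function(e) NULL)
        if (is.null(vals)) {
          failures[[length(failures) + 1L]] <-
            data.frame(K = K, realization = r, method = method)
          next
        }
        for (target in c("4", "1"))
          rows[[length(rows) + 1L]] <- data.frame(
            K = K, realization = r, method = method, target = target,
            measure = names(vals[[target]]), value = unname(vals[[target]]))
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (is.null(results)) NULL else do.call(rbind, lapply(split(
    results, results[c("K", "method", "target", "measure")], drop = TRUE),
    function(d) data.frame(
      K = d$K[1], method = d$method[1], target = d$target[1],
      measure = d$measure[1],
      bias = abs(mean(d$value) - theoretical[[d$target[1]]][[d$measure[1]]]),
      variance = stats::var(d$value), n = nrow(d))))
  if (!is.null(summary)) rownames(summary) <- NULL
  structure(
    list(results = results, summary = summary, theoretical = theoretical,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         simulation = "I"),
    class = "benchmark_report"
  )
}

#' Benchmark II: cTE bias and network reconstruction on random networks
#'
#' For each `K` and realization, draws a fresh random ground-truth network
#' (ten channels, VAR(10), density 0.5, coefficients uniform in
#' `[-0.6, 0.6]`, innovation variance 0.1), simulates `N = K * 100`
#' samples, estimates the cTE matrix by each requested method, and scores
#' the estimate against the truth: `BIAS`/`BIASN` from [bias_metrics()] and
#' `FPR`/`FNR`/`ACC` from [classification_metrics()] using each method's
#' significance rule (IAAFT surrogates for OLS, coefficient support for
#' LASSO).
#'
#' @inheritParams run_simulation1
#' @param n_surrogates surrogate count for the OLS significance test.
#' @return An object of class `benchmark_report` with tidy `results`
#'   (K, realization, method, metric, value), per-(K, method) `summary`
#'   (mean and sd of each metric), and `failures`.
#' @export
run_simulation2 <- function(k_values = c(1, 2, 5, 10, 30),
                            n_realizations = 100L, base_seed = 1L,
                            methods = c("ols", "lasso"),
                            n_surrogates = 100L,
                            lasso_repeats = 10L, lasso_grid_size = 300L) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list(); failures <- list()
  for (K in k_values) {
    N <- K * 100L
    for (r in seq_len(n_realizations)) {
      net_seed <- derive_seed(base_seed, K * 100000L + r)
      gtn <- build_simulation2_model(seed = net_seed)
      y <- simulate_var(gtn$model, N, seed = derive_seed(net_seed, 3L))
      for (method in methods) {
        scored <- tryCatch({
          if (method == "ols") {
            mask <- surrogate_significance_cte(
              y, gtn$model$p, n_surrogates = n_surrogates,
              seed = derive_seed(net_seed, 5L))
            est <- attr(mask, "observed")
          } else {
            fit <- identify_lasso(y, gtn$model$p,
                                  grid_size = lasso_grid_size,
                                  repeats = lasso_repeats,
                                  seed = derive_seed(net_seed, 7L))$model
            mask <- sparsity_significance_cte(fit)
            est <- suppressWarnings(cte_matrix(fit))
          }
          c(bias_metrics(gtn$theoretical_cte, est, gtn$adjacency),
            classification_metrics(gtn$adjacency, mask))
        }, error = function(e) NULL)
        if (is.null(scored)) {
          failures[[length(failures) + 1L]] <-
            data.frame(K = K, realization = r, method = method)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, realization = r, method = method,
          metric = names(scored), value = unlist(scored, use.names = FALSE))
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (is.null(results)) NULL else do.call(rbind, lapply(split(
    results, results[c("K", "method", "metric")], drop = TRUE),
    function(d) data.frame(
      K = d$K[1], method = d$method[1], metric = d$metric[1],
      mean = mean(d$value, na.rm = TRUE),
      sd = stats::sd(d$value), n = nrow(d))))
  if (!is.null(summary)) rownames(summary) <- NULL
  structure(
    list(results = results, summary = summary,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         simulation = "II"),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark report (Simulation %s): %d scored evaluations, %d failures\n",
              x$simulation, if (is.null(x$results)) 0L else nrow(x$results),
              if (is.null(x$failures)) 0L else nrow(x$failures)))
  print(utils::head(x$summary, 20))
  invisible(x)
}
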