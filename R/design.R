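# Experiment-design calculators: how many transformants cover the mutation
# space, and how read length and phred score limit the fraction of error-free
# reads.

#' Probability that a read of length L is entirely error-free
#'
#' Given a per-base phred score q (per-base accuracy `1 - 10^(-q/10)`), the
#' probability that all L bases of a read are called correctly is
#' `(1 - 10^(-q/10))^L`, assuming independent errors.
#'
#' @param q Phred score (>= 0). Vectorized.
#' @param L Read/sequence length (>= 0). Vectorized.
#' @return Probability in (0, 1].
#' @export
#' @examples
#' error_free_fraction(30, 1)    # 0.999
#' error_free_fraction(30, 158)  # ~0.854
error_free_fraction <- function(q, L) {
  if (any(L < 0)) stop("L must be non-negative", call. = FALSE)
  if (any(q < 0)) stop("q must be non-negative", call. = FALSE)
  (1 - 10^(-q / 10))^L
}

# Size of the mutation space: 3L single substitutions, or 9*C(L,2) pairs of
# substitutions at two distinct positions.
mutation_space_size <- function(L, order = c("single", "double")) {
  order <- match.arg(order)
  M <- switch(order, single = 3 * L, double = 9 * choose(L, 2))
  if (M <= 0) stop("mutation space is empty for this L/order", call. = FALSE)
  M
}

#' Expected fraction of the mutation space covered at least k times
#'
#' Analytic per-mutation marginal for the coverage simulation: drawing n
#' transformants i.i.d. uniformly over a mutation space of size M, each
#' particular mutation is seen Binomial(n, 1/M) times, so the expected
#' fraction covered at least k times is `1 - pbinom(k - 1, n, 1/M)`.
#'
#' @param L Sequence length.
#' @param n Number of transformants drawn.
#' @param k Coverage threshold (>= 1).
#' @param order `"single"` (space 3L) or `"double"` (space 9*C(L,2); a
#'   transformant carries substitutions at two distinct positions).
#' @return Expected covered fraction in \[0, 1\].
#' @export
#' @examples
#' expected_coverage_fraction(109, 3000, k = 5)  # ~0.95
expected_coverage_fraction <- function(L, n, k = 1L, order = c("single", "double")) {
  stopifnot(n >= 0, k >= 1)
  M <- mutation_space_size(L, order)
  1 - pbinom(k - 1, size = n, prob = 1 / M)
}

#' Simulate mutant-library coverage under uniform random mutagenesis
#'
#' Each run draws `n_transformants` mutants i.i.d. from the mutation space
#' (uniformly by default, or with per-class weights) and records the fraction
#' of the space represented at least `k` times. The per-run fractions describe
#' how likely an error-prone-PCR library of a given size is to contain every
#' possible mutation at the required depth.
#'
#' @inheritParams expected_coverage_fraction
#' @param n_transformants Transformants drawn per run.
#' @param n_runs Number of independent runs.
#' @param seed Integer seed (mandatory; the RNG state is restored afterwards).
#' @param weights Optional non-negative weight per mutation-space class
#'   (length M) for a non-uniform mutational spectrum; default uniform.
#' @return An object of class `coverage_sim` with fields `L`,
#'   `n_transformants`, `order`, `k`, `per_run_fractions`, `seed`.
#' @export
#' @examples
#' cs <- simulate_coverage(109, 3000, n_runs = 50, k = 5, seed = 1)
#' mean(cs$per_run_fractions)
simulate_coverage <- function(L, n_transformants, n_runs = 1000L, k = 1L,
                              order = c("single", "double"), seed,
                              weights = NULL) {
  order <- match.arg(order)
  stopifnot(L >= 1, n_transformants >= 1, n_runs >= 1, k >= 1)
  M <- mutation_space_size(L, order)
  if (!is.null(weights)) {
    stopifnot(length(weights) == M, all(weights >= 0), sum(weights) > 0)
  }
  fractions <- with_local_seed(seed, {
    vapply(seq_len(n_runs), function(i) {
      draws <- if (is.null(weights)) {
        sample.int(M, n_transformants, replace = TRUE)
      } else {
        sample.int(M, n_transformants, replace = TRUE, prob = weights)
      }
      mean(tabulate(draws, nbins = M) >= k)
    }, numeric(1))
  })
  structure(
    list(L = L, n_transformants = n_transformants, order = order, k = k,
         per_run_fractions = fractions, seed = seed),
    class = "coverage_sim"
  )
}

#' @export
print.coverage_sim <- function(x, ...) {
  cat("coverage_sim: L=", x$L, ", ", x$order, " mutations, n=",
      x$n_transformants, ", k>=", x$k, ", ", length(x$per_run_fractions),
      " runs\n", sep = "")
  print(summary(x$per_run_fractions))
  invisible(x)
}

#' Summarize a coverage simulation
#'
#' @param object A `coverage_sim`.
#' @param ... Unused.
#' @return A list with mean, standard deviation, and boxplot quartiles of the
#'   per-run covered fractions.
#' @export
summary.coverage_sim <- function(object, ...) {
  f <- object$per_run_fractions
  list(mean = mean(f), sd = sd(f),
       quartiles = as.list(quantile(f, c(0, 0.25, 0.5, 0.75, 1))),
       analytic_mean = expected_coverage_fraction(
         object$L, object$n_transformants, object$k, object$order))
}

#' Monte-Carlo probability of full single-mutation coverage
#'
#' Estimates the probability that drawing `n` single-mutant transformants
#' uniformly covers every one of the 3L possible substitutions at least once
#' (the coupon-collector success probability).
#'
#' @param L Sequence length.
#' @param n Transformants per run.
#' @param n_runs Monte-Carlo runs.
#' @param seed Integer seed.
#' @return Estimated probability in \[0, 1\].
#' @export
prob_full_coverage <- function(L, n, n_runs = 1000L, seed) {
  if (n < 3 * L) return(0)  # pigeonhole
  cs <- simulate_coverage(L, n, n_runs = n_runs, k = 1L, order = "single",
                          seed = seed)
  mean(cs$per_run_fractions == 1)
}
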