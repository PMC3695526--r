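# Negative-binomial differential-abundance machinery for single-mutation
# counts: median-of-ratios size factors, method-of-moments dispersion
# estimation with a fitted mean-dispersion trend, a conditioned two-sided
# exact test on condition sums, and Benjamini-Hochberg correction.

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over mutations i (taken
#' over rows with all-positive counts) of `k_ij / geomean_v(k_iv)`. If no row
#' has all-positive counts the function falls back to column-total
#' normalization (scaled to geometric mean 1) with a warning.
#'
#' @param counts Non-negative integer matrix (mutations x samples).
#' @return Numeric vector of per-sample size factors.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 4, 2, 4, 8), ncol = 2)
#' size_factors(m)   # second column twice as deep
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok)) {
    warning("no mutation has positive counts in every sample; ",
            "falling back to column-total normalization", call. = FALSE)
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample(s) with all-zero counts", call. = FALSE)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts, 2L, function(col) {
    median(exp(log(col[ok]) - loggeo[ok]))
  })
}

#' Method-of-moments dispersion estimates with a fitted trend
#'
#' Normalized counts `q_ij = k_ij / s_j` give a per-mutation base mean
#' `qbar_i` and a pooled within-condition variance `v_i` (conditions with at
#' least two replicates contribute, weighted by their degrees of freedom).
#' The raw method-of-moments dispersion is
#' `alpha_raw_i = (v_i - qbar_i * zhat) / qbar_i^2` with
#' `zhat = qbar_i * mean(1/s_j)` (the shot-noise term). A smooth
#' mean-dispersion trend is fitted by local regression on the log scale over
#' rows with positive raw estimates, and the final per-mutation dispersion is
#' the conservative `max(alpha_raw, trend, floor)` -- with only a few
#' replicates the per-row estimate alone is too noisy.
#'
#' @param counts Count matrix (mutations x samples).
#' @param conditions Factor/character of condition labels per sample.
#' @param sf Size factors (default [size_factors()]).
#' @param floor Lower bound on the dispersion (default 1e-8).
#' @return Numeric vector of dispersions (NA for all-zero rows), with
#'   attributes `raw` and `trend`.
#' @export
estimate_dispersions <- function(counts, conditions, sf = size_factors(counts),
                                 floor = 1e-8) {
  counts <- as.matrix(counts)
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(counts), length(sf) == ncol(counts))
  reps <- table(conditions)
  if (!any(reps >= 2L)) {
    stop("at least one condition needs >= 2 replicates", call. = FALSE)
  }
  q <- sweep(counts, 2L, sf, "/")
  qbar <- rowMeans(q)
  # pooled within-condition variance, df-weighted
  ss <- 0
  df <- 0
  for (cond in names(reps)[reps >= 2L]) {
    sel <- conditions == cond
    qc <- q[, sel, drop = FALSE]
    ss <- ss + rowSums((qc - rowMeans(qc))^2)
    df <- df + sum(sel) - 1L
  }
  v <- ss / df
  zhat <- qbar * mean(1 / sf)
  alpha_raw <- ifelse(qbar > 0, (v - zhat) / qbar^2, NA_real_)

  # Trend: local regression of the variance-mean relationship on the log
  # scale over all rows (not only rows with positive raw dispersion, which
  # would bias the trend upward), then converted to a dispersion.
  use <- which(qbar > 0 & v > 0)
  trend <- rep(0, nrow(counts))
  if (length(use) >= 10L) {
    td <- data.frame(x = log(qbar[use]), y = log(v[use]))
    fit <- tryCatch(
      loess(y ~ x, data = td, span = 0.9, degree = 1, family = "symmetric"),
      error = function(e) NULL)
    if (!is.null(fit)) {
      x <- log(pmax(qbar, exp(min(td$x))))
      x <- pmin(x, max(td$x))                    # clamp: no extrapolation
      pred <- tryCatch(predict(fit, data.frame(x = x)),
                       error = function(e) rep(NA_real_, length(x)))
      v_fit <- ifelse(is.finite(pred), exp(pred), NA_real_)
      trend <- ifelse(is.finite(v_fit) & qbar > 0,
                      pmax((v_fit - zhat) / qbar^2, 0), 0)
    }
  }
  if (all(trend == 0) && length(use) > 0L) {
    a_pos <- alpha_raw[is.finite(alpha_raw) & alpha_raw > 0]
    if (length(use) < 10L && length(a_pos) > 0L) {
      trend <- rep(median(a_pos), nrow(counts))
    }
  }
  final <- pmax(ifelse(is.finite(alpha_raw), alpha_raw, 0), trend, floor)
  final[qbar == 0] <- NA_real_
  attr(final, "raw") <- alpha_raw
  attr(final, "trend") <- trend
  final
}

# Density of a sum of NB counts with common normalized mean q0, given size
# factors sf and dispersion alpha: mean mu = q0*sum(sf), raw variance
# v = mu + alpha*q0^2*sum(sf^2).
dnb_sum <- function(x, q0, sf, alpha) {
  mu <- q0 * sum(sf)
  v <- mu + alpha * q0^2 * sum(sf^2)
  if (v <= mu * (1 + 1e-12)) {
    dpois(x, lambda = mu)
  } else {
    size <- mu^2 / (v - mu)
    dnbinom(x, size = size, mu = mu)
  }
}

#' Conditioned negative-binomial exact test
#'
#' Tests whether the split of the pooled count `k_S = k_A + k_B` between two
#' conditions is surprising under a common-abundance null. The condition sums
#' are modeled as negative binomials whose means and variances are assembled
#' from the size factors and the dispersion; conditioning on `k_S`, the
#' two-sided p-value is the total probability of all partitions `a + b = k_S`
#' no more likely than the observed one:
#' `p = sum over {Pr(a,b) <= Pr(k_A,k_B)} Pr(a,b) / sum over all Pr(a,b)`.
#'
#' In the limit `alpha -> 0` with equal size factors this reduces to the
#' two-sided exact binomial test of `k_A` out of `k_S`.
#'
#' @param counts_a,counts_b Integer replicate counts for the mutation in each
#'   condition.
#' @param sf_a,sf_b Size factors of the corresponding samples.
#' @param alpha Dispersion for this mutation (>= 0).
#' @return Two-sided p-value in (0, 1\]; `NA` when `k_S == 0` (no test).
#' @export
nb_exact_test <- function(counts_a, counts_b, sf_a, sf_b, alpha) {
  ka <- sum(counts_a)
  kb <- sum(counts_b)
  ks <- ka + kb
  if (ks < 1L) return(NA_real_)
  q0 <- ks / (sum(sf_a) + sum(sf_b))
  a <- 0:ks
  pa <- dnb_sum(a, q0, sf_a, alpha)
  pb <- dnb_sum(ks - a, q0, sf_b, alpha)
  joint <- pa * pb
  tot <- sum(joint)
  if (tot <= 0) return(1)
  pobs <- joint[ka + 1L]
  min(1, sum(joint[joint <= pobs * (1 + 1e-7)]) / tot)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps [stats::p.adjust()]).
#'
#' @param p Vector of p-values (NA allowed; kept NA).
#' @return Adjusted p-values, monotone and >= p.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Per-mutation enrichment table for a two-condition contrast
#'
#' Runs the full testing pipeline on the samples belonging to the two
#' conditions: size factors (median of ratios on the contrast submatrix),
#' dispersion estimation, the conditioned NB exact test per mutation, and
#' Benjamini-Hochberg correction. A mutation is called `over` when its
#' adjusted p-value is below `alpha` and its normalized mean is higher in the
#' contrast condition than in the baseline, `under` in the opposite case, and
#' `ns` otherwise.
#'
#' Phenotypic sorting deliberately enriches a sizeable subset of mutations,
#' which violates the mostly-null assumption behind global median-of-ratios
#' normalization and biases size factors toward the enriched rows. When the
#' count matrix carries a reference with a mutagenized core, the size factors
#' are therefore estimated on the primer-flank rows only (mutations outside
#' the core): their counts come from sequencing errors on unmutated templates
#' and from unenriched flank library members, so they are neutral to the
#' sorting condition by construction and serve as built-in control rows. Set
#' `normalization_rows` to override (e.g. `"all"` to use every row).
#'
#' @param mcm A `mutation_count_matrix` (or a plain counts matrix, in which
#'   case `condition_of` must give a condition label per column).
#' @param baseline,contrast Condition labels. For a `mutation_count_matrix`,
#'   conditions default to `plasmid_gate` (e.g. `"srna_all"`, `"srna_high"`).
#' @param alpha Significance threshold on the adjusted p-value (default 0.05).
#' @param condition_of Optional explicit condition label per sample column.
#' @param normalization_rows Rows used for size-factor estimation: `"auto"`
#'   (primer-flank control rows when available, all rows otherwise),
#'   `"all"`, or a logical/integer row index vector.
#' @return Data frame (class `enrichment_result`) with one row per mutation:
#'   `mutation`, `position`, `baseline_mean`, `contrast_mean` (normalized),
#'   `log2_ratio`, `p_value`, `p_adjusted`, `call`.
#' @export
enrichment_table <- function(mcm, baseline, contrast, alpha = 0.05,
                             condition_of = NULL,
                             normalization_rows = "auto") {
  flank_rows <- NULL
  if (inherits(mcm, "mutation_count_matrix")) {
    counts <- mcm$counts
    if (is.null(condition_of)) {
      condition_of <- paste(mcm$samples$plasmid, mcm$samples$gate, sep = "_")
    }
    mutations <- mcm$mutations
    region <- mcm$mutated_region
    if (!is.null(region)) {
      fl <- mutations$position < region[1L] | mutations$position >= region[2L]
      if (any(fl)) flank_rows <- which(fl)
    }
  } else {
    counts <- as.matrix(mcm)
    if (is.null(condition_of)) {
      stop("condition_of is required for a plain counts matrix", call. = FALSE)
    }
    mutations <- data.frame(position = seq_len(nrow(counts)) - 1L)
    rownames(counts) <- rownames(counts) %||%
      paste0("row", seq_len(nrow(counts)))
  }
  for (cond in c(baseline, contrast)) {
    if (sum(condition_of == cond) < 1L) {
      stop("condition '", cond, "' not present in the samples", call. = FALSE)
    }
  }
  sel_a <- which(condition_of == baseline)
  sel_b <- which(condition_of == contrast)
  sub <- counts[, c(sel_a, sel_b), drop = FALSE]
  norm_idx <- seq_len(nrow(sub))
  if (identical(normalization_rows, "auto")) {
    # require a reasonable number of usable control rows before trusting them
    if (!is.null(flank_rows) &&
        sum(rowSums(sub[flank_rows, , drop = FALSE] == 0) == 0) >= 20L) {
      norm_idx <- flank_rows
    }
  } else if (!identical(normalization_rows, "all")) {
    norm_idx <- normalization_rows
  }
  sf <- size_factors(sub[norm_idx, , drop = FALSE])
  sf_a <- sf[seq_along(sel_a)]
  sf_b <- sf[seq_along(sel_b) + length(sel_a)]
  conds <- rep(c("A", "B"), c(length(sel_a), length(sel_b)))
  disp <- estimate_dispersions(sub, conds, sf)

  ca <- counts[, sel_a, drop = FALSE]
  cb <- counts[, sel_b, drop = FALSE]
  base_mean <- rowMeans(sweep(ca, 2L, sf_a, "/"))
  contr_mean <- rowMeans(sweep(cb, 2L, sf_b, "/"))
  n <- nrow(counts)
  pval <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(disp[i])) next
    pval[i] <- nb_exact_test(ca[i, ], cb[i, ], sf_a, sf_b, disp[i])
  }
  padj <- bh_adjust(pval)
  call <- rep("ns", n)
  sig <- !is.na(padj) & padj < alpha
  call[sig & contr_mean > base_mean] <- "over"
  call[sig & contr_mean < base_mean] <- "under"
  call[sig & contr_mean == base_mean] <- "ns"  # no direction, no call
  out <- data.frame(
    mutation = rownames(counts),
    position = mutations$position,
    baseline_mean = base_mean,
    contrast_mean = contr_mean,
    log2_ratio = log2(contr_mean) - log2(base_mean),
    p_value = pval,
    p_adjusted = padj,
    call = call,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "contrast") <- contrast
  attr(out, "alpha") <- alpha
  attr(out, "dispersions") <- disp
  class(out) <- c("enrichment_result", "data.frame")
  out
}
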