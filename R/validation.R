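# Statistical validation of SSM rankings: a ties-tolerant bootstrap
# one-sided Kolmogorov-Smirnov test on pairwise similarity distributions, and
# hold-out cross-validation of rankings against a hypergeometric null.

# One-sided two-sample KS statistic D+ = sup_x [F_b(x) - F_a(x)], evaluated at
# the pooled data points; ties allowed.
ks_dplus <- function(a, b) {
  na <- length(a); nb <- length(b)
  w <- c(a, b)
  o <- order(w, method = "radix")
  step <- ifelse(o <= na, -1 / na, 1 / nb)
  z <- cumsum(step)
  ws <- w[o]
  last_of_tie <- c(diff(ws) > 0, TRUE)
  max(0, z[last_of_tie])
}

#' Bootstrap one-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests the null of equal distributions against the alternative that
#' `sample_a` is stochastically larger than `sample_b` (the cdf of `a` lies
#' below the cdf of `b`). The statistic is `D+ = sup_x [F_b(x) - F_a(x)]`;
#' its null distribution is estimated by `n_boot` resamples drawn with
#' replacement from the pooled sample, which makes the test valid in the
#' presence of ties. The p-value uses add-one smoothing,
#' `(1 + #resampled D+ >= observed) / (n_boot + 1)`, so it is never 0.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param n_boot number of bootstrap resamples (>= 1000).
#' @param seed optional integer seed; the test is reproducible when set.
#' @return a list of class `ks_boot` with `statistic`, `p.value`, `n_boot`.
#' @export
ks_boot <- function(sample_a, sample_b, n_boot = 1000L, seed = NULL) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty")
  if (n_boot < 1000L) stop("n_boot must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  d_obs <- ks_dplus(sample_a, sample_b)
  pooled <- c(sample_a, sample_b)
  na <- length(sample_a); nb <- length(sample_b); np <- na + nb
  n_ge <- 0L
  for (i in seq_len(n_boot)) {
    idx <- sample.int(np, np, replace = TRUE)
    if (ks_dplus(pooled[idx[seq_len(na)]], pooled[idx[-seq_len(na)]]) >= d_obs)
      n_ge <- n_ge + 1L
  }
  structure(list(statistic = d_obs,
                 p.value = (1 + n_ge) / (n_boot + 1),
                 n_boot = n_boot),
            class = "ks_boot")
}

#' @export
print.ks_boot <- function(x, ...) {
  cat(sprintf("bootstrap one-sided KS test: D+ = %.4f, p = %.4g (%d resamples)\n",
              x$statistic, x$p.value, x$n_boot))
  invisible(x)
}

#' Back-to-back histogram of two pairwise-similarity distributions
#'
#' Bins both samples on \[0, 1\] at 0.1 intervals (left-closed bins, the last
#' bin closed on both sides), the layout of a population pyramid contrasting
#' disease-pair similarities with all-gene-pair similarities.
#'
#' @param disease_pairs,all_pairs numeric vectors of similarities in \[0, 1\];
#'   the disease side must be non-empty.
#' @return a list of class `pyramid_histogram` with `breaks` and the two
#'   10-bin count vectors `disease` and `all`.
#' @export
pyramid <- function(disease_pairs, all_pairs) {
  if (length(disease_pairs) == 0L) stop("disease side is empty")
  vals <- c(disease_pairs, all_pairs)
  if (any(vals < 0 | vals > 1)) stop("similarity values must lie in [0, 1]")
  breaks <- seq(0, 1, by = 0.1)
  bin <- function(x) {
    as.integer(table(cut(x, breaks, right = FALSE, include.lowest = TRUE)))
  }
  structure(list(breaks = breaks,
                 disease = bin(disease_pairs),
                 all = bin(all_pairs)),
            class = "pyramid_histogram")
}

#' Upper tail of the hypergeometric distribution at a (possibly fractional)
#' threshold
#'
#' `P(X >= ceiling(threshold))` for `X ~ Hypergeometric(N, K, n)`: the
#' probability of drawing at least that many of the `K` marked genes when `n`
#' genes are drawn without replacement from a population of `N`. A fractional
#' threshold (a cross-validation mean count) is rounded up — counts are
#' integers, and this is the conservative reading of "at least the mean".
#'
#' @param N population size; `K` marked genes; `n` draws.
#' @param threshold real-valued count threshold.
#' @return a probability.
#' @export
hypergeom_sf <- function(N, K, n, threshold) {
  if (K < 0 || K > N || n < 0 || n > N) stop("invalid hypergeometric parameters")
  k <- ceiling(threshold)
  if (k <= 0) return(1)
  if (k > min(K, n)) return(0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Power of the cross-validation test against the hypergeometric null
#'
#' With `q` the smallest integer whose hypergeometric cdf reaches `1 - alpha`,
#' the power is the fraction of cross-validation counts strictly greater than
#' `q`.
#'
#' @param counts integer vector of per-iteration disease-gene counts.
#' @param N,K,n hypergeometric parameters (population, marked, draws).
#' @param alpha significance level in (0, 1).
#' @return the power, in \[0, 1\].
#' @export
cv_power <- function(counts, N, K, n, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  q <- stats::qhyper(1 - alpha, K, N - K, n)
  mean(counts > q)
}

#' Hold-out cross-validation of the prioritization ranking
#'
#' Repeatedly hides `holdout` disease genes among the candidates, ranks the
#' enlarged candidate set against the remaining disease genes, and counts how
#' many hidden disease genes land in each top window. The count distribution
#' is confronted with the hypergeometric null of a random ordering
#' (`N = n_candidates + holdout` genes of which `K = holdout` are disease
#' genes, `n = w` drawn): per window the upper-tail p-value at the mean count
#' and the power at level `alpha` are reported.
#'
#' Because SSM between a gene and a disease gene does not depend on which
#' disease genes are held out, the full similarity matrix is computed once
#' and each iteration only averages over the retained disease columns;
#' results are identical to re-ranking from scratch. Iteration `i` draws its
#' hold-out set from a substream derived from `seed` and `i`, so count `i` is
#' stable under changes of `n_iter`.
#'
#' @param candidates named list of candidate profiles.
#' @param disease_set named list of disease gene profiles (more than
#'   `holdout` genes).
#' @param graph an `ontology_graph`; `ic` an `ic_table`.
#' @param ic an `ic_table`.
#' @param n_iter number of hold-out iterations.
#' @param holdout number of disease genes hidden per iteration.
#' @param windows integer vector of top-window widths.
#' @param alpha level for the power computation.
#' @param seed integer seed driving all hold-out draws.
#' @return a list of class `cross_val_result`: `counts` (n_iter x windows
#'   matrix), `means`, `p_values`, `power`, plus `N`, `K`, `windows`,
#'   `alpha`, `seed`.
#' @export
cross_validate <- function(candidates, disease_set, graph, ic,
                           n_iter = 10000L, holdout = 8L,
                           windows = c(100L, 75L, 50L, 8L),
                           alpha = 0.01, seed = 1L) {
  if (holdout >= length(disease_set))
    stop("holdout must be smaller than the disease set")
  if (anyDuplicated(c(names(candidates), names(disease_set))))
    stop("candidate and disease gene ids must be distinct")
  n_rank <- length(candidates) + holdout
  if (any(windows > n_rank))
    stop("window wider than the ranked list")
  all_prof <- c(candidates, disease_set)
  s <- ssm_matrix(all_prof, disease_set, graph, ic)
  gene_ids <- rownames(s)
  cand_rows <- seq_along(candidates)
  dis_ids <- names(disease_set)
  counts <- matrix(0L, n_iter, length(windows),
                   dimnames = list(NULL, paste0("w", windows)))
  for (i in seq_len(n_iter)) {
    set.seed(derive_seed(seed, i))
    hold <- sample(dis_ids, holdout)
    rest <- setdiff(dis_ids, hold)
    rows <- c(cand_rows, match(hold, gene_ids))
    score <- rowMeans(s[rows, rest, drop = FALSE])
    ord <- order(-score, gene_ids[rows])
    ranked <- gene_ids[rows][ord]
    for (k in seq_along(windows))
      counts[i, k] <- sum(ranked[seq_len(windows[k])] %in% hold)
  }
  means <- colMeans(counts)
  p_values <- vapply(seq_along(windows), function(k)
    hypergeom_sf(n_rank, holdout, windows[k], means[k]), 0)
  pw <- vapply(seq_along(windows), function(k)
    cv_power(counts[, k], n_rank, holdout, windows[k], alpha), 0)
  structure(list(counts = counts, means = means,
                 p_values = stats::setNames(p_values, colnames(counts)),
                 power = stats::setNames(pw, colnames(counts)),
                 N = n_rank, K = holdout, windows = windows,
                 alpha = alpha, seed = seed),
            class = "cross_val_result")
}

#' @export
print.cross_val_result <- function(x, ...) {
  cat(sprintf("cross-validation: %d iterations, N = %d, K = %d\n",
              nrow(x$counts), x$N, x$K))
  print(data.frame(window_width = x$windows,
                   mean_value = round(unname(x$means), 3),
                   p_value = signif(unname(x$p_values), 3),
                   power = round(unname(x$power), 3)))
  invisible(x)
}

#' Write a cross-validation report (window_width, mean_value, p_value, power)
#' and, optionally, the per-iteration counts
#'
#' @param cv a `cross_val_result`.
#' @param path output TSV for the summary.
#' @param counts_path optional TSV for per-iteration counts.
#' @export
write_crossval <- function(cv, path, counts_path = NULL) {
  out <- data.frame(window_width = cv$windows,
                    mean_value = sprintf("%.3f", cv$means),
                    p_value = sprintf("%.6g", cv$p_values),
                    power = sprintf("%.3f", cv$power))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(counts_path))
    utils::write.table(cv$counts, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
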