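# GO-term enrichment for prioritized gene lists: a score-based empirical test
# for candidates, Fisher's exact test for disease genes against a
# score-percentile non-disease class, and the specificity-weighted GOscore.

# Propagate each profile to its ancestor closure: a gene is annotated with C
# when any of its direct terms is C or a descendant of C (true-path rule,
# consistent with the IC counting rule).
propagate_profiles <- function(profiles, graph) {
  lapply(profiles, function(terms)
    unique(unlist(lapply(terms, ancestors, graph = graph), use.names = FALSE)))
}

#' Empirical score-based p-value for a GO term over ranked candidates
#'
#' The observed statistic is the mean prioritization score (SSMavg) of the
#' candidates annotated with the term (directly or via a descendant). The
#' null is the distribution of mean scores of random candidate lists of the
#' same size, drawn without replacement within each list; the p-value is
#' `(1 + #null means >= observed) / (1 + n_random)` (add-one smoothing, so
#' the smallest attainable p is `1/(n_random + 1)`).
#'
#' @param term a term id annotating at least one ranked candidate.
#' @param ranking ranking `data.frame` from [rank_candidates()].
#' @param corpus an `annotation_corpus` supplying candidate annotations.
#' @param graph an `ontology_graph`.
#' @param n_random number of random lists.
#' @param seed optional integer seed.
#' @return the empirical p-value.
#' @export
candidate_term_pvalue <- function(term, ranking, corpus, graph,
                                  n_random = 10000L, seed = NULL) {
  stopifnot_term(graph, term)
  prop <- propagate_profiles(corpus$direct[ranking$gene], graph)
  hit <- vapply(prop, function(tt) term %in% tt, NA)
  n_i <- sum(hit)
  if (n_i == 0L) stop(sprintf("term %s annotates no ranked candidate", term))
  if (!is.null(seed)) set.seed(seed)
  scores <- ranking$ssm_avg
  obs <- mean(scores[hit])
  null_means <- random_list_means(scores, n_i, n_random)
  (1 + sum(null_means >= obs)) / (1 + n_random)
}

# Means of `n_random` random sublists of size n_i (without replacement within
# each list): the empirical null for the score-based enrichment test.
random_list_means <- function(scores, n_i, n_random) {
  N <- length(scores)
  vapply(seq_len(n_random),
         function(j) mean(scores[sample.int(N, n_i)]), 0)
}

#' Non-disease gene class from the candidate score distribution
#'
#' Candidates scoring strictly below the 95th percentile (linear
#' interpolation between order statistics) of all candidate scores; the
#' pragmatic stand-in for "known non-disease" genes when future discoveries
#' cannot be anticipated.
#'
#' @param ranking ranking `data.frame`.
#' @param percentile percentile cut in (0, 100).
#' @return character vector of gene ids (possibly empty when all scores tie).
#' @export
nondisease_class <- function(ranking, percentile = 95) {
  if (nrow(ranking) == 0L) stop("empty ranking")
  thr <- stats::quantile(ranking$ssm_avg, percentile / 100, type = 7, names = FALSE)
  ranking$gene[ranking$ssm_avg < thr]
}

#' One-sided Fisher's exact test for disease-gene term enrichment
#'
#' Tests whether disease genes are over-represented among the genes annotated
#' with a term, via the exact hypergeometric tail of the 2x2 table
#' (`a` disease annotated, `b` non-disease annotated, `c` disease not
#' annotated, `d` non-disease not annotated).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return the one-sided (greater) p-value.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("contingency counts must be non-negative")
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                     alternative = "greater")$p.value
}

#' Specificity-weighted enrichment score for a GO term
#'
#' `GOscore = IC * (-log10 p)`: an enriched term counts for more when it is
#' rare (informative) in the annotation corpus. Zero when `p = 1`.
#'
#' @param ic_value the term's information content in nats (>= 0).
#' @param p_value the term's enrichment p-value in (0, 1].
#' @return the score (>= 0).
#' @export
go_score <- function(ic_value, p_value) {
  if (any(ic_value < 0)) stop("IC must be non-negative")
  if (any(p_value <= 0 | p_value > 1)) stop("p-value must lie in (0, 1]")
  ic_value * (-log10(p_value))
}

#' GO-term enrichment report for candidate or disease genes
#'
#' In `candidates` mode every term annotating at least one ranked candidate
#' (true-path propagated) receives the empirical score-based p-value; random
#' null lists are shared across terms of equal annotated-list size, which is
#' exactly the per-size empirical null. In `disease` mode every term
#' annotating at least one disease gene is tested by one-sided Fisher's exact
#' test of disease vs non-disease class membership, where the non-disease
#' class comes from [nondisease_class()] and the gene universe is the union
#' of the two classes (candidates above the percentile cut belong to
#' neither). Rows are filtered at `p < alpha` and sorted by GOscore
#' descending within each namespace.
#'
#' @param mode `"candidates"` or `"disease"`.
#' @param ranking ranking `data.frame` of the candidates.
#' @param corpus an `annotation_corpus` covering all genes involved.
#' @param graph an `ontology_graph`.
#' @param ic an `ic_table` (for GOscore weights).
#' @param disease_genes character vector of disease gene ids (disease mode).
#' @param n_random random lists per size (candidates mode).
#' @param alpha reporting threshold on the p-value.
#' @param percentile non-disease percentile cut (disease mode).
#' @param seed optional integer seed (candidates mode).
#' @return `data.frame` with columns `term_id`, `namespace`, `n_genes`,
#'   `p_value`, `go_score`, `term_name`.
#' @export
enrichment_report <- function(mode = c("candidates", "disease"),
                              ranking, corpus, graph, ic,
                              disease_genes = NULL,
                              n_random = 10000L, alpha = 0.01,
                              percentile = 95, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "candidates") {
    prop <- propagate_profiles(corpus$direct[ranking$gene], graph)
    scores <- ranking$ssm_avg
    term_genes <- split(rep(seq_along(prop), lengths(prop)),
                        unlist(prop, use.names = FALSE))
    sizes <- lengths(term_genes)
    null_by_size <- lapply(stats::setNames(nm = unique(sizes)), function(k)
      random_list_means(scores, as.integer(k), n_random))
    p <- vapply(seq_along(term_genes), function(t) {
      obs <- mean(scores[term_genes[[t]]])
      nm <- null_by_size[[as.character(sizes[t])]]
      (1 + sum(nm >= obs)) / (1 + n_random)
    }, 0)
    rows <- data.frame(term_id = names(term_genes),
                       n_genes = unname(sizes),
                       p_value = p, stringsAsFactors = FALSE)
  } else {
    if (is.null(disease_genes)) stop("disease mode needs disease_genes")
    nd <- nondisease_class(ranking, percentile)
    dis <- intersect(disease_genes, names(corpus$direct))
    if (length(dis) == 0L) stop("no annotated disease genes")
    prop <- propagate_profiles(corpus$direct[c(dis, nd)], graph)
    is_dis <- c(rep(TRUE, length(dis)), rep(FALSE, length(nd)))
    terms <- unique(unlist(prop[seq_along(dis)], use.names = FALSE))
    p <- vapply(terms, function(t) {
      hit <- vapply(prop, function(tt) t %in% tt, NA)
      fisher_enrichment(sum(hit & is_dis), sum(hit & !is_dis),
                        sum(!hit & is_dis), sum(!hit & !is_dis))
    }, 0)
    n_genes <- vapply(terms, function(t)
      sum(vapply(prop[seq_along(dis)], function(tt) t %in% tt, NA)), 0L)
    rows <- data.frame(term_id = terms, n_genes = n_genes,
                       p_value = unname(p), stringsAsFactors = FALSE)
  }
  rows <- rows[rows$p_value < alpha, , drop = FALSE]
  rows$go_score <- if (nrow(rows)) go_score(ic_lookup(ic, rows$term_id), rows$p_value) else numeric(0)
  rows$namespace <- vapply(rows$term_id, function(t) graph$terms[[t]]$namespace, "")
  rows$term_name <- vapply(rows$term_id, function(t) graph$terms[[t]]$name, "")
  rows <- rows[order(rows$namespace, -rows$go_score, rows$term_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows[, c("term_id", "namespace", "n_genes", "p_value", "go_score", "term_name")]
}

#' Write an enrichment report as TSV
#'
#' @param report `data.frame` from [enrichment_report()].
#' @param path output file.
#' @export
write_enrichment <- function(report, path) {
  out <- report
  out$p_value <- sprintf("%.6g", out$p_value)
  out$go_score <- sprintf("%.3f", out$go_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
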