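#' Mean SSM of one candidate against a disease gene set (SSMavg)
#'
#' @param candidate non-empty character vector of term ids (the candidate's
#'   annotation profile).
#' @param disease_set non-empty named list of disease gene profiles.
#' @param graph an `ontology_graph`.
#' @param ic an `ic_table`.
#' @return the arithmetic mean SSM, in \[0, 1\].
#' @export
ssm_avg <- function(candidate, disease_set, graph, ic) {
  if (length(disease_set) == 0L) stop("disease set is empty")
  check_profile(candidate, "candidate")
  mean(vapply(disease_set, function(d) ssm(candidate, d, graph, ic), 0))
}

#' Rank candidate genes by average similarity to the disease set
#'
#' Every candidate with at least one annotation is scored by its mean SSM
#' against all disease genes and the table is sorted by score descending,
#' ties broken by gene id ascending so ranks are reproducible. Candidates
#' with empty annotation sets are excluded with a warning (they cannot be
#' scored), never an error. A disease gene appearing among the candidates is
#' scored like any other candidate; hold-out cross-validation relies on this.
#'
#' @param candidates named list of candidate profiles (term-id vectors).
#' @param disease_set named list of disease gene profiles.
#' @inheritParams ssm_avg
#' @return a `data.frame` with columns `gene`, `ssm_avg`, `rank`.
#' @export
rank_candidates <- function(candidates, disease_set, graph, ic) {
  if (length(candidates) == 0L) stop("no candidates")
  if (length(disease_set) == 0L) stop("disease set is empty")
  empty <- lengths(candidates) == 0L
  if (any(empty)) {
    warning(sprintf("excluded %d unannotated candidate(s): %s",
                    sum(empty), paste(names(candidates)[empty], collapse = ", ")))
    candidates <- candidates[!empty]
  }
  if (length(candidates) == 0L) stop("no annotated candidates remain")
  if (anyDuplicated(names(candidates))) stop("duplicate candidate gene ids")
  s <- ssm_matrix(candidates, disease_set, graph, ic)
  score <- rowMeans(s)
  ord <- order(-score, names(candidates))
  data.frame(gene = names(candidates)[ord],
             ssm_avg = unname(score[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Write a ranking table as TSV (gene_id, ssm_avg to 6 decimals, rank)
#'
#' @param ranking a ranking `data.frame` from [rank_candidates()].
#' @param path output file.
#' @export
write_ranking <- function(ranking, path) {
  out <- data.frame(gene_id = ranking$gene,
                    ssm_avg = sprintf("%.6f", ranking$ssm_avg),
                    rank = ranking$rank)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
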