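# End-to-end workflow: load ontology + annotations, score candidates,
# validate the ranking, characterize the gene lists functionally.

#' Assemble a run configuration
#'
#' Numeric defaults are the standard analysis settings: 10000 hold-out
#' iterations with 8 genes held out, top windows 100/75/50/8, significance
#' level 0.01, 10000 random lists for the score-based enrichment null, and a
#' 95th-percentile cut for the non-disease class.
#'
#' @param obo,gene2go,disease_list,candidate_list input file paths.
#' @param out_dir output directory (created if absent).
#' @param taxon taxonomy filter for gene2go (default 9606).
#' @param denominator_mode probability denominator, see [term_probability()].
#' @param n_iter,holdout,windows,alpha cross-validation settings.
#' @param n_random random lists for candidate enrichment.
#' @param percentile non-disease class percentile.
#' @param seed integer seed, mandatory for the stochastic commands.
#' @return a list of class `run_config`.
#' @export
run_config <- function(obo = NULL, gene2go = NULL, disease_list = NULL,
                       candidate_list = NULL, out_dir = ".",
                       taxon = 9606L,
                       denominator_mode = "gene_products",
                       n_iter = 10000L, holdout = 8L,
                       windows = c(100L, 75L, 50L, 8L), alpha = 0.01,
                       n_random = 10000L, percentile = 95, seed = NULL) {
  stopifnot(n_iter >= 1, holdout >= 1, all(windows >= 1),
            alpha > 0, alpha < 1, n_random >= 1,
            percentile > 0, percentile < 100)
  structure(as.list(environment()), class = "run_config")
}

load_inputs <- function(config) {
  graph <- parse_obo(config$obo)
  corpus <- read_gene2go(config$gene2go, taxon = config$taxon, graph = graph)
  p <- term_probability(graph, corpus, config$denominator_mode)
  ic <- information_content(p)
  disease_ids <- read_gene_list(config$disease_list)
  disease <- gene_profiles(corpus, disease_ids)
  message(sprintf("disease genes: %d listed, %d annotated",
                  length(disease_ids), length(disease)))
  candidates <- NULL
  if (!is.null(config$candidate_list)) {
    cand_ids <- setdiff(read_gene_list(config$candidate_list), names(disease))
    candidates <- gene_profiles(corpus, cand_ids)
    message(sprintf("candidate genes: %d listed, %d annotated",
                    length(cand_ids), length(candidates)))
  }
  list(graph = graph, corpus = corpus, ic = ic,
       disease = disease, candidates = candidates)
}

write_manifest <- function(config, out_dir, command) {
  paths <- unlist(config[c("obo", "gene2go", "disease_list", "candidate_list")])
  sums <- tools::md5sum(paths[!is.na(paths)])
  lines <- c(
    paste0("command: ", command),
    paste0("seed: ", if (is.null(config$seed)) "none" else config$seed),
    paste0("taxon: ", config$taxon),
    paste0("denominator_mode: ", config$denominator_mode),
    sprintf("param %s: %s",
            c("n_iter", "holdout", "windows", "alpha", "n_random", "percentile"),
            c(config$n_iter, config$holdout,
              paste(config$windows, collapse = ","), config$alpha,
              config$n_random, config$percentile)),
    sprintf("input %s md5 %s", names(sums), unname(sums))
  )
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}

#' Run one pipeline command
#'
#' Commands: `make-fixtures` writes the toy fixture as OBO + gene2go + gene
#' lists into `out_dir`; `score` writes the candidate ranking; `validate-ks`
#' compares the disease pairwise SSM distribution with the all-annotated-gene
#' distribution (bootstrap KS + pyramid histogram); `validate-cv` runs the
#' hold-out cross-validation; `enrich-candidates` and `enrich-disease` write
#' the enrichment reports. Every command writes a `manifest.txt` echoing the
#' configuration, seed and input checksums.
#'
#' @param config a `run_config`.
#' @param command one of the commands above.
#' @return invisibly, a list of the objects computed (also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config,
                         command = c("score", "validate-ks", "validate-cv",
                                     "enrich-candidates", "enrich-disease",
                                     "make-fixtures")) {
  command <- match.arg(command)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (command == "make-fixtures") {
    fx <- fixture_T1()
    write_obo(fx$graph, file.path(out_dir, "t1.obo"))
    write_gene2go(fx$corpus, file.path(out_dir, "t1_gene2go.tsv"))
    writeLines(c("g1", "g2"), file.path(out_dir, "t1_disease.txt"))
    writeLines(c("g3", "g4"), file.path(out_dir, "t1_candidates.txt"))
    return(invisible(fx))
  }

  inputs <- load_inputs(config)
  write_manifest(config, out_dir, command)
  result <- switch(
    command,
    "score" = {
      ranking <- rank_candidates(inputs$candidates, inputs$disease,
                                 inputs$graph, inputs$ic)
      write_ranking(ranking, file.path(out_dir, "ranking.tsv"))
      ranking
    },
    "validate-ks" = {
      if (is.null(config$seed)) stop("validate-ks needs a seed")
      dis_pairs <- pairwise_values(pairwise_ssm(inputs$disease,
                                                inputs$graph, inputs$ic))
      all_pairs <- pairwise_values(pairwise_ssm(inputs$corpus$direct,
                                                inputs$graph, inputs$ic))
      kb <- ks_boot(dis_pairs, all_pairs, seed = config$seed)
      pyr <- pyramid(dis_pairs, all_pairs)
      utils::write.table(
        data.frame(bin_low = pyr$breaks[-11], bin_high = pyr$breaks[-1],
                   disease = pyr$disease, all_genes = pyr$all),
        file.path(out_dir, "pyramid.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(sprintf("D_plus\t%.6f\np_value\t%.6g", kb$statistic, kb$p.value),
                 file.path(out_dir, "ks_boot.tsv"))
      list(ks = kb, pyramid = pyr)
    },
    "validate-cv" = {
      if (is.null(config$seed)) stop("validate-cv needs a seed")
      cv <- cross_validate(inputs$candidates, inputs$disease,
                           inputs$graph, inputs$ic,
                           n_iter = config$n_iter, holdout = config$holdout,
                           windows = config$windows, alpha = config$alpha,
                           seed = config$seed)
      write_crossval(cv, file.path(out_dir, "crossval.tsv"),
                     file.path(out_dir, "crossval_counts.tsv"))
      cv
    },
    "enrich-candidates" = {
      if (is.null(config$seed)) stop("enrich-candidates needs a seed")
      ranking <- rank_candidates(inputs$candidates, inputs$disease,
                                 inputs$graph, inputs$ic)
      rep <- enrichment_report("candidates", ranking, inputs$corpus,
                               inputs$graph, inputs$ic,
                               n_random = config$n_random,
                               alpha = config$alpha, seed = config$seed)
      write_enrichment(rep, file.path(out_dir, "enrichment_candidates.tsv"))
      rep
    },
    "enrich-disease" = {
      ranking <- rank_candidates(inputs$candidates, inputs$disease,
                                 inputs$graph, inputs$ic)
      rep <- enrichment_report("disease", ranking, inputs$corpus,
                               inputs$graph, inputs$ic,
                               disease_genes = names(inputs$disease),
                               alpha = config$alpha,
                               percentile = config$percentile)
      write_enrichment(rep, file.path(out_dir, "enrichment_disease.tsv"))
      rep
    }
  )
  invisible(result)
}
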