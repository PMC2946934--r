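#' Construct an annotation corpus from a gene -> terms mapping
#'
#' @param direct named list; each element a character vector of direct term
#'   ids for one gene. Genes with zero terms are rejected.
#' @param graph optional `ontology_graph`; when supplied, annotations to terms
#'   absent from the graph are dropped with a warning and genes left empty are
#'   removed.
#' @return an `annotation_corpus`: list with `direct`, `n_genes`,
#'   `n_associations`.
#' @export
annotation_corpus <- function(direct, graph = NULL) {
  if (length(direct) == 0L) stop("corpus has no genes")
  if (is.null(names(direct)) || any(!nzchar(names(direct))))
    stop("corpus genes must be named")
  if (anyDuplicated(names(direct))) stop("duplicate gene ids in corpus")
  direct <- lapply(direct, function(x) sort(unique(as.character(x))))
  if (!is.null(graph)) {
    known <- names(graph$terms)
    n_drop <- sum(vapply(direct, function(x) sum(!x %in% known), 0L))
    if (n_drop > 0L) {
      warning(sprintf("dropped %d annotation(s) to terms absent from the graph", n_drop))
      direct <- lapply(direct, function(x) x[x %in% known])
    }
  }
  empty <- lengths(direct) == 0L
  if (any(empty)) {
    warning(sprintf("removed %d gene(s) with no surviving annotations: %s",
                    sum(empty), paste(names(direct)[empty], collapse = ", ")))
    direct <- direct[!empty]
  }
  if (length(direct) == 0L) stop("no annotated genes survive filtering")
  structure(
    list(direct = direct,
         n_genes = length(direct),
         n_associations = sum(lengths(direct))),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf("annotation_corpus: %d genes, %d direct associations\n",
              x$n_genes, x$n_associations))
  invisible(x)
}

#' Read an NCBI gene2go-style annotation table
#'
#' Expects the 8-column tab-separated NCBI layout
#' (`tax_id, GeneID, GO_ID, Evidence, Qualifier, GO_term, PubMed, Category`),
#' header line starting with `#`; extra trailing columns are tolerated. Rows
#' are filtered to `taxon`, `NOT`-qualified annotations are dropped (a NOT
#' annotation is not a positive functional statement), duplicate (gene, term)
#' pairs collapse to one association, and malformed rows are skipped with a
#' message. Evidence codes, including IEA, are kept by default; pass
#' `evidence` to whitelist codes.
#'
#' @param path file path (or character vector of lines).
#' @param taxon integer NCBI taxonomy id to retain (default 9606, human).
#' @param graph optional `ontology_graph` used to drop annotations to unknown
#'   terms (see [annotation_corpus()]).
#' @param evidence optional character vector of evidence codes to keep.
#' @return an `annotation_corpus`.
#' @export
read_gene2go <- function(path, taxon = 9606L, graph = NULL, evidence = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 8L
  if (any(!ok))
    message(sprintf("skipped %d malformed gene2go row(s)", sum(!ok)))
  fields <- fields[ok]
  if (length(fields) == 0L) stop("no parseable gene2go rows")
  m <- do.call(rbind, lapply(fields, `[`, 1:8))
  keep <- m[, 1L] == as.character(taxon)
  keep <- keep & !grepl("\\bNOT\\b", m[, 5L])
  if (!is.null(evidence)) keep <- keep & m[, 4L] %in% evidence
  if (!any(keep)) stop("no gene2go rows survive filtering")
  gene <- m[keep, 2L]
  term <- m[keep, 3L]
  message(sprintf("gene2go: %d rows read, %d retained for taxon %s (%d genes)",
                  length(fields), sum(keep), taxon, length(unique(gene))))
  annotation_corpus(split(term, gene)[unique(gene)], graph = graph)
}

#' Write a corpus in the gene2go dialect
#'
#' @param corpus an `annotation_corpus`.
#' @param path output file; `NULL` returns the lines.
#' @param taxon taxonomy id to stamp on every row.
#' @return invisibly, the written lines.
#' @export
write_gene2go <- function(corpus, path = NULL, taxon = 9606L) {
  rows <- unlist(lapply(names(corpus$direct), function(g) {
    paste(taxon, g, corpus$direct[[g]], "IEA", "-", "-", "-", "Process",
          sep = "\t")
  }), use.names = FALSE)
  out <- c("#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
           rows)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored; the list
#' is deduplicated preserving first-occurrence order.
#'
#' @param path file path (or character vector of lines).
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty gene list")
  unique(lines)
}

#' Extract gene profiles (annotation term sets) from a corpus
#'
#' Genes absent from the corpus (i.e. without GO annotations) are dropped with
#' a warning naming them, mirroring the standard exclusion of unannotated
#' genes from similarity scoring.
#'
#' @param corpus an `annotation_corpus`.
#' @param genes character vector of gene ids; `NULL` takes every corpus gene.
#' @return named list mapping gene id to its character vector of direct terms.
#' @export
gene_profiles <- function(corpus, genes = NULL) {
  if (is.null(genes)) return(corpus$direct)
  missing <- setdiff(genes, names(corpus$direct))
  if (length(missing))
    warning(sprintf("%d gene(s) have no annotations and were dropped: %s",
                    length(missing), paste(missing, collapse = ", ")))
  genes <- intersect(genes, names(corpus$direct))
  if (length(genes) == 0L) stop("no requested gene has annotations")
  corpus$direct[genes]
}
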