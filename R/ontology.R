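#' Parse an OBO 1.2 flat file into an ontology graph
#'
#' Reads `[Term]` stanzas and keeps the two subsumption relations of the Gene
#' Ontology, `is_a` and `relationship: part_of`; every other relationship type
#' is dropped. Obsolete terms (and any edges they declare) are removed with a
#' warning. One root per namespace is detected as the term left without
#' retained parents.
#'
#' @param path path to an OBO file, or a character vector of its lines.
#' @return an object of class `ontology_graph`: a list with
#'   - `terms`: named list, one entry per term with fields `id`, `name`,
#'     `namespace`, `parents` (character vector of parent ids) and
#'     `relations` (relation type per parent);
#'   - `roots`: named character vector, one root id per namespace.
#' @details The parent relation must be acyclic; a cycle aborts the parse and
#'   the error names one term on the cycle. A parent reference to a term not
#'   defined in the file is also an error.
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- trimws(lines)

  # split into stanzas
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) stop("no stanzas found in OBO input")
  ends <- c(starts[-1L] - 1L, length(lines))
  terms <- list()
  n_obsolete <- 0L
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    body <- lines[seq(starts[k] + 1L, ends[k])]
    body <- body[nzchar(body)]
    tag <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    val <- sub("\\s*!.*$", "", val)  # strip trailing '! name' comments
    id <- val[tag == "id"][1L]
    if (is.na(id)) stop("[Term] stanza without an id tag")
    if (any(tag == "is_obsolete" & val == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    parents <- val[tag == "is_a"]
    rels <- rep("is_a", length(parents))
    rel_lines <- val[tag == "relationship"]
    if (length(rel_lines)) {
      rel_type <- sub("\\s.*$", "", rel_lines)
      rel_target <- trimws(sub("^\\S+\\s+", "", rel_lines))
      keep <- rel_type == "part_of"
      parents <- c(parents, rel_target[keep])
      rels <- c(rels, rep("part_of", sum(keep)))
    }
    ns <- val[tag == "namespace"][1L]
    if (is.na(ns)) ns <- "default"
    terms[[id]] <- list(
      id = id,
      name = if (any(tag == "name")) val[tag == "name"][1L] else id,
      namespace = ns,
      parents = parents,
      relations = rels
    )
  }
  if (n_obsolete > 0L)
    warning(sprintf("dropped %d obsolete term(s) at load", n_obsolete))
  new_ontology_graph(terms)
}

# Build and validate the graph object from a named term list.
new_ontology_graph <- function(terms) {
  ids <- names(terms)
  for (tm in terms) {
    unknown <- setdiff(tm$parents, ids)
    if (length(unknown))
      stop(sprintf("term %s references unknown parent %s", tm$id, unknown[1L]))
  }
  # Kahn topological sort for cycle detection
  n_parents <- vapply(terms, function(tm) length(tm$parents), 0L)
  children <- split(
    rep(ids, n_parents),
    unlist(lapply(terms, `[[`, "parents"), use.names = FALSE)
  )
  indeg <- n_parents
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    on_cycle <- ids[indeg > 0L]
    stop(sprintf("cycle detected in ontology; involves term %s", on_cycle[1L]))
  }
  root_ids <- ids[n_parents == 0L]
  ns_of_root <- vapply(terms[root_ids], `[[`, "", "namespace")
  if (anyDuplicated(ns_of_root))
    stop(sprintf("namespace %s has more than one root",
                 ns_of_root[duplicated(ns_of_root)][1L]))
  roots <- root_ids
  names(roots) <- ns_of_root
  structure(
    list(terms = terms, roots = roots, .anc = new.env(parent = emptyenv())),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d namespace(s) [%s]\n",
              length(x$terms), length(x$roots),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

term_ids <- function(graph) names(graph$terms)

stopifnot_term <- function(graph, id) {
  if (!id %in% names(graph$terms)) stop(sprintf("unknown term id: %s", id))
}

#' Reflexive-transitive ancestor closure of a term
#'
#' Follows `is_a` and `part_of` edges along every path to the namespace root;
#' the result includes the term itself. Memoised on the graph object so repeat
#' queries are O(1).
#'
#' @param graph an `ontology_graph`.
#' @param term a term id present in the graph.
#' @return character vector of ancestor term ids (including `term`).
#' @export
ancestors <- function(graph, term) {
  stopifnot_term(graph, term)
  cache <- graph$.anc
  memo_anc <- function(id) {
    hit <- cache[[id]]
    if (!is.null(hit)) return(hit)
    out <- unique(c(id, unlist(lapply(graph$terms[[id]]$parents, memo_anc),
                              use.names = FALSE)))
    assign(id, out, envir = cache)
    out
  }
  memo_anc(term)
}

#' Descendant closure of a term (including the term itself)
#'
#' @inheritParams ancestors
#' @return character vector of term ids whose ancestor closure contains `term`.
#' @export
descendants <- function(graph, term) {
  stopifnot_term(graph, term)
  ids <- term_ids(graph)
  ids[vapply(ids, function(i) term %in% ancestors(graph, i), NA)]
}

#' Per-term annotation probabilities over a corpus
#'
#' A gene counts toward term `c` when any of its direct annotations is `c` or
#' a descendant of `c` (the true-path rule). With
#' `denominator_mode = "gene_products"` (default) the probability is the gene
#' count over the number of annotated genes; `"associations"` divides by the
#' number of direct (gene, term) pairs instead. Namespace roots are clamped to
#' probability 1 in both modes so that root information content is exactly 0.
#' Terms with zero count are omitted.
#'
#' @param graph an `ontology_graph`.
#' @param corpus an `annotation_corpus` (see [read_gene2go()]).
#' @param denominator_mode `"gene_products"` or `"associations"`.
#' @return named numeric vector of probabilities in (0, 1].
#' @export
term_probability <- function(graph, corpus,
                             denominator_mode = c("gene_products", "associations")) {
  denominator_mode <- match.arg(denominator_mode)
  if (corpus$n_genes == 0L) stop("empty annotation corpus")
  bad <- setdiff(unique(unlist(corpus$direct, use.names = FALSE)), term_ids(graph))
  if (length(bad))
    stop(sprintf("corpus references term absent from graph: %s", bad[1L]))
  counts <- integer(0)
  tab <- table(unlist(lapply(corpus$direct, function(terms) {
    unique(unlist(lapply(terms, ancestors, graph = graph), use.names = FALSE))
  }), use.names = FALSE))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  denom <- switch(denominator_mode,
                  gene_products = corpus$n_genes,
                  associations = corpus$n_associations)
  p <- counts / denom
  p[names(p) %in% graph$roots] <- 1
  p
}

#' Information content from a probability table
#'
#' IC(c) = -ln p(c), in nats. Roots (p = 1) get exactly 0.
#'
#' @param p named numeric vector of probabilities in (0, 1].
#' @return an `ic_table`: list with `ic` and `p`, both named numeric vectors.
#' @export
information_content <- function(p) {
  if (any(p <= 0 | p > 1)) stop("probabilities must lie in (0, 1]")
  ic <- -log(p)
  ic[p == 1] <- 0
  structure(list(ic = ic, p = p), class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("ic_table: %d terms, IC range [%.4f, %.4f] nats\n",
              length(x$ic), min(x$ic), max(x$ic)))
  invisible(x)
}

#' Serialize an ontology graph as OBO 1.2 text
#'
#' @param graph an `ontology_graph`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return invisibly, the character vector of OBO lines.
#' @export
write_obo <- function(graph, path = NULL) {
  out <- c("format-version: 1.2", "")
  for (tm in graph$terms) {
    out <- c(out, "[Term]",
             paste0("id: ", tm$id),
             paste0("name: ", tm$name),
             paste0("namespace: ", tm$namespace))
    if (length(tm$parents)) {
      is_isa <- tm$relations == "is_a"
      out <- c(out,
               if (any(is_isa)) paste0("is_a: ", tm$parents[is_isa]),
               if (any(!is_isa)) paste0("relationship: part_of ", tm$parents[!is_isa]))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
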