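# Seeded synthetic ontologies and annotation corpora. These emulate the
# statistical structure the validation machinery assumes -- a multi-root DAG
# with heavy-tailed annotation frequencies, and a "disease module" of genes
# sharing rare, specific terms -- so every statistic in the package is
# testable without downloading GO or gene2go.

#' Parameters of a synthetic ontology/corpus fixture
#'
#' @param n_terms terms per namespace (including the root).
#' @param n_layers depth of the layered DAG below the root.
#' @param max_parents maximum parents per non-root term.
#' @param n_namespaces number of disconnected namespace components.
#' @param n_genes number of annotated genes.
#' @param mean_annotations mean direct annotations per gene (each gene gets
#'   `1 + Poisson(mean_annotations - 1)` terms).
#' @param module_size number of disease-module genes (0 for a null corpus).
#' @param n_module_terms rare deepest-layer terms shared by the module (1-3).
#' @param power_exponent exponent of the power-law over term annotation
#'   frequencies (GO annotation counts are heavy-tailed).
#' @param seed integer seed.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 120L, n_layers = 6L, max_parents = 3L,
                         n_namespaces = 1L, n_genes = 550L,
                         mean_annotations = 4, module_size = 50L,
                         n_module_terms = 2L, power_exponent = 1.5,
                         seed = 1L) {
  stopifnot(n_terms > n_layers, n_layers >= 1, max_parents >= 1,
            n_namespaces >= 1, n_genes >= 1, mean_annotations >= 1,
            module_size >= 0, module_size < n_genes,
            n_module_terms >= 1, n_module_terms <= 3, power_exponent > 0)
  structure(as.list(environment()), class = "fixture_spec")
}

#' The canonical hand-checkable toy fixture
#'
#' One namespace: root `R`; `A`, `B` is_a `R`; `A1`, `A2` is_a `A`;
#' `B1` is_a `B`. Five genes: `g1 = {A1}`, `g2 = {A2}`, `g3 = {A1, A2}`,
#' `g4 = {B1}`, `g5 = {B}` (6 direct associations). Every worked example in
#' the package documentation computes on this fixture.
#'
#' @return list with `graph` (an `ontology_graph`) and `corpus`
#'   (an `annotation_corpus`).
#' @export
fixture_T1 <- function() {
  mk <- function(id, parents = character(0)) {
    list(id = id, name = paste("term", id), namespace = "synthetic",
         parents = parents, relations = rep("is_a", length(parents)))
  }
  graph <- new_ontology_graph(list(
    R = mk("R"),
    A = mk("A", "R"), B = mk("B", "R"),
    A1 = mk("A1", "A"), A2 = mk("A2", "A"),
    B1 = mk("B1", "B")
  ))
  corpus <- annotation_corpus(list(
    g1 = "A1", g2 = "A2", g3 = c("A1", "A2"), g4 = "B1", g5 = "B"
  ))
  list(graph = graph, corpus = corpus)
}

#' Random layered DAG ontology
#'
#' Each namespace gets a root (layer 0) and `n_terms - 1` further terms
#' spread over `n_layers` layers; every non-root term draws 1..`max_parents`
#' parents uniformly from strictly shallower layers, so the graph is acyclic
#' by construction. Deterministic given `spec$seed`.
#'
#' @param spec a `fixture_spec`.
#' @return an `ontology_graph`; term layers are kept in the `layers`
#'   attribute (named integer vector) for downstream corpus generators.
#' @export
random_dag <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(derive_seed(spec$seed, 0L))
  terms <- list()
  layers <- integer(0)
  idx <- 0L
  for (ns in seq_len(spec$n_namespaces)) {
    ns_label <- paste0("synthetic_", ns)
    tid <- function(k) sprintf("SYN:%07d", k)
    root <- tid(idx + 1L)
    terms[[root]] <- list(id = root, name = paste0("root_", ns),
                          namespace = ns_label,
                          parents = character(0), relations = character(0))
    layers[root] <- 0L
    # spread the remaining terms over layers, at least one per layer
    n_rest <- spec$n_terms - 1L
    layer_of <- sort(c(seq_len(spec$n_layers),
                       sample(spec$n_layers, n_rest - spec$n_layers, replace = TRUE)))
    ids <- tid(idx + 1L + seq_len(n_rest))
    for (j in seq_len(n_rest)) {
      lower <- c(root, ids[which(layer_of < layer_of[j])])
      n_par <- min(sample.int(spec$max_parents, 1L), length(lower))
      parents <- sample(lower, n_par)
      # roughly 1 part_of edge in 5, the GO mix of subsumption relations
      rels <- ifelse(stats::runif(n_par) < 0.2, "part_of", "is_a")
      terms[[ids[j]]] <- list(id = ids[j], name = paste0("t", idx + 1L + j),
                              namespace = ns_label,
                              parents = parents, relations = rels)
      layers[ids[j]] <- layer_of[j]
    }
    idx <- idx + spec$n_terms
  }
  g <- new_ontology_graph(terms)
  attr(g, "layers") <- layers
  g
}

#' Synthetic annotation corpus with an optional disease module
#'
#' Background genes draw their direct annotations independently from all
#' non-root terms with power-law weights (shallow terms frequent, deep terms
#' rare). The first `module_size` genes -- the disease module -- additionally
#' share `n_module_terms` designated terms picked from the deepest layer, so
#' their pairwise SSM exceeds the background's through a common specific
#' ancestor. With `module_size = 0` the corpus is an exchangeable null.
#' Deterministic given `spec$seed`.
#'
#' @param graph an `ontology_graph` from [random_dag()] (needs the `layers`
#'   attribute).
#' @param spec the `fixture_spec` used to build `graph`.
#' @return list with `corpus` (an `annotation_corpus`), `disease_genes`
#'   (character vector, empty for a null corpus) and `module_terms`.
#' @export
clustered_corpus <- function(graph, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  layers <- attr(graph, "layers")
  if (is.null(layers)) stop("graph lacks the layers attribute of random_dag()")
  set.seed(derive_seed(spec$seed, 1L))
  pool <- names(layers)[layers > 0L]
  pool <- pool[order(layers[pool], pool)]
  w <- seq_along(pool)^(-spec$power_exponent)
  deepest <- names(layers)[layers == max(layers)]
  module_terms <- sample(deepest, min(spec$n_module_terms, length(deepest)))
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  k <- 1L + stats::rpois(spec$n_genes, spec$mean_annotations - 1)
  direct <- lapply(seq_len(spec$n_genes), function(g)
    sample(pool, min(k[g], length(pool)), prob = w))
  names(direct) <- genes
  disease <- character(0)
  if (spec$module_size > 0L) {
    disease <- genes[seq_len(spec$module_size)]
    direct[disease] <- lapply(direct[disease], function(t)
      unique(c(t, module_terms)))
  }
  list(corpus = annotation_corpus(direct),
       disease_genes = disease,
       module_terms = module_terms)
}
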