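# Independent brute-force oracles. These deliberately avoid the package's
# vectorized similarity context: ancestors are enumerated by explicit path
# walking, counterparts and sums by plain loops.

oracle_ancestors <- function(graph, id) {
  out <- character(0)
  stack <- id
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(stack, graph$terms[[v]]$parents)
  }
  unique(out)
}

oracle_ic <- function(ic, t) {
  v <- ic$ic[[t]]
  if (is.null(v) || is.na(v)) 0 else v
}

oracle_shared_ic <- function(graph, ic, c1, c2) {
  common <- intersect(oracle_ancestors(graph, c1), oracle_ancestors(graph, c2))
  if (length(common) == 0L) return(0)
  max(vapply(common, oracle_ic, 0, ic = ic))
}

oracle_lin <- function(graph, ic, c1, c2) {
  den <- oracle_ic(ic, c1) + oracle_ic(ic, c2)
  if (den == 0) return(0)
  num <- 2 * oracle_shared_ic(graph, ic, c1, c2)
  if (num == 0) 0 else num / den
}

oracle_counterpart <- function(graph, ic, c, other) {
  other <- unique(other)
  sh <- vapply(other, function(t) oracle_shared_ic(graph, ic, c, t), 0)
  own <- vapply(other, oracle_ic, 0, ic = ic)
  other[order(-sh, own, other)][1L]
}

oracle_directed <- function(g_from, g_to, graph, ic) {
  g_from <- unique(g_from)
  num <- 0
  den <- 0
  for (c in g_from) {
    cp <- oracle_counterpart(graph, ic, c, g_to)
    num <- num + oracle_shared_ic(graph, ic, c, cp)
    den <- den + oracle_ic(ic, c) + oracle_ic(ic, cp)
  }
  if (den == 0) 0 else 2 * num / den
}

oracle_ssm <- function(g1, g2, graph, ic) {
  (oracle_directed(g1, g2, graph, ic) + oracle_directed(g2, g1, graph, ic)) / 2
}

# Exact hypergeometric upper tail by enumeration of the support.
oracle_hyper_sf <- function(N, K, n, k) {
  supp <- max(0, n - (N - K)):min(K, n)
  pm <- exp(lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n))
  sum(pm[supp >= k])
}

oracle_fisher_greater <- function(a, b, c, d) {
  oracle_hyper_sf(a + b + c + d, a + c, a + b, a)
}

# A small random DAG + corpus + IC bundle for property tests; profiles are
# the corpus gene annotation sets, so every profile term has an IC entry.
random_instance <- function(seed, n_terms = 40L, n_genes = 25L) {
  spec <- fixture_spec(n_terms = n_terms, n_layers = 4L, max_parents = 3L,
                       n_genes = n_genes, mean_annotations = 3,
                       module_size = 0L, seed = seed)
  graph <- random_dag(spec)
  corpus <- clustered_corpus(graph, spec)$corpus
  ic <- information_content(term_probability(graph, corpus))
  list(graph = graph, corpus = corpus, ic = ic,
       profiles = corpus$direct)
}
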