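# Core of the gene-gene semantic similarity measure (SSM): Lin term-term
# similarity through the most informative common ancestor (MICA), extended to
# annotation sets by counterpart matching.

ic_lookup <- function(ic, terms, default = 0) {
  v <- ic$ic[terms]
  v[is.na(v)] <- default
  unname(v)
}

# Precomputed state for repeated SSM evaluations over a fixed term universe:
# term index, per-term IC (terms unseen in the corpus imputed at the maximum
# observed IC, i.e. the most specific observed probability), and the matrix of
# shared IC values IC(MICA(t1, t2)) for every term pair.
ssm_context <- function(graph, ic, terms) {
  terms <- sort(unique(terms))
  unknown <- setdiff(terms, names(graph$terms))
  if (length(unknown)) stop(sprintf("unknown term id: %s", unknown[1L]))
  icv <- ic$ic[terms]
  if (anyNA(icv)) {
    message(sprintf(
      "%d term(s) absent from the IC table; imputing IC of the most specific observed term",
      sum(is.na(icv))))
    icv[is.na(icv)] <- max(ic$ic)
  }
  names(icv) <- terms
  anc <- lapply(terms, ancestors, graph = graph)
  anc_universe <- unique(unlist(anc, use.names = FALSE))
  anc_ic <- ic_lookup(ic, anc_universe)
  # universe terms appear in their own closures; keep imputed ICs consistent
  anc_ic[match(terms, anc_universe)] <- unname(icv)
  anc_idx <- lapply(anc, match, table = anc_universe)
  nT <- length(terms)
  shared <- matrix(0, nT, nT, dimnames = list(terms, terms))
  for (i in seq_len(nT)) {
    ai <- anc_idx[[i]]
    for (j in i:nT) {
      common <- ai[ai %in% anc_idx[[j]]]
      if (length(common)) {
        s <- max(anc_ic[common])
        shared[i, j] <- s
        shared[j, i] <- s
      }
    }
  }
  list(terms = terms, icv = icv, shared = shared)
}

# Map a profile's terms to context indices, pre-ordered for the deterministic
# counterpart tie-break: smaller IC first, then lexicographic term id. The
# smaller-IC preference keeps the identity law exact: when a profile holds a
# term and its own descendant, both tie on shared IC against the term itself,
# and only the shallower (the term itself) leaves the normalizer unchanged.
ctx_index <- function(ctx, terms) {
  idx <- match(terms, ctx$terms)
  if (anyNA(idx)) stop("profile term missing from similarity context")
  idx[order(ctx$icv[idx], ctx$terms[idx])]
}

ctx_directed <- function(ctx, i_from, i_to) {
  M <- ctx$shared[i_from, i_to, drop = FALSE]
  cp <- max.col(M, ties.method = "first")
  num <- 2 * sum(M[cbind(seq_along(i_from), cp)])
  den <- sum(ctx$icv[i_from] + ctx$icv[i_to[cp]])
  if (den == 0) 0 else num / den
}

ctx_ssm <- function(ctx, i1, i2) {
  (ctx_directed(ctx, i1, i2) + ctx_directed(ctx, i2, i1)) / 2
}

check_profile <- function(terms, who = "profile") {
  if (length(terms) == 0L) stop(sprintf("%s has an empty term set", who))
  invisible(terms)
}

#' Most informative common ancestor of two terms
#'
#' The common ancestor (over the reflexive ancestor closures) with maximum
#' information content; ties resolved to the lexicographically smallest id.
#' Terms in different namespaces share no ancestor and yield `NA`, which
#' downstream similarity treats as shared IC 0.
#'
#' @param graph an `ontology_graph`.
#' @param ic an `ic_table`.
#' @param c1,c2 term ids.
#' @return a term id, or `NA_character_` when no common ancestor exists.
#' @export
mica <- function(graph, ic, c1, c2) {
  common <- intersect(ancestors(graph, c1), ancestors(graph, c2))
  if (length(common) == 0L) return(NA_character_)
  icc <- ic_lookup(ic, common)
  common <- common[icc == max(icc)]
  sort(common)[1L]
}

#' Lin similarity between two ontology terms
#'
#' `2 * IC(MICA) / (IC(c1) + IC(c2))`; defined as 0 when the terms share no
#' ancestor or when both carry zero information (root-only annotations).
#'
#' @inheritParams mica
#' @return a similarity in \[0, 1\].
#' @export
lin_similarity <- function(graph, ic, c1, c2) {
  m <- mica(graph, ic, c1, c2)
  denom <- sum(ic_lookup(ic, c(c1, c2)))
  if (is.na(m) || denom == 0) return(0)
  2 * ic_lookup(ic, m) / denom
}

#' Counterpart of a term within another gene's annotation set
#'
#' The term of `other` sharing the most information with `c` (maximum
#' IC of the common ancestor); ties broken by smaller own IC, then
#' lexicographic term id, so rankings built on SSM are reproducible. The
#' smaller-IC resolution is what keeps SSM exactly 1 for identical
#' annotation sets: against a tied descendant, the term itself is the
#' counterpart that does not inflate the global-description normalizer.
#'
#' @inheritParams mica
#' @param c a term id.
#' @param other non-empty character vector of term ids.
#' @return a term id from `other`.
#' @export
counterpart <- function(graph, ic, c, other) {
  check_profile(other, "counterpart target")
  ctx <- ssm_context(graph, ic, c(c, other))
  i_to <- ctx_index(ctx, unique(other))
  M <- ctx$shared[match(c, ctx$terms), i_to]
  ctx$terms[i_to[which.max(M)]]
}

#' Directed set similarity of one gene's annotations against another's
#'
#' Each term of `g_from` is matched to its counterpart in `g_to`; the summed
#' shared (MICA) ICs are normalized by the IC of the global description,
#' `sum(IC(c) + IC(counterpart(c)))`. Zero when the denominator is zero
#' (all-root annotation sets).
#'
#' @param g_from,g_to non-empty character vectors of term ids.
#' @inheritParams mica
#' @return a similarity in \[0, 1\].
#' @export
directed_similarity <- function(g_from, g_to, graph, ic) {
  check_profile(g_from); check_profile(g_to)
  ctx <- ssm_context(graph, ic, c(g_from, g_to))
  ctx_directed(ctx, ctx_index(ctx, unique(g_from)), ctx_index(ctx, unique(g_to)))
}

#' Semantic similarity measure (SSM) between two genes
#'
#' The mean of the two directed set similarities. Symmetric, in \[0, 1\],
#' equal to 1 for identical annotation sets and 0 for sets sharing only
#' namespace roots; for singleton profiles it reduces exactly to
#' [lin_similarity()].
#'
#' @param g1,g2 non-empty character vectors of term ids (gene profiles).
#' @inheritParams mica
#' @return a similarity in \[0, 1\].
#' @export
ssm <- function(g1, g2, graph, ic) {
  check_profile(g1); check_profile(g2)
  ctx <- ssm_context(graph, ic, c(g1, g2))
  ctx_ssm(ctx, ctx_index(ctx, unique(g1)), ctx_index(ctx, unique(g2)))
}

# SSM between every profile of `a` and every profile of `b`, sharing one
# context; workhorse for ranking and cross-validation.
ssm_matrix <- function(a, b, graph, ic) {
  for (g in names(a)) check_profile(a[[g]], g)
  for (g in names(b)) check_profile(b[[g]], g)
  ctx <- ssm_context(graph, ic, unlist(c(a, b), use.names = FALSE))
  ia <- lapply(a, function(t) ctx_index(ctx, unique(t)))
  ib <- lapply(b, function(t) ctx_index(ctx, unique(t)))
  out <- matrix(0, length(a), length(b), dimnames = list(names(a), names(b)))
  for (i in seq_along(ia)) for (j in seq_along(ib))
    out[i, j] <- ctx_ssm(ctx, ia[[i]], ib[[j]])
  out
}

#' Pairwise SSM matrix over a set of gene profiles
#'
#' @param profiles named list of gene profiles (character vectors of term
#'   ids); names are gene ids and must be unique.
#' @inheritParams mica
#' @return symmetric numeric matrix with unit diagonal, gene ids as dimnames.
#' @export
pairwise_ssm <- function(profiles, graph, ic) {
  if (length(profiles) < 2L) stop("need at least two profiles")
  if (anyDuplicated(names(profiles))) stop("duplicate gene ids")
  for (g in names(profiles)) check_profile(profiles[[g]], g)
  ctx <- ssm_context(graph, ic, unlist(profiles, use.names = FALSE))
  idx <- lapply(profiles, function(t) ctx_index(ctx, unique(t)))
  n <- length(profiles)
  out <- matrix(1, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- ctx_ssm(ctx, idx[[i]], idx[[j]])
    out[i, j] <- v
    out[j, i] <- v
  }
  out
}

#' Flatten the upper triangle of a pairwise similarity matrix
#'
#' @param m a symmetric similarity matrix as returned by [pairwise_ssm()].
#' @return numeric vector of the off-diagonal pairwise values.
#' @export
pairwise_values <- function(m) m[upper.tri(m)]

#' Write a similarity matrix as square TSV with gene-id header row and column
#'
#' @param m similarity matrix.
#' @param path output file.
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.table(cbind(gene = rownames(m), format(m, digits = 6)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
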