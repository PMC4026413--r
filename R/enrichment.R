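# Over-representation analysis over an is-a ontology DAG with the
# hypergeometric test conditional on the DAG structure: terms are tested
# children-first, and a term whose children already reached significance
# is re-tested after removing the genes those children explain.

#' Construct an ontology DAG
#'
#' @param terms data.frame with columns `id`, `name`.
#' @param edges data.frame with columns `child`, `parent` (is-a edges).
#'   May be empty for a single-term ontology.
#' @return object of class `lel_ontology` holding the term table, edge
#'   list, and the igraph representation (edges child -> parent).
#' @export
lel_ontology <- function(terms, edges = data.frame(child = character(0),
                                                   parent = character(0))) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(terms))) {
    lel_error("lel_invalid_input", "terms need columns id, name")
  }
  if (anyDuplicated(terms$id)) lel_error("lel_invalid_input", "term ids must be unique")
  if (nrow(edges) > 0) {
    unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
    if (length(unknown)) {
      lel_error("lel_invalid_input",
                sprintf("edges reference unknown terms: %s", paste(unknown, collapse = ", ")))
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$id
  )
  if (!igraph::is_dag(g)) lel_error("lel_structure_error", "ontology contains a cycle")
  roots <- terms$id[!(terms$id %in% edges$child)]
  if (length(roots) != 1L) {
    lel_error("lel_structure_error",
              sprintf("ontology must have a single root, found %d", length(roots)))
  }
  structure(list(terms = terms, edges = edges, graph = g, root = roots),
            class = "lel_ontology")
}

#' @export
print.lel_ontology <- function(x, ...) {
  cat(sprintf("lel_ontology: %d terms, %d is-a edges, root %s\n",
              nrow(x$terms), nrow(x$edges), x$root))
  invisible(x)
}

# Terms in child-before-parent order, ties broken by term id for
# determinism across platforms.
topo_children_first <- function(ontology) {
  ids <- ontology$terms$id
  parents_of <- split(ontology$edges$parent, ontology$edges$child)
  children_left <- table(factor(ontology$edges$parent, levels = ids))
  n_children_left <- as.integer(children_left)
  names(n_children_left) <- ids
  avail <- sort(ids[n_children_left == 0L])
  out <- character(0)
  while (length(avail)) {
    t <- avail[1]
    avail <- avail[-1]
    out <- c(out, t)
    for (p in parents_of[[t]] %||% character(0)) {
      n_children_left[p] <- n_children_left[p] - 1L
      if (n_children_left[p] == 0L) avail <- sort(c(avail, p))
    }
  }
  if (length(out) != length(ids)) lel_error("lel_structure_error", "ontology contains a cycle")
  out
}

#' Propagate annotations up the DAG (true-path rule)
#'
#' Closes a direct gene-to-term annotation map over the ontology: each
#' term's gene set becomes the union of its own direct annotations and
#' those of all its descendants.
#'
#' @param ontology an [lel_ontology()].
#' @param annotation data.frame with columns `gene`, `term` (direct
#'   annotations).
#' @return named list mapping every term id to its closed gene set
#'   (sorted, upper-cased symbols).
#' @export
propagate_annotations <- function(ontology, annotation) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(annotation))) {
    lel_error("lel_invalid_input", "annotation needs columns gene, term")
  }
  unknown <- setdiff(unique(annotation$term), ontology$terms$id)
  if (length(unknown)) {
    lel_error("lel_invalid_input",
              sprintf("annotations to unknown terms: %s", paste(unknown, collapse = ", ")))
  }
  direct <- lapply(
    split(normalize_symbols(annotation$gene), annotation$term),
    unique
  )
  children_of <- split(ontology$edges$child, ontology$edges$parent)
  closed <- vector("list", nrow(ontology$terms))
  names(closed) <- ontology$terms$id
  for (t in topo_children_first(ontology)) {
    gs <- direct[[t]] %||% character(0)
    for (ch in children_of[[t]] %||% character(0)) gs <- c(gs, closed[[ch]])
    closed[[t]] <- sort(unique(gs))
  }
  closed
}

#' One-sided hypergeometric over-representation test
#'
#' Upper-tail inclusive probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: drawing a list of `n` genes from a
#' universe of `N` of which `K` carry the term, the chance of seeing at
#' least the observed `k` carriers.
#'
#' @param k observed overlap (list genes annotated to the term).
#' @param K term size in the universe.
#' @param n gene-list size.
#' @param N universe size.
#' @return the p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  k <- check_count(k, "k", min = 0L); K <- check_count(K, "K", min = 0L)
  n <- check_count(n, "n", min = 0L); N <- check_count(N, "N", min = 0L)
  if (k > min(K, n) || K > N || n > N) {
    lel_error("lel_invalid_input", "inconsistent hypergeometric counts")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Conditional over-representation analysis
#'
#' Tests every term of the DAG for over-representation of `gene_list`
#' within `universe`, conditional on the DAG structure: terms are
#' processed children before parents (ties broken by term id), and a
#' term with significant children (p < `alpha_cond`) is tested after
#' removing, from both its count and its size, the genes annotated to
#' those significant children. `alpha_cond = 0` disables conditioning
#' and reproduces the unconditional test.
#'
#' @param ontology an [lel_ontology()].
#' @param closed closed annotation map from [propagate_annotations()].
#' @param gene_list character vector of gene symbols (subset of
#'   `universe`).
#' @param universe character vector of gene symbols forming the test
#'   universe.
#' @param alpha_cond child-significance cutoff used for conditioning
#'   (default 0.05).
#' @param adjust apply BH adjustment to the resulting p-values (off by
#'   default; the conditional test customarily reports raw p).
#' @return data.frame with columns `term`, `name`, `p`, `count`, `size`,
#'   `conditioned` (and `adj_p` when `adjust = TRUE`), sorted by p.
#' @export
conditional_enrichment <- function(ontology, closed, gene_list, universe,
                                   alpha_cond = 0.05, adjust = FALSE) {
  alpha_cond <- check_fraction(alpha_cond, "alpha_cond")
  gene_list <- unique(normalize_symbols(gene_list))
  universe <- unique(normalize_symbols(universe))
  if (!all(gene_list %in% universe)) {
    lel_error("lel_invalid_input", "gene list must be a subset of the universe")
  }
  n <- length(gene_list)
  N <- length(universe)
  children_of <- split(ontology$edges$child, ontology$edges$parent)

  ord <- topo_children_first(ontology)
  p_vals <- stats::setNames(rep(NA_real_, length(ord)), ord)
  count <- stats::setNames(integer(length(ord)), ord)
  size <- stats::setNames(integer(length(ord)), ord)
  conditioned <- stats::setNames(logical(length(ord)), ord)

  for (t in ord) {
    genes_t <- intersect(closed[[t]] %||% character(0), universe)
    sig_children <- character(0)
    for (ch in children_of[[t]] %||% character(0)) {
      if (!is.na(p_vals[[ch]]) && p_vals[[ch]] < alpha_cond) sig_children <- c(sig_children, ch)
    }
    if (length(sig_children)) {
      absorbed <- unique(unlist(closed[sig_children], use.names = FALSE))
      genes_t <- setdiff(genes_t, absorbed)
      conditioned[[t]] <- TRUE
    }
    K <- length(genes_t)
    k <- length(intersect(genes_t, gene_list))
    size[[t]] <- K
    count[[t]] <- k
    p_vals[[t]] <- if (K == 0L) 1 else hypergeom_test(k, K, n, N)
  }

  out <- data.frame(
    term = ord,
    name = ontology$terms$name[match(ord, ontology$terms$id)],
    p = unname(p_vals),
    count = unname(count),
    size = unname(size),
    conditioned = unname(conditioned),
    stringsAsFactors = FALSE
  )
  if (adjust) out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
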