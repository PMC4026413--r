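# Cross-study concordance: the observed intersection of two DE gene
# lists is referred to a permutation null built from random gene lists
# drawn from the reference study's probe universe, with the exact
# hypergeometric tail as a deterministic cross-check.

#' Observed overlap of two gene lists
#'
#' Intersection size after symbol normalization (upper-casing and
#' whitespace stripping); duplicates within a list count once.
#'
#' @param model_list,reference_list character vectors of gene symbols.
#' @return integer intersection count.
#' @export
observed_overlap <- function(model_list, reference_list) {
  length(intersect(unique(normalize_symbols(model_list)),
                   unique(normalize_symbols(reference_list))))
}

#' Exact hypergeometric overlap p-value
#'
#' Upper-tail inclusive probability that a random list of
#' `model_list_size` genes drawn without replacement from a universe of
#' `universe_size` genes shares at least `observed` genes with a fixed
#' reference list of `reference_de_size` genes. Serves as the analytic
#' oracle for [permutation_overlap_test()].
#'
#' @param observed observed intersection count.
#' @param model_list_size size of the drawn list.
#' @param reference_de_size size of the reference DE list.
#' @param universe_size size of the reference universe.
#' @return the exact tail probability.
#' @export
hypergeometric_overlap_p <- function(observed, model_list_size,
                                     reference_de_size, universe_size) {
  observed <- check_count(observed, "observed", min = 0L)
  model_list_size <- check_count(model_list_size, "model_list_size", min = 0L)
  reference_de_size <- check_count(reference_de_size, "reference_de_size", min = 0L)
  universe_size <- check_count(universe_size, "universe_size", min = 0L)
  if (observed > min(model_list_size, reference_de_size) ||
      model_list_size > universe_size || reference_de_size > universe_size) {
    lel_error("lel_invalid_input", "inconsistent overlap counts")
  }
  stats::phyper(observed - 1, reference_de_size,
                universe_size - reference_de_size, model_list_size,
                lower.tail = FALSE)
}

#' Permutation test for gene-list overlap
#'
#' Draws `n_perm` random gene lists of size `model_list_size` without
#' replacement from the reference universe, records each list's
#' intersection with the reference DE list, and reports the empirical
#' p-value `(#\{null >= observed\} + 1) / (n_perm + 1)`. Ties count as
#' extreme and the +1 keeps the p-value away from zero, matching the
#' customary `<1/n_perm` reporting floor when no null draw reaches the
#' observed overlap. The exact hypergeometric tail is reported alongside.
#'
#' @param model_list_size number of genes drawn per permutation
#'   (the study drew lists of the length of its filtered DE list).
#' @param reference_universe character vector: all probes/genes of the
#'   reference study.
#' @param reference_de_list character vector: the reference study's DE
#'   genes (subset of the universe).
#' @param observed the observed intersection count being tested.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `lel_overlap`: list with `observed`,
#'   `n_perm`, `null_sizes`, `p_empirical`, `p_label` (e.g. `"<0.001"`
#'   when no null value reaches the observed), `p_exact`, `seed`.
#' @export
permutation_overlap_test <- function(model_list_size, reference_universe,
                                     reference_de_list, observed,
                                     n_perm = 1000L, seed = 1L) {
  model_list_size <- check_count(model_list_size, "model_list_size", min = 0L)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  observed <- check_count(observed, "observed", min = 0L)
  universe <- unique(normalize_symbols(reference_universe))
  ref <- unique(normalize_symbols(reference_de_list))
  if (!all(ref %in% universe)) {
    lel_error("lel_invalid_input", "reference DE list must be a subset of the universe")
  }
  if (model_list_size > length(universe)) {
    lel_error("lel_invalid_input", "model_list_size exceeds the reference universe")
  }
  is_ref <- universe %in% ref
  withr::with_seed(seed, {
    null_sizes <- vapply(seq_len(n_perm), function(i) {
      sum(is_ref[sample.int(length(universe), model_list_size)])
    }, integer(1))
  })
  n_ge <- sum(null_sizes >= observed)
  p_emp <- (n_ge + 1) / (n_perm + 1)
  p_label <- if (n_ge == 0) sprintf("<%g", 1 / n_perm) else format(p_emp)
  structure(
    list(
      observed = observed,
      n_perm = n_perm,
      null_sizes = null_sizes,
      p_empirical = p_emp,
      p_label = p_label,
      p_exact = hypergeometric_overlap_p(observed, model_list_size,
                                         length(ref), length(universe)),
      seed = seed
    ),
    class = "lel_overlap"
  )
}

#' Overlap test from the lists themselves
#'
#' Computes the observed intersection of `model_list` and
#' `reference_de_list` and runs [permutation_overlap_test()] with the
#' model list's own length as the permutation list size.
#'
#' @param model_list character vector: the model study's DE genes.
#' @inheritParams permutation_overlap_test
#' @return an `lel_overlap` object (see [permutation_overlap_test()]);
#'   also carries `venn` counts (A-only, B-only, intersection).
#' @export
overlap_test <- function(model_list, reference_de_list, reference_universe,
                         n_perm = 1000L, seed = 1L) {
  model <- unique(normalize_symbols(model_list))
  ref <- unique(normalize_symbols(reference_de_list))
  obs <- length(intersect(model, ref))
  out <- permutation_overlap_test(
    model_list_size = length(model),
    reference_universe = reference_universe,
    reference_de_list = reference_de_list,
    observed = obs, n_perm = n_perm, seed = seed
  )
  out$venn <- c(model_only = length(setdiff(model, ref)),
                reference_only = length(setdiff(ref, model)),
                intersection = obs)
  out
}

#' @export
print.lel_overlap <- function(x, ...) {
  cat(sprintf("overlap test: observed %d, empirical p %s (exact %.3g), %d permutations\n",
              x$observed, x$p_label, x$p_exact, x$n_perm))
  invisible(x)
}
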