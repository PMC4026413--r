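# Synthetic-data generator. Emulates the design of the LEL organ-culture
# microarray study: four matched replicate pairs (R1-R4), two conditions
# (total mucosa at 0 h = reference, epithelium-depleted mucosa at 5 h =
# treated), probe-level intensities with per-array affine calibration,
# multiplicative + additive noise, and a known fraction of truly
# differential probes with log2 effects up to ~5.

#' Simulation configuration
#'
#' All parameters of the synthetic expression generator. Defaults emulate
#' the matched four-pair organ-culture design: per-array affine
#' calibration, log-normal signal, multiplicative noise on the log scale
#' and additive noise on the intensity scale, and differential effects
#' drawn from +-N(2.5, 1) truncated at |lfc| >= 0.5 so that the customary
#' adjusted-p / fold-change filters are meaningful on synthetic data.
#'
#' @param n_probes number of probes on the synthetic array.
#' @param n_subjects number of matched subject pairs (the study used 4).
#' @param frac_de fraction of probes that are truly differential.
#' @param lfc_mean,lfc_sd mean and sd of the magnitude of true log2
#'   effects, truncated below at `lfc_min`.
#' @param lfc_min truncation point; every true effect satisfies
#'   `|lfc| >= lfc_min`.
#' @param prop_up probability a differential probe is upregulated
#'   (default 0.44, the up-fraction observed in the study's DE list).
#' @param sigma_bio per-subject biological sd (log2 scale); the subject
#'   effect is shared between a subject's two samples and cancels in
#'   paired differences.
#' @param sigma_mult multiplicative (log2-scale) measurement noise sd.
#' @param sigma_add additive (intensity-scale) measurement noise sd.
#' @param baseline_mean,baseline_sd mean and sd of baseline log2
#'   abundances across probes.
#' @param offset_range range of per-array calibration offsets a_i
#'   (intensity units), drawn uniformly; or a numeric vector of exactly
#'   `2 * n_subjects` offsets to use as-is.
#' @param scale_range range of per-array calibration scales b_i (> 0),
#'   drawn uniformly; or a vector of `2 * n_subjects` scales.
#' @param seed integer seed; one seed drives all draws through a single
#'   generator, so identical seeds give bit-identical output.
#' @return a list of class `lel_sim_config`.
#' @export
sim_config <- function(n_probes = 2000L, n_subjects = 4L, frac_de = 0.05,
                       lfc_mean = 2.5, lfc_sd = 1, lfc_min = 0.5,
                       prop_up = 0.44,
                       sigma_bio = 0.5, sigma_mult = 0.25, sigma_add = 20,
                       baseline_mean = 8, baseline_sd = 2,
                       offset_range = c(20, 80), scale_range = c(0.7, 1.4),
                       seed = 1L) {
  cfg <- list(
    n_probes = check_count(n_probes, "n_probes"),
    n_subjects = check_count(n_subjects, "n_subjects"),
    frac_de = check_fraction(frac_de, "frac_de"),
    lfc_mean = check_nonneg(lfc_mean, "lfc_mean"),
    lfc_sd = check_nonneg(lfc_sd, "lfc_sd"),
    lfc_min = check_nonneg(lfc_min, "lfc_min"),
    prop_up = check_fraction(prop_up, "prop_up"),
    sigma_bio = check_nonneg(sigma_bio, "sigma_bio"),
    sigma_mult = check_nonneg(sigma_mult, "sigma_mult"),
    sigma_add = check_nonneg(sigma_add, "sigma_add"),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = check_nonneg(baseline_sd, "baseline_sd"),
    offset_range = as.numeric(offset_range),
    scale_range = as.numeric(scale_range),
    seed = check_count(seed, "seed", min = 0L)
  )
  n_arrays <- 2L * cfg$n_subjects
  if (!length(cfg$offset_range) %in% c(2L, n_arrays)) {
    lel_error("lel_invalid_config", "offset_range must be a range or one offset per array")
  }
  if (!length(cfg$scale_range) %in% c(2L, n_arrays)) {
    lel_error("lel_invalid_config", "scale_range must be a range or one scale per array")
  }
  if (any(cfg$scale_range <= 0)) {
    lel_error("lel_invalid_config", "array scales must be > 0")
  }
  structure(cfg, class = "lel_sim_config")
}

# Truncated-normal magnitudes via the inverse CDF, so the draw count is
# fixed and seeded runs are reproducible regardless of truncation point.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic paired expression dataset with known truth
#'
#' Raw intensities follow
#' `y = a_i + b_i * 2^(mu_g + subject_g + lfc_g * treated + e_mult) + e_add`,
#' clipped at zero, where `a_i`, `b_i` are per-array affine calibration
#' parameters, `mu_g` baseline log2 abundance, and `lfc_g` the true log2
#' effect of differential probes. The truth table records every
#' differential probe and its effect.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (an [lel_dataset()] on the raw
#'   intensity scale), `truth` (data.frame: probe_id, gene, is_de,
#'   true_log2fc), and `calibration` (data.frame: sample_id, a, b).
#' @export
generate_expression_dataset <- function(config) {
  if (!inherits(config, "lel_sim_config")) config <- do.call(sim_config, config)
  n_probes <- config$n_probes
  n_subj <- config$n_subjects
  n_arrays <- 2L * n_subj

  subjects <- sprintf("R%d", seq_len(n_subj))
  samples <- data.frame(
    sample_id = c(sprintf("%s_0h", subjects), sprintf("%s_5h", subjects)),
    subject_id = rep(subjects, 2L),
    condition = rep(c("reference", "treated"), each = n_subj),
    stringsAsFactors = FALSE
  )

  withr::with_seed(config$seed, {
    mu <- stats::rnorm(n_probes, config$baseline_mean, config$baseline_sd)

    n_de <- round(config$frac_de * n_probes)
    is_de <- rep(FALSE, n_probes)
    if (n_de > 0) is_de[sample.int(n_probes, n_de)] <- TRUE
    lfc <- numeric(n_probes)
    if (n_de > 0) {
      mag <- rtruncnorm_lower(n_de, config$lfc_mean, config$lfc_sd, config$lfc_min)
      sign_up <- stats::rbinom(n_de, 1L, config$prop_up) == 1L
      lfc[is_de] <- ifelse(sign_up, mag, -mag)
    }

    if (length(config$offset_range) == n_arrays) {
      a <- config$offset_range
    } else {
      a <- stats::runif(n_arrays, config$offset_range[1], config$offset_range[2])
    }
    if (length(config$scale_range) == n_arrays) {
      b <- config$scale_range
    } else {
      b <- stats::runif(n_arrays, config$scale_range[1], config$scale_range[2])
    }

    subj_eff <- matrix(stats::rnorm(n_probes * n_subj, 0, config$sigma_bio),
                       n_probes, n_subj)

    log2sig <- matrix(0, n_probes, n_arrays)
    for (j in seq_len(n_arrays)) {
      subj <- match(samples$subject_id[j], subjects)
      treated <- samples$condition[j] == "treated"
      log2sig[, j] <- mu + subj_eff[, subj] + if (treated) lfc else 0
    }
    log2sig <- log2sig + matrix(stats::rnorm(n_probes * n_arrays, 0, config$sigma_mult),
                                n_probes, n_arrays)

    raw <- sweep(sweep(2^log2sig, 2L, b, `*`), 2L, a, `+`) +
      matrix(stats::rnorm(n_probes * n_arrays, 0, config$sigma_add),
             n_probes, n_arrays)
    raw[raw < 0] <- 0
  })

  probes <- data.frame(
    probe_id = sprintf("P%06d", seq_len(n_probes)),
    gene = sprintf("G%06d", seq_len(n_probes)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    probe_id = probes$probe_id,
    gene = probes$gene,
    is_de = is_de,
    true_log2fc = lfc,
    stringsAsFactors = FALSE
  )
  list(
    dataset = lel_dataset(raw, samples, probes, scale = "raw"),
    truth = truth,
    calibration = data.frame(sample_id = samples$sample_id, a = a, b = b,
                             stringsAsFactors = FALSE)
  )
}

#' Generate a toy rooted ontology DAG with gene annotations
#'
#' Builds an acyclic, singly rooted is-a DAG of `n_terms` terms (each term
#' has at most `max_children` children; a quarter of non-root terms get a
#' second parent so the graph is a genuine DAG, not a tree) and annotates
#' `n_genes` synthetic genes to one to three terms each.
#'
#' @param n_terms number of terms (>= 1); term 1 is the root.
#' @param max_children maximum number of children per term.
#' @param n_genes number of genes to annotate.
#' @param seed integer seed.
#' @return list with `ontology` (an [lel_ontology()]) and `annotation`
#'   (data.frame: gene, term).
#' @export
generate_ontology <- function(n_terms, max_children = 3L, n_genes = 50L, seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms")
  max_children <- check_count(max_children, "max_children")
  n_genes <- check_count(n_genes, "n_genes")
  ids <- sprintf("T%04d", seq_len(n_terms))

  withr::with_seed(seed, {
    child <- character(0)
    parent <- character(0)
    n_children <- integer(n_terms)
    if (n_terms > 1L) {
      for (i in 2:n_terms) {
        free <- which(n_children[seq_len(i - 1L)] < max_children)
        p <- if (length(free) == 1L) free else sample(free, 1L)
        child <- c(child, ids[i]); parent <- c(parent, ids[p])
        n_children[p] <- n_children[p] + 1L
        if (i > 2L && stats::runif(1) < 0.25) {
          free2 <- setdiff(which(n_children[seq_len(i - 1L)] < max_children), p)
          if (length(free2) > 0L) {
            p2 <- if (length(free2) == 1L) free2 else sample(free2, 1L)
            child <- c(child, ids[i]); parent <- c(parent, ids[p2])
            n_children[p2] <- n_children[p2] + 1L
          }
        }
      }
    }
    genes <- sprintf("G%06d", seq_len(n_genes))
    ann_gene <- character(0)
    ann_term <- character(0)
    for (g in genes) {
      k <- sample(1:3, 1L)
      terms_g <- if (n_terms == 1L) ids else sample(ids, min(k, n_terms))
      ann_gene <- c(ann_gene, rep(g, length(terms_g)))
      ann_term <- c(ann_term, terms_g)
    }
  })

  ontology <- lel_ontology(
    terms = data.frame(id = ids, name = sprintf("synthetic term %d", seq_len(n_terms)),
                       stringsAsFactors = FALSE),
    edges = data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
  )
  list(ontology = ontology,
       annotation = data.frame(gene = ann_gene, term = ann_term,
                               stringsAsFactors = FALSE))
}

#' Generate a synthetic external reference study
#'
#' Emulates a published comparator study (e.g. an in vivo inflamed-tissue
#' DE list) against which cross-study overlap is tested. The reference DE
#' list shares `ceiling(concordance * n_de)` genes with the truth DE set;
#' the remainder is drawn from non-differential genes. The reference
#' universe contains every simulated gene, padded with reference-only
#' genes up to `universe_size`.
#'
#' @param truth truth table from [generate_expression_dataset()].
#' @param universe_size size of the reference probe universe; must be at
#'   least the number of simulated genes.
#' @param concordance fraction in `[0, 1]` of the truth DE genes present
#'   in the reference DE list.
#' @param ref_size size of the reference DE list; defaults to the number
#'   of truth DE genes.
#' @param seed integer seed.
#' @return list with `ref_list` and `ref_universe` (character vectors of
#'   gene symbols).
#' @export
generate_reference_study <- function(truth, universe_size, concordance,
                                     ref_size = NULL, seed = 1L) {
  concordance <- check_fraction(concordance, "concordance")
  universe_size <- check_count(universe_size, "universe_size")
  genes <- normalize_symbols(truth$gene)
  de_genes <- unique(genes[truth$is_de])
  non_de <- unique(genes[!truth$is_de])
  if (is.null(ref_size)) ref_size <- length(de_genes)
  ref_size <- check_count(ref_size, "ref_size", min = 0L)
  if (universe_size < length(unique(genes))) {
    lel_error("lel_invalid_config", "universe_size smaller than the simulated gene set")
  }
  n_extra <- universe_size - length(unique(genes))
  extra <- if (n_extra > 0) sprintf("REF%06d", seq_len(n_extra)) else character(0)

  n_shared <- min(ceiling(concordance * length(de_genes)), ref_size, length(de_genes))
  withr::with_seed(seed, {
    shared <- if (n_shared > 0) sample(de_genes, n_shared) else character(0)
    pool <- c(non_de, extra)
    n_rest <- ref_size - n_shared
    if (n_rest > length(pool)) {
      lel_error("lel_invalid_config", "ref_size too large for the non-DE universe")
    }
    rest <- if (n_rest > 0) sample(pool, n_rest) else character(0)
  })
  list(ref_list = sort(c(shared, rest)),
       ref_universe = sort(unique(c(genes, extra))))
}
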