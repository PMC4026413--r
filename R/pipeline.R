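# End-to-end driver: simulate (or load) -> normalize -> differential
# expression -> selection -> conditional enrichment -> cross-study
# overlap -> heatmap preparation. Every stage is seeded from the single
# pipeline seed, so a run is fully reproducible from its configuration.

#' Pipeline configuration
#'
#' Collects the parameters of every stage. Stage seeds are derived
#' deterministically from the single `seed`.
#'
#' @param sim a [sim_config()] for the synthetic dataset (its `seed` is
#'   overridden by the pipeline seed).
#' @param trim trimmed-fit fraction for normalization.
#' @param adj_p_cut,abs_lfc_cut DE selection thresholds.
#' @param alpha_cond conditioning cutoff for enrichment.
#' @param n_terms,max_children toy-ontology shape.
#' @param concordance fraction of truth DE genes shared by the synthetic
#'   reference study.
#' @param universe_pad reference-only genes added to the reference
#'   universe beyond the simulated genes.
#' @param n_perm permutations for the overlap test.
#' @param seed master seed.
#' @return list of class `lel_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), trim = 0.9,
                            adj_p_cut = 0.01, abs_lfc_cut = 1,
                            alpha_cond = 0.05,
                            n_terms = 30L, max_children = 3L,
                            concordance = 0.6, universe_pad = 500L,
                            n_perm = 1000L, seed = 1L) {
  seed <- check_count(seed, "seed", min = 0L)
  sim$seed <- (seed * 7L) %% 2147483629L
  structure(list(
    sim = sim, trim = check_fraction(trim, "trim"),
    adj_p_cut = adj_p_cut, abs_lfc_cut = check_nonneg(abs_lfc_cut, "abs_lfc_cut"),
    alpha_cond = check_fraction(alpha_cond, "alpha_cond"),
    n_terms = check_count(n_terms, "n_terms"),
    max_children = check_count(max_children, "max_children"),
    concordance = check_fraction(concordance, "concordance"),
    universe_pad = check_count(universe_pad, "universe_pad", min = 0L),
    n_perm = check_count(n_perm, "n_perm"),
    seed = seed
  ), class = "lel_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; the optional `sim`
#' mapping holds [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return an `lel_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    lel_error("lel_io_error", "the yaml package is required to read YAML configurations")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) cfg$sim <- do.call(sim_config, cfg$sim)
  do.call(pipeline_config, cfg)
}

stage_seed <- function(config, k) (config$seed * 7L + k) %% 2147483629L

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a paired expression dataset with known truth, fits the
#' glog calibration, runs the paired moderated-t analysis with BH
#' adjustment, applies the selection filter, tests the upregulated list
#' for conditional term over-representation against a toy ontology,
#' tests up- and downregulated lists for overlap with a synthetic
#' reference study, and prepares the z-transformed, clustered heatmap
#' matrix of selected probes.
#'
#' @param config an [lel_pipeline_config()][pipeline_config].
#' @param out_dir optional directory; when given, the normalized matrix,
#'   DE table, gene lists, enrichment table, and null distributions are
#'   written there as TSV.
#' @param verbose log per-stage row counts to standard error.
#' @return a report list with elements `dataset`, `truth`,
#'   `calibration`, `de`, `selection`, `up_genes`, `down_genes`,
#'   `enrichment`, `overlap_up`, `overlap_down`, `heatmap`,
#'   `performance`, and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(paste0("[lelpipe] ", fmt), ...))

  say("simulate: %d probes, %d subject pairs, frac_de %.3f (seed %d)",
      config$sim$n_probes, config$sim$n_subjects, config$sim$frac_de, config$seed)
  sim <- generate_expression_dataset(config$sim)

  say("normalize: trimmed glog calibration (trim %.2f)", config$trim)
  cal <- fit_calibration(sim$dataset, trim = config$trim)

  say("diffexp: paired moderated t on %d probes", nrow(cal$dataset$exprs))
  de <- run_diffexp(cal$dataset)
  sel <- select_de(de, adj_p_cut = config$adj_p_cut, abs_lfc_cut = config$abs_lfc_cut)
  up_genes <- de_gene_list(sel$up)
  down_genes <- de_gene_list(sel$down)
  say("select: %d up, %d down (adj p < %g, |logFC| >= %g)",
      nrow(sel$up), nrow(sel$down), config$adj_p_cut, config$abs_lfc_cut)

  onto <- generate_ontology(config$n_terms, config$max_children,
                            n_genes = config$sim$n_probes,
                            seed = stage_seed(config, 3L))
  closed <- propagate_annotations(onto$ontology, onto$annotation)
  ann_universe <- intersect(unique(normalize_symbols(onto$annotation$gene)),
                            unique(normalize_symbols(de$gene)))
  enr <- conditional_enrichment(onto$ontology, closed,
                                intersect(up_genes, ann_universe),
                                ann_universe, alpha_cond = config$alpha_cond)
  say("enrich: %d terms tested, universe %d genes", nrow(enr), length(ann_universe))

  truth_up <- sim$truth; truth_up$is_de <- sim$truth$is_de & sim$truth$true_log2fc > 0
  truth_down <- sim$truth; truth_down$is_de <- sim$truth$is_de & sim$truth$true_log2fc < 0
  universe_size <- config$sim$n_probes + config$universe_pad
  ref_up <- generate_reference_study(truth_up, universe_size, config$concordance,
                                     seed = stage_seed(config, 5L))
  ref_down <- generate_reference_study(truth_down, universe_size, config$concordance,
                                       seed = stage_seed(config, 6L))
  overlap_up <- if (length(up_genes)) {
    overlap_test(up_genes, ref_up$ref_list, ref_up$ref_universe,
                 n_perm = config$n_perm, seed = stage_seed(config, 7L))
  }
  overlap_down <- if (length(down_genes)) {
    overlap_test(down_genes, ref_down$ref_list, ref_down$ref_universe,
                 n_perm = config$n_perm, seed = stage_seed(config, 8L))
  }
  if (!is.null(overlap_up)) {
    say("overlap (up): observed %d, empirical p %s", overlap_up$observed, overlap_up$p_label)
  }
  if (!is.null(overlap_down)) {
    say("overlap (down): observed %d, empirical p %s", overlap_down$observed, overlap_down$p_label)
  }

  sel_probes <- c(sel$up$probe_id, sel$down$probe_id)
  heatmap <- if (length(sel_probes) >= 2L) {
    heatmap_prepare(cal$dataset$exprs[sel_probes, , drop = FALSE])
  }

  report <- list(
    dataset = sim$dataset, truth = sim$truth, calibration = cal,
    de = de, selection = sel, up_genes = up_genes, down_genes = down_genes,
    enrichment = enr, overlap_up = overlap_up, overlap_down = overlap_down,
    heatmap = heatmap,
    performance = evaluate_de(de, sim$truth, adj_p_cut = config$adj_p_cut,
                              abs_lfc_cut = 0),
    config = config
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_expression_tsv(cal$dataset, out_dir)
    utils::write.table(as.data.frame(de), file.path(out_dir, "de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_list(up_genes, file.path(out_dir, "up.txt"))
    write_gene_list(down_genes, file.path(out_dir, "down.txt"))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(overlap_up)) {
      utils::write.table(data.frame(null_size = overlap_up$null_sizes),
                         file.path(out_dir, "overlap_up_null.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    say("wrote outputs to %s", out_dir)
  }
  report
}
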