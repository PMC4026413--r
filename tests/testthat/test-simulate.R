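test_that("identical seeds give bit-identical datasets, different seeds differ", {
  cfg <- sim_config(n_probes = 200, seed = 42)
  s1 <- generate_expression_dataset(cfg)
  s2 <- generate_expression_dataset(cfg)
  expect_identical(s1$dataset$exprs, s2$dataset$exprs)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_expression_dataset(sim_config(n_probes = 200, seed = 43))
  expect_false(identical(s1$dataset$exprs, s3$dataset$exprs))
})

test_that("frac_de = 0 yields a truth table without differential probes", {
  sim <- generate_expression_dataset(sim_config(n_probes = 100, frac_de = 0, seed = 1))
  expect_false(any(sim$truth$is_de))
  expect_true(all(sim$truth$true_log2fc == 0))
})

test_that("truth table marks effects exactly for differential probes", {
  sim <- generate_expression_dataset(sim_config(n_probes = 500, frac_de = 0.2,
                                                lfc_min = 0.5, seed = 5))
  expect_true(all(abs(sim$truth$true_log2fc[sim$truth$is_de]) >= 0.5))
  expect_true(all(sim$truth$true_log2fc[!sim$truth$is_de] == 0))
  expect_equal(sum(sim$truth$is_de), round(0.2 * 500))
})

test_that("every subject contributes exactly one sample per condition", {
  sim <- generate_expression_dataset(sim_config(n_probes = 60, n_subjects = 5, seed = 2))
  s <- sim$dataset$samples
  tab <- table(s$subject_id, s$condition)
  expect_true(all(tab == 1))
  expect_equal(ncol(sim$dataset$exprs), 10)
})

test_that("with zero noise the glog back-transform recovers effects exactly", {
  n_sub <- 3
  cfg <- sim_config(
    n_probes = 80, n_subjects = n_sub, frac_de = 0.25, seed = 9,
    sigma_bio = 0, sigma_mult = 0, sigma_add = 0,
    offset_range = rep(50, 2 * n_sub), scale_range = rep(1.5, 2 * n_sub)
  )
  sim <- generate_expression_dataset(cfg)
  y <- sim$dataset$exprs
  x <- log2((y - 50) / 1.5)   # exact affine inverse of the generator
  d <- x[, 4:6] - x[, 1:3]    # treated minus reference, per subject
  expect_equal(unname(rowMeans(d)), sim$truth$true_log2fc, tolerance = 1e-10)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_probes = 0), class = "lel_invalid_config")
  expect_error(sim_config(n_subjects = -1), class = "lel_invalid_config")
  expect_error(sim_config(frac_de = 1.5), class = "lel_invalid_config")
  expect_error(sim_config(sigma_add = -1), class = "lel_invalid_config")
  expect_error(sim_config(scale_range = c(-1, 2)), class = "lel_invalid_config")
})

test_that("generated ontologies are acyclic, singly rooted, and reproducible", {
  for (seed in 1:5) {
    gen <- generate_ontology(n_terms = 25, max_children = 3, n_genes = 40, seed = seed)
    onto <- gen$ontology
    expect_true(igraph::is_dag(onto$graph))
    roots <- setdiff(onto$terms$id, onto$edges$child)
    expect_length(roots, 1)
    # every term reaches the root
    reach <- igraph::subcomponent(onto$graph, roots, mode = "in")$name
    expect_setequal(reach, onto$terms$id)
    expect_true(all(gen$annotation$term %in% onto$terms$id))
  }
  g1 <- generate_ontology(10, 2, 15, seed = 7)
  g2 <- generate_ontology(10, 2, 15, seed = 7)
  expect_identical(g1$ontology$terms, g2$ontology$terms)
  expect_identical(g1$ontology$edges, g2$ontology$edges)
  expect_identical(g1$annotation, g2$annotation)
})

test_that("a single-term ontology holds all annotations on the root", {
  gen <- generate_ontology(n_terms = 1, n_genes = 8, seed = 3)
  expect_equal(nrow(gen$ontology$edges), 0)
  expect_true(all(gen$annotation$term == gen$ontology$terms$id[1]))
  closed <- propagate_annotations(gen$ontology, gen$annotation)
  expect_setequal(closed[[1]], unique(normalize_symbols(gen$annotation$gene)))
})

test_that("reference-study concordance bounds the truth intersection", {
  sim <- generate_expression_dataset(sim_config(n_probes = 300, frac_de = 0.1, seed = 4))
  de_genes <- normalize_symbols(sim$truth$gene[sim$truth$is_de])

  full <- generate_reference_study(sim$truth, universe_size = 400, concordance = 1, seed = 1)
  expect_setequal(intersect(full$ref_list, de_genes), de_genes)

  none <- generate_reference_study(sim$truth, universe_size = 400, concordance = 0, seed = 1)
  expect_length(intersect(none$ref_list, de_genes), 0)

  half <- generate_reference_study(sim$truth, universe_size = 400, concordance = 0.5, seed = 1)
  expect_length(intersect(half$ref_list, de_genes), ceiling(0.5 * length(de_genes)))
  expect_length(half$ref_universe, 400)

  expect_error(generate_reference_study(sim$truth, 400, concordance = 1.2),
               class = "lel_invalid_config")
})

test_that("pipeline DE calls agree with an independent paired-t oracle", {
  n_sub <- 4
  cfg <- sim_config(n_probes = 2000, frac_de = 0.1, n_subjects = n_sub, seed = 21)
  sim <- generate_expression_dataset(cfg)

  # oracle route, fully outside the package: exact affine inverse with the
  # true calibration, ordinary paired t per probe, Bonferroni at 0.05
  a <- sim$calibration$a; b <- sim$calibration$b
  x <- log2(pmax(sweep(sweep(sim$dataset$exprs, 2, a, `-`), 2, b, `/`), 2^-10))
  d <- x[, (n_sub + 1):(2 * n_sub)] - x[, 1:n_sub]
  p_oracle <- apply(d, 1, function(z) stats::t.test(z)$p.value)
  called_oracle <- p_oracle < 0.05 / length(p_oracle)
  truth_de <- sim$truth$is_de
  recall_oracle <- sum(called_oracle & truth_de) / sum(truth_de)
  fdr_oracle <- if (sum(called_oracle)) {
    sum(called_oracle & !truth_de) / sum(called_oracle)
  } else 0

  # package route, matched procedure: fitted calibration, ordinary t
  # (zero-weight prior), Bonferroni at the same level
  cal <- fit_calibration(sim$dataset)
  prior0 <- structure(list(d0 = 0, s0_sq = 1), class = "lel_variance_prior")
  de <- run_diffexp(cal$dataset, prior = prior0)
  called_pkg <- stats::p.adjust(de$p, "bonferroni") < 0.05
  recall_pkg <- sum(called_pkg & truth_de) / sum(truth_de)
  fdr_pkg <- if (sum(called_pkg)) sum(called_pkg & !truth_de) / sum(called_pkg) else 0

  expect_lt(abs(recall_pkg - recall_oracle), 0.1)
  expect_lt(abs(fdr_pkg - fdr_oracle), 0.1)
})
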