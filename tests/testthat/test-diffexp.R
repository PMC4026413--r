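test_that("paired fit reproduces direct arithmetic on the differences", {
  ds <- make_paired_dataset(c(2, 1, 3, 2))
  fit <- fit_paired(ds)
  expect_equal(unname(fit$logFC[1]), mean(c(2, 1, 3, 2)))
  expect_equal(unname(fit$s2[1]), var(c(2, 1, 3, 2)))
  expect_equal(fit$df_resid, 3)
  expect_equal(fit$v, 1 / 4)

  ones <- fit_paired(make_paired_dataset(c(1, 1, 1, 1)))
  expect_equal(unname(ones$logFC[1]), 1)
  expect_equal(unname(ones$s2[1]), 0)

  zeros <- fit_paired(make_paired_dataset(c(0, 0, 0, 0)))
  expect_equal(unname(zeros$logFC[1]), 0)
})

test_that("design errors name the offending subject", {
  ds <- make_paired_dataset(c(1, 2, 1))
  ds$samples$condition[4] <- "reference"   # S1 loses its treated sample
  expect_error(fit_paired(ds), regexp = "S1", class = "lel_design_error")
  one <- make_paired_dataset(2)
  expect_error(fit_paired(one), class = "lel_insufficient_replication")
})

test_that("variance prior is recovered from scaled inverse-chi-square draws", {
  set.seed(101)
  d0 <- 4; s0 <- 0.05; df <- 3; n <- 1e4
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  prior <- fit_variance_prior(s2, df)
  expect_lt(abs(prior$d0 / d0 - 1), 0.25)
  expect_lt(abs(prior$s0_sq / s0 - 1), 0.10)
})

test_that("variance prior matches limma's moment estimator", {
  set.seed(7)
  s2 <- 0.1 * rf(5000, 3, 6)
  prior <- fit_variance_prior(s2, 3)
  lf <- limma::fitFDist(s2, df1 = 3)
  expect_equal(prior$d0, lf$df2, tolerance = 1e-6)
  expect_equal(prior$s0_sq, lf$scale, tolerance = 1e-6)
})

test_that("constant variances give an infinite prior at the common value", {
  prior <- fit_variance_prior(rep(0.3, 50), 3)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s0_sq, 0.3)
})

test_that("mixing variance populations lowers the prior degrees of freedom", {
  set.seed(55)
  df <- 3; d0 <- 20
  pop1 <- 0.02 * d0 / rchisq(4000, d0) * rchisq(4000, df) / df
  pop2 <- 0.50 * d0 / rchisq(4000, d0) * rchisq(4000, df) / df
  d0_pooled <- fit_variance_prior(c(pop1, pop2), df)$d0
  expect_lt(d0_pooled, fit_variance_prior(pop1, df)$d0)
  expect_lt(d0_pooled, fit_variance_prior(pop2, df)$d0)
})

test_that("moderated t matches the closed-form posterior-variance formulas", {
  prior <- structure(list(d0 = 4, s0_sq = 0.09), class = "lel_variance_prior")
  mt <- moderated_t(logFC = 1, s2 = 0.04, df_resid = 3, prior = prior, v = 1 / 4)
  s2_post <- (4 * 0.09 + 3 * 0.04) / (4 + 3)
  t_exp <- 1 / sqrt(s2_post * 0.25)
  expect_equal(mt$t, t_exp)
  expect_equal(mt$df_total, 7)
  expect_equal(mt$p, 2 * pt(-abs(t_exp), df = 7))
})

test_that("moderated t reduces to the ordinary paired t as d0 -> 0", {
  d <- c(1.2, 0.4, 0.9, 1.6)
  prior0 <- structure(list(d0 = 0, s0_sq = 1), class = "lel_variance_prior")
  mt <- moderated_t(mean(d), var(d), 3, prior0, 1 / 4)
  tt <- t.test(d)
  expect_equal(mt$t, unname(tt$statistic))
  expect_equal(mt$p, tt$p.value)
})

test_that("an infinite prior fixes every posterior variance at s0_sq", {
  priorInf <- structure(list(d0 = Inf, s0_sq = 0.2), class = "lel_variance_prior")
  mt <- moderated_t(c(1, -2, 0.5), c(0.1, 0.9, 0.001), 3, priorInf, 1 / 4)
  expect_true(all(mt$s2_post == 0.2))
  expect_equal(mt$p[1], 2 * pnorm(-abs(1 / sqrt(0.2 / 4))))
})

test_that("zero posterior variance yields flagged signed-infinite statistics", {
  prior0 <- structure(list(d0 = 0, s0_sq = 1), class = "lel_variance_prior")
  mt <- moderated_t(c(2, -3), c(0, 0), 3, prior0, 1 / 4)
  expect_identical(mt$t, c(Inf, -Inf))
  expect_identical(mt$p, c(0, 0))
  expect_true(all(mt$degenerate))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(rep(0.02, 7)), rep(0.02, 7))
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p4), bh_oracle(p4))
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    p <- round(runif(n), sample(1:4, 1))
    expect_equal(bh_adjust(p), bh_oracle(pmax(p, 1e-300)))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), class = "lel_invalid_input")
  expect_error(bh_adjust(c(0.1, -0.1)), class = "lel_invalid_input")
})

test_that("the whole moderated pipeline agrees with limma on simulated data", {
  sim <- generate_expression_dataset(sim_config(n_probes = 600, seed = 3))
  cal <- fit_calibration(sim$dataset)
  de <- run_diffexp(cal$dataset)

  s <- cal$dataset$samples
  design <- stats::model.matrix(
    ~ 0 + factor(s$subject_id) +
      factor(s$condition, levels = c("reference", "treated"))
  )
  colnames(design) <- c(levels(factor(s$subject_id)), "treated")
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(cal$dataset$exprs, design), coefficients = "treated"))

  expect_equal(de$logFC, unname(fit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(attr(de, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(de$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
  expect_equal(de$adj_p, unname(p.adjust(fit$p.value[, 1], "BH")), tolerance = 1e-8)
})

test_that("selection applies both the adjusted-p and fold-change cuts", {
  de <- data.frame(
    probe_id = sprintf("P%d", 1:5),
    gene = c("A", "B", "C", "D", "E"),
    logFC = c(2, 0.5, -1.5, -0.9, 1.2),
    adj_p = c(0.001, 0.001, 0.005, 0.0001, 0.5),
    stringsAsFactors = FALSE
  )
  sel <- select_de(de, adj_p_cut = 0.01, abs_lfc_cut = 1)
  expect_equal(sel$up$gene, "A")        # B excluded: |logFC| 0.5 < 1
  expect_equal(sel$down$gene, "C")      # D excluded, E not significant
  empty <- select_de(de[0, ], 0.01, 1)
  expect_equal(nrow(empty$up), 0)
  expect_equal(nrow(empty$down), 0)
})

test_that("symbol collapse keeps the best adjusted p per gene", {
  de <- data.frame(
    probe_id = sprintf("P%d", 1:3),
    gene = c("X", "x ", "Y"),
    logFC = c(3, 2.5, 2),
    adj_p = c(0.002, 0.0005, 0.001),
    stringsAsFactors = FALSE
  )
  sel <- select_de(de, 0.01, 1, collapse_genes = TRUE)
  expect_equal(nrow(sel$up), 2)
  expect_equal(sel$up$adj_p[sel$up$gene == "x "], 0.0005)
  expect_setequal(de_gene_list(sel$up), c("X", "Y"))
})

test_that("false positives are controlled under the global null", {
  sim <- generate_expression_dataset(sim_config(n_probes = 2000, frac_de = 0, seed = 77))
  cal <- fit_calibration(sim$dataset)
  de <- run_diffexp(cal$dataset)
  frac <- mean(de$adj_p < 0.05)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(de))
  expect_lte(frac, bound)
})

test_that("power at four pairs recovers strong effects", {
  cfg <- sim_config(n_probes = 2000, frac_de = 0.1, lfc_min = 2, lfc_mean = 2.5,
                    n_subjects = 4, seed = 31)
  sim <- generate_expression_dataset(cfg)
  cal <- fit_calibration(sim$dataset)
  de <- run_diffexp(cal$dataset)
  perf <- evaluate_de(de, sim$truth, adj_p_cut = 0.01, abs_lfc_cut = 0)
  expect_gt(perf$recall, 0.8)
})
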