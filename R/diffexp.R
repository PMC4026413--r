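# Paired differential expression with empirical-Bayes variance
# moderation: per-probe within-subject differences, a scaled-F prior on
# the residual variances fitted by trigamma moment matching, moderated t
# statistics on augmented degrees of freedom, and Benjamini-Hochberg
# adjustment, followed by the study's adjusted-p / fold-change selection
# filter.

#' Fit the paired linear model
#'
#' Reduces the paired two-condition design to within-subject differences
#' (treated minus reference): the log2 fold change is the mean
#' difference, the residual variance the sample variance of the
#' differences on `n_subjects - 1` degrees of freedom, and the unscaled
#' variance of the estimate is `v = 1 / n_subjects`. Equivalent to a
#' subject-blocked linear model with a condition contrast.
#'
#' @param dataset a glog-scale [lel_dataset()].
#' @return list with `logFC`, `s2`, `df_resid`, `v`, and the per-subject
#'   difference matrix `diffs`.
#' @export
fit_paired <- function(dataset) {
  design <- paired_design(dataset)
  n <- length(design$subjects)
  if (n < 2L) {
    lel_error("lel_insufficient_replication", "paired analysis needs at least 2 subjects")
  }
  e <- dataset$exprs
  diffs <- e[, design$treated, drop = FALSE] - e[, design$reference, drop = FALSE]
  colnames(diffs) <- design$subjects
  logFC <- rowMeans(diffs)
  s2 <- rowSums((diffs - logFC)^2) / (n - 1L)
  list(logFC = logFC, s2 = s2, df_resid = n - 1L, v = 1 / n, diffs = diffs)
}

# Inverse of trigamma by monotone Newton iteration (trigamma is strictly
# decreasing on (0, Inf)); solved on y directly, tolerance 1e-8.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits the scaled-F model `s2 ~ s0_sq * F(df_resid, d0)` by moment
#' matching on `log(s2)`: the excess of `var(log s2)` over
#' `trigamma(df_resid / 2)` determines the prior degrees of freedom `d0`
#' through the trigamma function, and the mean of `log(s2)` then gives
#' the prior variance `s0_sq`. When the empirical dispersion does not
#' exceed what sampling alone explains, `d0 = Inf` is returned and
#' `s0_sq` is the common variance.
#'
#' @param s2 vector of per-probe residual variances (>= 10 finite
#'   positive values).
#' @param df_resid residual degrees of freedom shared by all probes.
#' @return list of class `lel_variance_prior` with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df_resid) {
  df_resid <- check_count(df_resid, "df_resid")
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 10L) {
    lel_error("lel_invalid_input", "need at least 10 finite positive variances")
  }
  z <- log(s2[ok])
  # centred so that E[z] = log(s0_sq) under the scaled-F model
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  ev <- mean(e)
  vz <- stats::var(z)
  excess <- vz - trigamma(df_resid / 2)
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(ev)
    if (vz == 0) s0_sq <- s2[ok][1]
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "lel_variance_prior")
}

#' Moderated t statistics
#'
#' Shrinks each probe's variance toward the prior,
#' `s2_post = (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)`, and tests
#' `t = logFC / sqrt(s2_post * v)` on `df_resid + d0` degrees of freedom
#' (a normal reference when `d0 = Inf`). With `d0 = 0` this is the
#' ordinary paired t-test.
#'
#' @param logFC per-probe log2 fold changes.
#' @param s2 per-probe residual variances.
#' @param df_resid residual degrees of freedom.
#' @param prior an [fit_variance_prior()] result (or list with `d0`,
#'   `s0_sq`).
#' @param v unscaled variance of the fold-change estimate
#'   (`1 / n_subjects` for the paired design).
#' @return data.frame with `t`, `p`, `df_total`, `s2_post`, and a
#'   `degenerate` flag for probes whose posterior variance is zero (these
#'   get signed infinite t and p = 0).
#' @export
moderated_t <- function(logFC, s2, df_resid, prior, v) {
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (!is.finite(d0) && d0 > 0) {
    s2_post <- rep(s0, length(s2))
    df_total <- Inf
  } else {
    if (d0 < 0 || s0 <= 0) lel_error("lel_invalid_parameter", "invalid variance prior")
    s2_post <- (d0 * s0 + df_resid * s2) / (d0 + df_resid)
    df_total <- df_resid + d0
  }
  degenerate <- s2_post <= 0
  t_mod <- ifelse(degenerate, sign(logFC) * Inf, logFC / sqrt(s2_post * v))
  p <- if (is.finite(df_total)) {
    2 * stats::pt(-abs(t_mod), df = df_total)
  } else {
    2 * stats::pnorm(-abs(t_mod))
  }
  p[degenerate] <- 0
  data.frame(t = t_mod, p = p, df_total = df_total, s2_post = s2_post,
             degenerate = degenerate)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Raw p-values are floored at
#' `1e-300` before adjustment to avoid zero-division in log-scale
#' reporting.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    lel_error("lel_invalid_input", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(pmax(p, 1e-300), method = "BH")
}

#' Run the full paired moderated-t analysis
#'
#' Chains [fit_paired()], [fit_variance_prior()], [moderated_t()], and
#' [bh_adjust()] into the per-probe differential expression table.
#'
#' @param dataset a glog-scale [lel_dataset()].
#' @param prior optional variance prior; estimated from the data when
#'   `NULL`.
#' @return data.frame of class `lel_de` with columns `probe_id`, `gene`,
#'   `logFC`, `s2`, `df_resid`, `t`, `p`, `adj_p`, `df_total`.
#' @export
run_diffexp <- function(dataset, prior = NULL) {
  fit <- fit_paired(dataset)
  if (is.null(prior)) prior <- fit_variance_prior(fit$s2, fit$df_resid)
  mt <- moderated_t(fit$logFC, fit$s2, fit$df_resid, prior, fit$v)
  out <- data.frame(
    probe_id = dataset$probes$probe_id,
    gene = dataset$probes$gene,
    logFC = unname(fit$logFC),
    s2 = unname(fit$s2),
    df_resid = fit$df_resid,
    t = mt$t,
    p = mt$p,
    adj_p = bh_adjust(mt$p),
    df_total = mt$df_total,
    stringsAsFactors = FALSE
  )
  attr(out, "prior") <- prior
  class(out) <- c("lel_de", "data.frame")
  out
}

#' Select differentially expressed probes
#'
#' Applies the study's selection filter: adjusted p below `adj_p_cut`
#' and absolute log2 fold change at least `abs_lfc_cut` (0 disables the
#' fold-change requirement). Selection is probe-level; duplicated gene
#' symbols are retained unless `collapse_genes = TRUE`, which keeps the
#' best adjusted p per symbol.
#'
#' @param de an `lel_de` table (or data.frame with `gene`, `logFC`,
#'   `adj_p`).
#' @param adj_p_cut adjusted-p cutoff in `(0, 1]` (default 0.01).
#' @param abs_lfc_cut absolute log2 fold-change cutoff (default 1).
#' @param collapse_genes deduplicate gene symbols, keeping the smallest
#'   adjusted p.
#' @return list with data.frames `up` and `down` (sorted by adjusted p).
#' @export
select_de <- function(de, adj_p_cut = 0.01, abs_lfc_cut = 1, collapse_genes = FALSE) {
  if (length(adj_p_cut) != 1L || !is.finite(adj_p_cut) || adj_p_cut <= 0 || adj_p_cut > 1) {
    lel_error("lel_invalid_parameter", "adj_p_cut must lie in (0, 1]")
  }
  abs_lfc_cut <- check_nonneg(abs_lfc_cut, "abs_lfc_cut")
  de <- as.data.frame(de)
  pick <- function(rows) {
    out <- de[rows, , drop = FALSE]
    out <- out[order(out$adj_p), , drop = FALSE]
    if (collapse_genes) out <- out[!duplicated(normalize_symbols(out$gene)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  sig <- de$adj_p < adj_p_cut
  list(
    up = pick(sig & de$logFC >= abs_lfc_cut),
    down = pick(sig & de$logFC <= -abs_lfc_cut)
  )
}

#' Extract normalized gene symbols from a selection
#'
#' @param selection one element (`up` or `down`) of a [select_de()]
#'   result, or any data.frame with a `gene` column.
#' @param unique_symbols drop duplicate symbols (default `TRUE`).
#' @return character vector of upper-cased gene symbols.
#' @export
de_gene_list <- function(selection, unique_symbols = TRUE) {
  g <- normalize_symbols(selection$gene)
  g <- g[!is.na(g) & g != "" & g != "NA"]
  if (unique_symbols) g <- unique(g)
  g
}

#' Evaluate DE calls against simulation truth
#'
#' @param de an `lel_de` table.
#' @param truth truth table from [generate_expression_dataset()].
#' @param adj_p_cut,abs_lfc_cut selection thresholds (see [select_de()]).
#' @return list with `recall`, `fdr`, `n_called`, `n_true`.
#' @export
evaluate_de <- function(de, truth, adj_p_cut = 0.01, abs_lfc_cut = 0) {
  sel <- select_de(de, adj_p_cut = adj_p_cut, abs_lfc_cut = abs_lfc_cut)
  called <- c(sel$up$probe_id, sel$down$probe_id)
  true_de <- truth$probe_id[truth$is_de]
  n_called <- length(called)
  tp <- length(intersect(called, true_de))
  list(
    recall = if (length(true_de)) tp / length(true_de) else NA_real_,
    fdr = if (n_called) (n_called - tp) / n_called else 0,
    n_called = n_called,
    n_true = length(true_de)
  )
}
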