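# qRT-PCR transcript-count processing: housekeeping normalization to
# PPIB (peptidylprolyl isomerase B) and relative scaling to a reference
# condition, aggregated with experiment as the replication unit.

#' Normalize transcript counts to the PPIB housekeeping gene
#'
#' `1000 * target / ppib`: transcripts per 1000 transcripts of PPIB,
#' correcting for differences in mRNA content between samples.
#'
#' @param target target-gene transcript counts (>= 0).
#' @param ppib PPIB transcript counts (> 0).
#' @return normalized values.
#' @export
normalize_to_ppib <- function(target, ppib) {
  if (any(!is.finite(ppib) | ppib <= 0)) {
    lel_error("lel_undefined_normalization", "PPIB transcript counts must be > 0")
  }
  if (any(!is.finite(target) | target < 0)) {
    lel_error("lel_invalid_input", "target transcript counts must be >= 0")
  }
  1000 * target / ppib
}

#' Scale condition values relative to a reference condition
#'
#' Divides every condition's value by the reference condition's value,
#' so the reference maps to exactly 1 and all other conditions to
#' fractions/multiples of it.
#'
#' @param values named numeric vector (names are condition labels).
#' @param reference the reference condition label.
#' @return scaled values, same names.
#' @export
relative_to_reference <- function(values, reference) {
  if (!reference %in% names(values)) {
    lel_error("lel_invalid_input", sprintf("reference condition '%s' not present", reference))
  }
  ref_val <- values[[reference]]
  if (!is.finite(ref_val) || ref_val <= 0) {
    lel_error("lel_invalid_input", "reference condition value must be > 0")
  }
  values / ref_val
}

#' Normalize and summarize a qPCR table
#'
#' Computes transcripts per 1000 PPIB per row, optionally rescales each
#' experiment's values for a gene relative to a reference condition
#' (reference set to 1), and aggregates across independent experiments
#' (mean, SEM = sd / sqrt(n), n). Normalization and scaling happen per
#' experiment before averaging, respecting experiment as the
#' replication unit.
#'
#' @param table data.frame with columns `experiment`, `condition`,
#'   `gene`, `target_count`, `ppib_count`.
#' @param reference_condition optional condition label; when given,
#'   values are scaled within each (experiment, gene) so this condition
#'   equals 1.
#' @return list with `per_sample` (the row-level normalized/scaled
#'   table) and `summary` (per gene x condition: mean, sem, n).
#' @export
qpcr_normalize <- function(table, reference_condition = NULL) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  needed <- c("experiment", "condition", "gene", "target_count", "ppib_count")
  if (!all(needed %in% names(table))) {
    lel_error("lel_invalid_input",
              sprintf("qPCR table needs columns: %s", paste(needed, collapse = ", ")))
  }
  table$normalized <- normalize_to_ppib(table$target_count, table$ppib_count)

  if (!is.null(reference_condition)) {
    key <- interaction(table$experiment, table$gene, drop = TRUE)
    scaled <- unlist(lapply(split(seq_len(nrow(table)), key), function(idx) {
      vals <- stats::setNames(table$normalized[idx], table$condition[idx])
      relative_to_reference(vals, reference_condition)
    }), use.names = FALSE)
    table$relative <- NA_real_
    table$relative[unlist(split(seq_len(nrow(table)), key), use.names = FALSE)] <- scaled
  }

  value_col <- if (is.null(reference_condition)) "normalized" else "relative"
  agg <- stats::aggregate(
    table[[value_col]],
    by = list(gene = table$gene, condition = table$condition),
    FUN = function(x) c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
  )
  summary <- data.frame(
    gene = agg$gene,
    condition = agg$condition,
    mean = agg$x[, "mean"],
    sem = agg$x[, "sem"],
    n = as.integer(agg$x[, "n"]),
    stringsAsFactors = FALSE
  )
  list(per_sample = table, summary = summary)
}
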