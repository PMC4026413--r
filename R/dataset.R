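# Expression container: a probe x sample intensity (or stabilized) matrix
# together with the sample sheet of a paired two-condition design and a
# probe -> gene annotation. Modeled on the plain list-of-matrix containers
# used throughout limma.

#' Construct an expression dataset
#'
#' Bundles a probe-by-sample matrix with its sample sheet (subject pairing
#' and condition) and probe annotation. The design is paired: every subject
#' must contribute exactly one `reference` and one `treated` sample.
#'
#' @param exprs numeric matrix, probes in rows, samples in columns. Column
#'   names must match `samples$sample_id`.
#' @param samples data.frame with columns `sample_id`, `subject_id`,
#'   `condition` (values `"reference"` or `"treated"`), one row per column
#'   of `exprs`.
#' @param probes data.frame with columns `probe_id`, `gene`, one row per
#'   row of `exprs`. Probe ids must be unique; gene symbols may repeat.
#' @param scale `"raw"` for scanner intensities, `"glog"` after
#'   variance-stabilizing transformation.
#' @return an object of class `lel_dataset`.
#' @export
lel_dataset <- function(exprs, samples, probes, scale = c("raw", "glog")) {
  scale <- match.arg(scale)
  exprs <- as.matrix(exprs)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subject_id", "condition") %in% names(samples))) {
    lel_error("lel_invalid_input", "sample sheet needs columns sample_id, subject_id, condition")
  }
  if (!all(c("probe_id", "gene") %in% names(probes))) {
    lel_error("lel_invalid_input", "probe annotation needs columns probe_id, gene")
  }
  if (nrow(samples) != ncol(exprs)) {
    lel_error("lel_invalid_input", "sample sheet rows must match matrix columns")
  }
  if (nrow(probes) != nrow(exprs)) {
    lel_error("lel_invalid_input", "probe annotation rows must match matrix rows")
  }
  if (anyDuplicated(probes$probe_id)) {
    dup <- unique(probes$probe_id[duplicated(probes$probe_id)])
    lel_error("lel_invalid_input",
              sprintf("duplicate probe ids: %s", paste(dup, collapse = ", ")))
  }
  if (!all(samples$condition %in% c("reference", "treated"))) {
    lel_error("lel_invalid_input", "condition must be 'reference' or 'treated'")
  }
  rownames(exprs) <- probes$probe_id
  colnames(exprs) <- samples$sample_id
  structure(
    list(exprs = exprs, samples = samples, probes = probes, scale = scale),
    class = "lel_dataset"
  )
}

#' @export
print.lel_dataset <- function(x, ...) {
  cat(sprintf("lel_dataset: %d probes x %d samples (%s scale)\n",
              nrow(x$exprs), ncol(x$exprs), x$scale))
  cat(sprintf("  subjects: %s\n", paste(unique(x$samples$subject_id), collapse = ", ")))
  invisible(x)
}

#' @export
dim.lel_dataset <- function(x) dim(x$exprs)

# Checks pairing and returns the sample sheet split into matched
# reference/treated column indices, ordered by subject.
paired_design <- function(dataset) {
  s <- dataset$samples
  subjects <- unique(s$subject_id)
  ref_idx <- integer(length(subjects))
  trt_idx <- integer(length(subjects))
  for (i in seq_along(subjects)) {
    rows <- s$subject_id == subjects[i]
    r <- which(rows & s$condition == "reference")
    t <- which(rows & s$condition == "treated")
    if (length(r) != 1L || length(t) != 1L) {
      lel_error("lel_design_error",
                sprintf("subject '%s' must have exactly one reference and one treated sample",
                        subjects[i]))
    }
    ref_idx[i] <- r
    trt_idx[i] <- t
  }
  list(subjects = subjects, reference = ref_idx, treated = trt_idx)
}
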