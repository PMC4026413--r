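# Shared fixture builders and independent oracles used across test files.

# A tiny paired dataset with prescribed within-subject differences for one
# probe of interest; remaining probes are constant background.
make_paired_dataset <- function(diffs, n_probes = 3, base = 8) {
  n <- length(diffs)
  subjects <- sprintf("S%d", seq_len(n))
  samples <- data.frame(
    sample_id = c(sprintf("%s_ref", subjects), sprintf("%s_trt", subjects)),
    subject_id = rep(subjects, 2),
    condition = rep(c("reference", "treated"), each = n),
    stringsAsFactors = FALSE
  )
  m <- matrix(base, n_probes, 2 * n)
  m[1, (n + 1):(2 * n)] <- base + diffs
  probes <- data.frame(probe_id = sprintf("P%03d", seq_len(n_probes)),
                       gene = sprintf("G%03d", seq_len(n_probes)),
                       stringsAsFactors = FALSE)
  lel_dataset(m, samples, probes, scale = "glog")
}

# Brute-force BH step-up: adj(i) = min over j with p(j) >= p(i) of
# min(1, m * p(j) / rank(j)), ranks with ties taking the largest position.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# Exhaustive hypergeometric upper tail by enumerating all n-subsets of a
# universe of size N whose first K elements carry the property.
enum_hyper_tail <- function(k, K, n, N) {
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)
}

# Naive complete-linkage agglomeration over a distance matrix; returns the
# sorted sequence of merge heights.
complete_linkage_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf
    pair <- c(NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; pair <- c(i, j) }
      }
    }
    heights <- c(heights, best)
    clusters[[pair[1]]] <- c(clusters[[pair[1]]], clusters[[pair[2]]])
    clusters[[pair[2]]] <- NULL
  }
  heights
}

# Three-level toy ontology: root R with children A and B; C under A.
# Direct annotations: C g1-g4, A g5-g6, B g7-g10, R g11-g12.
toy_dag <- function() {
  onto <- lel_ontology(
    terms = data.frame(id = c("R", "A", "B", "C"),
                       name = c("root", "branch A", "branch B", "leaf C"),
                       stringsAsFactors = FALSE),
    edges = data.frame(child = c("A", "B", "C"), parent = c("R", "R", "A"),
                       stringsAsFactors = FALSE)
  )
  ann <- data.frame(
    gene = sprintf("g%d", 1:12),
    term = c(rep("C", 4), rep("A", 2), rep("B", 4), rep("R", 2)),
    stringsAsFactors = FALSE
  )
  list(ontology = onto, annotation = ann)
}
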