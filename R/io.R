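# Plain-text readers and writers. All tabular formats are TSV; numeric
# fields tolerate decimal commas (as printed in the study's tables,
# e.g. "5,1" for 5.1). Writers and readers round-trip losslessly.

parse_decimal <- function(x) {
  out <- suppressWarnings(as.numeric(gsub(",", ".", trimws(x), fixed = TRUE)))
  out
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) lel_error("lel_io_error", sprintf("file not found: %s", path))
  fields <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1])[1]
    lel_error("lel_parse_error",
              sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                      path, bad, fields[bad], fields[1]))
  }
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = character(0))
}

#' Read an expression matrix with its sample sheet
#'
#' The matrix file is TSV with first column `probe_id` and one column
#' per sample (header = sample ids); decimal commas are accepted. The
#' sample sheet has columns `sample_id`, `subject_id`, `condition`. An
#' optional probe annotation file maps `probe_id` to `gene`; without it
#' the probe id doubles as the gene symbol.
#'
#' @param path path to the matrix TSV.
#' @param samples_path path to the sample sheet TSV.
#' @param probes_path optional path to a probe annotation TSV.
#' @param scale `"raw"` or `"glog"` (see [lel_dataset()]).
#' @return an [lel_dataset()].
#' @export
read_expression_tsv <- function(path, samples_path, probes_path = NULL,
                                scale = "raw") {
  tab <- read_tsv_checked(path)
  if (names(tab)[1] != "probe_id") {
    lel_error("lel_parse_error", sprintf("%s: first column must be 'probe_id'", path))
  }
  probe_id <- tab[[1]]
  dup <- unique(probe_id[duplicated(probe_id)])
  if (length(dup)) {
    lel_error("lel_parse_error",
              sprintf("%s: duplicate probe id(s): %s", path, paste(dup, collapse = ", ")))
  }
  m <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L,
              dimnames = list(probe_id, names(tab)[-1]))
  for (j in 2:ncol(tab)) {
    vals <- parse_decimal(tab[[j]])
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      lel_error("lel_parse_error",
                sprintf("%s: non-numeric cell at line %d, column '%s': '%s'",
                        path, bad + 1L, names(tab)[j], tab[[j]][bad]))
    }
    m[, j - 1L] <- vals
  }
  samples <- read_tsv_checked(samples_path)
  probes <- if (!is.null(probes_path)) {
    read_tsv_checked(probes_path)
  } else {
    data.frame(probe_id = probe_id, gene = probe_id, stringsAsFactors = FALSE)
  }
  m <- m[, samples$sample_id, drop = FALSE]
  lel_dataset(m, samples, probes[match(probe_id, probes$probe_id), , drop = FALSE],
              scale = scale)
}

#' Write an expression dataset as TSV files
#'
#' Writes `matrix.tsv` (first column `probe_id`, header = sample ids),
#' `samples.tsv`, and `probes.tsv` into `dir`.
#'
#' @param dataset an [lel_dataset()].
#' @param dir output directory (created if missing).
#' @param digits significant digits for intensities (default 10, enough
#'   for lossless round-trips at test precision).
#' @return invisibly, the paths written.
#' @export
write_expression_tsv <- function(dataset, dir, digits = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "samples.tsv", "probes.tsv"))
  tab <- data.frame(probe_id = dataset$probes$probe_id,
                    signif(dataset$exprs, digits),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$samples, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$probes, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a gene list (one symbol per line)
#' @param path file path.
#' @return character vector of normalized symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- normalize_symbols(x)
  x[x != ""]
}

#' Write a gene list (one symbol per line)
#' @param genes character vector.
#' @param path file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(normalize_symbols(genes), path)
  invisible(path)
}

#' Read an ontology from an edge-list TSV
#'
#' Columns `term_id`, `parent_id`, `name`; the root's `parent_id` is
#' empty or `NA`. A term with several parents repeats its row.
#'
#' @param path file path.
#' @return an [lel_ontology()].
#' @export
read_ontology_tsv <- function(path) {
  tab <- read_tsv_checked(path)
  if (!all(c("term_id", "parent_id", "name") %in% names(tab))) {
    lel_error("lel_parse_error", "ontology TSV needs columns term_id, parent_id, name")
  }
  keep <- !duplicated(tab$term_id)
  terms <- data.frame(id = tab$term_id[keep], name = tab$name[keep],
                      stringsAsFactors = FALSE)
  has_parent <- !is.na(tab$parent_id) & tab$parent_id != "" & tab$parent_id != "NA"
  edges <- data.frame(child = tab$term_id[has_parent],
                      parent = tab$parent_id[has_parent],
                      stringsAsFactors = FALSE)
  lel_ontology(terms, edges)
}

#' Write an ontology to an edge-list TSV
#' @param ontology an [lel_ontology()].
#' @param path file path.
#' @export
write_ontology_tsv <- function(ontology, path) {
  rows <- merge(ontology$terms, ontology$edges,
                by.x = "id", by.y = "child", all.x = TRUE)
  out <- data.frame(term_id = rows$id,
                    parent_id = ifelse(is.na(rows$parent), "", rows$parent),
                    name = rows$name, stringsAsFactors = FALSE)
  out <- out[order(out$term_id, out$parent_id), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ontology from a minimal OBO file
#'
#' Parses only `[Term]` stanzas with `id:`, `name:`, and `is_a:` lines
#' (the subset needed for is-a DAG enrichment).
#'
#' @param path file path.
#' @return an [lel_ontology()].
#' @export
read_obo <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  in_term <- FALSE
  id <- NULL; nm <- NULL
  ids <- character(0); names_ <- character(0)
  child <- character(0); parent <- character(0)
  flush <- function() {
    if (!is.null(id)) {
      ids <<- c(ids, id)
      names_ <<- c(names_, nm %||% id)
    }
  }
  for (ln in lines) {
    if (ln == "[Term]") { flush(); in_term <- TRUE; id <- NULL; nm <- NULL; next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; id <- NULL; nm <- NULL; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) nm <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      child <- c(child, id); parent <- c(parent, target)
    }
  }
  flush()
  lel_ontology(data.frame(id = ids, name = names_, stringsAsFactors = FALSE),
               data.frame(child = child, parent = parent, stringsAsFactors = FALSE))
}

#' Read a gene-to-term annotation TSV
#'
#' Columns `gene` and `term` (or `term_id`).
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `term`.
#' @export
read_annotation_tsv <- function(path) {
  tab <- read_tsv_checked(path)
  term_col <- intersect(c("term", "term_id"), names(tab))[1]
  if (is.na(term_col) || !"gene" %in% names(tab)) {
    lel_error("lel_parse_error", "annotation TSV needs columns gene and term (or term_id)")
  }
  data.frame(gene = tab$gene, term = tab[[term_col]], stringsAsFactors = FALSE)
}

#' Read a differential-expression table in the published-supplement dialect
#'
#' Accepts the column headers used in the study's supplementary export
#' (`Gene symbol`, `logFC`, `adj. P.Val`) as well as this package's own
#' `de.tsv` columns (`gene`, `logFC`, `adj_p`), matching headers
#' case-insensitively. Decimal commas (e.g. `5,1`, `7,50E-05`) are
#' converted.
#'
#' @param path file path.
#' @return data.frame with columns `gene`, `logFC`, `adj_p`.
#' @export
read_de_table <- function(path) {
  tab <- read_tsv_checked(path)
  canon <- function(x) gsub("[^a-z]", "", tolower(x))
  nm <- canon(names(tab))
  gene_col <- match(TRUE, nm %in% c("genesymbol", "gene"))
  lfc_col <- match(TRUE, nm %in% c("logfc", "log2fc", "log2foldchange"))
  p_col <- match(TRUE, nm %in% c("adjpval", "adjp", "adjustedpvalue", "adjpvalue"))
  if (anyNA(c(gene_col, lfc_col, p_col))) {
    lel_error("lel_parse_error",
              "DE table needs gene symbol, logFC, and adjusted-p columns")
  }
  lfc <- parse_decimal(tab[[lfc_col]])
  adj_p <- parse_decimal(tab[[p_col]])
  if (anyNA(lfc) || anyNA(adj_p)) {
    bad <- which(is.na(lfc) | is.na(adj_p))[1]
    lel_error("lel_parse_error",
              sprintf("%s: non-numeric value at line %d", path, bad + 1L))
  }
  data.frame(gene = tab[[gene_col]], logFC = lfc, adj_p = adj_p,
             stringsAsFactors = FALSE)
}
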