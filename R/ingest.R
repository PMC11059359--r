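# Readers and writers for the plain-text formats the pipeline touches:
# gene x sample TSV matrices, design tables, GMT gene sets, drug profile
# directories and the screen report.

#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must have a header of sample ids and a first column `gene_id`.
#' Gene ids are uppercased; duplicate gene ids (e.g. multiple probes mapping
#' to one gene) are collapsed to the row with the largest variance across
#' samples, the standard deterministic microarray convention. With
#' `value_kind = "counts"` all values must be non-negative integers.
#'
#' @param path file path.
#' @param value_kind `"continuous"` (default) or `"counts"`.
#' @return numeric matrix with gene rownames and sample colnames; the value
#'   kind is recorded in `attr(, "value_kind")`.
#' @export
read_expression_tsv <- function(path, value_kind = c("continuous", "counts")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                          data.table = FALSE)
  if (nrow(dt) == 0 || ncol(dt) < 2) {
    format_error(sprintf("empty or sample-less matrix in %s", path))
  }
  gene_ids <- toupper(as.character(dt[[1]]))
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      format_error(sprintf("non-numeric values in column '%s' of %s",
                           names(vals)[j], path))
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- gene_ids
  if (anyNA(mat)) format_error(sprintf("missing values in %s", path))
  if (value_kind == "counts") {
    if (any(mat < 0) || any(mat != round(mat))) {
      bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)[1, ]
      format_error(sprintf(
        "counts must be non-negative integers; offending cell row '%s', column '%s'",
        rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
    }
    storage.mode(mat) <- "integer"
  }
  mat <- collapse_duplicate_genes(mat)
  attr(mat, "value_kind") <- value_kind
  log_msg("read_expression_tsv: %d genes x %d samples from %s",
          nrow(mat), ncol(mat), path)
  mat
}

# keep, per duplicated id, the row with maximal across-sample variance
collapse_duplicate_genes <- function(mat) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  v <- apply(mat, 1, var)
  ord <- order(rownames(mat), -v)         # within id: highest variance first
  mat <- mat[ord, , drop = FALSE]
  mat[!duplicated(rownames(mat)), , drop = FALSE]
}

#' Write an expression matrix (or drug profile) as TSV
#'
#' Genes as rows, first column `gene_id`, remaining columns samples or cell
#' lines. Inverse of [read_expression_tsv()].
#'
#' @param mat numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_expression_tsv <- function(mat, path) {
  check_expression_matrix(mat)
  dt <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read/write a two-column sample design table
#'
#' TSV with columns `sample_id` and `group` (values `control` or `case`).
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(d))) {
    format_error(sprintf("%s must have columns sample_id and group", path))
  }
  check_design(d)
  d
}

#' @rdname read_design_tsv
#' @param design data.frame with columns `sample_id`, `group`.
#' @export
write_design_tsv <- function(design, path) {
  check_design(design)
  data.table::fwrite(design[, c("sample_id", "group")], path, sep = "\t")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: `term<TAB>description<TAB>gene1<TAB>gene2...`, one
#' set per line; the description column is required but may be empty. Member
#' ids are uppercased. A line without at least one member is a format error.
#'
#' @param path file path.
#' @return named list (term id -> list with `name` and `genes`); empty file
#'   gives an empty collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      format_error(sprintf("GMT line %d: need term, description and >= 1 member", i))
    }
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      format_error(sprintf("GMT line %d: no gene members", i))
    }
    out[[parts[1]]] <- list(name = parts[2], genes = genes)
  }
  out
}

#' Read a drug profile library from a directory of TSV files
#'
#' Each `*.tsv` file is one drug (file name without extension = drug id),
#' with genes as rows and one score column per cell line.
#'
#' @param dir directory path.
#' @return named list of genes x cell-lines score matrices.
#' @export
read_drug_library <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) io_error(sprintf("no .tsv drug profiles in %s", dir))
  profiles <- lapply(files, read_expression_tsv)
  names(profiles) <- sub("\\.tsv$", "", basename(files))
  lapply(profiles, function(m) { attr(m, "value_kind") <- NULL; m })
}

#' @rdname read_drug_library
#' @param profiles named list of score matrices.
#' @export
write_drug_library <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(profiles)) {
    write_expression_tsv(profiles[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' Write a screen report: per-cohort ranking TSVs plus a JSON summary
#'
#' Each cohort's ranking is written as
#' `ranking_<cohort>.tsv` with columns `drug_id, et, st_cos, theta_deg,
#' ct_logp, ensemble, rank`, sorted by rank; the JSON summary records the
#' top-k sets, the cross-cohort `common_candidates` and the provenance block.
#' Re-reading a ranking TSV reproduces the ranking order exactly.
#'
#' @param screen_result a `screen_result` from [run_screen()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_screen_report <- function(screen_result, dir) {
  if (!inherits(screen_result, "screen_result")) {
    param_error("screen_result must come from run_screen()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) io_error(sprintf("cannot create directory %s", dir))
  paths <- character(0)
  for (cohort in names(screen_result$cohorts)) {
    ens <- screen_result$cohorts[[cohort]]
    tab <- data.frame(drug_id = ens$drug_id, et = ens$et, st_cos = ens$st_cos,
                      theta_deg = ens$theta_deg, ct_logp = ens$ct,
                      ensemble = ens$final, rank = ens$rank,
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$rank), , drop = FALSE]
    p <- file.path(dir, paste0("ranking_", cohort, ".tsv"))
    data.table::fwrite(tab, p, sep = "\t")
    paths <- c(paths, p)
  }
  summary <- list(
    top_k = screen_result$top_k,
    top_candidates = lapply(screen_result$cohorts, function(ens) {
      ens$drug_id[order(ens$rank)][seq_len(min(screen_result$top_k, nrow(ens)))]
    }),
    common_candidates = screen_result$common_candidates,
    provenance = screen_result$provenance
  )
  jp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA, null = "list")
  invisible(c(paths, jp))
}
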