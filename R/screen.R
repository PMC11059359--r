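# Orchestration: per-cohort screening, cross-cohort candidate intersection,
# forward (concordance) similarity mode, and gene-set over-representation.

#' Screen one cohort against a drug library
#'
#' Runs the full chain: preprocessing (winsorize, quantile-normalize,
#' standardize) -> DEG selection -> disease signature -> per-drug ET/ST/CT ->
#' rank ensemble. Deterministic given its inputs.
#'
#' @param mat raw continuous genes x samples matrix.
#' @param design data.frame with `sample_id`, `group`.
#' @param drug_library named list of genes x cell-lines score matrices (or
#'   bare named score vectors).
#' @param cap direction-set cap for signatures (default 150).
#' @param alpha,lfc_min,tests DEG selection parameters, see [select_degs()].
#' @param aggregate cell-line aggregation, `"median"` or `"mean"`.
#' @param weights ensemble weights for (et, st, ct).
#' @param winsor_low,winsor_high,quantile_norm,standardize preprocessing
#'   switches, see [preprocess_matrix()].
#' @return the [ensemble()] data.frame; the disease DEG table is attached as
#'   attribute `deg_table`.
#' @export
screen_cohort <- function(mat, design, drug_library, cap = 150,
                          alpha = 0.05, lfc_min = 1.0, tests = "both",
                          aggregate = "median", weights = c(1, 1, 1),
                          winsor_low = 0.01, winsor_high = 0.99,
                          quantile_norm = TRUE, standardize = TRUE) {
  if (length(drug_library) == 0 || is.null(names(drug_library))) {
    param_error("screen stage: drug_library must be a non-empty named list")
  }
  pre <- tryCatch(
    preprocess_matrix(mat, winsor_low, winsor_high, quantile_norm, standardize),
    error = function(e) stop("preprocess stage: ", conditionMessage(e)))
  degs <- tryCatch(select_degs(pre, design, alpha, lfc_min, tests),
                   error = function(e) stop("degselect stage: ",
                                            conditionMessage(e)))
  disease_sig <- build_signature(degs, cap = cap)

  rows <- lapply(names(drug_library), function(id) {
    prof <- drug_library[[id]]
    scores <- if (is.matrix(prof)) {
      aggregate_cell_lines(prof, aggregate)
    } else {
      prof
    }
    drug_sig <- build_signature(scores, cap = cap)
    cbind(data.frame(drug_id = id, stringsAsFactors = FALSE),
          score_drug(disease_sig, drug_sig))
  })
  ens <- ensemble(do.call(rbind, rows), weights = weights)
  attr(ens, "deg_table") <- degs
  ens
}

#' Intersect top-k candidates across cohort screens
#'
#' @param ensemble_results named list (>= 2) of [ensemble()] data.frames
#'   screened against the same drug library.
#' @param top_k per-cohort candidate list size (default 10).
#' @return list with `common_candidates` (sorted character vector) and
#'   `ranks` (data.frame: per-cohort rank of each common candidate).
#' @export
intersect_candidates <- function(ensemble_results, top_k = 10) {
  if (length(ensemble_results) < 2) param_error("need >= 2 cohort screens")
  if (top_k < 1) param_error("top_k must be >= 1")
  ids <- lapply(ensemble_results, function(e) sort(e$drug_id))
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]]))) {
    param_error("cohorts were screened against different drug libraries")
  }
  tops <- lapply(ensemble_results, function(e) {
    e$drug_id[order(e$rank)][seq_len(min(top_k, nrow(e)))]
  })
  common <- sort(Reduce(intersect, tops))
  ranks <- data.frame(drug_id = common, stringsAsFactors = FALSE)
  for (nm in names(ensemble_results)) {
    e <- ensemble_results[[nm]]
    ranks[[paste0("rank_", nm)]] <- e$rank[match(common, e$drug_id)]
  }
  list(common_candidates = common, ranks = ranks)
}

#' Run a multi-cohort screen and collect the cross-cohort candidates
#'
#' @param cohorts named list, each element a list with `matrix` and `design`.
#' @param drug_library named list of drug profiles shared by all cohorts.
#' @param top_k per-cohort candidate list size.
#' @param exclude optional character vector of drug ids to drop before
#'   screening (e.g. prior-use or failed-trial compounds).
#' @param ... passed to [screen_cohort()].
#' @return object of class `screen_result`: list with `cohorts` (named
#'   ensembles), `top_k`, `common_candidates`, `candidate_ranks`,
#'   `provenance`.
#' @export
run_screen <- function(cohorts, drug_library, top_k = 10, exclude = NULL,
                       ...) {
  if (length(cohorts) == 0 || is.null(names(cohorts))) {
    param_error("cohorts must be a non-empty named list")
  }
  if (!is.null(exclude)) {
    drug_library <- drug_library[!names(drug_library) %in% exclude]
    if (length(drug_library) == 0) param_error("exclusion removed every drug")
  }
  ens <- lapply(cohorts, function(co) {
    screen_cohort(co$matrix, co$design, drug_library, ...)
  })
  if (length(ens) >= 2) {
    inter <- intersect_candidates(ens, top_k = top_k)
  } else {
    top <- ens[[1]]$drug_id[order(ens[[1]]$rank)][seq_len(min(top_k,
                                                              nrow(ens[[1]])))]
    inter <- list(common_candidates = sort(top),
                  ranks = data.frame(drug_id = sort(top)))
  }
  dots <- list(...)
  structure(
    list(cohorts = ens, top_k = top_k,
         common_candidates = inter$common_candidates,
         candidate_ranks = inter$ranks,
         provenance = list(
           package = "revscreen",
           version = as.character(utils::packageVersion("revscreen")),
           n_drugs = length(drug_library),
           n_excluded = length(exclude),
           cohort_dims = lapply(cohorts, function(co) dim(co$matrix)),
           cohort_checksums = vapply(cohorts, function(co) {
             signif(sum(co$matrix), 12)
           }, numeric(1)),
           params = dots)),
    class = "screen_result"
  )
}

#' Forward (concordance) similarity between two signatures
#'
#' The sign-flipped counterpart of the reversal enrichment score:
#' `S = (es_up - es_down) / 2 = -et`, positive when the two profiles are
#' concordant. Used to compare a DEG pattern against a reference pattern
#' (e.g. a proliferation signature) rather than to reverse it.
#'
#' @param signature_a,signature_b `signature_profile` objects; `signature_b`
#'   provides the direction sets located within `signature_a`'s ranking.
#' @return list with `s`, `es_up`, `es_down`.
#' @export
similarity_mode_score <- function(signature_a, signature_b) {
  et <- enrichment_test(signature_a, signature_b)
  list(s = (et$es_up - et$es_down) / 2, es_up = et$es_up,
       es_down = et$es_down)
}

#' Hypergeometric over-representation analysis of a gene list
#'
#' Per term: the upper-tail hypergeometric p of the query/term overlap given
#' the universe, with BH adjustment across tested terms. Terms are
#' intersected with the universe first; terms with fewer than 3 members in
#' the universe are skipped. Results are sorted by p, then term id.
#'
#' @param query_genes character vector, a subset of `universe_genes`.
#' @param gene_set_collection a [read_gmt()]-style named list.
#' @param universe_genes character vector of measured genes.
#' @return data.frame with `term_id`, `term_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `q`.
#' @export
ora_hypergeom <- function(query_genes, gene_set_collection, universe_genes) {
  query <- unique(toupper(query_genes))
  universe <- unique(toupper(universe_genes))
  if (length(query) == 0 || length(universe) == 0) {
    param_error("query and universe must be non-empty")
  }
  if (!all(query %in% universe)) {
    param_error("query genes must be a subset of the universe")
  }
  rows <- list()
  for (term in names(gene_set_collection)) {
    set <- intersect(toupper(gene_set_collection[[term]]$genes), universe)
    if (length(set) < 3) next
    k <- length(intersect(set, query))
    rows[[term]] <- data.frame(
      term_id = term, term_name = gene_set_collection[[term]]$name,
      overlap = k, set_size = length(set), query_size = length(query),
      universe_size = length(universe),
      p = hyper_upper_tail(k, length(set), length(query), length(universe)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      overlap = integer(0), set_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p = numeric(0), q = numeric(0)))
  }
  tab <- do.call(rbind, rows)
  tab$q <- adjust_bh(tab$p)
  tab <- tab[order(tab$p, tab$term_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
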