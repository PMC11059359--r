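# The three drug-disease scores and their ensemble.
#
# ET (enrichment test): an unweighted two-sided Kolmogorov-Smirnov running-sum
#   statistic locating the drug's up/down gene sets within the disease
#   ranking; et = (es_down - es_up) / 2, positive when the drug opposes the
#   disease signature (drug-up genes at the bottom of the disease ranking and
#   drug-down genes at the top).
# ST (similarity test): cosine between the two profiles' signed DEG score
#   vectors; a larger angle (lower cosine) means stronger opposition, so the
#   reversal score is -cos.
# CT (contingency test): one-sided Fisher-exact (hypergeometric upper-tail)
#   p-values for the two oppositely-directed DEG overlaps, combined by
#   Fisher's method; ct = -log10 of the combined p.

#' Build a ranked signature with capped direction sets
#'
#' From a [select_degs()] table the per-gene score is `log2fc` and the
#' direction sets are restricted to called DEGs: `up_set` holds the top
#' `min(cap, #up-called)` called-up genes by score, `down_set` the analogous
#' genes from the bottom of the ranking. From a bare named score vector
#' (drug profiles carry no DE calls) the sets are the top positive and bottom
#' negative scorers, each capped. Ties are broken by gene id, so repeated
#' builds are identical.
#'
#' @param x a DEG table (data.frame with `gene_id`, `log2fc`, `direction`) or
#'   a named numeric vector of per-gene scores.
#' @param cap maximal size of each direction set (default 150).
#' @return object of class `signature_profile`: list with `ranked_genes`
#'   (descending score), `scores` (named, same order), `up_set`, `down_set`,
#'   `cap`.
#' @export
build_signature <- function(x, cap = 150) {
  if (cap < 1) param_error("cap must be >= 1")
  if (is.data.frame(x)) {
    if (nrow(x) == 0) param_error("empty DEG table")
    scores <- setNames(x$log2fc, x$gene_id)
    up_called <- x$gene_id[x$direction == "up"]
    down_called <- x$gene_id[x$direction == "down"]
  } else if (is.numeric(x)) {
    if (length(x) == 0 || is.null(names(x))) {
      param_error("scores must be a non-empty named numeric vector")
    }
    scores <- x
    up_called <- names(x)[x > 0]
    down_called <- names(x)[x < 0]
  } else {
    param_error("x must be a DEG table or a named numeric score vector")
  }
  if (anyDuplicated(names(scores))) param_error("duplicated gene ids")

  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  ranked <- names(scores)
  up_rank <- ranked[ranked %in% up_called]        # already descending
  down_rank <- rev(ranked[ranked %in% down_called])  # ascending from bottom
  structure(
    list(ranked_genes = ranked, scores = scores,
         up_set = up_rank[seq_len(min(cap, length(up_rank)))],
         down_set = down_rank[seq_len(min(cap, length(down_rank)))],
         cap = cap),
    class = "signature_profile"
  )
}

#' Unweighted KS-style running-sum enrichment score
#'
#' With the gene set occupying positions `p_1 < ... < p_t` of a ranked list of
#' length `n`, the statistic is `a = max_j (j/t - p_j/n)` (concentration at
#' the top) versus `b = max_j (p_j/n - (j-1)/t)` (at the bottom);
#' `ES = a` if `a >= b`, else `-b`. ES lies in (-1, 1].
#'
#' @param ranked_list character vector of unique gene ids, best-ranked first.
#' @param gene_set non-empty subset of `ranked_list`.
#' @return scalar enrichment score.
#' @export
ks_enrichment <- function(ranked_list, gene_set) {
  if (anyDuplicated(ranked_list)) param_error("ranked_list must be unique")
  if (length(gene_set) == 0) param_error("gene_set is empty")
  pos <- match(unique(gene_set), ranked_list)
  if (anyNA(pos)) param_error("gene_set members absent from ranked_list")
  pos <- sort(pos)
  n <- length(ranked_list)
  t <- length(pos)
  j <- seq_len(t)
  a <- max(j / t - pos / n)
  b <- max(pos / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Reversal enrichment test between a disease and a drug signature
#'
#' Both signatures are restricted to their shared gene universe. `es_up`
#' locates the drug's up-set within the disease ranking, `es_down` the
#' drug's down-set; `et = (es_down - es_up) / 2` is positive for reversal
#' (drug-up genes depressed in disease, drug-down genes elevated). If the
#' shared universe is empty or either drug set empties under restriction the
#' drug is scored as missing (`NA`) with a warning.
#'
#' @param disease_signature,drug_signature `signature_profile` objects.
#' @return list with `es_up`, `es_down`, `et`, `n_shared`.
#' @export
enrichment_test <- function(disease_signature, drug_signature) {
  shared <- intersect(disease_signature$ranked_genes,
                      drug_signature$ranked_genes)
  up <- intersect(drug_signature$up_set, shared)
  down <- intersect(drug_signature$down_set, shared)
  if (length(shared) == 0 || length(up) == 0 || length(down) == 0) {
    warning("enrichment_test: empty shared universe or direction set; scored as missing")
    return(list(es_up = NA_real_, es_down = NA_real_, et = NA_real_,
                n_shared = length(shared)))
  }
  ranking <- disease_signature$ranked_genes[
    disease_signature$ranked_genes %in% shared]
  es_up <- ks_enrichment(ranking, up)
  es_down <- ks_enrichment(ranking, down)
  list(es_up = es_up, es_down = es_down, et = (es_down - es_up) / 2,
       n_shared = length(shared))
}

#' Cosine similarity test between two signed DEG score vectors
#'
#' The inputs are the two profiles' scores on a common gene axis (see
#' [st_vectors()]). Returns the cosine, the angle theta in degrees, and the
#' reversal score `-cos` (a larger angle, i.e. stronger opposition, scores
#' higher). A zero vector or fewer than 3 shared dimensions gives `NA` with a
#' warning.
#'
#' @param disease_vector,drug_vector equal-length numeric vectors.
#' @return list with `st_cos`, `theta_deg`, `st_score`.
#' @export
similarity_test <- function(disease_vector, drug_vector) {
  if (length(disease_vector) != length(drug_vector)) {
    param_error("vectors must have equal length")
  }
  if (length(disease_vector) < 3) {
    warning("similarity_test: fewer than 3 shared dimensions; scored as missing")
    return(list(st_cos = NA_real_, theta_deg = NA_real_, st_score = NA_real_))
  }
  cs <- cosine_similarity(disease_vector, drug_vector)
  if (is.na(cs)) {
    warning("similarity_test: zero vector; scored as missing")
    return(list(st_cos = NA_real_, theta_deg = NA_real_, st_score = NA_real_))
  }
  cs <- max(-1, min(1, cs))
  list(st_cos = cs, theta_deg = acos(cs) * 180 / pi, st_score = -cs)
}

#' Build the ST vector pair for two signatures
#'
#' The vector space is the union of the two profiles' DEG sets (up and down),
#' intersected with both measured universes. Each profile contributes its
#' signed score where the gene is one of its DEGs and 0 where the gene is
#' merely measured.
#'
#' @param sig_a,sig_b `signature_profile` objects.
#' @return list with numeric vectors `a` and `b` on the common gene axis.
#' @export
st_vectors <- function(sig_a, sig_b) {
  deg_a <- c(sig_a$up_set, sig_a$down_set)
  deg_b <- c(sig_b$up_set, sig_b$down_set)
  axis <- sort(intersect(union(deg_a, deg_b),
                         intersect(names(sig_a$scores), names(sig_b$scores))))
  va <- ifelse(axis %in% deg_a, sig_a$scores[axis], 0)
  vb <- ifelse(axis %in% deg_b, sig_b$scores[axis], 0)
  list(a = setNames(as.numeric(va), axis), b = setNames(as.numeric(vb), axis))
}

#' Contingency test of oppositely-directed DEG overlaps
#'
#' One-sided Fisher exact (hypergeometric upper-tail) p-values for the
#' drug-up / disease-down overlap and the drug-down / disease-up overlap in a
#' universe of `universe_size` measured genes, combined by Fisher's method
#' (chi-squared, 4 df); `ct = -log10` of the combined p.
#'
#' @param disease_up,disease_down,drug_up,drug_down character gene sets; the
#'   two sets of each profile must be disjoint and lie within the universe.
#' @param universe_size number of genes measured in both profiles.
#' @return list with `ct_p_updown`, `ct_p_downup`, `ct`.
#' @export
contingency_test <- function(disease_up, disease_down, drug_up, drug_down,
                             universe_size) {
  sets <- list(disease_up, disease_down, drug_up, drug_down)
  if (any(vapply(sets, length, 1L) > universe_size)) {
    param_error("a gene set is larger than the universe")
  }
  if (length(intersect(disease_up, disease_down)) > 0 ||
      length(intersect(drug_up, drug_down)) > 0) {
    param_error("up and down sets of one profile must be disjoint")
  }
  p_updown <- hyper_upper_tail(length(intersect(drug_up, disease_down)),
                               length(disease_down), length(drug_up),
                               universe_size)
  p_downup <- hyper_upper_tail(length(intersect(drug_down, disease_up)),
                               length(disease_up), length(drug_down),
                               universe_size)
  x2 <- -2 * (log(p_updown) + log(p_downup))
  p_comb <- pchisq(x2, df = 4, lower.tail = FALSE)
  list(ct_p_updown = p_updown, ct_p_downup = p_downup,
       ct = -log10(p_comb))
}

# P(X >= k) for X ~ Hypergeom(universe N, K marked, n drawn)
hyper_upper_tail <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Aggregate a multi-cell-line drug profile into one score vector
#'
#' Per-gene median (default) or mean across cell lines; all lines of a drug
#' are treated as replicates of one consensus perturbation signature.
#'
#' @param profile genes x cell-lines numeric matrix.
#' @param method `"median"` or `"mean"`.
#' @return named numeric vector of per-gene scores.
#' @export
aggregate_cell_lines <- function(profile, method = c("median", "mean")) {
  method <- match.arg(method)
  if (!is.matrix(profile) || is.null(rownames(profile))) {
    param_error("profile must be a matrix with gene rownames")
  }
  if (method == "median") {
    row_medians(profile)
  } else {
    rowMeans(profile)
  }
}

# vectorised row medians: one global order() call instead of nrow median()s
row_medians <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nc == 1) return(setNames(m[, 1], rownames(m)))
  sorted <- matrix(m[order(row(m), m)], ncol = nc, byrow = TRUE)
  med <- if (nc %% 2 == 1) {
    sorted[, (nc + 1) / 2]
  } else {
    rowMeans(sorted[, nc / 2 + 0:1, drop = FALSE])
  }
  setNames(med, rownames(m))
}

#' Score one drug against a disease signature (ET + ST + CT)
#'
#' @param disease_signature,drug_signature `signature_profile` objects.
#' @return one-row data.frame with `es_up`, `es_down`, `et`, `st_cos`,
#'   `theta_deg`, `ct_p_updown`, `ct_p_downup`, `ct`, `n_overlap_genes`.
#' @export
score_drug <- function(disease_signature, drug_signature) {
  et <- enrichment_test(disease_signature, drug_signature)
  v <- st_vectors(disease_signature, drug_signature)
  st <- similarity_test(v$a, v$b)
  shared <- intersect(disease_signature$ranked_genes,
                      drug_signature$ranked_genes)
  ct <- contingency_test(
    intersect(disease_signature$up_set, shared),
    intersect(disease_signature$down_set, shared),
    intersect(drug_signature$up_set, shared),
    intersect(drug_signature$down_set, shared),
    length(shared))
  data.frame(es_up = et$es_up, es_down = et$es_down, et = et$et,
             st_cos = st$st_cos, theta_deg = st$theta_deg,
             ct_p_updown = ct$ct_p_updown, ct_p_downup = ct$ct_p_downup,
             ct = ct$ct, n_overlap_genes = length(shared))
}

#' Combine per-drug ET/ST/CT scores into a final ensemble ranking
#'
#' Within each test, drugs are ranked in the reversal direction (`et`
#' descending, `-st_cos` descending, `ct` descending) with average ranks for
#' ties; the normalized rank is `(n + 1 - rank) / n` in (0, 1], and the final
#' score is the (weighted) mean of the three normalized ranks. The final
#' ordering is descending with ties broken by drug id. Drugs with any missing
#' component are flagged and placed after all complete drugs.
#'
#' @param score_table data.frame with columns `drug_id`, `et`, `st_cos`, `ct`
#'   (extra columns are carried through).
#' @param weights length-3 positive weights for (et, st, ct); default equal.
#' @return data.frame sorted by `rank` with added columns `rank_et`,
#'   `rank_st`, `rank_ct`, `final`, `rank`, `missing`.
#' @export
ensemble <- function(score_table, weights = c(1, 1, 1)) {
  if (!is.data.frame(score_table) || nrow(score_table) == 0) {
    param_error("score_table must be a non-empty data.frame")
  }
  need <- c("drug_id", "et", "st_cos", "ct")
  if (!all(need %in% names(score_table))) {
    param_error("score_table needs columns drug_id, et, st_cos, ct")
  }
  if (length(weights) != 3 || any(weights <= 0)) {
    param_error("weights must be 3 positive numbers")
  }
  w <- weights / sum(weights)
  tab <- score_table
  tab$missing <- is.na(tab$et) | is.na(tab$st_cos) | is.na(tab$ct)
  comp <- which(!tab$missing)
  n <- length(comp)
  if (n == 0) param_error("no drug has all three scores")

  tab$rank_et <- tab$rank_st <- tab$rank_ct <- NA_real_
  tab$rank_et[comp] <- rank(-tab$et[comp], ties.method = "average")
  tab$rank_st[comp] <- rank(tab$st_cos[comp], ties.method = "average")
  tab$rank_ct[comp] <- rank(-tab$ct[comp], ties.method = "average")
  norm <- function(r) (n + 1 - r) / n
  tab$final <- NA_real_
  tab$final[comp] <- w[1] * norm(tab$rank_et[comp]) +
    w[2] * norm(tab$rank_st[comp]) + w[3] * norm(tab$rank_ct[comp])

  ord <- order(tab$missing, -ifelse(is.na(tab$final), -Inf, tab$final),
               tab$drug_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
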