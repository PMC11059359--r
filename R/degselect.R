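# DEG selection between control and case samples by multiple statistical
# tests: Welch t (parametric) + Mann-Whitney rank-sum (nonparametric),
# conservatively combined by taking the larger p, then BH-adjusted.
# The per-gene tests are row-vectorised so that whole-matrix screens stay
# fast; scalar wrappers expose the same computations for single gene pairs
# (both are cross-checked against stats::t.test / stats::wilcox.test in the
# test suite).

# ---- row-vectorised engines ------------------------------------------------

row_welch_t <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  if (na < 2 || nb < 2) param_error("each group needs >= 2 samples")
  a <- mat[, idx_a, drop = FALSE]; b <- mat[, idx_b, drop = FALSE]
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- rowSums((a - m_a)^2) / (na - 1)
  v_b <- rowSums((b - m_b)^2) / (nb - 1)
  se2 <- v_a / na + v_b / nb
  stat <- (m_a - m_b) / sqrt(se2)
  stat[se2 == 0 & m_a == m_b] <- 0          # two constant, equal groups
  df <- se2^2 / ((v_a / na)^2 / (na - 1) + (v_b / nb)^2 / (nb - 1))
  df[!is.finite(df)] <- na + nb - 2
  p <- 2 * pt(-abs(stat), df)
  list(statistic = stat, p = pmin(p, 1))
}

row_rank_sum <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  if (na < 2 || nb < 2) param_error("each group needs >= 2 samples")
  n <- na + nb
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  ranks <- t(apply(sub, 1, rank, ties.method = "average"))
  u <- rowSums(ranks[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  has_ties <- apply(sub, 1, function(x) anyDuplicated(x) > 0)
  p <- numeric(nrow(sub))
  mu <- na * nb / 2

  exact <- !has_ties & n <= 20
  if (any(exact)) {
    ue <- u[exact]
    pe <- ifelse(ue > mu,
                 2 * pwilcox(ue - 1, na, nb, lower.tail = FALSE),
                 2 * pwilcox(ue, na, nb))
    p[exact] <- pmin(pe, 1)
  }
  if (any(!exact)) {
    tie_term <- apply(sub[!exact, , drop = FALSE], 1, function(x) {
      tt <- table(x); sum(tt^3 - tt)
    })
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- u[!exact] - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)     # continuity correction
    pa <- 2 * pnorm(-abs(z))
    pa[sigma2 == 0] <- 1                        # all values tied
    p[!exact] <- pmin(pa, 1)
  }
  list(statistic = u, p = p)
}

# ---- scalar operations -----------------------------------------------------

#' Welch's unequal-variance t test
#'
#' Welch t statistic with Satterthwaite degrees of freedom and a two-sided p
#' from the t distribution, for group a minus group b.
#'
#' @param group_a_values,group_b_values numeric vectors, each of length >= 2.
#' @return list with `statistic` and `p`.
#' @export
welch_t <- function(group_a_values, group_b_values) {
  if (length(group_a_values) < 2 || length(group_b_values) < 2) {
    param_error("each group needs >= 2 values")
  }
  r <- row_welch_t(matrix(c(group_a_values, group_b_values), nrow = 1),
                   seq_along(group_a_values),
                   length(group_a_values) + seq_along(group_b_values))
  list(statistic = unname(r$statistic), p = unname(r$p))
}

#' Mann-Whitney rank-sum test
#'
#' U statistic for group a (number of (a, b) pairs with a > b, via the
#' rank-sum identity). The two-sided p is exact (from the Wilcoxon null
#' distribution) when the combined sample size is at most 20 and there are no
#' ties, and a normal approximation with tie and continuity correction
#' otherwise.
#'
#' @inheritParams welch_t
#' @return list with `statistic` (U for group a) and `p`.
#' @export
rank_sum_test <- function(group_a_values, group_b_values) {
  if (length(group_a_values) < 2 || length(group_b_values) < 2) {
    param_error("each group needs >= 2 values")
  }
  r <- row_rank_sum(matrix(c(group_a_values, group_b_values), nrow = 1),
                    seq_along(group_a_values),
                    length(group_a_values) + seq_along(group_b_values))
  list(statistic = unname(r$statistic), p = unname(r$p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values, clipped to 1 and monotone in the sorted order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    param_error("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes for a control-vs-case contrast
#'
#' Per gene: the case-minus-control mean difference (`log2fc`, on whatever
#' scale the input matrix is on -- the screening chain standardizes genes
#' first, so the default `lfc_min` is in standardized units), the Welch t and
#' Mann-Whitney tests, a combined p (the larger of the two when
#' `tests = "both"`, which is conservative), the BH q over all genes, and a
#' direction call: `up` if `q < alpha`, `|log2fc| >= lfc_min` and
#' `log2fc > 0`; `down` analogously; otherwise `ns`.
#'
#' @param mat preprocessed genes x samples matrix.
#' @param design data.frame with `sample_id`, `group` covering all columns.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_min minimal absolute mean difference (default 1.0).
#' @param tests `"both"` (default), `"welch"` or `"ranksum"`.
#' @return data.frame (one row per gene, input order) with columns `gene_id`,
#'   `log2fc`, `t_stat`, `t_p`, `u_stat`, `u_p`, `p_combined`, `q`,
#'   `direction`.
#' @export
select_degs <- function(mat, design, alpha = 0.05, lfc_min = 1.0,
                        tests = c("both", "welch", "ranksum")) {
  tests <- match.arg(tests)
  check_expression_matrix(mat)
  check_design(design, mat)
  if (!(alpha > 0 && alpha < 1) || lfc_min < 0) {
    param_error("need 0 < alpha < 1 and lfc_min >= 0")
  }
  idx_ctrl <- match(design$sample_id[design$group == "control"], colnames(mat))
  idx_case <- match(design$sample_id[design$group == "case"], colnames(mat))
  if (length(idx_ctrl) < 2 || length(idx_case) < 2) {
    param_error("each group needs >= 2 samples")
  }

  log2fc <- rowMeans(mat[, idx_case, drop = FALSE]) -
    rowMeans(mat[, idx_ctrl, drop = FALSE])
  tt <- row_welch_t(mat, idx_case, idx_ctrl)
  uu <- row_rank_sum(mat, idx_case, idx_ctrl)
  p_combined <- switch(tests,
                       both = pmax(tt$p, uu$p),
                       welch = tt$p,
                       ranksum = uu$p)
  q <- adjust_bh(p_combined)
  direction <- rep("ns", nrow(mat))
  called <- q < alpha & abs(log2fc) >= lfc_min
  direction[called & log2fc > 0] <- "up"
  direction[called & log2fc < 0] <- "down"

  log_msg("select_degs: %d up, %d down of %d genes (alpha %.3g, lfc %.3g)",
          sum(direction == "up"), sum(direction == "down"), nrow(mat),
          alpha, lfc_min)
  data.frame(gene_id = rownames(mat), log2fc = log2fc,
             t_stat = unname(tt$statistic), t_p = unname(tt$p),
             u_stat = unname(uu$statistic), u_p = unname(uu$p),
             p_combined = unname(p_combined), q = unname(q),
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Remove library-wide common genes from drug DEG tables
#'
#' A gene called (up or down) in more than `max_frac` of the drugs is
#' considered a tissue/assay-common response rather than a drug-specific one
#' and is reset to `ns` in every table. This deterministic frequency filter
#' stands in for platform-specific common-gene-set removal.
#'
#' @param drug_deg_tables named list of [select_degs()]-style data.frames
#'   (>= 2 tables).
#' @param max_frac maximal calling frequency tolerated (default 0.33).
#' @return list with `tables` (filtered) and `removed_genes`.
#' @export
remove_common_genes <- function(drug_deg_tables, max_frac = 0.33) {
  if (length(drug_deg_tables) < 2) {
    param_error("need at least 2 drug DEG tables")
  }
  if (max_frac < 0 || max_frac > 1) param_error("max_frac must be in [0, 1]")
  calls <- lapply(drug_deg_tables, function(tab) {
    tab$gene_id[tab$direction != "ns"]
  })
  freq <- table(unlist(calls)) / length(drug_deg_tables)
  removed <- sort(names(freq)[freq > max_frac])
  tables <- lapply(drug_deg_tables, function(tab) {
    tab$direction[tab$gene_id %in% removed] <- "ns"
    tab
  })
  list(tables = tables, removed_genes = removed)
}
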