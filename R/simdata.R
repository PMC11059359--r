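# Synthetic cohorts, drug libraries and count matrices with recorded truth.

#' Simulate a two-group expression cohort with planted DEGs
#'
#' Generates a microarray-like continuous gene-by-sample matrix: per-gene
#' baselines plus independent Gaussian noise, with a planted set of genes
#' shifted up (or down) in case samples by `effect * noise_sd`, i.e. `effect`
#' is the standardized mean difference in units of the within-group SD.
#' The ground truth (which genes were planted, in which direction) is returned
#' so downstream stages can be validated without external data.
#'
#' @param n_genes number of genes.
#' @param n_de_up,n_de_down number of planted up-/down-regulated genes
#'   (shifted in the case group).
#' @param effect standardized mean shift (unitless, >= 0).
#' @param n_control,n_case samples per group (each >= 2).
#' @param noise_sd within-group Gaussian noise SD (> 0).
#' @param baseline_mean,baseline_sd distribution of per-gene baselines on the
#'   log-intensity-like scale.
#' @param seed integer seed; the generator never mutates global RNG state.
#' @return list with elements `matrix` (genes x samples, dimnames set),
#'   `design` (data.frame `sample_id`, `group` with levels control/case) and
#'   `truth` (class `cohort_truth`: `gene_ids`, `planted_up`, `planted_down`,
#'   `effect`, `noise_sd`, `n_control`, `n_case`, `seed`).
#' @examples
#' co <- simulate_cohort(n_genes = 200, n_de_up = 5, n_de_down = 5,
#'                       effect = 3, n_control = 5, n_case = 5, seed = 1)
#' dim(co$matrix)
#' @export
simulate_cohort <- function(n_genes, n_de_up, n_de_down, effect,
                            n_control, n_case, noise_sd = 1,
                            baseline_mean = 7, baseline_sd = 1, seed) {
  if (n_genes < 1 || n_control < 2 || n_case < 2) {
    param_error("n_genes must be >= 1 and both groups must have >= 2 samples")
  }
  if (n_de_up < 0 || n_de_down < 0 || n_de_up + n_de_down > n_genes) {
    param_error("need 0 <= n_de_up + n_de_down <= n_genes")
  }
  if (effect < 0) param_error("effect must be >= 0")
  if (noise_sd <= 0) param_error("noise_sd must be > 0")

  with_preserved_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    sample_ids <- c(sprintf("CTRL_%02d", seq_len(n_control)),
                    sprintf("CASE_%02d", seq_len(n_case)))
    group <- rep(c("control", "case"), c(n_control, n_case))

    planted <- sample(gene_ids, n_de_up + n_de_down)
    planted_up <- sort(planted[seq_len(n_de_up)])
    planted_down <- sort(planted[seq_len(n_de_down) + n_de_up])

    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    mat <- baseline + matrix(rnorm(n_genes * (n_control + n_case), 0, noise_sd),
                             nrow = n_genes)
    dimnames(mat) <- list(gene_ids, sample_ids)
    shift <- effect * noise_sd
    case_cols <- which(group == "case")
    mat[planted_up, case_cols] <- mat[planted_up, case_cols] + shift
    mat[planted_down, case_cols] <- mat[planted_down, case_cols] - shift

    truth <- structure(
      list(gene_ids = gene_ids, planted_up = planted_up,
           planted_down = planted_down, effect = effect, noise_sd = noise_sd,
           n_control = n_control, n_case = n_case, seed = as.integer(seed)),
      class = "cohort_truth"
    )
    log_msg("simulate_cohort: %d genes x %d samples, %d planted (seed %d)",
            n_genes, ncol(mat), length(planted), as.integer(seed))
    list(matrix = mat,
         design = data.frame(sample_id = sample_ids, group = group,
                             stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate a drug perturbation library against a cohort's planted signature
#'
#' Each drug contributes one gene-level differential-score vector per cell
#' line. Reversers carry `-reversal_strength` times the planted disease
#' pattern plus noise, mimickers carry `+reversal_strength` times it, and the
#' remaining drugs are pure noise. All cell lines of a drug share its true
#' pattern; per-line noise is independent, emulating one consensus signature
#' observed across multiple cell lines.
#'
#' @param cohort_truth a `cohort_truth` record from [simulate_cohort()].
#' @param n_drugs library size.
#' @param n_reversers,n_mimickers planted counts (sum <= n_drugs).
#' @param reversal_strength unitless multiplier (>= 0) applied to the planted
#'   disease pattern (sign flipped for reversers).
#' @param n_cell_lines profiles per drug.
#' @param noise_sd per-line Gaussian noise SD.
#' @param seed integer seed.
#' @return list with `profiles` (named list: drug id -> genes x cell-lines
#'   score matrix) and `truth` (class `library_truth`: `reverser_ids`,
#'   `mimicker_ids`, `null_ids`, `reversal_strength`, `n_cell_lines`, `seed`).
#' @export
simulate_drug_library <- function(cohort_truth, n_drugs,
                                  n_reversers = 1, n_mimickers = 0,
                                  reversal_strength = 2, n_cell_lines = 3,
                                  noise_sd = 1, seed) {
  if (!inherits(cohort_truth, "cohort_truth")) {
    param_error("cohort_truth must come from simulate_cohort()")
  }
  if (n_drugs < 1 || n_reversers < 0 || n_mimickers < 0 ||
      n_reversers + n_mimickers > n_drugs) {
    param_error("need 0 <= n_reversers + n_mimickers <= n_drugs")
  }
  if (reversal_strength < 0) param_error("reversal_strength must be >= 0")
  if (n_cell_lines < 1) param_error("n_cell_lines must be >= 1")
  n_planted_genes <- length(cohort_truth$planted_up) +
    length(cohort_truth$planted_down)
  if (n_planted_genes == 0 && (n_reversers + n_mimickers) > 0) {
    param_error("cohort has no planted genes: nothing to reverse or mimic")
  }

  with_preserved_seed(seed, {
    gene_ids <- cohort_truth$gene_ids
    pattern <- setNames(numeric(length(gene_ids)), gene_ids)
    shift <- cohort_truth$effect * cohort_truth$noise_sd
    pattern[cohort_truth$planted_up] <- shift
    pattern[cohort_truth$planted_down] <- -shift

    drug_ids <- sprintf("DRUG_%03d", seq_len(n_drugs))
    roles <- rep("null", n_drugs)
    planted_idx <- sample(n_drugs, n_reversers + n_mimickers)
    roles[planted_idx[seq_len(n_reversers)]] <- "reverser"
    roles[planted_idx[seq_len(n_mimickers) + n_reversers]] <- "mimicker"

    line_ids <- if (n_cell_lines <= 3) {
      c("HL60", "MCF7", "PC3")[seq_len(n_cell_lines)]
    } else {
      sprintf("CL%02d", seq_len(n_cell_lines))
    }

    profiles <- vector("list", n_drugs)
    names(profiles) <- drug_ids
    for (i in seq_len(n_drugs)) {
      base <- switch(roles[i],
                     reverser = -reversal_strength * pattern,
                     mimicker = reversal_strength * pattern,
                     null = pattern * 0)
      prof <- base + matrix(rnorm(length(gene_ids) * n_cell_lines, 0, noise_sd),
                            nrow = length(gene_ids))
      dimnames(prof) <- list(gene_ids, line_ids)
      profiles[[i]] <- prof
    }

    truth <- structure(
      list(reverser_ids = drug_ids[roles == "reverser"],
           mimicker_ids = drug_ids[roles == "mimicker"],
           null_ids = drug_ids[roles == "null"],
           reversal_strength = reversal_strength,
           n_cell_lines = n_cell_lines, seed = as.integer(seed)),
      class = "library_truth"
    )
    log_msg("simulate_drug_library: %d drugs (%d reversers, %d mimickers), %d lines",
            n_drugs, n_reversers, n_mimickers, n_cell_lines)
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate an RNA-seq-like count matrix with known low-expression genes
#'
#' Counts are negative-binomial (dispersion 0.1) with per-gene means drawn
#' uniformly from `mean_range`. A `dropout_frac` fraction of genes is forced
#' to have fewer than `min_samples` samples with at least `min_count` counts
#' (so [filter_low_counts()] must remove exactly those genes); the remaining
#' genes are guaranteed to pass the filter.
#'
#' @param n_genes,n_samples matrix dimensions; `n_samples >= min_samples`.
#' @param mean_range length-2 numeric, range of per-gene NB means.
#' @param dropout_frac fraction of genes forced below the filter, in [0, 1].
#' @param seed integer seed.
#' @param min_count,min_samples the filter thresholds the truth is built for.
#' @return list with `counts` (integer matrix, dimnames set) and `low_genes`
#'   (character vector: exactly the genes the filter must remove).
#' @export
simulate_counts <- function(n_genes, n_samples, mean_range = c(100, 1000),
                            dropout_frac, seed, min_count = 5,
                            min_samples = 8) {
  if (n_genes < 1 || n_samples < min_samples) {
    param_error("need n_genes >= 1 and n_samples >= min_samples")
  }
  if (dropout_frac < 0 || dropout_frac > 1) {
    param_error("dropout_frac must be in [0, 1]")
  }
  if (length(mean_range) != 2 || any(mean_range <= 0)) {
    param_error("mean_range must be two positive values")
  }

  with_preserved_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    mu <- runif(n_genes, mean_range[1], mean_range[2])
    counts <- matrix(rnbinom(n_genes * n_samples, mu = rep(mu, n_samples),
                             size = 10),
                     nrow = n_genes, dimnames = list(gene_ids, sample_ids))

    n_low <- round(dropout_frac * n_genes)
    low_genes <- sort(sample(gene_ids, n_low))
    for (g in low_genes) {
      n_ok <- sample.int(min_samples, 1) - 1L  # 0 .. min_samples - 1
      ok <- sample.int(n_samples, n_ok)
      row <- sample.int(min_count, n_samples, replace = TRUE) - 1L  # < min_count
      row[ok] <- pmax(counts[g, ok], min_count)
      counts[g, ] <- row
    }
    # guarantee every non-low gene passes the filter (NB draws with high mean
    # essentially always do; this makes the truth record exact by construction)
    high <- setdiff(gene_ids, low_genes)
    for (g in high) {
      passing <- which(counts[g, ] >= min_count)
      if (length(passing) < min_samples) {
        fix <- sample(setdiff(seq_len(n_samples), passing),
                      min_samples - length(passing))
        counts[g, fix] <- min_count
      }
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, low_genes = low_genes)
  })
}
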