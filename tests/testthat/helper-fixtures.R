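# Shared fixture builders (all data generated in code).

small_cohort <- function(seed = 1, n_genes = 300, effect = 3) {
  simulate_cohort(n_genes = n_genes, n_de_up = 10, n_de_down = 10,
                  effect = effect, n_control = 8, n_case = 8, seed = seed)
}

# Two cohorts with disjoint planted gene sets plus one drug library whose
# single planted reverser opposes both cohorts' patterns (built by reversing
# the union pattern of the two disjoint planted sets).
two_cohort_fixture <- function(seed, n_genes = 2000, n_de = 50,
                               n_drugs = 50, strength = 2) {
  co_a <- simulate_cohort(n_genes, n_de, n_de, effect = 3,
                          n_control = 10, n_case = 10, seed = seed)
  planted_a <- c(co_a$truth$planted_up, co_a$truth$planted_down)
  s <- seed + 10000
  repeat {
    co_b <- simulate_cohort(n_genes, n_de, n_de, effect = 3,
                            n_control = 10, n_case = 10, seed = s)
    planted_b <- c(co_b$truth$planted_up, co_b$truth$planted_down)
    if (length(intersect(planted_a, planted_b)) == 0) break
    s <- s + 1
  }
  joint_truth <- structure(
    list(gene_ids = co_a$truth$gene_ids,
         planted_up = sort(c(co_a$truth$planted_up, co_b$truth$planted_up)),
         planted_down = sort(c(co_a$truth$planted_down,
                               co_b$truth$planted_down)),
         effect = co_a$truth$effect, noise_sd = co_a$truth$noise_sd,
         n_control = 10, n_case = 10, seed = as.integer(seed)),
    class = "cohort_truth")
  lib <- simulate_drug_library(joint_truth, n_drugs = n_drugs,
                               n_reversers = 1, n_mimickers = 0,
                               reversal_strength = strength,
                               n_cell_lines = 3, seed = seed + 77)
  list(cohort_a = co_a, cohort_b = co_b, library = lib)
}
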