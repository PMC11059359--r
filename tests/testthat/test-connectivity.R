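test_that("signatures cap direction sets and break score ties by gene id", {
  tab <- data.frame(
    gene_id = sprintf("g%d", 1:10),
    log2fc = c(5, 4, 3, 2, 1, -0.5, -1, -2, -3, 0.2),
    direction = c(rep("up", 5), rep("down", 4), "ns"),
    stringsAsFactors = FALSE)
  sig <- build_signature(tab, cap = 2)
  expect_identical(sig$up_set, c("g1", "g2"))     # top called-up by score
  expect_identical(sig$down_set, c("g9", "g8"))   # from the bottom
  expect_length(sig$ranked_genes, 10)             # ranking keeps all genes

  wide <- build_signature(tab, cap = 100)
  expect_setequal(wide$up_set, sprintf("g%d", 1:5))
  expect_setequal(wide$down_set, sprintf("g%d", 6:9))

  tied <- setNames(c(1, 1, -1, -1), c("B", "A", "D", "C"))
  s1 <- build_signature(tied, cap = 1)
  expect_identical(s1$ranked_genes, c("A", "B", "C", "D"))
  expect_identical(s1$up_set, "A")
  expect_identical(build_signature(tied, cap = 1), s1)
  expect_error(build_signature(numeric(0)), class = "revscreen_parameter_error")
})

test_that("ks_enrichment reproduces hand-derived running-sum values", {
  genes <- sprintf("g%02d", 1:10)
  expect_equal(ks_enrichment(genes, genes[c(1, 2)]), 0.8)
  expect_equal(ks_enrichment(genes, genes[c(9, 10)]), -0.9)
  expect_equal(ks_enrichment(genes, genes), -1 / 10)  # degenerate whole-list set
  expect_error(ks_enrichment(genes, character(0)),
               class = "revscreen_parameter_error")
  expect_error(ks_enrichment(genes, "absent"),
               class = "revscreen_parameter_error")
})

test_that("ks_enrichment equals the brute-force walk on random configurations", {
  withr::with_seed(5, {
    for (i in 1:200) {
      n <- sample(3:40, 1)
      genes <- sprintf("g%03d", 1:n)
      set <- sample(genes, sample(seq_len(n), 1))
      expect_equal(ks_enrichment(genes, set), brute_force_es(genes, set),
                   tolerance = 1e-12)
    }
  })
})

test_that("reversing the ranking exchanges the two one-sided deviations", {
  # reversal maps the deviation pair (a, b) to (b - 1/n, a + 1/n), so the
  # reversed ES is fully determined by the forward pair
  withr::with_seed(6, {
    for (i in 1:50) {
      n <- sample(5:30, 1)
      genes <- sprintf("g%03d", 1:n)
      set <- sample(genes, sample(2:min(5, n - 1), 1))
      ab <- brute_force_ab(genes, set)
      got <- ks_enrichment(rev(genes), set)
      a_rev <- ab$b - 1 / n
      b_rev <- ab$a + 1 / n
      if (abs(a_rev - b_rev) < 1e-9) {
        # exact tie between the deviations: magnitude is determined,
        # the sign falls to floating-point rounding of the running sums
        expect_equal(abs(got), a_rev, tolerance = 1e-12)
      } else if (a_rev > b_rev) {
        expect_equal(got, a_rev, tolerance = 1e-12)
      } else {
        expect_equal(got, -b_rev, tolerance = 1e-12)
      }
    }
  })
  # on a symmetric toy configuration the mimicker exactly mirrors the reverser
  disease <- toy_signature(10, 1:2, 9:10)
  mimic <- toy_signature(10, up_positions = 1:2, down_positions = 9:10)
  reverser <- toy_signature(10, up_positions = 9:10, down_positions = 1:2)
  expect_equal(enrichment_test(disease, mimic)$et,
               -enrichment_test(disease, reverser)$et)
})

test_that("the enrichment test signs mimickers negative and reversers positive", {
  disease <- toy_signature(10, up_positions = 1:2, down_positions = 9:10)
  mimic <- disease                      # same sets, same ranking
  expect_lt(enrichment_test(disease, mimic)$et, 0)

  reverser <- toy_signature(10, up_positions = 9:10, down_positions = 1:2)
  r <- enrichment_test(disease, reverser)
  expect_equal(r$es_up, -0.9)
  expect_equal(r$es_down, 0.8)
  expect_equal(r$et, 0.85)
  expect_gt(r$et, 0)
})

test_that("drugs without usable sets in the shared universe score as missing", {
  disease <- toy_signature(10, 1:2, 9:10)
  stranger <- build_signature(setNames(c(2, -2, 1), c("x1", "x2", "x3")))
  expect_warning(r <- enrichment_test(disease, stranger), "missing")
  expect_true(is.na(r$et))
})

test_that("the similarity test returns cosine, angle and the -cos reversal score", {
  v <- c(1, -2, 3)
  self <- similarity_test(v, v)
  expect_equal(self$st_cos, 1)
  expect_equal(self$theta_deg, 0)
  anti <- similarity_test(v, -v)
  expect_equal(anti$st_cos, -1)
  expect_equal(anti$theta_deg, 180)
  expect_equal(anti$st_score, 1)
  mid <- similarity_test(c(1, 1, 0), c(1, 0, 0))
  expect_equal(mid$st_cos, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(mid$theta_deg, 45, tolerance = 1e-10)
  expect_warning(z <- similarity_test(c(0, 0, 0), v), "zero vector")
  expect_true(is.na(z$st_cos))
})

test_that("ST vectors zero-fill measured non-DEG genes on the union axis", {
  a <- toy_signature(6, up_positions = 1, down_positions = 6)
  b <- toy_signature(6, up_positions = 2, down_positions = 5)
  v <- st_vectors(a, b)
  expect_identical(names(v$a), sort(c("g01", "g06", "g02", "g05")))
  expect_equal(unname(v$a[c("g02", "g05")]), c(0, 0))  # measured, not a's DEGs
  expect_equal(unname(v$b[c("g01", "g06")]), c(0, 0))
  expect_equal(unname(v$a["g01"]), unname(a$scores["g01"]))
})

test_that("the contingency test reproduces the exact hypergeometric tail", {
  uni <- sprintf("u%03d", 1:20)
  drug_up <- uni[1:5]; disease_down <- uni[c(1, 2, 3, 6)]  # overlap 3
  r <- contingency_test(disease_up = uni[15:16], disease_down = disease_down,
                        drug_up = drug_up, drug_down = uni[17:18],
                        universe_size = 20)
  expect_equal(r$ct_p_updown, 155 / 4845, tolerance = 1e-14)

  none <- contingency_test(character(0), uni[1:4], uni[5:9], character(0), 20)
  expect_equal(none$ct_p_updown, 1)
  expect_equal(none$ct_p_downup, 1)
  expect_equal(none$ct, 0)
  expect_gte(none$ct, 0)

  expect_error(contingency_test(uni, uni[1], uni[2], uni[3], 5),
               class = "revscreen_parameter_error")
  expect_error(contingency_test(uni[1:3], uni[3:4], uni[5], uni[6], 20),
               class = "revscreen_parameter_error")
})

test_that("contingency p decreases monotonically in the overlap", {
  uni <- sprintf("u%03d", 1:50)
  p_at <- function(k) {
    drug_up <- c(uni[seq_len(k)], uni[10 + seq_len(8 - k)])  # size 8, overlap k
    contingency_test(character(0), uni[1:10], drug_up = drug_up,
                     drug_down = character(0), 50)$ct_p_updown
  }
  ps <- vapply(0:8, p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_equal(ps[1], 1)
})

test_that("directional Fisher p-values are super-uniform under a null overlap", {
  withr::with_seed(12, {
    uni <- sprintf("u%03d", 1:200)
    ps <- replicate(2000, {
      contingency_test(character(0), sample(uni, 30),
                       drug_up = sample(uni, 30), drug_down = character(0),
                       200)$ct_p_updown
    })
    expect_lte(mean(ps <= 0.05), 0.07)
  })
})

test_that("the rank ensemble reproduces hand-computed normalized ranks", {
  unanimous <- data.frame(drug_id = c("A", "B", "C"),
                          et = c(0.9, 0.1, 0.2),
                          st_cos = c(-0.9, 0.5, 0.1),
                          ct = c(10, 1, 2), stringsAsFactors = FALSE)
  ens <- ensemble(unanimous)
  expect_identical(ens$drug_id[1], "A")
  expect_equal(ens$final[1], 1.0)

  # X ranks (1, 1, 2), Y ranks (2, 2, 1): final X = (1 + 1 + 0.5)/3
  two <- data.frame(drug_id = c("X", "Y"), et = c(2, 1),
                    st_cos = c(-0.9, -0.1), ct = c(1, 5),
                    stringsAsFactors = FALSE)
  ens2 <- ensemble(two)
  expect_equal(ens2$final[ens2$drug_id == "X"], (1 + 1 + 0.5) / 3,
               tolerance = 1e-12)
  expect_equal(ens2$final[ens2$drug_id == "Y"], (0.5 + 0.5 + 1) / 3,
               tolerance = 1e-12)
  expect_identical(ens2$drug_id[ens2$rank == 1], "X")

  shuffled <- ensemble(two[2:1, ])
  expect_equal(shuffled, ens2)
})

test_that("improving one component never lowers a drug's final score", {
  base <- data.frame(drug_id = sprintf("D%d", 1:5),
                     et = c(0.5, 0.3, 0.1, -0.2, -0.4),
                     st_cos = c(-0.5, -0.1, 0.2, 0.4, 0.6),
                     ct = c(5, 4, 3, 2, 1), stringsAsFactors = FALSE)
  f0 <- ensemble(base)
  better <- base
  better$et[3] <- 0.2   # improves D3 without crossing any other drug
  f1 <- ensemble(better)
  expect_gte(f1$final[f1$drug_id == "D3"], f0$final[f0$drug_id == "D3"])
})

test_that("drugs with missing components are flagged and ranked last", {
  tab <- data.frame(drug_id = c("A", "B", "C"), et = c(0.5, NA, 0.1),
                    st_cos = c(-0.5, -0.9, 0), ct = c(3, 8, 1),
                    stringsAsFactors = FALSE)
  ens <- ensemble(tab)
  expect_identical(ens$drug_id[ens$rank == 3], "B")
  expect_true(ens$missing[ens$drug_id == "B"])
  expect_true(all(ens$final[!ens$missing] > 0 & ens$final[!ens$missing] <= 1))
  expect_error(ensemble(tab[2, ]), class = "revscreen_parameter_error")
})
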