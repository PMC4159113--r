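sig_toy <- function() {
  # 3 genes with inhibitor fold changes -2, -1, +1 (treated - control)
  vals <- matrix(c(3, 4, 6,   # treated sample
                   5, 5, 5),  # control sample
                 ncol = 2, dimnames = list(c("gDn2", "gDn1", "gUp1"),
                                           c("trt", "ctl")))
  expression_matrix(vals)
}

test_that("derive_signature ranks by fold change with deterministic ties", {
  m <- sig_toy()
  top2 <- derive_signature(m, "trt", "ctl", direction = "down", top_n = 2)
  expect_setequal(top2$members, c("gDn2", "gDn1"))
  all3 <- derive_signature(m, "trt", "ctl", top_n = 3)
  expect_setequal(all3$members, c("gDn2", "gDn1", "gUp1"))
  up1 <- derive_signature(m, "trt", "ctl", direction = "up", top_n = 1)
  expect_equal(up1$members, "gUp1")
  expect_error(derive_signature(m, "trt", "ctl", top_n = 4), "exceeds")

  # exact ties resolved by gene id byte order
  tied <- toy_expr(matrix(c(1, 1, 1, 2, 2, 2), ncol = 2,
                          dimnames = list(c("b", "a", "c"), c("t", "c"))))
  expect_equal(derive_signature(tied, "t", "c", top_n = 2)$members,
               c("a", "b"))
})

test_that("zero-noise planted inhibitor response is recovered exactly", {
  sim <- simulate_cellline_experiment(cellline_sim_params(
    n_genes = 3000, noise_sd = 0, inhibitor_down = 120, seed = 5))
  md <- sim$expression$metadata
  trt <- rownames(md)[md$treatment == "inhibitor"]
  ctl <- rownames(md)[md$genotype == "dedifferentiated" &
                        md$treatment == "vehicle"]
  got <- derive_signature(sim$expression, trt, ctl, "down", 120)
  expect_setequal(got$members, sim$truth$inhibitor_down$members)
})

test_that("cohort scores are signature-gene sums with coverage accounting", {
  vals <- matrix(c(3, 5, 10,
                   3, 5, 2), ncol = 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m <- expression_matrix(vals)
  sig <- gene_set("sig", c("g1", "g2"))
  st <- score_cohort(m, sig)
  expect_equal(st$score, c(8, 8))               # 3+5 for both samples
  expect_equal(attr(st, "coverage"), 1)

  # linearity: adding c to every signature gene of one sample
  vals2 <- vals; vals2[c("g1", "g2"), "s1"] <- vals2[c("g1", "g2"), "s1"] + 2
  st2 <- score_cohort(expression_matrix(vals2), sig)
  expect_equal(st2$score[1], st$score[1] + 2 * 2)

  # missing signature genes are dropped with a coverage warning
  wide <- gene_set("wide", c("g1", "g2", "zz1", "zz2", "zz3"))
  expect_warning(stw <- score_cohort(m, wide), "coverage")
  expect_equal(attr(stw, "coverage"), 0.4)
  expect_equal(stw$score, st$score)
  expect_error(score_cohort(m, gene_set("none", "qq")), "zero coverage")
})

test_that("scores are permutation-equivariant over samples", {
  set.seed(21)
  m <- toy_expr(matrix(rnorm(30 * 8, 7), 30, 8))
  sig <- gene_set("s", paste0("g", 1:10))
  st <- score_cohort(m, sig)
  perm <- c(5, 1, 8, 3, 2, 7, 4, 6)
  stp <- score_cohort(expression_matrix(m$values[, perm]), sig)
  expect_equal(stp$score, st$score[perm])
  expect_equal(stp$sample_id, st$sample_id[perm])
})

test_that("stratification sizes follow floor(fraction * n) with ties resolved", {
  set.seed(22)
  m <- toy_expr(matrix(rnorm(10 * 20, 7), 10, 20))
  st <- stratify(score_cohort(m, gene_set("s", paste0("g", 1:10))), 0.15)
  expect_equal(sum(st$stratum == "high"), 3)    # floor(0.15 * 20)
  expect_equal(sum(st$stratum == "low"), 3)
  expect_equal(sum(st$stratum == "mid"), 14)
  # high stratum really holds the top scores
  expect_gte(min(st$score[st$stratum == "high"]),
             max(st$score[st$stratum == "mid"]))

  # all-equal scores: deterministic sample-id labeling, sizes intact
  meq <- toy_expr(matrix(5, 4, 12))
  seq_st <- stratify(score_cohort(meq, gene_set("s", paste0("g", 1:4))), 0.25)
  expect_equal(sum(seq_st$stratum == "high"), 3)
  expect_equal(sum(seq_st$stratum == "low"), 3)
  expect_identical(seq_st$stratum,
                   stratify(score_cohort(meq,
                                         gene_set("s", paste0("g", 1:4))),
                            0.25)$stratum)
  expect_error(stratify(score_cohort(meq, gene_set("s", "g1")), 0.05),
               "too few")
})

test_that("stratifying strong-signal cohorts concentrates true top activities", {
  co <- simulate_cohort(cohort_sim_params(n_samples = 100, n_genes = 400,
                                          signature_size = 80, beta = 3,
                                          noise_sd = 0.1, seed = 30))
  st <- stratify(score_cohort(co$expression, co$signature), 0.15)
  truth_order <- names(sort(co$activity, decreasing = TRUE))
  expect_setequal(st$sample_id[st$stratum == "high"], truth_order[1:15])
  expect_setequal(st$sample_id[st$stratum == "low"], rev(truth_order)[1:15])
})

test_that("spearman_rho matches the midrank oracle and handles monotone limits", {
  expect_equal(spearman_rho(1:10, log(1:10 + 2)), 1)   # monotone transform
  expect_equal(spearman_rho(1:7, rev(1:7)), -1)
  # frozen hand computation with a tie: x=(1,2,3,4), y=(1,1,3,4)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 1, 3, 4)),
               4.5 / sqrt(22.5), tolerance = 1e-12)
  set.seed(23)
  for (i in 1:50) {
    x <- sample(1:6, 20, replace = TRUE)       # heavy ties
    y <- rnorm(20) + x
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Monte Carlo correlation p-value honors its contracts", {
  co <- simulate_cohort(cohort_sim_params(n_samples = 60, n_genes = 300,
                                          signature_size = 50, seed = 31))
  # self-correlation: rho 1, minimal attainable p
  self_scores <- score_cohort(co$expression, co$signature)
  res <- mc_correlation_pvalue(co$expression, co$signature, self_scores,
                               reps = 200, seed = 99)
  expect_equal(res$rho_obs, 1)
  expect_equal(res$p_value, 1 / 201)
  expect_equal(res$set_size, 50)

  # determinism: identical call, identical seed -> bit-identical result
  res2 <- mc_correlation_pvalue(co$expression, co$signature, self_scores,
                                reps = 200, seed = 99)
  expect_identical(res, res2)

  # p bounded within [1/(reps+1), 1] under an unrelated score vector
  noise <- setNames(rnorm(60), samples(co$expression))
  rn <- mc_correlation_pvalue(co$expression, co$signature, noise,
                              reps = 100, seed = 7)
  expect_gte(rn$p_value, 1 / 101)
  expect_lte(rn$p_value, 1)
  expect_error(mc_correlation_pvalue(co$expression, co$signature,
                                     self_scores, reps = 50, seed = 1),
               ">= 100")
  expect_error(mc_correlation_pvalue(co$expression, co$signature,
                                     self_scores, reps = 200),
               "seed")
})

test_that("scores track the latent activity on default-strength cohorts", {
  # calibration reference: beta = 0.8, noise 0.5, n = 200 (generator defaults)
  co <- simulate_cohort(cohort_sim_params(seed = 2))
  st <- score_cohort(co$expression, co$signature)
  rho <- spearman_rho(st$score, co$activity[st$sample_id])
  expect_gte(rho, 0.9)
})
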