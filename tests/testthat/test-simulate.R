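test_that("cell-line generator is deterministic and internally consistent", {
  p <- cellline_sim_params(n_genes = 2600, noise_sd = 0.3, seed = 8)
  s1 <- simulate_cellline_experiment(p)
  s2 <- simulate_cellline_experiment(p)
  expect_identical(s1$expression$values, s2$expression$values)

  tr <- s1$truth
  # planted overlap algebra holds by construction
  expect_length(tr$common_induced$members, 44)
  expect_setequal(tr$common_induced$members,
                  intersect(tr$ros_induced_diff$members,
                            tr$ros_induced_dediff$members))
  expect_setequal(tr$preactivated$members,
                  intersect(tr$ros_induced_diff$members,
                            tr$dediff_up$members))
  expect_setequal(tr$uniquely_induced$members,
                  setdiff(tr$preactivated$members,
                          tr$ros_induced_dediff$members))
  expect_length(tr$uniquely_induced$members, 38)
  expect_length(tr$differential$members, 1694)

  # arms and replicates materialize in the metadata
  md <- s1$expression$metadata
  expect_equal(sum(md$genotype == "differentiated" &
                     md$treatment == "oxidant"), 3)
  expect_equal(sum(md$treatment == "inhibitor"), 3)
})

test_that("generator parameter validation rejects inconsistent set sizes", {
  expect_error(cellline_sim_params(common_induced = 200), "exceeds")
  expect_error(cellline_sim_params(preactivated = 900), "fit inside")
  expect_error(cellline_sim_params(preactivated_induced_dediff = 60),
               "exceeds")
  expect_error(cellline_sim_params(n_genes = 100), "planted sets need")
  expect_error(cohort_sim_params(signature_size = 10000), "exceeds")
})

test_that("zero-noise simulation is recovered exactly by the calling chain", {
  sim <- simulate_cellline_experiment(cellline_sim_params(
    n_genes = 2600, noise_sd = 0, seed = 3))
  md <- sim$expression$metadata
  arm <- function(g, t) rownames(md)[md$genotype == g & md$treatment == t]
  ind_diff <- up_regulated_set(
    sim$expression,
    contrast_spec(arm("differentiated", "oxidant"),
                  arm("differentiated", "vehicle")))
  ind_dediff <- up_regulated_set(
    sim$expression,
    contrast_spec(arm("dedifferentiated", "oxidant"),
                  arm("dedifferentiated", "vehicle")))
  basal_up <- up_regulated_set(
    sim$expression,
    contrast_spec(arm("dedifferentiated", "vehicle"),
                  arm("differentiated", "vehicle")))
  expect_setequal(ind_diff$members, sim$truth$ros_induced_diff$members)
  expect_setequal(ind_dediff$members, sim$truth$ros_induced_dediff$members)
  expect_setequal(basal_up$members, sim$truth$dediff_up$members)
  pre <- preactivated_set(ind_diff, basal_up)
  expect_setequal(pre$members, sim$truth$preactivated$members)
  expect_length(pre$members, 54)
})

test_that("cohort generator links expression, survival and response to activity", {
  co <- simulate_cohort(cohort_sim_params(n_samples = 150, n_genes = 500,
                                          signature_size = 100, seed = 9))
  expect_identical(
    co$expression$values,
    simulate_cohort(cohort_sim_params(n_samples = 150, n_genes = 500,
                                      signature_size = 100,
                                      seed = 9))$expression$values)
  # signature genes carry the activity loading, background genes do not
  sig_cor <- cor(colMeans(co$expression$values[co$signature$members, ]),
                 co$activity)
  bg <- setdiff(genes(co$expression), co$signature$members)
  bg_cor <- cor(colMeans(co$expression$values[bg, ]), co$activity)
  expect_gt(sig_cor, 0.9)
  expect_lt(abs(bg_cor), 0.5)
  # survival times censored at the horizon
  expect_lte(max(co$survival$time), 60)
  expect_true(all(co$response$category %in%
                    c("complete", "partial", "stable_progressive")))

  # high activity lowers response probability (kappa > 0 default)
  top <- names(sort(co$activity, decreasing = TRUE))[1:40]
  bottom <- names(sort(co$activity))[1:40]
  resp <- co$response$category %in% c("complete", "partial")
  names(resp) <- co$response$sample_id
  expect_gt(mean(resp[bottom]), mean(resp[top]))
})

test_that("kappa = 0 removes the response-activity link up to sampling noise", {
  co <- simulate_cohort(cohort_sim_params(n_samples = 400, n_genes = 200,
                                          signature_size = 50, kappa = 0,
                                          seed = 10))
  resp <- co$response$category %in% c("complete", "partial")
  names(resp) <- co$response$sample_id
  top <- names(sort(co$activity, decreasing = TRUE))[1:100]
  bottom <- names(sort(co$activity))[1:100]
  # difference within binomial noise of zero (3 SE)
  se <- sqrt(2 * 0.25 / 100)
  expect_lt(abs(mean(resp[top]) - mean(resp[bottom])), 3 * se)
})

test_that("generator outputs round-trip through the IO layer losslessly", {
  sim <- simulate_cellline_experiment(cellline_sim_params(
    n_genes = 2600, seed = 4))
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".gmt")
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(sim$expression, ep)
  write_sample_metadata(sim$expression$metadata, mp)
  write_gmt(sim$truth, gp)
  back <- read_expression_tsv(ep, metadata = mp)
  expect_equal(back$values, sim$expression$values)
  expect_equal(back$metadata, sim$expression$metadata)
  sets <- read_gmt(gp)
  expect_setequal(sets$preactivated$members, sim$truth$preactivated$members)
  expect_equal(length(sets), length(sim$truth))
})
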