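test_that("ddct_fold implements 2^-ddCt with its identities", {
  expect_equal(ddct_fold(25, 20, 24, 20), 0.5)
  expect_equal(ddct_fold(23, 20, 24, 20), 2.0)
  set.seed(15)
  for (i in 1:20) {
    cq <- runif(4, 15, 35)
    expect_equal(ddct_fold(cq[1], cq[2], cq[1], cq[2]), 1)  # calibrator vs self
    shift <- runif(1, -3, 3)
    expect_equal(ddct_fold(cq[1] + shift, cq[2] + shift,
                           cq[3] + shift, cq[4] + shift),
                 ddct_fold(cq[1], cq[2], cq[3], cq[4]))  # shift invariance
  }
})

test_that("noiseless simulated experiments recover planted folds exactly", {
  plant <- data.frame(gene_id = "g1", line = "L1", temperature = 5, time = 6,
                      log2fold = 3)  # 8-fold induction
  cfg <- cq_sim_config(genes = c("g1", "g2"), planted_log2fold = plant,
                       noise_sd = 0)
  rel <- relative_expression(simulate_cq(cfg, seed = 1))
  expect_equal(rel$fold[rel$gene_id == "g1" & rel$time == 6], 8)
  expect_equal(rel$fold[rel$gene_id == "g2" & rel$time == 6], 1)
  expect_equal(rel$fold[rel$time == 0], c(1, 1))  # calibrator rows
})

test_that("noisy replicates recover planted folds within the sampling envelope", {
  plant <- data.frame(gene_id = "g1", line = "L1", temperature = 5, time = 6,
                      log2fold = 3)
  cfg <- cq_sim_config(genes = "g1", planted_log2fold = plant,
                       noise_sd = 0.2, n_replicates = 3)
  est <- vapply(1:200, function(s) {
    rel <- relative_expression(simulate_cq(cfg, seed = s))
    rel$fold[rel$time == 6]
  }, numeric(1))
  expect_gte(median(est), 6.5)
  expect_lte(median(est), 9.8)
  # closed-form oracle: ddCt error is Gaussian with sd sqrt(4 sd^2 / n)
  # (replicate-mean target and reference noise at both the treated and the
  # calibrator cell); the fraction recovered within 25% must match it
  s_ddct <- sqrt(4 * 0.2^2 / 3)
  coverage <- pnorm(log2(1.25) / s_ddct) - pnorm(log2(0.75) / s_ddct)
  mc_sd <- sqrt(coverage * (1 - coverage) / 200)
  expect_lt(abs(mean(abs(est - 8) / 8 < 0.25) - coverage), 3 * mc_sd)
})

test_that("anova_tukey matches the hand-computed F and separates extremes", {
  a <- anova_tukey(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                   rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(a$F, 3)           # SSB = 6, SSW = 6 on (2, 6) df
  expect_equal(a$df, c(2, 6))
  expect_false(a$undefined)

  set.seed(16)
  vals <- c(rnorm(5, 0, 1), rnorm(5, 0, 1), rnorm(5, 50, 1))
  g <- rep(c("a", "b", "c"), each = 5)
  a2 <- anova_tukey(vals, g)
  expect_false(a2$letters[["c"]] %in% a2$letters[c("a", "b")])

  # identical means with noise: all groups share a letter (usually);
  # checked via the p-value rather than the stochastic letter display
  vals3 <- c(rnorm(6), rnorm(6), rnorm(6))
  a3 <- anova_tukey(vals3, rep(c("a", "b", "c"), each = 6))
  expect_true(is.numeric(a3$p))

  azero <- anova_tukey(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_true(azero$undefined)
  expect_error(anova_tukey(1:3, c("a", "a", "b")), "2 replicates")
})

test_that("heatmap_matrix builds log2 grids and clusters identical rows together", {
  rel <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                    line = "L1", temperature = 5, time = rep(c(0, 6), 2),
                    log2_fold = c(0, 1, 2, 0))
  m <- heatmap_matrix(rel)
  expect_equal(unname(m), matrix(c(0, 2, 1, 0), 2, 2), ignore_attr = TRUE)

  rel3 <- data.frame(gene_id = rep(c("a", "b", "c"), each = 3),
                     line = "L1", temperature = 5, time = rep(c(0, 6, 24), 3),
                     log2_fold = c(0, 1, 2, 5, -1, 3, 0, 1, 2))
  m3 <- heatmap_matrix(rel3, cluster = TRUE)
  ord <- rownames(m3)
  expect_equal(abs(which(ord == "a") - which(ord == "c")), 1)  # identical rows adjacent
  m3b <- heatmap_matrix(rel3, cluster = TRUE)
  expect_identical(rownames(m3b), rownames(m3))  # deterministic order
  expect_error(heatmap_matrix(rel3[0, ]), "empty")
})
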