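test_that("TPM densities match the length-normalised formula", {
  # hand evaluation: A(n=100, L=1000), B(n=300, L=1500)
  d <- tpm_density(c(100, 300), c(1000, 1500))
  expect_equal(d, c(1e6 / 3, 2e6 / 3), tolerance = 1e-12)
  # single expressed gene takes the whole million
  expect_equal(tpm_density(5, 1234), 1e6)
  # scale invariance and unit sum
  d2 <- tpm_density(2 * c(100, 300), c(1000, 1500))
  expect_equal(d, d2)
  expect_equal(sum(d), 1e6)
  expect_error(tpm_density(c(0, 0), c(100, 100)), "empty sample")
  expect_error(tpm_density(c(1, 2), c(0, 100)), "lengths")
})

test_that("density columns of a table all sum to one million", {
  tbl <- small_count_table()
  d <- density_table(tbl)
  expect_equal(unname(colSums(d)), rep(1e6, ncol(d)), tolerance = 1e-6)
  # invariant under uniform count scaling
  tbl2 <- tbl
  cc <- setdiff(colnames(tbl2), c("gene_id", "length"))
  tbl2[cc] <- tbl2[cc] * 3L
  expect_equal(density_table(tbl2), d)
})

test_that("replicate pooling sums counts and keeps the manifest", {
  tbl <- small_count_table()
  pooled <- pool_replicates(tbl, "WT", "poly")
  expect_equal(as.vector(pooled), tbl$WT_poly_rep1 + tbl$WT_poly_rep2)
  expect_setequal(attr(pooled, "pooled_samples"),
                  c("WT_poly_rep1", "WT_poly_rep2"))
  # single replicate is the identity
  tbl1 <- tbl[c("gene_id", "length", "WT_poly_rep1", "WT_sub_rep1")]
  expect_equal(as.vector(pool_replicates(tbl1, "WT", "poly")),
               tbl1$WT_poly_rep1)
  expect_error(pool_replicates(tbl, "KO", "poly"), "no samples")
})

test_that("polysome index is the poly share of the two densities", {
  expect_equal(unname(polysome_index(3, 3)), 0.5)
  expect_equal(unname(polysome_index(0, 5)), 0)
  expect_equal(unname(polysome_index(4e5, 6e5)), 0.4)
  expect_true(is.na(polysome_index(0, 0)))
  # swapping fractions complements the index
  dp <- runif(20); ds <- runif(20)
  expect_equal(polysome_index(dp, ds), 1 - polysome_index(ds, dp))
  expect_true(all(polysome_index(dp, ds) >= 0 &
                    polysome_index(dp, ds) <= 1))
})

test_that("PSR is the log2 PI ratio with undefined propagation", {
  expect_equal(unname(polysome_shift_ratio(0.5, 0.5)), 0)
  expect_equal(unname(polysome_shift_ratio(0.25, 0.5)), -1)
  # the 0.85-fold ratio prints as -0.23 at two decimals
  expect_equal(round(polysome_shift_ratio(0.85 * 0.4, 0.4), 2), -0.23,
               ignore_attr = TRUE)
  expect_true(is.na(polysome_shift_ratio(0, 0.5)))
  expect_true(is.na(polysome_shift_ratio(0.5, 0)))
  expect_true(is.na(polysome_shift_ratio(NA, 0.5)))
  # antisymmetry under genotype swap
  a <- runif(30, 0.05, 0.95); b <- runif(30, 0.05, 0.95)
  expect_equal(polysome_shift_ratio(a, b), -polysome_shift_ratio(b, a))
})

test_that("pooled-variance t on replicate PIs matches oracles", {
  # hand-checkable case: t ~ 12.25 on 4 df
  res <- psr_significance(matrix(c(0.30, 0.32, 0.28), 1),
                          matrix(c(0.50, 0.52, 0.48), 1))
  expect_equal(res$t, -12.24745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2.576e-4, tolerance = 1e-3)
  # closed-form and t.test oracles on random 3-replicate inputs
  set.seed(7)
  for (i in 1:20) {
    x <- runif(3); y <- runif(3)
    got <- psr_significance(matrix(x, 1), matrix(y, 1))$p_value
    expect_equal(got, pooled_t_p(x, y), tolerance = 1e-10)
    expect_equal(got, t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("degenerate and untestable t cases follow the conventions", {
  # zero pooled variance, equal means -> p = 1
  res <- psr_significance(matrix(c(0.4, 0.6), 1), matrix(c(0.4, 0.6), 1))
  expect_equal(res$p_value, 1)
  expect_equal(res$t, 0)
  # equal-variance groups with identical values, different means -> p = 0
  res <- psr_significance(matrix(c(0.3, 0.3), 1), matrix(c(0.5, 0.5), 1))
  expect_equal(res$p_value, 0)
  # replicate order does not matter
  x <- c(0.2, 0.5, 0.4); y <- c(0.6, 0.3, 0.7)
  expect_equal(psr_significance(matrix(x, 1), matrix(y, 1))$p_value,
               psr_significance(matrix(rev(x), 1),
                                matrix(y[c(2, 1, 3)], 1))$p_value)
  # fewer than two replicates -> NA, not an error
  res <- psr_significance(matrix(0.4, 1), matrix(c(0.5, 0.6), 1))
  expect_true(is.na(res$p_value))
})

test_that("shift classification splits on sign and significance", {
  tbl <- data.frame(gene_id = c("a", "b", "c", "d"),
                    PSR = c(-1, -1, 1, NA),
                    p_value = c(0.001, 0.2, 0.01, 0.01))
  cls <- classify_shifted_genes(tbl)$class
  expect_equal(as.character(cls),
               c("down", "unchanged", "up", "undefined"))
})

test_that("GO input lists use inclusive two-decimal log2 bounds", {
  tbl <- data.frame(gene_id = c("at", "zero", "below", "up"),
                    PSR = c(-0.23, 0, -0.25, 0.20))
  lists <- go_input_filter(tbl)
  expect_setequal(lists$down, c("at", "below"))
  expect_equal(lists$up, "up")
  expect_equal(unname(lists$thresholds), c(-0.23, 0.20))
  expect_error(go_input_filter(tbl, down_fold = 0), "fold")
})

test_that("expression filter is strictly greater-than", {
  d <- matrix(c(0.4, 0.5, 0.6, 5.0), ncol = 1)
  expect_equal(expression_filter(d), c(FALSE, FALSE, TRUE, TRUE))
  d3 <- cbind(c(0.4, 0.6, 5.0), c(0.4, 0.6, 5.0))
  expect_equal(sum(expression_filter(d3)), 2)
})

test_that("full pipeline recovers planted indices without noise", {
  cfg <- polysome_sim_config(n_genes = 60, total_reads_per_sample = 1e7,
                             shifted_fraction = 0.2, true_delta_psr = -1,
                             n_replicates = 2, dispersion = 0, seed = 3)
  sim <- generate_polysome_experiment(cfg)
  res <- psr_analysis(sim$counts, min_mean_tpm = 0)
  m <- merge(res, sim$truth$genes, by = "gene_id")
  expect_equal(m$PI_wt, m$pi_wt, tolerance = 2e-3)
  expect_equal(m$PSR, m$true_psr, tolerance = 2e-2)
  # genotype swap negates the PSR column
  swapped <- psr_analysis(sim$counts, wt = "NRS", mut = "WT",
                          min_mean_tpm = 0)
  expect_equal(swapped$PSR, -res$PSR)
})
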