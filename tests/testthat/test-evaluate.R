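test_that("boundary Jaccard handles identity, overlap, and flanks", {
  a <- c(100000, 200000, 300000)
  expect_equal(jaccard_boundaries(a, a, 50000), 1)
  b <- c(100000, 200000, 400000)
  expect_equal(jaccard_boundaries(a, b, 50000), 0.5)
  expect_equal(jaccard_boundaries(numeric(), numeric(), 50000), 1)

  # off-by-one boundaries only match under a flank
  expect_equal(jaccard_boundaries(100000, 140000, 50000), 0)
  expect_equal(jaccard_boundaries(100000, 140000, 50000, flank_bp = 50000), 1)
})

test_that("flanked matching is one-to-one and greedy by distance", {
  a <- c(100000, 130000)
  b <- c(110000)
  # both a-boundaries overlap b; only one may claim the match
  expect_equal(jaccard_boundaries(a, b, 10000, flank_bp = 50000), 1 / 2)
})

test_that("Jaccard variants are symmetric and bounded", {
  set.seed(41)
  for (i in 1:20) {
    a <- sort(sample(1:100, sample(3:10, 1))) * 25000
    b <- sort(sample(1:100, sample(3:10, 1))) * 25000
    j1 <- jaccard_boundaries(a, b, 25000)
    expect_equal(j1, jaccard_boundaries(b, a, 25000))
    expect_gte(j1, 0); expect_lte(j1, 1)
    j2 <- jaccard_boundaries(a, b, 25000, flank_bp = 50000)
    expect_equal(j2, jaccard_boundaries(b, a, 25000, flank_bp = 50000))
    expect_gte(j2, j1 - 1e-12)
  }
})

test_that("cross-resolution Jaccard snaps to the coarser grid", {
  # same boundary seen by a 25 kb and a 50 kb call
  expect_equal(modified_jaccard(125000, 25000, 100000, 50000), 1)
  expect_equal(modified_jaccard(c(100000, 300000), 50000,
                                c(100000, 300000), 50000),
               jaccard_boundaries(c(100000, 300000), c(100000, 300000),
                                  50000))
  expect_equal(modified_jaccard(100000, 25000, 500000, 50000), 0)
  expect_error(modified_jaccard(1e5, 30000, 1e5, 50000), "common grid")
})

test_that("perturbations at level 0 are identities (noise, sparsity)", {
  sim <- simulate_matrix(sim_spec(c(10, 10), count_noise = "poisson",
                                  seed = 3))
  for (mode in c("noise", "sparsity"))
    expect_identical(perturb_matrix(sim$cm, mode, 0, seed = 1)$values,
                     sim$cm$values)
})

test_that("sparsity zeroes the requested fraction of cells", {
  sim <- simulate_matrix(sim_spec(c(50, 50), within_intensity = 10,
                                  between_intensity = 2))
  p <- perturb_matrix(sim$cm, "sparsity", 0.5, seed = 9)
  ut <- upper.tri(p$values, diag = TRUE)
  expect_equal(mean(p$values[ut] == 0), 0.5, tolerance = 0.01)
  expect_equal(p$values, t(p$values))
})

test_that("noise adds the constant to the requested fraction of cells", {
  sim <- simulate_matrix(sim_spec(c(20, 20), within_intensity = 10,
                                  between_intensity = 2))
  p <- perturb_matrix(sim$cm, "noise", 0.25, constant = 2, seed = 9)
  ut <- which(upper.tri(p$values, diag = TRUE))
  delta <- p$values[ut] - sim$cm$values[ut]
  expect_true(all(delta %in% c(0, 2)))
  expect_equal(sum(delta == 2), round(0.25 * length(ut)))
})

test_that("downsampling keeps the requested fraction of contacts", {
  sim <- simulate_matrix(sim_spec(c(30, 30), within_intensity = 20,
                                  between_intensity = 4,
                                  count_noise = "poisson", seed = 2))
  p <- perturb_matrix(sim$cm, "downsample", 0.25, seed = 9)
  ut <- upper.tri(p$values, diag = TRUE)
  expect_equal(sum(p$values[ut]), round(0.25 * sum(sim$cm$values[ut])))
  expect_equal(p$values, t(p$values))
  # cells empty in the source stay empty
  expect_true(all(p$values[sim$cm$values == 0] == 0))
})

test_that("perturbation is reproducible under a seed and restores the RNG", {
  sim <- simulate_matrix(sim_spec(c(20, 20)))
  set.seed(123)
  before <- .Random.seed
  p1 <- perturb_matrix(sim$cm, "sparsity", 0.3, seed = 77)
  expect_identical(.Random.seed, before)
  p2 <- perturb_matrix(sim$cm, "sparsity", 0.3, seed = 77)
  expect_identical(p1$values, p2$values)
})

test_that("enrichment p-values hit the add-one floor when null cannot win", {
  bnd <- c(10, 20, 30) * 25000
  ann <- data.frame(start = bnd - 1000, end = bnd + 1000)
  res <- permutation_enrichment(bnd, ann, chrom_length = 5e7,
                                resolution = 25000, B = 99, flank_bp = 50000,
                                seed = 4)
  expect_gte(res$observed_count, 1)
  # nulls can land near the annotations, so only the bound is guaranteed
  expect_gte(res$p_enrich, 1 / 100)
  expect_lte(res$p_enrich, 1)
  expect_lte(res$p_deplete, 1)

  # annotations confined to a region the null can never reach densely
  dense <- data.frame(start = rep(bnd, each = 40) - 1000,
                      end = rep(bnd, each = 40) + 1000)
  res2 <- permutation_enrichment(bnd, dense, chrom_length = 5e8,
                                 resolution = 25000, B = 99,
                                 flank_bp = 50000, seed = 4)
  expect_equal(res2$p_enrich, 1 / 100)
})

test_that("an empty annotation set gives zero counts and p_enrich 1", {
  res <- permutation_enrichment(c(250000, 500000),
                                data.frame(start = numeric(),
                                           end = numeric()),
                                chrom_length = 1e7, resolution = 25000,
                                B = 19, seed = 1)
  expect_equal(res$observed_count, 0)
  expect_equal(res$p_enrich, 1)
})

test_that("gap bins are excluded from null placement", {
  n_bin <- 400
  gap <- rep(FALSE, n_bin); gap[101:400] <- TRUE
  # annotations tile the open bins densely, so any draw there must count
  ann <- data.frame(start = (0:100) * 25000, end = (1:101) * 25000)
  res <- permutation_enrichment(50 * 25000, ann,
                                chrom_length = n_bin * 25000,
                                resolution = 25000, gap_mask = gap,
                                B = 50, seed = 6)
  # all null draws fall among the first 100 bins, where annotations are
  expect_true(all(res$null_counts > 0))
})

test_that("Fisher combination matches the chi-square tail exactly", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.2), 0.2)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               gamma_fisher(c(0.05, 0.05)), tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747866, tolerance = 1e-6)
  set.seed(43)
  for (i in 1:10) {
    p <- runif(sample(2:6, 1))
    expect_equal(fisher_combine(p), gamma_fisher(p), tolerance = 1e-12)
  }
  expect_error(fisher_combine(c(0, 0.5)), "zero_floor")
  expect_equal(fisher_combine(c(0, 0.5), zero_floor = 0.01),
               fisher_combine(c(0.01, 0.5)))
})
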