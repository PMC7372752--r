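test_that("window arithmetic and the resolution cap follow from 2 Mb / r", {
  cfg <- window_config(resolution = 25000)
  expect_equal(cfg$w, 80)
  expect_equal(cfg$max_resolution, 200000)
  expect_s3_class(window_config(resolution = 200000), "WindowConfig")
  expect_error(window_config(resolution = 250000), "exceeds")
  expect_error(window_config(resolution = 25000, n_eigenvectors = 1),
               "two eigenvectors")
})

test_that("the normalized Laplacian matches hand computation", {
  expect_equal(build_laplacian(matrix(c(2, 1, 1, 2), 2)),
               matrix(c(2, 1, 1, 2) / 3, 2))
  expect_equal(build_laplacian(diag(4)), diag(4))
  expect_error(build_laplacian(matrix(c(1, 0, 0, 0), 2)), "marginal")
})

test_that("Laplacian spectrum is bounded with leading eigenvalue 1", {
  set.seed(21)
  for (i in 1:10) {
    v <- matrix(runif(36, 0.2, 3), 6)
    v <- v + t(v)
    ev <- eigen(build_laplacian(v), symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(ev[1] - 1), 1e-10)
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
})

test_that("unit-circle projection separates blocks and flags junctions", {
  v <- block_values(c(6, 6), within = 1, between = 0)
  diag(v) <- 1
  proj <- project_eigenvectors(build_laplacian(v), 2)
  expect_equal(unname(sqrt(rowSums(proj$unit_rows^2))), rep(1, 12))
  pts <- unique(round(proj$unit_rows, 8))
  expect_equal(nrow(pts), 2)
  expect_gt(proj$gap_vector[6], 1)
  expect_equal(proj$gap_vector[-6], rep(0, 10), tolerance = 1e-8)
  expect_true(all(proj$gap_vector >= 0 & proj$gap_vector <= 2))
  expect_equal(sort(proj$eigenvalues, decreasing = TRUE), proj$eigenvalues)
})

test_that("k = 1 projection collapses to signs; identical rows give gap 0", {
  v <- block_values(c(4, 4), within = 5, between = 1)
  proj1 <- project_eigenvectors(build_laplacian(v), 1)
  expect_true(all(abs(abs(proj1$unit_rows) - 1) < 1e-12))
  # rows inside one block are identical rows of L: zero gap, exactly
  proj2 <- project_eigenvectors(build_laplacian(v), 2)
  expect_identical(proj2$gap_vector[1], 0)
  expect_error(project_eigenvectors(build_laplacian(v), 9), "dimension")
})

test_that("candidate count, ranking, and tie-breaks follow the w/5 rule", {
  gap <- rep(0.1, 9)
  expect_length(candidate_boundaries(gap, 10, 5), 2)
  expect_equal(candidate_boundaries(gap, 10, 5), c(2, 3))  # left-most ties
  gap[7] <- 5
  expect_equal(candidate_boundaries(gap, 10, 5)[1], 8)     # spike ranks first
  expect_error(candidate_boundaries(rep(0.1, 8), 9, 5), "two TADs")
})

test_that("silhouette model selection finds the planted cluster count", {
  v <- block_values(c(10, 10, 10), within = 10, between = 1)
  proj <- project_eigenvectors(build_laplacian(v), 2)
  cand <- candidate_boundaries(proj$gap_vector, 30, 5)
  score <- silhouette_partition(v, cand)
  expect_equal(score$m, 3)
  expect_equal(score$boundaries, c(11, 21))
  expect_true(all(score$per_cluster_s >= -1 & score$per_cluster_s <= 1))
  expect_equal(score$mean_s, mean(score$per_cluster_s))
  # independent route: prefix-sum silhouette over the same cuts
  expect_equal(score$mean_s, prefix_silhouette(1 / (v + 1), c(11, 21)),
               tolerance = 1e-12)
})

test_that("a uniform window scores below the organization threshold", {
  v <- matrix(4, 20, 20)
  cand <- candidate_boundaries(rep(0, 19), 20, 5)
  score <- silhouette_partition(v, cand)
  expect_equal(score$mean_s, 0)
  cm <- contact_matrix(v, 25000)
  res <- call_window(cm, 1, window_config(resolution = 25000,
                                          window_bp = 20 * 25000))
  expect_false(res$organized)
  expect_equal(nrow(res$tads), 0)
})

test_that("window calling keeps a 5-bin TAD but drops a 4-bin segment", {
  sim <- simulate_matrix(sim_spec(c(15, 5), within_intensity = 10,
                                  between_intensity = 1))
  cfg <- window_config(resolution = 25000, window_bp = 20 * 25000)
  res <- call_window(sim$cm, 1, cfg)
  expect_true(res$organized)
  expect_equal(res$tads$end_bin, c(15, 20))

  sim2 <- simulate_matrix(sim_spec(c(10, 4, 5, 11), within_intensity = 10,
                                   between_intensity = 1, min_block = 4))
  cfg2 <- window_config(resolution = 25000, window_bp = 30 * 25000)
  res2 <- call_window(sim2$cm, 1, cfg2)
  widths <- res2$tads$end_bin - res2$tads$start_bin + 1
  expect_false(any(widths < 5))
  expect_false(any(res2$tads$start_bin == 11 & res2$tads$end_bin == 14))
  expect_equal(min(widths), 5)
})

test_that("the sweep reproduces a single-window call on short matrices", {
  sim <- simulate_matrix(sim_spec(c(20, 20, 20), within_intensity = 10,
                                  between_intensity = 2))
  cfg <- window_config(resolution = 25000, window_bp = 30 * 25000)  # w = 30
  tads <- call_tads(sim$cm, cfg)
  expect_equal(tads$end_bin, c(20, 40, 60))

  # matrix shorter than the window: sweep degenerates to one window
  cfg_wide <- window_config(resolution = 25000)
  expect_equal(call_tads(sim$cm, cfg_wide)$end_bin,
               call_window(sim$cm, 1, cfg_wide)$tads$end_bin)
})

test_that("TADs flank a centromeric gap but are never called inside it", {
  v <- block_values(c(20, 20), within = 10, between = 2)
  n <- 50
  full <- matrix(2, n, n)
  full[1:20, 1:20] <- v[1:20, 1:20]
  full[31:50, 31:50] <- v[21:40, 21:40]
  gap <- 21:30
  full[gap, ] <- 0; full[, gap] <- 0
  cm <- contact_matrix(full, 25000)
  cm <- apply_gap_mask(cm, find_gap_bins(cm))
  tads <- call_tads(cm, window_config(resolution = 25000,
                                      window_bp = 40 * 25000))
  expect_equal(tads$start_bin, c(1, 31))
  expect_equal(tads$end_bin, c(20, 50))
})

test_that("calling is deterministic and yields sorted disjoint TADs", {
  set.seed(31)
  sim <- simulate_matrix(sim_spec(c(12, 25, 8, 18, 30),
                                  within_intensity = 20,
                                  between_intensity = 3,
                                  count_noise = "poisson", seed = 5))
  cfg <- window_config(resolution = 25000)
  t1 <- call_tads(sim$cm, cfg)
  t2 <- call_tads(sim$cm, cfg)
  expect_identical(t1, t2)
  expect_true(all(diff(t1$start_bin) > 0))
  expect_true(all(t1$start_bin[-1] > t1$end_bin[-nrow(t1)]))
  expect_true(all(t1$end_bin - t1$start_bin + 1 >= 5))
})

test_that("configuration resolution must match the matrix", {
  cm <- contact_matrix(matrix(1, 20, 20), 50000)
  expect_error(call_tads(cm, window_config(resolution = 25000)),
               "resolution")
})
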