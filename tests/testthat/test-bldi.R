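test_that("JZS BF10 matches the brute-force quadrature oracle to 1e-6", {
  for (t in c(0, 0.5, 1, 2.16, 3, 5)) {
    for (n1 in c(3, 5, 20)) {
      for (n2 in c(3, 10, 37)) {
        for (rscale in c(0.5, 0.707, 1)) {
          impl <- jzs_bf_two_sample(t = t, n1 = n1, n2 = n2,
                                    rscale = rscale)$bf10
          oracle <- oracle_jzs_bf(t, n1, n2, rscale)
          expect_lt(abs(impl - oracle) / oracle, 1e-6)
        }
      }
    }
  }
})

test_that("BF10 at t = 0 favours the null for all group sizes", {
  for (n1 in c(2, 3, 10, 37)) {
    for (n2 in c(2, 5, 20)) {
      expect_lt(jzs_bf_two_sample(t = 0, n1 = n1, n2 = n2)$bf10, 1)
    }
  }
})

test_that("null BF10(t = 0, n, n) decreases as n grows", {
  bfs <- vapply(c(5, 10, 20, 40, 80, 160), function(n)
    jzs_bf_two_sample(t = 0, n1 = n, n2 = n)$bf10, numeric(1))
  expect_true(all(diff(bfs) < 0))
})

test_that("BF10 increases strictly with |t| and decreases in wide priors", {
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, function(t)
    jzs_bf_two_sample(t = t, n1 = 12, n2 = 9)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bf_two_sample(t = -2.5, n1 = 12, n2 = 9)$bf10,
               jzs_bf_two_sample(t = 2.5, n1 = 12, n2 = 9)$bf10,
               tolerance = 1e-9)
  # widening the prior at fixed data pushes BF10 toward 0
  wide <- vapply(c(0.707, 2, 8, 32, 128), function(r)
    jzs_bf_two_sample(t = 2, n1 = 10, n2 = 10, rscale = r)$bf10, numeric(1))
  expect_true(all(diff(wide) < 0))
  expect_lt(wide[length(wide)], 0.1)
})

test_that("BF from data: identical groups favour H0, separated favour H1", {
  x <- c(1.2, 0.8, 1.1, 0.9, 1.0, 1.3, 0.7, 1.05, 0.95, 1.15)
  res0 <- jzs_bf_two_sample(x, x + 1e-9 * seq_along(x))
  expect_lt(res0$bf10, 1)
  expect_equal(res0$t_stat, 0, tolerance = 1e-4)
  set.seed(31)
  a <- stats::rnorm(10, 0, 1); b <- stats::rnorm(10, 10, 1)
  expect_gt(jzs_bf_two_sample(a, b)$bf10, 3)
})

test_that("degenerate groups yield not_tested, never an error", {
  expect_equal(jzs_bf_two_sample(1, c(2, 3, 4))$category, "not_tested")
  expect_equal(jzs_bf_two_sample(c(1, 1, 1), c(1, 1, 1))$category,
               "not_tested")
  expect_equal(jzs_bf_two_sample(numeric(0), c(1, 2))$category,
               "not_tested")
})

test_that("evidence categories follow the substantial thresholds", {
  expect_equal(categorize_bf(3), "substantial_H1")
  expect_equal(categorize_bf(1), "inconclusive")
  expect_equal(categorize_bf(1 / 3), "inconclusive")
  expect_equal(categorize_bf(0.2), "substantial_H0")
  expect_equal(categorize_bf(c(10, 0.5, 0.1)),
               c("substantial_H1", "inconclusive", "substantial_H0"))
  expect_error(categorize_bf(0), "positive")
  expect_error(categorize_bf(-1), "positive")
})

test_that("bf_map tests the right voxels and aligns scores by id", {
  # 7 patients, 4 voxels: v1 lesioned in 3 with scores mixed like the
  # intact set, v2 lesioned in only 2 (filtered), v3 lesioned in all
  # (no intact), v4 lesioned in exactly the 3 low-score patients
  shape <- c(4L, 1L, 1L)
  pats <- rbind(c(0, 1, 1, 1), c(1, 1, 1, 1), c(0, 0, 1, 1),
                c(1, 0, 1, 0), c(0, 0, 1, 0), c(1, 0, 1, 0),
                c(0, 0, 1, 0))
  vols <- lapply(1:7, function(p)
    tiny_volume(pats[p, ], shape, sprintf("p%d", p)))
  vm <- build_voxel_matrix(vols)
  scores <- c(p1 = -5, p2 = -4.5, p3 = -5.5, p4 = 10, p5 = 11, p6 = 9,
              p7 = 10.5)
  bm <- bf_map(vm, scores)
  tab <- bm$table
  expect_equal(nrow(tab), 2L)  # v2, v3 dropped by the coverage filter
  v1 <- tab[tab$i == 0, ]; v4 <- tab[tab$i == 3, ]
  expect_gt(v4$bf10, 3)
  expect_equal(v4$category, "substantial_H1")
  expect_lt(v1$bf10, 1)
  expect_lt(v1$bf10, v4$bf10)
  # shuffled score names give identical results
  bm2 <- bf_map(vm, scores[sample(names(scores))])
  expect_equal(bm2$table, tab)
  expect_error(bf_map(vm, scores[-1]), "missing")
  expect_error(bf_map(vm, unname(scores)), "named")
})

test_that("deduplicated map equals the naive per-voxel loop", {
  cfg <- small_config(seed = 5)
  coh <- generate_cohort(cfg)
  prof <- behavioural_profiles(coh$trials)
  stroke <- prof[prof$group == "stroke", ]
  scores <- stats::setNames(stroke$tde_mean, stroke$participant_id)
  vm <- build_voxel_matrix(coh$lesions)
  bm <- bf_map(vm, scores)
  vmf <- coverage_filter(vm, 3, 2)
  naive <- vapply(seq_len(ncol(vmf$matrix)), function(v) {
    les <- vmf$matrix[, v] == 1
    r <- jzs_bf_two_sample(scores[vmf$patient_ids][les],
                           scores[vmf$patient_ids][!les])
    if (r$category == "not_tested") NA_real_ else r$bf10
  }, numeric(1))
  expect_identical(bm$table$bf10, naive)
})
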