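# Programmatic fixtures: everything is built in code at test time.

# tiny lesion volumes on an n1 x n2 x n3 grid from a flat 0/1 vector
tiny_volume <- function(flat, shape, id, affine = NULL) {
  if (is.null(affine)) affine <- diag(4)
  lesion_volume(array(flat, dim = shape), affine, id)
}

# voxel matrix with prescribed column sums on a patients x voxels layout
matrix_with_colsums <- function(colsums, n_patients) {
  cols <- lapply(colsums, function(k) rep(c(1, 0), c(k, n_patients - k)))
  mat <- do.call(cbind, cols)
  vols <- lapply(seq_len(n_patients), function(p)
    tiny_volume(mat[p, ], c(length(colsums), 1L, 1L), sprintf("p%02d", p)))
  build_voxel_matrix(vols)
}

# small, fast synthetic config (coarse grid, fewer patients) for IO-heavy
# pipeline tests; statistics do not depend on grid size
small_config <- function(seed = 1L, ...) {
  args <- list(
    grid_shape = c(16L, 16L, 16L), voxel_size_mm = 10,
    n_controls = 10L, n_patients = 14L, n_seeded_hits = 3L,
    lesion_radius_range_mm = c(20, 50),
    critical_region = list(center = c(12L, 9L, 9L), radius_mm = 22),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_cohort_config, args)
}

expect_group_test_matches_ttest <- function(gt, ht) {
  expect_equal(gt$statistic, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(gt$df, unname(ht$parameter), tolerance = 1e-10)
  expect_equal(gt$p_two_tailed, ht$p.value, tolerance = 1e-10)
}
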