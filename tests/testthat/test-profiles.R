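make_long_rows <- function(id, group, side, upright, left, right) {
  data.frame(participant_id = id, group = group, lesion_side = side,
             posture = rep(c("upright", "left10", "right10"), each = 2),
             trial = rep(1:2, 3),
             adjustment = rep(c(upright, left, right), each = 2),
             stringsAsFactors = FALSE)
}

test_that("profiles map postures to tilt directions by lesion side", {
  # control: dir1 = leftward; raw signs kept
  # right lesion: dir1 = right10 (ipsilesional), raw signs kept
  # left lesion: dir1 = left10, all signs flipped
  beh <- rbind(
    make_long_rows("c1", "control", "none", 2, -8, 12),
    make_long_rows("s1", "stroke", "right", 2, 12, -8),
    make_long_rows("s2", "stroke", "left", -2, 8, -12))
  attr(beh, "format") <- "long"
  prof <- suppressWarnings(behavioural_profiles(beh))
  expect_equal(prof$tde_dir1, rep(10, 3))
  expect_equal(prof$tde_dir2, rep(10, 3))
  expect_equal(prof$tde_mean, rep(10, 3))
  expect_equal(prof$svba_upright_oriented, c(2, 2, 2))
})

test_that("profiles reject inconsistent metadata and missing postures", {
  bad <- make_long_rows("c1", "control", "left", 0, 0, 0)
  attr(bad, "format") <- "long"
  expect_error(suppressWarnings(behavioural_profiles(bad)), "none")
  miss <- make_long_rows("s1", "stroke", "right", 0, 1, 2)
  miss <- miss[miss$posture != "left10", ]
  attr(miss, "format") <- "long"
  expect_error(behavioural_profiles(miss), "left10")
  odd <- make_long_rows("c1", "control", "none", 0, 1, 2)
  odd$posture[1] <- "sideways"
  expect_error(behavioural_profiles(odd), "posture label")
})

test_that("wide and long schemas give identical profiles", {
  beh <- rbind(make_long_rows("c1", "control", "none", 1, -5, 9),
               make_long_rows("s1", "stroke", "left", 3, 2, -4))
  attr(beh, "format") <- "long"
  long_prof <- suppressWarnings(behavioural_profiles(beh))
  wide <- data.frame(participant_id = c("c1", "s1"),
                     group = c("control", "stroke"),
                     lesion_side = c("none", "left"),
                     svba_upright = c(1, 3), svba_left = c(-5, 2),
                     svba_right = c(9, -4), stringsAsFactors = FALSE)
  attr(wide, "format") <- "wide"
  wide_prof <- behavioural_profiles(wide)
  cols <- c("tde_dir1", "tde_dir2", "tde_mean", "svba_upright_oriented")
  expect_equal(long_prof[cols], wide_prof[cols])
})

test_that("read_behaviour round-trips both schemas and sniffs separators", {
  beh <- rbind(make_long_rows("c1", "control", "none", 1, -5, 9),
               make_long_rows("s1", "stroke", "right", 0, 4, -2))
  path_csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(beh, path_csv, row.names = FALSE)
  got <- read_behaviour(path_csv)
  expect_identical(attr(got, "format"), "long")
  expect_equal(got$adjustment, beh$adjustment)
  path_tsv <- withr::local_tempfile(fileext = ".tsv")
  wide <- data.frame(participant_id = "c1", group = "control",
                     lesion_side = "none", svba_upright = 1,
                     svba_left = -5, svba_right = 9)
  utils::write.table(wide, path_tsv, sep = "\t", row.names = FALSE)
  got2 <- read_behaviour(path_tsv)
  expect_identical(attr(got2, "format"), "wide")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_behaviour(bad), "schema")
})

test_that("labelling uses unrounded control statistics and strict cut-off", {
  prof <- data.frame(
    participant_id = c(paste0("c", 1:4), paste0("s", 1:3)),
    group = rep(c("control", "stroke"), c(4, 3)),
    lesion_side = rep(c("none", "right"), c(4, 3)),
    tde_mean = c(20, 24, 26, 30, -5, 2.49, 25),
    stringsAsFactors = FALSE)
  prof$label <- "unlabelled"
  out <- label_profiles(prof, k = 1.5)
  # controls: mean 25, sd sqrt(options) -> cutoff = 25 - 1.5*sd
  s <- stats::sd(c(20, 24, 26, 30))
  expect_equal(attr(out, "cutoff"), 25 - 1.5 * s)
  expect_equal(out$label, c(rep("unlabelled", 4),
                            ifelse(c(-5, 2.49, 25) < 25 - 1.5 * s,
                                   "abnormal", "normal")))
  expect_error(label_profiles(prof[5:7, ]), "control")
})

test_that("group_tests reproduces the battery on a synthetic cohort", {
  coh <- generate_cohort(synthetic_cohort_config(seed = 3))
  prof <- behavioural_profiles(coh$trials)
  gt <- group_tests(prof)
  ctrl <- prof[prof$group == "control", ]
  strk <- prof[prof$group == "stroke", ]
  expect_group_test_matches_ttest(
    gt$tde_between_groups,
    stats::t.test(ctrl$tde_mean, strk$tde_mean, var.equal = TRUE))
  expect_group_test_matches_ttest(
    gt$tilt_direction_stroke,
    stats::t.test(strk$tde_dir1, strk$tde_dir2, paired = TRUE))
  expect_group_test_matches_ttest(gt$upright_control,
                                  stats::t.test(ctrl$svba_upright_oriented))
  expect_equal(gt$summary$n, c(20, 37))
})
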