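three_step_rough <- function() {
  milling_protocol("rough_3step", list(
    milling_step(1000, 300, 3, 5),
    milling_step(500, 300, 1.8, 3),
    milling_step(300, 300, 1.0, 1.5)), "rough")
}

test_that("protocols round-trip through the text grammar", {
  p <- milling_protocol("minimal", list(milling_step(300, 60, 1, 2)), "fine")
  txt <- write_protocol(p)
  expect_identical(write_protocol(parse_protocol(txt)), txt)

  # staged rough protocol with currents decreasing 1 nA -> 0.3 nA
  p3 <- three_step_rough()
  back <- parse_protocol(write_protocol(p3))
  expect_equal(vapply(back$steps, `[[`, numeric(1), "current"), c(1000, 500, 300))
  expect_equal(length(back$steps), 3)
})

test_that("protocol round-trip is the identity for fuzzed protocols", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(1:5, 1)
    steps <- lapply(seq_len(n), function(j)
      milling_step(round(runif(1, 10, 3000), 3), round(runif(1, 1, 4000), 2),
                   round(runif(1, 0, 5), 3), round(runif(1, 0.5, 8), 3),
                   round(runif(1, -2, 2), 2)))
    p <- milling_protocol(paste0("fuzz", i), steps,
                          sample(c("rough", "fine"), 1))
    txt <- write_protocol(p)
    expect_identical(write_protocol(parse_protocol(txt)), txt)
  }
})

test_that("malformed protocols raise parse errors naming the problem", {
  expect_fibclem_error(parse_protocol("name: x\n[step]\ntime: 5\npattern_distance: 1\npattern_height: 2"),
                       "parse_error")
  err <- tryCatch(parse_protocol("name: x\n[step]\ntime: 5\npattern_distance: 1\npattern_height: 2"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "current")
  expect_fibclem_error(parse_protocol("name: x\n[step]\ncurrent: abc\ntime: 1\npattern_distance: 1\npattern_height: 1"),
                       "parse_error")
  expect_fibclem_error(parse_protocol("garbage line\n"), "parse_error")
})

test_that("lamella compilation yields paired clipped patterns per step", {
  tgt <- lamella_target(c(0, 0), width = 10, extremes = c(-6, 6))
  seqs <- compile_lamella_patterns(three_step_rough(), tgt)
  expect_equal(nrow(seqs), 6)
  expect_true(all(seqs$width == 10))
  # inner-edge gaps strictly decrease with the step index
  upper <- seqs[seq(1, 6, by = 2), ]
  lower <- seqs[seq(2, 6, by = 2), ]
  gaps <- (lower$center_y - lower$height / 2) - (upper$center_y + upper$height / 2)
  expect_equal(gaps, c(3, 1.8, 1.0))
  expect_true(all(diff(gaps) < 0))
  # geometric construction oracle: inner edges at +- pattern_distance / 2
  expect_equal(upper$center_y + upper$height / 2, -gaps / 2)
  # no command crosses the extremes
  expect_true(all(seqs$center_y - seqs$height / 2 >= -6 - 1e-9))
  expect_true(all(seqs$center_y + seqs$height / 2 <= 6 + 1e-9))
  # scan directions mill toward the lamella face
  expect_equal(upper$scan_direction, rep("top_to_bottom", 3))
  expect_equal(lower$scan_direction, rep("bottom_to_top", 3))
})

test_that("patterns clip at asymmetric extremes", {
  # extreme only 1 um above the upper pattern inner edge, 5 um pattern height
  tgt <- lamella_target(c(0, 0), width = 8, extremes = c(-1.5, 8))
  p <- milling_protocol("x", list(milling_step(500, 60, 1, 5)))
  seqs <- compile_lamella_patterns(p, tgt)
  upper <- seqs[1, ]
  expect_equal(upper$height, 1)  # clipped from 5 to extreme - inner edge
  expect_equal(upper$center_y - upper$height / 2, -1.5)
  lower <- seqs[2, ]
  expect_equal(lower$height, 5)  # room below
})

test_that("expansion joints are mirror-symmetric and obey the offset arithmetic", {
  tgt <- lamella_target(c(2, 0), width = 10, extremes = c(-6, 6),
                        expansion_joints = TRUE, joint_offset = 1.5,
                        joint_width = 0.5)
  j <- expansion_joint_patterns(tgt)
  expect_equal(nrow(j), 2)
  expect_equal(j$center_x, c(2 - (5 + 1.5), 2 + (5 + 1.5)))
  expect_equal(j$center_y, c(0, 0))
  expect_equal(mean(j$center_x), 2)  # symmetric about lamella center x
  off <- lamella_target(c(2, 0), 10, c(-6, 6), expansion_joints = FALSE)
  expect_equal(nrow(expansion_joint_patterns(off)), 0)
})

test_that("trench compilation reproduces the published horseshoe geometry", {
  seqs <- compile_trench_patterns(chunk_width = 20, chunk_depth_y = 20,
                                  trench_w = 40, trench_h = 15,
                                  side_offset = 15, side_trench_w = 10,
                                  side_trench_h = 40)
  expect_equal(nrow(seqs), 3)
  expect_true(all(seqs$shape == "regular_cross_section"))
  # two 40 x 15 trenches symmetric about the 20 um block
  par <- seqs[1:2, ]
  expect_equal(par$width, c(40, 40))
  expect_equal(par$height, c(15, 15))
  gap <- (par$center_y[2] - par$height[2] / 2) - (par$center_y[1] + par$height[1] / 2)
  expect_equal(gap, 20)
  # 10 x 40 side trench offset to the left
  side <- seqs[3, ]
  expect_equal(c(side$width, side$height), c(10, 40))
  expect_lt(side$center_x, 0)
  # mirrored layout flips x
  mir <- compile_trench_patterns(mirror = TRUE)
  expect_equal(mir$center_x, -seqs$center_x)
  expect_fibclem_error(compile_trench_patterns(chunk_depth_y = 0),
                       "invalid_geometry")
  expect_fibclem_error(compile_trench_patterns(chunk_depth_y = 20, trench_h = 25,
                                               chunk_width = 60),
                       "invalid_geometry")
})

test_that("pattern sequences round-trip through the tab-separated file format", {
  seqs <- compile_trench_patterns()
  txt <- write_pattern_sequence(seqs)
  back <- parse_pattern_sequence(txt)
  expect_equal(as.data.frame(back), as.data.frame(seqs))
  expect_fibclem_error(parse_pattern_sequence("rectangle\t1\t2"), "parse_error")
})

test_that("volume imaging plans interleave mill and acquire with exact advance", {
  p1 <- volume_imaging_plan(c(14.3, 2.0), 100, 1)
  expect_equal(p1$action, c("mill", "acquire"))
  p130 <- volume_imaging_plan(c(14.3, 2.0), 100, 130)
  expect_equal(nrow(p130), 260)
  expect_equal(max(p130$front_nm), 13000)  # 13 um total advance
  expect_equal(nrow(volume_imaging_plan(c(1, 1), 100, 0)), 0)
})

test_that("electron dose reproduces the printed per-image doses", {
  expect_equal(round(electron_dose(50, 1, 16, 10.377), 3), 0.464)
  expect_equal(round(electron_dose(50, 1, 16, 19.271), 3), 0.134)
  expect_equal(signif(electron_dose(13, 0.25, 64, 3.4), 3), 1.12)
  expect_equal(electron_dose(0, 1, 16, 10), 0)
})

test_that("electron dose scales linearly in beam factors and inversely with pixel area", {
  base <- electron_dose(50, 1, 16, 10)
  expect_equal(electron_dose(100, 1, 16, 10), 2 * base)
  expect_equal(electron_dose(50, 2, 16, 10), 2 * base)
  expect_equal(electron_dose(50, 1, 32, 10), 2 * base)
  expect_equal(electron_dose(50, 1, 16, 20), base / 4)
})

test_that("success rate summarizes the benchmark counts", {
  stats <- ongrid_session_counts()
  expect_equal(sum(stats$target_sites), 77)
  expect_equal(sum(stats$fine_milled), 64)
  expect_equal(success_rate(stats), 83.1)
  expect_equal(success_rate(session_stats("x", 10, 10)), 100)
  cr <- stats[stats$sample == "C. reinhardtii", ]
  expect_equal(success_rate(cr), 62.5)
  expect_fibclem_error(success_rate(session_stats("x", 0, 0)), "zero_sites")
  expect_fibclem_error(session_stats("x", 5, 6), "param_error")
})

test_that("retention rate and session time budget do their bookkeeping", {
  expect_equal(retention_rate(7, 10), 70)
  expect_fibclem_error(retention_rate(1, 0), "zero_sites")
  tb <- session_time_budget(c(20, 20, 20, 20), budget_hr = 1,
                            condensation_rate_nm_hr = 50)
  expect_equal(tb$within_budget, c(TRUE, TRUE, TRUE, FALSE))
  # first lamella sits 40 min under 50 nm/hr condensation
  expect_equal(tb$condensation_nm[1], 40 / 60 * 50)
})
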