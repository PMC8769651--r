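# 24 um field of view: reference images span far more than the ~8 um
# lamella site, as on a real grid square, so realignment has stable context
std_specimen <- function(seed = 1)
  block_specimen(240, 240, 60, voxel_size = 100, mill_rate = 50)

std_rough <- function(step_s = 120)
  milling_protocol("rough", list(
    milling_step(1000, step_s, 3, 4),
    milling_step(500, step_s, 1.5, 2.5),
    milling_step(300, step_s, 1.0, 1.5)), "rough")

std_fine <- function(gap = 0.3)
  milling_protocol("fine", list(milling_step(100, 30, gap, 0.8)), "fine")

std_target <- function() lamella_target(c(0, 0), width = 8, extremes = c(-5, 5))

test_that("image acquisition is deterministic and beam shift translates the view", {
  spec <- std_specimen()
  st <- instrument_state(pixel_size_nm = 400, noise_counts = 500, seed = 5)
  a <- acquire_image(st, spec, "SEM")
  b <- acquire_image(st, spec, "SEM")
  expect_identical(a, b)

  st2 <- instrument_state(pixel_size_nm = 400, seed = 5)
  ref <- acquire_image(st2, spec, "SEM")
  st2$beam_shift_um <- c(0, -1)  # 1 um along +x
  shifted <- acquire_image(st2, spec, "SEM")
  est <- phase_correlate(ref, shifted)
  expect_equal(as.numeric(est), c(0, 1000 / 400), tolerance = 0.05)
})

test_that("the FIB view of a flat surface is y-compressed by sin(angle)", {
  spec <- std_specimen()
  st <- instrument_state(pixel_size_nm = 400, seed = 2, beam = beam_geometry(52))
  sem <- acquire_image(st, spec, "SEM")
  fib <- acquire_image(st, spec, "FIB")
  expect_equal(nrow(fib) / nrow(sem), sin(52 * pi / 180), tolerance = 0.05)
  expect_equal(ncol(fib), ncol(sem))
})

test_that("milling respects the volume budget, additivity and zero time", {
  vox_um3 <- (0.1)^3
  mk <- function() block_specimen(80, 80, 40, voxel_size = 100, mill_rate = 2)
  one_pattern <- function(cx, cy, w, h, t) pattern_sequence(
    "rectangle", cx, cy, w, h, t, 1000, "top_to_bottom")

  # through-hole: generous budget cuts exactly the footprint
  spec <- mk()
  st <- instrument_state(seed = 1)
  n0 <- fibclem:::specimen_voxel_count(spec)
  mill(st, spec, one_pattern(0, 0, 2, 1, 1000))
  removed <- n0 - fibclem:::specimen_voxel_count(spec)
  expect_equal(removed, 20 * 10 * 40, tolerance = 0.05 * 20 * 10 * 40)
  # hole goes all the way through the interior of the footprint
  expect_true(all(spec$labels[38:43, 33:48, ] == 0L))

  # budget-limited: removed volume equals rate * current * time
  spec2 <- mk()
  n0 <- fibclem:::specimen_voxel_count(spec2)
  mill(st, spec2, one_pattern(0, 0, 4, 4, 10))  # 2 um^3/nA.s * 1 nA * 10 s
  removed2 <- n0 - fibclem:::specimen_voxel_count(spec2)
  expect_equal(removed2, floor(2 * 1 * 10 / vox_um3))

  # zero (epsilon) time removes nothing measurable
  spec3 <- mk()
  n0 <- fibclem:::specimen_voxel_count(spec3)
  mill(st, spec3, one_pattern(0, 0, 2, 2, 1e-9))
  expect_equal(n0 - fibclem:::specimen_voxel_count(spec3), 0)

  # additivity of disjoint patterns
  spec4 <- mk()
  n0 <- fibclem:::specimen_voxel_count(spec4)
  mill(st, spec4, one_pattern(-2, -2, 1, 1, 10))
  r1 <- n0 - fibclem:::specimen_voxel_count(spec4)
  mill(st, spec4, one_pattern(2, 2, 1, 1, 10))
  r2 <- n0 - fibclem:::specimen_voxel_count(spec4) - r1
  spec5 <- mk()
  n0 <- fibclem:::specimen_voxel_count(spec5)
  mill(st, spec5, bind_rows_patterns <- dplyr::bind_rows(
    one_pattern(-2, -2, 1, 1, 10), one_pattern(2, 2, 1, 1, 10)))
  expect_equal(n0 - fibclem:::specimen_voxel_count(spec5), r1 + r2)

  # out-of-field pattern warns and is a no-op
  spec6 <- mk()
  n0 <- fibclem:::specimen_voxel_count(spec6)
  expect_warning(mill(st, spec6, one_pattern(100, 100, 1, 1, 10)),
                 class = "fibclem_pattern_outside")
  expect_equal(fibclem:::specimen_voxel_count(spec6), n0)
})

test_that("realign classifies stage versus beam-shift corrections at 10 um", {
  spec <- std_specimen()
  st <- instrument_state(pixel_size_nm = 400, seed = 3)
  drv <- sim_driver(spec, st)
  st$base_offset_um <- c(0, 0)
  ref <- drv$acquire_image("FIB")
  grid <- drv$pixel_grid()

  st$base_offset_um <- c(0.5, 0)
  r1 <- realign(ref, drv$acquire_image("FIB"), grid)
  expect_equal(r1$mode, "beam_shift")
  expect_lt(abs(r1$offset_um[1] - 0.5), 0.05)

  # large offsets need a field of view beyond the threshold: 48 um specimen
  spec_big <- block_specimen(240, 240, 20, voxel_size = 200, mill_rate = 50)
  stb <- instrument_state(pixel_size_nm = 400, seed = 3)
  drvb <- sim_driver(spec_big, stb)
  refb <- drvb$acquire_image("FIB")
  stb$base_offset_um <- c(12, 0)
  r2 <- realign(refb, drvb$acquire_image("FIB"), drvb$pixel_grid(),
                stage_threshold_um = 10)
  expect_equal(r2$mode, "stage")
  expect_lt(abs(r2$offset_um[1] - 12), 1)

  st$base_offset_um <- c(0, 0)
  r3 <- realign(ref, drv$acquire_image("FIB"), grid)
  expect_lt(sqrt(sum(r3$offset_um^2)), 0.05)
})

test_that("current-change realignment is beam-shift only and cancels planted offsets", {
  spec <- std_specimen()
  st <- instrument_state(pixel_size_nm = 400, seed = 4,
                         current_offsets = list(`1000` = c(0.3, 0)))
  r <- realign_on_current_change(st, spec, old_current = 100, new_current = 1000)
  expect_equal(r$mode, "beam_shift")
  expect_lt(abs(r$offset_um[1] - 0.3), 0.05)
  # after the applied correction the effective offset is near zero
  expect_lt(max(abs(fibclem:::effective_offset_um(st))), 0.05)

  st2 <- instrument_state(pixel_size_nm = 400, seed = 4)
  r2 <- realign_on_current_change(st2, spec, 100, 1000)
  expect_equal(r2$mode, "beam_shift")
  expect_lt(max(abs(r2$offset_um)), 0.05)
  # the contract holds regardless of offset magnitude
  st3 <- instrument_state(pixel_size_nm = 400, seed = 4,
                          current_offsets = list(`1000` = c(15, 0)))
  expect_equal(realign_on_current_change(st3, spec, 100, 1000)$mode, "beam_shift")
})

test_that("a drift-free session mills lamellae to the protocol thickness", {
  drv <- sim_driver(std_specimen(), instrument_state(pixel_size_nm = 400, seed = 3),
                    recall_error_um = 0.5)
  res <- run_lamella_session(list(std_target()), std_rough(), std_fine(0.3), drv)
  expect_true(res$outcomes$ok)
  # 300 nm target, 100 nm voxels: +- 1 voxel
  expect_lte(abs(res$outcomes$thickness_nm - 300), 100)
  expect_lt(res$outcomes$placement_error_px, 2)
})

test_that("sessions follow rough-all-then-fine-all ordering", {
  # three lamella sites at distinct stage positions on a 24 x 48 um specimen
  spec <- block_specimen(240, 480, 60, voxel_size = 100, mill_rate = 50)
  drv <- sim_driver(spec, instrument_state(pixel_size_nm = 400, seed = 6),
                    recall_error_um = 0.3,
                    stage_positions = list(c(0, -16), c(0, 0), c(0, 16)),
                    fov_um = 14)
  tgts <- list(lamella_target(c(0, 0), 6, c(-5, 5)),
               lamella_target(c(0, 0), 6, c(-5, 5)),
               lamella_target(c(0, 0), 6, c(-5, 5)))
  res <- run_lamella_session(tgts, std_rough(step_s = 30), std_fine(), drv)
  moves <- vapply(Filter(function(e) e$op == "move_stage", res$log),
                  function(e) e$position, numeric(1))
  # setup visits 1..3, rough visits 1..3, fine visits 1..3
  expect_equal(as.numeric(moves), rep(1:3, 3))
  expect_true(all(res$outcomes$ok))
})

test_that("uncorrected 60 nm/min drift misplaces the lamella by its time integral", {
  spec <- std_specimen()
  st <- instrument_state(pixel_size_nm = 400, drift_nm_min = c(60, 0), seed = 3)
  drv <- sim_driver(spec, st, recall_error_um = 0)
  # 30-minute rough stage (3 steps x 2 patterns x 300 s)
  res <- run_lamella_session(list(std_target()), std_rough(step_s = 300), NULL,
                             drv, realign_positions = FALSE,
                             realign_currents = FALSE)
  expect_gt(res$outcomes$placement_error_um, 1.4)
  expect_lt(res$outcomes$placement_error_um, 2.1)
})

test_that("realignment keeps placement under 2 px despite 60 nm/min drift", {
  spec <- std_specimen()
  st <- instrument_state(pixel_size_nm = 400, drift_nm_min = c(60, 0), seed = 3)
  drv <- sim_driver(spec, st, recall_error_um = 0.5)
  res <- run_lamella_session(list(std_target()), std_rough(step_s = 300),
                             std_fine(), drv)
  expect_lt(res$outcomes$placement_error_px, 2)
  expect_lte(abs(res$outcomes$thickness_nm - 300), 100)
})

test_that("volume sessions slice a buried sphere with correct bookkeeping", {
  lab <- array(0L, c(60, 60, 60))
  g <- expand.grid(y = 0:59, x = 0:59, z = 0:59)
  lab[(g$x - 30)^2 + (g$y - 30)^2 + (g$z - 30)^2 <= 12^2] <- 1L
  spec <- virtual_specimen(lab, voxel_size = 100)
  drv <- sim_driver(spec, instrument_state(seed = 1))
  stk <- run_volume_session(drv, window = c(6, 6), slice_thickness = 200,
                            n_slices = 25)
  areas <- apply(stk$data > 0, 3, sum)
  expect_equal(which.max(areas), round(30 * 100 / 200))
  # grow-then-shrink profile
  upto <- which.max(areas)
  expect_true(all(diff(areas[9:upto]) >= 0))
  expect_true(all(diff(areas[upto:21]) <= 0))
  expect_equal(stk$grid$slice_thickness, 200)

  # front advance: 10 x 100 nm slices clear exactly 1 um
  spec2 <- block_specimen(40, 40, 40, voxel_size = 100)
  drv2 <- sim_driver(spec2, instrument_state(seed = 1))
  run_volume_session(drv2, c(4, 4), 100, 10)
  expect_true(all(spec2$labels[, , 1:10][spec2$labels[, , 1:10] != 0] == 0))
  expect_true(all(spec2$labels[, , 11:40] == 1L))

  # n = 0 gives an empty stack; leaving the specimen truncates with a warning
  stk0 <- run_volume_session(drv2, c(4, 4), 100, 0)
  expect_equal(dim(stk0$data)[3], 0)
  expect_warning(run_volume_session(drv2, c(4, 4), 2000, 10),
                 class = "fibclem_front_exit")
})

test_that("generators are seeded, reproducible and honor their contracts", {
  g1 <- synth_bead_image(5, 6, 10, seed = 7)
  g2 <- synth_bead_image(5, 6, 10, seed = 7)
  expect_identical(g1$image, g2$image)
  expect_equal(nrow(g1$truth), 5)
  expect_gte(min(dist(as.matrix(g1$truth))), 4 * 6)

  v <- synth_flm_volume(tibble::tibble(x = 20, y = 20, z = 12),
                        psf_xyz = c(2, 2, 4), seed = 1)
  # anisotropic PSF: fitted z-extent exceeds xy-extent
  prof_x <- v$volume[21, , 13]; prof_z <- v$volume[21, 21, ]
  sd_est <- function(p) {
    w <- p / sum(p); xs <- seq_along(p) - 1
    sqrt(sum(w * (xs - sum(w * xs))^2))
  }
  expect_gt(sd_est(prof_z), sd_est(prof_x))

  expect_error(synth_bead_image(5, 6, 10), class = "fibclem_param_error")
  expect_error(synth_curtain(matrix(0, 8, 8), period = -1, amplitude = 1, seed = 1),
               class = "fibclem_param_error")
})

test_that("session closed loop tolerates drifts up to 120 nm/min", {
  for (drift in c(60, 120)) {
    spec <- std_specimen()
    st <- instrument_state(pixel_size_nm = 400, drift_nm_min = c(drift, 0),
                           seed = 11)
    drv <- sim_driver(spec, st, recall_error_um = 0.5)
    res <- run_lamella_session(list(std_target()), std_rough(step_s = 240),
                               std_fine(), drv)
    expect_lt(res$outcomes$placement_error_px, 2)
  }
})
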