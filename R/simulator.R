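# Simulated microscope driver and voxelized virtual specimen. The simulator
# executes pattern sequences, renders SEM/FIB views with drift and noise,
# and closes the loop for realignment and automated-session tests without
# any instrument API. Rendering is orthographic surface shading, not a
# physical SEM model; milling removes a constant volume per nA.s of beam
# exposure. These are calibration conventions of the virtual specimen, not
# physics claims.
#
# Geometry conventions: the specimen label array is [y, x, z] with z the
# ion-beam (depth) axis; pattern coordinates are true specimen um relative
# to the volume center; the FIB rendering compresses y by
# sin(inter_beam_angle) relative to the SEM rendering.

#' Voxelized virtual specimen
#'
#' @param labels 3-D integer array (`[y, x, z]`); 0 = vacuum, > 0 =
#'   material id.
#' @param voxel_size Isotropic voxel edge in nm.
#' @param mill_rates Named vector, um^3 removed per nA.s, per material id
#'   (default 1 for every material present).
#' @param reflectance Named vector of rendering intensities per material id.
#' @param texture_seed Seed for the frozen-surface texture (ice granularity,
#'   contaminants) that rendering multiplies onto the surface intensity;
#'   `NULL` disables texture. Realignment needs some texture to correlate.
#' @return An environment of class `virtual_specimen` (milling mutates it).
#' @export
virtual_specimen <- function(labels, voxel_size, mill_rates = NULL,
                             reflectance = NULL, texture_seed = 1L) {
  stopifnot(length(dim(labels)) == 3L)
  if (voxel_size <= 0) stop_fibclem("param_error", "voxel_size must be positive")
  mats <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(mill_rates)) mill_rates <- setNames(rep(1, length(mats)), mats)
  if (any(mill_rates <= 0)) stop_fibclem("param_error", "mill rates must be positive")
  if (is.null(reflectance))
    reflectance <- setNames(0.3 + 0.7 * seq_along(mats) / max(length(mats), 1), mats)
  env <- new.env(parent = emptyenv())
  env$labels <- labels
  env$voxel_size <- voxel_size
  env$mill_rates <- mill_rates
  env$reflectance <- reflectance
  d <- dim(labels)
  env$texture <- if (is.null(texture_seed)) matrix(1, d[1], d[2]) else
    with_seed(texture_seed, {
      tx <- matrix(runif(d[1] * d[2], 0.5, 1.5), d[1], d[2])
      k <- gaussian_kernel1d(4)
      0.4 + 0.6 * convolve1d(convolve1d(tx, k, 1), k, 2)
    })
  class(env) <- "virtual_specimen"
  env
}

#' Uniform block specimen
#'
#' @param ny,nx,nz Dimensions in voxels.
#' @param voxel_size Voxel edge in nm.
#' @param material Material id of the block.
#' @param mill_rate um^3 per nA.s.
#' @return A [virtual_specimen()].
#' @export
block_specimen <- function(ny, nx, nz, voxel_size = 50, material = 1L,
                           mill_rate = 5) {
  virtual_specimen(array(as.integer(material), c(ny, nx, nz)), voxel_size,
                   mill_rates = setNames(mill_rate, material))
}

specimen_voxel_count <- function(specimen) sum(specimen$labels > 0)

# surface height field: 0-based z of the first material voxel per (y, x)
specimen_surface <- function(specimen) {
  d <- dim(specimen$labels)
  top <- matrix(NA_real_, d[1], d[2])
  surf_lab <- matrix(0L, d[1], d[2])
  remaining <- matrix(TRUE, d[1], d[2])
  for (z in seq_len(d[3])) {
    sl <- specimen$labels[, , z]
    newly <- remaining & sl > 0
    if (any(newly)) {
      top[newly] <- z - 1
      surf_lab[newly] <- sl[newly]
      remaining <- remaining & !newly
    }
    if (!any(remaining)) break
  }
  list(top = top, label = surf_lab)
}

# deterministic seeded evaluation without disturbing the global RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Instrument state for the simulated driver
#'
#' @param pixel_size_nm Rendering pixel size (nm/px) of acquired images.
#' @param drift_nm_min Linear stage drift velocity `c(dy, dx)` in nm/min
#'   (instrument specifications quote up to 60 nm/min).
#' @param current_offsets Named list mapping current (pA, as character) to a
#'   per-current beam misalignment `c(dy, dx)` in um (synthetic by
#'   construction; the real effect is an imperfect cross-current alignment).
#' @param noise_counts Poisson rendering counts per unit intensity
#'   (0 disables noise).
#' @param seed Integer seed for all stochastic rendering.
#' @param beam [beam_geometry()].
#' @return An environment of class `instrument_state`.
#' @export
instrument_state <- function(pixel_size_nm = 400, drift_nm_min = c(0, 0),
                             current_offsets = list(), noise_counts = 0,
                             seed = 1L, beam = beam_geometry()) {
  env <- new.env(parent = emptyenv())
  env$pixel_size_nm <- pixel_size_nm
  env$drift_nm_min <- drift_nm_min
  env$current_offsets <- current_offsets
  env$noise_counts <- noise_counts
  env$seed <- as.integer(seed)
  env$beam <- beam
  env$time_min <- 0
  env$current <- 50
  env$base_offset_um <- c(0, 0)   # stage recall error (dy, dx)
  env$beam_shift_um <- c(0, 0)    # applied correction (dy, dx)
  env$stage_position <- 0L
  env$viewport_center_um <- c(0, 0)  # (y, x) stage coordinates of the FOV
  env$fov_um <- NULL                 # field of view edge; NULL = full field
  env$log <- list()
  class(env) <- "instrument_state"
  env
}

state_log <- function(state, op, ...) {
  state$log[[length(state$log) + 1]] <- c(list(op = op, time_min = state$time_min), list(...))
  invisible(NULL)
}

# effective specimen displacement seen in images / applied to patterns,
# (dy, dx) in um
effective_offset_um <- function(state) {
  co <- state$current_offsets[[as.character(state$current)]] %||% c(0, 0)
  state$base_offset_um + state$drift_nm_min * state$time_min / 1000 + co -
    state$beam_shift_um
}

#' Acquire a simulated SEM or FIB image
#'
#' Orthographic rendering of the specimen surface: intensity is the surface
#' material's reflectance shaded by depth, with optional Poisson noise. The
#' current stage-recall error, accumulated drift, per-current beam offset
#' and applied beam shift translate the image; the FIB view is compressed
#' in y by `sin(inter_beam_angle)` relative to the SEM view. Deterministic
#' for a given state seed and clock.
#'
#' @param state An [instrument_state()].
#' @param specimen A [virtual_specimen()].
#' @param beam `"SEM"` or `"FIB"`.
#' @return Numeric image matrix.
#' @export
acquire_image <- function(state, specimen, beam = c("SEM", "FIB")) {
  beam <- match.arg(beam)
  surf <- specimen_surface(specimen)
  d <- dim(specimen$labels)
  refl <- c(0, specimen$reflectance)[match(surf$label, c(0, as.integer(names(specimen$reflectance))))]
  refl[is.na(refl)] <- 0
  depth_shade <- ifelse(is.na(surf$top), 0, 1 - 0.5 * surf$top / max(d[3] - 1, 1))
  img <- matrix(refl * depth_shade, d[1], d[2]) * specimen$texture
  # crop to the stage viewport: each stored position images its own region
  if (!is.null(state$fov_um)) {
    half <- state$fov_um * 1000 / specimen$voxel_size / 2
    cy <- (d[1] - 1) / 2 + state$viewport_center_um[1] * 1000 / specimen$voxel_size
    cx <- (d[2] - 1) / 2 + state$viewport_center_um[2] * 1000 / specimen$voxel_size
    rows <- max(1L, round(cy - half) + 1L):min(d[1], round(cy + half) + 1L)
    cols <- max(1L, round(cx - half) + 1L):min(d[2], round(cx + half) + 1L)
    img <- img[rows, cols, drop = FALSE]
  }
  # resample to the rendering pixel size (anti-alias filter when minifying)
  scale <- specimen$voxel_size / state$pixel_size_nm
  if (scale < 1) {
    k <- gaussian_kernel1d(0.5 / scale)
    img <- convolve1d(convolve1d(img, k, 1), k, 2)
  }
  ny <- max(8L, round(nrow(img) * scale)); nx <- max(8L, round(ncol(img) * scale))
  g <- expand.grid(y = (0:(ny - 1)) / scale, x = (0:(nx - 1)) / scale)
  img <- matrix(interp2(img, g$y, g$x, fill = 0), ny, nx)
  off <- effective_offset_um(state) * 1000 / state$pixel_size_nm  # px
  if (beam == "FIB") {
    # compress first, then translate in the FIB frame: a single
    # interpolation pass per image keeps subpixel offsets unbiased
    s <- sin(deg2rad(state$beam$inter_beam_angle))
    nyf <- max(4L, round(ny * s))
    gf <- expand.grid(y = (0:(nyf - 1)) / s, x = 0:(nx - 1))
    img <- matrix(interp2(img, gf$y, gf$x, fill = 0), nyf, nx)
    off[1] <- off[1] * s
  }
  if (any(abs(off) > 1e-9)) img <- shift_image(img, off[1], off[2], wrap = TRUE)
  if (state$noise_counts > 0) {
    img <- with_seed(state$seed + round(state$time_min * 60),
                     matrix(rpois(length(img), pmax(img, 0) * state$noise_counts),
                            nrow(img)) / state$noise_counts)
  }
  state_log(state, "acquire", beam = beam)
  img
}

# voxel index range (1-based) covered by a um interval centered on the array
um_to_voxel_range <- function(center_um, size_um, n, voxel_nm) {
  ctr_vox <- (n - 1) / 2 + center_um * 1000 / voxel_nm
  half <- size_um * 1000 / voxel_nm / 2
  lo <- ceiling(ctr_vox - half + 0.5)
  hi <- floor(ctr_vox + half + 0.5)
  c(max(1L, lo + 0L), min(n, hi))
}

#' Execute a pattern sequence on the virtual specimen
#'
#' For each command, voxels inside the pattern footprint (projected along
#' the beam/z axis) are removed front-to-back until the removed volume
#' reaches `mill_rate * current * time`; the in-layer removal order follows
#' the scan direction. Pattern positions are displaced by the instrument's
#' current effective offset, so uncorrected drift misplaces the milled
#' features. The session clock advances by each command's milling time
#' before removal (the last material removed defines the final face).
#'
#' @param state An [instrument_state()].
#' @param specimen A [virtual_specimen()] (mutated in place).
#' @param seq A [pattern_sequence()] with `depth_or_time` in seconds.
#' @return The specimen, invisibly; removed voxel counts are logged.
#' @export
mill <- function(state, specimen, seq) {
  d <- dim(specimen$labels)
  vox_um3 <- (specimen$voxel_size * 1e-3)^3
  for (i in seq_len(nrow(seq))) {
    cmd <- seq[i, ]
    state$time_min <- state$time_min + cmd$depth_or_time / 60
    off <- effective_offset_um(state) + state$viewport_center_um
    xr <- um_to_voxel_range(cmd$center_x + off[2], cmd$width, d[2], specimen$voxel_size)
    yr <- um_to_voxel_range(cmd$center_y + off[1], cmd$height, d[1], specimen$voxel_size)
    if (xr[1] > xr[2] || yr[1] > yr[2]) {
      warn_fibclem("pattern_outside", sprintf("pattern %d lies outside the specimen; skipped", i))
      next
    }
    budget_um3 <- mean(specimen$mill_rates) * (cmd$current * 1e-3) * cmd$depth_or_time
    budget_vox <- floor(budget_um3 / vox_um3)
    removed <- 0L
    ys <- yr[1]:yr[2]
    if (cmd$scan_direction == "bottom_to_top") ys <- rev(ys)
    for (z in seq_len(d[3])) {
      if (removed >= budget_vox) break
      layer <- specimen$labels[ys, xr[1]:xr[2], z, drop = FALSE]
      filled <- which(layer > 0)
      if (length(filled) == 0) next
      take <- min(length(filled), budget_vox - removed)
      # remove rows in scan order within the layer
      rowi <- ((filled - 1) %% length(ys)) + 1
      ord <- order(rowi, filled)
      sel <- filled[ord[seq_len(take)]]
      layer[sel] <- 0L
      specimen$labels[ys, xr[1]:xr[2], z] <- layer
      removed <- removed + take
    }
    state_log(state, "mill", pattern = i, removed_vox = removed,
              current = cmd$current)
  }
  invisible(specimen)
}

# pixel calibration of the FIB rendering: the FIB view compresses the
# specimen y axis by sin(inter_beam_angle), so one FIB image pixel spans
# 1/sin(angle) specimen pixels along y.
fib_view_grid <- function(state) {
  s <- sin(deg2rad(state$beam$inter_beam_angle))
  pixel_grid(state$pixel_size_nm, state$pixel_size_nm / s)
}

#' Image-based realignment decision
#'
#' Measures the displacement of `live` relative to `reference` by subpixel
#' phase correlation and classifies the correction: stage movements for
#' large offsets (beyond `stage_threshold_um`, 10 um on the modeled
#' systems), beam shifts for subtle ones.
#'
#' @param reference,live Same-shape image matrices.
#' @param grid A [pixel_grid()] giving the image pixel size.
#' @param stage_threshold_um Stage-vs-beam-shift decision threshold in um.
#' @param upsample Phase-correlation upsampling.
#' @return A list with `mode` (`"stage"` or `"beam_shift"`), `offset_um`
#'   (`c(dy, dx)`) and `confidence`.
#' @export
realign <- function(reference, live, grid, stage_threshold_um = 10,
                    upsample = 10L) {
  stopifnot(inherits(grid, "pixel_grid"))
  s <- phase_correlate(reference, live, upsample)
  off_um <- c(s[1] * grid$pixel_size_y, s[2] * grid$pixel_size_x) / 1000
  mode <- if (sqrt(sum(off_um^2)) > stage_threshold_um) "stage" else "beam_shift"
  list(mode = mode, offset_um = off_um, confidence = attr(s, "confidence"))
}

#' Beam-shift realignment across a current change
#'
#' Acquires a reference image at the previous current and a live image at
#' the new current, measures their offset and returns (and applies) a
#' beam-shift-only correction -- the stage never moves for current-change
#' compensation.
#'
#' @param state An [instrument_state()].
#' @param specimen A [virtual_specimen()].
#' @param old_current,new_current Currents in pA.
#' @param apply Apply the correction to the state's beam shift.
#' @return A list with `mode = "beam_shift"` and `offset_um`.
#' @export
realign_on_current_change <- function(state, specimen, old_current, new_current,
                                      apply = TRUE, upsample = 20L) {
  state$current <- old_current
  ref <- acquire_image(state, specimen, "FIB")
  state$current <- new_current
  live <- acquire_image(state, specimen, "FIB")
  s <- phase_correlate(ref, live, upsample)
  g <- fib_view_grid(state)
  off_um <- c(s[1] * g$pixel_size_y, s[2] * g$pixel_size_x) / 1000
  if (apply) state$beam_shift_um <- state$beam_shift_um + off_um
  state_log(state, "realign_current", old = old_current, new = new_current)
  list(mode = "beam_shift", offset_um = off_um)
}

#' Simulated driver
#'
#' Bundles a specimen and instrument state behind the driver contract used
#' by the session runners: `acquire_image`, `mill`, `move_stage`,
#' `beam_shift`, `set_current`. Any object exposing these closures (e.g. a
#' wrapper around a real microscope API) is interchangeable with the
#' simulator in [run_lamella_session()] and [run_volume_session()].
#'
#' @param specimen A [virtual_specimen()].
#' @param state An [instrument_state()].
#' @param recall_error_um Stage position recall error magnitude (um);
#'   each `move_stage` draws a fresh error of this scale (seeded).
#' @param stage_positions Optional list of `c(y, x)` stage coordinates (um,
#'   relative to the specimen center), one per position index; each stored
#'   position then images and mills its own region of the specimen.
#' @param fov_um Field-of-view edge of acquired images in um (`NULL` = the
#'   full specimen extent).
#' @return A list of class `sim_driver`.
#' @export
sim_driver <- function(specimen, state = instrument_state(),
                       recall_error_um = 1, stage_positions = NULL,
                       fov_um = NULL) {
  n_moves <- 0L
  state$fov_um <- fov_um
  drv <- list(
    specimen = specimen,
    state = state,
    stage_positions = stage_positions,
    acquire_image = function(beam = "FIB") acquire_image(state, specimen, beam),
    mill = function(seq) mill(state, specimen, seq),
    move_stage = function(position) {
      n_moves <<- n_moves + 1L
      err <- with_seed(state$seed + 7919L * n_moves,
                       rnorm(2, 0, recall_error_um))
      state$stage_position <- position
      if (!is.null(stage_positions))
        state$viewport_center_um <- stage_positions[[position]]
      state$base_offset_um <- err
      state$beam_shift_um <- c(0, 0)
      state$time_min <- state$time_min + 0.5  # stage settle
      state_log(state, "move_stage", position = position)
      invisible(err)
    },
    stage_correct = function(offset_um) {
      state$base_offset_um <- state$base_offset_um - offset_um
      state_log(state, "stage_correct", offset = offset_um)
    },
    beam_shift = function(offset_um) {
      state$beam_shift_um <- state$beam_shift_um + offset_um
      state_log(state, "beam_shift", offset = offset_um)
    },
    set_current = function(pA) {
      state$current <- pA
      state_log(state, "set_current", current = pA)
    },
    pixel_grid = function() fib_view_grid(state)
  )
  class(drv) <- "sim_driver"
  drv
}

# realign the driver against a stored reference image (position recall)
driver_realign <- function(driver, reference, stage_threshold_um = 10) {
  live <- driver$acquire_image("FIB")
  r <- realign(reference, live, driver$pixel_grid(), stage_threshold_um)
  if (r$confidence <= 0) return(NULL)
  if (r$mode == "stage") {
    driver$stage_correct(r$offset_um)
    # beam-shift polish after the coarse stage move
    live2 <- driver$acquire_image("FIB")
    r2 <- realign(reference, live2, driver$pixel_grid(), stage_threshold_um)
    driver$beam_shift(r2$offset_um)
  } else {
    driver$beam_shift(r$offset_um)
  }
  r
}

#' Run an automated on-grid lamella milling session
#'
#' Mirrors the staged automation flow: reference images are stored per
#' position, rough milling runs for every position, then fine milling for
#' every position. A series of realignments precisely recalls the target
#' position for each milling step: the driver realigns against the stored
#' reference on every position recall and before every step (stage moves
#' for offsets above the threshold, beam shifts otherwise), and a
#' beam-shift-only realignment compensates cross-current misalignment on
#' every current change. A failed realignment marks the position failed and
#' the session continues.
#'
#' @param positions List of [lamella_target()]s.
#' @param rough,fine [milling_protocol()]s (`fine = NULL` runs rough only).
#' @param driver A [sim_driver()] (or contract-compatible driver).
#' @param realign_positions Realign against the stored reference on recall
#'   and before each step.
#' @param realign_currents Realign on current changes.
#' @param probe_z_um Depth (um) at which lamella thickness/placement are
#'   probed in the final specimen.
#' @return A list with `outcomes` (tibble: position, ok, thickness_nm,
#'   placement_error_um, placement_error_px) and `specimen`.
#' @export
run_lamella_session <- function(positions, rough, fine, driver,
                                realign_positions = TRUE,
                                realign_currents = TRUE,
                                probe_z_um = NULL) {
  stopifnot(length(positions) >= 1)
  state <- driver$state
  refs <- vector("list", length(positions))
  for (i in seq_along(positions)) {
    driver$move_stage(i)
    # registration-time reference: acquired with the recall error corrected
    state$base_offset_um <- c(0, 0)
    refs[[i]] <- driver$acquire_image("FIB")
  }
  failed <- logical(length(positions))
  mill_stage <- function(protocol) {
    for (i in seq_along(positions)) {
      if (failed[i]) next
      driver$move_stage(i)
      if (realign_positions) {
        r <- driver_realign(driver, refs[[i]])
        if (is.null(r)) { failed[i] <<- TRUE; next }
      }
      prev_current <- state$current
      first <- TRUE
      for (s in protocol$steps) {
        if (realign_positions && !first) driver_realign(driver, refs[[i]])
        if (realign_currents && !isTRUE(all.equal(s$current, prev_current))) {
          realign_on_current_change(state, driver$specimen, prev_current, s$current)
        }
        driver$set_current(s$current)
        step_proto <- milling_protocol(protocol$name, list(s), protocol$stage)
        driver$mill(compile_lamella_patterns(step_proto, positions[[i]]))
        prev_current <- s$current
        first <- FALSE
      }
    }
  }
  mill_stage(rough)
  if (!is.null(fine)) mill_stage(fine)
  # measure outcomes from the specimen
  spec <- driver$specimen
  vox <- spec$voxel_size
  d <- dim(spec$labels)
  zp <- if (is.null(probe_z_um)) max(1L, round(d[3] / 4)) else
    max(1L, round(probe_z_um * 1000 / vox))
  outcomes <- lapply(seq_along(positions), function(i) {
    tgt <- positions[[i]]
    vc <- if (!is.null(driver$stage_positions)) driver$stage_positions[[i]] else c(0, 0)
    xr <- um_to_voxel_range(tgt$position[1] + vc[2], min(tgt$width / 2, 1), d[2], vox)
    col <- spec$labels[, round(mean(xr)), min(zp, d[3])]
    cy_vox <- (d[1] - 1) / 2 + (tgt$position[2] + vc[1]) * 1000 / vox + 1
    ext_vox <- (d[1] - 1) / 2 + (tgt$extremes + vc[1]) * 1000 / vox + 1
    runs <- rle(col > 0)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    # material runs strictly inside the extremes (excludes untouched bulk)
    hit <- which(runs$values & starts > ext_vox[1] & ends < ext_vox[2])
    if (length(hit) == 0)
      return(tibble::tibble(position = i, ok = FALSE, thickness_nm = 0,
                            placement_error_um = NA_real_,
                            placement_error_px = NA_real_))
    k <- hit[which.min(abs((starts[hit] + ends[hit]) / 2 - cy_vox))]
    thick <- runs$lengths[k] * vox
    ctr <- (starts[k] + ends[k]) / 2
    err_um <- abs(ctr - cy_vox) * vox / 1000
    tibble::tibble(position = i, ok = !failed[i], thickness_nm = thick,
                   placement_error_um = err_um,
                   placement_error_px = err_um * 1000 / state$pixel_size_nm)
  })
  list(outcomes = dplyr::bind_rows(outcomes), specimen = spec, log = state$log)
}

#' Run a slice-and-view volume imaging session
#'
#' Alternates milling (advancing the exposed front by `slice_thickness`
#' within the window) and SEM acquisition of the newly exposed plane.
#'
#' @param driver A [sim_driver()].
#' @param window `c(width, height)` imaging window in um (centered).
#' @param slice_thickness Slice thickness in nm.
#' @param n_slices Number of slices.
#' @return A [slice_stack()] of the acquired cross-sections (truncated with
#'   an `fibclem_front_exit` warning if the front leaves the specimen).
#' @export
run_volume_session <- function(driver, window, slice_thickness, n_slices) {
  spec <- driver$specimen
  state <- driver$state
  d <- dim(spec$labels)
  vox <- spec$voxel_size
  xr <- um_to_voxel_range(0, window[1], d[2], vox)
  yr <- um_to_voxel_range(0, window[2], d[1], vox)
  slices <- list()
  front_nm <- 0
  for (i in seq_len(n_slices)) {
    front_nm <- front_nm + slice_thickness
    z_hi <- round(front_nm / vox)
    if (z_hi > d[3]) {
      warn_fibclem("front_exit", "milling front left the specimen; stack truncated")
      break
    }
    if (z_hi >= 1)
      spec$labels[yr[1]:yr[2], xr[1]:xr[2], 1:z_hi] <- 0L
    state$time_min <- state$time_min + 0.2
    plane <- if (z_hi < d[3]) spec$labels[yr[1]:yr[2], xr[1]:xr[2], z_hi + 1]
    else matrix(0L, yr[2] - yr[1] + 1, xr[2] - xr[1] + 1)
    refl <- c(0, spec$reflectance)[match(plane, c(0L, as.integer(names(spec$reflectance))))]
    img <- matrix(refl, nrow(plane), ncol(plane))
    if (state$noise_counts > 0)
      img <- with_seed(state$seed + i,
                       matrix(rpois(length(img), pmax(img, 0) * state$noise_counts),
                              nrow(img)) / state$noise_counts)
    slices[[length(slices) + 1]] <- img
    state_log(state, "volume_slice", index = i, front_nm = front_nm)
  }
  if (length(slices) == 0)
    return(slice_stack(array(0, c(yr[2] - yr[1] + 1, xr[2] - xr[1] + 1, 0)),
                       pixel_grid(vox, vox, slice_thickness), state$beam))
  slice_stack(array(unlist(slices), c(dim(slices[[1]]), length(slices))),
              pixel_grid(vox, vox, slice_thickness), state$beam)
}

# synthetic fixture generators ----------------------------------------------

#' Synthetic test-data generators
#'
#' Every generator takes a mandatory seed and returns the fixture together
#' with a machine-readable ground-truth record.
#'
#' `synth_bead_image()`: `n` bright disks of the given radius at subpixel
#' centers with minimum pairwise separation `4 * radius`, plus Gaussian
#' noise at `1 / snr` of the disk amplitude.
#'
#' @param n Number of beads.
#' @param radius Bead radius in pixels.
#' @param snr Peak signal-to-noise ratio.
#' @param seed Integer seed (mandatory).
#' @param dim Image dimensions `c(ny, nx)`.
#' @return A list with `image` and `truth` (tibble `x`, `y`).
#' @export
synth_bead_image <- function(n, radius, snr, seed, dim = c(160, 160)) {
  if (missing(seed)) stop_fibclem("param_error", "seed is mandatory")
  if (n < 0 || radius < 1 || snr <= 0) stop_fibclem("param_error", "invalid generator parameters")
  ny <- dim[1]; nx <- dim[2]
  with_seed(seed, {
    pts <- matrix(numeric(0), 0, 2)
    guard <- 0
    while (nrow(pts) < n && guard < 10000) {
      guard <- guard + 1
      cand <- c(runif(1, 3 * radius, nx - 1 - 3 * radius),
                runif(1, 3 * radius, ny - 1 - 3 * radius))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= 4 * radius)
        pts <- rbind(pts, cand)
    }
    if (nrow(pts) < n)
      stop_fibclem("param_error", "could not place beads at the required separation")
    g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
    img <- matrix(0, ny, nx)
    for (i in seq_len(nrow(pts))) {
      d <- sqrt((g$x - pts[i, 1])^2 + (g$y - pts[i, 2])^2)
      img <- img + matrix(pmin(pmax(radius + 0.5 - d, 0), 1), ny, nx)
    }
    img <- pmin(img, 1) + matrix(rnorm(ny * nx, 0, 1 / snr), ny, nx)
    list(image = img, truth = tibble::tibble(x = pts[, 1], y = pts[, 2]))
  })
}

#' @rdname synth_bead_image
#'
#' @description `synth_flm_volume()`: anisotropic Gaussian blobs emulating
#' point-like fluorescence under the elongated axial PSF of a confocal
#' cryo-stage (`sigma_z > sigma_xy`).
#'
#' @param blobs Tibble with `x`, `y`, `z` (and optional `amplitude`)
#'   blob centers, or an integer count to place randomly.
#' @param psf_xyz PSF sigmas `c(sx, sy, sz)` in voxels.
#' @param vol_dim Volume dimensions `c(ny, nx, nz)`.
#' @return A list with `volume` and `truth`.
#' @export
synth_flm_volume <- function(blobs, psf_xyz, seed, vol_dim = c(48, 48, 24)) {
  if (missing(seed)) stop_fibclem("param_error", "seed is mandatory")
  ny <- vol_dim[1]; nx <- vol_dim[2]; nz <- vol_dim[3]
  with_seed(seed, {
    if (is.numeric(blobs) && length(blobs) == 1) {
      blobs <- tibble::tibble(
        x = runif(blobs, 4 * psf_xyz[1], nx - 1 - 4 * psf_xyz[1]),
        y = runif(blobs, 4 * psf_xyz[2], ny - 1 - 4 * psf_xyz[2]),
        z = runif(blobs, 3 * psf_xyz[3], nz - 1 - 3 * psf_xyz[3]))
    }
    if (!"amplitude" %in% names(blobs)) blobs$amplitude <- 1
    vol <- array(0, c(ny, nx, nz))
    g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1), z = 0:(nz - 1))
    for (i in seq_len(nrow(blobs))) {
      vol <- vol + array(blobs$amplitude[i] *
                           exp(-((g$x - blobs$x[i])^2 / (2 * psf_xyz[1]^2) +
                                   (g$y - blobs$y[i])^2 / (2 * psf_xyz[2]^2) +
                                   (g$z - blobs$z[i])^2 / (2 * psf_xyz[3]^2))),
                         c(ny, nx, nz))
    }
    list(volume = vol, truth = blobs)
  })
}

#' @rdname synth_bead_image
#'
#' @description `synth_curtain()`: adds vertical stripes (constant along y)
#' of the given period and amplitude, with a seeded random phase.
#'
#' @param image Base image.
#' @param period Stripe period in pixels.
#' @param amplitude Stripe amplitude (intensity units).
#' @return A list with `image` (corrupted) and `clean`.
#' @export
synth_curtain <- function(image, period, amplitude, seed) {
  if (missing(seed)) stop_fibclem("param_error", "seed is mandatory")
  if (period <= 0) stop_fibclem("param_error", "period must be positive")
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    stripes <- amplitude * sin(2 * pi * (0:(ncol(image) - 1)) / period + phase)
    list(image = image + matrix(stripes, nrow(image), ncol(image), byrow = TRUE),
         clean = image, stripes = stripes)
  })
}

#' @rdname synth_bead_image
#'
#' @description `synth_charge()`: adds a broad Gaussian intensity hill
#' emulating surface charging.
#'
#' @param sigma Hill sigma in pixels.
#' @param center Hill center `c(x, y)` (default image center).
#' @return A list with `image`, `clean` and `hill`.
#' @export
synth_charge <- function(image, sigma, amplitude, center = NULL) {
  ny <- nrow(image); nx <- ncol(image)
  if (is.null(center)) center <- c((nx - 1) / 2, (ny - 1) / 2)
  g <- expand.grid(y = 0:(ny - 1), x = 0:(nx - 1))
  hill <- matrix(amplitude * exp(-((g$x - center[1])^2 + (g$y - center[2])^2) /
                                   (2 * sigma^2)), ny, nx)
  list(image = image + hill, clean = image, hill = hill)
}

#' @rdname synth_bead_image
#'
#' @description `synth_drift_stack()`: replicates a base slice `n_slices`
#' times with cumulative per-slice translation (optionally noisy).
#'
#' @param base Base slice matrix.
#' @param drift_per_slice `c(dy, dx)` pixels per slice.
#' @param n_slices Number of slices.
#' @param noise_sd Additive Gaussian noise sd.
#' @param wrap Shift cyclically (a moving window over a larger field) rather
#'   than exposing fill borders.
#' @return A list with `stack` (3-D array) and `truth` (per-slice offsets).
#' @export
synth_drift_stack <- function(base, drift_per_slice, n_slices, seed,
                              noise_sd = 0, wrap = TRUE) {
  if (missing(seed)) stop_fibclem("param_error", "seed is mandatory")
  if (n_slices < 1) stop_fibclem("param_error", "n_slices must be >= 1")
  with_seed(seed, {
    arr <- array(0, c(dim(base), n_slices))
    offs <- tibble::tibble(slice = seq_len(n_slices),
                           dy = (seq_len(n_slices) - 1) * drift_per_slice[1],
                           dx = (seq_len(n_slices) - 1) * drift_per_slice[2])
    for (i in seq_len(n_slices)) {
      sl <- shift_image(base, offs$dy[i], offs$dx[i], fill = 0, wrap = wrap)
      if (noise_sd > 0) sl <- sl + matrix(rnorm(length(sl), 0, noise_sd), nrow(sl))
      arr[, , i] <- sl
    }
    list(stack = arr, truth = offs)
  })
}
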