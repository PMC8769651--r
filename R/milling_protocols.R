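# Milling protocols and pattern sequences. A protocol is a line-oriented
# text description of staged milling (currents, times, pattern gaps); the
# compiler turns it into a pattern sequence -- the ordered list of milling
# commands (shape, position, size, current, time) relative to a reference
# point -- which is what a driver executes.

PATTERN_SHAPES <- c("rectangle", "cleaning_cross_section", "regular_cross_section")
SCAN_DIRECTIONS <- c("top_to_bottom", "bottom_to_top")

#' Milling step and protocol constructors
#'
#' A step carries the beam current (pA), milling time (s), the gap between
#' the upper and lower milling patterns (um) -- which sets the remaining
#' lamella thickness -- the pattern height (um), and an overtilt angle kept
#' as metadata only.
#'
#' @param current Beam current in pA.
#' @param time Milling time in s.
#' @param pattern_distance Upper-to-lower pattern gap in um.
#' @param pattern_height Pattern height in um.
#' @param overtilt Overtilt in degrees (metadata; never applied).
#' @return `milling_step()` a list of class `milling_step`.
#' @export
milling_step <- function(current, time, pattern_distance, pattern_height,
                         overtilt = 0) {
  if (current <= 0 || time <= 0) stop_fibclem("param_error", "current and time must be positive")
  if (pattern_distance < 0) stop_fibclem("param_error", "pattern_distance must be >= 0")
  structure(list(current = current, time = time,
                 pattern_distance = pattern_distance,
                 pattern_height = pattern_height, overtilt = overtilt),
            class = "milling_step")
}

#' @rdname milling_step
#' @param name Protocol name.
#' @param steps List of [milling_step()]s (non-empty, executed in order).
#' @param stage `"rough"` or `"fine"`.
#' @return `milling_protocol()` a list of class `milling_protocol`.
#' @export
milling_protocol <- function(name, steps, stage = c("rough", "fine")) {
  stage <- match.arg(stage)
  if (length(steps) == 0) stop_fibclem("param_error", "protocol needs >= 1 step")
  stopifnot(all(vapply(steps, inherits, logical(1), "milling_step")))
  structure(list(name = name, steps = steps, stage = stage),
            class = "milling_protocol")
}

#' @export
print.milling_protocol <- function(x, ...) {
  cat("<milling_protocol>", x$name, sprintf("(%s, %d steps)\n", x$stage, length(x$steps)))
  for (s in x$steps)
    cat(sprintf("  %g pA, %g s, gap %g um, height %g um\n",
                s$current, s$time, s$pattern_distance, s$pattern_height))
  invisible(x)
}

#' @export
tidy.milling_protocol <- function(x, ...) {
  dplyr::bind_rows(lapply(x$steps, function(s)
    tibble::tibble(current_pA = s$current, time_s = s$time,
                   pattern_distance_um = s$pattern_distance,
                   pattern_height_um = s$pattern_height,
                   overtilt_deg = s$overtilt)))
}

# protocol text grammar ----------------------------------------------------
# name: <string>            header block
# stage: rough|fine
# [step]                    one block per step
# current: <pA>
# time: <s>
# pattern_distance: <um>
# pattern_height: <um>
# overtilt: <deg>           optional (default 0)

#' Parse / write milling protocols
#'
#' Line-oriented `key: value` grammar with one `[step]` header per milling
#' step; `#` starts a comment. `write_protocol()` emits the canonical form
#' and `parse_protocol(write_protocol(p))` round-trips losslessly.
#'
#' @param text Protocol text (single string or character vector of lines).
#' @param protocol A [milling_protocol()].
#' @param path Optional file to write to.
#' @return `parse_protocol()` a `milling_protocol`; `write_protocol()` the
#'   canonical text (invisibly when `path` is given).
#' @export
parse_protocol <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  header <- list()
  steps <- list()
  cur <- NULL
  required <- c("current", "time", "pattern_distance", "pattern_height")
  finish_step <- function(cur, lineno) {
    missing <- setdiff(required, names(cur))
    if (length(missing) > 0)
      stop_fibclem("parse_error",
                   sprintf("line %d: step missing field(s): %s", lineno,
                           paste(missing, collapse = ", ")))
    milling_step(cur$current, cur$time, cur$pattern_distance,
                 cur$pattern_height, cur$overtilt %||% 0)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (ln == "[step]") {
      if (!is.null(cur)) steps[[length(steps) + 1]] <- finish_step(cur, i)
      cur <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop_fibclem("parse_error", sprintf("line %d: malformed line '%s'", i, lines_raw[i]))
    key <- m[2]; val <- trimws(m[3])
    if (is.null(cur)) {
      if (!key %in% c("name", "stage"))
        stop_fibclem("parse_error", sprintf("line %d: unexpected key '%s' before [step]", i, key))
      header[[key]] <- val
    } else {
      if (!key %in% c(required, "overtilt"))
        stop_fibclem("parse_error", sprintf("line %d: unknown step field '%s'", i, key))
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop_fibclem("parse_error", sprintf("line %d: field '%s' is not numeric", i, key))
      cur[[key]] <- num
    }
  }
  if (!is.null(cur)) steps[[length(steps) + 1]] <- finish_step(cur, length(lines))
  if (is.null(header$name))
    stop_fibclem("parse_error", "protocol is missing a 'name' header")
  if (length(steps) == 0)
    stop_fibclem("parse_error", "protocol contains no [step] blocks")
  milling_protocol(header$name, steps, header$stage %||% "rough")
}

#' @rdname parse_protocol
#' @export
write_protocol <- function(protocol, path = NULL) {
  stopifnot(inherits(protocol, "milling_protocol"))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  out <- c(paste0("name: ", protocol$name), paste0("stage: ", protocol$stage))
  for (s in protocol$steps) {
    out <- c(out, "[step]",
             paste0("current: ", fmt(s$current)),
             paste0("time: ", fmt(s$time)),
             paste0("pattern_distance: ", fmt(s$pattern_distance)),
             paste0("pattern_height: ", fmt(s$pattern_height)),
             paste0("overtilt: ", fmt(s$overtilt)))
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(text, path, sep = ""); return(invisible(text)) }
  text
}

# pattern sequences ---------------------------------------------------------

#' Assemble a pattern sequence
#'
#' A pattern sequence is a tibble of milling commands executed in order;
#' positions are um offsets relative to a reference point on the reference
#' image (x right, y down).
#'
#' @param shape,center_x,center_y,width,height,depth_or_time,current,scan_direction
#'   Per-command columns: shape (one of rectangle, cleaning_cross_section,
#'   regular_cross_section), center offsets (um), width/height (um), milling
#'   depth (um) or time (s), current (pA), scan direction.
#' @param reference_image Identifier of the reference image.
#' @return A tibble of class `pattern_sequence`.
#' @export
pattern_sequence <- function(shape = character(), center_x = numeric(),
                             center_y = numeric(), width = numeric(),
                             height = numeric(), depth_or_time = numeric(),
                             current = numeric(),
                             scan_direction = character(),
                             reference_image = NA_character_) {
  if (length(shape) > 0) {
    stopifnot(all(shape %in% PATTERN_SHAPES), all(scan_direction %in% SCAN_DIRECTIONS))
    if (any(width <= 0) || any(height <= 0))
      stop_fibclem("param_error", "pattern width and height must be positive")
  }
  out <- tibble::tibble(shape = shape, center_x = center_x, center_y = center_y,
                        width = width, height = height,
                        depth_or_time = depth_or_time, current = current,
                        scan_direction = scan_direction)
  attr(out, "reference_image") <- reference_image
  class(out) <- c("pattern_sequence", class(out))
  out
}

bind_patterns <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (length(parts) == 0) return(pattern_sequence())
  out <- dplyr::bind_rows(lapply(parts, function(p) { class(p) <- class(tibble::tibble()); p }))
  class(out) <- c("pattern_sequence", class(out))
  out
}

#' Read / write pattern sequence files
#'
#' One command per line, tab-separated canonical field order
#' (shape, center_x, center_y, width, height, depth_or_time, current,
#' scan_direction); `#` starts a comment.
#'
#' @param seq A [pattern_sequence()].
#' @param text Pattern sequence text.
#' @param path Optional file path.
#' @return Text (write) or a `pattern_sequence` (parse).
#' @export
write_pattern_sequence <- function(seq, path = NULL) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  lines <- c("# shape\tcenter_x\tcenter_y\twidth\theight\tdepth_or_time\tcurrent\tscan_direction")
  if (nrow(seq) > 0)
    lines <- c(lines, apply(seq, 1, function(r)
      paste(r["shape"], fmt(as.numeric(r["center_x"])), fmt(as.numeric(r["center_y"])),
            fmt(as.numeric(r["width"])), fmt(as.numeric(r["height"])),
            fmt(as.numeric(r["depth_or_time"])), fmt(as.numeric(r["current"])),
            r["scan_direction"], sep = "\t")))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) { writeLines(text, path, sep = ""); return(invisible(text)) }
  text
}

#' @rdname write_pattern_sequence
#' @export
parse_pattern_sequence <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  if (length(lines) == 0) return(pattern_sequence())
  rows <- strsplit(lines, "\t")
  bad <- which(vapply(rows, length, integer(1)) != 8)
  if (length(bad) > 0)
    stop_fibclem("parse_error", sprintf("pattern line %d does not have 8 fields", bad[1]))
  m <- do.call(rbind, rows)
  pattern_sequence(shape = m[, 1], center_x = as.numeric(m[, 2]),
                   center_y = as.numeric(m[, 3]), width = as.numeric(m[, 4]),
                   height = as.numeric(m[, 5]), depth_or_time = as.numeric(m[, 6]),
                   current = as.numeric(m[, 7]), scan_direction = m[, 8])
}

# lamella targets -----------------------------------------------------------

#' Lamella milling target
#'
#' @param position Lamella center `c(x, y)` on the reference FIB image (um).
#' @param width Lamella width in um.
#' @param extremes `c(upper, lower)` y-limits (um, y down so upper < lower)
#'   beyond which no pattern may mill (protects grid bars).
#' @param expansion_joints Whether to cut micro-expansion joints.
#' @param joint_width,joint_offset,joint_height Joint geometry (um):
#'   rectangle width, gap between lamella edge and joint center, and joint
#'   height. The published workflow references external joint designs;
#'   these defaults are package choices and fully configurable.
#' @return A list of class `lamella_target`.
#' @export
lamella_target <- function(position, width, extremes, expansion_joints = FALSE,
                           joint_width = 0.5, joint_offset = 2,
                           joint_height = NULL) {
  position <- as.numeric(position)
  extremes <- as.numeric(extremes)
  if (!(extremes[1] < position[2] && position[2] < extremes[2]))
    stop_fibclem("invalid_target", "extremes must bracket the lamella position (y down)")
  if (width <= 0) stop_fibclem("invalid_target", "width must be positive")
  structure(list(position = position, width = width, extremes = extremes,
                 expansion_joints = isTRUE(expansion_joints),
                 joint_width = joint_width, joint_offset = joint_offset,
                 joint_height = joint_height %||% diff(extremes)),
            class = "lamella_target")
}

#' Compile a lamella protocol into a pattern sequence
#'
#' Each protocol step yields two rectangles above and below the lamella
#' center whose inner edges sit `pattern_distance / 2` from the center;
#' outer edges are clipped at the extreme milling points. The upper pattern
#' scans top-to-bottom and the lower bottom-to-top, so material is always
#' removed toward the lamella face. Commands are ordered by step, upper
#' before lower.
#'
#' @param protocol A [milling_protocol()].
#' @param target A [lamella_target()].
#' @return A [pattern_sequence()].
#' @export
compile_lamella_patterns <- function(protocol, target) {
  stopifnot(inherits(protocol, "milling_protocol"), inherits(target, "lamella_target"))
  cx <- target$position[1]; cy <- target$position[2]
  parts <- list()
  for (s in protocol$steps) {
    half_gap <- s$pattern_distance / 2
    # upper pattern: inner edge at cy - half_gap, extends upward
    up_inner <- cy - half_gap
    up_outer <- max(target$extremes[1], up_inner - s$pattern_height)
    # lower pattern: inner edge at cy + half_gap, extends downward
    lo_inner <- cy + half_gap
    lo_outer <- min(target$extremes[2], lo_inner + s$pattern_height)
    rows <- list()
    if (up_inner > up_outer)
      rows[[length(rows) + 1]] <- pattern_sequence(
        "rectangle", cx, (up_inner + up_outer) / 2, target$width,
        up_inner - up_outer, s$time, s$current, "top_to_bottom")
    if (lo_outer > lo_inner)
      rows[[length(rows) + 1]] <- pattern_sequence(
        "rectangle", cx, (lo_inner + lo_outer) / 2, target$width,
        lo_outer - lo_inner, s$time, s$current, "bottom_to_top")
    parts[[length(parts) + 1]] <- do.call(bind_patterns, rows)
  }
  do.call(bind_patterns, parts)
}

#' Micro-expansion joint patterns
#'
#' Two narrow relief cuts flanking the lamella left and right, milled
#' before rough milling to release tension in the frozen film. Returns an
#' empty sequence when the target has `expansion_joints = FALSE`.
#'
#' @param target A [lamella_target()].
#' @param current Joint milling current in pA.
#' @param time Joint milling time in s.
#' @return A [pattern_sequence()] with 0 or 2 commands, mirror-symmetric
#'   about the lamella center x.
#' @export
expansion_joint_patterns <- function(target, current = 500, time = 30) {
  stopifnot(inherits(target, "lamella_target"))
  if (!target$expansion_joints) return(pattern_sequence())
  off <- target$width / 2 + target$joint_offset
  cx <- target$position[1]; cy <- target$position[2]
  pattern_sequence(
    shape = rep("rectangle", 2),
    center_x = c(cx - off, cx + off), center_y = c(cy, cy),
    width = rep(target$joint_width, 2), height = rep(target$joint_height, 2),
    depth_or_time = rep(time, 2), current = rep(current, 2),
    scan_direction = rep("top_to_bottom", 2))
}

#' Lift-out trench patterns (horseshoe layout)
#'
#' Compiles the three regular-cross-section trenches that free an
#' extractable chunk from a bulk high-pressure-frozen specimen: two
#' parallel trenches symmetrically flanking the central block, plus one
#' perpendicular trench on the left closing the "C". The side-trench offset
#' is measured from the block center to the side-trench center (the
#' published description leaves the reference edge ambiguous; this
#' convention reproduces the printed 20 um block).
#'
#' @param chunk_width Block extent in x (um).
#' @param chunk_depth_y Block extent in y = gap between the parallel
#'   trenches (um).
#' @param trench_w,trench_h Parallel trench width/height (um).
#' @param side_offset Distance from block center to side-trench center (um).
#' @param side_trench_w,side_trench_h Side trench width/height (um).
#' @param current Milling current in pA.
#' @param time Milling time per trench in s.
#' @param mirror Mill the side trench on the right instead of the left.
#' @return A [pattern_sequence()] of 3 commands centered on the block.
#' @export
compile_trench_patterns <- function(chunk_width = 20, chunk_depth_y = 20,
                                    trench_w = 40, trench_h = 15,
                                    side_offset = 15, side_trench_w = 10,
                                    side_trench_h = 40, current = 1000,
                                    time = 1800, mirror = FALSE) {
  dims <- c(chunk_width, chunk_depth_y, trench_w, trench_h, side_offset,
            side_trench_w, side_trench_h)
  if (any(dims <= 0)) stop_fibclem("invalid_geometry", "all dimensions must be positive")
  sgn <- if (mirror) 1 else -1
  half_gap <- chunk_depth_y / 2
  seqs <- pattern_sequence(
    shape = rep("regular_cross_section", 3),
    center_x = c(0, 0, sgn * side_offset),
    center_y = c(-(half_gap + trench_h / 2), half_gap + trench_h / 2, 0),
    width = c(trench_w, trench_w, side_trench_w),
    height = c(trench_h, trench_h, side_trench_h),
    depth_or_time = rep(time, 3), current = rep(current, 3),
    scan_direction = rep("top_to_bottom", 3))
  # the trenches must not eat into the central block
  block <- c(-chunk_width / 2, chunk_width / 2, -chunk_depth_y / 2, chunk_depth_y / 2)
  for (i in seq_len(3)) {
    x0 <- seqs$center_x[i] - seqs$width[i] / 2; x1 <- seqs$center_x[i] + seqs$width[i] / 2
    y0 <- seqs$center_y[i] - seqs$height[i] / 2; y1 <- seqs$center_y[i] + seqs$height[i] / 2
    if (x0 < block[2] - 1e-9 && x1 > block[1] + 1e-9 &&
        y0 < block[4] - 1e-9 && y1 > block[3] + 1e-9)
      stop_fibclem("invalid_geometry", "trench footprint overlaps the central block")
  }
  seqs
}

#' Interleaved slice-and-view volume imaging plan
#'
#' @param window Imaging/milling window `c(width, height)` in um.
#' @param slice_thickness Ablated thickness per step in nm.
#' @param n_slices Number of slices (>= 0).
#' @param current Milling current in pA.
#' @return A tibble with `step`, `action` (`mill`/`acquire`) and
#'   `front_nm`, the cumulative front advance after the step: 2 rows per
#'   slice, alternating mill and acquire.
#' @export
volume_imaging_plan <- function(window, slice_thickness, n_slices,
                                current = 500) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 0) stop_fibclem("param_error", "n_slices must be >= 0")
  if (n_slices == 0)
    return(tibble::tibble(step = integer(), action = character(),
                          front_nm = numeric()))
  tibble::tibble(
    step = rep(seq_len(n_slices), each = 2),
    action = rep(c("mill", "acquire"), n_slices),
    front_nm = rep(seq_len(n_slices) * slice_thickness, each = 2))
}

# dose and session accounting -----------------------------------------------

ELEMENTARY_CHARGE <- 1.602176634e-19  # C

#' Electron dose per image
#'
#' `dose = current * dwell * line_integration / (e * pixel_area)` with the
#' pixel area in Angstrom^2 (1 nm^2 = 100 A^2). SEM imaging of unstained
#' cryo specimens budgets roughly 0.5-1.5 e/A^2 per slice.
#'
#' @param current Beam current in pA.
#' @param dwell Pixel dwell time in us.
#' @param line_integration Line integration count.
#' @param pixel_size Pixel size in nm.
#' @return Dose in electrons per Angstrom^2.
#' @export
electron_dose <- function(current, dwell, line_integration, pixel_size) {
  if (any(c(dwell, line_integration, pixel_size) <= 0) || current < 0)
    stop_fibclem("param_error", "dose inputs must be positive")
  electrons <- current * 1e-12 * dwell * 1e-6 * line_integration / ELEMENTARY_CHARGE
  electrons / (pixel_size^2 * 100)
}

#' Session statistics and success rate
#'
#' `session_stats()` validates a per-sample count table;
#' `success_rate()` returns `100 * sum(fine_milled) / sum(target_sites)`,
#' rounded to one decimal.
#'
#' @param sample Sample names.
#' @param target_sites Sites targeted per sample.
#' @param fine_milled Lamellae fine-milled per sample.
#' @param transferred Lamellae successfully transferred to the TEM
#'   (`NA` when not tracked).
#' @param thickness_range Optional per-sample thickness range strings (nm).
#' @return `session_stats()` a tibble; `success_rate()` a percentage.
#' @export
session_stats <- function(sample, target_sites, fine_milled,
                          transferred = NA_integer_,
                          thickness_range = NA_character_) {
  if (any(fine_milled > target_sites))
    stop_fibclem("param_error", "fine_milled cannot exceed target_sites")
  tibble::tibble(sample = sample, target_sites = as.integer(target_sites),
                 fine_milled = as.integer(fine_milled),
                 transferred = as.integer(transferred),
                 thickness_range = thickness_range)
}

#' @rdname session_stats
#' @param stats A [session_stats()] tibble.
#' @export
success_rate <- function(stats) {
  total <- sum(stats$target_sites)
  if (total == 0) stop_fibclem("zero_sites", "no target sites")
  round(100 * sum(stats$fine_milled) / total, 1)
}

#' Retention rate
#'
#' Percentage of lamellae in which the targeted structure was retained
#' (e.g. 7 of 10 3D-CLEM-targeted lipid droplets on titanium supports).
#'
#' @param retained,total Counts.
#' @return Percentage.
#' @export
retention_rate <- function(retained, total) {
  if (total <= 0) stop_fibclem("zero_sites", "total must be positive")
  100 * retained / total
}

#' Benchmark on-grid milling session counts
#'
#' The five-cell-type benchmark counts for automated on-grid lamella
#' milling (Sum159, HeLa, E. huxleyi, C. reinhardtii, S. cerevisiae):
#' 77 target sites, 64 fine-milled lamellae.
#'
#' @return A [session_stats()] tibble.
#' @export
ongrid_session_counts <- function() {
  session_stats(
    sample = c("Sum159", "HeLa", "E. huxleyi", "C. reinhardtii", "S. cerevisiae"),
    target_sites = c(22L, 22L, 9L, 16L, 8L),
    fine_milled = c(19L, 18L, 9L, 10L, 8L),
    transferred = c(17L, 18L, 9L, NA, 8L),
    thickness_range = c("70-410", "100-450", "175-470", "140-350", "190-300"))
}

#' Fine-milling session time budget
#'
#' Amorphous ice condensation on finished lamellae grows at the instrument
#' condensation rate (50 nm/hr in the systems modeled here), so the total
#' fine-milling time per grid is capped (1 hr by default). Returns per-site
#' feasibility under the budget and the condensation accrued by each
#' lamella between its completion and the session end.
#'
#' @param fine_times_min Per-site fine milling times in minutes.
#' @param budget_hr Total fine-milling budget in hours.
#' @param condensation_rate_nm_hr Ice condensation rate in nm/hr.
#' @return A tibble with `site`, `start_min`, `end_min`, `within_budget`
#'   and `condensation_nm` (growth until the budgeted session end for
#'   completed sites).
#' @export
session_time_budget <- function(fine_times_min, budget_hr = 1,
                                condensation_rate_nm_hr = 50) {
  end <- cumsum(fine_times_min)
  start <- end - fine_times_min
  within <- end <= budget_hr * 60 + 1e-9
  session_end <- min(budget_hr * 60, max(end))
  tibble::tibble(site = seq_along(fine_times_min), start_min = start,
                 end_min = end, within_budget = within,
                 condensation_nm = ifelse(within,
                                          (session_end - end) / 60 * condensation_rate_nm_hr,
                                          NA_real_))
}
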