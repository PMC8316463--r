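#' Construct a walkway layout
#'
#' A layout describes the physical geometry of one obstacle condition:
#' a straight walkway leading from a start line to a bookcase, with an
#' optional box obstacle placed across the walkway.  All lengths are in
#' centimetres.  The coordinate frame used throughout the package has its
#' origin at the centre of the start position, the x axis lateral
#' (positive to the walker's right) and the y axis pointing forward toward
#' the bookcase.
#'
#' @param obstacle_width Width (lateral extent) of the obstacle in cm.
#'   Use 0 for the no-obstacle baseline (NOBST).  The experimental
#'   conditions use 45, 90 or 135 cm (one to three 45 cm boxes).
#' @param obstacle_lateral_offset Signed lateral displacement of the
#'   obstacle centre from the walkway centreline; positive means shifted
#'   to the right.
#' @param obstacle_distance Distance (cm) from the start line to the front
#'   face of the obstacle.  The obstacle sits "across the middle" of the
#'   7.5 m walkway, so the default is 375.
#' @param walkway_width,walkway_length Walkway dimensions (cm); defaults
#'   213 and 750.
#' @param tape_width Width of the boundary tape strip (informational; the
#'   margins are measured to the walkway edge).
#' @param obstacle_depth Obstacle depth along the walking direction (cm).
#' @param shelf_height Height of the target shelf (cm), informational.
#' @param bookcase_width Width of the bookcase holding the target (cm).
#' @param am_left_override,am_right_override Optional published avoidance
#'   margin values that take precedence over the margins derived from the
#'   geometry (the published table rounds some margins, e.g. 83.5 where
#'   symmetric derivation gives 84).
#' @param label Optional condition label (e.g. "NOBST", "C4").
#' @param condition Optional numeric condition id.
#'
#' @return An object of class \code{walkway_layout}.
#' @seealso [build_layout()] for the eight standard conditions,
#'   [avoidance_margins()], [relative_distance()], [deviation_angles()].
#' @export
walkway_layout <- function(obstacle_width,
                           obstacle_lateral_offset = 0,
                           obstacle_distance = 375,
                           walkway_width = 213,
                           walkway_length = 750,
                           tape_width = 5,
                           obstacle_depth = 32,
                           shelf_height = 88,
                           bookcase_width = 90,
                           am_left_override = NULL,
                           am_right_override = NULL,
                           label = NULL,
                           condition = NA_integer_) {
  stopifnot(is.numeric(obstacle_width), length(obstacle_width) == 1L,
            obstacle_width >= 0,
            walkway_width > 0, walkway_length > 0)
  has_obs <- obstacle_width > 0
  if (has_obs) {
    if (obstacle_width + 2 * abs(obstacle_lateral_offset) > walkway_width)
      stop("obstacle (width ", obstacle_width, ", offset ",
           obstacle_lateral_offset, ") does not fit on a ", walkway_width,
           " cm walkway", call. = FALSE)
    if (obstacle_distance <= 0 || obstacle_distance >= walkway_length)
      stop("obstacle_distance must lie strictly between 0 and walkway_length",
           call. = FALSE)
  }
  for (ov in list(am_left_override, am_right_override)) {
    if (!is.null(ov) && !is.na(ov) && (ov <= 0 || ov > walkway_width))
      stop("margin override must be positive and <= walkway_width",
           call. = FALSE)
  }
  structure(list(
    condition = condition,
    label = if (is.null(label)) if (has_obs) "custom" else "NOBST" else label,
    walkway_width = walkway_width,
    walkway_length = walkway_length,
    tape_width = tape_width,
    obstacle_width = obstacle_width,
    obstacle_depth = obstacle_depth,
    obstacle_lateral_offset = obstacle_lateral_offset,
    obstacle_distance = obstacle_distance,
    shelf_height = shelf_height,
    bookcase_width = bookcase_width,
    am_left_override = if (is.null(am_left_override) || is.na(am_left_override))
      NULL else am_left_override,
    am_right_override = if (is.null(am_right_override) || is.na(am_right_override))
      NULL else am_right_override
  ), class = "walkway_layout")
}

#' @export
print.walkway_layout <- function(x, ...) {
  cat("<walkway_layout> ", x$label, "\n", sep = "")
  if (has_obstacle(x)) {
    am <- avoidance_margins(x)
    cat(sprintf("  obstacle %g cm wide, offset %+g cm, front face at %g cm\n",
                x$obstacle_width, x$obstacle_lateral_offset,
                x$obstacle_distance))
    cat(sprintf("  avoidance margins: left %g cm, right %g cm\n",
                am[["am_left"]], am[["am_right"]]))
  } else {
    cat("  no obstacle\n")
  }
  invisible(x)
}

#' Does a layout contain an obstacle?
#' @param layout A \code{walkway_layout}.
#' @return Logical scalar.
#' @export
has_obstacle <- function(layout) {
  stopifnot(inherits(layout, "walkway_layout"))
  layout$obstacle_width > 0
}

#' The eight standard obstacle conditions
#'
#' Returns the packaged condition table: condition id, label, obstacle
#' width, signed lateral offset and the published left/right avoidance
#' margins.  Condition 1 is the no-obstacle baseline (NOBST).  Lateral
#' offsets are reconstructed from the published margins (half their
#' difference); the published margins themselves are carried as overrides
#' because two of the centred rows are rounded relative to the symmetric
#' derivation (83.5 vs 84, 61.0 vs 61.5).
#'
#' @return A data.frame with one row per condition.
#' @export
condition_table <- function() {
  path <- system.file("extdata", "obstacle_conditions.csv",
                      package = "pathgaze", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Build the layout for a standard condition
#'
#' @param condition Condition id in 1..8, or a \code{walkway_layout} (passed
#'   through unchanged, allowing explicit custom geometry everywhere a
#'   condition id is accepted).
#' @param ... Passed to [walkway_layout()] to override defaults such as
#'   \code{obstacle_distance}.
#' @return A \code{walkway_layout}.
#' @examples
#' build_layout(7)          # 135 cm obstacle shifted right; margins 52/25
#' avoidance_margins(build_layout(2))
#' @export
build_layout <- function(condition, ...) {
  if (inherits(condition, "walkway_layout")) return(condition)
  tab <- condition_table()
  stopifnot(length(condition) == 1L)
  row <- tab[tab$condition == condition, ]
  if (nrow(row) != 1L)
    stop("unknown condition id: ", condition,
         " (expected 1..8)", call. = FALSE)
  walkway_layout(obstacle_width = row$obstacle_width,
                 obstacle_lateral_offset = row$obstacle_lateral_offset,
                 am_left_override = row$am_left,
                 am_right_override = row$am_right,
                 label = row$label,
                 condition = row$condition,
                 ...)
}

obstacle_corners <- function(layout) {
  # front-face outer corners of the obstacle: what constrains the turn
  x_l <- layout$obstacle_lateral_offset - layout$obstacle_width / 2
  x_r <- layout$obstacle_lateral_offset + layout$obstacle_width / 2
  list(left = c(x = x_l, y = layout$obstacle_distance),
       right = c(x = x_r, y = layout$obstacle_distance))
}

stop_if_nobst <- function(layout, what) {
  if (!has_obstacle(layout))
    stop(what, " is undefined for a no-obstacle (NOBST) layout",
         call. = FALSE)
}

#' Avoidance margins of a layout
#'
#' The avoidance margin on one side is the passable gap between the
#' obstacle's outer edge and the walkway edge on that side.  When the
#' layout carries published override values they are returned verbatim;
#' otherwise margins are derived from the geometry as
#' \code{walkway_width/2 - obstacle_width/2 -/+ obstacle_lateral_offset}.
#'
#' @param layout A \code{walkway_layout} with an obstacle.
#' @param use_overrides Honour override values when present (default TRUE).
#' @return Named numeric vector \code{c(am_left=, am_right=)} in cm.
#' @export
avoidance_margins <- function(layout, use_overrides = TRUE) {
  stopifnot(inherits(layout, "walkway_layout"))
  stop_if_nobst(layout, "avoidance margin")
  if (use_overrides && !is.null(layout$am_left_override) &&
      !is.null(layout$am_right_override)) {
    return(c(am_left = layout$am_left_override,
             am_right = layout$am_right_override))
  }
  half_gap <- (layout$walkway_width - layout$obstacle_width) / 2
  am <- c(am_left  = half_gap + layout$obstacle_lateral_offset,
          am_right = half_gap - layout$obstacle_lateral_offset)
  if (any(am <= 0)) stop("derived avoidance margin is not positive",
                         call. = FALSE)
  am
}

#' Relative distance to the obstacle edges
#'
#' \code{d_left}/\code{d_right} are the Euclidean distances from the centre
#' of the start position to the obstacle's front-face outer corner on each
#' side; \code{delta_d = d_right - d_left}.  An obstacle shifted to the
#' right gives positive \code{delta_d} (the right edge is farther).
#'
#' @param layout A \code{walkway_layout} with an obstacle.
#' @return Named list with \code{d_left}, \code{d_right}, \code{delta_d} (cm).
#' @export
relative_distance <- function(layout) {
  stopifnot(inherits(layout, "walkway_layout"))
  stop_if_nobst(layout, "relative distance")
  co <- obstacle_corners(layout)
  d_l <- sqrt(sum(co$left^2))
  d_r <- sqrt(sum(co$right^2))
  list(d_left = d_l, d_right = d_r, delta_d = d_r - d_l)
}

#' Deviation angles to the obstacle edges
#'
#' Each deviation angle is the unsigned angle (degrees) between the straight
#' line from the start centre to the target and the line from the start
#' centre to the obstacle's outer front corner on that side;
#' \code{delta_theta = theta_right - theta_left}.  Moving the target to the
#' left makes \code{delta_theta} positive (the right detour becomes the
#' larger deviation), moving it to the right makes it negative.
#'
#' @param layout A \code{walkway_layout} with an obstacle.
#' @param target_offset Signed lateral target position (cm; + = right of the
#'   shelf centre).  The target sits at the end of the walkway.
#' @return Named list with \code{theta_left}, \code{theta_right},
#'   \code{delta_theta} in degrees.
#' @export
deviation_angles <- function(layout, target_offset) {
  stopifnot(inherits(layout, "walkway_layout"), is.numeric(target_offset))
  stop_if_nobst(layout, "deviation angle")
  if (abs(target_offset) > layout$bookcase_width / 2)
    stop("target offset exceeds the bookcase half-width", call. = FALSE)
  co <- obstacle_corners(layout)
  ang_target <- atan2(target_offset, layout$walkway_length)
  ang <- function(corner) abs(atan2(corner[["x"]], corner[["y"]]) - ang_target)
  th_l <- ang(co$left) * 180 / pi
  th_r <- ang(co$right) * 180 / pi
  list(theta_left = th_l, theta_right = th_r, delta_theta = th_r - th_l)
}

#' Deviation from straight ahead (no-obstacle baseline)
#'
#' Angle (degrees, unsigned) between straight ahead and the start-to-target
#' line; defined for every layout including NOBST.
#' @inheritParams deviation_angles
#' @export
straight_deviation <- function(layout, target_offset) {
  stopifnot(inherits(layout, "walkway_layout"))
  abs(atan2(target_offset, layout$walkway_length)) * 180 / pi
}

#' Decision-geometry features for one condition x target cell
#'
#' @inheritParams deviation_angles
#' @return One-row data.frame with columns \code{condition},
#'   \code{target_offset_cm}, \code{d_left}, \code{d_right}, \code{delta_d},
#'   \code{theta_left}, \code{theta_right}, \code{delta_theta},
#'   \code{am_left}, \code{am_right}, \code{amr},
#'   \code{straight_deviation_deg}.  Obstacle-dependent columns are NA for a
#'   NOBST layout.
#' @export
geometry_features <- function(layout, target_offset) {
  layout <- build_layout(layout)
  base <- data.frame(condition = layout$condition,
                     label = layout$label,
                     target_offset_cm = target_offset,
                     stringsAsFactors = FALSE)
  if (!has_obstacle(layout)) {
    obs <- data.frame(d_left = NA_real_, d_right = NA_real_,
                      delta_d = NA_real_, theta_left = NA_real_,
                      theta_right = NA_real_, delta_theta = NA_real_,
                      am_left = NA_real_, am_right = NA_real_,
                      amr = NA_real_)
  } else {
    rd <- relative_distance(layout)
    da <- deviation_angles(layout, target_offset)
    am <- avoidance_margins(layout)
    obs <- data.frame(d_left = rd$d_left, d_right = rd$d_right,
                      delta_d = rd$delta_d,
                      theta_left = da$theta_left,
                      theta_right = da$theta_right,
                      delta_theta = da$delta_theta,
                      am_left = am[["am_left"]], am_right = am[["am_right"]],
                      amr = am[["am_right"]] / am[["am_left"]])
  }
  cbind(base, obs,
        straight_deviation_deg = straight_deviation(layout, target_offset))
}

#' Feature table over a full (or partial) design
#'
#' One row of decision features per condition x target cell, in the order
#' given (duplicates preserved).  The full experimental design is 8
#' conditions x 3 target positions = 24 cells.
#'
#' @param conditions Vector of condition ids (or list of layouts).
#' @param target_offsets Vector of target offsets in cm.
#' @param expand If TRUE (default) take the full cross of conditions and
#'   targets; if FALSE, treat the two vectors as paired cells.
#' @param ... Passed to [build_layout()].
#' @return data.frame as in [geometry_features()].
#' @examples
#' nrow(feature_table())  # 24
#' @export
feature_table <- function(conditions = 1:8,
                          target_offsets = c(-30, 0, 30),
                          expand = TRUE, ...) {
  if (length(conditions) == 0L || length(target_offsets) == 0L)
    stop("empty design", call. = FALSE)
  if (expand) {
    cells <- expand.grid(target = target_offsets, condition = conditions,
                         KEEP.OUT.ATTRS = FALSE)
    # condition-major ordering
    cells <- cells[, c("condition", "target")]
  } else {
    stopifnot(length(conditions) == length(target_offsets))
    cells <- data.frame(condition = conditions, target = target_offsets)
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    geometry_features(build_layout(cells$condition[[i]], ...),
                      cells$target[[i]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV
#' @param features data.frame from [feature_table()].
#' @param path Output file path.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
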