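#' Areas of interest for a layout
#'
#' Builds the rectangular ground-plane regions used to label gaze points:
#' the target zone (bookcase footprint plus a halo), the left and right
#' avoidance margins (the gaps beside the obstacle, over its depth extent
#' plus a halo), and the path (the walkway strip excluding the
#' margin/obstacle band and the target band).  Regions are pairwise
#' disjoint; margins are absent for a no-obstacle layout.  Exact region
#' extents are a package convention (configurable halos), not a published
#' quantity.
#'
#' @param layout \code{walkway_layout} or condition id.
#' @param target_offset Target lateral position (informational; the target
#'   zone covers the bookcase).
#' @param target_halo,margin_halo Halo widths in cm.
#' @return List of class \code{aoi_regions}; each region is a named vector
#'   \code{c(xmin, xmax, ymin, ymax)}.
#' @export
aoi_regions <- function(layout, target_offset = 0, target_halo = 10,
                        margin_halo = 10) {
  layout <- build_layout(layout)
  half <- layout$walkway_width / 2
  L <- layout$walkway_length
  rect <- function(xmin, xmax, ymin, ymax)
    c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  target <- rect(-layout$bookcase_width / 2 - target_halo,
                 layout$bookcase_width / 2 + target_halo,
                 L - target_halo, L + 22 + target_halo)
  out <- list(target = target)
  if (has_obstacle(layout)) {
    x_l <- layout$obstacle_lateral_offset - layout$obstacle_width / 2
    x_r <- layout$obstacle_lateral_offset + layout$obstacle_width / 2
    y0 <- layout$obstacle_distance - margin_halo
    y1 <- layout$obstacle_distance + layout$obstacle_depth + margin_halo
    out$margin_left  <- rect(-half, x_l, y0, y1)
    out$margin_right <- rect(x_r, half, y0, y1)
    out$path_pre  <- rect(-half, half, 0, y0)
    out$path_post <- rect(-half, half, y1, L - target_halo)
  } else {
    out$path_pre <- rect(-half, half, 0, L - target_halo)
  }
  attr(out, "layout") <- layout
  class(out) <- "aoi_regions"
  out
}

in_rect <- function(x, y, r) {
  x >= r[["xmin"]] & x <= r[["xmax"]] & y >= r[["ymin"]] & y <= r[["ymax"]]
}

#' Label gaze points by area of interest
#'
#' Deterministic point-in-rectangle test; target takes precedence, then
#' margins, then path; anything outside all regions (including the
#' obstacle footprint itself) is \code{none} and excluded from analysis.
#'
#' @param x,y Ground-plane coordinates (cm) in the start-centred frame.
#' @param regions [aoi_regions()].
#' @return Factor with levels \code{T, P, S_left, S_right, none}.
#' @export
label_aoi <- function(x, y, regions) {
  stopifnot(inherits(regions, "aoi_regions"), length(x) == length(y))
  lab <- rep("none", length(x))
  if (!is.null(regions$path_pre))
    lab[in_rect(x, y, regions$path_pre)] <- "P"
  if (!is.null(regions$path_post))
    lab[in_rect(x, y, regions$path_post)] <- "P"
  if (!is.null(regions$margin_left))
    lab[in_rect(x, y, regions$margin_left)] <- "S_left"
  if (!is.null(regions$margin_right))
    lab[in_rect(x, y, regions$margin_right)] <- "S_right"
  lab[in_rect(x, y, regions$target)] <- "T"
  factor(lab, levels = c("T", "P", "S_left", "S_right", "none"))
}

#' Project gaze rays to the ground plane
#'
#' Convenience helper for (origin, direction) gaze records: intersects each
#' ray with the ground plane z = 0.  Rays parallel to or pointing away from
#' the ground give NA.
#'
#' @param origin Matrix/data.frame with columns x, y, z (cm; z up).
#' @param direction Matrix/data.frame of unit (or any nonzero) direction
#'   vectors, columns x, y, z.
#' @return data.frame with \code{x_cm}, \code{y_cm} ground intersections.
#' @export
project_gaze_to_ground <- function(origin, direction) {
  origin <- as.matrix(origin); direction <- as.matrix(direction)
  stopifnot(ncol(origin) == 3, ncol(direction) == 3,
            nrow(origin) == nrow(direction))
  s <- -origin[, 3] / direction[, 3]
  s[!is.finite(s) | s < 0] <- NA_real_
  data.frame(x_cm = origin[, 1] + s * direction[, 1],
             y_cm = origin[, 2] + s * direction[, 2])
}

#' Per-AOI gaze dwell times
#'
#' Each sample contributes one nominal inter-sample interval of dwell.
#'
#' @param gaze data.frame with \code{x_cm}, \code{y_cm}.
#' @param regions [aoi_regions()].
#' @param rate_hz Nominal sampling rate (default 120).
#' @return Named numeric vector of dwell seconds for
#'   \code{T, P, S_left, S_right, none}.
#' @export
gaze_dwell <- function(gaze, regions, rate_hz = 120) {
  lab <- label_aoi(gaze$x_cm, gaze$y_cm, regions)
  table(lab) / rate_hz
}

#' Avoidance-margin gaze ratio
#'
#' The signed contrast of gaze time on the right vs left avoidance margin:
#' \deqn{AMGR = (t_{right} - t_{left}) / (t_{right} + t_{left})}
#' AMGR is in [-1, +1]; 0 means equal margin gaze, +1 all-right, -1
#' all-left.  When no gaze fell on either margin the ratio is undefined and
#' \code{NA} is returned (rows with undefined AMGR must be excluded from
#' regressions).
#'
#' @param gaze data.frame with \code{x_cm}, \code{y_cm}, or NULL when
#'   dwell times are given directly.
#' @param regions [aoi_regions()] for an obstacle condition.
#' @param rate_hz Nominal sampling rate.
#' @param dwell_left,dwell_right Optional explicit margin dwell times (s);
#'   bypass the gaze labelling.
#' @return AMGR in [-1, 1], or NA if undefined.
#' @export
amgr <- function(gaze = NULL, regions = NULL, rate_hz = 120,
                 dwell_left = NULL, dwell_right = NULL) {
  if (is.null(dwell_left) || is.null(dwell_right)) {
    stopifnot(inherits(regions, "aoi_regions"))
    if (is.null(regions$margin_left))
      stop("AMGR is undefined for a no-obstacle layout", call. = FALSE)
    dw <- gaze_dwell(gaze, regions, rate_hz)
    dwell_left <- dw[["S_left"]]; dwell_right <- dw[["S_right"]]
  }
  tot <- dwell_left + dwell_right
  if (tot <= 0) return(NA_real_)
  (dwell_right - dwell_left) / tot
}

#' Gaze allocation map
#'
#' 2-D Gaussian kernel density over the ground-plane gaze points (one
#' nominal sample interval of dwell per point), normalised by the trial
#' duration and affinely rescaled to the 0-10 display range.  When regions
#' are supplied only in-AOI samples enter the estimate.
#'
#' @param gaze data.frame with \code{x_cm}, \code{y_cm}.
#' @param duration_s Trial duration (s).
#' @param regions Optional [aoi_regions()] to restrict to in-AOI gaze.
#' @param bandwidth Isotropic kernel SD in cm (default 15).
#' @param grid_n Grid resolution per axis.
#' @param xlim,ylim Map extent; defaults cover the walkway.
#' @param rate_hz Nominal sampling rate.
#' @return List of class \code{allocation_map}: grid vectors \code{x},
#'   \code{y}, rescaled intensity matrix \code{z} (max 10), and the
#'   unscaled intensity \code{z_raw} (integrates to in-AOI dwell /
#'   duration).
#' @export
allocation_map <- function(gaze, duration_s, regions = NULL,
                           bandwidth = 15, grid_n = 50,
                           xlim = NULL, ylim = NULL, rate_hz = 120) {
  if (is.null(nrow(gaze)) || nrow(gaze) == 0L)
    stop("cannot build an allocation map from an empty gaze stream",
         call. = FALSE)
  if (!is.null(regions)) {
    keep <- label_aoi(gaze$x_cm, gaze$y_cm, regions) != "none"
    gaze <- gaze[keep, , drop = FALSE]
    if (nrow(gaze) == 0L)
      stop("no in-AOI gaze samples", call. = FALSE)
    lay <- attr(regions, "layout")
    if (is.null(xlim)) xlim <- c(-lay$walkway_width / 2 - 30,
                                 lay$walkway_width / 2 + 30)
    if (is.null(ylim)) ylim <- c(0, lay$walkway_length + 40)
  }
  if (is.null(xlim)) xlim <- range(gaze$x_cm) + c(-3, 3) * bandwidth
  if (is.null(ylim)) ylim <- range(gaze$y_cm) + c(-3, 3) * bandwidth
  # MASS::kde2d uses h/4 as the Gaussian SD
  kd <- MASS::kde2d(gaze$x_cm, gaze$y_cm, h = 4 * bandwidth, n = grid_n,
                    lims = c(xlim, ylim))
  dwell_total <- nrow(gaze) / rate_hz
  z_raw <- kd$z * dwell_total / duration_s
  rng <- range(z_raw)
  z <- if (diff(rng) > 0) (z_raw - rng[1]) / diff(rng) * 10 else
    z_raw * 0
  structure(list(x = kd$x, y = kd$y, z = z, z_raw = z_raw,
                 bandwidth = bandwidth),
            class = "allocation_map")
}

#' Write an allocation map as a plain-text matrix
#' @param map [allocation_map()].
#' @param path Output path (tab-separated; first row/column are grid
#'   coordinates).
#' @export
write_allocation_map <- function(map, path) {
  m <- rbind(c(NA, map$y), cbind(map$x, map$z))
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Gaze frequency per AOI, condition and target
#'
#' Counts gaze samples per area of interest for each condition x target
#' cell.  Margin counts can be reported merged (\code{S}) or split
#' (\code{S_left}/\code{S_right}); counting samples (not discrete gaze
#' events) is a package convention recorded in the output metadata.
#'
#' @param trials Trial table (columns \code{trial_id}, \code{condition},
#'   \code{target_offset_cm}).
#' @param gaze Long gaze table with \code{trial_id}, \code{x_cm},
#'   \code{y_cm}.
#' @param merge_margins Report margins as one S category (default TRUE).
#' @return Long data.frame: condition, target_offset_cm, aoi, count.
#'   NOBST rows carry no margin categories.
#' @export
gaze_frequency <- function(trials, gaze, merge_margins = TRUE) {
  stopifnot(nrow(trials) > 0)
  out <- list()
  by_trial <- split(gaze, gaze$trial_id)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    g <- by_trial[[as.character(tr$trial_id)]]
    regions <- aoi_regions(tr$condition, target_offset = tr$target_offset_cm)
    lab <- label_aoi(g$x_cm, g$y_cm, regions)
    counts <- table(lab)
    if (merge_margins) {
      counts <- c(T = counts[["T"]], P = counts[["P"]],
                  S = counts[["S_left"]] + counts[["S_right"]])
    } else {
      counts <- c(T = counts[["T"]], P = counts[["P"]],
                  S_left = counts[["S_left"]],
                  S_right = counts[["S_right"]])
    }
    if (is.null(regions$margin_left))
      counts <- counts[names(counts) %in% c("T", "P")]
    out[[i]] <- data.frame(condition = tr$condition,
                           target_offset_cm = tr$target_offset_cm,
                           aoi = names(counts), count = as.integer(counts),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- aggregate(count ~ condition + target_offset_cm + aoi, res, sum)
  res <- res[order(res$condition, res$target_offset_cm, res$aoi), ]
  rownames(res) <- NULL
  attr(res, "counting") <- "samples"
  res
}
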