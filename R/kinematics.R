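#' Gait speed from a trajectory
#'
#' Anterior-posterior (forward, y-axis) displacement divided by elapsed
#' time, so lateral excursions of the path do not enter.  The full segment
#' spans first to last sample; the to-margin segment stops at the
#' obstacle's longitudinal midline (front face + depth/2), with the
#' crossing time interpolated between samples.
#'
#' @param trajectory data.frame with \code{t_s}, \code{y_cm} (and
#'   typically \code{x_cm}).
#' @param segment "full" or "to_margin".
#' @param layout Required for \code{to_margin}: \code{walkway_layout} or
#'   condition id with an obstacle.
#' @return Speed in cm/s.
#' @export
gait_speed <- function(trajectory, segment = c("full", "to_margin"),
                       layout = NULL) {
  segment <- match.arg(segment)
  stopifnot(nrow(trajectory) >= 2L)
  t <- trajectory$t_s; y <- trajectory$y_cm
  if (segment == "full") {
    el <- t[length(t)] - t[1]
    if (el <= 0) stop("zero elapsed time", call. = FALSE)
    return((y[length(y)] - y[1]) / el)
  }
  if (is.null(layout))
    stop("to_margin speed needs the layout", call. = FALSE)
  layout <- build_layout(layout)
  if (!has_obstacle(layout))
    stop("to_margin speed is undefined for a no-obstacle layout",
         call. = FALSE)
  y_mid <- layout$obstacle_distance + layout$obstacle_depth / 2
  if (max(y) < y_mid)
    stop("trajectory never reaches the avoidance-margin midline",
         call. = FALSE)
  i <- which(y >= y_mid)[1]
  t_cross <- if (i == 1L) t[1] else {
    # linear interpolation between the straddling samples
    t[i - 1] + (t[i] - t[i - 1]) * (y_mid - y[i - 1]) / (y[i] - y[i - 1])
  }
  el <- t_cross - t[1]
  if (el <= 0) stop("zero elapsed time", call. = FALSE)
  (y_mid - y[1]) / el
}

#' Speed summary over a dataset
#'
#' Mean and standard error of the full-path and to-obstacle gait speeds
#' per condition x target cell.
#'
#' @param trials Trial table (\code{trial_id}, \code{condition},
#'   \code{target_offset_cm}).
#' @param trajectory Long trajectory table keyed by \code{trial_id}.
#' @return data.frame: condition, target_offset_cm, n, speed_full_mean,
#'   speed_full_se, speed_margin_mean, speed_margin_se (NA for NOBST).
#' @export
speed_summary <- function(trials, trajectory) {
  full <- numeric(nrow(trials)); marg <- rep(NA_real_, nrow(trials))
  by_trial <- split(trajectory, trajectory$trial_id)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    traj <- by_trial[[as.character(tr$trial_id)]]
    full[i] <- gait_speed(traj, "full")
    lay <- build_layout(tr$condition)
    if (has_obstacle(lay))
      marg[i] <- gait_speed(traj, "to_margin", lay)
  }
  se <- function(v) sd(v) / sqrt(length(v))
  cells <- unique(trials[, c("condition", "target_offset_cm")])
  out <- lapply(seq_len(nrow(cells)), function(k) {
    sel <- trials$condition == cells$condition[k] &
      trials$target_offset_cm == cells$target_offset_cm[k]
    data.frame(condition = cells$condition[k],
               target_offset_cm = cells$target_offset_cm[k],
               n = sum(sel),
               speed_full_mean = mean(full[sel]),
               speed_full_se = se(full[sel]),
               speed_margin_mean = mean(marg[sel]),
               speed_margin_se = se(marg[sel]))
  })
  res <- do.call(rbind, out)
  res[order(res$condition, res$target_offset_cm), ]
}

#' Start-foot frequency summary
#'
#' Percentage of right-foot starts per condition x target cell plus the
#' Pearson correlation between the start-foot indicator and the
#' chosen-side indicator (both right = 1).  The correlation is NA (with a
#' flag) when either indicator is constant.
#'
#' @param trials Trial table with \code{condition},
#'   \code{target_offset_cm}, \code{start_foot}, \code{chosen_side}.
#' @return List: \code{table} (wide data.frame, conditions as columns),
#'   \code{correlation}, \code{correlation_defined}.
#' @export
start_foot_summary <- function(trials) {
  stopifnot(all(c("start_foot", "condition", "target_offset_cm")
                %in% names(trials)))
  right <- as.integer(trials$start_foot == "right")
  cells <- aggregate(right,
                     by = list(condition = trials$condition,
                               target_offset_cm = trials$target_offset_cm),
                     FUN = function(v) 100 * mean(v))
  wide <- stats::reshape(cells, idvar = "target_offset_cm",
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^x\\.", "condition_", names(wide))
  wide <- wide[order(wide$target_offset_cm), ]
  rownames(wide) <- NULL
  has_side <- !is.na(trials$chosen_side)
  foot_r <- right[has_side]
  side_r <- as.integer(trials$chosen_side[has_side] == "right")
  defined <- var(foot_r) > 0 && var(side_r) > 0
  corr <- if (defined) stats::cor(foot_r, side_r) else NA_real_
  list(table = wide, correlation = corr, correlation_defined = defined)
}
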