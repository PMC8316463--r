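#' Simulation parameters
#'
#' Container for every tunable of the synthetic trial generator.  Defaults
#' encode the statistical structure the downstream analysis assumes: a
#' logistic path-choice model over the decision geometry with a 90%
#' right-side baseline at neutral geometry, phase-structured gaze streams
#' (early target+margin, mid margin, late target), gait that slows in
#' proportion to the margin deficit, and 0-10 judgment ratings driven by a
#' logistic psychometric crossing 15 cm left of the shelf centre.
#'
#' @param choice_coefficients Named numeric vector of logit-scale weights:
#'   \code{intercept}, \code{delta_theta} (per degree), \code{delta_d}
#'   (per cm), \code{amr} (per unit of AMR - 1, so the term vanishes at
#'   neutral symmetric margins), and optional interactions
#'   \code{delta_theta:delta_d}, \code{delta_theta:amr}.  The default
#'   intercept is \code{qlogis(0.9)} so that P(right) = 0.90 at neutral
#'   geometry; the default deviation-angle weight (-0.5) is chosen so a
#'   5 degree advantage makes the choice near-deterministic (>= 0.99), and
#'   the distance and margin-ratio weights are the published univariate
#'   middle-target slopes (-0.35, 4.67).
#' @param participant_sd Relative jitter applied to each participant's
#'   choice coefficients (multiplicative, uniform on 1 +/- this value).
#' @param gaze_phase_model data.frame with columns \code{t_start},
#'   \code{t_end} (fractions of trial duration, contiguous),
#'   \code{p_target}, \code{p_margin}, \code{p_path}, \code{p_none}
#'   (dwell probabilities, each row summing to 1).
#' @param margin_attention_gain How strongly margin gaze probability grows
#'   as the narrower margin shrinks below a comfortable reference (61 cm);
#'   1 means the probability scales by \code{1 + deficit/61}, renormalised.
#' @param margin_side_bias Probability that a margin gaze lands on the
#'   to-be-chosen side (makes AMGR predict choice).
#' @param gaze_rate_hz,trajectory_rate_hz Sampling rates (120 Hz eye
#'   tracker, 30 Hz position tracking).
#' @param gaze_segment_s Mean duration of one gaze fixation segment.
#' @param gaze_jitter_sd Per-sample 2-D Gaussian jitter (cm) around a
#'   fixation anchor.
#' @param speed_base Baseline gait speed, cm/s.
#' @param speed_margin_slowdown Speed reduction (cm/s) per cm by which the
#'   chosen avoidance margin falls short of \code{margin_reference}.
#' @param margin_reference Margin width (cm) below which walkers slow down.
#' @param trajectory_jitter_sd Positional jitter (cm) on trajectory samples.
#' @param judgment_threshold Signed target offset (cm) at which the
#'   judgment-test choice probability crosses 50%; negative = left of the
#'   shelf centre.
#' @param judgment_slope Psychometric slope, logit per cm.
#' @param judgment_noise_sd SD of the bounded rating noise (0-10 scale).
#' @param start_foot_p_right Named vector of P(start with right foot) for
#'   target positions \code{left}, \code{middle}, \code{right}.
#' @param n_participants,n_trials_per_cell Design sizes (12 and 3 in the
#'   experiment).
#' @param seed Root seed for [generate_dataset()].
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(choice_coefficients = c(intercept = qlogis(0.9),
                                               delta_theta = -0.5,
                                               delta_d = -0.35,
                                               amr = 4.67),
                       participant_sd = 0.1,
                       gaze_phase_model = default_gaze_phases(),
                       margin_attention_gain = 1,
                       margin_side_bias = 0.8,
                       gaze_rate_hz = 120,
                       trajectory_rate_hz = 30,
                       gaze_segment_s = 0.4,
                       gaze_jitter_sd = 5,
                       speed_base = 130,
                       speed_margin_slowdown = 0.6,
                       margin_reference = 84,
                       trajectory_jitter_sd = 1,
                       judgment_threshold = -15,
                       judgment_slope = 0.3,
                       judgment_noise_sd = 0.5,
                       start_foot_p_right = c(left = 0.52, middle = 0.65,
                                              right = 0.65),
                       n_participants = 12,
                       n_trials_per_cell = 3,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(n_participants >= 1, n_trials_per_cell >= 1)
  gp <- p$gaze_phase_model
  req <- c("t_start", "t_end", "p_target", "p_margin", "p_path", "p_none")
  if (!all(req %in% names(gp)))
    stop("gaze_phase_model must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(gp$t_end <= gp$t_start) || is.unsorted(gp$t_start))
    stop("gaze phase boundaries must be strictly increasing", call. = FALSE)
  psum <- rowSums(gp[, c("p_target", "p_margin", "p_path", "p_none")])
  if (any(abs(psum - 1) > 1e-8))
    stop("gaze phase dwell probabilities must sum to 1 in every phase",
         call. = FALSE)
  class(p) <- "sim_params"
  p
}

#' Default phase-structured gaze model
#'
#' Five phases of the normalised trial: early planning (target + margin),
#' approach, margin monitoring while passing the obstacle, re-acquiring the
#' target, and the final approach when path/margin gaze falls to almost
#' zero.
#' @return data.frame accepted by [sim_params()].
#' @export
default_gaze_phases <- function() {
  data.frame(
    t_start  = c(0.00, 0.10, 0.25, 0.45, 0.80),
    t_end    = c(0.10, 0.25, 0.45, 0.80, 1.00),
    p_target = c(0.45, 0.55, 0.30, 0.70, 0.93),
    p_margin = c(0.35, 0.20, 0.50, 0.10, 0.02),
    p_path   = c(0.15, 0.20, 0.15, 0.15, 0.03),
    p_none   = c(0.05, 0.05, 0.05, 0.05, 0.02)
  )
}

choice_linear_predictor <- function(features, coefficients) {
  cf <- function(name) if (name %in% names(coefficients))
    coefficients[[name]] else 0
  dt <- features$delta_theta
  dd <- features$delta_d
  amr1 <- features$amr - 1
  lp <- cf("intercept") + cf("delta_theta") * dt + cf("delta_d") * dd +
    cf("amr") * amr1 +
    cf("delta_theta:delta_d") * dt * dd +
    cf("delta_theta:amr") * dt * amr1
  if (any(!is.finite(lp)))
    stop("non-finite linear predictor (check features and coefficients)",
         call. = FALSE)
  lp
}

#' Model probability of choosing the right side
#'
#' Deterministic companion of [simulate_choice()]: the logistic choice
#' probability for given decision features under a coefficient set.
#'
#' @param features data.frame with columns \code{delta_theta},
#'   \code{delta_d}, \code{amr} (e.g. rows of [feature_table()]).
#' @param params A [sim_params()] object (or a bare named coefficient
#'   vector).
#' @return Numeric vector of P(right).
#' @export
choice_probability <- function(features, params = sim_params()) {
  coefficients <- if (inherits(params, "sim_params"))
    params$choice_coefficients else params
  plogis(choice_linear_predictor(features, coefficients))
}

#' Simulate path choices
#'
#' Draws Bernoulli right/left choices (right = 1) from the logistic choice
#' model.  Uses the current RNG state; seed upstream for reproducibility.
#'
#' @inheritParams choice_probability
#' @return Integer vector of choices (1 = right, 0 = left), one per row of
#'   \code{features}.
#' @export
simulate_choice <- function(features, params = sim_params()) {
  p <- choice_probability(features, params)
  rbinom(length(p), 1L, p)
}

#' Simulate choices from a univariate AMGR model
#'
#' @param amgr Numeric vector of avoidance-margin gaze ratios in [-1, 1].
#' @param coefficient Logit slope on AMGR.
#' @param intercept Logit intercept; default calibrated to P(right) = 0.9
#'   at AMGR = 0.
#' @return Integer choices (1 = right).
#' @export
simulate_amgr_choice <- function(amgr, coefficient,
                                 intercept = qlogis(0.9)) {
  rbinom(length(amgr), 1L, plogis(intercept + coefficient * amgr))
}

margin_midpoints <- function(layout) {
  half <- layout$walkway_width / 2
  x_l <- layout$obstacle_lateral_offset - layout$obstacle_width / 2
  x_r <- layout$obstacle_lateral_offset + layout$obstacle_width / 2
  c(left = (x_l - half) / 2, right = (x_r + half) / 2)
}

#' Simulate a walking trajectory
#'
#' Piecewise-linear path from the start centre through the chosen avoidance
#' margin's midpoint to the target, sampled at the trajectory rate with an
#' instantaneous speed that drops near the obstacle in proportion to the
#' chosen margin's deficit below the comfortable reference width.  The
#' samples stand in for the ankle midpoint: forward (y) displacement over
#' time is what the gait-speed measures consume.
#'
#' @param layout A \code{walkway_layout} or condition id.
#' @param side "left" or "right" (ignored for NOBST).
#' @param target_offset Target lateral position (cm).
#' @param params [sim_params()].
#' @return data.frame with columns \code{t_s}, \code{x_cm}, \code{y_cm}.
#' @export
simulate_trajectory <- function(layout, side = "right", target_offset = 0,
                                params = sim_params()) {
  layout <- build_layout(layout)
  if (has_obstacle(layout)) {
    side <- match.arg(side, c("left", "right"))
    am <- avoidance_margins(layout, use_overrides = FALSE)
    margin <- am[[paste0("am_", side)]]
    if (margin <= 0) stop("chosen side is not passable", call. = FALSE)
    mid_y <- layout$obstacle_distance + layout$obstacle_depth / 2
    waypoints <- rbind(c(0, 0),
                       c(0, max(0, layout$obstacle_distance - 200)),
                       c(margin_midpoints(layout)[[side]], mid_y),
                       c(target_offset, layout$walkway_length))
    deficit <- max(0, params$margin_reference - margin)
  } else {
    waypoints <- rbind(c(0, 0), c(target_offset, layout$walkway_length))
    deficit <- 0
    mid_y <- NA_real_
  }
  slow_from <- if (has_obstacle(layout)) layout$obstacle_distance - 150 else Inf
  slow_to <- if (has_obstacle(layout))
    layout$obstacle_distance + layout$obstacle_depth else Inf
  v_slow <- max(20, params$speed_base - params$speed_margin_slowdown * deficit)

  seg <- diff(waypoints)
  seg_len <- sqrt(rowSums(seg^2))
  cum_len <- c(0, cumsum(seg_len))
  total <- cum_len[length(cum_len)]
  point_at <- function(s) {
    i <- findInterval(s, cum_len, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), nrow(seg))
    frac <- (s - cum_len[i]) / seg_len[i]
    waypoints[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
  }
  dt <- 1 / params$trajectory_rate_hz
  s <- 0; t <- 0
  ss <- numeric(0); ts <- numeric(0)
  while (s < total) {
    ss <- c(ss, s); ts <- c(ts, t)
    y_here <- point_at(s)[1, 2]
    v <- if (y_here >= slow_from && y_here <= slow_to) v_slow else
      params$speed_base
    s <- s + v * dt
    t <- t + dt
  }
  ss <- c(ss, total); ts <- c(ts, t)
  pts <- point_at(ss)
  jx <- rnorm(length(ss), 0, params$trajectory_jitter_sd)
  jy <- rnorm(length(ss), 0, params$trajectory_jitter_sd)
  jx[c(1, length(ss))] <- 0; jy[c(1, length(ss))] <- 0
  data.frame(t_s = ts, x_cm = pts[, 1] + jx, y_cm = pts[, 2] + jy)
}

phase_probs_at <- function(frac, params, layout) {
  gp <- params$gaze_phase_model
  i <- findInterval(frac, gp$t_start, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), nrow(gp))
  pr <- c(target = gp$p_target[i], margin = gp$p_margin[i],
          path = gp$p_path[i], none = gp$p_none[i])
  if (!has_obstacle(layout)) {
    # no margins to look at: margin mass joins the target
    pr[["target"]] <- pr[["target"]] + pr[["margin"]]
    pr[["margin"]] <- 0
  } else {
    am <- avoidance_margins(layout, use_overrides = FALSE)
    deficit <- max(0, 61 - min(am))
    pr[["margin"]] <- pr[["margin"]] *
      (1 + params$margin_attention_gain * deficit / 61)
    pr <- pr / sum(pr)
  }
  pr
}

#' Simulate a gaze sample stream
#'
#' Fixation segments (exponential durations) are assigned an area of
#' interest from the phase-dependent categorical model; margin gazes land
#' on the to-be-chosen side with probability \code{margin_side_bias}.  Each
#' segment gets a ground-plane anchor inside its AOI region and the
#' 120 Hz samples scatter around it with Gaussian jitter.
#'
#' @param layout \code{walkway_layout} or condition id.
#' @param duration_s Trial duration (s).
#' @param side Chosen side ("left"/"right"), ignored for NOBST.
#' @param target_offset Target lateral position (cm).
#' @param params [sim_params()].
#' @return data.frame with columns \code{t_s}, \code{x_cm}, \code{y_cm}.
#' @export
simulate_gaze <- function(layout, duration_s, side = "right",
                          target_offset = 0, params = sim_params()) {
  layout <- build_layout(layout)
  regions <- aoi_regions(layout, target_offset = target_offset)
  # fixation segment boundaries
  t0 <- 0; starts <- numeric(0)
  while (t0 < duration_s) {
    starts <- c(starts, t0)
    t0 <- t0 + rexp(1, 1 / params$gaze_segment_s)
  }
  ends <- c(starts[-1], duration_s)
  anchor_in <- function(rect) c(runif(1, rect["xmin"], rect["xmax"]),
                                runif(1, rect["ymin"], rect["ymax"]))
  out_t <- list(); out_x <- list(); out_y <- list()
  dt <- 1 / params$gaze_rate_hz
  for (k in seq_along(starts)) {
    mid_frac <- ((starts[k] + ends[k]) / 2) / duration_s
    pr <- phase_probs_at(mid_frac, params, layout)
    aoi <- sample(names(pr), 1L, prob = pr)
    anchor <- switch(aoi,
      target = anchor_in(regions$target),
      path   = anchor_in(regions$path_pre),
      margin = {
        pick <- if (runif(1) < params$margin_side_bias) side else
          setdiff(c("left", "right"), side)
        anchor_in(regions[[paste0("margin_", pick)]])
      },
      none = c(layout$walkway_width / 2 + 40, runif(1, 0, layout$walkway_length)))
    tt <- seq(starts[k], ends[k], by = dt)
    if (length(tt) == 0L) next
    out_t[[k]] <- tt
    out_x[[k]] <- anchor[1] + rnorm(length(tt), 0, params$gaze_jitter_sd)
    out_y[[k]] <- anchor[2] + rnorm(length(tt), 0, params$gaze_jitter_sd)
  }
  data.frame(t_s = unlist(out_t), x_cm = unlist(out_x),
             y_cm = unlist(out_y))
}

#' Simulate the path-selection judgment test
#'
#' Each simulated rater rates, on a 0-10 scale, which side they would take
#' for each target offset; the expected rating is 10 x P(right) under a
#' logistic psychometric with the configured 50% crossing and slope, plus
#' bounded Gaussian noise.
#'
#' @param offsets Target offsets (cm), typically \code{seq(-35, 35, 5)}.
#' @param params [sim_params()].
#' @param n_raters Number of simulated raters (default
#'   \code{params$n_participants}).
#' @return data.frame with columns \code{rater}, \code{offset_cm},
#'   \code{rating}.
#' @export
simulate_judgment <- function(offsets = seq(-35, 35, by = 5),
                              params = sim_params(),
                              n_raters = params$n_participants) {
  if (any(abs(offsets) > 35))
    stop("judgment-test offsets are limited to +/- 35 cm", call. = FALSE)
  grid <- expand.grid(rater = seq_len(n_raters), offset_cm = offsets,
                      KEEP.OUT.ATTRS = FALSE)
  p <- plogis(params$judgment_slope *
                (grid$offset_cm - params$judgment_threshold))
  rating <- 10 * p + rnorm(nrow(grid), 0, params$judgment_noise_sd)
  grid$rating <- pmin(10, pmax(0, rating))
  grid[order(grid$rater, grid$offset_cm), ]
}

#' Generate a full synthetic dataset
#'
#' Runs the complete 8 condition x 3 target x n-trials design for every
#' simulated participant: path choice from the logistic model (with
#' participant-level coefficient jitter), start foot, trajectory, and gaze
#' stream.  Fully reproducible from \code{params$seed}.
#'
#' @param params [sim_params()].
#' @param conditions,target_offsets Design cells (defaults: full design).
#' @param keep_samples Keep per-trial trajectory/gaze samples (default
#'   TRUE; set FALSE for choice-only studies at large n).
#' @return List of class \code{pathgaze_dataset} with elements
#'   \code{trials} (one row per trial), \code{gaze} and \code{trajectory}
#'   (long-format sample tables keyed by \code{trial_id}), and
#'   \code{truth} (the generating parameters).
#' @export
generate_dataset <- function(params = sim_params(), conditions = 1:8,
                             target_offsets = c(-30, 0, 30),
                             keep_samples = TRUE) {
  set.seed(params$seed)
  layouts <- lapply(conditions, build_layout)
  names(layouts) <- as.character(conditions)
  trial_rows <- list(); gaze_rows <- list(); traj_rows <- list()
  id <- 0L
  participant_coefs <- vector("list", params$n_participants)
  for (p in seq_len(params$n_participants)) {
    jit <- runif(length(params$choice_coefficients),
                 1 - params$participant_sd, 1 + params$participant_sd)
    pc <- params$choice_coefficients * jit
    participant_coefs[[p]] <- pc
    for (ci in seq_along(conditions)) {
      layout <- layouts[[ci]]
      for (to in target_offsets) {
        feats <- geometry_features(layout, to)
        tgt_pos <- if (to < 0) "left" else if (to > 0) "right" else "middle"
        for (tr in seq_len(params$n_trials_per_cell)) {
          id <- id + 1L
          if (has_obstacle(layout)) {
            choice <- simulate_choice(feats, pc)
            side <- if (choice == 1L) "right" else "left"
          } else {
            side <- NA_character_
          }
          start_foot <- if (runif(1) < params$start_foot_p_right[[tgt_pos]])
            "right" else "left"
          traj <- simulate_trajectory(layout, if (is.na(side)) "right" else side,
                                      to, params)
          duration <- max(traj$t_s)
          gaze <- simulate_gaze(layout, duration, if (is.na(side)) "right"
                                else side, to, params)
          trial_rows[[id]] <- data.frame(
            trial_id = id, participant = p,
            condition = conditions[[ci]], target_offset_cm = to,
            trial = tr, chosen_side = side, start_foot = start_foot,
            duration_s = duration, stringsAsFactors = FALSE)
          if (keep_samples) {
            traj$trial_id <- id
            gaze$trial_id <- id
            traj_rows[[id]] <- traj
            gaze_rows[[id]] <- gaze
          }
        }
      }
    }
  }
  structure(list(
    trials = do.call(rbind, trial_rows),
    trajectory = if (keep_samples) do.call(rbind, traj_rows) else NULL,
    gaze = if (keep_samples) do.call(rbind, gaze_rows) else NULL,
    truth = list(params = params,
                 participant_coefficients = participant_coefs)
  ), class = "pathgaze_dataset")
}

#' @export
print.pathgaze_dataset <- function(x, ...) {
  cat("<pathgaze_dataset> ", nrow(x$trials), " trials, ",
      length(unique(x$trials$participant)), " participants\n", sep = "")
  invisible(x)
}

#' Write a dataset to plain-text artifacts
#'
#' @param dataset A \code{pathgaze_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.  Writes \code{trials.csv},
#'   \code{trajectory.csv}, \code{gaze.csv} and \code{truth.json}.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dataset$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  if (!is.null(dataset$trajectory))
    write.csv(dataset$trajectory, file.path(dir, "trajectory.csv"),
              row.names = FALSE)
  if (!is.null(dataset$gaze))
    write.csv(dataset$gaze, file.path(dir, "gaze.csv"), row.names = FALSE)
  truth <- dataset$truth
  truth$params$gaze_phase_model <- as.list(truth$params$gaze_phase_model)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
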