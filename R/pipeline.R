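#' Default pipeline configuration
#'
#' A complete, valid configuration for [run_pipeline()].  Blocks mirror
#' the package modules: \code{sim} is passed to [sim_params()], \code{aoi}
#' to [aoi_regions()], \code{kde} to [allocation_map()], \code{scanpath}
#' controls encoding/scoring, \code{model} the inference stage.
#'
#' @param seed Root seed recorded in the config and used by every
#'   stochastic stage.
#' @return A nested list of class \code{pipeline_config}.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sim = list(n_participants = 12, n_trials_per_cell = 3),
    aoi = list(target_halo = 10, margin_halo = 10),
    kde = list(bandwidth = 15, grid_n = 40),
    scanpath = list(graded = FALSE, gap_mode = "gap", export_fasta = TRUE),
    model = list(n_surrogates = 500, lambda = "cv", loocv_unit = "trial"),
    judgment = list(offsets = seq(-35, 35, by = 5))
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with (a subset of) the blocks of
#'   [default_pipeline_config()]; missing entries take defaults.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  for (blk in names(user)) {
    if (is.list(cfg[[blk]]) && is.list(user[[blk]])) {
      for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
    } else cfg[[blk]] <- user[[blk]]
  }
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(config) {
  problems <- character(0)
  if (is.null(config$seed) || !is.finite(config$seed))
    problems <- c(problems, "seed: missing or non-finite")
  if (!is.null(config$model$n_surrogates) &&
      config$model$n_surrogates < 100)
    problems <- c(problems, "model.n_surrogates: must be >= 100")
  if (!is.null(config$judgment$offsets) &&
      any(abs(config$judgment$offsets) > 35))
    problems <- c(problems, "judgment.offsets: limited to +/- 35 cm")
  if (length(problems) > 0)
    stop("invalid pipeline config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_artifact <- function(df, path, stage, seed, hash) {
  df$stage <- stage; df$seed <- seed; df$config_hash <- hash
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact: ", path,
         " (run the '", producer, "' stage first)", call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}

log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> features -> sequence -> model -> report over a
#' directory of plain-text artifacts.  Each stage reads its predecessors'
#' CSV outputs, every table carries provenance columns (stage, seed,
#' config hash), and a run manifest records the configuration.  With a
#' fixed config and seed the whole tree is reproducible.
#'
#' @param stage One of "all", "simulate", "features", "sequence",
#'   "model", "report".
#' @param config A \code{pipeline_config}, or path to a JSON config.
#' @param out_dir Output directory.
#' @param seed Optional override of \code{config$seed}.
#' @return \code{out_dir}, invisibly.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "features",
                                   "sequence", "model", "report"),
                         config = default_pipeline_config(),
                         out_dir, seed = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stages <- if (stage == "all")
    c("simulate", "features", "sequence", "model", "report") else stage
  timing <- list()
  for (st in stages) {
    t0 <- Sys.time()
    log_stage("stage ", st, " started")
    switch(st,
           simulate = stage_simulate(config, out_dir, hash),
           features = stage_features(config, out_dir, hash),
           sequence = stage_sequence(config, out_dir, hash),
           model = stage_model(config, out_dir, hash),
           report = stage_report(config, out_dir, hash))
    timing[[st]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log_stage("stage ", st, " done (", round(timing[[st]], 1), " s)")
  }
  manifest <- list(package = "pathgaze",
                   version = as.character(utils::packageVersion("pathgaze")),
                   stages = stages, seed = config$seed,
                   config_hash = hash, config = config,
                   timing_s = timing)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

stage_simulate <- function(config, out_dir, hash) {
  params <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
  ds <- generate_dataset(params)
  write_artifact(ds$trials, file.path(out_dir, "trials.csv"),
                 "simulate", config$seed, hash)
  write.csv(ds$trajectory, file.path(out_dir, "trajectory.csv"),
            row.names = FALSE)
  write.csv(ds$gaze, file.path(out_dir, "gaze.csv"), row.names = FALSE)
  jd <- simulate_judgment(config$judgment$offsets, params)
  write_artifact(jd, file.path(out_dir, "judgment.csv"),
                 "simulate", config$seed, hash)
  truth <- list(choice_coefficients =
                  as.list(params$choice_coefficients),
                judgment_threshold = params$judgment_threshold,
                judgment_slope = params$judgment_slope)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_features <- function(config, out_dir, hash) {
  trials <- require_artifact(file.path(out_dir, "trials.csv"), "simulate")
  gaze <- require_artifact(file.path(out_dir, "gaze.csv"), "simulate")
  geom <- feature_table()
  rows <- list()
  by_trial <- split(gaze, gaze$trial_id)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    g <- by_trial[[as.character(tr$trial_id)]]
    regions <- aoi_regions(tr$condition, target_offset = tr$target_offset_cm,
                           target_halo = config$aoi$target_halo,
                           margin_halo = config$aoi$margin_halo)
    dw <- gaze_dwell(g, regions)
    a <- if (!is.null(regions$margin_left))
      amgr(dwell_left = dw[["S_left"]], dwell_right = dw[["S_right"]])
    else NA_real_
    rows[[i]] <- data.frame(trial_id = tr$trial_id,
                            dwell_T = dw[["T"]], dwell_P = dw[["P"]],
                            dwell_SL = dw[["S_left"]],
                            dwell_SR = dw[["S_right"]],
                            dwell_none = dw[["none"]], amgr = a)
  }
  feats <- merge(trials, do.call(rbind, rows), by = "trial_id")
  key <- geom[, c("condition", "target_offset_cm", "delta_theta",
                  "delta_d", "amr")]
  feats <- merge(feats, key, by = c("condition", "target_offset_cm"),
                 sort = FALSE)
  feats <- feats[order(feats$trial_id), ]
  write_artifact(feats, file.path(out_dir, "features.csv"),
                 "features", config$seed, hash)
  write_artifact(gaze_frequency(trials, gaze),
                 file.path(out_dir, "gaze_frequency.csv"),
                 "features", config$seed, hash)
  write_feature_table(geom, file.path(out_dir, "geometry.csv"))
  # one allocation map per condition (all trials pooled)
  for (cond in unique(trials$condition)) {
    sel <- trials$condition == cond
    g <- gaze[gaze$trial_id %in% trials$trial_id[sel], , drop = FALSE]
    regions <- aoi_regions(cond)
    map <- allocation_map(g, duration_s = sum(trials$duration_s[sel]),
                          regions = regions,
                          bandwidth = config$kde$bandwidth,
                          grid_n = config$kde$grid_n)
    write_allocation_map(map, file.path(out_dir,
                                        sprintf("allocation_c%s.tsv", cond)))
  }
}

stage_sequence <- function(config, out_dir, hash) {
  trials <- require_artifact(file.path(out_dir, "trials.csv"), "simulate")
  gaze <- require_artifact(file.path(out_dir, "gaze.csv"), "simulate")
  enc <- encode_trial_scanpaths(trials, gaze,
                                gap_mode = config$scanpath$gap_mode)
  if (isTRUE(config$scanpath$export_fasta))
    export_fasta(enc$scanpaths, file.path(out_dir, "scanpaths.fasta"))
  scoring <- scanmatch_scoring(graded = isTRUE(config$scanpath$graded))
  sim <- similarity_matrix(enc$scanpaths, enc$condition, scoring)
  write_artifact(as.data.frame(sim$mean),
                 file.path(out_dir, "similarity_mean.csv"),
                 "sequence", config$seed, hash)
  write_artifact(as.data.frame(sim$sd),
                 file.path(out_dir, "similarity_sd.csv"),
                 "sequence", config$seed, hash)
  write_artifact(sim$scores, file.path(out_dir, "similarity_scores.csv"),
                 "sequence", config$seed, hash)
  # characteristic sequence and matrix C per condition
  chars <- list()
  for (cond in sort(unique(enc$condition))) {
    sp <- enc$scanpaths[enc$condition == cond]
    mats <- scanpath_matrices(sp)
    bary <- characteristic_scanpath(sp)
    chars[[length(chars) + 1L]] <-
      data.frame(condition = cond, segment = 1:100,
                 matrix_c = mats$matrix_c, barycenter = as.numeric(bary))
  }
  write_artifact(do.call(rbind, chars),
                 file.path(out_dir, "characteristic_sequences.csv"),
                 "sequence", config$seed, hash)
  invisible(sim$f_statistic)
}

stage_model <- function(config, out_dir, hash) {
  feats <- require_artifact(file.path(out_dir, "features.csv"), "features")
  obs <- feats[!is.na(feats$chosen_side), ]
  choice <- as.integer(obs$chosen_side == "right")
  target_pos <- ifelse(obs$target_offset_cm < 0, "left",
                       ifelse(obs$target_offset_cm > 0, "right", "middle"))
  # univariate fits in the published layout
  uni_rows <- list()
  add_uni <- function(label, x, ch) {
    f <- tryCatch(fit_choice_univariate(x, ch), error = function(e) NULL)
    uni_rows[[length(uni_rows) + 1L]] <<- data.frame(
      feature = label,
      coefficient = if (is.null(f)) NA_real_ else f$coefficient,
      p_value = if (is.null(f)) NA_real_ else f$p_value,
      separation = if (is.null(f)) NA else f$separation)
  }
  add_uni("delta_theta", obs$delta_theta, choice)
  for (tp in c("middle", "left", "right")) {
    sel <- target_pos == tp
    add_uni(paste0("delta_d_", tp), obs$delta_d[sel], choice[sel])
    add_uni(paste0("amr_", tp), obs$amr[sel], choice[sel])
  }
  write_artifact(do.call(rbind, uni_rows),
                 file.path(out_dir, "univariate_fits.csv"),
                 "model", config$seed, hash)
  # multivariate sparse model with bootstrap, partition and LOOCV
  mv <- fit_choice_multivariate(obs[, c("delta_theta", "delta_d", "amr")],
                                choice, lambda = config$model$lambda)
  bt <- bootstrap_effects(obs[, c("delta_theta", "delta_d", "amr")],
                          choice, fit = mv,
                          n_surrogates = config$model$n_surrogates,
                          seed = config$seed + 1L)
  part <- effect_partition(mv)
  unit <- if (identical(config$model$loocv_unit, "participant"))
    obs$participant else "trial"
  cv <- loocv_accuracy(obs[, c("delta_theta", "delta_d", "amr")],
                       choice, unit = unit)
  mv_tab <- data.frame(feature = names(mv$effects),
                       effect = unname(mv$effects),
                       ci_low = bt$ci[1, ], ci_high = bt$ci[2, ],
                       p_value = unname(bt$p_values),
                       partition_pct = unname(part[names(mv$effects)]))
  write_artifact(mv_tab, file.path(out_dir, "multivariate_fit.csv"),
                 "model", config$seed, hash)
  # gaze-ratio models on trials with defined AMGR
  ok <- !is.na(obs$amgr)
  am <- fit_amgr_models(obs$amgr[ok], obs$amr[ok], choice[ok])
  am_tab <- data.frame(
    model = c("univariate", "bivariate", "bivariate"),
    feature = c("amgr", "amgr", "amr"),
    coefficient = c(am$univariate$coefficient,
                    unname(am$bivariate$coefficients)),
    p_value = c(am$univariate$p_value, unname(am$bivariate$p_values)))
  write_artifact(am_tab, file.path(out_dir, "amgr_fits.csv"),
                 "model", config$seed, hash)
  # judgment threshold
  jd <- require_artifact(file.path(out_dir, "judgment.csv"), "simulate")
  jc <- judgment_threshold(jd)
  jl <- list(threshold_cm = jc$threshold_cm, slope = jc$slope,
             extrapolated = jc$extrapolated,
             loocv_accuracy_pct = cv$accuracy_pct,
             loocv_sd_pct = cv$sd_pct)
  jsonlite::write_json(jl, file.path(out_dir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_report <- function(config, out_dir, hash) {
  feats <- require_artifact(file.path(out_dir, "features.csv"), "features")
  trials <- require_artifact(file.path(out_dir, "trials.csv"), "simulate")
  traj <- require_artifact(file.path(out_dir, "trajectory.csv"), "simulate")
  obs <- feats[!is.na(feats$chosen_side), ]
  choice <- as.integer(obs$chosen_side == "right")
  tgt <- ifelse(obs$target_offset_cm < 0, "left",
                ifelse(obs$target_offset_cm > 0, "right", "middle"))
  # probability-curve data (choice probability vs each decision feature)
  for (feat in c("delta_d", "delta_theta", "amr")) {
    tab <- suppressWarnings(
      choice_probability_table(obs[[feat]], choice, tgt))
    write_artifact(tab, file.path(out_dir,
                                  sprintf("prob_curve_%s.csv", feat)),
                   "report", config$seed, hash)
  }
  write_artifact(speed_summary(trials, traj),
                 file.path(out_dir, "speed_summary.csv"),
                 "report", config$seed, hash)
  sf <- start_foot_summary(trials)
  write_artifact(sf$table, file.path(out_dir, "start_foot.csv"),
                 "report", config$seed, hash)
  jd <- require_artifact(file.path(out_dir, "judgment.csv"), "simulate")
  agg <- aggregate(rating ~ offset_cm, jd, mean)
  agg$p_right <- agg$rating / 10
  write_artifact(agg, file.path(out_dir, "judgment_curve.csv"),
                 "report", config$seed, hash)
  jsonlite::write_json(
    list(start_foot_choice_correlation = sf$correlation),
    file.path(out_dir, "report_summary.json"),
    auto_unbox = TRUE, digits = NA)
}
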