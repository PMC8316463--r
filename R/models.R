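#' Univariate logistic choice regression
#'
#' Maximum-likelihood logistic regression of path choice (right = 1,
#' left = 0) on a single decision feature, with the Wald p-value for the
#' slope.  Complete or quasi-complete separation is detected and flagged;
#' the slope is then reported as the (unbounded) estimate at the iteration
#' cap.
#'
#' @param x Numeric feature vector.
#' @param choice Integer/logical vector of choices (1 = right).
#' @return List: \code{coefficient}, \code{intercept}, \code{p_value},
#'   \code{se}, \code{separation} (logical), \code{fit} (the glm).
#' @export
fit_choice_univariate <- function(x, choice) {
  choice <- as.integer(choice)
  stopifnot(length(x) == length(choice), all(choice %in% 0:1))
  if (length(unique(choice)) < 2L)
    stop("both choice classes must be present", call. = FALSE)
  if (length(unique(x[is.finite(x)])) < 2L)
    stop("feature is constant; slope undefined", call. = FALSE)
  fit <- suppressWarnings(glm(choice ~ x, family = binomial()))
  sm <- summary(fit)$coefficients
  eps <- 1e-8
  separated <- !fit$converged ||
    all(fit$fitted.values > 1 - eps | fit$fitted.values < eps)
  list(coefficient = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       se = unname(sm[2, 2]),
       p_value = unname(sm[2, 4]),
       separation = separated,
       fit = fit)
}

standardize_columns <- function(m) {
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  scl[scl == 0] <- 1
  list(x = sweep(sweep(m, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

choice_design_matrix <- function(features, interactions = TRUE) {
  m <- as.matrix(features[, c("delta_theta", "delta_d", "amr")])
  std <- standardize_columns(m)
  x <- std$x
  if (interactions) {
    x <- cbind(x,
               "delta_theta:delta_d" = x[, "delta_theta"] * x[, "delta_d"],
               "delta_theta:amr" = x[, "delta_theta"] * x[, "amr"])
  }
  attr(x, "center") <- std$center
  attr(x, "scale") <- std$scale
  x
}

#' Multivariate sparse logistic choice model
#'
#' Fits the three-feature choice model (deviation-angle difference,
#' relative distance, avoidance-margin ratio, plus the two interactions of
#' distance and margin ratio with deviation angle) on features
#' standardised over the design.  Feature selection uses an L1 (LASSO)
#' penalty chosen by internal cross-validation; the selected set is then
#' refit by unpenalised maximum likelihood so the reported effects are not
#' shrunk.
#'
#' @param features data.frame with \code{delta_theta}, \code{delta_d},
#'   \code{amr}.
#' @param choice 0/1 choices (1 = right).
#' @param interactions Include the two deviation-angle interactions.
#' @param lambda Either "cv" (default: \code{cv.glmnet} lambda.min) or a
#'   numeric penalty.
#' @param nfolds Folds for the internal CV.
#' @return Object of class \code{choice_model_fit}: standardized-scale
#'   \code{effects} (refit coefficients), \code{intercept},
#'   \code{selected}, \code{lambda}, scaling attributes, and the refit
#'   \code{glm}.
#' @export
fit_choice_multivariate <- function(features, choice, interactions = TRUE,
                                    lambda = "cv", nfolds = 10) {
  choice <- as.integer(choice)
  if (length(unique(choice)) < 2L)
    stop("both choice classes must be present", call. = FALSE)
  x <- choice_design_matrix(features, interactions)
  dup <- duplicated(t(x))
  if (any(dup))
    warning("collinear (duplicate) feature columns: ",
            paste(colnames(x)[dup], collapse = ", "))
  if (identical(lambda, "cv")) {
    cv <- glmnet::cv.glmnet(x, choice, family = "binomial", alpha = 1,
                            nfolds = nfolds, standardize = FALSE)
    lam <- cv$lambda.min
  } else lam <- lambda
  l1 <- glmnet::glmnet(x, choice, family = "binomial", alpha = 1,
                       lambda = lam, standardize = FALSE)
  beta <- as.numeric(l1$beta)
  names(beta) <- rownames(l1$beta)
  selected <- names(beta)[beta != 0]
  # unpenalised refit on the selected set for unbiased effects
  effects <- setNames(rep(0, ncol(x)), colnames(x))
  if (length(selected) > 0) {
    df <- data.frame(choice = choice, x[, selected, drop = FALSE],
                     check.names = FALSE)
    refit <- suppressWarnings(glm(choice ~ ., data = df,
                                  family = binomial()))
    effects[selected] <- coef(refit)[-1]
    intercept <- unname(coef(refit)[1])
  } else {
    refit <- suppressWarnings(glm(choice ~ 1, family = binomial()))
    intercept <- unname(coef(refit)[1])
  }
  structure(list(effects = effects, intercept = intercept,
                 selected = selected, lambda = lam,
                 lasso_coefficients = beta,
                 center = attr(x, "center"), scale = attr(x, "scale"),
                 interactions = interactions, fit = refit,
                 features = features, choice = choice),
            class = "choice_model_fit")
}

#' @export
print.choice_model_fit <- function(x, ...) {
  cat("<choice_model_fit> standardized effects (L1-selected, ML refit):\n")
  print(round(x$effects, 4))
  if (!is.null(x$partition)) {
    cat("effect partition (%):\n"); print(round(x$partition, 2))
  }
  invisible(x)
}

#' Surrogate bootstrap inference for choice-model effects
#'
#' Two seeded resampling procedures, reflecting the two readings of a
#' "bootstrap with shuffled surrogate data": (a) label-shuffle surrogates
#' give a null distribution per effect and a p-value (the fraction of
#' surrogate |effect| at least as large as observed); (b) case-resampled
#' refits give percentile 95% confidence intervals.
#'
#' @param features,choice Data as in [fit_choice_multivariate()]; for a
#'   univariate model pass a one-column data.frame via \code{fitter}.
#' @param fitter Function(features, choice) returning a named numeric
#'   vector of effects.  Default refits the multivariate model with the
#'   fixed penalty of \code{fit} (no re-CV inside resamples).
#' @param fit A \code{choice_model_fit} used for the default fitter and
#'   the observed effects.
#' @param n_surrogates Number of shuffles/resamples (>= 100; default 2000).
#' @param seed RNG seed.
#' @return List: \code{observed}, \code{p_values}, \code{ci} (2 x k matrix
#'   of percentile bounds), \code{n_surrogates}, \code{seed}.
#' @export
bootstrap_effects <- function(features, choice, fit = NULL, fitter = NULL,
                              n_surrogates = 2000, seed = 1L) {
  if (n_surrogates < 100)
    stop("n_surrogates must be at least 100", call. = FALSE)
  choice <- as.integer(choice)
  if (is.null(fitter)) {
    if (is.null(fit)) fit <- fit_choice_multivariate(features, choice)
    lam <- fit$lambda
    interactions <- fit$interactions
    fitter <- function(f, ch)
      fit_choice_multivariate(f, ch, interactions = interactions,
                              lambda = lam)$effects
  }
  observed <- fitter(features, choice)
  k <- length(observed)
  set.seed(seed)
  null_mat <- matrix(NA_real_, n_surrogates, k)
  for (b in seq_len(n_surrogates)) {
    null_mat[b, ] <- tryCatch(fitter(features, sample(choice)),
                              error = function(e) rep(NA_real_, k))
  }
  p <- vapply(seq_len(k), function(j) {
    nm <- null_mat[, j]
    mean(abs(nm[!is.na(nm)]) >= abs(observed[j]))
  }, numeric(1))
  boot_mat <- matrix(NA_real_, n_surrogates, k)
  n <- length(choice)
  for (b in seq_len(n_surrogates)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_mat[b, ] <- tryCatch(
      fitter(features[idx, , drop = FALSE], choice[idx]),
      error = function(e) rep(NA_real_, k))
  }
  ci <- apply(boot_mat, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  se <- apply(boot_mat, 2, sd, na.rm = TRUE)
  colnames(ci) <- names(observed)
  list(observed = observed, p_values = setNames(p, names(observed)),
       ci = ci, se = setNames(se, names(observed)),
       n_surrogates = n_surrogates, seed = seed)
}

#' Partition of the total effect across the three main features
#'
#' Each main effect's share is its absolute standardized effect divided by
#' the sum of the three absolute main effects, as a percentage summing to
#' 100.  Interactions are excluded from the denominator.  The formula is a
#' package reconstruction of the published "ratio to total effect"; the
#' original computation is not printed anywhere.
#'
#' @param fit A \code{choice_model_fit}, or a named numeric vector of
#'   effects containing \code{delta_theta}, \code{delta_d}, \code{amr}.
#' @return Named numeric vector of percentages summing to 100.
#' @export
effect_partition <- function(fit) {
  eff <- if (inherits(fit, "choice_model_fit")) fit$effects else fit
  main <- abs(eff[c("delta_theta", "delta_d", "amr")])
  if (any(is.na(main))) stop("main effects missing", call. = FALSE)
  if (sum(main) == 0) stop("all main effects are zero", call. = FALSE)
  main / sum(main) * 100
}

#' Leave-one-out cross-validated accuracy
#'
#' Refits the model with each unit (trial row, or participant block) held
#' out and predicts the held-out choice at a 0.5 threshold (a predicted
#' probability of exactly 0.5 counts as incorrect).  Accuracy is reported
#' as mean and SD of per-fold correctness.
#'
#' @param features,choice Data as in [fit_choice_multivariate()].
#' @param unit "trial" (default) or a vector of participant ids defining
#'   the fold blocks.
#' @param fitter Function(features, choice) returning a prediction
#'   function(features) -> probability.  The default fits the unpenalised
#'   three-feature logistic model (no interactions) for speed and
#'   determinism inside folds.
#' @return List: \code{accuracy_pct}, \code{sd_pct}, \code{n_folds},
#'   \code{fold_correct}.
#' @export
loocv_accuracy <- function(features, choice, unit = "trial",
                           fitter = NULL) {
  choice <- as.integer(choice)
  n <- length(choice)
  stopifnot(nrow(features) == n)
  folds <- if (identical(unit, "trial")) seq_len(n) else {
    stopifnot(length(unit) == n)
    match(unit, unique(unit))
  }
  uf <- unique(folds)
  if (length(uf) < 2L) stop("need at least 2 folds", call. = FALSE)
  if (is.null(fitter)) {
    fitter <- function(f, ch) {
      df <- data.frame(ch = ch, f[, c("delta_theta", "delta_d", "amr")])
      m <- suppressWarnings(glm(ch ~ delta_theta + delta_d + amr,
                                data = df, family = binomial()))
      function(newf) predict(m, newdata = newf, type = "response")
    }
  }
  correct <- numeric(0)
  fold_acc <- numeric(length(uf))
  for (i in seq_along(uf)) {
    hold <- folds == uf[i]
    if (length(unique(choice[!hold])) < 2L)
      stop("degenerate fold: one class absent in training data",
           call. = FALSE)
    pred <- fitter(features[!hold, , drop = FALSE], choice[!hold])
    p <- pred(features[hold, , drop = FALSE])
    ok <- as.integer((p > 0.5) == (choice[hold] == 1L) & p != 0.5)
    fold_acc[i] <- mean(ok)
    correct <- c(correct, ok)
  }
  list(accuracy_pct = 100 * mean(fold_acc),
       sd_pct = 100 * sd(fold_acc),
       n_folds = length(uf),
       fold_correct = fold_acc)
}

#' Psychometric threshold of the judgment test
#'
#' Treats mean ratings / 10 as P(right) and fits a two-parameter logistic
#' psychometric \eqn{P(x) = logis(k (x - x_0))} by least squares; the
#' threshold is the fitted 50% crossing \eqn{x_0}.  A crossing outside the
#' offset range is flagged as extrapolated.
#'
#' @param ratings data.frame with \code{offset_cm} and \code{rating}
#'   (0-10), e.g. from [simulate_judgment()]; multiple raters are averaged
#'   per offset.
#' @return List of class \code{judgment_curve}: \code{threshold_cm},
#'   \code{slope}, \code{offsets}, \code{p_right}, \code{fitted},
#'   \code{extrapolated}, \code{monotone_increasing_violations}.
#' @export
judgment_threshold <- function(ratings) {
  stopifnot(all(c("offset_cm", "rating") %in% names(ratings)))
  agg <- aggregate(rating ~ offset_cm, ratings, mean)
  agg <- agg[order(agg$offset_cm), ]
  if (nrow(agg) < 4L)
    stop("need ratings at >= 4 distinct offsets", call. = FALSE)
  p <- pmin(1, pmax(0, agg$rating / 10))
  x <- agg$offset_cm
  loss <- function(par) sum((plogis(par[2] * (x - par[1])) - p)^2)
  # crossing init: first sign change of p - 0.5, else range midpoint
  init_th <- if (any(p < 0.5) && any(p > 0.5))
    (x[max(which(p < 0.5))] + x[min(which(p > 0.5))]) / 2
  else mean(range(x))
  opt <- optim(c(init_th, 0.2), loss, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  th <- opt$par[1]; k <- opt$par[2]
  mono_viol <- sum(diff(p) < -1e-9)  # p should be non-decreasing in offset
  structure(list(threshold_cm = th, slope = k,
                 offsets = x, p_right = p,
                 fitted = plogis(k * (x - th)),
                 extrapolated = th < min(x) || th > max(x),
                 monotone_increasing_violations = mono_viol,
                 converged = opt$convergence == 0),
            class = "judgment_curve")
}

#' @export
print.judgment_curve <- function(x, ...) {
  side <- if (x$threshold_cm < 0) "left of" else if (x$threshold_cm > 0)
    "right of" else "at"
  cat(sprintf(
    "<judgment_curve> 50%% crossing at %.1f cm (%s shelf centre)%s\n",
    x$threshold_cm, side, if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Gaze-ratio choice models
#'
#' Univariate (AMGR) and bivariate (AMGR + AMR) logistic regressions of
#' path choice.  Rows with undefined AMGR (no margin gaze) are refused:
#' filter them upstream.
#'
#' @param amgr Avoidance-margin gaze ratios in [-1, 1].
#' @param amr Avoidance-margin ratios.
#' @param choice 0/1 choices (1 = right).
#' @return List with \code{univariate} (as [fit_choice_univariate()]) and
#'   \code{bivariate} (glm coefficients, se, p-values).
#' @export
fit_amgr_models <- function(amgr, amr, choice) {
  if (any(is.na(amgr)))
    stop("undefined AMGR rows present; filter them before fitting",
         call. = FALSE)
  uni <- fit_choice_univariate(amgr, choice)
  df <- data.frame(choice = as.integer(choice), amgr = amgr, amr = amr)
  bi <- suppressWarnings(glm(choice ~ amgr + amr, data = df,
                             family = binomial()))
  sm <- summary(bi)$coefficients
  list(univariate = uni,
       bivariate = list(coefficients = coef(bi)[-1],
                        intercept = unname(coef(bi)[1]),
                        se = sm[-1, 2], p_values = sm[-1, 4], fit = bi))
}

#' Empirical choice probability by binned feature
#'
#' Choice fractions (P(right)) with exact binomial confidence intervals
#' per feature bin and target position; the long format feeds probability
#' curve plots directly.
#'
#' @param feature Numeric feature values, one per trial.
#' @param choice 0/1 choices.
#' @param target Target-position labels, one per trial (optional).
#' @param breaks Bin breaks or number of bins (default 8).
#' @return data.frame: target, bin midpoint, n, p_right, ci_low, ci_high.
#' @export
choice_probability_table <- function(feature, choice, target = NULL,
                                     breaks = 8) {
  choice <- as.integer(choice)
  if (is.null(target)) target <- rep("all", length(choice))
  if (length(breaks) == 1L)
    breaks <- seq(min(feature), max(feature), length.out = breaks + 1L)
  bin <- cut(feature, breaks, include.lowest = TRUE)
  mids <- (utils::head(breaks, -1) + breaks[-1]) / 2
  out <- list()
  for (tg in unique(target)) {
    for (b in seq_along(levels(bin))) {
      sel <- target == tg & as.integer(bin) == b
      n <- sum(sel)
      if (n == 0L) next
      k <- sum(choice[sel])
      bt <- stats::binom.test(k, n)
      out[[length(out) + 1L]] <- data.frame(
        target = tg, feature_mid = mids[b], n = n, p_right = k / n,
        ci_low = bt$conf.int[1], ci_high = bt$conf.int[2])
    }
  }
  dropped <- length(unique(target)) * length(levels(bin)) - length(out)
  if (dropped > 0)
    warning(dropped, " empty target x bin cells dropped")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
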