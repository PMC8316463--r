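#' Construct a scanpath from symbols
#'
#' A scanpath is the duration-normalised gaze object sequence of one trial:
#' exactly 100 symbols over \code{T} (target), \code{P} (path), \code{S}
#' (avoidance margin, sides merged) and \code{"-"} (no in-AOI gaze in the
#' bin).  The numeric view maps T to 2, P to 5, S to 10 and gaps to NA.
#'
#' @param symbols Character vector of length 100 over T/P/S/-.
#' @param trial_id Optional identifier.
#' @return Object of class \code{scanpath} with fields \code{symbols} and
#'   \code{numeric}.
#' @export
as_scanpath <- function(symbols, trial_id = NA) {
  symbols <- as.character(symbols)
  if (length(symbols) != 100L)
    stop("a scanpath has exactly 100 symbols, got ", length(symbols),
         call. = FALSE)
  if (!all(symbols %in% AOI_SYMBOLS))
    stop("scanpath symbols must be one of T, P, S, -", call. = FALSE)
  num <- unname(AOI_NUMERIC[symbols])  # NA for "-"
  structure(list(trial_id = trial_id, symbols = symbols, numeric = num),
            class = "scanpath")
}

#' @export
print.scanpath <- function(x, ...) {
  cat("<scanpath ", if (!is.na(x$trial_id)) paste0("#", x$trial_id, " "),
      ">\n  ", paste(x$symbols, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Encode a trial's gaze stream as a scanpath
#'
#' The trial is normalised to its duration and divided into 100 equal time
#' bins.  Each bin takes the majority in-AOI label among its samples (left
#' and right margins merge into \code{S}); ties break toward the label
#' with the longest dwell and then by the fixed order T > S > P.  Bins
#' with no in-AOI samples become gap symbols (or repeat the previous label
#' with \code{gap_mode = "carry"}).
#'
#' @param gaze data.frame with \code{t_s}, \code{x_cm}, \code{y_cm}.
#' @param regions [aoi_regions()].
#' @param duration_s Trial duration; defaults to the last sample time.
#' @param gap_mode "gap" (default) or "carry".
#' @param trial_id Optional identifier.
#' @return A \code{scanpath}.
#' @export
encode_scanpath <- function(gaze, regions, duration_s = NULL,
                            gap_mode = c("gap", "carry"), trial_id = NA) {
  gap_mode <- match.arg(gap_mode)
  if (is.null(nrow(gaze)) || nrow(gaze) == 0L)
    stop("cannot encode a scanpath from an empty gaze stream", call. = FALSE)
  if (is.null(duration_s)) duration_s <- max(gaze$t_s)
  lab <- as.character(label_aoi(gaze$x_cm, gaze$y_cm, regions))
  lab[lab %in% c("S_left", "S_right")] <- "S"
  bin <- pmin(pmax(ceiling(gaze$t_s / duration_s * 100), 1L), 100L)
  symbols <- rep("-", 100L)
  for (b in unique(bin)) {
    counts <- table(lab[bin == b])
    counts <- counts[names(counts) %in% c("T", "S", "P")]
    if (length(counts) == 0L) next
    # majority; ties resolved by dwell (== count) then fixed order T > S > P
    ord <- match(names(counts), c("T", "S", "P"))
    counts <- counts[order(-counts, ord)]
    symbols[b] <- names(counts)[1L]
  }
  if (gap_mode == "carry") {
    last <- "-"
    for (b in seq_len(100L)) {
      if (symbols[b] == "-") symbols[b] <- last else last <- symbols[b]
    }
  }
  as_scanpath(symbols, trial_id = trial_id)
}

#' Scanpath matrix set for a group of trials
#'
#' @param scanpaths List of \code{scanpath} objects.
#' @return List with \code{matrix_a} (N x 100 symbols), \code{matrix_b}
#'   (N x 100 numeric, NA at gaps) and \code{matrix_c} (length-100 column
#'   means of B, gaps ignored).
#' @export
scanpath_matrices <- function(scanpaths) {
  if (length(scanpaths) == 0L) stop("no scanpaths given", call. = FALSE)
  a <- do.call(rbind, lapply(scanpaths, `[[`, "symbols"))
  b <- do.call(rbind, lapply(scanpaths, `[[`, "numeric"))
  cbar <- colMeans(b, na.rm = TRUE)
  list(matrix_a = a, matrix_b = b, matrix_c = cbar)
}

#' Scanpath scoring scheme
#'
#' Substitution scores for the Needleman-Wunsch alignment.  The default is
#' identity scoring (match 1, mismatch 0, inserted-gap score 0).  The
#' graded scheme scores a substitution by closeness of the numeric codes,
#' \code{1 - |n_i - n_j| / 8}, so T-P (3 apart) scores higher than T-S (8
#' apart).  Gap symbols within a sequence earn no credit against anything.
#'
#' @param match,mismatch Scores for identical / differing AOI symbols.
#' @param gap_penalty Additive score for aligning a symbol against an
#'   inserted gap (usually <= 0; default 0).
#' @param graded Use the graded numeric-distance substitution scores.
#' @return List of class \code{scanmatch_scoring} with the 4 x 4
#'   substitution matrix (rows/cols T, P, S, -) and the gap penalty.
#' @export
scanmatch_scoring <- function(match = 1, mismatch = 0, gap_penalty = 0,
                              graded = FALSE) {
  sub <- matrix(mismatch, 4, 4, dimnames = list(AOI_SYMBOLS, AOI_SYMBOLS))
  diag(sub) <- match
  if (graded) {
    num <- c(2, 5, 10)
    for (i in 1:3) for (j in 1:3)
      sub[i, j] <- 1 - abs(num[i] - num[j]) / 8
  }
  sub["-", ] <- 0; sub[, "-"] <- 0
  structure(list(sub = sub, gap_penalty = gap_penalty),
            class = "scanmatch_scoring")
}

scanpath_codes <- function(x) match(x$symbols, AOI_SYMBOLS)

self_score <- function(codes, sub) sum(diag(sub)[codes])

#' Scanpath similarity (ScanMatch-style global alignment)
#'
#' Needleman-Wunsch global alignment score of two scanpaths under the
#' scoring scheme, normalised into [0, 1] by the maximum attainable score
#' (the self-alignment score of the sequence with more scoreable symbols).
#' Identical scanpaths score exactly 1; the score is symmetric.
#'
#' @param a,b \code{scanpath} objects.
#' @param scoring [scanmatch_scoring()].
#' @return Similarity in [0, 1].
#' @export
scanpath_similarity <- function(a, b, scoring = scanmatch_scoring()) {
  stopifnot(inherits(a, "scanpath"), inherits(b, "scanpath"),
            inherits(scoring, "scanmatch_scoring"))
  ca <- scanpath_codes(a); cb <- scanpath_codes(b)
  denom <- max(self_score(ca, scoring$sub), self_score(cb, scoring$sub))
  if (denom <= 0)
    stop("maximum attainable alignment score is not positive under this ",
         "scoring scheme", call. = FALSE)
  raw <- nw_score_cpp(ca, cb, scoring$sub, scoring$gap_penalty)
  min(1, max(0, raw / denom))
}

#' Pairwise similarity summary across condition groups
#'
#' Computes every pairwise scanpath similarity and summarises mean and SD
#' per condition pair.  Within-condition cells exclude self-pairs.  Raw
#' (unnormalised) alignment scores are carried alongside the normalised
#' ones.  An overall one-way F statistic comparing within-condition scores
#' across conditions is attached.
#'
#' @param scanpaths List of \code{scanpath}s.
#' @param condition Vector (length = number of scanpaths) of condition
#'   labels.
#' @param scoring [scanmatch_scoring()].
#' @return List with \code{mean} and \code{sd} (condition x condition
#'   matrices), \code{scores} (long data.frame of all pairs) and
#'   \code{f_statistic}.
#' @export
similarity_matrix <- function(scanpaths, condition,
                              scoring = scanmatch_scoring()) {
  n <- length(scanpaths)
  stopifnot(n >= 2L, length(condition) == n)
  conds <- sort(unique(condition))
  codes <- lapply(scanpaths, scanpath_codes)
  selfs <- vapply(codes, self_score, numeric(1), sub = scoring$sub)
  pairs_i <- integer(0); pairs_j <- integer(0)
  idx <- utils::combn(n, 2)
  raw <- numeric(ncol(idx)); norm <- numeric(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    denom <- max(selfs[i], selfs[j])
    if (denom <= 0) stop("degenerate (all-gap) scanpath pair", call. = FALSE)
    raw[k] <- nw_score_cpp(codes[[i]], codes[[j]], scoring$sub,
                           scoring$gap_penalty)
    norm[k] <- min(1, max(0, raw[k] / denom))
  }
  scores <- data.frame(i = idx[1, ], j = idx[2, ],
                       condition_i = condition[idx[1, ]],
                       condition_j = condition[idx[2, ]],
                       raw = raw, score = norm)
  m <- matrix(NA_real_, length(conds), length(conds),
              dimnames = list(conds, conds))
  s <- m
  for (a in seq_along(conds)) for (b in seq_along(conds)) {
    if (a > b) next
    sel <- (scores$condition_i == conds[a] & scores$condition_j == conds[b]) |
           (scores$condition_i == conds[b] & scores$condition_j == conds[a])
    v <- scores$score[sel]
    m[a, b] <- m[b, a] <- mean(v)
    s[a, b] <- s[b, a] <- sd(v)
  }
  within <- scores[scores$condition_i == scores$condition_j, ]
  fstat <- if (nrow(within) > length(conds) &&
               length(unique(within$condition_i)) > 1) {
    stats::oneway.test(score ~ condition_i, data = within,
                       var.equal = TRUE)$statistic[[1]]
  } else NA_real_
  list(mean = m, sd = s, scores = scores, f_statistic = fstat)
}

impute_gaps <- function(num) {
  # nearest-neighbour style fill so DBA can run on sequences with gap bins
  if (all(is.na(num))) return(NULL)
  idx <- which(!is.na(num))
  filled <- stats::approx(idx, num[idx], xout = seq_along(num),
                          method = "constant", rule = 2, f = 0)$y
  filled
}

#' Characteristic scanpath by DTW barycenter averaging
#'
#' Computes a length-100 consensus numeric sequence for a set of scanpaths
#' by dynamic-time-warping barycenter averaging (DBA): starting from the
#' medoid, each iteration aligns every sequence to the current barycenter
#' by DTW and replaces each barycenter coordinate with the mean of the
#' values aligned to it, until the summed DTW cost stops improving.  Gap
#' bins are filled from the nearest labelled bin before averaging;
#' sequences that are entirely gaps are dropped.
#'
#' @param scanpaths List of \code{scanpath}s (or numeric vectors).
#' @param max_iter Maximum DBA iterations (default 30).
#' @param tol Convergence tolerance on the objective.
#' @return Numeric vector of length 100 with values in [2, 10];
#'   attribute \code{objective} holds the per-iteration summed DTW cost.
#' @export
characteristic_scanpath <- function(scanpaths, max_iter = 30, tol = 1e-6) {
  if (length(scanpaths) == 0L) stop("no scanpaths given", call. = FALSE)
  seqs <- lapply(scanpaths, function(s)
    if (inherits(s, "scanpath")) impute_gaps(s$numeric) else as.numeric(s))
  seqs <- Filter(Negate(is.null), seqs)
  if (length(seqs) == 0L)
    stop("all scanpaths are entirely gaps", call. = FALSE)
  n <- length(seqs)
  # medoid initialisation
  if (n == 1L) {
    bary <- seqs[[1L]]
    attr(bary, "objective") <- 0
    return(bary)
  }
  dsum <- numeric(n)
  for (i in seq_len(n)) {
    dsum[i] <- sum(vapply(seqs, function(s) dtw_cost_cpp(seqs[[i]], s),
                          numeric(1)))
  }
  bary <- seqs[[which.min(dsum)]]
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    # rowsum handles repeated barycenter indices along the warping path
    acc <- numeric(length(bary)); cnt <- numeric(length(bary)); obj <- 0
    for (s in seqs) {
      al <- dtw_path_cpp(bary, s)
      obj <- obj + al$cost
      add <- rowsum(s[al$index2], al$index1)
      ids <- as.integer(rownames(add))
      acc[ids] <- acc[ids] + add[, 1]
      cnt <- cnt + tabulate(al$index1, nbins = length(bary))
    }
    objective <- c(objective, obj)
    new_bary <- ifelse(cnt > 0, acc / cnt, bary)
    if (it > 1 && objective[it - 1] - obj < tol) { bary <- new_bary; break }
    bary <- new_bary
  }
  attr(bary, "objective") <- objective
  bary
}

#' Export scanpaths to FASTA
#'
#' One record per scanpath (residues T/P/S with '-' for gap bins), for use
#' with external alignment viewers.
#'
#' @param scanpaths List of \code{scanpath}s.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
export_fasta <- function(scanpaths, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA export", call. = FALSE)
  if (length(scanpaths) == 0L) {
    warning("no scanpaths to export; writing an empty file")
    file.create(path)
    return(invisible(path))
  }
  ids <- vapply(seq_along(scanpaths), function(i) {
    tid <- scanpaths[[i]]$trial_id
    if (is.na(tid)) paste0("scanpath_", i) else as.character(tid)
  }, character(1))
  seqs <- vapply(scanpaths, function(s) paste(s$symbols, collapse = ""),
                 character(1))
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read scanpaths from FASTA
#' @param path FASTA file written by [export_fasta()].
#' @return List of \code{scanpath}s.
#' @export
read_scanpath_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA import", call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i)
    as_scanpath(strsplit(as.character(set[[i]]), "")[[1]],
                trial_id = names(set)[i]))
}

#' Encode every trial of a dataset
#'
#' @param trials Trial table (needs \code{trial_id}, \code{condition},
#'   \code{target_offset_cm}, \code{duration_s}).
#' @param gaze Long gaze table keyed by \code{trial_id}.
#' @param gap_mode Passed to [encode_scanpath()].
#' @return List with \code{scanpaths} (list) and \code{condition} (vector),
#'   aligned by position.
#' @export
encode_trial_scanpaths <- function(trials, gaze, gap_mode = "gap") {
  sp <- vector("list", nrow(trials))
  by_trial <- split(gaze, gaze$trial_id)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    g <- by_trial[[as.character(tr$trial_id)]]
    regions <- aoi_regions(tr$condition, target_offset = tr$target_offset_cm)
    sp[[i]] <- encode_scanpath(g, regions, duration_s = tr$duration_s,
                               gap_mode = gap_mode, trial_id = tr$trial_id)
  }
  list(scanpaths = sp, condition = trials$condition)
}
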