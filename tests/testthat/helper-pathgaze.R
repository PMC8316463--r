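# Shared fixtures and independent oracles, built in code at test time.

# gaze stream fixture: n samples at a fixed point, spanning `duration` s
gaze_at <- function(x, y, n = 120, duration = 1) {
  data.frame(t_s = seq(0, duration, length.out = n),
             x_cm = rep(x, n), y_cm = rep(y, n))
}

# centre of a rectangular AOI region
region_mid <- function(rect) {
  c(x = mean(rect[c("xmin", "xmax")]), y = mean(rect[c("ymin", "ymax")]))
}

# random scanpath over the full alphabet (including gaps)
rand_scanpath <- function(p_gap = 0.1) {
  sym <- sample(c("T", "P", "S"), 100, replace = TRUE)
  sym[runif(100) < p_gap] <- "-"
  as_scanpath(sym)
}

# Brute-force recursive Needleman-Wunsch oracle (no memoisation),
# independent of the package's dynamic-programming implementation.
nw_oracle <- function(a, b, sub, gap) {
  n <- length(a); m <- length(b)
  if (n == 0L && m == 0L) return(0)
  if (n == 0L) return(m * gap)
  if (m == 0L) return(n * gap)
  max(nw_oracle(a[-n], b[-m], sub, gap) + sub[a[n], b[m]],
      nw_oracle(a[-n], b, sub, gap) + gap,
      nw_oracle(a, b[-m], sub, gap) + gap)
}

# geometry features of the 21 obstacle-condition cells (no NOBST rows)
obstacle_cells <- function() {
  ft <- feature_table()
  ft[!is.na(ft$delta_d), ]
}

# quick logistic slope refit (x, 0/1 y) used for bootstrap SEs in tests
logit_slope <- function(x, y) {
  f <- suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
  unname(f$coefficients[2])
}

# case-resampling bootstrap SE of a univariate logistic slope
boot_slope_se <- function(x, y, B = 200) {
  n <- length(y)
  reps <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    logit_slope(x[i], y[i])
  }, numeric(1))
  sd(reps)
}
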