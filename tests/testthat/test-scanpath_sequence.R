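test_that("encoding normalises any trial to 100 labelled bins", {
  reg <- aoi_regions(1)
  sp <- encode_scanpath(gaze_at(0, 760, n = 240, duration = 2), reg,
                        duration_s = 2)
  expect_identical(sp$symbols, rep("T", 100))
  expect_identical(sp$numeric, rep(2, 100))
  for (dur in c(0.7, 3.21, 6, 11.04)) {
    g <- gaze_at(0, 760, n = max(10, round(dur * 120)), duration = dur)
    expect_length(encode_scanpath(g, reg, duration_s = dur)$symbols, 100)
  }
  # target -> path -> target thirds
  g3 <- rbind(gaze_at(0, 760, n = 100, duration = 1),
              transform(gaze_at(0, 100, n = 100, duration = 1),
                        t_s = t_s + 1.001),
              transform(gaze_at(0, 760, n = 100, duration = 1),
                        t_s = t_s + 2.002))
  s3 <- encode_scanpath(g3, reg, duration_s = 3.002)$symbols
  expect_identical(unique(s3[5:30]), "T")
  expect_identical(unique(s3[40:60]), "P")
  expect_identical(unique(s3[75:95]), "T")
  expect_error(encode_scanpath(gaze_at(0, 0)[0, ], reg), "empty")
})

test_that("gap bins are marked, or carried when requested", {
  reg <- aoi_regions(1)
  g <- rbind(gaze_at(0, 760, n = 50, duration = 1),
             transform(gaze_at(0, 100, n = 50, duration = 1), t_s = t_s + 2))
  sp_gap <- encode_scanpath(g, reg, duration_s = 3)
  expect_true(any(sp_gap$symbols == "-"))
  expect_true(all(is.na(sp_gap$numeric[sp_gap$symbols == "-"])))
  sp_carry <- encode_scanpath(g, reg, duration_s = 3, gap_mode = "carry")
  expect_false(any(sp_carry$symbols == "-"))
  expect_identical(sp_carry$symbols[40], "T")  # carried across the silence
})

test_that("matrix set: symbols, numeric view and gap-ignoring means", {
  one <- as_scanpath(rep("P", 100))
  m1 <- scanpath_matrices(list(one))
  expect_identical(as.numeric(m1$matrix_c), one$numeric)
  two <- scanpath_matrices(list(as_scanpath(rep("T", 100)),
                                as_scanpath(rep("S", 100))))
  expect_identical(as.numeric(two$matrix_c), rep(6, 100))
  same <- replicate(4, as_scanpath(rep(c("T", "S"), 50)), simplify = FALSE)
  expect_identical(as.numeric(scanpath_matrices(same)$matrix_c),
                   same[[1]]$numeric)
  # gaps are excluded from the column mean
  g1 <- as_scanpath(c("T", rep("T", 99)))
  g2 <- as_scanpath(c("-", rep("T", 99)))
  expect_identical(scanpath_matrices(list(g1, g2))$matrix_c[1], 2)
  expect_error(scanpath_matrices(list()), "no scanpaths")
})

test_that("similarity: normalisation, symmetry, scheme behaviour", {
  a <- as_scanpath(rep("T", 100)); s <- as_scanpath(rep("S", 100))
  expect_equal(scanpath_similarity(a, a), 1)
  expect_equal(scanpath_similarity(a, s), 0)
  set.seed(71)
  for (i in 1:20) {
    x <- rand_scanpath(); y <- rand_scanpath()
    sxy <- scanpath_similarity(x, y)
    expect_equal(sxy, scanpath_similarity(y, x))
    expect_gte(sxy, 0); expect_lte(sxy, 1)
    expect_equal(scanpath_similarity(x, x), 1)
  }
  # graded scheme: T is closer to P than to S
  p <- as_scanpath(rep("P", 100))
  graded <- scanmatch_scoring(graded = TRUE)
  expect_gt(scanpath_similarity(a, p, graded),
            scanpath_similarity(a, s, graded))
  # degenerate scoring is refused
  allgap <- as_scanpath(rep("-", 100))
  expect_error(scanpath_similarity(allgap, allgap), "not positive")
})

test_that("alignment equals the brute-force recursive oracle", {
  sc <- scanmatch_scoring()
  set.seed(72)
  for (i in 1:100) {
    na_ <- sample(1:8, 1); nb <- sample(1:8, 1)
    a <- sample(1:3, na_, replace = TRUE)
    b <- sample(1:3, nb, replace = TRUE)
    expect_identical(pathgaze:::nw_score_cpp(a, b, sc$sub, sc$gap_penalty),
                     nw_oracle(a, b, sc$sub, sc$gap_penalty))
  }
  # also under a nonzero gap penalty and graded substitution
  gr <- scanmatch_scoring(graded = TRUE, gap_penalty = -0.3)
  for (i in 1:30) {
    a <- sample(1:3, sample(1:6, 1), replace = TRUE)
    b <- sample(1:3, sample(1:6, 1), replace = TRUE)
    expect_equal(pathgaze:::nw_score_cpp(a, b, gr$sub, gr$gap_penalty),
                 nw_oracle(a, b, gr$sub, gr$gap_penalty))
  }
})

test_that("similarity matrix summarises condition pairs symmetrically", {
  same <- replicate(6, as_scanpath(rep("T", 100)), simplify = FALSE)
  res <- similarity_matrix(same, rep(c("A", "B"), each = 3))
  expect_true(all(res$mean == 1))
  expect_identical(res$mean, t(res$mean))
  # two maximally dissimilar groups
  grp <- c(replicate(3, as_scanpath(rep("T", 100)), simplify = FALSE),
           replicate(3, as_scanpath(rep("S", 100)), simplify = FALSE))
  res2 <- similarity_matrix(grp, rep(c("T", "S"), each = 3))
  expect_equal(res2$mean["S", "T"], 0)
  expect_equal(res2$mean["T", "T"], 1)
  expect_equal(res2$mean["S", "S"], 1)
})

test_that("DBA barycenter: fixed point, bounds and frozen small case", {
  same <- replicate(5, as_scanpath(rep(c("T", "S"), 50)), simplify = FALSE)
  b <- characteristic_scanpath(same)
  expect_equal(as.numeric(b), same[[1]]$numeric)
  # frozen oracle case: identity DTW path, differing coordinate averaged
  small <- characteristic_scanpath(list(c(2, 5, 2), c(2, 10, 2)))
  expect_equal(as.numeric(small), c(2, 7.5, 2))
  set.seed(73)
  sps <- replicate(8, rand_scanpath(), simplify = FALSE)
  bary <- characteristic_scanpath(sps)
  expect_length(bary, 100)
  expect_true(all(bary >= 2 & bary <= 10))
  obj <- attr(bary, "objective")
  expect_true(all(diff(obj) <= 1e-9))
  expect_error(characteristic_scanpath(list()), "no scanpaths")
})

test_that("FASTA export round-trips the symbol sequences", {
  skip_if_not_installed("Biostrings")
  set.seed(74)
  sps <- replicate(3, rand_scanpath(), simplify = FALSE)
  sps[[1]]$trial_id <- "trial_9"
  f <- tempfile(fileext = ".fasta")
  export_fasta(sps, f)
  back <- read_scanpath_fasta(f)
  expect_identical(back[[1]]$symbols, sps[[1]]$symbols)
  expect_identical(back[[2]]$symbols, sps[[2]]$symbols)
  expect_identical(back[[1]]$trial_id, "trial_9")
  f2 <- tempfile(fileext = ".fasta")
  expect_warning(export_fasta(list(), f2), "no scanpaths")
  expect_true(file.exists(f2))
})
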