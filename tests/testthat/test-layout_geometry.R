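test_that("standard conditions reproduce the published margins exactly", {
  tab <- condition_table()
  for (cond in 2:8) {
    am <- avoidance_margins(build_layout(cond))
    row <- tab[tab$condition == cond, ]
    expect_identical(unname(am[["am_left"]]), row$am_left)
    expect_identical(unname(am[["am_right"]]), row$am_right)
  }
  expect_equal(unname(avoidance_margins(build_layout(2))),
               c(83.5, 83.5))
  expect_equal(unname(avoidance_margins(build_layout(7))),
               c(52, 25))
})

test_that("layout construction validates its geometry", {
  expect_error(build_layout(9), "unknown condition")
  expect_error(walkway_layout(250), "does not fit")
  expect_error(walkway_layout(90, obstacle_lateral_offset = 70),
               "does not fit")
  expect_error(walkway_layout(90, obstacle_distance = 800),
               "obstacle_distance")
  expect_error(walkway_layout(90, am_left_override = -3), "override")
})

test_that("derived margins: symmetry, fallback and the published rounding", {
  # centred 135 cm obstacle: derivation and published value agree (39, 39)
  expect_equal(unname(avoidance_margins(walkway_layout(135))), c(39, 39))
  # centred 90 cm: derivation gives 61.5 but the published table prints 61.0
  derived <- avoidance_margins(build_layout(3), use_overrides = FALSE)
  printed <- avoidance_margins(build_layout(3))
  expect_equal(unname(derived), c(61.5, 61.5))
  expect_equal(unname(printed), c(61, 61))
  expect_lt(max(abs(derived - printed)), 1 + 1e-12)
  # sign convention: obstacle shifted right narrows the right margin
  am <- avoidance_margins(walkway_layout(90, obstacle_lateral_offset = 22))
  expect_lt(am[["am_right"]], am[["am_left"]])
  expect_error(avoidance_margins(walkway_layout(0)), "NOBST")
})

test_that("relative distance follows the corner geometry and sign rules", {
  expect_equal(relative_distance(walkway_layout(90))$delta_d, 0)
  expect_gt(relative_distance(
    walkway_layout(90, obstacle_lateral_offset = 15))$delta_d, 0)
  rd <- relative_distance(walkway_layout(90, obstacle_distance = 375))
  expect_equal(rd$d_left, sqrt(375^2 + 45^2))
  expect_equal(rd$d_right, sqrt(375^2 + 45^2))
  expect_error(relative_distance(walkway_layout(0)), "NOBST")
})

test_that("deviation angles: zero at symmetric centre, signed by target side", {
  lay <- walkway_layout(90)
  expect_equal(deviation_angles(lay, 0)$delta_theta, 0)
  expect_gt(deviation_angles(lay, -30)$delta_theta, 0)   # target left
  expect_lt(deviation_angles(lay, 30)$delta_theta, 0)    # target right
  # mirror symmetry for a centred obstacle
  for (k in c(10, 25, 40)) {
    lay45 <- walkway_layout(45, bookcase_width = 90)
    expect_equal(deviation_angles(lay45, min(k, 45))$delta_theta,
                 -deviation_angles(lay45, -min(k, 45))$delta_theta)
  }
  expect_error(deviation_angles(walkway_layout(0), 0), "NOBST")
})

test_that("angles agree with an explicit vector-arithmetic oracle", {
  # oracle: acos of the normalised dot product on corner coordinates
  set.seed(41)
  for (i in 1:100) {
    w <- runif(1, 30, 140)
    off <- runif(1, -1, 1) * (213 - w) / 2 * 0.9
    dist <- runif(1, 200, 600)
    tgt <- runif(1, -45, 45)
    lay <- walkway_layout(w, obstacle_lateral_offset = off,
                          obstacle_distance = dist)
    got <- deviation_angles(lay, tgt)
    v_t <- c(tgt, 750)
    for (side in c("left", "right")) {
      xc <- off + if (side == "right") w / 2 else -w / 2
      v_c <- c(xc, dist)
      cosang <- sum(v_t * v_c) / sqrt(sum(v_t^2) * sum(v_c^2))
      oracle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      expect_equal(got[[paste0("theta_", side)]], oracle,
                   tolerance = 1e-9)
    }
  }
})

test_that("feature table covers the design and preserves duplicates", {
  ft <- feature_table()
  expect_equal(nrow(ft), 24)
  expect_equal(sum(is.na(ft$delta_d)), 3)  # the three NOBST cells
  expect_true(all(!is.na(ft$straight_deviation_deg)))
  expect_equal(nrow(feature_table(conditions = 3, target_offsets = 0)), 1)
  dup <- feature_table(conditions = c(2, 2), target_offsets = c(0, 0),
                       expand = FALSE)
  expect_equal(nrow(dup), 2)
  expect_identical(dup[1, ], structure(dup[2, ], row.names = 1L))
})

test_that("signed-feature invariants hold across random layouts", {
  set.seed(99)
  for (i in 1:50) {
    off <- runif(1, -30, 30)
    lay <- walkway_layout(90, obstacle_lateral_offset = off)
    expect_equal(sign(relative_distance(lay)$delta_d), sign(off))
    # for a centred obstacle delta_theta is opposite in sign to the target
    tgt <- runif(1, -45, 45)
    cen <- walkway_layout(135)
    expect_equal(sign(deviation_angles(cen, tgt)$delta_theta), -sign(tgt))
  }
})

test_that("mirrored layouts invert the margin ratio", {
  mk <- function(off, aml, amr)
    geometry_features(walkway_layout(90, obstacle_lateral_offset = off,
                                     am_left_override = aml,
                                     am_right_override = amr), 0)
  a <- mk(22, 84, 40); b <- mk(-22, 40, 84)
  expect_equal(a$amr, 1 / b$amr)
})
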