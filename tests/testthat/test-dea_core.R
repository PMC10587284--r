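test_that("a lone vessel defines its own frontier", {
  rs <- make_refset(X = matrix(c(70, 150), 1), Y = matrix(c(2, 3), 1))
  te <- solve_te(rs)
  cu <- solve_cu(rs)
  expect_equal(te$theta1, 1)
  expect_equal(te$te, 1)
  expect_equal(cu$cu, 1)
})

test_that("a dominated vessel's expansion factor reflects the dominance gap", {
  # identical inputs; outputs (2,2) vs (1,1): the second can double
  rs <- make_refset(X = matrix(c(5, 5, 100, 100), 2),
                    Y = matrix(c(2, 1, 2, 1), 2))
  te <- solve_te(rs)
  expect_equal(te$theta1, c(1, 2))
  expect_equal(te$te, c(1, 0.5))
})

test_that("LP optima agree with the simplex-grid brute force", {
  withr::local_seed(101)
  steps_for <- c(`2` = 400L, `3` = 120L, `4` = 60L, `5` = 40L)
  for (i in 1:12) {
    J <- sample(2:5, 1)
    inst <- random_instance(J)
    rs <- make_refset(inst$X, inst$Y)
    sol <- solve_te(rs)
    z <- attr(sol, "z")
    for (j in seq_len(J)) {
      br <- grid_bracket(inst$X, inst$Y, inst$X[j, ], inst$Y[j, ],
                         steps = steps_for[[as.character(J)]])
      expect_gte(sol$theta1[j], br[["lower"]] - 1e-8)
      expect_lte(sol$theta1[j], br[["upper"]] + 1e-8)
      check_lp_certificate(z[j, ], sol$theta1[j], inst$X, inst$Y,
                           inst$X[j, ], inst$Y[j, ])
    }
  }
})

test_that("relaxing variable inputs never shrinks the expansion factor", {
  withr::local_seed(102)
  for (i in 1:25) {
    inst <- random_instance(sample(2:10, 1), N = 3)
    rs <- make_refset(inst$X, inst$Y)
    t1 <- solve_te(rs)$theta1
    t2 <- solve_cu(rs)$theta2
    expect_true(all(t2 >= t1 - 1e-8))
    expect_true(all(t1 >= 1 - 1e-9))
  }
})

test_that("slack variable-input constraints leave capacity equal to efficiency", {
  # vessel 3 is dominated but holds the largest variable input, so its
  # variable-input constraint is already slack at the TE optimum
  X <- matrix(c(5, 5, 5,      # fixed input
                100, 120, 200), 3)
  Y <- matrix(c(4, 5, 2,
                4, 5, 2), 3)
  rs <- make_refset(X, Y)
  te <- solve_te(rs)
  z3 <- attr(te, "z")[3, ]
  # slackness of the variable-input constraint at the TE optimum
  expect_lt(sum(z3 * X[, 2]), X[3, 2] - 1)
  cu <- solve_cu(rs)
  expect_equal(cu$theta2[3], te$theta1[3], tolerance = 1e-9)
  expect_equal(cu$cu[3] / te$te[3], 1, tolerance = 1e-9)
})

test_that("scores are invariant to rescaling any input or output column", {
  cfg <- fleet_config(n_vessels = 12, years = 2000:2002, seed = 21)
  sim <- simulate_fleet(cfg)
  panel <- join_ssb(sim$panel, sim$ssb)
  base <- dea_scores(panel)

  # tonnes -> kilograms on both catches (outputs scale by 1000)
  kg <- panel
  kg$y_yft <- kg$y_yft * 1000
  kg$y_skj <- kg$y_skj * 1000
  expect_equal(dea_scores(kg)$te, base$te, tolerance = 1e-8)
  expect_equal(dea_scores(kg)$cu, base$cu, tolerance = 1e-8)

  # single input column rescale
  ft <- panel
  ft$length_m <- ft$length_m * 3.28
  expect_equal(dea_scores(ft)$te, base$te, tolerance = 1e-8)
  # single output column rescale
  one <- panel
  one$y_skj <- one$y_skj * 50
  expect_equal(dea_scores(one)$ucu, base$ucu, tolerance = 1e-8)
})

test_that("unbiased capacity utilisation is the ratio of the two scores", {
  cfg <- fleet_config(n_vessels = 10, years = 2001:2003, seed = 22)
  sim <- simulate_fleet(cfg)
  sc <- dea_scores(join_ssb(sim$panel, sim$ssb))
  expect_equal(sc$ucu, sc$cu / sc$te, tolerance = 1e-12)
  # spot check of the ratio arithmetic
  expect_equal(0.6 / 0.8, 0.75)
})

test_that("every reference set carries at least one fully efficient vessel", {
  cfg <- fleet_config(n_vessels = 14, years = 1995:2000, seed = 23)
  sim <- simulate_fleet(cfg)
  sc <- dea_scores(join_ssb(sim$panel, sim$ssb))
  peak <- dplyr::summarise(dplyr::group_by(sc, year, strategy),
                           top = max(te), .groups = "drop")
  expect_true(all(peak$top == 1))
})

test_that("dropping the convexity constraint (constant returns) never lowers theta", {
  withr::local_seed(103)
  for (i in 1:10) {
    inst <- random_instance(sample(2:6, 1))
    rs <- make_refset(inst$X, inst$Y)
    vrs <- solve_te(rs)$theta1
    for (j in seq_len(nrow(inst$X))) {
      J <- nrow(inst$X); M <- ncol(inst$Y); N <- ncol(inst$X)
      A <- rbind(cbind(inst$Y[j, ], -t(inst$Y)), cbind(0, t(inst$X)))
      b <- c(rep(0, M), inst$X[j, ])
      crs <- fleetdea:::.lp_solve_cpp(c(1, rep(0, J)), A, b,
                                      rep(0L, M + N))
      expect_identical(crs$status, 0L)
      expect_gte(crs$objval, vrs[j] - 1e-8)
    }
  }
})

test_that("appending a dominated vessel leaves other scores unchanged", {
  withr::local_seed(104)
  inst <- random_instance(5)
  base <- solve_te(make_refset(inst$X, inst$Y))$theta1
  dominated <- list(X = rbind(inst$X, inst$X[1, ] * 1.1),
                    Y = rbind(inst$Y, inst$Y[1, ] * 0.9))
  grown <- solve_te(make_refset(dominated$X, dominated$Y))$theta1
  expect_equal(grown[1:5], base, tolerance = 1e-9)
  # a vessel dominating everyone weakly increases every expansion factor
  dominator <- list(X = rbind(inst$X, apply(inst$X, 2, min)),
                    Y = rbind(inst$Y, apply(inst$Y, 2, max) * 1.5))
  pushed <- solve_te(make_refset(dominator$X, dominator$Y))$theta1
  expect_true(all(pushed[1:5] >= base - 1e-9))
})

test_that("vessels without positive sets are excluded from the reference set", {
  panel <- make_panel(vessel_id = c("a", "b", "c"), year = 2000,
                      length_m = c(70, 75, 80),
                      days_fished = c(150, 160, 170),
                      n_sets = c(60, 0, 70),
                      y_yft = c(1e-4, 2e-4, 3e-4),
                      y_skj = c(1e-4, 2e-4, 3e-4))
  rs <- build_reference_set(panel, 2000, "FOB")
  expect_identical(rs$dmu_ids, c("a", "c"))
  expect_identical(rs$excluded$vessel_id, "b")
  expect_error(build_reference_set(panel, 2001, "FOB"), "2001")
  expect_error(build_reference_set(panel, 2000, "FSC"), "FSC")
})

test_that("annual means aggregate correctly and flag singleton groups", {
  sc <- tibble::tibble(
    vessel_id = c("a", "b", "c"),
    year = c(2000L, 2000L, 2001L), strategy = "FOB",
    theta1 = 1, theta2 = 1,
    te = c(0.5, 1.0, 0.8), cu = c(0.4, 0.9, 0.6),
    ucu = c(0.8, 0.9, 0.75), lp_status = "optimal"
  )
  am <- annual_means(sc)
  te2000 <- am[am$year == 2000 & am$metric == "te", ]
  expect_equal(te2000$mean, 0.75)
  expect_equal(te2000$se, stats::sd(c(0.5, 1)) / sqrt(2))
  single <- am[am$year == 2001 & am$metric == "te", ]
  expect_equal(single$se, 0)
  expect_false(single$se_defined)
})

test_that("a capacity-utilisation score translates into management quantities", {
  imp <- capacity_implications(0.80)
  expect_equal(imp$potential_catch_gain, 0.25)
  expect_equal(imp$capacity_excess, 0.20)
  expect_error(capacity_implications(1.2))
})
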