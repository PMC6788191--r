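test_that("expected gains match their closed forms", {
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
  eg <- expected_gains(pars, c(0.5, 1))
  expect_equal(eg$Ea, -10)
  expect_equal(eg$En, -8)
  # beta = 0 collapses the school's no-caution gain to -a p
  expect_equal(expected_gains(pars, c(0.3, 0))$En, -pars$a * pars$p)
  # alpha = 1: a careless student always faces the full loss
  expect_equal(expected_gains(pars, c(1, 0.4))$Sn, -pars$p)
  # population averages are the mixture identities
  for (pars in draw_params(50, seed = 11)) {
    s <- stats::runif(2)
    eg <- expected_gains(pars, s)
    expect_equal(eg$Ec, s[1] * eg$Ea + (1 - s[1]) * eg$En)
    expect_equal(eg$Sc, s[2] * eg$Sa + (1 - s[2]) * eg$Sn)
  }
})

test_that("closed-form flows equal share x (1 - share) x gain advantage", {
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
  expect_equal(school_flow(pars, c(0.5, 1)), -0.5)
  pars2 <- game_params(cc = 8, cs = 4, p = 12, a = 0.5, b = 0.5)
  expect_equal(student_flow(pars2, c(0, 0.5)), 1.0)
  set.seed(23)
  for (pars in draw_params(1000, seed = 23)) {
    s <- stats::runif(2)
    eg <- expected_gains(pars, s)
    expect_equal(school_flow(pars, s),
                 s[1] * (1 - s[1]) * (eg$Ea - eg$En), tolerance = 1e-12)
    expect_equal(student_flow(pars, s),
                 s[2] * (1 - s[2]) * (eg$Sa - eg$Sn), tolerance = 1e-12)
  }
})

test_that("flows vanish on all four corners for any parameters", {
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (pars in draw_params(100, seed = 3)) {
    for (i in 1:4) {
      expect_identical(school_flow(pars, corners[i, ]), 0)
      expect_identical(student_flow(pars, corners[i, ]), 0)
    }
  }
})

test_that("generic bimatrix replicator agrees with the closed forms", {
  set.seed(101)
  worst <- 0
  for (pars in draw_params(1000, seed = 101)) {
    s <- stats::runif(2)
    f_closed <- c(school_flow(pars, s), student_flow(pars, s))
    f_generic <- generic_bimatrix_flow(build_payoff_matrix(pars), s)
    worst <- max(worst, max(abs(f_closed - f_generic)))
  }
  expect_lt(worst, 1e-12)
})

test_that("degenerate and strict matrices behave as their cells dictate", {
  # identical cells everywhere: no payoff differences, zero flow
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 0.5, b = 0.5)
  m <- build_payoff_matrix(pars)
  m$student[] <- -1
  m$school[] <- -2
  expect_equal(generic_bimatrix_flow(m, c(0.3, 0.7)), c(0, 0))
  # the strict-override matrix induces different flows than the closed forms
  ms <- build_payoff_matrix(game_params(cc = 10, cs = 6, p = 5, a = 1,
                                        b = 1, rule = "strict_override"))
  s <- c(0.3, 0.7)
  pars11 <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 1)
  expect_false(isTRUE(all.equal(
    generic_bimatrix_flow(ms, s),
    c(school_flow(pars11, s), student_flow(pars11, s)))))
})

test_that("interior equilibrium matches both closed forms", {
  eq <- interior_equilibrium(game_params(cc = 10, cs = 6, p = 5,
                                         a = 0, b = 1))
  expect_equal(eq$alpha, 5 / 6)
  expect_equal(eq$beta, 10 / 11)
  expect_true(eq$valid)
  # alpha* also equals 1 - (cs - p)/(b cs - a p) wherever defined
  for (pars in draw_params(1000, seed = 57)) {
    d <- pars$b * pars$cs - pars$a * pars$p
    if (abs(d) < 1e-6 ||
        abs((1 - pars$a) * pars$p + pars$b * pars$cs) < 1e-6) next
    eq <- interior_equilibrium(pars)
    alt <- 1 - (pars$cs - pars$p) / d
    expect_equal(eq$alpha, alt, tolerance = 1e-12)
  }
  # cc = a p puts beta* on the boundary: not a valid interior point
  eq0 <- interior_equilibrium(suppressWarnings(
    game_params(cc = 5, cs = 6, p = 5, a = 1, b = 1)))
  expect_equal(eq0$beta, 0)
  expect_false(eq0$valid)
  # vanishing denominators are named
  expect_error(interior_equilibrium(game_params(cc = 10, cs = 5, p = 5,
                                                a = 0.5, b = 0.5)),
               "b\\*cs - a\\*p")
})

test_that("rest-point enumeration finds the corners plus the interior point", {
  rp <- find_rest_points(game_params(cc = 10, cs = 6, p = 5, a = 0, b = 1))
  expect_equal(nrow(rp), 5)
  expect_true(all(apply(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1),
                              c(5 / 6, 10 / 11)), 1, function(pt) {
    any(abs(rp[, 1] - pt[1]) < 1e-9 & abs(rp[, 2] - pt[2]) < 1e-9)
  })))
  # without a valid interior point only the corners remain
  rp4 <- find_rest_points(game_params(cc = 10, cs = 6, p = 5,
                                      a = 0.9, b = 0.1))
  expect_equal(nrow(rp4), 4)
})

test_that("trajectories from corners are constant and verdicts match an
           independent Euler integration", {
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
  tr0 <- integrate_game(pars, c(1, 0), t_max = 50)
  expect_true(all(tr0$states[, "alpha"] == 1))
  expect_true(all(tr0$states[, "beta"] == 0))

  # scenario-1 parameters: both populations abandon caution
  tr <- integrate_game(pars, c(0.5, 0.5))
  expect_corner(tr, c(0, 0))
  expect_equal(euler_final(pars, c(0.5, 0.5), t_max = 60), c(0, 0),
               tolerance = 1e-3)

  # high-loss, high-reimbursement parameters: mutual caution
  pars2 <- suppressWarnings(game_params(cc = 8, cs = 10, p = 12,
                                        a = 0.5, b = 0.9))
  tr2 <- integrate_game(pars2, c(0.5, 0.5))
  expect_corner(tr2, c(1, 1))
  expect_equal(euler_final(pars2, c(0.5, 0.5), t_max = 60), c(1, 1),
               tolerance = 1e-3)
})

test_that("the unit square is forward-invariant up to numerical drift", {
  worst <- 0
  for (pars in draw_params(20, seed = 5)) {
    tr <- integrate_game(pars, c(0.37, 0.81), t_max = 200)
    worst <- max(worst, tr$max_boundary_violation)
  }
  expect_lte(worst, 1e-9)
})

test_that("rescaling all monetary parameters rescales flows but preserves
           rest points and verdicts", {
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 0, b = 1)
  k <- 7.3
  pars_k <- game_params(cc = k * 10, cs = k * 6, p = k * 5, a = 0, b = 1)
  s <- c(0.4, 0.6)
  expect_equal(school_flow(pars_k, s), k * school_flow(pars, s),
               tolerance = 1e-12)
  expect_equal(student_flow(pars_k, s), k * student_flow(pars, s),
               tolerance = 1e-12)
  expect_equal(find_rest_points(pars_k), find_rest_points(pars),
               tolerance = 1e-12)
  tr <- integrate_game(pars, c(0.2, 0.3))
  tr_k <- integrate_game(pars_k, c(0.2, 0.3))
  expect_identical(tr$verdict, tr_k$verdict)
  expect_equal(tr$corner, tr_k$corner)
})
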