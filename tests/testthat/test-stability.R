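test_that("Jacobian is diagonal at corners and matches finite differences", {
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
  J0 <- game_jacobian(pars, c(0, 0))
  expect_equal(J0, diag(c(pars$a * pars$p - pars$cc,
                          (1 - pars$a) * pars$p -
                            (1 - pars$b) * pars$cs)),
               ignore_attr = TRUE)
  # off-diagonals vanish at all four corners
  for (pt in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    J <- game_jacobian(pars, pt)
    expect_identical(unname(J[1, 2]), 0)
    expect_identical(unname(J[2, 1]), 0)
  }
  # central finite differences of the flows, step 1e-6
  set.seed(19)
  h <- 1e-6
  for (pars in draw_params(200, seed = 19)) {
    s <- stats::runif(2, 0.05, 0.95)
    J <- game_jacobian(pars, s)
    fd <- matrix(0, 2, 2)
    for (j in 1:2) {
      up <- s; up[j] <- up[j] + h
      dn <- s; dn[j] <- dn[j] - h
      fd[1, j] <- (school_flow(pars, up) - school_flow(pars, dn)) / (2 * h)
      fd[2, j] <- (student_flow(pars, up) - student_flow(pars, dn)) / (2 * h)
    }
    expect_equal(unclass(J)[1:2, 1:2], fd,
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("the off-diagonal variant is not the derivative but agrees at
           corners", {
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 0.2, b = 0.9)
  s <- c(0.3, 0.6)
  J <- game_jacobian(pars, s)
  expect_false(isTRUE(all.equal(unname(J[2, 1]), attr(J, "j21_variant"))))
  for (pt in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    Jc <- game_jacobian(pars, pt)
    expect_identical(attr(Jc, "j21_variant"), unname(Jc[2, 1]))
  }
})

test_that("corner determinant/trace closed forms equal the direct Jacobian", {
  worst <- 0
  for (pars in draw_params(1000, seed = 31)) {
    ct <- corner_det_trace(pars)
    for (i in 1:4) {
      J <- game_jacobian(pars, c(ct$alpha[i], ct$beta[i]))
      worst <- max(worst, abs(ct$det[i] - det(J)),
                   abs(ct$tr[i] - sum(diag(J))))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("corner determinant/trace examples and pi identities hold", {
  pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
  ct <- corner_det_trace(pars)
  o <- ct[ct$alpha == 0 & ct$beta == 0, ]
  expect_equal(o$det, 15)   # (-5) * (-3)
  expect_equal(o$tr, -8)
  rep <- classify_equilibria(pars)
  expect_identical(rep$equilibria$class[rep$equilibria$alpha == 0 &
                                          rep$equilibria$beta == 0], "ESS")
  # Det at (1,1) factorises as pi2 * pi3
  for (pars in draw_params(100, seed = 13)) {
    g <- as.numeric(net_gains(pars))
    ct <- corner_det_trace(pars)
    expect_equal(ct$det[ct$alpha == 1 & ct$beta == 1], g[2] * g[3],
                 tolerance = 1e-12)
  }
})

test_that("corner ESS classification follows the net-gain predicates", {
  for (pars in draw_params(500, seed = 47)) {
    g <- as.numeric(net_gains(pars))
    if (any(abs(g) < 1e-9)) next
    rep <- classify_equilibria(pars)
    eq <- rep$equilibria
    is_ess <- function(a, b) {
      eq$class[abs(eq$alpha - a) < 1e-9 & abs(eq$beta - b) < 1e-9] == "ESS"
    }
    expect_identical(unname(is_ess(0, 0)), g[1] < 0 && g[4] < 0)
    expect_identical(unname(is_ess(1, 1)), g[2] > 0 && g[3] > 0)
    expect_identical(unname(is_ess(0, 1)), g[2] < 0 && g[4] > 0)
    expect_identical(unname(is_ess(1, 0)), g[1] > 0 && g[3] < 0)
  }
})

test_that("scenario rows classify as tabulated", {
  # scenario 1: all gains negative -> origin ESS, opposite corner unstable,
  # mixed corners saddles
  rep1 <- classify_equilibria(game_params(cc = 10, cs = 6, p = 5,
                                          a = 1, b = 0.5))
  eq1 <- rep1$equilibria[1:4, ]
  expect_identical(rep1$scenario, "1")
  expect_identical(eq1$class[order(eq1$alpha, eq1$beta)],
                   c("ESS", "saddle", "saddle", "unstable"))
  # scenario 7 -> (0,1) is the unique ESS
  rep7 <- classify_equilibria(game_params(cc = 16, cs = 4, p = 12,
                                          a = 0.5, b = 0.5))
  expect_identical(rep7$scenario, "7")
  eq7 <- rep7$equilibria
  expect_identical(eq7$class[eq7$alpha == 0 & eq7$beta == 1], "ESS")
  expect_identical(sum(eq7$class == "ESS"), 1L)
  # scenario 10: all four corners saddles, no ESS anywhere
  rep10 <- classify_equilibria(find_scenario_params(10))
  expect_identical(rep10$scenario, "10")
  expect_true(all(rep10$equilibria$class[1:4] == "saddle"))
  expect_false(any(rep10$equilibria$class == "ESS"))
})

test_that("the interior equilibrium is never an ESS", {
  n_checked <- 0
  for (pars in draw_params(500, seed = 61)) {
    eq <- tryCatch(interior_equilibrium(pars), error = function(e) NULL)
    if (is.null(eq) || !eq$valid) next
    rep <- classify_equilibria(pars)
    int_row <- rep$equilibria[-(1:4), ]
    expect_equal(nrow(int_row), 1)
    expect_true(int_row$class %in% c("saddle", "non-hyperbolic"))
    # both diagonal entries vanish at the rest point, so the trace is 0
    expect_equal(int_row$tr, 0,
                 tolerance = 1e-10 * max(1, abs(int_row$det)))
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 20)
})

test_that("boundary parameter sets report non-hyperbolic corners", {
  pars <- suppressWarnings(game_params(cc = 400, cs = 1000, p = 1000,
                                       a = 0.75, b = 0.5))  # pi3 = 0
  rep <- classify_equilibria(pars)
  expect_identical(rep$scenario, "boundary")
  expect_true(any(rep$equilibria$class == "non-hyperbolic"))
})
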