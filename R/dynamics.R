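#' Expected gains of the two populations
#'
#' Closed-form expected gains under the parametric payoff matrix, given the
#' state profile `(alpha, beta)` — the probabilities that the school,
#' respectively the students and their guardians, play "appropriate
#' caution":
#' \itemize{
#'   \item school: `Ea = -cc`, `En = -beta (p + b cs) - (1 - beta) a p`,
#'     average `Ec = alpha Ea + (1 - alpha) En`;
#'   \item students: `Sa = -alpha cs - (1 - alpha)(1 - b) cs`,
#'     `Sn = -alpha p - (1 - alpha)(1 - a) p`,
#'     average `Sc = beta Sa + (1 - beta) Sn`.
#' }
#'
#' @param params A [game_params()] object (the closed forms are defined on
#'   the parametric matrix; the rule tag is ignored here).
#' @param state Numeric `c(alpha, beta)` in the unit square.
#' @return A list with components `Ea`, `En`, `Ec`, `Sa`, `Sn`, `Sc`
#'   (currency units).
#' @examples
#' pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
#' expected_gains(pars, c(0.5, 1))
#' @export
expected_gains <- function(params, state) {
  stopifnot(inherits(params, "game_params"))
  state <- check_state(state)
  alpha <- state[1]; beta <- state[2]
  cc <- params$cc; cs <- params$cs; p <- params$p
  a <- params$a; b <- params$b
  Ea <- -cc
  En <- -beta * (p + b * cs) - (1 - beta) * a * p
  Sa <- -alpha * cs - (1 - alpha) * (1 - b) * cs
  Sn <- -alpha * p - (1 - alpha) * (1 - a) * p
  list(Ea = Ea, En = En, Ec = alpha * Ea + (1 - alpha) * En,
       Sa = Sa, Sn = Sn, Sc = beta * Sa + (1 - beta) * Sn)
}

#' Replicator flow of the school population
#'
#' Closed-form replicated dynamic equation for the share `alpha` of schools
#' playing "appropriate caution":
#' `dalpha/dt = alpha (1 - alpha) (beta ((1-a) p + b cs) - (cc - a p))`.
#'
#' @inheritParams expected_gains
#' @return `dalpha/dt` (numeric scalar).
#' @examples
#' school_flow(game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5),
#'             c(0.5, 1))
#' @export
school_flow <- function(params, state) {
  stopifnot(inherits(params, "game_params"))
  state <- check_state(state)
  school_flow_raw(params, state[1], state[2])
}

#' Replicator flow of the student population
#'
#' Closed-form replicated dynamic equation for the share `beta` of students
#' (and guardians) playing "appropriate caution":
#' `dbeta/dt = beta (1 - beta) (((1-a) p - (1-b) cs) - (b cs - a p) alpha)`.
#'
#' @inheritParams expected_gains
#' @return `dbeta/dt` (numeric scalar).
#' @examples
#' student_flow(game_params(cc = 8, cs = 4, p = 12, a = 0.5, b = 0.5),
#'              c(0, 0.5))
#' @export
student_flow <- function(params, state) {
  stopifnot(inherits(params, "game_params"))
  state <- check_state(state)
  student_flow_raw(params, state[1], state[2])
}

# unchecked, vectorised flow kernels (used by the integrator)
school_flow_raw <- function(params, alpha, beta) {
  alpha * (1 - alpha) *
    (beta * ((1 - params$a) * params$p + params$b * params$cs) -
       (params$cc - params$a * params$p))
}

student_flow_raw <- function(params, alpha, beta) {
  beta * (1 - beta) *
    (((1 - params$a) * params$p - (1 - params$b) * params$cs) -
       (params$b * params$cs - params$a * params$p) * alpha)
}

#' Two-population replicator flow built directly from a payoff bimatrix
#'
#' Generic replicator dynamics for any 2x2 bimatrix: each strategy's share
#' grows at rate share x (1 - share) x (fitness of the strategy minus the
#' other strategy's fitness), with fitnesses computed purely from the payoff
#' cells and the opponent population mix. This serves as an independent
#' oracle for the closed-form flows on the parametric matrix, and as the
#' dynamics of the strict-override matrix (whose flows differ from the
#' closed forms).
#'
#' @param matrix A [build_payoff_matrix()] result (`payoff_bimatrix`).
#' @param state Numeric `c(alpha, beta)`: school and student
#'   appropriate-caution shares.
#' @return Numeric `c(dalpha, dbeta)`.
#' @examples
#' m <- build_payoff_matrix(game_params(cc = 10, cs = 6, p = 5,
#'                                      a = 0.5, b = 0.5))
#' generic_bimatrix_flow(m, c(0.3, 0.7))
#' @export
generic_bimatrix_flow <- function(matrix, state) {
  stopifnot(inherits(matrix, "payoff_bimatrix"))
  state <- check_state(state)
  alpha <- state[1]; beta <- state[2]
  S <- matrix$student; C <- matrix$school
  # school (column player): fitness against the student mix beta
  f_school_ac <- beta * C[1, 1] + (1 - beta) * C[2, 1]
  f_school_nc <- beta * C[1, 2] + (1 - beta) * C[2, 2]
  # student (row player): fitness against the school mix alpha
  f_stud_ac <- alpha * S[1, 1] + (1 - alpha) * S[1, 2]
  f_stud_nc <- alpha * S[2, 1] + (1 - alpha) * S[2, 2]
  c(alpha * (1 - alpha) * (f_school_ac - f_school_nc),
    beta * (1 - beta) * (f_stud_ac - f_stud_nc))
}

#' Interior equilibrium of the replicator system
#'
#' The interior rest point where both replicator brackets vanish:
#' `alpha* = ((1-a) p - (1-b) cs) / (b cs - a p)` and
#' `beta* = (cc - a p) / ((1-a) p + b cs)`. The point is a rest point of
#' the dynamics whenever defined; the validity flag is `TRUE` iff both
#' coordinates lie strictly inside (0, 1), i.e. the point lies in the open
#' unit square.
#'
#' @param params A [game_params()] object.
#' @param tol Relative tolerance for detecting a vanishing denominator.
#' @return A list with `alpha`, `beta` and logical `valid`.
#' @examples
#' interior_equilibrium(game_params(cc = 10, cs = 6, p = 5, a = 0, b = 1))
#' @export
interior_equilibrium <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "game_params"))
  sc <- param_scale(params)
  d_alpha <- params$b * params$cs - params$a * params$p
  d_beta <- (1 - params$a) * params$p + params$b * params$cs
  if (abs(d_alpha) <= tol * sc) {
    stop("degenerate interior equilibrium: denominator b*cs - a*p vanishes",
         call. = FALSE)
  }
  if (abs(d_beta) <= tol * sc) {
    stop("degenerate interior equilibrium: denominator (1-a)*p + b*cs ",
         "vanishes", call. = FALSE)
  }
  alpha <- ((1 - params$a) * params$p - (1 - params$b) * params$cs) / d_alpha
  beta <- (params$cc - params$a * params$p) / d_beta
  list(alpha = alpha, beta = beta,
       valid = alpha > 0 && alpha < 1 && beta > 0 && beta < 1)
}

#' Enumerate all rest points of the replicator system on the unit square
#'
#' Solves `school_flow = 0` and `student_flow = 0` over \[0, 1\]^2 using the
#' factored structure of the flows: each flow vanishes on its own boundary
#' faces or on the zero line of its bracket term. All cross-combinations of
#' candidate coordinates are formed and kept when the flow norm vanishes to
#' tolerance. For a parameter set with a valid interior equilibrium this
#' yields exactly five distinct rest points: the four corners plus the
#' interior point.
#'
#' @param params A [game_params()] object (parametric rule).
#' @param tol Relative tolerance on the flow norm for accepting a rest
#'   point.
#' @return A matrix with columns `alpha`, `beta`, one row per rest point.
#' @examples
#' find_rest_points(game_params(cc = 10, cs = 6, p = 5, a = 0, b = 1))
#' @export
find_rest_points <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "game_params"))
  sc <- param_scale(params)
  alphas <- c(0, 1)
  betas <- c(0, 1)
  eq <- tryCatch(interior_equilibrium(params), error = function(e) NULL)
  if (!is.null(eq)) {
    if (eq$alpha >= 0 && eq$alpha <= 1) alphas <- c(alphas, eq$alpha)
    if (eq$beta >= 0 && eq$beta <= 1) betas <- c(betas, eq$beta)
  }
  cand <- expand.grid(alpha = alphas, beta = betas)
  norm2 <- vapply(seq_len(nrow(cand)), function(i) {
    f <- c(school_flow_raw(params, cand$alpha[i], cand$beta[i]),
           student_flow_raw(params, cand$alpha[i], cand$beta[i]))
    sqrt(sum(f^2))
  }, numeric(1))
  keep <- cand[norm2 <= tol * sc, , drop = FALSE]
  keep <- keep[!duplicated(round(keep, 10)), , drop = FALSE]
  out <- as.matrix(keep)
  rownames(out) <- NULL
  out
}

#' Integrate the replicator dynamics
#'
#' Numerically integrates the two-population replicator system from an
#' initial state with an adaptive-step variable-order implicit multistep
#' solver (Adams/BDF, [deSolve::ode()] method `"vode"`; relative tolerance
#' `1e-10`, absolute `1e-12` by default). The flows are smooth low-degree
#' polynomials; the implicit scheme keeps step sizes large during the long
#' exponential decay towards an attracting corner, where the decay rate
#' scales with the monetary magnitude of the parameters. Parametric-rule
#' parameter sets use the closed-form flows; strict-override sets use the
#' generic bimatrix flow on the strict payoff matrix. States are clipped to
#' the unit square after integration; the maximum boundary overshoot before
#' clipping is recorded (the exact field is tangent to the boundary, so any
#' overshoot is purely numerical and should stay below ~1e-9).
#'
#' The convergence verdict is
#' \itemize{
#'   \item `"corner"` when the final state is within `corner_tol` of a
#'     corner and the flow magnitude there is below `flow_tol`;
#'   \item `"interior"` when the final state is within `corner_tol` of a
#'     valid interior equilibrium;
#'   \item `"undecided"` otherwise (cycling or unresolved within `t_max`).
#' }
#'
#' @param params A [game_params()] object.
#' @param init Initial state `c(alpha, beta)`.
#' @param t_max Integration horizon (time units arbitrary; default 500).
#' @param rtol,atol Solver relative/absolute tolerances.
#' @param corner_tol Distance threshold for corner/interior verdicts.
#' @param flow_tol Flow-norm threshold for the corner verdict.
#' @param n_out Number of equally spaced output times (including `t = 0`).
#' @return An object of class `game_trajectory`: list with `times`, `states`
#'   (matrix with columns `alpha`, `beta`, clipped), `verdict`, `corner`
#'   (the corner reached, or `NULL`), `final_state`, `flow_norm` at the
#'   final state, `max_boundary_violation`, and the `params` and settings
#'   used.
#' @examples
#' pars <- game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5)
#' traj <- integrate_game(pars, c(0.5, 0.5))
#' traj$verdict
#' @export
integrate_game <- function(params, init, t_max = 500,
                           rtol = 1e-10, atol = 1e-12,
                           corner_tol = 1e-3, flow_tol = 1e-8,
                           n_out = 501) {
  stopifnot(inherits(params, "game_params"))
  init <- check_state(init)
  stopifnot(is.numeric(t_max), t_max > 0)
  # The exact field is tangent to the unit square, but floating-point noise
  # can push a share infinitesimally outside, where the raw polynomial field
  # may amplify the excursion (share * (1 - share) changes sign). The RHS
  # therefore evaluates the flow at the clipped state and adds a linear
  # restoring term on the out-of-bounds excess, leaving the field unchanged
  # on the square and keeping overshoots at solver-tolerance level.
  restore_rate <- max(1, param_scale(params))
  if (params$rule == "parametric") {
    rhs <- function(t, y, parms) {
      yc <- pmin(pmax(y, 0), 1)
      list(c(school_flow_raw(params, yc[1], yc[2]),
             student_flow_raw(params, yc[1], yc[2])) -
             restore_rate * (y - yc))
    }
    flow_at <- function(s) c(school_flow_raw(params, s[1], s[2]),
                             student_flow_raw(params, s[1], s[2]))
  } else {
    m <- build_payoff_matrix(params)
    flow_cells <- function(alpha, beta) {
      S <- m$student; C <- m$school
      c(alpha * (1 - alpha) *
          ((beta * C[1, 1] + (1 - beta) * C[2, 1]) -
             (beta * C[1, 2] + (1 - beta) * C[2, 2])),
        beta * (1 - beta) *
          ((alpha * S[1, 1] + (1 - alpha) * S[1, 2]) -
             (alpha * S[2, 1] + (1 - alpha) * S[2, 2])))
    }
    rhs <- function(t, y, parms) {
      yc <- pmin(pmax(y, 0), 1)
      list(flow_cells(yc[1], yc[2]) - restore_rate * (y - yc))
    }
    flow_at <- function(s) flow_cells(s[1], s[2])
  }
  times <- seq(0, t_max, length.out = n_out)
  sol <- deSolve::ode(y = c(alpha = init[1], beta = init[2]), times = times,
                      func = rhs, parms = NULL, method = "vode",
                      rtol = rtol, atol = atol)
  states <- unname(sol[, c("alpha", "beta"), drop = FALSE])
  if (any(!is.finite(states))) {
    bad <- which(!is.finite(rowSums(states)))[1]
    stop(sprintf("non-finite flow encountered at t = %g, state (%g, %g)",
                 sol[bad, 1], states[bad, 1], states[bad, 2]), call. = FALSE)
  }
  max_violation <- max(0, max(states - 1), max(-states))
  states <- pmin(pmax(states, 0), 1)
  colnames(states) <- c("alpha", "beta")
  final <- states[nrow(states), ]
  fnorm <- sqrt(sum(flow_at(final)^2))

  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  dists <- sqrt(rowSums((corners - matrix(final, 4, 2, byrow = TRUE))^2))
  verdict <- "undecided"
  corner <- NULL
  if (min(dists) < corner_tol && fnorm < flow_tol) {
    verdict <- "corner"
    corner <- corners[which.min(dists), ]
  } else if (params$rule == "parametric") {
    eq <- tryCatch(interior_equilibrium(params), error = function(e) NULL)
    if (!is.null(eq) && eq$valid &&
        sqrt((final[1] - eq$alpha)^2 + (final[2] - eq$beta)^2) < corner_tol) {
      verdict <- "interior"
    }
  }
  structure(list(times = unname(sol[, 1]), states = states,
                 verdict = verdict, corner = corner,
                 final_state = final, flow_norm = fnorm,
                 max_boundary_violation = max_violation,
                 params = params,
                 settings = list(t_max = t_max, rtol = rtol, atol = atol,
                                 corner_tol = corner_tol,
                                 flow_tol = flow_tol, n_out = n_out)),
            class = "game_trajectory")
}

#' @export
print.game_trajectory <- function(x, ...) {
  cat("Replicator trajectory (rule:", x$params$rule, ")\n")
  cat(sprintf("  start (%g, %g) -> final (%.6g, %.6g) at t = %g\n",
              x$states[1, 1], x$states[1, 2],
              x$final_state[1], x$final_state[2], max(x$times)))
  if (x$verdict == "corner") {
    cat(sprintf("  verdict: corner (%g, %g)\n", x$corner[1], x$corner[2]))
  } else {
    cat("  verdict:", x$verdict, "\n")
  }
  cat(sprintf("  flow norm at final state: %.3g; max boundary overshoot: %.3g\n",
              x$flow_norm, x$max_boundary_violation))
  invisible(x)
}

#' @export
plot.game_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "time", ylab = "share playing appropriate caution",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = c("school (alpha)", "students (beta)"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
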