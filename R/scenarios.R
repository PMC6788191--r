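#' Specification of a simulation case
#'
#' Bundles the fixed monetary parameters, the sweep ranges for the liability
#' shares `a` and `b`, the initial state and the expected evolutionary
#' outcome per liability rule for a parameter-sweep case study.
#'
#' @param id Case identifier (any scalar; the five canonical studies use
#'   1-5).
#' @param p,cc,cs Fixed monetary parameters (see [game_params()]).
#' @param a_range,b_range Sweep ranges (length-2 numeric within \[0, 1\]).
#' @param init Initial state, default `c(0.5, 0.5)`.
#' @param expected Named list with elements `strict` and `proportional`,
#'   each a corner `c(alpha, beta)` or `NULL` when no outcome is claimed;
#'   used to mark sweep-cell agreement.
#' @param metadata Optional list of annotations carried through unchanged.
#' @return An object of class `case_spec`.
#' @seealso [liability_cases()] for the five canonical studies,
#'   [run_case()] to execute one.
#' @export
case_spec <- function(id, p, cc, cs,
                      a_range = c(0, 1), b_range = c(0, 1),
                      init = c(0.5, 0.5),
                      expected = list(strict = NULL, proportional = NULL),
                      metadata = list()) {
  stopifnot(length(a_range) == 2L, length(b_range) == 2L,
            all(a_range >= 0 & a_range <= 1),
            all(b_range >= 0 & b_range <= 1),
            a_range[1] < a_range[2], b_range[1] < b_range[2])
  check_positive_scalar(p, "p")
  check_positive_scalar(cc, "cc")
  check_positive_scalar(cs, "cs")
  init <- check_state(init)
  structure(list(id = id, p = p, cc = cc, cs = cs,
                 a_range = as.numeric(a_range),
                 b_range = as.numeric(b_range),
                 init = init, expected = expected, metadata = metadata),
            class = "case_spec")
}

#' The five canonical simulation cases
#'
#' Parameter sets of the five case studies of the liability game, all
#' started from `(0.5, 0.5)` and swept over the liability shares:
#' \describe{
#'   \item{case 1}{`p = 5, cc = 10, cs = 6` — both prevention costs high;
#'     expected outcome (no caution, no caution) under either rule.}
#'   \item{case 2}{`p = 12, cc = 8, cs = 10` — high reimbursement share
#'     `b`; expected (appropriate caution, appropriate caution).}
#'   \item{case 3}{`p = 12, cc = 8, cs = 4` — high accident loss; claimed
#'     outcome (appropriate caution, appropriate caution) under the strict
#'     rule but (no caution, appropriate caution) under the proportional
#'     rule. The proportional claim is analytically impossible on this
#'     parameter set (`pi2 > 0` and `pi3 > 0` for all `a`, `b`, so (1,1) is
#'     the unique corner ESS); [run_case()] records the disagreement cells.}
#'   \item{case 4}{`p = 12, cc = 16, cs = 4` — student caution cheap,
#'     school caution dear; expected (no caution, appropriate caution).
#'     Under the strict reading `a = 1, b = 1` this holds, but parts of the
#'     sweep near `a = 1, b = 0` have `pi4 < 0` and converge to (0,0)
#'     instead; disagreements are recorded.}
#'   \item{case 5}{`p = 1000, cc = 400, cs = 1000, a in [0.5, 1]` — cheap
#'     school caution, high loss; claimed outcome (appropriate caution, no
#'     caution). Here `cs = p` makes `pi3 = 0`: every cell is a boundary
#'     (non-hyperbolic) case and no outcome is asserted. The case's
#'     unexplained annotation `lambda = 1/100` is carried as metadata
#'     only.}
#' }
#'
#' @return A named list of five [case_spec()] objects.
#' @export
liability_cases <- function() {
  list(
    case1 = case_spec(1, p = 5, cc = 10, cs = 6,
                      expected = list(strict = c(0, 0),
                                      proportional = c(0, 0))),
    case2 = case_spec(2, p = 12, cc = 8, cs = 10,
                      expected = list(strict = c(1, 1),
                                      proportional = c(1, 1))),
    case3 = case_spec(3, p = 12, cc = 8, cs = 4,
                      expected = list(strict = c(1, 1),
                                      proportional = c(0, 1))),
    case4 = case_spec(4, p = 12, cc = 16, cs = 4,
                      expected = list(strict = c(0, 1),
                                      proportional = c(0, 1))),
    case5 = case_spec(5, p = 1000, cc = 400, cs = 1000,
                      a_range = c(0.5, 1),
                      expected = list(strict = c(1, 0),
                                      proportional = c(1, 0)),
                      metadata = list(lambda = 1 / 100,
                                      boundary = "cs = p makes pi3 = 0"))
  )
}

#' Run a parameter-sweep case
#'
#' Integrates the replicator dynamics from the case's initial state for
#' every cell of an (a, b) grid, attaches the per-cell scenario label and
#' convergence verdict, compares against the case's expected outcome, and
#' additionally runs the strict-override dynamics once. The comparison
#' convention: the "strict rule" is represented by the cell closest to
#' `a = 1, b = 1` (plus the strict-override run); the "proportional rule"
#' is summarized by the modal verdict over interior cells with
#' `0.1 <= a, b <= 0.9`. Disagreement cells (verdict differing from the
#' expected corner) are recorded, never suppressed or averaged away.
#'
#' @param spec A [case_spec()] object.
#' @param grid_resolution Cells per axis (default 21; >= 2).
#' @param t_max Integration horizon per cell.
#' @param ... Further arguments passed to [integrate_game()].
#' @return An object of class `sweep_result`: list with the `spec`, the
#'   per-cell data frame `grid` (columns `a`, `b`, `scenario`, `verdict`,
#'   `corner_alpha`, `corner_beta`, `category`, `agree`, `diagnostic`), the
#'   `strict_override` trajectory verdict, `modal_verdict` over interior
#'   cells, `disagreements` (subset of `grid`), and
#'   `max_boundary_violation`.
#' @examples
#' res <- run_case(liability_cases()$case1, grid_resolution = 5, t_max = 200)
#' res$modal_verdict
#' @export
run_case <- function(spec, grid_resolution = 21, t_max = 500, ...) {
  stopifnot(inherits(spec, "case_spec"), grid_resolution >= 2)
  a_vals <- seq(spec$a_range[1], spec$a_range[2],
                length.out = grid_resolution)
  b_vals <- seq(spec$b_range[1], spec$b_range[2],
                length.out = grid_resolution)
  cells <- expand.grid(a = a_vals, b = b_vals)
  n <- nrow(cells)
  scenario <- character(n)
  verdict <- character(n)
  corner_alpha <- rep(NA_real_, n)
  corner_beta <- rep(NA_real_, n)
  diagnostic <- rep(NA_character_, n)
  max_viol <- 0
  for (i in seq_len(n)) {
    pars <- new_game_params(spec$cc, spec$cs, spec$p,
                            cells$a[i], cells$b[i])
    scenario[i] <- classify_scenario(net_gains(pars))
    tr <- tryCatch(
      integrate_game(pars, spec$init, t_max = t_max, ...),
      error = function(e) e
    )
    if (inherits(tr, "error")) {
      verdict[i] <- "error"
      diagnostic[i] <- conditionMessage(tr)
      next
    }
    max_viol <- max(max_viol, tr$max_boundary_violation)
    verdict[i] <- tr$verdict
    if (tr$verdict == "corner") {
      corner_alpha[i] <- tr$corner[1]
      corner_beta[i] <- tr$corner[2]
    }
  }

  # cell categories for the rule comparison
  strict_cell <- which.min((cells$a - 1)^2 + (cells$b - 1)^2)
  interior <- cells$a >= 0.1 & cells$a <= 0.9 &
    cells$b >= 0.1 & cells$b <= 0.9
  category <- ifelse(seq_len(n) == strict_cell, "strict_corner",
                     ifelse(interior, "interior", "edge"))

  verdict_label <- ifelse(verdict == "corner",
                          sprintf("corner (%g,%g)", corner_alpha,
                                  corner_beta),
                          verdict)
  expected_label <- function(corner) {
    if (is.null(corner)) NA_character_
    else sprintf("corner (%g,%g)", corner[1], corner[2])
  }
  exp_strict <- expected_label(spec$expected$strict)
  exp_prop <- expected_label(spec$expected$proportional)
  agree <- rep(NA, n)
  agree[category == "strict_corner"] <-
    verdict_label[category == "strict_corner"] == exp_strict
  agree[category == "interior"] <-
    verdict_label[category == "interior"] == exp_prop

  grid <- data.frame(a = cells$a, b = cells$b, scenario = scenario,
                     verdict = verdict_label,
                     corner_alpha = corner_alpha,
                     corner_beta = corner_beta,
                     category = category, agree = agree,
                     diagnostic = diagnostic)

  strict_pars <- new_game_params(spec$cc, spec$cs, spec$p, 1, 1,
                                 rule = "strict_override")
  strict_tr <- integrate_game(strict_pars, spec$init, t_max = t_max, ...)
  max_viol <- max(max_viol, strict_tr$max_boundary_violation)

  interior_verdicts <- verdict_label[category == "interior"]
  modal <- if (length(interior_verdicts)) {
    names(sort(table(interior_verdicts), decreasing = TRUE))[1]
  } else NA_character_

  structure(list(
    spec = spec, grid = grid,
    strict_override = list(verdict = strict_tr$verdict,
                           corner = strict_tr$corner,
                           final_state = strict_tr$final_state),
    modal_verdict = modal,
    expected = list(strict = exp_strict, proportional = exp_prop),
    disagreements = grid[!is.na(grid$agree) & !grid$agree, , drop = FALSE],
    max_boundary_violation = max_viol
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep result, case", x$spec$id,
      sprintf("(p = %g, cc = %g, cs = %g)\n", x$spec$p, x$spec$cc,
              x$spec$cs))
  cat("  grid:", nrow(x$grid), "cells; modal interior verdict:",
      x$modal_verdict, "\n")
  cat("  expected: strict", x$expected$strict, "/ proportional",
      x$expected$proportional, "\n")
  so <- x$strict_override
  cat("  strict-override run:",
      if (so$verdict == "corner")
        sprintf("corner (%g,%g)", so$corner[1], so$corner[2])
      else so$verdict, "\n")
  cat("  disagreement cells:", nrow(x$disagreements), "\n")
  invisible(x)
}

#' Phase portrait: flow field, interior equilibrium and basin regions
#'
#' Samples the replicator flow on a regular lattice over the unit square
#' and, when the interior equilibrium lies strictly inside, partitions the
#' square into the four rectangles delimited by `(alpha*, beta*)` with the
#' conventional attractor assignment: region I (upper-left) to (0,1),
#' region II (upper-right) to (1,1), region III (lower-left) to (0,0),
#' region IV (lower-right) to (1,0). When no corner is an ESS (the
#' all-saddle sign pattern, whose interior point is a centre), the result
#' is additionally flagged `cycling_expected`: the rectangle partition is
#' then only the conventional narrative, as trajectories orbit the centre
#' instead of converging.
#'
#' @param params A [game_params()] object.
#' @param n Lattice points per axis (default 15).
#' @return An object of class `phase_portrait`: list with the `field` data
#'   frame (`alpha`, `beta`, `dalpha`, `dbeta`), `interior` (list or
#'   `NULL`), `regions` (data frame or `NULL`), logical `cycling_expected`,
#'   and the `params`.
#' @examples
#' phase_portrait(game_params(cc = 10, cs = 6, p = 5, a = 0, b = 1), n = 5)
#' @export
phase_portrait <- function(params, n = 15) {
  stopifnot(inherits(params, "game_params"), n >= 2)
  lattice <- seq(0, 1, length.out = n)
  field <- expand.grid(alpha = lattice, beta = lattice)
  if (params$rule == "parametric") {
    field$dalpha <- school_flow_raw(params, field$alpha, field$beta)
    field$dbeta <- student_flow_raw(params, field$alpha, field$beta)
  } else {
    m <- build_payoff_matrix(params)
    fl <- t(vapply(seq_len(nrow(field)), function(i) {
      generic_bimatrix_flow(m, c(field$alpha[i], field$beta[i]))
    }, numeric(2)))
    field$dalpha <- fl[, 1]
    field$dbeta <- fl[, 2]
  }

  eq <- tryCatch(interior_equilibrium(params), error = function(e) NULL)
  regions <- NULL
  cycling <- FALSE
  if (params$rule == "parametric") {
    gains <- net_gains(params)
    cycling <- nrow(ess_corners(gains)) == 0L &&
      classify_scenario(gains) != "boundary" &&
      !is.null(eq) && eq$valid
    if (!is.null(eq) && eq$valid) {
      regions <- data.frame(
        region = c("I", "II", "III", "IV"),
        alpha_range = c(sprintf("[0, %.6g)", eq$alpha),
                        sprintf("(%.6g, 1]", eq$alpha),
                        sprintf("[0, %.6g)", eq$alpha),
                        sprintf("(%.6g, 1]", eq$alpha)),
        beta_range = c(sprintf("(%.6g, 1]", eq$beta),
                       sprintf("(%.6g, 1]", eq$beta),
                       sprintf("[0, %.6g)", eq$beta),
                       sprintf("[0, %.6g)", eq$beta)),
        attractor_alpha = c(0, 1, 0, 1),
        attractor_beta = c(1, 1, 0, 0)
      )
    }
  }
  if (is.null(regions) && !cycling && !is.null(eq) && !eq$valid) {
    eq <- c(eq, list(note = "outside the open unit square; field-only"))
  }
  structure(list(field = field, interior = eq, regions = regions,
                 cycling_expected = cycling, params = params),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat("Phase portrait (", nrow(x$field), "field samples )\n")
  if (!is.null(x$interior) && isTRUE(x$interior$valid)) {
    cat(sprintf("  interior equilibrium: (%.6g, %.6g)\n",
                x$interior$alpha, x$interior$beta))
  } else {
    cat("  no interior equilibrium in the open unit square\n")
  }
  if (x$cycling_expected) {
    cat("  no corner ESS: cycling expected around the interior centre\n")
  }
  if (!is.null(x$regions)) {
    print(x$regions, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.phase_portrait <- function(x, scale = 0.05, ...) {
  f <- x$field
  norm <- sqrt(f$dalpha^2 + f$dbeta^2)
  f <- f[norm > 0, ]  # rest points carry no arrow
  norm <- norm[norm > 0]
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "alpha (school)", ylab = "beta (students)", ...)
  graphics::arrows(f$alpha, f$beta,
                   f$alpha + scale * f$dalpha / norm,
                   f$beta + scale * f$dbeta / norm,
                   length = 0.03, col = "grey40")
  if (!is.null(x$interior) && isTRUE(x$interior$valid)) {
    graphics::points(x$interior$alpha, x$interior$beta, pch = 19,
                     col = "firebrick")
    graphics::abline(v = x$interior$alpha, h = x$interior$beta,
                     lty = 3, col = "firebrick")
  }
  invisible(x)
}
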