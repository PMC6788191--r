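#' Build the 2x2 payoff bimatrix
#'
#' Constructs the payoff bimatrix of the liability game. The student (with
#' guardians) is the row player, the school the column player; both choose
#' between `appropriate_caution` and `no_caution`. Payoffs are net incomes
#' (non-positive in this model: prevention costs and borne accident losses).
#'
#' Under the parametric rule the four cells are, as (student, school) pairs:
#' \describe{
#'   \item{(AC, AC)}{`(-cs, -cc)` — both pay their own prevention cost, no
#'     accident.}
#'   \item{(AC student, NC school)}{`(-(1-b) cs, -p - b cs)` — accident; the
#'     careless school bears the full loss plus the share `b` of the
#'     student's prevention cost.}
#'   \item{(NC student, AC school)}{`(-p, -cc)` — accident; the careless
#'     student bears the full loss.}
#'   \item{(NC, NC)}{`(-(1-a) p, -a p)` — accident; the loss is split by the
#'     share `a`.}
#' }
#'
#' Under `rule = "strict_override"` the school bears the full accident loss
#' whenever an accident occurs — even when only the student was careless —
#' and additionally the student's prevention cost in the (AC student, NC
#' school) cell. School payoffs across the four cells are `-cc`, `-p - cs`,
#' `-cc - p`, `-p`; the student's payoff is 0 in every cell where the
#' student is not paying their own prevention cost. Note the strict rule is
#' *not* the `a = 1, b = 1` limit of the parametric rule: the two differ in
#' the (NC student, AC school) cell, where the strict rule shifts the loss
#' `p` from the careless student onto the cautious school.
#'
#' @param params A [game_params()] object.
#' @return An object of class `payoff_bimatrix`: a list with 2x2 matrices
#'   `student` and `school` (rows: student strategy, columns: school
#'   strategy, dimnames `appropriate_caution` / `no_caution`) and the `rule`
#'   tag.
#' @examples
#' build_payoff_matrix(game_params(cc = 10, cs = 6, p = 5, a = 0.5, b = 0.5))
#' @export
build_payoff_matrix <- function(params) {
  stopifnot(inherits(params, "game_params"))
  strat <- c("appropriate_caution", "no_caution")
  dn <- list(student = strat, school = strat)
  cc <- params$cc; cs <- params$cs; p <- params$p
  a <- params$a; b <- params$b
  if (params$rule == "parametric") {
    student <- matrix(c(-cs,            -(1 - b) * cs,
                        -p,             -(1 - a) * p),
                      nrow = 2, byrow = TRUE, dimnames = dn)
    school  <- matrix(c(-cc,            -p - b * cs,
                        -cc,            -a * p),
                      nrow = 2, byrow = TRUE, dimnames = dn)
  } else {
    student <- matrix(c(-cs, 0,
                        0,   0),
                      nrow = 2, byrow = TRUE, dimnames = dn)
    school  <- matrix(c(-cc,      -p - cs,
                        -cc - p,  -p),
                      nrow = 2, byrow = TRUE, dimnames = dn)
  }
  structure(list(student = student, school = school, rule = params$rule),
            class = "payoff_bimatrix")
}

#' @export
print.payoff_bimatrix <- function(x, ...) {
  cat("Payoff bimatrix (student, school), rule:", x$rule, "\n")
  zap <- function(v) { v[v == 0] <- 0; v }  # drop signed zeros
  cells <- matrix(sprintf("(%g, %g)", zap(x$student), zap(x$school)),
                  nrow = 2, dimnames = dimnames(x$student))
  print(cells, quote = FALSE)
  invisible(x)
}

#' Corner net-income differentials
#'
#' The four net gains from switching to "appropriate caution" at the corners
#' of the strategy square, computed on the parametric payoff matrix
#' (independent of the rule tag):
#' \describe{
#'   \item{pi1 `= a p - cc`}{school's gain from caution when students are
#'     careless;}
#'   \item{pi2 `= p + b cs - cc`}{school's gain from caution when students
#'     are cautious;}
#'   \item{pi3 `= p - cs`}{students' gain from caution when the school is
#'     cautious;}
#'   \item{pi4 `= (1-a) p - (1-b) cs`}{students' gain from caution when the
#'     school is careless.}
#' }
#' Their signs determine which corner, if any, is an ESS. Note
#' `pi2 - pi1 = (1-a) p + b cs >= 0` always, so `pi1 > 0` implies
#' `pi2 > 0`.
#'
#' @param params A [game_params()] object.
#' @return An object of class `net_gains`: named numeric vector
#'   `(pi1, pi2, pi3, pi4)` with a `scale` attribute (monetary magnitude,
#'   used for sign tolerances).
#' @examples
#' net_gains(game_params(cc = 10, cs = 6, p = 5, a = 1, b = 0.5))
#' @export
net_gains <- function(params) {
  stopifnot(inherits(params, "game_params"))
  g <- c(pi1 = params$a * params$p - params$cc,
         pi2 = params$p + params$b * params$cs - params$cc,
         pi3 = params$p - params$cs,
         pi4 = (1 - params$a) * params$p - (1 - params$b) * params$cs)
  structure(g, scale = param_scale(params), class = "net_gains")
}

#' @export
print.net_gains <- function(x, ...) {
  cat("Corner net gains:\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

# The ten tabulated strict-sign patterns, in matching order; columns are the
# required signs of (pi1, pi2, pi3, pi4); NA = unconstrained.
scenario_patterns <- function() {
  rbind(
    `1`  = c(-1, -1, -1, -1),
    `2`  = c(-1,  1, -1, -1),
    `3`  = c(-1,  1,  1, -1),
    `4`  = c(-1, -1,  1, -1),
    `5`  = c(-1,  1,  1,  1),
    `6`  = c( 1,  1,  1, -1),
    `7`  = c(-1, -1,  1,  1),
    `8`  = c(-1, -1, -1,  1),
    `9`  = c( 1, NA, -1,  1),
    `10` = c(-1,  1, -1,  1)
  )
}

#' Map a sign pattern of net gains to its stability scenario
#'
#' Matches the strict sign pattern of `(pi1, pi2, pi3, pi4)` against the ten
#' tabulated scenarios of the stability discrimination table. Scenarios 1-8
#' are fully specified four-sign patterns; scenario 9 (`pi1 > 0, pi3 < 0,
#' pi4 > 0`) and scenario 10 (`pi1 pi2 < 0, pi3 pi4 < 0, pi1 pi3 > 0`) are
#' matched afterwards. Any component within tolerance of zero yields
#' `"boundary"` (non-hyperbolic corners must not receive a silent ESS
#' verdict). Two feasible strict patterns, `(+,+,-,-)` and `(+,+,+,+)`, fall
#' outside the tabulation and return `"unlisted"`; their equilibria are
#' still fully classified by [classify_equilibria()].
#'
#' @param gains A [net_gains()] object (or numeric vector `pi1..pi4`).
#' @param tol Absolute tolerance below which a component counts as zero;
#'   default `1e-12 * max(|cc|, |cs|, |p|)` (falls back to `1e-12` if the
#'   gains carry no scale attribute).
#' @return A character scalar: `"1"`..`"10"`, `"boundary"`, or
#'   `"unlisted"`.
#' @examples
#' classify_scenario(net_gains(game_params(cc = 10, cs = 6, p = 5,
#'                                         a = 1, b = 0.5)))
#' @export
classify_scenario <- function(gains, tol = NULL) {
  g <- as.numeric(gains)
  stopifnot(length(g) == 4L, all(is.finite(g)))
  if (is.null(tol)) {
    sc <- attr(gains, "scale")
    tol <- 1e-12 * if (is.null(sc)) 1 else max(1, sc)
  }
  if (any(abs(g) <= tol)) return("boundary")
  s <- sign(g)
  if (s[1] > 0 && s[2] < 0) {
    stop("infeasible sign pattern: pi1 > 0 with pi2 < 0 is impossible for ",
         "valid parameters (pi2 - pi1 = (1-a)p + b cs >= 0)", call. = FALSE)
  }
  pat <- scenario_patterns()
  for (i in seq_len(nrow(pat))) {
    row <- pat[i, ]
    ok <- is.na(row) | row == s
    if (all(ok)) return(rownames(pat)[i])
  }
  "unlisted"
}

# ESS corner designated by each tabulated scenario (NULL for 10 = none).
# "unlisted" patterns resolve through ess_corners() instead.
scenario_ess_corner <- function(label) {
  switch(label,
         `1` = , `2` = , `3` = , `4` = c(0, 0),
         `5` = , `6` = c(1, 1),
         `7` = , `8` = c(0, 1),
         `9` = c(1, 0),
         `10` = NULL,
         boundary = NULL,
         unlisted = NULL,
         stop("unknown scenario label: ", label, call. = FALSE))
}

# Corner-ESS predicates in terms of the net gains:
# (0,0) ESS <=> pi1<0 & pi4<0 ; (1,1) <=> pi2>0 & pi3>0 ;
# (0,1) <=> pi2<0 & pi4>0 ; (1,0) <=> pi1>0 & pi3<0.
# Returns a matrix of ESS corners (possibly 0 rows).
ess_corners <- function(gains, tol = 0) {
  g <- as.numeric(gains)
  corners <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  keep <- c(g[1] < -tol && g[4] < -tol,
            g[2] < -tol && g[4] >  tol,
            g[1] >  tol && g[3] < -tol,
            g[2] >  tol && g[3] >  tol)
  corners[keep, , drop = FALSE]
}
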