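#' Model parameters for the injury-liability evolutionary game
#'
#' Bundles the five scalar parameters of the two-population game played
#' between a school and the students and their guardians over
#' accident-prevention effort, together with the liability rule used to
#' construct payoffs.
#'
#' Both players choose between "appropriate caution" (undertake common-sense
#' prevention effort, at cost `cc` for the school, `cs` for the student) and
#' "no caution". An accident, costing `p` in total, occurs whenever at least
#' one player is careless. Under the parametric (proportional) rule the
#' school bears the share `a` of the loss when neither side is cautious, and
#' reimburses the share `b` of the student's prevention cost when only the
#' student was cautious. Under the strict rule (`rule = "strict_override"`)
#' the school bears the full loss whenever an accident occurs, regardless of
#' its own caution, and the a, b shares play no role in the payoffs.
#'
#' The usual cost ordering `cs < cc` is not enforced (several standard case
#' studies violate it); a warning is emitted when `cs >= cc`.
#'
#' @param cc School prevention cost, currency units, > 0.
#' @param cs Student/guardian prevention cost, currency units, > 0.
#' @param p Total accident loss, currency units, > 0.
#' @param a School's share of the accident loss when neither side is
#'   cautious; dimensionless, in \[0, 1\].
#' @param b Share of the student's prevention cost borne by the school when
#'   only the student is cautious; dimensionless, in \[0, 1\].
#' @param rule Liability rule: `"parametric"` (default; loss split by `a`,
#'   `b`) or `"strict_override"` (school bears the full loss whenever an
#'   accident occurs).
#'
#' @return An object of class `game_params`: a named list with elements
#'   `cc`, `cs`, `p`, `a`, `b`, `rule`.
#' @examples
#' game_params(cc = 10, cs = 6, p = 5, a = 0.5, b = 0.5)
#' @export
game_params <- function(cc, cs, p, a, b,
                        rule = c("parametric", "strict_override")) {
  rule <- match.arg(rule)
  check_positive_scalar(cc, "cc")
  check_positive_scalar(cs, "cs")
  check_positive_scalar(p, "p")
  check_unit_scalar(a, "a")
  check_unit_scalar(b, "b")
  if (cs >= cc) {
    warning("cs >= cc: student prevention cost is not below the school's; ",
            "proceeding (the cost ordering is not enforced)", call. = FALSE)
  }
  new_game_params(cc, cs, p, a, b, rule)
}

# internal constructor: validated inputs, no cs/cc warning (used in sweeps)
new_game_params <- function(cc, cs, p, a, b, rule = "parametric") {
  structure(list(cc = cc, cs = cs, p = p, a = a, b = b, rule = rule),
            class = "game_params")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("parameter `%s` must be a finite scalar > 0 (got %s)",
                 name, format(x)[1]), call. = FALSE)
  }
  invisible(x)
}

check_unit_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("parameter `%s` must lie in [0, 1] (got %s)",
                 name, format(x)[1]), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.game_params <- function(x, ...) {
  cat("Injury-liability game parameters (rule: ", x$rule, ")\n", sep = "")
  cat(sprintf("  cc = %g (school prevention cost)\n", x$cc))
  cat(sprintf("  cs = %g (student prevention cost)\n", x$cs))
  cat(sprintf("  p  = %g (total accident loss)\n", x$p))
  cat(sprintf("  a  = %g (school's loss share)\n", x$a))
  cat(sprintf("  b  = %g (student prevention-cost share borne by school)\n",
              x$b))
  invisible(x)
}

# monetary scale of a parameter set, used to set relative tolerances
param_scale <- function(params) {
  max(abs(params$cc), abs(params$cs), abs(params$p))
}

# validate a state profile (alpha, beta); returns c(alpha, beta)
check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state))) {
    stop("state must be a finite numeric vector c(alpha, beta)",
         call. = FALSE)
  }
  if (any(state < 0) || any(state > 1)) {
    stop(sprintf("state (%g, %g) outside the unit square [0,1]^2",
                 state[1], state[2]), call. = FALSE)
  }
  as.numeric(state)
}

#' Draw random valid parameter sets
#'
#' Samples parameter sets uniformly for property checks and basin sampling:
#' costs and losses uniform on `cost_range`, shares `a`, `b` uniform on
#' \[0, 1\]. Respects the current RNG state, so wrap in [set.seed()] for
#' reproducibility.
#'
#' @param n Number of parameter sets to draw.
#' @param cost_range Range (min, max) for `cc`, `cs` and `p`, both > 0.
#' @param rule Liability rule assigned to every draw.
#' @return A list of `n` [game_params()] objects.
#' @examples
#' set.seed(1)
#' draws <- random_params(3)
#' @export
random_params <- function(n, cost_range = c(0.5, 20), rule = "parametric") {
  stopifnot(length(cost_range) == 2L, all(cost_range > 0),
            cost_range[1] < cost_range[2])
  replicate(n, new_game_params(
    cc = stats::runif(1, cost_range[1], cost_range[2]),
    cs = stats::runif(1, cost_range[1], cost_range[2]),
    p  = stats::runif(1, cost_range[1], cost_range[2]),
    a  = stats::runif(1),
    b  = stats::runif(1),
    rule = rule
  ), simplify = FALSE)
}
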