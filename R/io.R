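# Configuration parsing/validation and deterministic serialization.

config_defaults <- function() {
  list(
    rule = "parametric",
    integration = list(t_max = 500, rtol = 1e-10, atol = 1e-12,
                       corner_tol = 1e-3, flow_tol = 1e-8, n_out = 501),
    sweep = list(a_min = 0, a_max = 1, b_min = 0, b_max = 1,
                 resolution = 21),
    output = list(dir = ".", formats = c("csv", "json")),
    seed = NULL
  )
}

#' Load and validate a run configuration
#'
#' Reads a structured-text configuration (YAML, or JSON when the file
#' extension is `.json`), validates every field against its domain, rejects
#' unknown keys, and fills defaults for everything optional. The required
#' keys are the five model parameters `cc`, `cs`, `p`, `a`, `b`; optional
#' are `rule` and the blocks `integration` (`t_max`, `rtol`, `atol`,
#' `corner_tol`, `flow_tol`, `n_out`), `sweep` (`a_min`, `a_max`, `b_min`,
#' `b_max`, `resolution`), `output` (`dir`, `formats`) and `seed` (only
#' used when sampling initial conditions for basin maps). The fully
#' resolved configuration is returned and should be echoed into every
#' output for reproducibility.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config`: the resolved configuration
#'   list.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines("cc: 10\ncs: 6\np: 5\na: 0.5\nb: 0.5", cfg_file)
#' load_config(cfg_file)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  resolve_config(raw)
}

#' Resolve and validate a configuration list
#'
#' Performs the same validation and default-filling as [load_config()] on
#' an in-memory list.
#'
#' @param raw A named list of configuration values.
#' @return An object of class `run_config`.
#' @export
resolve_config <- function(raw) {
  if (!is.list(raw)) stop("configuration must be a key/value mapping",
                          call. = FALSE)
  defaults <- config_defaults()
  known_top <- c("cc", "cs", "p", "a", "b", "rule",
                 "integration", "sweep", "output", "seed")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in c("cc", "cs", "p", "a", "b")) {
    if (is.null(raw[[key]])) {
      stop("missing required configuration key: ", key, call. = FALSE)
    }
  }
  num_scalar <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("configuration key `%s` must be a finite number", key),
           call. = FALSE)
    }
    as.numeric(x)
  }
  domain_pos <- function(x, key) {
    x <- num_scalar(x, key)
    if (x <= 0) stop(sprintf("configuration key `%s` must be > 0 (got %g)",
                             key, x), call. = FALSE)
    x
  }
  domain_unit <- function(x, key) {
    x <- num_scalar(x, key)
    if (x < 0 || x > 1) {
      stop(sprintf("configuration key `%s` = %g outside [0, 1]", key, x),
           call. = FALSE)
    }
    x
  }
  cfg <- list(
    cc = domain_pos(raw$cc, "cc"),
    cs = domain_pos(raw$cs, "cs"),
    p = domain_pos(raw$p, "p"),
    a = domain_unit(raw$a, "a"),
    b = domain_unit(raw$b, "b"),
    rule = if (is.null(raw$rule)) defaults$rule else raw$rule
  )
  if (!cfg$rule %in% c("parametric", "strict_override")) {
    stop("configuration key `rule` must be \"parametric\" or ",
         "\"strict_override\" (got \"", cfg$rule, "\")", call. = FALSE)
  }
  fill_block <- function(name, checks) {
    block <- raw[[name]]
    def <- defaults[[name]]
    if (is.null(block)) return(def)
    if (!is.list(block)) {
      stop("configuration block `", name, "` must be a mapping",
           call. = FALSE)
    }
    unknown <- setdiff(names(block), names(def))
    if (length(unknown)) {
      stop("unknown key(s) in block `", name, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- utils::modifyList(def, block)
    for (key in names(checks)) out[[key]] <- checks[[key]](out[[key]],
                                                           paste0(name, ".", key))
    out
  }
  cfg$integration <- fill_block("integration", list(
    t_max = domain_pos, rtol = domain_pos, atol = domain_pos,
    corner_tol = domain_pos, flow_tol = domain_pos, n_out = domain_pos))
  cfg$sweep <- fill_block("sweep", list(
    a_min = domain_unit, a_max = domain_unit,
    b_min = domain_unit, b_max = domain_unit, resolution = domain_pos))
  if (cfg$sweep$a_min >= cfg$sweep$a_max ||
      cfg$sweep$b_min >= cfg$sweep$b_max) {
    stop("sweep ranges must satisfy a_min < a_max and b_min < b_max",
         call. = FALSE)
  }
  out_block <- raw$output
  if (is.null(out_block)) {
    cfg$output <- defaults$output
  } else {
    unknown <- setdiff(names(out_block), names(defaults$output))
    if (length(unknown)) {
      stop("unknown key(s) in block `output`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg$output <- utils::modifyList(defaults$output, out_block)
    bad <- setdiff(cfg$output$formats, c("csv", "json"))
    if (length(bad)) {
      stop("output.formats must be drawn from {csv, json}", call. = FALSE)
    }
  }
  cfg$seed <- if (is.null(raw$seed)) NULL else {
    s <- num_scalar(raw$seed, "seed")
    if (s != round(s)) stop("configuration key `seed` must be an integer",
                            call. = FALSE)
    as.integer(s)
  }
  structure(cfg, class = "run_config")
}

#' Extract the game parameters from a resolved configuration
#'
#' @param config A `run_config` object from [load_config()].
#' @return A [game_params()] object.
#' @export
config_params <- function(config) {
  stopifnot(inherits(config, "run_config"))
  game_params(cc = config$cc, cs = config$cs, p = config$p,
              a = config$a, b = config$b, rule = config$rule)
}

#' Write a resolved configuration back to YAML
#'
#' Round-trips with [load_config()]: writing a resolved configuration and
#' reloading it yields an identical resolved configuration.
#'
#' @param config A `run_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$seed <- config$seed  # drop NULL cleanly
  lst <- lst[!vapply(lst, is.null, logical(1))]
  yaml::write_yaml(lst, path, precision = 12)
  invisible(path)
}

# fixed-precision number formatting: 12 significant digits, "." decimal
format_num <- function(x) sprintf("%.12g", x)

#' Export a trajectory as delimited text
#'
#' Writes the time series as CSV with header `t,alpha,beta`, "." as the
#' decimal separator and 12 significant digits, so repeated runs with
#' identical configuration are byte-stable.
#'
#' @param trajectory A `game_trajectory` from [integrate_game()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "game_trajectory"))
  lines <- c("t,alpha,beta",
             paste(format_num(trajectory$times),
                   format_num(trajectory$states[, "alpha"]),
                   format_num(trajectory$states[, "beta"]), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Export a classification or trajectory report as JSON
#'
#' Serializes a stability report or trajectory verdict as structured text
#' with snake_case keys and 12 significant digits. When a resolved
#' configuration is supplied it is echoed into the report.
#'
#' @param x A `stability_report` or `game_trajectory`.
#' @param path Output path.
#' @param config Optional `run_config` echoed under `config`.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, config = NULL) {
  payload <- if (inherits(x, "stability_report")) {
    eq <- x$equilibria
    list(
      parameters = x$params[c("cc", "cs", "p", "a", "b", "rule")],
      net_gains = as.list(stats::setNames(as.numeric(x$gains),
                                          c("pi1", "pi2", "pi3", "pi4"))),
      scenario = x$scenario,
      equilibria = lapply(seq_len(nrow(eq)), function(i) {
        list(alpha = eq$alpha[i], beta = eq$beta[i],
             det = eq$det[i], tr = eq$tr[i], class = eq$class[i])
      })
    )
  } else if (inherits(x, "game_trajectory")) {
    list(
      parameters = x$params[c("cc", "cs", "p", "a", "b", "rule")],
      verdict = x$verdict,
      corner = if (is.null(x$corner)) NULL else as.numeric(x$corner),
      final_state = as.numeric(x$final_state),
      flow_norm = x$flow_norm,
      max_boundary_violation = x$max_boundary_violation,
      settings = x$settings
    )
  } else {
    stop("unsupported object for JSON report", call. = FALSE)
  }
  if (!is.null(config)) payload$config <- unclass(config)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(12),
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
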