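#' Run configuration
#'
#' Bundles every tunable of a measurement run: the binarization threshold,
#' the lambda start value (accepted as milli-lambda, i.e. an integer such as
#' 1000 for lambda = 1, matching the convention of entering lambda times
#' 1000), the sampling grid, the energy cut fractions, the hill-climb
#' constants, the operator id and the RNG seed. All fields are defaulted and
#' fully serialized into every result row, so any run is reproducible from
#' its records.
#'
#' @param threshold Binarization threshold, 0-255.
#' @param lambda_start Start lambda; values above 10 are read as milli-lambda.
#' @param cut_top,cut_bottom Energy cut fractions.
#' @param delta0,decay,delta_min Hill-climb constants.
#' @param tau_min,tau_max,step Sampling grid.
#' @param operator Operator identifier.
#' @param seed RNG seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(threshold = 128, lambda_start = 1000,
                       cut_top = 0.05, cut_bottom = 0.10,
                       delta0 = 0.5, decay = 1.6, delta_min = 0.005,
                       tau_min = -20, tau_max = 20, step = 0.05,
                       operator = "P1", seed = 1) {
  cfg <- structure(
    list(threshold = threshold, lambda_start = lambda_start,
         cut_top = cut_top, cut_bottom = cut_bottom,
         delta0 = delta0, decay = decay, delta_min = delta_min,
         tau_min = tau_min, tau_max = tau_max, step = step,
         operator = operator, seed = seed),
    class = "run_config")
  # validate by constructing the component configs
  energy_config(cfg$cut_top, cfg$cut_bottom)
  hill_climb_config(cfg$delta0, cfg$decay, cfg$delta_min)
  curve_sampling(cfg$tau_min, cfg$tau_max, cfg$step)
  cfg
}

#' Read a run configuration from a key = value file
#'
#' Lines of the form `key = value` (or `key=value`); `#` starts a comment.
#' Unknown keys are rejected. Keys are the arguments of [run_config()].
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file (flags win over the file).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.+)$", lines))
  if (any(lengths(parts) != 3)) {
    pc_abort(paste0("Malformed config line in ", path),
             "pathcurve_bad_config")
  }
  keys <- vapply(parts, `[`, "", 2)
  vals <- trimws(vapply(parts, `[`, "", 3))
  allowed <- names(formals(run_config))
  if (length(bad <- setdiff(keys, allowed)) > 0) {
    pc_abort(paste0("Unknown config key(s): ", paste(bad, collapse = ", ")),
             "pathcurve_bad_config")
  }
  args <- stats::setNames(as.list(vals), keys)
  num <- setdiff(allowed, "operator")
  args[names(args) %in% num] <- lapply(args[names(args) %in% num], as.numeric)
  args <- utils::modifyList(args, list(...))
  do.call(run_config, args)
}

#' Component configs from a run configuration
#' @param cfg A [run_config()].
#' @return `energy_config`, `hill_climb_config` or `curve_sampling`.
#' @export
as_energy_config <- function(cfg) energy_config(cfg$cut_top, cfg$cut_bottom)

#' @rdname as_energy_config
#' @export
as_hill_climb_config <- function(cfg)
  hill_climb_config(cfg$delta0, cfg$decay, cfg$delta_min)

#' @rdname as_energy_config
#' @export
as_curve_sampling <- function(cfg)
  curve_sampling(cfg$tau_min, cfg$tau_max, cfg$step)
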