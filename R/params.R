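#' Simulation parameters
#'
#' Construct and validate the full parameter set of a simulation run.
#' Defaults are the study conditions used throughout: a population of
#' `n = 100` labs, base rate `b = 0.1`, power `W = 0.8`, initial false
#' positive rate `alpha0 = 0.05`, startup funds `G0 = 10`, grant size
#' `G = 10`, sample size `d = 10` for death/birth/funding events, and
#' mutation standard deviation `epsilon = 0.01`.
#'
#' @param n Number of labs in the population.
#' @param b Base rate: probability that a newly selected hypothesis is
#'   true.
#' @param W Statistical power: probability that a true hypothesis yields
#'   a positive result.
#' @param alpha0 Initial false positive rate of every founding lab.
#' @param G0 Startup funds of every new lab (1 fund = 1 study).
#' @param G Grant size, in funds.
#' @param d Number of labs sampled for each death, birth and funding
#'   event.
#' @param epsilon Standard deviation of the Gaussian mutation applied to
#'   the inherited false positive rate.
#' @param r Peer-review efficacy: probability that an erroneous result
#'   (one incongruent with the hypothesis's truth) is blocked from
#'   publication.
#' @param p Probability that a negative result is publishable (positive
#'   results are always publishable).
#' @param strategy Funding allocation strategy: `"PH"` (most
#'   publications), `"MI"` (lowest alpha), `"RA"` (uniform random),
#'   `"MS"` (MI with probability `X`, else RA), or `"ML"` (uniform over
#'   applicants with alpha <= `A`).
#' @param X Mixing proportion for the `"MS"` strategy.
#' @param A Qualification threshold for the `"ML"` modified lottery.
#' @param selection_mode `"strong"` (parent = most-published lab of a
#'   random `d`-sample) or `"proportional"` (parent chosen from the whole
#'   population with probability proportional to publications).
#' @param iterations Number of iterations to run.
#' @param seed Integer seed; a run is fully determined by `(seed, params)`.
#' @param record_interval Record the state every this many iterations.
#' @param fdr_window Trailing window (iterations) for the windowed false
#'   discovery rate attached to each record.
#' @param do_evolution,do_funding Stage switches; disabling either
#'   freezes the corresponding dynamics (used for oracle validation).
#' @param auto_refund If `TRUE`, every lab is topped up to at least one
#'   fund before each Science stage (oracle validation only).
#'
#' @return A validated object of class `"lab_params"`.
#' @seealso [validate_params()], [read_params()], [run_simulation()]
#' @examples
#' p <- lab_params(strategy = "ML", A = 0.3, iterations = 1000)
#' p
#' @export
lab_params <- function(n = 100, b = 0.1, W = 0.8, alpha0 = 0.05,
                       G0 = 10, G = 10, d = 10, epsilon = 0.01,
                       r = 0, p = 0,
                       strategy = c("PH", "MI", "RA", "MS", "ML"),
                       X = NULL, A = NULL,
                       selection_mode = c("strong", "proportional"),
                       iterations = 100000, seed = 1,
                       record_interval = 100, fdr_window = 10000,
                       do_evolution = TRUE, do_funding = TRUE,
                       auto_refund = FALSE) {
  strategy <- match.arg(strategy)
  selection_mode <- match.arg(selection_mode)
  params <- structure(list(
    n = as.integer(n), b = b, W = W, alpha0 = alpha0,
    G0 = as.integer(G0), G = as.integer(G), d = as.integer(d),
    epsilon = epsilon, r = r, p = p,
    strategy = strategy,
    X = if (is.null(X) || is.na(X)) NULL else as.numeric(X),
    A = if (is.null(A) || is.na(A)) NULL else as.numeric(A),
    selection_mode = selection_mode,
    iterations = as.integer(iterations), seed = as.integer(seed),
    record_interval = as.integer(record_interval),
    fdr_window = as.integer(fdr_window),
    do_evolution = isTRUE(do_evolution),
    do_funding = isTRUE(do_funding),
    auto_refund = isTRUE(auto_refund)
  ), class = "lab_params")
  validate_params(params)
}

#' Validate a parameter set
#'
#' Checks every invariant of a [lab_params()] object and returns it
#' unchanged if all hold. Each rejection names the offending field.
#'
#' @param params A `"lab_params"` object (or a bare list with the same
#'   fields).
#' @return `params`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- params[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      fail(field, "must be a probability in [0, 1]")
  }
  chk_count <- function(field, min = 0L) {
    v <- params[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != as.integer(v))
      fail(field, sprintf("must be an integer >= %d", min))
  }
  for (f in c("b", "W", "alpha0", "r", "p")) chk_prob(f)
  chk_count("n", 1L)
  chk_count("d", 1L)
  chk_count("G", 0L)
  chk_count("G0", 0L)
  chk_count("iterations", 0L)
  chk_count("record_interval", 1L)
  chk_count("fdr_window", 1L)
  if (!is.numeric(params$epsilon) || params$epsilon < 0)
    fail("epsilon", "must be a non-negative number")
  if (params$d > params$n) fail("d", "cannot exceed the population size n")
  if (!params$strategy %in% c("PH", "MI", "RA", "MS", "ML"))
    fail("strategy", "must be one of PH, MI, RA, MS, ML")
  if (params$strategy == "MS") {
    if (is.null(params$X)) fail("X", "must be set for the MS strategy")
    chk_prob("X")
  }
  if (params$strategy == "ML") {
    if (is.null(params$A)) fail("A", "must be set for the ML strategy")
    chk_prob("A")
  }
  if (!params$selection_mode %in% c("strong", "proportional"))
    fail("selection_mode", "must be 'strong' or 'proportional'")
  invisible(params)
}

#' @export
print.lab_params <- function(x, ...) {
  strat <- x$strategy
  if (strat == "MS") strat <- sprintf("MS(X = %g)", x$X)
  if (strat == "ML") strat <- sprintf("ML(A = %g)", x$A)
  cat("Lab population simulation parameters\n")
  cat(sprintf("  population:  n = %d labs, alpha0 = %g, G0 = %d funds\n",
              x$n, x$alpha0, x$G0))
  cat(sprintf("  science:     b = %g, W = %g, p = %g, r = %g\n",
              x$b, x$W, x$p, x$r))
  cat(sprintf("  evolution:   d = %d, epsilon = %g, selection = %s\n",
              x$d, x$epsilon, x$selection_mode))
  cat(sprintf("  funding:     strategy = %s, G = %d\n", strat, x$G))
  cat(sprintf("  run:         %d iterations, seed %d, record every %d\n",
              x$iterations, x$seed, x$record_interval))
  invisible(x)
}

# Fields serialized to/from config files, in canonical order.
params_fields <- function() {
  c("n", "b", "W", "alpha0", "G0", "G", "d", "epsilon", "r", "p",
    "strategy", "X", "A", "selection_mode", "iterations", "seed",
    "record_interval", "fdr_window", "do_evolution", "do_funding",
    "auto_refund")
}

#' Read or write a parameter set as YAML or JSON
#'
#' Config files mirror the [lab_params()] field names exactly; the
#' format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#' `read_params()` validates on read, and `overrides` (a named list,
#' e.g. from CLI flags) take precedence over file values.
#'
#' @param path File path.
#' @param overrides Named list of field values overriding the file.
#' @param params A `"lab_params"` object to write.
#' @return `read_params()` returns a validated `"lab_params"`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path, overrides = list()) {
  vals <- read_config(path)
  vals <- vals[intersect(names(vals), params_fields())]
  vals <- modifyList(vals, overrides)
  do.call(lab_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  vals <- unclass(params)[params_fields()]
  vals <- vals[!vapply(vals, is.null, logical(1))]
  write_config(vals, path)
  invisible(path)
}

read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
}
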