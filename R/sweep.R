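#' Specify a replicated parameter sweep
#'
#' A sweep crosses named parameter axes (or takes an explicit condition
#' table) over a base parameter set and runs `replicates` seeded runs
#' per condition. Seeds derive deterministically from the canonical
#' condition enumeration: condition `i`, replicate `j` uses seed
#' `seed_base + 100003*(i-1) + (j-1)`, so execution order is irrelevant
#' and appending conditions never changes existing results.
#'
#' @param base A [lab_params()] object supplying every field not swept.
#' @param axes Named list of value vectors to cross with
#'   [expand.grid()] (e.g. `list(strategy = c("PH","RA"), G = c(10,85))`).
#'   Ignored when `conditions` is given.
#' @param conditions Optional data frame, one row per condition, columns
#'   named after [lab_params()] fields (for linked axes such as
#'   `p = r`).
#' @param replicates Runs per condition.
#' @param seed_base Base seed.
#' @param iterations Run length (overrides `base`).
#' @param equilibrium_window Final window (iterations) for equilibrium
#'   statistics.
#' @return An object of class `"sweep_spec"`.
#' @examples
#' spec <- sweep_spec(lab_params(iterations = 2000),
#'                    axes = list(strategy = c("MI", "RA")),
#'                    replicates = 2)
#' @export
sweep_spec <- function(base, axes = NULL, conditions = NULL,
                       replicates = 5, seed_base = 1,
                       iterations = base$iterations,
                       equilibrium_window = 10000) {
  if (is.null(conditions)) {
    stopifnot(!is.null(axes), length(names(axes)) == length(axes))
    conditions <- expand.grid(axes, stringsAsFactors = FALSE,
                              KEEP.OUT.ATTRS = FALSE)
  }
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1,
            replicates >= 1)
  bad <- setdiff(names(conditions), params_fields())
  if (length(bad) > 0)
    stop("unknown parameter axis: ", paste(bad, collapse = ", "))
  structure(list(base = base, conditions = conditions,
                 replicates = as.integer(replicates),
                 seed_base = as.integer(seed_base),
                 iterations = as.integer(iterations),
                 equilibrium_window = as.integer(equilibrium_window)),
            class = "sweep_spec")
}

#' @rdname sweep_spec
#' @param condition,replicate Canonical condition index and replicate
#'   index (1-based).
#' @details `sweep_seed` exposes the seed derivation rule.
#' @export
sweep_seed <- function(seed_base, condition, replicate) {
  as.integer((seed_base + 100003 * (condition - 1) + (replicate - 1)) %%
               2147483647)
}

# Parameters of one condition x replicate cell.
condition_params <- function(spec, condition, replicate) {
  vals <- unclass(spec$base)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  over <- as.list(spec$conditions[condition, , drop = FALSE])
  over <- over[!vapply(over, is.na, logical(1))]
  vals <- modifyList(vals, over)
  vals$iterations <- spec$iterations
  vals$seed <- sweep_seed(spec$seed_base, condition, replicate)
  do.call(lab_params, vals)
}

#' Run a replicated parameter sweep
#'
#' Runs every condition x replicate cell of a [sweep_spec()] and
#' aggregates equilibrium statistics (final-window mean alpha and
#' windowed false discovery rate) across replicates.
#'
#' @param spec A `"sweep_spec"` object.
#' @param .order Optional permutation of cell execution order (results
#'   are independent of it; used to test the contract).
#' @return An object of class `"lab_sweep"`: a list with `runs` (one
#'   row per condition x replicate: condition index, swept values, seed,
#'   `alpha_eq`, `F_eq`, `convergence`, `total_publications`),
#'   `summary` (per-condition mean/median/sd across replicates), and
#'   `spec`.
#' @export
run_sweep <- function(spec, .order = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  n_cond <- nrow(spec$conditions)
  cells <- expand.grid(replicate = seq_len(spec$replicates),
                       condition = seq_len(n_cond))
  ord <- if (is.null(.order)) seq_len(nrow(cells)) else .order
  rows <- vector("list", nrow(cells))
  for (k in ord) {
    ci <- cells$condition[k]
    ri <- cells$replicate[k]
    pars <- condition_params(spec, ci, ri)
    sim <- run_simulation(pars)
    eq <- equilibrium_stats(sim, spec$equilibrium_window)
    last <- sim$record[nrow(sim$record), ]
    rows[[k]] <- cbind(
      data.frame(condition = ci, replicate = ri, seed = pars$seed),
      spec$conditions[ci, , drop = FALSE],
      data.frame(alpha_eq = eq$alpha_eq, F_eq = eq$F_eq,
                 convergence = convergence_iteration(
                   sim, spec$equilibrium_window),
                 total_publications = last$cum_publications,
                 row.names = NULL)
    )
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  agg <- lapply(split(runs, runs$condition), function(g) {
    cbind(g[1L, c("condition", names(spec$conditions)), drop = FALSE],
          data.frame(replicates = nrow(g),
                     alpha_eq_mean = mean(g$alpha_eq),
                     alpha_eq_median = median(g$alpha_eq),
                     alpha_eq_sd = sd(g$alpha_eq),
                     F_eq_mean = mean(g$F_eq, na.rm = TRUE),
                     F_eq_median = median(g$F_eq, na.rm = TRUE),
                     F_eq_sd = sd(g$F_eq),
                     row.names = NULL))
  })
  summary_df <- do.call(rbind, agg)
  summary_df <- summary_df[order(summary_df$condition), , drop = FALSE]
  rownames(summary_df) <- NULL
  structure(list(runs = runs, summary = summary_df, spec = spec),
            class = "lab_sweep")
}

#' @export
print.lab_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep: %d conditions x %d replicates, %d iterations each\n",
              nrow(x$spec$conditions), x$spec$replicates,
              x$spec$iterations))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
summary.lab_sweep <- function(object, ...) object$summary

#' @export
plot.lab_sweep <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$condition, s$F_eq_mean, type = "b", ylim = c(0, 1),
                 xlab = "condition", ylab = "equilibrium F / mean alpha",
                 main = "Equilibrium statistics by condition", ...)
  graphics::lines(s$condition, s$alpha_eq_mean, type = "b", lty = 2,
                  pch = 2)
  graphics::legend("topright", legend = c("windowed F", "mean alpha"),
                   lty = 1:2, pch = 1:2, bty = "n")
  invisible(x)
}

#' Relative reduction of a rate
#'
#' `(f_reference - f_treatment) / f_reference`, expressed as a
#' percentage; the headline comparison between a modified lottery and a
#' pure funding lottery.
#'
#' @param f_treatment Rate under the treatment condition.
#' @param f_reference Rate under the reference condition; must be
#'   positive.
#' @return Percentage reduction (negative if the treatment is worse).
#' @examples
#' relative_reduction(0.2, 0.8)     # 75
#' relative_reduction(0.368, 0.92)  # 60
#' @export
relative_reduction <- function(f_treatment, f_reference) {
  if (any(f_reference <= 0)) stop("f_reference must be positive")
  100 * (f_reference - f_treatment) / f_reference
}

#' Read a sweep specification from YAML or JSON
#'
#' Reads a config file with optional keys `axes` (named lists of
#' values), `conditions` (list of per-condition field maps),
#' `replicates`, `seed_base`, `iterations`, `equilibrium_window`, and
#' `base` (overrides applied to `base` before sweeping). Bundled
#' reduced-scale specifications for the main computational experiments
#' live in `system.file("extdata", package = "labevolve")`.
#'
#' @param path Config file path.
#' @param base A [lab_params()] object used for unswept fields.
#' @return A `"sweep_spec"` object.
#' @export
read_sweep_spec <- function(path, base = lab_params()) {
  cfg <- read_config(path)
  if (!is.null(cfg$base)) {
    vals <- unclass(base)
    vals <- vals[!vapply(vals, is.null, logical(1))]
    base <- do.call(lab_params, modifyList(vals, cfg$base))
  }
  conditions <- NULL
  if (!is.null(cfg$conditions)) {
    conditions <- do.call(rbind, lapply(cfg$conditions, function(cc) {
      as.data.frame(cc, stringsAsFactors = FALSE)
    }))
  }
  args <- list(base = base, axes = cfg$axes, conditions = conditions)
  for (f in c("replicates", "seed_base", "iterations",
              "equilibrium_window")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  do.call(sweep_spec, args)
}
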