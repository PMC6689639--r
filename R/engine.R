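#' Initialize a lab population
#'
#' Creates the founding population: `n` labs with false positive rate
#' `alpha0`, startup funds `G0`, age 0 and empty publication records.
#'
#' @param params A validated [lab_params()] object.
#' @return A data frame with columns `id`, `alpha`, `funds`, `age`,
#'   `publications`, `erroneous_publications`.
#' @export
init_labs <- function(params) {
  data.frame(
    id = seq_len(params$n),
    alpha = rep(params$alpha0, params$n),
    funds = rep(params$G0, params$n),
    age = rep(0L, params$n),
    publications = rep(0L, params$n),
    erroneous_publications = rep(0L, params$n)
  )
}

#' @rdname init_labs
#' @return `sim_state` returns a list with `labs`, `iteration`,
#'   `cum_publications` and `cum_erroneous`.
#' @export
sim_state <- function(params) {
  list(labs = init_labs(params), iteration = 0L,
       cum_publications = 0, cum_erroneous = 0)
}

#' Advance the simulation by one iteration
#'
#' Applies the three stages in order -- Science ([run_science_step()]),
#' Evolution ([run_evolution_step()]), Grant-Seeking
#' ([run_funding_step()]) -- then increments the age of every surviving
#' lab by one (the newborn ends its birth iteration at age 0). Consumes
#' R's global RNG in the same draw order as the compiled engine, so
#' stepping in R reproduces a compiled run exactly.
#'
#' @param state A state list from [sim_state()].
#' @param params A validated [lab_params()] object.
#' @return A list with the advanced `state` and the iteration's `stats`
#'   (investigations, publications, erroneous_publications, awarded,
#'   winner_alpha, dead_funds, funds_total).
#' @export
sim_step <- function(state, params) {
  labs <- state$labs
  if (params$auto_refund) labs$funds <- pmax(labs$funds, 1L)
  sci <- run_science_step(labs, params)
  labs <- sci$labs
  child_id <- NA_integer_
  dead_funds <- 0L
  if (params$do_evolution) {
    ev <- run_evolution_step(labs, params)
    labs <- ev$labs
    child_id <- ev$event$child_id
    dead_funds <- ev$event$dead_funds
  }
  awarded <- FALSE
  winner_alpha <- NA_real_
  if (params$do_funding) {
    fu <- run_funding_step(labs, params)
    labs <- fu$labs
    if (!is.na(fu$award$winner_id)) {
      awarded <- TRUE
      winner_alpha <- labs$alpha[match(fu$award$winner_id, labs$id)]
    }
  }
  survivor <- if (is.na(child_id)) rep(TRUE, nrow(labs)) else labs$id != child_id
  labs$age <- labs$age + as.integer(survivor)
  state$labs <- labs
  state$iteration <- state$iteration + 1L
  state$cum_publications <- state$cum_publications + sci$stats$publications
  state$cum_erroneous <- state$cum_erroneous + sci$stats$erroneous_publications
  stats <- list(
    investigations = sci$stats$investigations,
    publications = sci$stats$publications,
    erroneous_publications = sci$stats$erroneous_publications,
    awarded = awarded, winner_alpha = winner_alpha,
    dead_funds = dead_funds, funds_total = sum(labs$funds)
  )
  list(state = state, stats = stats)
}

#' Run a full simulation
#'
#' Runs `params$iterations` iterations from the initialized population,
#' fully determined by `params$seed`. The state is recorded at iteration
#' 0, every `record_interval` iterations, and at the final iteration:
#' the community mean false positive rate, the cumulative false
#' discovery rate of the published literature, and a trailing-window
#' false discovery rate (window `fdr_window`).
#'
#' @param params A validated [lab_params()] object.
#' @param engine `"compiled"` (default; C++ loop) or `"r"` (iterated
#'   [sim_step()]). Both consume the RNG identically and produce the
#'   same trajectories.
#' @param keep_stats If `TRUE`, per-iteration stage tallies are kept
#'   (funds ledger terms, award records); memory scales with
#'   `iterations`.
#' @return An object of class `"lab_sim"`: a list with `record` (data
#'   frame: iteration, mean_alpha, fdr_cumulative, fdr_windowed,
#'   cum_publications, cum_erroneous), `labs` (final population),
#'   `params`, `engine`, and optionally `stats`.
#' @examples
#' sim <- run_simulation(lab_params(iterations = 2000, seed = 42))
#' summary(sim)
#' @export
run_simulation <- function(params, engine = c("compiled", "r"),
                           keep_stats = FALSE) {
  validate_params(params)
  engine <- match.arg(engine)
  set.seed(params$seed)
  if (engine == "compiled") {
    res <- run_engine_cpp(
      params$n, params$b, params$W, params$alpha0, params$G0, params$G,
      params$d, params$epsilon, params$r, params$p,
      match(params$strategy, c("PH", "MI", "RA", "MS", "ML")),
      if (is.null(params$X)) 0 else params$X,
      if (is.null(params$A)) 0 else params$A,
      match(params$selection_mode, c("strong", "proportional")),
      params$iterations, params$record_interval,
      params$do_evolution, params$do_funding, params$auto_refund,
      keep_stats
    )
    record <- data.frame(
      iteration = res$times, mean_alpha = res$mean_alpha,
      cum_publications = res$cum_publications,
      cum_erroneous = res$cum_erroneous
    )
    labs <- data.frame(
      id = res$id, alpha = res$alpha, funds = res$funds, age = res$age,
      publications = res$publications,
      erroneous_publications = res$erroneous_publications
    )
    stats <- if (keep_stats) {
      data.frame(
        iteration = seq_len(params$iterations),
        investigations = res$stat_investigations,
        publications = res$stat_publications,
        erroneous_publications = res$stat_erroneous,
        awarded = as.logical(res$stat_awarded),
        winner_alpha = res$stat_winner_alpha,
        dead_funds = res$stat_dead_funds,
        funds_total = res$stat_funds_total
      )
    }
  } else {
    state <- sim_state(params)
    rec <- list(record_row(state))
    stat_rows <- if (keep_stats) vector("list", params$iterations)
    for (t in seq_len(params$iterations)) {
      out <- sim_step(state, params)
      state <- out$state
      if (keep_stats) stat_rows[[t]] <- out$stats
      if (t %% params$record_interval == 0L || t == params$iterations) {
        rec[[length(rec) + 1L]] <- record_row(state)
      }
    }
    record <- do.call(rbind, rec)
    labs <- state$labs
    stats <- if (keep_stats) {
      cbind(iteration = seq_len(params$iterations),
            do.call(rbind, lapply(stat_rows, as.data.frame)))
    }
  }
  record$fdr_cumulative <- fdr(record$cum_erroneous, record$cum_publications)
  record$fdr_windowed <- windowed_fdr(record$iteration,
                                      record$cum_publications,
                                      record$cum_erroneous,
                                      params$fdr_window)
  record <- record[, c("iteration", "mean_alpha", "fdr_cumulative",
                       "fdr_windowed", "cum_publications", "cum_erroneous")]
  rownames(record) <- NULL
  structure(list(record = record, labs = labs, params = params,
                 engine = engine,
                 stats = if (keep_stats) stats else NULL),
            class = "lab_sim")
}

record_row <- function(state) {
  data.frame(iteration = state$iteration,
             mean_alpha = mean_alpha(state$labs),
             cum_publications = state$cum_publications,
             cum_erroneous = state$cum_erroneous)
}

# Trailing-window false discovery rate at each recorded time, from the
# cumulative series. NA before a full window has elapsed or when no
# publication fell inside the window.
windowed_fdr <- function(times, cum_pub, cum_err, window) {
  j <- findInterval(times - window, times)
  out <- rep(NA_real_, length(times))
  ok <- j >= 1L & times >= window
  dp <- cum_pub[ok] - cum_pub[j[ok]]
  de <- cum_err[ok] - cum_err[j[ok]]
  out[ok] <- ifelse(dp > 0, de / dp, NA_real_)
  out
}

#' Community mean false positive rate
#'
#' Arithmetic mean of the false positive rate over all extant labs.
#'
#' @param x A lab data frame, a [sim_state()] list, or a `"lab_sim"`
#'   object (final population).
#' @return A probability.
#' @export
mean_alpha <- function(x) {
  labs <- if (is.data.frame(x)) x else x$labs
  if (is.null(labs) || nrow(labs) == 0L) stop("empty population")
  sum(labs$alpha) / nrow(labs)
}

#' False discovery rate of the published literature
#'
#' The fraction of published results that are erroneous (incongruent
#' with the true epistemic state of their hypothesis). Undefined -- and
#' reported as `NA`, never 0 -- while nothing has been published.
#'
#' @param erroneous Count(s) of erroneous publications.
#' @param publications Count(s) of publications.
#' @return `erroneous / publications`, `NA` where `publications == 0`.
#' @export
fdr <- function(erroneous, publications) {
  stopifnot(all(erroneous <= publications))
  ifelse(publications > 0, erroneous / publications, NA_real_)
}

#' Detect convergence of a recorded series
#'
#' Finds the first index at which the trailing-window mean of the
#' series comes within `tolerance` of the final trailing-window mean
#' and remains so for the rest of the series, requiring the condition
#' to be sustained for at least one further full window (so a series
#' still drifting at its end is reported as not converged).
#'
#' @param series Numeric vector of recorded values (e.g. mean alpha).
#' @param window Trailing-window length, in elements of `series`.
#' @param tolerance Absolute tolerance on the trailing mean.
#' @return The 1-based index of `series` at which convergence is first
#'   sustained, or `NA` if never.
#' @export
detect_convergence <- function(series, window, tolerance) {
  stopifnot(window >= 1, tolerance > 0)
  window <- as.integer(window)
  N <- length(series)
  if (N < 2L * window) return(NA_integer_)
  cs0 <- c(0, cumsum(series))
  j <- window:N
  trail <- (cs0[j + 1L] - cs0[j - window + 1L]) / window
  ok <- abs(trail - trail[length(trail)]) <= tolerance
  sustained <- rev(cumprod(rev(ok))) == 1
  pos <- which(sustained)[1L]
  if (is.na(pos)) return(NA_integer_)
  idx <- window + pos - 1L
  if (idx > N - window) return(NA_integer_)
  idx
}

#' @rdname detect_convergence
#' @param sim A `"lab_sim"` object.
#' @details `convergence_iteration` applies [detect_convergence()] to
#'   the recorded mean-alpha trajectory of a run, with `window` given in
#'   iterations, and returns the iteration number.
#' @export
convergence_iteration <- function(sim, window = 10000, tolerance = 0.05) {
  rec <- sim$record
  w_pts <- max(1L, as.integer(round(window / sim$params$record_interval)))
  idx <- detect_convergence(rec$mean_alpha, w_pts, tolerance)
  if (is.na(idx)) NA_integer_ else rec$iteration[idx]
}

#' Equilibrium summaries of a run
#'
#' Mean recorded community false positive rate and mean windowed false
#' discovery rate over the final `window` iterations of a run. Used for
#' between-condition comparisons, where the cumulative F would be
#' contaminated by burn-in.
#'
#' @param sim A `"lab_sim"` object.
#' @param window Length of the final window, in iterations.
#' @return A list with `alpha_eq` and `F_eq`.
#' @export
equilibrium_stats <- function(sim, window = 10000) {
  rec <- sim$record
  T_end <- max(rec$iteration)
  sel <- rec$iteration > T_end - window
  list(alpha_eq = mean(rec$mean_alpha[sel]),
       F_eq = mean(rec$fdr_windowed[sel], na.rm = TRUE))
}

#' @export
print.lab_sim <- function(x, ...) {
  rec <- x$record
  last <- rec[nrow(rec), ]
  strat <- x$params$strategy
  cat(sprintf("Lab population simulation (%s, n = %d, G = %d, %d iterations)\n",
              strat, x$params$n, x$params$G, x$params$iterations))
  cat(sprintf("  final mean false positive rate: %.4f (alpha0 = %g)\n",
              last$mean_alpha, x$params$alpha0))
  cat(sprintf("  cumulative false discovery rate: %s (%d / %d publications)\n",
              ifelse(is.na(last$fdr_cumulative), "undefined",
                     sprintf("%.4f", last$fdr_cumulative)),
              last$cum_erroneous, last$cum_publications))
  invisible(x)
}

#' @export
summary.lab_sim <- function(object, window = 10000, tolerance = 0.05, ...) {
  eq <- equilibrium_stats(object, window)
  out <- list(params = object$params,
              final = object$record[nrow(object$record), ],
              alpha_eq = eq$alpha_eq, F_eq = eq$F_eq,
              convergence = convergence_iteration(object, window, tolerance))
  class(out) <- "summary.lab_sim"
  out
}

#' @export
print.summary.lab_sim <- function(x, ...) {
  cat(sprintf("Strategy %s, %d iterations, seed %d\n",
              x$params$strategy, x$params$iterations, x$params$seed))
  cat(sprintf("  equilibrium mean alpha: %.4f\n", x$alpha_eq))
  cat(sprintf("  equilibrium windowed F: %s\n",
              ifelse(is.na(x$F_eq), "undefined", sprintf("%.4f", x$F_eq))))
  cat(sprintf("  cumulative F:           %s\n",
              ifelse(is.na(x$final$fdr_cumulative), "undefined",
                     sprintf("%.4f", x$final$fdr_cumulative))))
  cat(sprintf("  convergence iteration:  %s\n",
              ifelse(is.na(x$convergence), "not converged",
                     format(x$convergence))))
  invisible(x)
}

#' @export
plot.lab_sim <- function(x, ...) {
  rec <- x$record
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(rec$iteration, rec$mean_alpha, type = "l", ylim = c(0, 1),
       xlab = "iteration", ylab = expression(bar(alpha)),
       main = sprintf("Mean false positive rate (%s)", x$params$strategy),
       ...)
  graphics::abline(h = x$params$alpha0, lty = 3)
  plot(rec$iteration, rec$fdr_cumulative, type = "l", ylim = c(0, 1),
       xlab = "iteration", ylab = "F",
       main = "False discovery rate (cumulative and windowed)", ...)
  graphics::lines(rec$iteration, rec$fdr_windowed, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.lab_sim <- function(x, ...) x$record

#' Write a run to disk
#'
#' Writes the recorded trajectory as CSV (columns iteration,
#' mean_alpha, fdr_cumulative, fdr_windowed, cum_publications,
#' cum_erroneous) plus a JSON sidecar (`<path>.json`) with the full
#' parameter set and seed.
#'
#' @param sim A `"lab_sim"` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_run <- function(sim, path) {
  utils::write.csv(sim$record, path, row.names = FALSE)
  jsonlite::write_json(
    unclass(sim$params)[!vapply(sim$params, is.null, logical(1))],
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
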