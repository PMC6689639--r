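test_that("a zero-iteration run records only the initial state", {
  sim <- run_simulation(quick_params(iterations = 0))
  expect_identical(nrow(sim$record), 1L)
  expect_equal(sim$record$mean_alpha, 0.05)
  expect_true(is.na(sim$record$fdr_cumulative))
  expect_equal(sim$labs, init_labs(sim$params))
})

test_that("runs are fully determined by the seed", {
  p <- quick_params(iterations = 500, seed = 5, strategy = "MS", X = 0.3)
  a <- run_simulation(p)
  b <- run_simulation(p)
  expect_identical(a$record, b$record)
  expect_identical(a$labs, b$labs)
  c <- run_simulation(quick_params(iterations = 500, seed = 6,
                                   strategy = "MS", X = 0.3))
  expect_false(identical(a$record, c$record))
})

test_that("the R stepper and the compiled engine produce the same trajectories", {
  cases <- list(
    list(strategy = "PH"), list(strategy = "MI"), list(strategy = "RA"),
    list(strategy = "MS", X = 0.4), list(strategy = "ML", A = 0.2),
    list(strategy = "PH", selection_mode = "proportional"),
    list(strategy = "RA", p = 0.5, r = 0.5),
    list(strategy = "RA", do_evolution = FALSE, do_funding = FALSE,
         auto_refund = TRUE)
  )
  for (case in cases) {
    p <- do.call(quick_params, c(case, iterations = 150, seed = 3))
    a <- run_simulation(p, engine = "compiled")
    b <- run_simulation(p, engine = "r")
    expect_equal(a$record, b$record, tolerance = 1e-12)
    expect_equal(a$labs, b$labs, tolerance = 1e-15)
  }
})

test_that("an iteration applies Science, then Evolution, then Grant-Seeking", {
  p <- quick_params(strategy = "PH")
  set.seed(9)
  state <- sim_state(p)
  out <- sim_step(state, p)

  # recompose manually with the same RNG stream
  set.seed(9)
  labs <- init_labs(p)
  sci <- run_science_step(labs, p)
  ev <- run_evolution_step(sci$labs, p)
  fu <- run_funding_step(ev$labs, p)
  labs2 <- fu$labs
  labs2$age <- labs2$age + as.integer(labs2$id != ev$event$child_id)
  expect_identical(out$state$labs, labs2)
  expect_equal(out$state$cum_publications, sci$stats$publications)
})

test_that("the funds ledger closes every iteration", {
  for (strat in list(list(strategy = "PH"), list(strategy = "ML", A = 0.2))) {
    p <- do.call(lab_params, c(strat, n = 50, d = 5, iterations = 2000,
                               seed = 13, p = 0.2, r = 0.2))
    sim <- run_simulation(p, keep_stats = TRUE)
    st <- sim$stats
    total0 <- p$n * p$G0
    lhs <- st$funds_total
    rhs <- c(total0, head(st$funds_total, -1)) - st$investigations +
      p$G * st$awarded - st$dead_funds + p$G0
    expect_identical(lhs, rhs)
    # population size and counter monotonicity
    expect_identical(nrow(sim$labs), p$n)
    expect_true(all(diff(sim$record$cum_publications) >= 0))
    expect_true(all(diff(sim$record$cum_erroneous) >= 0))
    expect_true(all(sim$record$mean_alpha >= 0 & sim$record$mean_alpha <= 1))
    f <- sim$record$fdr_cumulative
    expect_true(all(is.na(f) | (f >= 0 & f <= 1)))
  }
})

test_that("perfect peer review keeps the literature error-free all run", {
  p <- lab_params(n = 40, d = 5, iterations = 3000, r = 1, p = 0.6, seed = 2)
  sim <- run_simulation(p)
  expect_true(all(sim$record$cum_erroneous == 0))
  expect_true(all(sim$record$fdr_cumulative[sim$record$cum_publications > 0] == 0))
})

test_that("without mutation the community trait never moves", {
  p <- lab_params(n = 30, d = 5, epsilon = 0, iterations = 2000, seed = 4)
  sim <- run_simulation(p)
  expect_identical(length(unique(sim$record$mean_alpha)), 1L)
  expect_equal(sim$record$mean_alpha, rep(p$alpha0, nrow(sim$record)))
})

test_that("mean_alpha and fdr compute their defining ratios", {
  expect_equal(mean_alpha(make_labs(rep(0.05, 7))), 0.05)
  expect_equal(mean_alpha(make_labs(c(0, 1))), 0.5)
  set.seed(14)
  labs <- make_labs(runif(31))
  expect_equal(mean_alpha(labs), sum(labs$alpha) / 31)
  expect_error(mean_alpha(make_labs(numeric(0))), "empty")

  expect_equal(fdr(0, 100), 0)
  expect_equal(fdr(25, 100), 0.25)
  expect_true(is.na(fdr(0, 0)))
  expect_error(fdr(5, 4))
})

test_that("the windowed F matches a direct recomputation from the cumulative series", {
  p <- lab_params(n = 40, d = 5, iterations = 1500, record_interval = 50,
                  fdr_window = 500, seed = 8, p = 0.3)
  rec <- run_simulation(p)$record
  last <- nrow(rec)
  back <- which(rec$iteration == rec$iteration[last] - 500)
  expect_equal(rec$fdr_windowed[last],
               (rec$cum_erroneous[last] - rec$cum_erroneous[back]) /
                 (rec$cum_publications[last] - rec$cum_publications[back]))
  expect_true(all(is.na(rec$fdr_windowed[rec$iteration < 500])))
})

test_that("convergence detection finds sustained plateaus and rejects drifts", {
  expect_identical(detect_convergence(rep(0.3, 100), 10, 0.01), 10L)
  expect_true(is.na(detect_convergence(seq(0, 1, length.out = 100), 10, 0.001)))
  ramp_then_flat <- c(seq(0, 0.8, length.out = 40), rep(0.8, 80))
  idx <- detect_convergence(ramp_then_flat, 10, 0.01)
  expect_false(is.na(idx))
  expect_lte(idx, 40 + 10)
  expect_true(is.na(detect_convergence(rep(0.3, 10), 10, 0.01)))
})
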