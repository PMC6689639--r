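test_that("publication probability has the stated closed form", {
  # positive congruent results always publishable
  expect_equal(publication_probability(TRUE, TRUE, p = 0.3, r = 0.5), 1)
  # false positive: blocked by review with probability r
  expect_equal(publication_probability(FALSE, TRUE, p = 0.3, r = 0.5), 0.5)
  # correct negative: only the negative-result filter applies
  expect_equal(publication_probability(FALSE, FALSE, p = 0.7, r = 0.9), 0.7)
  # false negative: both filters, independently and multiplicatively
  expect_equal(publication_probability(TRUE, FALSE, p = 0.4, r = 0.25), 0.3)
})

test_that("hypothesis and investigation draws have the right probabilities", {
  set.seed(21)
  expect_false(any(draw_hypothesis(0, 1000)))
  expect_true(all(draw_hypothesis(1, 1000)))
  expect_false(any(investigate(rep(FALSE, 1000), alpha = 0, W = 0.8)))
  expect_true(all(investigate(rep(FALSE, 1000), alpha = 1, W = 0.8)))

  n <- 1e5
  freq_b <- mean(draw_hypothesis(0.1, n))
  expect_lt(abs(freq_b - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  freq_W <- mean(investigate(rep(TRUE, n), alpha = 0.05, W = 0.8))
  expect_lt(abs(freq_W - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  freq_a <- mean(investigate(rep(FALSE, n), alpha = 0.05, W = 0.8))
  expect_lt(abs(freq_a - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("publication frequencies per outcome cell match the closed form", {
  set.seed(22)
  n <- 1e5
  h <- draw_hypothesis(0.3, n)
  s <- investigate(h, alpha = 0.2, W = 0.8)
  q <- publication_probability(h, s, p = 0.4, r = 0.6)
  published <- runif(n) < q
  for (cell in split(seq_len(n), interaction(h, s, drop = TRUE))) {
    k <- length(cell)
    obs <- sum(published[cell])
    expected <- q[cell[1]]
    # chi-square goodness of fit against the Bernoulli cell probability
    if (expected %in% c(0, 1)) {
      expect_identical(obs, as.integer(round(k * expected)))
    } else {
      chisq <- (obs - k * expected)^2 / (k * expected * (1 - expected))
      expect_lt(chisq, qchisq(0.999, df = 1))
    }
  }
})

test_that("a science step spends funds, logs investigations and respects filters", {
  set.seed(23)
  params <- quick_params(p = 1, r = 0)
  # no funded labs: nothing happens
  labs0 <- make_labs(rep(0.05, 10), funds = 0L)
  out0 <- run_science_step(labs0, params)
  expect_identical(out0$labs, labs0)
  expect_identical(out0$stats$investigations, 0L)

  # everything publishable when p = 1, r = 0
  labs1 <- make_labs(rep(0.05, 30), funds = 5L)
  out1 <- run_science_step(labs1, params)
  expect_equal(out1$stats$publications, 30)
  expect_equal(out1$stats$investigations, 30)
  expect_equal(sum(out1$labs$funds), sum(labs1$funds) - 30)

  # fund conservation and tally bounds under random parameters
  for (i in 1:20) {
    pr <- lab_params(n = 15, d = 3, p = runif(1), r = runif(1),
                     b = runif(1), W = runif(1))
    labs <- make_labs(runif(15), funds = sample(0:2, 15, replace = TRUE))
    out <- run_science_step(labs, pr)
    expect_equal(sum(out$labs$funds),
                 sum(labs$funds) - out$stats$investigations)
    expect_lte(out$stats$publications, out$stats$investigations)
    expect_lte(out$stats$investigations, nrow(labs))
    expect_true(all(out$labs$erroneous_publications <= out$labs$publications))
    expect_equal(out$stats$investigations, sum(labs$funds >= 1))
  }
})

test_that("perfect review blocks every erroneous result and p = 0 blocks negatives", {
  set.seed(24)
  for (i in 1:10) {
    labs <- make_labs(runif(25), funds = 1L)
    out_r1 <- run_science_step(labs, lab_params(n = 25, p = runif(1), r = 1))
    expect_false(any(out_r1$investigations$published &
                       out_r1$investigations$erroneous))
    out_p0 <- run_science_step(labs, lab_params(n = 25, p = 0, r = runif(1)))
    expect_false(any(out_p0$investigations$published &
                       !out_p0$investigations$result_positive))
  }
})
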