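test_that("death selects the oldest of the sample with uniform tie-breaking", {
  set.seed(31)
  labs <- make_labs(rep(0.05, 4), age = c(3L, 7L, 7L, 2L))
  picks <- replicate(4000, select_death(labs, d = 4))
  expect_true(all(picks %in% c(2L, 3L)))
  frac <- mean(picks == 2L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))

  # distinct ages: deterministic
  labs2 <- make_labs(rep(0.05, 5), age = c(1L, 9L, 3L, 4L, 0L))
  expect_true(all(replicate(50, select_death(labs2, d = 5)) == 2L))

  # all ages equal, d = n: uniform over all labs
  labs3 <- make_labs(rep(0.05, 5), age = 2L)
  tab <- table(factor(replicate(5000, select_death(labs3, d = 5)),
                      levels = 1:5))
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})

test_that("parent selection follows publication counts in both modes", {
  set.seed(32)
  labs <- make_labs(rep(0.1, 3), publications = c(5L, 9L, 2L))
  expect_true(all(replicate(50, select_parent(labs, d = 3, "strong")) == 2L))

  # proportional: publications [1, 3] -> probabilities 0.25 / 0.75
  labs2 <- make_labs(rep(0.1, 2), publications = c(1L, 3L))
  picks <- replicate(4000, select_parent(labs2, d = 2, "proportional"))
  expect_lt(abs(mean(picks == 2L) - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))

  # all-zero publications: uniform in both modes
  labs3 <- make_labs(rep(0.1, 4))
  for (mode in c("strong", "proportional")) {
    tab <- table(factor(replicate(4000, select_parent(labs3, 4, mode)),
                        levels = 1:4))
    expect_gt(chisq.test(tab)$p.value, 1e-4)
  }
})

test_that("mutation adds a clamped Gaussian with standard deviation epsilon", {
  set.seed(33)
  expect_identical(mutate_alpha(0.05, epsilon = 0), 0.05)
  hi <- mutate_alpha(rep(1, 1e4), epsilon = 0.01)
  expect_true(all(hi <= 1))
  lo <- mutate_alpha(rep(0, 1e4), epsilon = 0.01)
  expect_true(all(lo >= 0))

  x <- mutate_alpha(rep(0.5, 1e5), epsilon = 0.01)
  expect_lt(abs(mean(x) - 0.5), 3 * 0.01 / sqrt(1e5))
  expect_lt(abs(sd(x) - 0.01) / 0.01, 0.03)
})

test_that("an evolution step replaces exactly one lab with a fresh child", {
  set.seed(34)
  # n = 2, d = 1: the sampled lab dies, the other is the forced parent
  params <- lab_params(n = 2, d = 1, epsilon = 0)
  for (i in 1:20) {
    labs <- make_labs(c(0.2, 0.8), age = c(5L, 1L))
    out <- run_evolution_step(labs, params)
    expect_identical(nrow(out$labs), 2L)
    expect_false(out$event$dead_id == out$event$child_id)
    expect_false(out$event$parent_id == out$event$dead_id)
    # zero mutation: child alpha equals the parent's exactly
    expect_identical(out$event$child_alpha,
                     labs$alpha[labs$id == out$event$parent_id])
    child <- out$labs[out$labs$id == out$event$child_id, ]
    expect_identical(child$age, 0L)
    expect_identical(child$publications, 0L)
    expect_identical(child$erroneous_publications, 0L)
    expect_identical(child$funds, params$G0)
  }
})

test_that("with no trait-publication coupling the mean trait drifts neutrally", {
  set.seed(35)
  params <- lab_params(n = 50, d = 10, epsilon = 0.01)
  labs <- make_labs(rep(0.5, 50))
  drifts <- numeric(1000)
  for (t in 1:1000) {
    before <- mean_alpha(labs)
    labs <- run_evolution_step(labs, params)$labs
    drifts[t] <- mean_alpha(labs) - before
  }
  se <- sd(drifts) / sqrt(length(drifts))
  expect_lt(abs(mean(drifts)), 3 * se)
  expect_true(all(labs$alpha >= 0 & labs$alpha <= 1))
})

test_that("strong selection favours the trait correlated with publications", {
  set.seed(36)
  alphas <- seq(0.1, 0.9, length.out = 20)
  labs <- make_labs(alphas, publications = as.integer(round(100 * alphas)))
  parents <- replicate(2000, select_parent(labs, d = 5, "strong"))
  parent_alpha <- labs$alpha[match(parents, labs$id)]
  expect_gt(mean(parent_alpha), mean(labs$alpha))
})
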