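test_that("neighbor moves are valid, distinct and uniform over position pairs", {
  # k = 2: the sole neighbor is the reversed pair, for both kinds
  for (kind in c("swap", "reverse"))
    expect_equal(neighbor_order(1:2, kind), 2:1)
  set.seed(3)
  for (i in 1:50) {
    ord <- sample(6)
    for (kind in c("swap", "reverse")) {
      nb <- neighbor_order(ord, kind)
      expect_setequal(nb, 1:6)
      expect_false(identical(nb, ord))
    }
  }
  # uniformity over the 10 unordered position pairs at k = 5
  set.seed(13)
  n <- 10000
  hits <- table(replicate(n, {
    nb <- neighbor_order(1:5, "swap")
    paste(which(nb != 1:5), collapse = "-")
  }))
  expect_length(hits, 10)
  p <- 1 / 10
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(hits / n - p) < 3 * se + 1e-9))
})

test_that("acceptance probability implements the Metropolis rule", {
  expect_equal(accept_prob(10, 10, 1), 1)   # ties always accepted
  expect_equal(accept_prob(10, 9, 0.5), 1)  # improvements always accepted
  expect_equal(accept_prob(10, 10 + 2, 2), exp(-1))
  # monotone: non-increasing in the uphill gap, non-decreasing in c
  deltas <- seq(0.1, 5, by = 0.1)
  p_by_delta <- accept_prob(0, deltas, 1.5)
  expect_true(all(diff(p_by_delta) <= 0))
  cs <- seq(0.1, 5, by = 0.1)
  p_by_c <- accept_prob(0, 1, cs)
  expect_true(all(diff(p_by_c) >= 0))
  expect_error(accept_prob(1, 2, 0), "positive")
})

test_that("cooling schedules start at A and decrease to a positive floor", {
  for (sched in c("linear", "geometric", "log")) {
    cfg <- sa_config(schedule = sched, m = 500)
    expect_equal(cooling(0, cfg), 2)   # c_0 = A = 2
    cs <- cooling(0:500, cfg)
    expect_true(all(diff(cs) <= 0))
    expect_true(all(cs > 0))
  }
  cfg <- sa_config(m = 100)
  expect_equal(cooling(100, cfg), 2 * (1 - 100 / 101))
  expect_error(cooling(101, cfg), "\\[0, m\\]")
  expect_error(sa_config(A = -1), "positive")
})

test_that("near-zero temperature degenerates to strict descent", {
  set.seed(29)
  deltas <- runif(10000, 1e-6, 10)
  p <- accept_prob(0, deltas, 1e-12)
  expect_true(all(p == 0))
  expect_true(all(runif(10000) >= p))  # no worsening move would be taken
})

test_that("anneal honors its contract on small instances", {
  # k = 2: unique order, SARF = the single interval
  D2 <- distance_matrix(matrix(c(0, 4, 4, 0), 2))
  f2 <- anneal(D2, sa_config(seed = 1, eval_budget = 10))
  expect_equal(f2$order, 1:2)
  expect_equal(f2$sarf, 4)
  # k = 6 collinear at 20 cM: identity is the exhaustive optimum
  D6 <- true_distance_matrix(demo_genome(), group = 4)
  f6 <- anneal(D6, sa_config(seed = 2))
  expect_equal(f6$order, 1:6)
  expect_equal(f6$sarf, exhaustive_best_order(D6)$sarf)
  expect_error(anneal(D2, sa_config()), NA)
})

test_that("anneal trajectory is monotone and consistent with the best order", {
  set.seed(31)
  D <- rand_dist(9)
  f <- anneal(D, sa_config(seed = 5), trajectory_thin = 1)
  tr <- f$trajectory
  expect_true(all(diff(tr$best_sarf) <= 1e-9))
  expect_true(all(tr$best_sarf <= tr$current_sarf + 1e-9))
  # reported SARF equals an independent recomputation on the best order
  expect_equal(f$sarf, sarf(f$order, D))
  expect_equal(tail(tr$best_sarf, 1), f$sarf, tolerance = 1e-8)
  expect_true(all(diff(tr$temperature) <= 1e-12))
})

test_that("anneal matches the exhaustive oracle on k = 8 in 19 of 20 runs", {
  set.seed(37)
  D <- rand_dist(8)
  opt <- exhaustive_best_order(D)$sarf
  sarfs <- vapply(1:20, function(s)
    anneal(D, sa_config(seed = 100 + s), trajectory_thin = 0)$sarf, 1)
  expect_true(all(sarfs >= opt - 1e-9))
  expect_gte(sum(abs(sarfs - opt) < 1e-9), 19)
})

test_that("anneal is reproducible under a fixed seed", {
  set.seed(43)
  D <- rand_dist(12)
  f1 <- anneal(D, sa_config(seed = 77, eval_budget = 2000))
  f2 <- anneal(D, sa_config(seed = 77, eval_budget = 2000))
  expect_identical(f1$order, f2$order)
  expect_identical(f1$trajectory, f2$trajectory)
  f3 <- anneal(D, sa_config(seed = 78, eval_budget = 2000))
  expect_false(identical(f1$trajectory, f3$trajectory))
})

test_that("anneal recovers the true order of every benchmark group", {
  g <- demo_genome()
  for (grp in 1:4) {
    D <- true_distance_matrix(g, grp)
    f <- anneal(D, sa_config(seed = 50 + grp), trajectory_thin = 0)
    expect_equal(f$order, seq_len(nrow(D$d)))
    expect_equal(f$sarf, 100)
  }
})

test_that("alternative schedules and the swap kernel still order small groups", {
  D <- true_distance_matrix(demo_genome(), group = 4)
  for (sched in c("geometric", "log")) {
    f <- anneal(D, sa_config(schedule = sched, seed = 61), trajectory_thin = 0)
    expect_equal(f$sarf, 100)
  }
  fs <- anneal(D, sa_config(neighborhood = "swap", seed = 62),
               trajectory_thin = 0)
  expect_equal(fs$sarf, 100)
})
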