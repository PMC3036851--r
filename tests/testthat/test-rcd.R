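test_that("build_chain follows collinear distances and handles k = 2", {
  D6 <- true_distance_matrix(demo_genome(), group = 4)
  expect_equal(canonicalize_order(build_chain(D6)), 1:6)
  D2 <- distance_matrix(matrix(c(0, 3, 3, 0), 2),
                        r = matrix(c(0, 0.1, 0.1, 0), 2))
  expect_equal(sort(build_chain(D2)), 1:2)
  Dn <- distance_matrix(D6$d)  # no r companion
  expect_error(build_chain(Dn), "'r'")
})

test_that("build_chain reproduces a hand-traced greedy on an adversarial matrix", {
  # r designed so greedy misplaces marker 5: closest pair is (1,2); 3 then 4
  # join on the right; 5 is nearest to terminal 4 even though the best full
  # order would interleave it elsewhere.
  r <- matrix(0.5, 5, 5)
  set_r <- function(i, j, v) r[i, j] <<- r[j, i] <<- v
  set_r(1, 2, 0.01)
  set_r(2, 3, 0.05)
  set_r(3, 4, 0.08)
  set_r(4, 5, 0.10)
  set_r(1, 5, 0.12)
  set_r(2, 5, 0.40); set_r(3, 5, 0.45)
  set_r(1, 3, 0.30); set_r(1, 4, 0.35); set_r(2, 4, 0.38)
  diag(r) <- 0
  D <- distance_matrix(r_to_cm_mat(r), r = r)
  # hand trace: chain (1,2); append 3 at right (0.05 < 0.30); append 4 at
  # right (0.08 < 0.35); append 5 at right (0.10 vs 0.12 at left terminal 1)
  expect_equal(build_chain(D), c(1L, 2L, 3L, 4L, 5L))
})

test_that("chain tie-breaking is by lowest marker index, then left terminal", {
  r <- matrix(0.5, 4, 4)
  r[1, 2] <- r[2, 1] <- 0.1
  r[3, 4] <- r[4, 3] <- 0.1   # tied seed pairs: (1,2) wins lexicographically
  r[1, 3] <- r[3, 1] <- 0.2
  r[2, 4] <- r[4, 2] <- 0.2   # tied terminal attachments: left terminal wins
  diag(r) <- 0
  D <- distance_matrix(r_to_cm_mat(r), r = r)
  # hand trace: seed (1,2) (lexicographically first of the tied pairs);
  # 3 ties 4 at 0.2 and attaches at the LEFT terminal -> (3,1,2);
  # 4 is then closest to the new left terminal 3 (0.1) -> (4,3,1,2)
  expect_equal(build_chain(D), c(4L, 3L, 1L, 2L))
})

test_that("ripple never worsens SARF and repairs single adjacent swaps", {
  D6 <- true_distance_matrix(demo_genome(), group = 4)
  # already optimal: unchanged
  expect_equal(ripple(1:6, D6, 2), 1:6)
  expect_equal(ripple(1:6, D6, 3), 1:6)
  # one adjacent pair swapped out of a collinear optimum: window 2 fixes it
  broken <- c(1L, 2L, 4L, 3L, 5L, 6L)
  expect_equal(ripple(broken, D6, 2), 1:6)
  expect_error(ripple(1:6, D6, 4), "2 or 3")
  set.seed(53)
  for (i in 1:20) {
    D <- rand_dist(7, with_r = TRUE)
    ord <- sample(7)
    for (w in 2:3) {
      out <- ripple(ord, D, w)
      expect_lte(sarf(out, D), sarf(ord, D) + 1e-9)
    }
  }
})

test_that("rcd is deterministic and exhaustive at k = 3", {
  set.seed(59)
  for (i in 1:20) {
    D <- rand_dist(3, with_r = TRUE)
    fit <- rcd(D)
    expect_equal(fit$sarf, exhaustive_best_order(D)$sarf)
    expect_identical(rcd(D)$order, fit$order)
  }
})

test_that("rcd recovers the true order of every benchmark group at 100 cM", {
  g <- demo_genome()
  for (grp in 1:4) {
    D <- true_distance_matrix(g, grp)
    fit <- rcd(D)
    expect_equal(fit$order, seq_len(nrow(D$d)))
    expect_equal(fit$sarf, 100)
  }
})

test_that("rcd never beats the exhaustive oracle and never loses to its chain", {
  # unstructured random matrices: only the lower bound is guaranteed
  set.seed(61)
  for (i in 1:40) {
    D <- rand_dist(sample(5:8, 1), with_r = TRUE)
    fit <- rcd(D)
    expect_gte(fit$sarf, exhaustive_best_order(D)$sarf - 1e-9)
    expect_lte(fit$sarf, fit$chain_sarf + 1e-9)
  }
})

test_that("rcd is optimal on most linkage-structured instances", {
  # matrices estimated from simulated linkage data, where greedy chain
  # growth is in its element (distances increase with map separation)
  g <- genome_spec(list(list(markers = paste0("x", 1:7),
                             pos = c(0, 8, 20, 34, 50, 68, 88))))
  eq <- 0
  for (i in 1:20) {
    gm <- simulate_f2(g, 100, seed = 200 + i)
    D <- recomb_matrix(gm)
    fit <- rcd(D)
    opt <- exhaustive_best_order(D)$sarf
    expect_gte(fit$sarf, opt - 1e-9)
    if (abs(fit$sarf - opt) < 1e-9) eq <- eq + 1
  }
  expect_gte(eq, 16)
})
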