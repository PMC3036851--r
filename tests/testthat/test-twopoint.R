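test_that("f2_joint_probs matches the degenerate cases and normalizes", {
  p0 <- f2_joint_probs(0)
  expect_equal(unname(diag(p0)), c(0.25, 0.5, 0.25))
  expect_equal(sum(abs(p0)) , 1)  # no off-diagonal mass without recombination
  # free recombination: independence of the two 1:2:1 marginals
  p5 <- f2_joint_probs(0.5)
  marg <- c(1, 2, 1) / 4
  expect_equal(p5, outer(marg, marg), ignore_attr = TRUE)
  for (r in c(0.01, 0.1, 0.25, 0.49))
    expect_equal(sum(f2_joint_probs(r)), 1)
  expect_error(f2_joint_probs(0.6), "\\[0, 0.5\\]")
  expect_error(f2_joint_probs(-0.1), "\\[0, 0.5\\]")
})

test_that("pair_counts tabulates pairwise-complete observations", {
  g1 <- c(0, 1, 2, NA, 1, 0)
  g2 <- c(0, 1, 2, 1, NA, 2)
  cnt <- pair_counts(g1, g2)
  expect_equal(sum(cnt), 4)
  expect_equal(cnt[1, 1], 1)  # (0,0)
  expect_equal(cnt[1, 3], 1)  # (0,2)
  expect_equal(cnt[2, 2], 1)
  expect_equal(cnt[3, 3], 1)
  expect_error(pair_counts(c(0, 3), c(0, 1)), "codes")
})

test_that("EM recovers exact and self-consistent estimates", {
  # all parental classes: no recombinants
  par_only <- matrix(0, 3, 3)
  par_only[1, 1] <- 20; par_only[3, 3] <- 22; par_only[2, 2] <- 41
  est <- est_rf_em(par_only)
  expect_equal(est$rhat, 0, tolerance = 1e-6)
  # counts exactly proportional to the model at r = 0.2: fixed point
  cnt <- round(f2_joint_probs(0.2) * 1e6)
  est2 <- est_rf_em(cnt)
  expect_equal(est2$rhat, 0.2, tolerance = 1e-4)
  expect_true(est2$converged)
  expect_gt(est2$lod, 0)
  expect_error(est_rf_em(matrix(0, 3, 3)), "empty")
  expect_error(est_rf_em(par_only, tol = 0), "positive")
})

test_that("EM agrees with the grid-search likelihood maximizer", {
  # the named small table, against a 5001-point grid oracle
  tab <- matrix(1, 3, 3)
  tab[1, 1] <- 20; tab[1, 2] <- 5; tab[2, 2] <- 40; tab[3, 2] <- 4
  tab[3, 3] <- 21
  expect_lt(abs(est_rf_em(tab)$rhat - grid_rf(tab)), 1e-3)
  # 200 random tables; log-likelihood trace never decreases
  set.seed(17)
  for (i in 1:200) {
    cnt <- rand_counts(sample(c(30, 80, 200), 1))
    est <- est_rf_em(cnt)
    expect_lt(abs(est$rhat - grid_rf(cnt)), 1e-3)
    expect_true(all(diff(est$loglik_trace) >= -1e-10))
  }
})

test_that("recomb_matrix recovers simulated recombination fractions", {
  g <- genome_spec(list(list(markers = c("p", "q"), pos = c(0, 5))))
  gm <- simulate_f2(g, 1000, seed = 23)
  D <- recomb_matrix(gm)
  r_true <- cm_to_r(5)
  se <- sqrt(r_true * (1 - r_true) / (2 * 1000))
  expect_lt(abs(D$r[1, 2] - r_true), 3 * se)
  expect_equal(D$d[1, 2], r_to_cm(D$r[1, 2]))
  # duplicate marker column: r and d collapse to zero
  gm2 <- cbind(unclass(gm), dup = unclass(gm)[, 1])
  D2 <- recomb_matrix(gm2)
  expect_equal(D2$r[1, 3], 0, tolerance = 1e-6)
  expect_equal(D2$d[1, 3], 0, tolerance = 1e-4)
  # symmetry and zero diagonal by construction
  gm3 <- simulate_f2(tiny_genome(), 120, seed = 31)
  D3 <- recomb_matrix(gm3, group = 2)
  expect_equal(D3$d, t(D3$d))
  expect_equal(diag(D3$d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(D3$markers, paste0("b", 1:4))
})

test_that("recomb_matrix is pairwise-complete and flags empty pairs", {
  g <- tiny_genome()
  gm <- simulate_f2(g, 60, seed = 41)
  miss <- inject_missing(gm, 0.2, seed = 42)
  D <- recomb_matrix(miss, group = 1)
  expect_true(all(is.finite(D$d)))
  # a pair with no complete observation is an estimation error naming it
  gm4 <- unclass(simulate_f2(g, 10, seed = 43))[, 1:3]
  gm4[1:5, 1] <- NA
  gm4[6:10, 2] <- NA
  expect_error(recomb_matrix(gm4), "a1.*a2|no complete")
})
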