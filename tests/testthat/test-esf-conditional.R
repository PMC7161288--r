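test_that("ESF closed forms: dichotomous pair, single item, log gamma_0 = 0", {
  a1 <- 0.4; a2 <- -0.9
  g <- esf_log(list(c(0, a1), c(0, a2)))
  expect_equal(g[1], 0)
  expect_equal(g[2], log(exp(a1) + exp(a2)), tolerance = 1e-12)
  expect_equal(g[3], a1 + a2, tolerance = 1e-12)
  a <- c(0, 0.3, -0.2, 0.5, 1.1)
  expect_equal(esf_log(list(a)), a, tolerance = 1e-12)
})

test_that("ESF recursion equals brute-force enumeration on 3x3 instances", {
  set.seed(42)
  for (rep in 1:5) {
    alpha <- lapply(1:3, function(i) c(0, rnorm(2)))
    expect_equal(esf_log(alpha), bf_esf(alpha), tolerance = 1e-10)
  }
})

test_that("conditional pattern probabilities match enumeration and normalize", {
  set.seed(7)
  alpha <- lapply(1:3, function(i) c(0, rnorm(2)))
  m <- rasch_model(alpha)
  pat <- all_patterns(c(3, 3, 3))
  w <- pattern_logweights(pat, alpha)
  r <- rowSums(pat)
  g <- bf_esf(alpha)
  for (ix in c(2, 9, 14, 23))
    expect_equal(conditional_pattern_logprob(m, pat[ix, ]),
                 w[ix] - g[r[ix] + 1], tolerance = 1e-10)
  for (rr in 0:6) {
    s <- sum(exp(apply(pat[r == rr, , drop = FALSE], 1, function(y)
      conditional_pattern_logprob(m, y))))
    expect_equal(s, 1, tolerance = 1e-10)
  }
  expect_equal(conditional_pattern_logprob(m, c(0, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(conditional_pattern_logprob(m, c(2, 2, 2)), 0, tolerance = 1e-12)
  expect_error(conditional_pattern_logprob(m, c(1, 0, 0), r = 2), "mismatch")
})

test_that("conditional item moments match enumeration and hit the extremes", {
  set.seed(8)
  alpha <- lapply(1:3, function(i) c(0, rnorm(2)))
  m <- rasch_model(alpha)
  pat <- all_patterns(c(3, 3, 3))
  w <- pattern_logweights(pat, alpha)
  r <- rowSums(pat)
  for (rr in 0:6) {
    pr <- exp(w[r == rr]); pr <- pr / sum(pr)
    for (i in 1:3) {
      yv <- pat[r == rr, i]
      mom <- conditional_item_moments(m, paste0("item", i), rr)
      expect_equal(mom$expected, sum(pr * yv), tolerance = 1e-10)
      expect_equal(mom$variance, sum(pr * yv^2) - sum(pr * yv)^2,
                   tolerance = 1e-10)
    }
  }
  m0 <- conditional_item_moments(m, "item2", c(0, 6))
  expect_equal(m0$expected, c(0, 2))
  expect_equal(m0$variance, c(0, 0))
})

test_that("GLLRM conditional probabilities match enumeration with LD and DIF", {
  set.seed(9)
  alpha <- lapply(1:3, function(i) c(0, rnorm(2)))
  names(alpha) <- paste0("item", 1:3)
  lam <- matrix(0, 3, 3); lam[2:3, 2:3] <- matrix(rnorm(4), 2)
  del <- matrix(0, 3, 2); del[2:3, 2] <- c(0.5, 1.1)
  m <- rasch_model(alpha, ld = list(c("item1", "item2")),
                   lambda = list("item1:item2" = lam),
                   dif = list(list(item = "item3", covariate = "sex")),
                   delta = list(del),
                   cov_levels = list(sex = c("Male", "Female")))
  pat <- all_patterns(c(3, 3, 3))
  r <- rowSums(pat)
  for (lev in 1:2) {
    w <- pattern_logweights(pat, alpha, lambda = list("1:2" = lam),
                            delta = list(list(item = 3, grid = del, level = lev)))
    prof <- list(sex = c("Male", "Female")[lev])
    for (ix in c(3, 11, 19)) {
      expect_equal(conditional_pattern_logprob(m, pat[ix, ], profile = prof),
                   w[ix] - logsumexp_ref(w[r == r[ix]]), tolerance = 1e-10)
    }
    for (rr in 0:6) {
      s <- sum(exp(apply(pat[r == rr, , drop = FALSE], 1, function(y)
        conditional_pattern_logprob(m, y, profile = prof))))
      expect_equal(s, 1, tolerance = 1e-10)
    }
  }
  # r = 0 is a single pattern regardless of interactions
  expect_equal(conditional_pattern_logprob(m, c(0, 0, 0),
                                           profile = list(sex = "Female")), 0)
})

test_that("GLLRM with empty term sets reduces exactly to the PCM", {
  d <- sim_pcm_data(400, seed = 123)
  f1 <- pcm_fit(d, paste0("item", 1:5), se = FALSE)
  f2 <- gllrm_fit(d, paste0("item", 1:5), ld = list(), dif = list(), se = FALSE)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  expect_equal(f1$par_named, f2$par_named, tolerance = 1e-8)
})

test_that("conditional sampler reproduces enumeration probabilities", {
  set.seed(10)
  alpha <- lapply(1:3, function(i) c(0, rnorm(2)))
  m <- rasch_model(alpha)
  draws <- sample_conditional_patterns(m, rep(3L, 20000))
  expect_true(all(rowSums(draws) == 3))
  pat <- all_patterns(c(3, 3, 3))
  w <- pattern_logweights(pat, alpha)
  r <- rowSums(pat)
  pr <- exp(w[r == 3]); pr <- pr / sum(pr)
  eI2 <- sum(pr * pat[r == 3, 2])
  expect_equal(mean(draws[, 2]), eI2, tolerance = 0.02)
})
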