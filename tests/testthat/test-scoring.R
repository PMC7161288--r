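test_that("WML estimates: symmetry, monotonicity, fine-grid oracle, finite extremes", {
  alpha <- test_alpha(5, locs = rep(0, 5))  # all locations zero
  m <- rasch_model(alpha)
  wt <- wml_theta(m, 0:20)
  expect_equal(wt$theta[11], 0, tolerance = 1e-6)   # r = Rmax/2 -> theta = 0
  expect_true(all(diff(wt$theta) > 0))
  expect_true(all(is.finite(wt$theta)) && all(is.finite(wt$se)))
  # fine-grid oracle for a few scores
  logK <- gllrm:::model_esf(m, 1)
  grid <- seq(-8, 8, by = 1e-3)
  for (rr in c(3, 10, 17)) {
    ll <- sapply(grid, function(th) {
      lw <- logK + (seq_along(logK) - 1) * th
      info <- gllrm:::score_moments_given_theta(logK, th)$V
      rr * th - logsumexp_ref(lw) + 0.5 * log(info)
    })
    expect_equal(wt$theta[rr + 1], grid[which.max(ll)], tolerance = 2e-3)
  }
})

test_that("test information matches the finite-difference oracle and vanishes in the tails", {
  alpha <- test_alpha()
  m <- rasch_model(alpha)
  logK <- gllrm:::model_esf(m, 1)
  ll <- function(th, r) {
    lw <- logK + (seq_along(logK) - 1) * th
    logK[r + 1] + r * th - logsumexp_ref(lw)
  }
  h <- 1e-4
  for (th0 in c(-1, 0, 1.5)) {
    fd <- -(ll(th0 + h, 5) - 2 * ll(th0, 5) + ll(th0 - h, 5)) / h^2
    expect_equal(test_information(m, th0), fd, tolerance = 1e-5)
  }
  expect_lt(test_information(m, 25), 1e-6)
  expect_lt(test_information(m, -25), 1e-6)
})

test_that("ignoring positive LD overstates measurement precision", {
  # the scale-free form of "locally dependent items convey less information":
  # on data generated with a positive LD pair, the LD-aware model implies
  # lower score reliability and person separation than a naive independence
  # fit of the same data (pointwise information functions are not comparable
  # across the two fits because their latent metrics differ)
  set.seed(46)
  alpha <- test_alpha()
  items <- names(alpha)
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  scA <- sim_scale(items, alpha, trait_sd = 1.4,
                   ld = list(c("item1", "item2")), ld_scalar = 0.4)
  cfg <- sim_config(n = 6000, covariates = list(),
                    scales = list(a = scA, b = sim_scale(c("f1", "f2"), filler)),
                    trait_cor = 0)
  d <- simulate_dataset(cfg, seed = 47)$data
  f_ld <- gllrm_fit(d, items, ld = list(c("item1", "item2")), se = FALSE)
  f_naive <- pcm_fit(d, items, se = FALSE)
  rel_ld <- mc_reliability(f_ld, fit_person_dist(d, f_ld), 40000, seed = 3)
  rel_naive <- mc_reliability(f_naive, fit_person_dist(d, f_naive), 40000,
                              seed = 3)
  expect_lt(rel_ld$reliability, rel_naive$reliability)
})

test_that("target index: degenerate distribution at the maximum gives 1, far away near 0", {
  alpha <- test_alpha()
  m <- rasch_model(alpha)
  op <- optimize(function(th) test_information(m, th), c(-8, 8), maximum = TRUE)
  ti1 <- target_index(m, data.frame(mean = op$maximum, sd = 1e-9, n = 1))
  expect_equal(ti1$index, 1, tolerance = 1e-4)
  ti0 <- target_index(m, data.frame(mean = -14, sd = 0.3, n = 1))
  expect_lt(ti0$index, 0.05)
  expect_gt(ti0$index, 0)
})

test_that("Cronbach's alpha: hand-computed matrix, parallel and independent items", {
  y <- matrix(c(0, 1, 2, 3, 4, 2,
                1, 1, 2, 4, 3, 2,
                0, 2, 3, 3, 4, 1), ncol = 3)
  colnames(y) <- paste0("item", 1:3)
  k <- 3
  vt <- var(rowSums(y)); vi <- sum(apply(y, 2, var))
  expect_equal(cronbach_alpha(response_data(y)), k / (k - 1) * (1 - vi / vt))
  set.seed(30)
  base <- sample(0:4, 400, replace = TRUE)
  ypar <- sapply(1:6, function(i) base)
  colnames(ypar) <- paste0("item", 1:6)
  expect_gt(cronbach_alpha(response_data(ypar)), 0.99)
  yind <- sapply(1:6, function(i) sample(0:4, 400, replace = TRUE))
  colnames(yind) <- paste0("item", 1:6)
  expect_lt(abs(cronbach_alpha(response_data(yind))), 0.15)
})

test_that("Monte Carlo reliability: matches alpha without LD, below it with LD, reproducible", {
  set.seed(31)
  # parallel items: the no-LD bound is tight and the LD inflation of alpha
  # is not masked by lower-bound slack
  alpha <- test_alpha(5, locs = rep(0, 5))
  items <- names(alpha)
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  cfg0 <- sim_config(n = 4000, covariates = list(),
                     scales = list(a = sim_scale(items, alpha, trait_sd = 1.4),
                                   b = sim_scale(c("f1", "f2"), filler)),
                     trait_cor = 0)
  d0 <- simulate_dataset(cfg0, seed = 32)$data
  fit0 <- pcm_fit(d0, items, se = FALSE)
  pd0 <- fit_person_dist(d0, fit0)
  r1 <- mc_reliability(fit0, pd0, n_sim = 40000, seed = 7)
  r2 <- mc_reliability(fit0, pd0, n_sim = 40000, seed = 7)
  expect_identical(r1$reliability, r2$reliability)  # bit-identical under seed
  a0 <- cronbach_alpha(d0, items)
  expect_lt(abs(r1$reliability - a0), 0.03)
  expect_warning(mc_reliability(fit0, pd0, n_sim = 500), "unstable")

  # positive LD: the LD-honouring reliability sits below alpha
  cfg1 <- cfg0
  cfg1$scales$a <- sim_scale(items, alpha, trait_sd = 1.4,
                             ld = list(c("item1", "item2")), ld_scalar = 0.5)
  d1 <- simulate_dataset(cfg1, seed = 33)$data
  fit1 <- gllrm_fit(d1, items, ld = list(c("item1", "item2")), se = FALSE)
  pd1 <- fit_person_dist(d1, fit1)
  rel1 <- mc_reliability(fit1, pd1, n_sim = 40000, seed = 8)
  a1 <- cronbach_alpha(d1, items)
  expect_lt(rel1$reliability, a1)
})

test_that("person separation: limits and determinism", {
  alpha <- test_alpha()
  m <- rasch_model(alpha)
  # trait variance tiny relative to noise: pure ties/noise limit 0.5
  s0 <- person_separation(m, data.frame(mean = 0, sd = 1e-4), 20000, seed = 9)
  expect_lt(abs(s0$separation - 0.5), 0.02)
  # an instrument with high information everywhere orders persons almost
  # perfectly (many items, well-spread thresholds)
  big <- rasch_model(test_alpha(40, locs = seq(-2, 2, length.out = 40)))
  s1 <- person_separation(big, data.frame(mean = 0, sd = 2), 20000, seed = 10)
  expect_gt(s1$separation, 0.9)
  s2 <- person_separation(big, data.frame(mean = 0, sd = 2), 20000, seed = 10)
  expect_identical(s1$separation, s2$separation)
  # second-implementation oracle: direct pairwise simulation from the model
  set.seed(11)
  pd <- data.frame(mean = 0, sd = 1.4)
  sep <- person_separation(m, pd, 40000, seed = 12)$separation
  th1 <- rnorm(40000, 0, 1.4); th2 <- rnorm(40000, 0, 1.4)
  y1 <- rowSums(simulate_given_theta(m, th1))
  y2 <- rowSums(simulate_given_theta(m, th2))
  tie <- y1 == y2
  ref <- mean((sign(y1 - y2) == sign(th1 - th2))[!tie]) * mean(!tie) +
    0.5 * mean(tie)
  expect_lt(abs(sep - ref), 0.01)
})

test_that("conversion table: identity without DIF, monotone and floor-anchored with DIF", {
  alpha <- test_alpha()
  m0 <- rasch_model(alpha)
  ct0 <- dif_conversion_table(m0)
  expect_equal(ct0$adjusted, ct0$observed)
  # model with DIF on item1 by sex
  del <- matrix(0, 5, 2); del[2:5, 2] <- 0.4 * (1:4)
  m1 <- rasch_model(alpha, dif = list(list(item = "item1", covariate = "sex")),
                    delta = list(del),
                    cov_levels = list(sex = c("Male", "Female")))
  ct1 <- dif_conversion_table(m1)
  for (lv in c("Male", "Female")) {
    adj <- ct1$adjusted[ct1$sex == lv]
    expect_true(all(diff(adj) > -1e-9))      # weakly increasing
    expect_lt(adj[1], 1.5)                   # r = 0 maps near the floor
  }
  expect_equal(ct1$adjusted[ct1$sex == "Male"], as.numeric(0:20))  # reference
  # Female endorses item1 more easily at equal trait: her observed scores
  # overstate the trait, so mid-range adjusted scores sit below observed
  fem <- ct1[ct1$sex == "Female", ]
  expect_lt(fem$adjusted[fem$observed == 10], 10)
})

test_that("kendall tau: identity, hand-enumerated pairs, independence", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(kendall_tau(x, x)$tau, 1)
  y <- c(2, 1, 4, 3, 5)  # 8 concordant, 2 discordant -> tau = 0.6
  expect_equal(kendall_tau(x, y)$tau, 0.6)
  set.seed(13)
  a <- sample(0:10, 600, replace = TRUE)
  b <- sample(0:10, 600, replace = TRUE)
  kt <- kendall_tau(a, b)
  expect_lt(abs(kt$tau), 0.08)
  expect_error(kendall_tau(rep(1, 10), 1:10), "constant")
})
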