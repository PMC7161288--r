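test_that("two dichotomous items: CML location difference equals log(n10/n01)", {
  # with two dichotomous items every non-extreme person has score 1, and the
  # conditional MLE of the location difference is log(n10 / n01)
  y <- rbind(matrix(rep(c(1L, 0L), 20), ncol = 2, byrow = TRUE),
             matrix(rep(c(0L, 1L), 10), ncol = 2, byrow = TRUE))
  colnames(y) <- paste0("item", 1:2)
  d <- response_data(y, ncat = 2L)
  fit <- pcm_fit(d, se = FALSE)
  diff12 <- fit$alpha$item1[2] - fit$alpha$item2[2]
  expect_equal(diff12, log(20 / 10), tolerance = 1e-6)

  # symmetric counts give equal locations
  y2 <- rbind(matrix(rep(c(1L, 0L), 15), ncol = 2, byrow = TRUE),
              matrix(rep(c(0L, 1L), 15), ncol = 2, byrow = TRUE))
  colnames(y2) <- paste0("item", 1:2)
  f2 <- pcm_fit(response_data(y2, ncat = 2L), se = FALSE)
  expect_equal(f2$alpha$item1[2], f2$alpha$item2[2], tolerance = 1e-6)
})

test_that("score equations hold at the CML solution", {
  d <- sim_pcm_data(800, seed = 21)
  items <- paste0("item", 1:5)
  fit <- pcm_fit(d, items, se = FALSE)
  mom <- gllrm:::conditional_moments_profile(fit, 1)
  expected_margin <- as.vector(mom$E %*% fit$counts[, 1])
  y <- d$responses[, items]
  r <- rowSums(y)
  used <- !is.na(r) & r > 0 & r < 20
  observed_margin <- colSums(y[used, ])
  expect_equal(expected_margin, unname(observed_margin), tolerance = 1e-6)
})

test_that("identification constraint and gauge invariance", {
  d <- sim_pcm_data(500, seed = 31)
  fit <- pcm_fit(d, paste0("item", 1:5), se = FALSE)
  # sum-zero item locations: mean threshold of item i is -alpha_i[m]/m
  locs <- vapply(fit$alpha, function(a) -a[length(a)] / (length(a) - 1), 0)
  expect_equal(sum(locs), 0, tolerance = 1e-8)
  # warm-starting from a gauge-shifted vector lands on the same solution
  shifted <- fit$par_named + rnorm(length(fit$par_named), 0, 0.3)
  fit2 <- pcm_fit(d, paste0("item", 1:5), start = shifted, se = FALSE)
  expect_equal(fit2$par_named, fit$par_named, tolerance = 1e-5)
  expect_equal(fit2$logLik, fit$logLik, tolerance = 1e-8)
})

test_that("model_dof matches the free-parameter arithmetic", {
  expect_identical(model_dof(rep(5L, 14)), 55L)
  expect_identical(model_dof(rep(5L, 7)), 27L)
  expect_identical(model_dof(rep(5L, 7), ld = list(c(1, 2))), 27L + 16L)
  expect_identical(model_dof(rep(5L, 5), dif = list(list(item = 1, nlevels = 2))),
                   19L + 4L)
})

test_that("null categories are collapsed with a warning and recorded", {
  d <- sim_pcm_data(300, seed = 41)
  y <- d$responses
  y[, "item1"][y[, "item1"] == 4L] <- 3L  # category 4 never observed
  d2 <- response_data(y)
  expect_warning(fit <- pcm_fit(d2, paste0("item", 1:5), se = FALSE),
                 "collapsed")
  expect_equal(fit$ncat[["item1"]], 4L)
  expect_false(is.null(fit$collapse$item1))
  y[, "item2"] <- ifelse(y[, "item2"] > 0L, 1L, 0L) * 0L
  expect_error(pcm_fit(response_data(y), paste0("item", 1:5)),
               "single observed category")
})

test_that("interaction parameters of a generating GLLRM are recovered", {
  set.seed(51)
  alpha <- test_alpha()
  items <- names(alpha)
  lam0 <- 0.3; del0 <- 0.25
  scA <- sim_scale(items, alpha, trait_sd = 1.5,
                   ld = list(c("item1", "item2")), ld_scalar = lam0,
                   dif = list(list(item = "item3", covariate = "sex")),
                   dif_scalar = del0)
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  cfg <- sim_config(n = 3000,
                    covariates = list(sex = c(Male = .5, Female = .5)),
                    scales = list(a = scA,
                                  b = sim_scale(c("f1", "f2"), filler)),
                    trait_cor = 0)
  d <- simulate_dataset(cfg, seed = 99)$data
  fit <- gllrm_fit(d, items, ld = list(c("item1", "item2")),
                   dif = list(list(item = "item3", covariate = "sex")))
  st <- fit$se_table
  lam_rows <- grepl("^lambda", st$parameter) & !st$flagged
  ab <- do.call(rbind, lapply(strsplit(st$parameter[lam_rows], ":"),
                              function(x) as.numeric(utils::tail(x, 2))))
  z_lam <- (st$estimate[lam_rows] - lam0 * ab[, 1] * ab[, 2]) / st$se[lam_rows]
  expect_true(all(abs(z_lam) < 3.5))
  del_rows <- grepl("^delta", st$parameter) & !st$flagged
  yy <- as.numeric(vapply(strsplit(st$parameter[del_rows], ":"),
                          function(x) x[4], ""))
  z_del <- (st$estimate[del_rows] - del0 * yy) / st$se[del_rows]
  expect_true(all(abs(z_del) < 3.5))
})

test_that("each true interaction term increases the conditional log-likelihood", {
  set.seed(61)
  alpha <- test_alpha()
  items <- names(alpha)
  scA <- sim_scale(items, alpha, trait_sd = 1.5,
                   ld = list(c("item1", "item2")), ld_scalar = 0.3,
                   dif = list(list(item = "item3", covariate = "sex")),
                   dif_scalar = 0.3)
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  cfg <- sim_config(n = 2000, covariates = list(sex = c(Male = .5, Female = .5)),
                    scales = list(a = scA, b = sim_scale(c("f1", "f2"), filler)),
                    trait_cor = 0)
  d <- simulate_dataset(cfg, seed = 71)$data
  f0 <- pcm_fit(d, items, se = FALSE)
  f1 <- gllrm_fit(d, items, ld = list(c("item1", "item2")), se = FALSE)
  f2 <- gllrm_fit(d, items, ld = list(c("item1", "item2")),
                  dif = list(list(item = "item3", covariate = "sex")),
                  se = FALSE)
  expect_gt(f1$logLik, f0$logLik)
  expect_gt(f2$logLik, f1$logLik)
})

test_that("specification errors are caught", {
  d <- sim_pcm_data(200, seed = 81)
  expect_error(gllrm_fit(d, paste0("item", 1:5),
                         ld = list(c("item1", "item1"))), "distinct")
  expect_error(gllrm_fit(d, paste0("item", 1:5),
                         ld = list(c("item1", "item2"), c("item2", "item3"))),
               "disjoint")
  expect_error(gllrm_fit(d, paste0("item", 1:5),
                         dif = list(list(item = "item1", covariate = "nope"))),
               "covariate")
})
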