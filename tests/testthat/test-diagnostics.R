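test_that("gamma coefficient: perfect association, reversal, hand-counted table", {
  x <- c(0, 1, 2, 3, 4, 0, 2)
  expect_equal(gamma_coefficient(x, x)$gamma, 1)
  expect_equal(gamma_coefficient(x, -x)$gamma, -1)
  # 2x2 table [[10,5],[5,10]]: C = 100, D = 25, gamma = 0.6
  x2 <- rep(c(0, 0, 1, 1), c(10, 5, 5, 10))
  y2 <- rep(c(0, 1, 0, 1), c(10, 5, 5, 10))
  g <- gamma_coefficient(x2, y2)
  expect_equal(g$C, 100)
  expect_equal(g$D, 25)
  expect_equal(g$gamma, 0.6)
})

test_that("gamma equals the O(n^2) brute-force pair count on random data", {
  set.seed(12)
  for (rep in 1:4) {
    x <- sample(0:4, 150, replace = TRUE)
    y <- pmin(4, pmax(0, x + sample(-2:2, 150, replace = TRUE)))
    expect_equal(gamma_coefficient(x, y)$gamma, bf_gamma(x, y),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("CLR test is zero for duplicated groups and detects nothing on null data", {
  d <- sim_pcm_data(600, seed = 15)
  items <- paste0("item", 1:5)
  fit <- pcm_fit(d, items, se = FALSE)
  # duplicate every person so the two halves are identical
  y2 <- rbind(d$responses, d$responses)
  d2 <- response_data(y2, covariates = rbind(d$covariates, d$covariates))
  fit2 <- pcm_fit(d2, items, se = FALSE)
  grpcov <- data.frame(g = factor(rep(c("a", "b"), each = nrow(d$responses))))
  d3 <- response_data(y2, covariates = cbind(grpcov, rbind(d$covariates, d$covariates)))
  fit3 <- pcm_fit(d3, items, se = FALSE)
  out <- clr_test(d3, fit3, "g")
  expect_lt(out$statistic, 1e-4)
  expect_equal(out$df, 19)
  # homogeneity on plain null data: statistic positive, df consistent
  hom <- clr_test(d, fit, "score")
  expect_gte(hom$statistic, 0)
  expect_gte(hom$df, 1)
  expect_true(hom$p_value >= 0 && hom$p_value <= 1)
})

test_that("kelderman screening rejects included or overlapping candidates", {
  d <- sim_pcm_data(400, seed = 16)
  items <- paste0("item", 1:5)
  fit <- gllrm_fit(d, items, ld = list(c("item1", "item2")), se = FALSE)
  expect_error(kelderman_lr(d, fit, list(items = c("item1", "item2"))),
               "already")
  expect_error(kelderman_lr(d, fit, list(items = c("item2", "item3"))),
               "overlaps")
  fit2 <- gllrm_fit(d, items,
                    dif = list(list(item = "item1", covariate = "sex")),
                    se = FALSE)
  expect_error(kelderman_lr(d, fit2,
                            list(item = "item1", covariate = "sex")),
               "already")
  # a valid candidate returns a proper test row
  kt <- kelderman_lr(d, fit2, list(items = c("item2", "item3")))
  expect_gte(kt$statistic, 0)
  expect_gte(kt$df, 1)
})

test_that("item fit flags an under-discriminating item and LD depresses fit", {
  set.seed(17)
  alpha <- test_alpha()
  items <- names(alpha)
  # one flat (under-discriminating) item
  scA <- sim_scale(items, alpha, trait_sd = 1.5,
                   discrimination = c(item4 = 0.4))
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  cfg <- sim_config(n = 3000, covariates = list(sex = c(Male = .5, Female = .5)),
                    scales = list(a = scA, b = sim_scale(c("f1", "f2"), filler)),
                    trait_cor = 0)
  d <- simulate_dataset(cfg, seed = 18)$data
  fit <- pcm_fit(d, items, se = FALSE)
  itf <- conditional_item_fit(d, fit, B = 199)
  expect_gt(itf$infit[itf$item == "item4"], 1)
  expect_gt(itf$outfit[itf$item == "item4"], 1)
  expect_lt(itf$infit_p[itf$item == "item4"], 0.05)

  # an item duplicated verbatim: extreme LD, fit statistics below 1
  y <- d$responses
  y[, "item5"] <- y[, "item4"]
  d2 <- response_data(y, covariates = d$covariates)
  fit2 <- pcm_fit(d2, items, se = FALSE)
  itf2 <- conditional_item_fit(d2, fit2, B = 199)
  expect_lt(itf2$infit[itf2$item == "item4"], 1)
  expect_lt(itf2$infit[itf2$item == "item5"], 1)
})

test_that("partial gammas are near zero under conditional independence", {
  d <- sim_pcm_data(3000, seed = 19)
  items <- paste0("item", 1:5)
  pg <- partial_gamma_ld(d, "item1", "item2", items)
  expect_lt(abs(pg$gamma_avg), 2.5 * pg$se_avg + 1e-12)
  pgd <- partial_gamma_dif(d, "item1", "sex", items)
  expect_lt(abs(pgd$gamma), 2.5 * pgd$se + 1e-12)
  expect_error(partial_gamma_ld(d, "item1", "item1", items), "itself")
  dd <- d
  dd$covariates$sex <- factor(rep("Male", nrow(d$responses)),
                              levels = c("Male", "Female"))
  expect_error(partial_gamma_dif(dd, "item1", "sex", items), "single")
})

test_that("partial gamma detects an injected LD pair with the right sign", {
  set.seed(20)
  alpha <- test_alpha()
  items <- names(alpha)
  scA <- sim_scale(items, alpha, trait_sd = 1.5,
                   ld = list(c("item1", "item2")), ld_scalar = 0.3)
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  cfg <- sim_config(n = 4000, covariates = list(),
                    scales = list(a = scA, b = sim_scale(c("f1", "f2"), filler)),
                    trait_cor = 0)
  d <- simulate_dataset(cfg, seed = 21)$data
  pg <- partial_gamma_ld(d, "item1", "item2", items)
  expect_gt(pg$gamma_avg, 0.1)
  # invariant to relabeling the pair
  pg2 <- partial_gamma_ld(d, "item2", "item1", items)
  expect_equal(pg2$gamma_avg, pg$gamma_avg, tolerance = 1e-12)
})

test_that("ICC table: conforming items stay inside the band, flat items do not", {
  set.seed(22)
  alpha <- test_alpha()
  items <- names(alpha)
  scA <- sim_scale(items, alpha, trait_sd = 1.5,
                   discrimination = c(item4 = 0.35))
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  cfg <- sim_config(n = 4000, covariates = list(),
                    scales = list(a = scA, b = sim_scale(c("f1", "f2"), filler)),
                    trait_cor = 0)
  d <- simulate_dataset(cfg, seed = 23)$data
  fit <- pcm_fit(d, items, se = FALSE)
  t1 <- icc_table(d, fit, "item1")
  big <- t1$n >= 30
  expect_gt(mean(t1$observed[big] >= t1$lower[big] &
                 t1$observed[big] <= t1$upper[big]), 0.8)
  expect_true(all(t1$n > 0))
  # the flat item's observed curve is shallower than expected
  t4 <- icc_table(d, fit, "item4")
  big4 <- t4$n >= 30
  slope_obs <- coef(lm(observed ~ score, data = t4[big4, ]))[2]
  slope_exp <- coef(lm(expected ~ score, data = t4[big4, ]))[2]
  expect_lt(slope_obs, slope_exp)
})

test_that("unidimensionality test: null under one trait, rejection under two", {
  set.seed(24)
  alpha_a <- test_alpha()
  alpha_b <- test_alpha(3, locs = c(-0.2, 0, 0.2))
  names(alpha_b) <- paste0("item", 6:8)
  one_cfg <- function(rho) {
    sim_config(n = 3000, covariates = list(),
               scales = list(a = sim_scale(names(alpha_a), alpha_a, trait_sd = 1.4),
                             b = sim_scale(names(alpha_b), alpha_b, trait_sd = 1.4)),
               trait_cor = rho)
  }
  # common trait
  sim1 <- simulate_dataset(one_cfg(1), seed = 25)
  fa <- pcm_fit(sim1$data, names(alpha_a), se = FALSE)
  fb <- pcm_fit(sim1$data, names(alpha_b), se = FALSE)
  u1 <- unidimensionality_test(sim1$data, fa, fb, n_sim = 60000, n_boot = 100)
  expect_gt(u1$p_value, 0.05)
  expect_lt(abs(u1$gamma_obs - u1$gamma_exp), 3 * u1$se_diff)
  # two distinct traits, rho = 0.6
  sim2 <- simulate_dataset(one_cfg(0.6), seed = 26)
  fa2 <- pcm_fit(sim2$data, names(alpha_a), se = FALSE)
  fb2 <- pcm_fit(sim2$data, names(alpha_b), se = FALSE)
  u2 <- unidimensionality_test(sim2$data, fa2, fb2, n_sim = 60000, n_boot = 100)
  expect_lt(u2$gamma_obs, u2$gamma_exp)
  expect_lt(u2$p_value, 0.05)
  expect_error(unidimensionality_test(sim2$data, fa2, fa2), "disjoint")
})
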