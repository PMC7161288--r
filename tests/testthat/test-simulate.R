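test_that("configuration validation catches bad inputs before sampling", {
  alpha <- test_alpha(3)
  expect_error(sim_scale(names(alpha), alpha, discrimination = c(item1 = -1)),
               "positive")
  expect_error(sim_scale(names(alpha), alpha, ld = list(c("item1", "item2"))),
               "parallel")
  sc <- sim_scale(names(alpha), alpha)
  expect_error(sim_config(10, covariates = list(sex = c(Male = .7, Female = .5)),
                          scales = list(a = sc, b = sc)), "sum to 1")
  expect_error(sim_config(10, scales = list(a = sc, b = sc), trait_cor = 1.4),
               "trait_cor")
  sc_dif <- sim_scale(names(alpha), alpha,
                      dif = list(list(item = "item1", covariate = "ghost")),
                      dif_scalar = 0.2)
  expect_error(sim_config(10, covariates = list(), scales = list(a = sc_dif, b = sc)),
               "not declared")
})

test_that("a fixed seed reproduces the data set exactly", {
  cfg <- pss14_sim_config(n = 500)
  s1 <- simulate_dataset(cfg, seed = 404)
  s2 <- simulate_dataset(cfg, seed = 404)
  expect_identical(s1$data$responses, s2$data$responses)
  expect_identical(s1$data$covariates, s2$data$covariates)
  expect_identical(s1$correlates, s2$correlates)
  s3 <- simulate_dataset(cfg, seed = 405)
  expect_false(identical(s1$data$responses, s3$data$responses))
})

test_that("covariate prevalences land inside their binomial intervals", {
  cfg <- pss14_sim_config(n = 20000, correlates = FALSE)
  sim <- simulate_dataset(cfg, seed = 31416)
  pf <- mean(sim$data$covariates$sex == "Female")
  ci <- qbinom(c(.0025, .9975), 20000, 0.619) / 20000
  expect_gt(pf, ci[1]); expect_lt(pf, ci[2])
  pe <- mean(sim$data$covariates$education == "TechnicalOrUniversity")
  ci2 <- qbinom(c(.0025, .9975), 20000, 0.675) / 20000
  expect_gt(pe, ci2[1]); expect_lt(pe, ci2[2])
})

test_that("rank-one interaction scalars map monotonically to realized partial gamma", {
  alpha <- test_alpha()
  items <- names(alpha)
  filler <- test_alpha(2, locs = c(0, 0)); names(filler) <- c("f1", "f2")
  gam <- sapply(c(-0.3, 0, 0.3, 0.6), function(s) {
    scA <- sim_scale(items, alpha, trait_sd = 1.4,
                     ld = list(c("item1", "item2")), ld_scalar = s)
    cfg <- sim_config(n = 20000, covariates = list(),
                      scales = list(a = scA, b = sim_scale(c("f1", "f2"), filler)),
                      trait_cor = 0)
    d <- simulate_dataset(cfg, seed = 55)$data
    partial_gamma_ld(d, "item1", "item2", items)$gamma_avg
  })
  expect_true(all(diff(gam) > 0))
  expect_lt(abs(gam[2]), 0.05)  # scalar 0 -> gamma near 0
})

test_that("calibrate_effect finds the requested magnitude and keeps its sign", {
  cfg <- pss14_sim_config(n = 500, correlates = FALSE)
  expect_identical(as.numeric(calibrate_effect(
    cfg, "stress", list(items = c("item1", "item2")), 0,
    n_calib = 5000)), 0)
  sc <- calibrate_effect(cfg, "stress", list(items = c("item1", "item2")),
                         0.18, item_set = pss14_final_items()$stress,
                         n_calib = 40000, tol = 0.01)
  expect_gt(as.numeric(sc), 0)
  expect_lt(abs(attr(sc, "realized_gamma") - 0.18), 0.011)
  sc2 <- calibrate_effect(cfg, "control", list(item = "item10", covariate = "sex"),
                          -0.23, item_set = pss14_final_items()$control,
                          n_calib = 40000, tol = 0.01)
  expect_lt(as.numeric(sc2), 0)
  expect_error(calibrate_effect(cfg, "stress", list(items = c("item3", "item11")),
                                0.2), "not declared")
})

test_that("null generator passes the basic conditional-independence screen", {
  # alpha = 1 discrimination, no LD/DIF: item fit near 1 and partial gammas
  # near zero at moderate n
  d <- sim_pcm_data(2000, seed = 66)
  items <- paste0("item", 1:5)
  fit <- pcm_fit(d, items, se = FALSE)
  itf <- conditional_item_fit(d, fit, B = 199)
  expect_true(all(abs(itf$infit - 1) < 0.12))
  pg <- partial_gamma_dif(d, "item2", "sex", items)
  expect_lt(abs(pg$gamma), 3 * pg$se)
})

test_that("measure_realized_structure reports realized against target effects", {
  cfg <- pss14_sim_config(n = 30000, correlates = FALSE)
  sim <- simulate_dataset(cfg, seed = 77)
  tab <- measure_realized_structure(sim, item_sets = pss14_final_items())
  expect_true(all(c("quantity", "realized", "target") %in% names(tab)))
  eff <- tab[grepl("^(LD|DIF)", tab$quantity), ]
  expect_equal(nrow(eff), 8)
  expect_true(all(sign(eff$realized) == sign(eff$target)))
  expect_true(all(abs(eff$realized - eff$target) < 0.06))
  sg <- tab[tab$quantity == "subscale_gamma", ]
  expect_lt(abs(sg$realized - 0.527), 0.03)
})
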