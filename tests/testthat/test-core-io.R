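test_that("likert codes are shifted to 0-based and out-of-range cells dropped", {
  spec <- scale_spec("toy", c("item1", "item2"), ncat = 5L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,item1,item2", "a,1,5", "b,3,9", "c,5,2"), f)
  expect_warning(d <- read_responses(f, spec, id_column = "person_id"),
                 "1 out-of-range")
  expect_equal(unname(d$responses[, "item1"]), c(0L, 2L, 4L))
  expect_equal(unname(d$responses[1, "item2"]), 4L)
  expect_true(is.na(d$responses[2, "item2"]))
})

test_that("write/read round trip reproduces the matrix cell for cell", {
  set.seed(11)
  y <- matrix(sample(c(0:4, NA), 60, replace = TRUE), 12, 5)
  colnames(y) <- paste0("item", 1:5)
  d <- response_data(y, covariates = data.frame(
    sex = factor(rep(c("Male", "Female"), 6), levels = c("Male", "Female"))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_responses(d, f)
  d2 <- read_responses(f, scale_spec("toy", paste0("item", 1:5)),
                       covariate_names = "sex", id_column = "person_id")
  expect_identical(unname(d2$responses), unname(d$responses))
  expect_equal(as.character(d2$covariates$sex), as.character(d$covariates$sex))
})

test_that("loader rejects unknown item columns and duplicate ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,item1,item2", "a,1,2", "a,2,3"), f)
  expect_error(read_responses(f, scale_spec("toy", c("item1", "item9"))),
               "unknown item")
  spec <- scale_spec("toy", c("item1", "item2"))
  expect_error(
    suppressWarnings(read_responses(f, spec, id_column = "person_id")),
    "unique")
})

test_that("reverse scoring maps endpoints, fixes midpoints, is an involution", {
  set.seed(5)
  y <- matrix(sample(c(0:4, NA), 200, replace = TRUE), 40, 5)
  colnames(y) <- paste0("item", 1:5)
  d <- response_data(y)
  spec <- scale_spec("toy", paste0("item", 1:5),
                     reverse_scored = c("item2", "item4"))
  r <- apply_reverse_scoring(d, spec)
  expect_equal(r$responses[, "item2"], 4L - y[, "item2"])
  expect_identical(r$responses[, "item1"], y[, "item1"])
  expect_true(all(r$responses[which(y[, "item2"] == 2), "item2"] == 2))
  rr <- apply_reverse_scoring(r, spec)
  expect_identical(rr$responses, d$responses)
})

test_that("total scores respect bounds and flag incomplete cases", {
  y <- rbind(rep(0L, 5), rep(4L, 5), c(1L, 2L, NA, 3L, 0L))
  colnames(y) <- paste0("item", 1:5)
  d <- response_data(y)
  ts <- total_scores(d)
  expect_equal(ts$score[1:2], c(0L, 20L))
  expect_true(is.na(ts$score[3]) && !ts$valid[3])
  expect_error(total_scores(d, character()), "empty")
  set.seed(2)
  d2 <- sim_pcm_data(200, seed = 77)
  ts2 <- total_scores(d2, paste0("item", 1:5))
  expect_true(all(ts2$score >= 0 & ts2$score <= 20, na.rm = TRUE))
})

test_that("the bundled scale layout splits 14 items into the two subscales", {
  full <- pss14_spec("full")
  stress <- pss14_spec("stress")
  control <- pss14_spec("control")
  expect_length(full$items, 14)
  expect_setequal(c(stress$items, control$items), full$items)
  expect_length(intersect(stress$items, control$items), 0)
  expect_setequal(full$reverse_scored, stress$items)
})
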