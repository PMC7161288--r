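# Person-side quantities: Warm's weighted maximum likelihood trait
# estimates, test information and targeting, reliability (Cronbach's alpha
# and the LD-adjusted Monte Carlo estimate), person separation, DIF score
# conversion, and Kendall's tau for criterion validity.

# log P(R = r | theta) over all r for one profile: logK[r] + r*theta - logD
score_logdist <- function(logK, theta) {
  lw <- outer(theta, seq_along(logK) - 1) + rep(logK, each = length(theta))
  lw - row_logsumexp(lw)
}

score_moments_given_theta <- function(logK, theta) {
  ld <- score_logdist(logK, theta)
  pr <- exp(ld)
  r <- seq_along(logK) - 1
  e <- as.vector(pr %*% r)
  v <- as.vector(pr %*% r^2) - e^2
  list(E = e, V = pmax(v, 0))
}

#' Test information function
#'
#' Fisher information of the total score about the latent trait,
#' `I(theta) = Var(R | theta)`. Locally dependent item pairs contribute
#' through their joint (composite) score distribution, so LD reduces the
#' information relative to independent items with the same margins.
#'
#' @param model a fitted or [rasch_model()] object.
#' @param theta numeric vector of trait values.
#' @param profile covariate profile (required with DIF terms), or a profile
#'   row index via `profile_index`.
#' @param profile_index alternative to `profile`: row of `model$profiles`.
#' @return numeric vector `I(theta)`.
#' @export
test_information <- function(model, theta, profile = NULL, profile_index = NULL) {
  p <- profile_index %||% match_profile(model, profile)
  logK <- model_esf(model, p)
  score_moments_given_theta(logK, theta)$V
}

#' Warm's weighted maximum likelihood trait estimate for a total score
#'
#' Maximizes the weighted log-likelihood `r*theta - log D(theta) +
#' 0.5*log I(theta)`, where `D` is the score-distribution normalizer. The
#' weighting keeps the estimate finite at the extreme scores 0 and R_max.
#'
#' @param model a fitted or [rasch_model()] object.
#' @param r total score(s), 0..R_max.
#' @param profile covariate profile (subgroup-specific item parameters are
#'   used when the model has DIF terms).
#' @param profile_index alternative to `profile`.
#' @param interval search interval on the latent scale.
#' @return data frame with `r`, `theta`, `se` (`1/sqrt(I(theta))`).
#' @export
wml_theta <- function(model, r, profile = NULL, profile_index = NULL,
                      interval = c(-12, 12)) {
  p <- profile_index %||% match_profile(model, profile)
  if (any(r < 0 | r > model$rmax)) stop("score out of range 0..R_max")
  logK <- model_esf(model, p)
  obj <- function(theta, rr) {
    lw <- logK + (seq_along(logK) - 1) * theta
    info <- score_moments_given_theta(logK, theta)$V
    rr * theta - logsumexp(lw) + 0.5 * log(info)
  }
  out <- vapply(r, function(rr) {
    op <- optimize(obj, interval, rr = rr, maximum = TRUE, tol = 1e-9)
    op$maximum
  }, 0)
  se <- 1 / sqrt(score_moments_given_theta(logK, out)$V)
  data.frame(r = r, theta = out, se = se)
}

#' Estimate the person distribution under a normality assumption
#'
#' Estimates a normal latent distribution (mean, SD) per DIF-defined
#' subgroup by matching the observed total-score mean and variance to the
#' model-implied moments of the normal mixture
#' (`E[R] = E_theta E[R | theta]`, `Var[R] = Var_theta E[R | theta] +
#' E_theta Var[R | theta]`). Moment matching avoids the biases of plugging
#' in person-estimate moments directly: WML estimates shrink toward the
#' centre at extreme scores and carry measurement noise, so their spread
#' does not estimate the latent spread.
#'
#' @param data the [response_data()] the model was fitted to.
#' @param model a fitted model.
#' @return data frame with one row per covariate profile: `mean`, `sd`, `n`
#'   plus the profile columns.
#' @export
fit_person_dist <- function(data, model) {
  data2 <- apply_model_recode(data, model)
  y <- data2$responses[, model$items, drop = FALSE]
  ok <- rowSums(is.na(y)) == 0L
  for (cv in names(model$cov_levels)) ok <- ok & !is.na(data2$covariates[[cv]])
  r_all <- rowSums(y[ok, , drop = FALSE])
  pidx <- if (nrow(model$profiles) == 1L) rep(1L, length(r_all))
          else profile_index_of(model, data2$covariates[ok, , drop = FALSE])
  P <- nrow(model$profiles)
  out <- model$profiles
  out$mean <- NA_real_; out$sd <- NA_real_; out$n <- 0L
  grid_mix <- function(logK, mu, sigma) {
    gx <- seq(mu - 6 * sigma, mu + 6 * sigma, length.out = 121L)
    wts <- dnorm(gx, mu, sigma); wts <- wts / sum(wts)
    mom <- score_moments_given_theta(logK, gx)
    m1 <- sum(wts * mom$E)
    v1 <- sum(wts * (mom$V + mom$E^2)) - m1^2
    c(m1, v1)
  }
  for (p in seq_len(P)) {
    sel <- pidx == p
    if (sum(sel) < 2L) next
    logK <- model_esf(model, p)
    obs <- c(mean(r_all[sel]), var(r_all[sel]))
    objective <- function(par) {
      mm <- grid_mix(logK, par[1], exp(par[2]))
      (mm[1] - obs[1])^2 + (sqrt(mm[2]) - sqrt(obs[2]))^2
    }
    # start near a crude inverse of the score mean
    wt <- wml_theta(model, max(1L, min(model$rmax - 1L, round(obs[1]))),
                    profile_index = p)
    op <- optim(c(wt$theta, log(1)), objective, method = "Nelder-Mead",
                control = list(reltol = 1e-10, maxit = 500))
    out$mean[p] <- op$par[1]
    out$sd[p] <- exp(op$par[2])
    out$n[p] <- sum(sel)
  }
  out
}

#' Test Information Target Index and target score
#'
#' Targeting index: the mean test information over the person distribution
#' divided by the maximum attainable test information,
#' `E[I(theta)] / max I(theta)`, in (0, 1]. The target score is the expected
#' total score at the trait value that maximizes the information function.
#' Reported per covariate profile, plus an `overall` row weighting profiles
#' by their person counts.
#'
#' @param model a fitted or [rasch_model()] object.
#' @param person_dist data frame as returned by [fit_person_dist()] (per
#'   profile `mean`, `sd`, optionally `n`).
#' @param grid_points quadrature points for the expectation.
#' @return data frame per profile: `index`, `target_score`, `theta_max`,
#'   `mean_score`.
#' @export
target_index <- function(model, person_dist, grid_points = 161L) {
  P <- nrow(model$profiles)
  rows <- lapply(seq_len(P), function(p) {
    logK <- model_esf(model, p)
    infof <- function(th) score_moments_given_theta(logK, th)$V
    op <- optimize(infof, c(-10, 10), maximum = TRUE, tol = 1e-8)
    imax <- op$objective
    mu <- person_dist$mean[p]; sdv <- person_dist$sd[p]
    if (sdv <= 0) {
      imean <- infof(mu)
    } else {
      gx <- seq(mu - 6 * sdv, mu + 6 * sdv, length.out = grid_points)
      wts <- dnorm(gx, mu, sdv); wts <- wts / sum(wts)
      imean <- sum(wts * infof(gx))
    }
    mom <- score_moments_given_theta(logK, c(op$maximum, mu))
    cbind(model$profiles[p, , drop = FALSE],
          data.frame(index = imean / imax, target_score = mom$E[1],
                     theta_max = op$maximum, mean_score = mom$E[2]))
  })
  out <- do.call(rbind, rows)
  if (!is.null(person_dist$n) && P > 1L) {
    w <- person_dist$n / sum(person_dist$n)
    overall <- out[1, , drop = FALSE]
    for (cv in names(model$cov_levels)) overall[[cv]] <- "overall"
    overall$index <- sum(w * out$index)
    overall$target_score <- sum(w * out$target_score)
    overall$theta_max <- sum(w * out$theta_max)
    overall$mean_score <- sum(w * out$mean_score)
    out <- rbind(out, overall)
  }
  rownames(out) <- NULL
  out
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` over complete cases.
#'
#' @param data a [response_data()].
#' @param items item set.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(data, items = colnames(data$responses)) {
  y <- data$responses[, items, drop = FALSE]
  y <- y[rowSums(is.na(y)) == 0L, , drop = FALSE]
  if (nrow(y) < 2L) stop("need at least two complete cases")
  k <- ncol(y)
  vt <- var(rowSums(y))
  if (vt == 0) stop("zero total-score variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(y, 2, var)) / vt)
}

#' Monte Carlo reliability adjusted for local dependence
#'
#' Simulates `(theta, Y)` pairs from the fitted model and the given person
#' distribution and returns `Var(E[R | theta]) / Var(R)`, the proportion of
#' true-score variance in the total score. Because the simulation honours
#' the model's LD structure, the estimate is not inflated by local
#' dependence the way Cronbach's alpha is. With DIF terms present the
#' reliability is computed for each subgroup independently.
#'
#' @param model a fitted model.
#' @param person_dist per-profile `mean`/`sd` data frame
#'   ([fit_person_dist()]).
#' @param n_sim Monte Carlo persons per subgroup (default 20000; a warning
#'   is issued below 1000).
#' @param seed optional integer seed for reproducibility.
#' @return data frame per profile with `reliability`.
#' @export
mc_reliability <- function(model, person_dist, n_sim = 20000L, seed = NULL) {
  if (n_sim < 1000L) warning("n_sim < 1000 gives unstable reliability estimates")
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(model$profiles)
  out <- model$profiles
  out$reliability <- NA_real_
  for (p in seq_len(P)) {
    logK <- model_esf(model, p)
    theta <- rnorm(n_sim, person_dist$mean[p], person_dist$sd[p])
    mom <- score_moments_given_theta(logK, theta)
    # Var(R) decomposed as Var(E[R|theta]) + E(Var[R|theta]); only the theta
    # draw is Monte Carlo, the inner moments are exact
    out$reliability[p] <- var(mom$E) / (var(mom$E) + mean(mom$V))
  }
  rownames(out) <- NULL
  out
}

#' Person separation probability
#'
#' The probability that the total scores of two random persons rank them in
#' the same order as their true latent traits. Tied total scores count as
#' half agreement; exactly tied traits have probability zero under a normal
#' person distribution.
#'
#' @inheritParams mc_reliability
#' @param n_sim Monte Carlo person pairs per subgroup.
#' @return data frame per profile with `separation`.
#' @export
person_separation <- function(model, person_dist, n_sim = 20000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(model$profiles)
  out <- model$profiles
  out$separation <- NA_real_
  r <- 0:model$rmax
  for (p in seq_len(P)) {
    logK <- model_esf(model, p)
    th1 <- rnorm(n_sim, person_dist$mean[p], person_dist$sd[p])
    th2 <- rnorm(n_sim, person_dist$mean[p], person_dist$sd[p])
    draw_scores <- function(th) {
      pr <- exp(score_logdist(logK, th))
      cp <- t(apply(pr, 1, cumsum))
      u <- runif(length(th))
      rowSums(u > cp)
    }
    r1 <- draw_scores(th1); r2 <- draw_scores(th2)
    agree <- sign(r1 - r2) == sign(th1 - th2)
    ties <- r1 == r2
    out$separation[p] <- mean(agree[!ties]) * mean(!ties) + 0.5 * mean(ties)
  }
  rownames(out) <- NULL
  out
}

#' DIF score conversion table
#'
#' Places every subgroup's observed total scores on the reference subgroup's
#' score metric: for subgroup g and observed score r, the trait is estimated
#' by WML under g's item parameters, and the adjusted score is the expected
#' total score at that trait under the reference subgroup's parameters
#' (including its LD terms). The reference subgroup maps to itself.
#'
#' @param model a fitted model (with DIF terms; without DIF the table is the
#'   identity).
#' @param reference named list/character of covariate levels defining the
#'   reference subgroup; defaults to each covariate's reference (first)
#'   level.
#' @return data frame (class `conversion_table`): profile columns,
#'   `observed`, `theta`, `adjusted`, `adjusted_rounded`.
#' @export
dif_conversion_table <- function(model, reference = NULL) {
  P <- nrow(model$profiles)
  if (is.null(reference))
    reference <- lapply(model$cov_levels, `[`, 1L)
  pref <- match_profile(model, reference)
  logK_ref <- model_esf(model, pref)
  rows <- lapply(seq_len(P), function(p) {
    wt <- wml_theta(model, 0:model$rmax, profile_index = p)
    if (p == pref) adj <- as.numeric(0:model$rmax)
    else adj <- score_moments_given_theta(logK_ref, wt$theta)$E
    cbind(model$profiles[rep(p, model$rmax + 1L), , drop = FALSE],
          data.frame(observed = 0:model$rmax, theta = wt$theta,
                     adjusted = adj, adjusted_rounded = round(adj)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  class(out) <- c("conversion_table", "data.frame")
  out
}

#' Observed versus DIF-adjusted subgroup score comparison
#'
#' Applies a [dif_conversion_table()] to each person's observed total score
#' and summarizes, per level of the chosen covariate: mean observed score,
#' mean adjusted score, their standard errors, and the bias
#' (observed - adjusted). The group contrast on the adjusted scale estimates
#' the score difference net of measurement bias.
#'
#' @param data a [response_data()].
#' @param model the fitted model the table belongs to.
#' @param table a [dif_conversion_table()].
#' @param covariate covariate whose levels are compared.
#' @return list with `by_group` (one row per level) and `diff_adjusted`
#'   (last minus first level on the adjusted scale; equals the observed
#'   difference minus the bias difference).
#' @export
adjusted_group_comparison <- function(data, model, table, covariate) {
  mp <- model_persons(data, model)
  # include extreme scorers too: conversion covers 0..R_max
  data2 <- apply_model_recode(data, model)
  y <- data2$responses[, model$items, drop = FALSE]
  ok <- rowSums(is.na(y)) == 0L
  covs <- names(model$cov_levels)
  for (cv in covs) ok <- ok & !is.na(data2$covariates[[cv]])
  cvv <- data2$covariates[[covariate]]
  if (is.null(cvv)) stop("unknown covariate: ", covariate)
  ok <- ok & !is.na(cvv)
  r <- rowSums(y[ok, , drop = FALSE])
  covdat <- data2$covariates[ok, , drop = FALSE]
  pidx <- profile_index_of(model, covdat)
  # lookup adjusted score by (profile, observed)
  tp <- profile_index_of(model, table[, covs, drop = FALSE])
  key <- paste(tp, table$observed)
  adj <- table$adjusted[match(paste(pidx, r), key)]
  if (anyNA(adj)) stop("conversion table does not cover all observed scores")
  gv <- factor(covdat[[covariate]])
  by_group <- do.call(rbind, lapply(levels(gv), function(l) {
    sel <- gv == l
    data.frame(level = l, n = sum(sel),
               observed_mean = mean(r[sel]),
               observed_se = sd(r[sel]) / sqrt(sum(sel)),
               adjusted_mean = mean(adj[sel]),
               adjusted_se = sd(adj[sel]) / sqrt(sum(sel)),
               bias = mean(r[sel]) - mean(adj[sel]),
               stringsAsFactors = FALSE)
  }))
  nl <- nrow(by_group)
  list(by_group = by_group,
       diff_adjusted = by_group$adjusted_mean[nl] - by_group$adjusted_mean[1],
       diff_observed = by_group$observed_mean[nl] - by_group$observed_mean[1])
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation with a normal-approximation p-value,
#' suitable for heavily tied ordinal scores.
#'
#' @param x,y paired vectors.
#' @return data frame with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("tau undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  data.frame(tau = unname(cor(x, y, method = "kendall")),
             p_value = ct$p.value, n = length(x))
}
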