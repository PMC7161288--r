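# Synthetic-data generator: PSS-14-like ordinal response data with known
# ground truth -- two correlated latent traits driving a negatively worded
# and a positively worded subscale, uniform LD and uniform DIF injected as
# rank-one log-linear interactions, deliberately under-discriminating items,
# and auxiliary criterion-validity correlates.

#' Configuration of one simulated subscale
#'
#' @param items item names.
#' @param alpha named list of item-category parameter vectors (first element
#'   0); the generating model is `w(y | theta) = alpha_y + a_i * y * theta`
#'   plus interaction terms.
#' @param discrimination named numeric vector of discrimination multipliers
#'   `a_i` (default 1 for every item); `a_i < 1` produces the flat,
#'   under-discriminating item characteristic curve of a poorly measuring
#'   item. Used for generation only; fitting always assumes `a = 1`.
#' @param ld list of LD pairs; `ld_scalar` gives one rank-one magnitude per
#'   pair (`lambda[a, b] = scalar * a * b`).
#' @param dif list of DIF terms `list(item =, covariate =)`; `dif_scalar`
#'   one magnitude per term (`delta[y, level] = scalar * y * (level - 1)`).
#' @param trait_mean,trait_sd normal trait distribution of the subscale.
#' @param trait_effects named list: covariate -> named numeric shift of the
#'   trait mean per level (reference level 0), e.g.
#'   `list(sex = c(Male = 0, Female = 0.3))`.
#' @param target_gamma optional named numeric of intended partial-gamma
#'   magnitudes per term (bookkeeping for [measure_realized_structure()]).
#' @return a `sim_scale` list.
#' @export
sim_scale <- function(items, alpha, discrimination = NULL, ld = list(),
                      ld_scalar = numeric(), dif = list(),
                      dif_scalar = numeric(), trait_mean = 0, trait_sd = 1.5,
                      trait_effects = list(), target_gamma = NULL) {
  names(alpha) <- items
  a <- setNames(rep(1, length(items)), items)
  if (!is.null(discrimination)) a[names(discrimination)] <- discrimination
  if (any(a <= 0)) stop("discrimination multipliers must be positive")
  ld <- normalize_ld(ld)
  dif <- normalize_dif(dif)
  if (length(ld) != length(ld_scalar)) stop("ld_scalar must parallel ld")
  if (length(dif) != length(dif_scalar)) stop("dif_scalar must parallel dif")
  if (trait_sd <= 0) stop("trait_sd must be positive")
  structure(list(items = items, alpha = alpha, discrimination = a,
                 ld = ld, ld_scalar = ld_scalar, dif = dif,
                 dif_scalar = dif_scalar, trait_mean = trait_mean,
                 trait_sd = trait_sd, trait_effects = trait_effects,
                 target_gamma = target_gamma), class = "sim_scale")
}

#' Simulation configuration
#'
#' @param n number of persons.
#' @param covariates named list: covariate -> named prevalence vector (must
#'   sum to 1; the first level is the reference).
#' @param scales named list of two [sim_scale()] objects.
#' @param trait_cor correlation between the two subscale traits (on their
#'   native orientations).
#' @param correlates optional named list of auxiliary criterion measures:
#'   `list(name = list(scale = "stress", tau = -0.3))`; each is generated as
#'   a continuous monotone transform of the named subscale's trait with
#'   Kendall tau approximately as requested (via the Greiner relation
#'   `rho = sin(pi * tau / 2)` for bivariate normal ranks).
#' @param target_subscale_gamma intended between-subscale gamma after
#'   reverse-scoring the first scale (bookkeeping).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n, covariates = list(), scales, trait_cor = 0,
                       correlates = list(), target_subscale_gamma = NULL) {
  if (n < 1) stop("n must be positive")
  for (cv in names(covariates)) {
    pr <- covariates[[cv]]
    if (abs(sum(pr) - 1) > 1e-8) stop("prevalences of ", cv, " must sum to 1")
    if (any(pr < 0)) stop("negative prevalence for ", cv)
  }
  if (abs(trait_cor) > 1) stop("trait_cor must lie in [-1, 1]")
  if (length(scales) != 2L) stop("exactly two scales are required")
  for (sc in scales) {
    for (d in sc$dif)
      if (!d$covariate %in% names(covariates))
        stop("DIF covariate not declared: ", d$covariate)
    for (cv in names(sc$trait_effects))
      if (!cv %in% names(covariates))
        stop("trait-effect covariate not declared: ", cv)
  }
  structure(list(n = n, covariates = covariates, scales = scales,
                 trait_cor = trait_cor, correlates = correlates,
                 target_subscale_gamma = target_subscale_gamma),
            class = "sim_config")
}

# vectorized categorical sampling given per-row log-weights
sample_rows <- function(lw) {
  mx <- do.call(pmax, lapply(seq_len(ncol(lw)), function(j) lw[, j]))
  pr <- exp(lw - mx)
  cp <- pr %*% upper.tri(diag(ncol(lw)), diag = TRUE)
  u <- runif(nrow(lw)) * cp[, ncol(lw)]
  as.integer(rowSums(u > cp) + 1L)  # 1-based column index
}

# Simulate one subscale's responses given trait values and covariates.
# Returns an integer matrix (n x items). Generation respects the dependence
# graph: singleton items are conditionally independent given theta, LD pairs
# are drawn from their 2-item joint distribution.
simulate_scale_responses <- function(sc, theta, covdat) {
  n <- length(theta)
  k <- length(sc$items)
  y <- matrix(0L, n, k)
  colnames(y) <- sc$items
  ncat <- vapply(sc$alpha, length, 0L)
  dif_shift <- function(item) {
    # n-vector of per-person DIF weight multipliers: sum_t scalar_t * code
    out <- rep(0, n)
    for (t in seq_along(sc$dif)) {
      if (sc$dif[[t]]$item != item) next
      cv <- covdat[[sc$dif[[t]]$covariate]]
      out <- out + sc$dif_scalar[t] * (as.integer(cv) - 1L)
    }
    out
  }
  in_pair <- unlist(sc$ld)
  for (pi in seq_along(sc$ld)) {
    pair <- sc$ld[[pi]]
    m1 <- ncat[pair[1]] - 1L; m2 <- ncat[pair[2]] - 1L
    cells <- as.matrix(expand.grid(0:m1, 0:m2))
    a1 <- sc$discrimination[pair[1]]; a2 <- sc$discrimination[pair[2]]
    base <- sc$alpha[[pair[1]]][cells[, 1] + 1L] +
      sc$alpha[[pair[2]]][cells[, 2] + 1L] +
      sc$ld_scalar[pi] * cells[, 1] * cells[, 2]
    lw <- outer(theta, a1 * cells[, 1] + a2 * cells[, 2]) +
      matrix(base, n, nrow(cells), byrow = TRUE) +
      outer(dif_shift(pair[1]), cells[, 1]) +
      outer(dif_shift(pair[2]), cells[, 2])
    ci <- sample_rows(lw)
    y[, pair[1]] <- cells[ci, 1]
    y[, pair[2]] <- cells[ci, 2]
  }
  for (it in setdiff(sc$items, in_pair)) {
    m <- ncat[it] - 1L
    lw <- outer(sc$discrimination[it] * theta + dif_shift(it), 0:m) +
      matrix(sc$alpha[[it]], n, m + 1L, byrow = TRUE)
    y[, it] <- sample_rows(lw) - 1L
  }
  y
}

#' Simulate a dataset from a configuration
#'
#' Draws covariates by prevalence, a bivariate-normal trait pair, responses
#' from the two subscales' generating models (with LD/DIF interactions and
#' discrimination multipliers), and any auxiliary correlates.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `data` (a [response_data()]), `correlates` (data frame
#'   or `NULL`), `theta` (n x 2 matrix of generating traits), and `config`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  covdat <- if (length(config$covariates)) {
    as.data.frame(lapply(config$covariates, function(pr) {
      factor(sample(names(pr), n, replace = TRUE, prob = pr),
             levels = names(pr))
    }))
  } else NULL
  z1 <- rnorm(n)
  z2 <- config$trait_cor * z1 + sqrt(1 - config$trait_cor^2) * rnorm(n)
  zz <- cbind(z1, z2)
  theta <- matrix(0, n, 2)
  ymats <- vector("list", 2L)
  for (s in 1:2) {
    sc <- config$scales[[s]]
    mu <- rep(sc$trait_mean, n)
    for (cv in names(sc$trait_effects))
      mu <- mu + sc$trait_effects[[cv]][as.character(covdat[[cv]])]
    theta[, s] <- mu + sc$trait_sd * zz[, s]
    ymats[[s]] <- simulate_scale_responses(sc, theta[, s], covdat)
  }
  y <- cbind(ymats[[1]], ymats[[2]])
  nm <- colnames(y)
  num <- suppressWarnings(as.integer(sub("^\\D+", "", nm)))
  if (!anyNA(num)) y <- y[, order(num), drop = FALSE]
  correlates <- NULL
  if (length(config$correlates)) {
    correlates <- as.data.frame(lapply(config$correlates, function(cr) {
      s <- if (identical(cr$scale, names(config$scales)[2])) 2L else 1L
      rho <- sin(pi * cr$tau / 2)
      rho * zz[, s] + sqrt(1 - rho^2) * rnorm(n)
    }))
  }
  colnames(theta) <- names(config$scales)
  ncat_all <- c(vapply(config$scales[[1]]$alpha, length, 0L),
                vapply(config$scales[[2]]$alpha, length, 0L))
  list(data = response_data(y, covariates = covdat,
                            ncat = unname(ncat_all[colnames(y)])),
       correlates = correlates, theta = theta, config = config)
}

#' Simulate responses from a fitted model at given trait values
#'
#' Draws response patterns from a (fitted or constructed) model's
#' distribution given the latent trait, block by block: singleton items are
#' conditionally independent given theta, LD pairs are drawn from their
#' joint cell distribution, and DIF enters through each person's covariate
#' profile.
#'
#' @param model a fitted or [rasch_model()] object.
#' @param theta trait values (one per person).
#' @param prof covariate profile index per person (default all 1).
#' @return integer response matrix.
#' @export
simulate_given_theta <- function(model, theta, prof = NULL) {
  n <- length(theta)
  if (is.null(prof)) prof <- rep(1L, n)
  prof <- rep_len(as.integer(prof), n)
  W <- model_weights(model)
  y <- matrix(0L, n, length(model$items))
  colnames(y) <- model$items
  for (p in unique(prof)) {
    sel <- which(prof == p)
    for (b in seq_along(model$blocks)) {
      bl <- model$blocks[[b]]
      lw <- outer(theta[sel], bl$s) +
        matrix(W[[p]][[b]], length(sel), length(bl$s), byrow = TRUE)
      ci <- sample_rows(lw)
      for (jj in seq_along(bl$items))
        y[sel, bl$items[jj]] <- bl$cells[ci, jj]
    }
  }
  y
}

# Fast path for calibration: simulate only one scale's responses (the
# between-scale correlation cannot affect within-scale stratified gammas).
simulate_one_scale <- function(config, s, n, seed) {
  set.seed(seed)
  covdat <- if (length(config$covariates)) {
    as.data.frame(lapply(config$covariates, function(pr)
      factor(sample(names(pr), n, replace = TRUE, prob = pr),
             levels = names(pr))))
  } else NULL
  sc <- config$scales[[s]]
  mu <- rep(sc$trait_mean, n)
  for (cv in names(sc$trait_effects))
    mu <- mu + sc$trait_effects[[cv]][as.character(covdat[[cv]])]
  theta <- mu + sc$trait_sd * rnorm(n)
  y <- simulate_scale_responses(sc, theta, covdat)
  response_data(y, covariates = covdat,
                ncat = unname(vapply(sc$alpha, length, 0L)[colnames(y)]))
}

#' Calibrate a rank-one interaction magnitude to a target partial gamma
#'
#' Bisects the scalar magnitude of one LD or DIF term against the realized
#' partial Goodman-Kruskal gamma in a large simulated sample (common random
#' numbers across evaluations), until the realized gamma is within `tol` of
#' the target.
#'
#' @param config a [sim_config()].
#' @param scale name or index of the subscale containing the term.
#' @param term `list(items = c(i, j))` for LD or `list(item =, covariate =)`
#'   for DIF; must already be declared in the scale.
#' @param target target partial gamma in (-1, 1).
#' @param item_set item set over which the restscore/total-score
#'   stratification is computed (default: the scale's items); use the final
#'   model's item set to match a reported effect size.
#' @param n_calib persons per simulation replicate.
#' @param n_rep independent simulation replicates averaged per evaluation
#'   (averaging reduces the Monte Carlo noise that otherwise limits the
#'   achievable calibration precision).
#' @param tol gamma tolerance (default 0.005).
#' @param interval initial bracket for the scalar.
#' @param seed seed base; evaluation replicate j reuses seed + 1000 * (j-1),
#'   so evaluations share random numbers across bisection steps.
#' @return the calibrated scalar magnitude (with attribute
#'   `realized_gamma`).
#' @export
calibrate_effect <- function(config, scale, term, target, item_set = NULL,
                             n_calib = 150000L, n_rep = 1L, tol = 0.005,
                             interval = c(-1.5, 1.5), seed = 20201L) {
  s <- if (is.character(scale)) match(scale, names(config$scales)) else scale
  sc <- config$scales[[s]]
  if (is.null(item_set)) item_set <- sc$items
  is_ld <- !is.null(term$items)
  if (is_ld) {
    pair <- sort(as.character(term$items))
    tix <- match(paste(pair, collapse = ":"),
                 vapply(sc$ld, paste, "", collapse = ":"))
    if (is.na(tix)) stop("LD term not declared in the scale")
  } else {
    tix <- match(paste(term$item, term$covariate),
                 vapply(sc$dif, function(d) paste(d$item, d$covariate), ""))
    if (is.na(tix)) stop("DIF term not declared in the scale")
  }
  eval_gamma <- function(x) {
    cfg <- config
    if (is_ld) cfg$scales[[s]]$ld_scalar[tix] <- x
    else cfg$scales[[s]]$dif_scalar[tix] <- x
    g <- vapply(seq_len(n_rep), function(j) {
      d <- simulate_one_scale(cfg, s, as.integer(n_calib),
                              seed = seed + 1000L * (j - 1L))
      if (is_ld)
        partial_gamma_ld(d, pair[1], pair[2], item_set)$gamma_avg
      else
        partial_gamma_dif(d, term$item, term$covariate, item_set)$gamma
    }, 0)
    mean(g)
  }
  if (target == 0) {
    out <- 0
    attr(out, "realized_gamma") <- eval_gamma(0)
    return(out)
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- eval_gamma(lo); fhi <- eval_gamma(hi)
  tries <- 0L
  while ((flo > target || fhi < target) && tries < 4L) {
    lo <- lo * 2; hi <- hi * 2
    flo <- eval_gamma(lo); fhi <- eval_gamma(hi)
    tries <- tries + 1L
  }
  if (flo > target || fhi < target)
    stop("target partial gamma unreachable within the scalar bracket")
  mid <- 0; fmid <- NA_real_
  for (it in seq_len(40L)) {
    mid <- (lo + hi) / 2
    fmid <- eval_gamma(mid)
    # stop on the gamma tolerance, or once further scalar refinement is
    # below the Monte Carlo resolution of the evaluations
    if (abs(fmid - target) < tol || (hi - lo) < 0.01) break
    if (fmid < target) lo <- mid else hi <- mid
  }
  out <- mid
  attr(out, "realized_gamma") <- fmid
  out
}

#' Realized versus target structure of a simulated dataset
#'
#' Recomputes, from a simulated dataset, every injected effect size: the
#' partial gamma of each LD and DIF term (within the item sets supplied),
#' the between-subscale gamma after reverse-scoring the first scale, and
#' covariate prevalences, next to their targets.
#'
#' @param sim result of [simulate_dataset()].
#' @param item_sets optional named list (per scale) of item sets over which
#'   the stratified gammas are computed (default: all scale items).
#' @return data frame with `quantity`, `realized`, `target`.
#' @export
measure_realized_structure <- function(sim, item_sets = NULL) {
  config <- sim$config
  rows <- list()
  addrow <- function(q, r, t) rows[[length(rows) + 1L]] <<-
    data.frame(quantity = q, realized = r, target = t, stringsAsFactors = FALSE)
  for (sname in names(config$scales)) {
    sc <- config$scales[[sname]]
    iset <- item_sets[[sname]] %||% sc$items
    for (pi in seq_along(sc$ld)) {
      pair <- sc$ld[[pi]]
      if (!all(pair %in% iset)) next
      g <- partial_gamma_ld(sim$data, pair[1], pair[2], iset)$gamma_avg
      addrow(term_key(list(items = pair)), g,
             unname(sc$target_gamma[term_key(list(items = pair))] %||% NA_real_))
    }
    for (t in seq_along(sc$dif)) {
      d <- sc$dif[[t]]
      if (!d$item %in% iset) next
      g <- partial_gamma_dif(sim$data, d$item, d$covariate, iset)$gamma
      addrow(term_key(d), g,
             unname(sc$target_gamma[term_key(d)] %||% NA_real_))
    }
  }
  # between-subscale gamma, first scale reverse-scored
  sc1 <- config$scales[[1]]; sc2 <- config$scales[[2]]
  i1 <- item_sets[[1]] %||% sc1$items
  i2 <- item_sets[[2]] %||% sc2$items
  y <- sim$data$responses
  m1 <- sim$data$ncat[i1] - 1L
  ra <- rowSums(matrix(m1, nrow(y), length(i1), byrow = TRUE) -
                  y[, i1, drop = FALSE])
  rb <- rowSums(y[, i2, drop = FALSE])
  addrow("subscale_gamma", gamma_coefficient(ra, rb)$gamma,
         config$target_subscale_gamma %||% NA_real_)
  for (cv in names(config$covariates)) {
    pr <- config$covariates[[cv]]
    for (l in names(pr)[-1])
      addrow(paste0("prevalence:", cv, ":", l),
             mean(sim$data$covariates[[cv]] == l), unname(pr[l]))
  }
  do.call(rbind, rows)
}
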