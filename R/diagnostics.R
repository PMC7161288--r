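# Item-analysis diagnostics: conditional likelihood ratio tests, conditional
# infit/outfit, Kelderman LR screening of LD/DIF candidates, (partial)
# Goodman-Kruskal gamma effect sizes, ICC tables, and the two-subscale
# unidimensionality test.

# Recode a data object according to a fitted model's null-category collapse
# map, so downstream computations line up with the model's category coding.
apply_model_recode <- function(data, model) {
  if (is.null(model$collapse)) return(data)
  for (it in names(model$collapse)) {
    map <- model$collapse[[it]]
    if (is.null(map)) next
    y <- data$responses[, it]
    data$responses[, it] <- ifelse(is.na(y), NA_integer_, map[y + 1L])
    data$ncat[it] <- max(map) + 1L
  }
  data
}

# Persons usable under a model: complete on items (and DIF covariates),
# non-extreme total score. Returns indices plus scores and profile indices.
model_persons <- function(data, model) {
  data <- apply_model_recode(data, model)
  y <- data$responses[, model$items, drop = FALSE]
  ok <- rowSums(is.na(y)) == 0L
  covs <- names(model$cov_levels)
  for (cv in covs) ok <- ok & !is.na(data$covariates[[cv]])
  r <- rowSums(y)
  keep <- ok & !is.na(r) & r > 0L & r < model$rmax
  pidx <- rep(1L, nrow(y)); mult <- 1L
  for (cv in covs) {
    li <- match(as.character(data$covariates[[cv]]), model$cov_levels[[cv]])
    pidx <- pidx + (li - 1L) * mult
    mult <- mult * length(model$cov_levels[[cv]])
  }
  list(idx = which(keep), y = y[keep, , drop = FALSE], r = r[keep],
       pidx = pidx[keep])
}

#' Conditional likelihood ratio test of parameter invariance
#'
#' Splits the sample into groups and compares the sum of the group-wise
#' maximized conditional log-likelihoods with the pooled one:
#' `CLR = 2 * (sum_g l_g - l_pooled)`, asymptotically chi-squared with
#' `sum_g df_g - df_pooled` degrees of freedom. Splitting at the median
#' total score ("homogeneity") tests overall fit; splitting by an exogenous
#' variable tests global DIF. Group refits retain the pooled model's LD/DIF
#' structure, except that DIF terms on the splitting covariate (constant
#' within groups) are dropped.
#'
#' @param data the [response_data()] the model was fitted to.
#' @param model a fitted [gllrm_fit()]/[pcm_fit()] model.
#' @param grouping `"score"` for the lower/higher-score homogeneity split
#'   (ties to the low group), or the name of a covariate.
#' @return a data frame (class `gllrm_test`) with `statistic`, `df`,
#'   `p_value`, `grouping`.
#' @export
clr_test <- function(data, model, grouping = "score") {
  data2 <- apply_model_recode(data, model)
  mp <- model_persons(data, model)
  if (grouping == "score") {
    med <- median(mp$r)
    gidx <- ifelse(mp$r <= med, "low", "high")
  } else {
    if (is.null(data$covariates) || !grouping %in% names(data$covariates))
      stop("unknown grouping covariate: ", grouping)
    gidx <- as.character(data2$covariates[[grouping]][mp$idx])
    if (anyNA(gidx)) {
      keep <- !is.na(gidx)
      mp$idx <- mp$idx[keep]; gidx <- gidx[keep]
    }
  }
  groups <- unique(gidx)
  if (length(groups) < 2L)
    stop("grouping produces fewer than two groups")
  dif_g <- model$dif
  if (grouping != "score")
    dif_g <- Filter(function(d) d$covariate != grouping, model$dif)
  ll_g <- 0; df_g <- 0L
  for (g in groups) {
    sub <- subset_response_data(data2, mp$idx[gidx == g])
    rr <- rowSums(sub$responses[, model$items, drop = FALSE])
    if (all(rr == 0L | rr == sum(sub$ncat[model$items] - 1L), na.rm = TRUE))
      stop("group ", g, " contains only extreme scores")
    fit <- gllrm_fit(sub, model$items, ld = model$ld, dif = dif_g,
                     start = model, se = FALSE,
                     fixed_values = model$par_named)
    ll_g <- ll_g + fit$logLik
    df_g <- df_g + fit$df
  }
  stat <- max(0, 2 * (ll_g - model$logLik))
  df <- df_g - model$df
  structure(data.frame(test = "CLR", grouping = grouping, statistic = stat,
                       df = df, p_value = pchisq(stat, df, lower.tail = FALSE),
                       stringsAsFactors = FALSE),
            class = c("gllrm_test", "data.frame"))
}

# gradient of the conditional log-likelihood (free parameterization) at
# theta for arbitrary observed stacked cell counts, from the stored fit
# state; the Hessian does not depend on the observed counts.
fitstate_grad <- function(model, theta, Ovec) {
  fs <- model$fitstate
  Wvec <- fs$W0 + drop(fs$Mmat %*% theta)
  Dvec <- numeric(length(Wvec))
  P <- length(fs$seg)
  for (p in seq_len(P)) {
    if (!fs$use_profile[p]) next
    w_list <- lapply(fs$seg[[p]], function(ix) Wvec[ix])
    res <- .cml_expected_cpp(fs$s_list, w_list, fs$counts[, p])
    for (b in seq_along(fs$seg[[p]]))
      Dvec[fs$seg[[p]][[b]]] <- Ovec[fs$seg[[p]][[b]]] - res$M[[b]]
  }
  drop(crossprod(fs$Mmat, Dvec))
}

# conditional moments E, V (k x (rmax+1)) per profile at a free-parameter
# vector theta (possibly different from the fitted one)
moments_at_theta <- function(model, theta) {
  fs <- model$fitstate
  Wvec <- fs$W0 + drop(fs$Mmat %*% theta)
  k <- length(model$items)
  lapply(seq_along(fs$seg), function(p) {
    w_list <- lapply(fs$seg[[p]], function(ix) Wvec[ix])
    post <- .block_posteriors_cpp(fs$s_list, w_list)
    RR <- length(post$logK)
    E <- matrix(0, k, RR); E2 <- matrix(0, k, RR)
    for (b in seq_along(model$blocks)) {
      bl <- model$blocks[[b]]
      Pb <- post$P[[b]]
      for (jj in seq_along(bl$items)) {
        i <- bl$items[jj]
        yv <- bl$cells[, jj]
        E[i, ] <- colSums(Pb * yv)
        E2[i, ] <- colSums(Pb * yv^2)
      }
    }
    list(E = E, V = pmax(E2 - E^2, 0))
  })
}

#' Conditional infit and outfit item fit statistics
#'
#' Standardizes each response against its conditional moments given the
#' person's total score (and covariate profile): `z = (y - E) / sqrt(V)`.
#' Outfit is the mean of `z^2`; infit is the information-weighted version
#' `sum (y - E)^2 / sum V`. Both have expected value 1 under the model.
#' Their sampling distribution is obtained by a parametric bootstrap:
#' response patterns are redrawn conditional on each person's observed total
#' score (and covariate profile) from the fitted model, the CML estimates
#' are re-solved on each replicate (chord-Newton steps reusing the observed
#' information), and the replicate statistic is computed against its own
#' refitted moments -- without the refit the bootstrap distribution ignores
#' estimation adaptation and the p-values are markedly conservative.
#' Two-sided p-values are bootstrap percentiles.
#'
#' @param data the [response_data()] the model was fitted to.
#' @param model a fitted model.
#' @param B bootstrap replicates (default 400).
#' @param refit_steps chord-Newton refit iterations per replicate (default 4;
#'   0 disables the estimation correction).
#' @return data frame with one row per item: `outfit`, `outfit_se`,
#'   `outfit_p`, `infit`, `infit_se`, `infit_p`, `n`.
#' @export
conditional_item_fit <- function(data, model, B = 400L, refit_steps = 4L) {
  mp <- model_persons(data, model)
  n <- length(mp$r)
  k <- length(model$items)
  P <- nrow(model$profiles)
  Ev <- matrix(0, n, k); Vv <- matrix(0, n, k)
  for (p in seq_len(P)) {
    sel <- mp$pidx == p
    if (!any(sel)) next
    mom <- conditional_moments_profile(model, p)
    Ev[sel, ] <- t(mom$E)[mp$r[sel] + 1L, , drop = FALSE]
    Vv[sel, ] <- t(mom$V)[mp$r[sel] + 1L, , drop = FALSE]
  }
  usable <- Vv > 1e-12  # degenerate cells carry no residual information
  n_skipped <- sum(!usable)
  obs_out <- obs_in <- numeric(k)
  for (i in seq_len(k)) {
    u <- usable[, i]
    z2 <- (mp$y[, i] - Ev[, i])^2
    obs_out[i] <- mean((z2 / Vv[, i])[u])
    obs_in[i] <- sum(z2[u]) / sum(Vv[u, i])
  }

  refit <- refit_steps > 0L && !is.null(model$fitstate) &&
    length(model$fitstate$theta) > 0L
  Hinv <- NULL
  if (refit) {
    fs <- model$fitstate
    p_free <- length(fs$theta)
    # observed information (independent of the observed counts); chord steps
    # reuse its inverse for every replicate
    eps <- 1e-5
    H <- matrix(0, p_free, p_free)
    Ovec0 <- numeric(length(fs$W0))
    for (j in seq_len(p_free)) {
      ej <- fs$theta; ej[j] <- ej[j] + eps
      ej2 <- fs$theta; ej2[j] <- ej2[j] - eps
      H[, j] <- (fitstate_grad(model, ej, Ovec0) -
                 fitstate_grad(model, ej2, Ovec0)) / (2 * eps)
    }
    Hinv <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hinv)) refit <- FALSE
  }

  # parametric bootstrap conditional on (r, profile)
  draws_p <- vector("list", P)
  for (p in seq_len(P)) {
    sel <- which(mp$pidx == p)
    if (!length(sel)) next
    draws_p[[p]] <- sample_conditional_patterns(model, rep(mp$r[sel], B), p)
  }
  boot_out <- matrix(NA_real_, B, k); boot_in <- matrix(NA_real_, B, k)
  fs <- model$fitstate
  cell_index <- function(ymat) {
    # stacked-cell observed counts for one replicate, per profile
    Ov <- numeric(length(fs$W0))
    for (p in seq_len(P)) {
      sel <- which(mp$pidx == p)
      if (!length(sel)) next
      yb <- ymat[[p]]
      for (b in seq_along(model$blocks)) {
        bl <- model$blocks[[b]]
        ci <- yb[, bl$items[1]] + 1L
        if (length(bl$items) == 2L)
          ci <- ci + model$ncat[bl$items[1]] * yb[, bl$items[2]]
        Ov[fs$seg[[p]][[b]]] <-
          tabulate(ci, nbins = length(fs$seg[[p]][[b]]))
      }
    }
    Ov
  }
  for (bb in seq_len(B)) {
    ymat <- vector("list", P)
    for (p in seq_len(P)) {
      sel <- which(mp$pidx == p)
      if (!length(sel)) next
      rows <- ((bb - 1L) * length(sel) + 1L):(bb * length(sel))
      ymat[[p]] <- draws_p[[p]][rows, , drop = FALSE]
    }
    if (refit) {
      Ov <- cell_index(ymat)
      th <- fs$theta
      for (it in seq_len(refit_steps)) {
        g <- fitstate_grad(model, th, Ov)
        if (!all(is.finite(g))) { th <- fs$theta; break }
        th <- th - drop(Hinv %*% g)
      }
      # chord steps with a fixed Hessian can diverge on extreme replicates;
      # fall back to the fitted parameters rather than poison the statistic
      if (!all(is.finite(th)) || max(abs(th - fs$theta)) > 5) th <- fs$theta
      moms <- moments_at_theta(model, th)
    } else {
      moms <- NULL
    }
    so <- si_num <- si_den <- nn <- numeric(k)
    for (p in seq_len(P)) {
      sel <- which(mp$pidx == p)
      if (!length(sel)) next
      if (is.null(moms)) {
        Eb <- Ev[sel, , drop = FALSE]; Vb <- Vv[sel, , drop = FALSE]
      } else {
        Eb <- t(moms[[p]]$E)[mp$r[sel] + 1L, , drop = FALSE]
        Vb <- t(moms[[p]]$V)[mp$r[sel] + 1L, , drop = FALSE]
      }
      u <- usable[sel, , drop = FALSE] & Vb > 1e-12
      z2 <- (ymat[[p]] - Eb)^2
      so <- so + colSums((z2 / Vb) * u)
      si_num <- si_num + colSums(z2 * u)
      si_den <- si_den + colSums(Vb * u)
      nn <- nn + colSums(u)
    }
    boot_out[bb, ] <- so / nn
    boot_in[bb, ] <- si_num / si_den
  }

  res <- data.frame(item = model$items, outfit = obs_out,
                    outfit_se = NA_real_, outfit_p = NA_real_,
                    infit = obs_in, infit_se = NA_real_, infit_p = NA_real_,
                    n = colSums(usable), stringsAsFactors = FALSE)
  # two-sided percentile p (the null distribution is right-skewed)
  pctl_p <- function(obs, boot) {
    boot <- boot[is.finite(boot)]
    if (length(boot) < 20L || !is.finite(obs)) return(NA_real_)
    lo <- (1 + sum(boot <= obs)) / (length(boot) + 1)
    hi <- (1 + sum(boot >= obs)) / (length(boot) + 1)
    min(1, 2 * min(lo, hi))
  }
  for (i in seq_len(k)) {
    res$outfit_se[i] <- sd(boot_out[, i])
    res$infit_se[i] <- sd(boot_in[, i])
    res$outfit_p[i] <- pctl_p(obs_out[i], boot_out[, i])
    res$infit_p[i] <- pctl_p(obs_in[i], boot_in[, i])
  }
  attr(res, "n_cells_skipped") <- n_skipped
  attr(res, "B") <- B
  res
}

#' Kelderman likelihood ratio test for one LD or DIF candidate term
#'
#' Tests whether augmenting the fitted model with a single uniform LD pair
#' or uniform DIF term better explains the responses:
#' `LR = 2 * (l_augmented - l_base)`, chi-squared with the number of added
#' free interaction parameters as degrees of freedom (`m_i * m_j` for an LD
#' pair of items with all cells observed, `m_i * (G - 1)` for DIF).
#'
#' @param data the [response_data()] the model was fitted to.
#' @param model the fitted base model.
#' @param candidate `list(items = c("a", "b"))` for LD, or
#'   `list(item =, covariate =)` for DIF.
#' @return a `gllrm_test` data frame row; an augmented fit failure is
#'   reported as `p_value = NA` with a note, not as evidence.
#' @export
kelderman_lr <- function(data, model, candidate) {
  if (!is.null(candidate$items)) {
    pair <- sort(as.character(candidate$items))
    keys <- vapply(model$ld, paste, "", collapse = ":")
    if (paste(pair, collapse = ":") %in% keys)
      stop("candidate LD pair already in the model")
    for (p0 in model$ld)
      if (any(pair %in% p0))
        stop("candidate LD pair overlaps an existing pair (pairs must be disjoint)")
    ld2 <- c(model$ld, list(pair)); dif2 <- model$dif
    label <- term_key(list(items = pair))
  } else {
    keys <- vapply(model$dif, function(d) paste(d$item, d$covariate), "")
    if (paste(candidate$item, candidate$covariate) %in% keys)
      stop("candidate DIF term already in the model")
    ld2 <- model$ld
    dif2 <- c(model$dif, list(list(item = as.character(candidate$item),
                                   covariate = as.character(candidate$covariate))))
    label <- term_key(candidate)
  }
  data2 <- apply_model_recode(data, model)
  aug <- tryCatch(
    gllrm_fit(data2, model$items, ld = ld2, dif = dif2, start = model,
              se = FALSE),
    error = function(e) e)
  if (inherits(aug, "error")) {
    return(structure(data.frame(test = "KeldermanLR", grouping = label,
                                statistic = NA_real_, df = NA_integer_,
                                p_value = NA_real_,
                                stringsAsFactors = FALSE),
                     class = c("gllrm_test", "data.frame")))
  }
  # when the candidate introduces a covariate with missing values, the base
  # model must be re-evaluated on the augmented model's complete-case set
  base_ll <- model$logLik
  if (aug$n_used != model$n_used) {
    keep <- !is.na(data2$covariates[[candidate$covariate]])
    base2 <- gllrm_fit(subset_response_data(data2, keep), model$items,
                       ld = model$ld, dif = model$dif, start = model,
                       se = FALSE)
    base_ll <- base2$logLik
  }
  stat <- max(0, 2 * (aug$logLik - base_ll))
  df <- aug$df - model$df
  structure(data.frame(test = "KeldermanLR", grouping = label,
                       statistic = stat, df = df,
                       p_value = pchisq(stat, df, lower.tail = FALSE),
                       stringsAsFactors = FALSE),
            class = c("gllrm_test", "data.frame"))
}

# ---- Goodman-Kruskal gamma -------------------------------------------------

# concordance/discordance machinery on a contingency table
concordance_counts <- function(tab) {
  tab <- as.matrix(tab)
  R <- nrow(tab); C <- ncol(tab)
  L <- matrix(as.numeric(lower.tri(diag(R), diag = TRUE)), R, R)
  U <- matrix(as.numeric(upper.tri(diag(C), diag = TRUE)), C, C)
  cs <- L %*% tab %*% U  # cs[i,j] = sum over k<=i, l<=j
  tot <- cs[R, C]
  csv <- function(i, j) if (i < 1 || j < 1) 0 else cs[i, j]
  Cij <- matrix(0, R, C); Dij <- matrix(0, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    Cij[i, j] <- csv(i - 1, j - 1) +
      (tot - cs[R, j] - cs[i, C] + cs[i, j])          # k<i,l<j and k>i,l>j
    Dij[i, j] <- (csv(i - 1, C) - csv(i - 1, j)) +    # k<i, l>j
      (csv(R, j - 1) - csv(i, j - 1))                 # k>i, l<j
  }
  list(C = sum(tab * Cij) / 2, D = sum(tab * Dij) / 2,
       Cij = Cij, Dij = Dij, tab = tab)
}

gamma_from_strata <- function(tabs) {
  Ctot <- 0; Dtot <- 0
  parts <- list()
  for (tb in tabs) {
    if (length(tb) == 0 || sum(tb) < 2) next
    cc <- concordance_counts(tb)
    if (cc$C + cc$D == 0) next
    Ctot <- Ctot + cc$C; Dtot <- Dtot + cc$D
    parts[[length(parts) + 1L]] <- cc
  }
  if (Ctot + Dtot == 0)
    return(list(gamma = NA_real_, se = NA_real_, C = 0, D = 0))
  gamma <- (Ctot - Dtot) / (Ctot + Dtot)
  # Goodman-Kruskal asymptotic variance, accumulated across strata
  acc <- 0
  for (cc in parts)
    acc <- acc + sum(cc$tab * (Dtot * cc$Cij - Ctot * cc$Dij)^2)
  v <- 16 * acc / (Ctot + Dtot)^4
  list(gamma = gamma, se = sqrt(v), C = Ctot, D = Dtot)
}

#' Goodman-Kruskal gamma rank correlation
#'
#' `gamma = (C - D) / (C + D)` over concordant and discordant pairs, with
#' the standard asymptotic standard error.
#'
#' @param x,y paired ordinal vectors (or factors).
#' @return data frame with `gamma`, `se`, `C`, `D`, `n`.
#' @export
gamma_coefficient <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop("no complete pairs")
  res <- gamma_from_strata(list(table(x, y)))
  if (is.na(res$gamma)) warning("gamma undefined: no concordant or discordant pairs")
  data.frame(gamma = res$gamma, se = res$se, C = res$C, D = res$D,
             n = length(x))
}

#' Partial gamma between two items given the restscores
#'
#' The local-dependence effect size: the Goodman-Kruskal gamma between the
#' two items' responses within strata of the restscore (the total score over
#' `item_set` minus the focal item), aggregated over strata by pooling
#' concordant and discordant pair counts. Both stratification directions are
#' computed (rest of i, rest of j) and their mean is reported as `gamma_avg`.
#'
#' @param data a [response_data()].
#' @param item_i,item_j the item pair.
#' @param item_set items defining the total score (must contain both).
#' @return data frame with `gamma_avg`, the two directional gammas and SEs.
#' @export
partial_gamma_ld <- function(data, item_i, item_j,
                             item_set = colnames(data$responses)) {
  if (item_i == item_j) stop("item paired with itself")
  if (!all(c(item_i, item_j) %in% item_set))
    stop("both items must be in item_set")
  y <- data$responses[, item_set, drop = FALSE]
  ok <- rowSums(is.na(y)) == 0L
  y <- y[ok, , drop = FALSE]
  r <- rowSums(y)
  one_direction <- function(strat_item) {
    rest <- r - y[, strat_item]
    tabs <- lapply(split(seq_len(nrow(y)), rest), function(ix)
      table(y[ix, item_i], y[ix, item_j]))
    gamma_from_strata(tabs)
  }
  d1 <- one_direction(item_i)
  d2 <- one_direction(item_j)
  if (is.na(d1$gamma) || is.na(d2$gamma))
    warning("partial gamma undefined in at least one direction")
  data.frame(item_i = item_i, item_j = item_j,
             gamma_avg = mean(c(d1$gamma, d2$gamma)),
             gamma_rest_i = d1$gamma, se_rest_i = d1$se,
             gamma_rest_j = d2$gamma, se_rest_j = d2$se,
             se_avg = sqrt(d1$se^2 + d2$se^2) / 2,
             stringsAsFactors = FALSE)
}

#' Partial gamma between an item and an exogenous variable given the total score
#'
#' The uniform-DIF effect size: gamma between the item response and the
#' covariate level within strata of the total score over `item_set`,
#' aggregated by pooling pair counts across strata.
#'
#' @param data a [response_data()].
#' @param item focal item.
#' @param covariate covariate name (binary or ordered levels).
#' @param item_set items defining the total score.
#' @return data frame with `gamma`, `se`.
#' @export
partial_gamma_dif <- function(data, item, covariate,
                              item_set = colnames(data$responses)) {
  if (!item %in% item_set) stop("item must be in item_set")
  cv <- data$covariates[[covariate]]
  if (is.null(cv)) stop("unknown covariate: ", covariate)
  y <- data$responses[, item_set, drop = FALSE]
  ok <- rowSums(is.na(y)) == 0L & !is.na(cv)
  y <- y[ok, , drop = FALSE]; cv <- cv[ok]
  if (length(unique(cv)) < 2L) stop("covariate has a single observed level")
  r <- rowSums(y)
  tabs <- lapply(split(seq_len(nrow(y)), r), function(ix)
    table(y[ix, item], as.integer(cv[ix])))
  res <- gamma_from_strata(tabs)
  if (is.na(res$gamma)) warning("partial gamma undefined (degenerate strata)")
  data.frame(item = item, covariate = covariate, gamma = res$gamma,
             se = res$se, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement (wraps
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Item characteristic curve table
#'
#' Per observed total score: group size, observed mean item response,
#' model-expected mean (mixed over the observed covariate-profile
#' composition of the score group for models with DIF), and a 95% band for
#' the observed mean under the model.
#'
#' @param data the [response_data()] the model was fitted to.
#' @param model a fitted model.
#' @param item item name.
#' @return data frame with columns `score`, `n`, `observed`, `expected`,
#'   `lower`, `upper`. Score groups with no persons are omitted.
#' @export
icc_table <- function(data, model, item) {
  i <- match(item, model$items)
  if (is.na(i)) stop("unknown item: ", item)
  mp <- model_persons(data, model)
  P <- nrow(model$profiles)
  moms <- lapply(seq_len(P), conditional_moments_profile, model = model)
  scores <- sort(unique(mp$r))
  out <- lapply(scores, function(rr) {
    sel <- mp$r == rr
    nn <- sum(sel)
    wts <- tabulate(mp$pidx[sel], nbins = P) / nn
    e_p <- vapply(moms, function(mm) mm$E[i, rr + 1L], 0)
    v_p <- vapply(moms, function(mm) mm$V[i, rr + 1L], 0)
    e <- sum(wts * e_p)
    v <- sum(wts * (v_p + e_p^2)) - e^2  # mixture variance
    half <- 1.96 * sqrt(v / nn)
    data.frame(score = rr, n = nn, observed = mean(mp$y[sel, i]),
               expected = e, lower = e - half, upper = e + half)
  })
  do.call(rbind, out)
}

#' Test of unidimensionality across two fitted subscales
#'
#' Compares the observed gamma correlation between two subscale total scores
#' with the gamma expected if both subscales measured one common trait. The
#' expected value is obtained by Monte Carlo: a single standard normal draw
#' is mapped into each subscale's latent metric through its estimated person
#' distribution, responses are simulated from both fitted models (covariate
#' profiles drawn with the observed frequencies), and gamma is computed on
#' the simulated score pairs. Under multidimensionality the observed
#' correlation is weaker than expected, so the test is one-sided
#' (`gamma_obs < gamma_exp` rejects unidimensionality).
#'
#' @param data the [response_data()] both models were fitted to; subscale
#'   items must be reverse-scored beforehand where needed so both scores
#'   point in the same direction.
#' @param model_a,model_b fitted subscale models on disjoint item sets.
#' @param n_sim Monte Carlo persons for the expected gamma (default 200000).
#' @param n_boot bootstrap resamples for the SE of the difference.
#' @return data frame with `gamma_obs`, `gamma_exp`, `se_diff`, `p_value`.
#' @export
unidimensionality_test <- function(data, model_a, model_b, n_sim = 2e5,
                                   n_boot = 200L) {
  if (length(intersect(model_a$items, model_b$items)))
    stop("subscale item sets must be disjoint")
  ya <- data$responses[, model_a$items, drop = FALSE]
  yb <- data$responses[, model_b$items, drop = FALSE]
  ok <- rowSums(is.na(ya)) == 0L & rowSums(is.na(yb)) == 0L
  for (cv in union(names(model_a$cov_levels), names(model_b$cov_levels)))
    ok <- ok & !is.na(data$covariates[[cv]])
  sa <- rowSums(ya[ok, , drop = FALSE])
  sb <- rowSums(yb[ok, , drop = FALSE])
  g_obs <- gamma_coefficient(sa, sb)
  # person distributions per subscale on their own latent metrics
  pd_a <- fit_person_dist(data, model_a)
  pd_b <- fit_person_dist(data, model_b)
  covdat <- if (!is.null(data$covariates)) data$covariates[ok, , drop = FALSE] else NULL
  z <- rnorm(n_sim)
  # one covariate draw per simulated person, shared by both subscales
  ix <- if (!is.null(covdat)) sample.int(nrow(covdat), n_sim, replace = TRUE)
        else rep(1L, n_sim)
  sim_scale <- function(model, pd) {
    prof <- if (is.null(covdat) || nrow(model$profiles) == 1L) rep(1L, n_sim)
            else profile_index_of(model, covdat[ix, , drop = FALSE])
    theta <- pd$mean[prof] + pd$sd[prof] * z
    ysim <- simulate_given_theta(model, theta, prof)
    rowSums(ysim)
  }
  ra <- sim_scale(model_a, pd_a)
  rb <- sim_scale(model_b, pd_b)
  g_exp <- gamma_coefficient(ra, rb)
  # bootstrap the observed gamma; MC error of the expected one in quadrature
  nb <- length(sa)
  gb <- vapply(seq_len(n_boot), function(b) {
    ix <- sample.int(nb, nb, replace = TRUE)
    gamma_from_strata(list(table(sa[ix], sb[ix])))$gamma
  }, 0)
  se_diff <- sqrt(var(gb) + g_exp$se^2)
  zstat <- (g_obs$gamma - g_exp$gamma) / se_diff
  data.frame(gamma_obs = g_obs$gamma, gamma_exp = g_exp$gamma,
             se_obs = g_obs$se, se_exp = g_exp$se, se_diff = se_diff,
             z = zstat, p_value = pnorm(zstat))
}

# profile index of each covariate row under a model (1 when the model has
# no DIF covariates)
profile_index_of <- function(model, covdat) {
  if (nrow(model$profiles) == 1L)
    return(rep(1L, if (is.null(covdat)) 1L else nrow(covdat)))
  pidx <- rep(1L, nrow(covdat)); mult <- 1L
  for (cv in names(model$cov_levels)) {
    li <- match(as.character(covdat[[cv]]), model$cov_levels[[cv]])
    pidx <- pidx + (li - 1L) * mult
    mult <- mult * length(model$cov_levels[[cv]])
  }
  pidx
}
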