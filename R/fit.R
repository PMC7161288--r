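# Conditional maximum likelihood fitting of the Partial Credit model and of
# Graphical Log-linear Rasch Models (PCM + uniform local dependence +
# uniform DIF interaction terms).
#
# Internal representation: the item set is partitioned into independent
# "blocks" -- single items, or a locally dependent item pair treated as one
# composite super-item. Each block has a cell table (all category
# combinations), an integer score per cell, and per-covariate-profile
# log-weights. All conditional quantities (normalizers, posteriors, moments,
# samples) are elementary-symmetric-function computations over blocks,
# delegated to compiled code.

# ---- specification helpers -------------------------------------------------

normalize_ld <- function(ld) {
  if (is.null(ld) || length(ld) == 0L) return(list())
  if (!is.list(ld)) ld <- list(ld)
  out <- lapply(ld, function(p) {
    p <- as.character(p)
    if (length(p) != 2L || p[1] == p[2])
      stop("an LD pair must name two distinct items")
    sort(p)
  })
  keys <- vapply(out, paste, "", collapse = ":")
  if (anyDuplicated(keys)) stop("duplicated LD pair")
  items_in_pairs <- unlist(out)
  if (anyDuplicated(items_in_pairs))
    stop("LD pairs must be disjoint (an item may appear in at most one pair)")
  out
}

normalize_dif <- function(dif) {
  if (is.null(dif) || length(dif) == 0L) return(list())
  if (!is.list(dif)) dif <- list(dif)
  out <- lapply(dif, function(d) {
    d <- as.list(d)
    if (is.null(names(d)) || !all(c("item", "covariate") %in% names(d)))
      d <- list(item = d[[1]], covariate = d[[2]])
    list(item = as.character(d$item), covariate = as.character(d$covariate))
  })
  keys <- vapply(out, function(d) paste(d$item, d$covariate), "")
  if (anyDuplicated(keys)) stop("duplicated DIF term")
  out
}

term_key <- function(term) {
  if (!is.null(term$items)) paste0("LD(", paste(sort(term$items), collapse = ","), ")")
  else paste0("DIF(", term$item, ",", term$covariate, ")")
}

# ---- data preparation ------------------------------------------------------

# Complete-case extraction, null-category handling, profile assignment.
# collapse_null = TRUE merges never-observed categories with the adjacent
# lower category (relabelling scores); FALSE keeps the score metric and
# fixes the unobserved categories' weights at -Inf instead (used for
# subgroup refits, where relabelling would break comparability of the
# conditional log-likelihoods).
prepare_cml_data <- function(data, items, dif, collapse_null = TRUE,
                             fixed_mode = FALSE) {
  stopifnot(inherits(data, "response_data"))
  missing_items <- setdiff(items, colnames(data$responses))
  if (length(missing_items))
    stop("items not in data: ", paste(missing_items, collapse = ", "))
  covs <- unique(vapply(dif, `[[`, "", "covariate"))
  if (length(covs)) {
    if (is.null(data$covariates) || !all(covs %in% names(data$covariates)))
      stop("DIF covariate(s) not in data: ",
           paste(setdiff(covs, names(data$covariates)), collapse = ", "))
  }
  y <- data$responses[, items, drop = FALSE]
  ok <- rowSums(is.na(y)) == 0L
  if (length(covs))
    for (cv in covs) ok <- ok & !is.na(data$covariates[[cv]])
  y <- y[ok, , drop = FALSE]
  ncat <- data$ncat[items]

  # Null (never observed) categories: collapse with the adjacent lower
  # category (recode map recorded and reported), or keep the score metric
  # and structurally drop them.
  collapse <- vector("list", length(items))
  names(collapse) <- items
  obs_cats <- vector("list", length(items))
  for (i in seq_along(items)) {
    m <- ncat[i] - 1L
    seen <- sort(unique(y[, i]))
    if (length(seen) < 2L)
      stop(sprintf("item %s shows a single observed category; cannot estimate",
                   items[i]))
    if (length(seen) < ncat[i] && collapse_null) {
      map <- integer(ncat[i])  # old category -> new category
      newc <- -1L
      for (yy in 0:m) {
        if (yy %in% seen) newc <- newc + 1L
        map[yy + 1L] <- max(newc, 0L)
      }
      y[, i] <- map[y[, i] + 1L]
      collapse[[i]] <- map
      ncat[i] <- length(seen)
      warning(sprintf(
        "item %s: %d unobserved categor%s collapsed with the adjacent lower category",
        items[i], m + 1L - length(seen), if (m + 1L - length(seen) > 1L) "ies" else "y"))
    }
    obs_cats[[i]] <- 0:(ncat[i] - 1L) %in% sort(unique(y[, i]))
  }
  names(obs_cats) <- items

  if (length(covs)) {
    lev <- lapply(covs, function(cv) levels(data$covariates[[cv]]))
    names(lev) <- covs
    profiles <- expand.grid(lev, stringsAsFactors = FALSE)
    pidx <- rep(1L, nrow(y))
    mult <- 1L
    covdat <- data$covariates[ok, , drop = FALSE]
    for (cv in covs) {
      li <- match(as.character(covdat[[cv]]), lev[[cv]])
      pidx <- pidx + (li - 1L) * mult
      mult <- mult * length(lev[[cv]])
    }
  } else {
    lev <- list()
    profiles <- data.frame(row.names = 1)
    pidx <- rep(1L, nrow(y))
  }

  r <- rowSums(y)
  rmax <- sum(ncat - 1L)
  if (fixed_mode) {
    # pinned parameters keep every pattern's probability positive, so only
    # the global extremes are uninformative; trimming at the observed
    # support would desynchronize the person set from a pooled fit
    rmin <- 0L; rtop <- rmax
  } else {
    rmin <- sum(vapply(obs_cats, function(o) min(which(o)) - 1L, 0L))
    rtop <- sum(vapply(obs_cats, function(o) max(which(o)) - 1L, 0L))
  }
  keep <- r > rmin & r < rtop
  list(y = y[keep, , drop = FALSE], r = r[keep], pidx = pidx[keep],
       items = items, ncat = ncat, collapse = collapse, obs_cats = obs_cats,
       cov_levels = lev, profiles = profiles,
       n_complete = nrow(y), n_used = sum(keep),
       n_extreme = sum(!keep), rmax = rmax)
}

# ---- block structure -------------------------------------------------------

build_blocks <- function(items, ncat, ld) {
  k <- length(items)
  in_pair <- rep(FALSE, k)
  blocks <- list()
  for (pair in ld) {
    idx <- match(pair, items)
    if (anyNA(idx)) stop("LD pair references an item outside the item set")
    in_pair[idx] <- TRUE
    cells <- as.matrix(expand.grid(0:(ncat[idx[1]] - 1L), 0:(ncat[idx[2]] - 1L)))
    dimnames(cells) <- NULL
    blocks[[length(blocks) + 1L]] <-
      list(items = idx, cells = cells, s = as.integer(rowSums(cells)))
  }
  for (i in seq_len(k)) {
    if (in_pair[i]) next
    cells <- matrix(0:(ncat[i] - 1L), ncol = 1L)
    blocks[[length(blocks) + 1L]] <-
      list(items = i, cells = cells, s = as.integer(cells[, 1L]))
  }
  # stable order: by first item index
  blocks[order(vapply(blocks, function(b) min(b$items), 0L))]
}

# log-weight vectors per block for one covariate profile (row of profiles df)
assemble_weights <- function(blocks, alpha, lambda, delta, dif, items,
                             profile_levels) {
  lapply(seq_along(blocks), function(b) {
    bl <- blocks[[b]]
    w <- rep(0, nrow(bl$cells))
    for (jj in seq_along(bl$items)) {
      i <- bl$items[jj]
      w <- w + alpha[[i]][bl$cells[, jj] + 1L]
    }
    if (length(bl$items) == 2L) {
      key <- paste(sort(items[bl$items]), collapse = ":")
      lam <- lambda[[key]]
      ij <- order(items[bl$items])  # lambda stored on sorted item order
      a <- bl$cells[, ij[1]]; bcat <- bl$cells[, ij[2]]
      w <- w + lam[cbind(a + 1L, bcat + 1L)]
    }
    if (length(dif)) {
      for (t in seq_along(dif)) {
        i <- match(dif[[t]]$item, items)
        if (i %in% bl$items) {
          jj <- which(bl$items == i)
          lv <- profile_levels[[dif[[t]]$covariate]]
          w <- w + delta[[t]][cbind(bl$cells[, jj] + 1L, lv)]
        }
      }
    }
    w
  })
}

# ---- parameter bookkeeping -------------------------------------------------

# The gauge freedom of the conditional likelihood (adding d*y to every
# item's alpha shifts all pattern weights by d*R) is removed by the sum-zero
# item-location constraint sum_i alpha_i[t_i] / t_i = 0 over the items' top
# observed categories t_i, implemented by treating the last item's
# top-observed-category parameter as dependent. With every category observed
# (the usual case) this is the sum-zero constraint on item locations.
# Categories never observed are handled per the preparation mode: after
# collapsing they no longer exist; in structural mode their alpha is fixed
# at -Inf ("dropped"), and if category 0 itself is unobserved the lowest
# observed category becomes the item's zero-fixed corner.
# When `fixed_values` is supplied (subgroup refits), parameters whose
# sufficient statistics are empty in the subset -- never-observed categories,
# empty interaction cells -- are pinned at the supplied (pooled) estimates
# instead of being estimated; pinning any alpha also fixes the gauge, so the
# sum-zero location constraint is dropped in that case.
make_parmap <- function(prep, ld, dif, obs_counts, fixed_values = NULL,
                        min_count = 5L) {
  items <- prep$items; ncat <- prep$ncat; k <- length(items)
  tcat <- vapply(prep$obs_cats, function(o) max(which(o)) - 1L, 0L)
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e
  pin <- function(name) {
    v <- if (!is.null(fixed_values)) unname(fixed_values[name]) else NA_real_
    if (is.na(v)) 0 else v
  }
  # Parameters supported by fewer than min_count observations are not
  # estimated: interaction cells below the threshold are fixed at zero (or,
  # in pinned subgroup-refit mode, at the supplied pooled values), and in
  # pinned mode sparse item-category parameters are pinned as well.
  # Estimating a log-linear parameter from a handful of observations makes
  # likelihood-ratio statistics heavy-tailed relative to their chi-square
  # reference.
  thr <- as.integer(min_count)
  athr <- if (is.null(fixed_values)) 1L else thr
  alpha_sparse <- lapply(seq_len(k), function(i)
    obs_counts$alpha_counts[[i]] < athr)
  any_alpha_pinned <- !is.null(fixed_values) &&
    any(vapply(seq_len(k), function(i) any(alpha_sparse[[i]][-1L]), TRUE))
  dep <- if (any_alpha_pinned) c(0L, 0L) else c(k, tcat[k])
  for (i in seq_len(k)) for (yy in seq_len(ncat[i] - 1L)) {
    if (i == dep[1] && yy == dep[2]) next
    nm <- sprintf("alpha:%s:%d", items[i], yy)
    if (alpha_sparse[[i]][yy + 1L]) {
      if (is.null(fixed_values))
        add(list(kind = "alpha", item = i, cat = yy, fixed = TRUE, drop = TRUE,
                 name = nm))
      else
        add(list(kind = "alpha", item = i, cat = yy, fixed = TRUE,
                 value = pin(nm), name = nm))
    } else
    add(list(kind = "alpha", item = i, cat = yy, name = nm))
  }
  for (pair in ld) {
    idx <- match(pair, items)
    key <- paste(pair, collapse = ":")
    for (a in seq_len(ncat[idx[1]] - 1L)) for (b in seq_len(ncat[idx[2]] - 1L)) {
      fixed <- obs_counts$lambda_counts[[key]][a, b] < thr
      nm <- sprintf("lambda:%s:%d:%d", key, a, b)
      add(list(kind = "lambda", pair = pair, a = a, b = b, fixed = fixed,
               value = if (fixed) pin(nm) else NA_real_, name = nm))
    }
  }
  for (t in seq_along(dif)) {
    i <- match(dif[[t]]$item, items)
    cv <- dif[[t]]$covariate
    levs <- prep$cov_levels[[cv]]
    for (yy in seq_len(ncat[i] - 1L)) for (l in 2:length(levs)) {
      fixed <- obs_counts$delta_counts[[t]][yy, l] < thr
      nm <- sprintf("delta:%s:%s:%d:%s", items[i], cv, yy, levs[l])
      add(list(kind = "delta", term = t, item = i, cat = yy, level = l,
               fixed = fixed, value = if (fixed) pin(nm) else NA_real_,
               name = nm))
    }
  }
  fixed <- vapply(entries, function(e) isTRUE(e$fixed), TRUE)
  list(entries = entries, free = which(!fixed), fixed = which(fixed),
       names = vapply(entries, `[[`, "", "name"), dep = dep, tcat = tcat)
}

unpack_params <- function(theta, parmap, prep, ld, dif) {
  items <- prep$items; ncat <- prep$ncat; k <- length(items)
  alpha <- lapply(ncat, function(m) rep(0, m))
  lambda <- list()
  for (pair in ld) {
    idx <- match(pair, items)
    lambda[[paste(pair, collapse = ":")]] <-
      matrix(0, ncat[idx[1]], ncat[idx[2]])
  }
  delta <- lapply(seq_along(dif), function(t) {
    i <- match(dif[[t]]$item, items)
    matrix(0, ncat[i], length(prep$cov_levels[[dif[[t]]$covariate]]))
  })
  full <- numeric(length(parmap$entries))
  full[parmap$free] <- theta
  dropped <- rep(FALSE, length(parmap$entries))
  for (e_i in parmap$fixed) {
    e <- parmap$entries[[e_i]]
    if (isTRUE(e$drop)) dropped[e_i] <- TRUE
    else if (!is.null(e$value) && !is.na(e$value)) full[e_i] <- e$value
  }
  for (e_i in seq_along(parmap$entries)) {
    e <- parmap$entries[[e_i]]
    v <- if (dropped[e_i]) -Inf else full[e_i]
    if (e$kind == "alpha") alpha[[e$item]][e$cat + 1L] <- v
    else if (e$kind == "lambda")
      lambda[[paste(e$pair, collapse = ":")]][e$a + 1L, e$b + 1L] <- v
    else delta[[e$term]][e$cat + 1L, e$level] <- v
  }
  # dependent alpha from the sum-zero location constraint (skipped when a
  # pinned alpha already fixes the gauge)
  dep <- parmap$dep
  if (dep[1] > 0L) {
    tc <- parmap$tcat
    ssum <- 0
    for (i in seq_len(k)) if (i != dep[1]) ssum <- ssum + alpha[[i]][tc[i] + 1L] / tc[i]
    alpha[[dep[1]]][dep[2] + 1L] <- -tc[dep[1]] * ssum
  }
  list(alpha = alpha, lambda = lambda, delta = delta)
}

# observed sufficient statistics: cell counts per block x profile, plus
# zero-cell flags for interaction grids
observed_counts <- function(prep, blocks, ld, dif) {
  P <- nrow(prep$profiles)
  O <- lapply(blocks, function(bl) matrix(0, nrow(bl$cells), P))
  cellidx <- lapply(blocks, function(bl) {
    if (length(bl$items) == 1L) prep$y[, bl$items] + 1L
    else {
      n1 <- prep$ncat[bl$items[1]]
      prep$y[, bl$items[1]] + 1L + n1 * prep$y[, bl$items[2]]
    }
  })
  for (b in seq_along(blocks)) {
    tb <- table(factor(cellidx[[b]], levels = seq_len(nrow(blocks[[b]]$cells))),
                factor(prep$pidx, levels = seq_len(P)))
    O[[b]] <- matrix(as.numeric(tb), nrow = nrow(blocks[[b]]$cells))
  }
  lambda_counts <- list()
  for (pair in ld) {
    idx <- match(pair, prep$items)
    b <- which(vapply(blocks, function(bl)
      identical(sort(bl$items), sort(idx)), TRUE))
    bl <- blocks[[b]]
    # block cells are expand.grid over (bl$items[1], bl$items[2]), which is
    # the sorted-name order the lambda grid is stored in
    n1 <- prep$ncat[bl$items[1]]; n2 <- prep$ncat[bl$items[2]]
    grid <- matrix(rowSums(O[[b]]), n1, n2)
    lambda_counts[[paste(pair, collapse = ":")]] <- grid[-1, -1, drop = FALSE]
  }
  delta_counts <- lapply(seq_along(dif), function(t) {
    i <- match(dif[[t]]$item, prep$items)
    cv <- dif[[t]]$covariate
    levs <- prep$cov_levels[[cv]]
    li <- match(cv, names(prep$cov_levels))
    mult <- c(1L, cumprod(vapply(prep$cov_levels, length, 0L)))[li]
    lev_of_profile <- ((seq_len(nrow(prep$profiles)) - 1L) %/% mult) %%
      length(levs) + 1L
    zm <- matrix(0, prep$ncat[i] - 1L, length(levs))
    for (yy in seq_len(prep$ncat[i] - 1L)) for (l in seq_along(levs))
      zm[yy, l] <- sum(prep$y[, i] == yy & lev_of_profile[prep$pidx] == l)
    zm
  })
  alpha_counts <- lapply(seq_along(prep$items), function(i)
    tabulate(prep$y[, i] + 1L, nbins = prep$ncat[i]))
  list(O = O, lambda_counts = lambda_counts, delta_counts = delta_counts,
       alpha_counts = alpha_counts)
}

# profile -> named list of level indices for each covariate
profile_levels_list <- function(prep) {
  P <- nrow(prep$profiles)
  lapply(seq_len(P), function(p) {
    out <- list()
    for (cv in names(prep$cov_levels))
      out[[cv]] <- match(prep$profiles[[cv]][p], prep$cov_levels[[cv]])
    out
  })
}

# ---- fitting ---------------------------------------------------------------

#' Fit a Graphical Log-linear Rasch Model by conditional maximum likelihood
#'
#' Fits the Partial Credit model extended with uniform local dependence
#' (item-pair interaction grids) and uniform DIF (item-by-covariate
#' interaction grids). Estimation maximizes the likelihood of the response
#' patterns conditional on each person's total score (and, within
#' DIF-defined subgroups, on the covariate profile), so person parameters
#' never enter. Persons with extreme scores (0 or the maximum) carry no
#' conditional information and are dropped; persons with missing responses
#' on the item set are excluded (complete-case analysis).
#'
#' Identification: item-category parameters use the corner constraint
#' `alpha_i[0] = 0` plus a sum-zero constraint on item locations across
#' items; interaction grids are corner-constrained at category 0 and at the
#' reference covariate level. Interaction cells with zero observed count are
#' fixed at zero and flagged (their standard errors are not reported).
#'
#' @param data a [response_data()].
#' @param items item columns to analyse (default: all).
#' @param ld list of locally dependent item pairs, each a character vector
#'   of two item names. Pairs must be disjoint.
#' @param dif list of uniform DIF terms, each `list(item =, covariate =)`.
#' @param start optional fitted model (or named numeric vector) used as a
#'   warm start; parameters are matched by name.
#' @param se compute standard errors (numeric observed information).
#' @param collapse_null how to handle never-observed categories: collapse
#'   them with the adjacent lower category (`TRUE`, the default, standard
#'   for a primary fit) or keep the score metric and fix their probability
#'   at zero (`FALSE`).
#' @param fixed_values named parameter vector (typically a pooled fit's
#'   `par_named`). When given, parameters with empty sufficient statistics
#'   in this data subset (never-observed categories, empty interaction
#'   cells) are pinned at these values rather than estimated, and categories
#'   are never collapsed -- the mode used for subgroup refits inside
#'   [clr_test()], where relabelling or boundary estimates would corrupt the
#'   likelihood-ratio comparison.
#' @param control list: `maxit` (BFGS iterations, default 400), `gtol`
#'   (per-observation gradient max-norm tolerance, default 1e-6; the
#'   absolute tolerance is `gtol * n_used`, floored at the machine-precision
#'   limit of the objective), `newton_steps` (polishing iterations, default
#'   25).
#' @return an object of class `gllrm` (also `pcm` when `ld` and `dif` are
#'   empty) with components `alpha`, `lambda`, `delta`, `logLik`, `df`
#'   (free-parameter count), `se_table`, and the block structure used for
#'   all downstream conditional computations.
#' @seealso [pcm_fit()], [model_dof()], [clr_test()], [conditional_item_fit()]
#' @export
gllrm_fit <- function(data, items = colnames(data$responses), ld = list(),
                      dif = list(), start = NULL, se = TRUE,
                      collapse_null = TRUE, fixed_values = NULL,
                      control = list()) {
  if (!is.null(fixed_values)) collapse_null <- FALSE
  ctrl <- modifyList(list(maxit = 400L, gtol = 1e-6, newton_steps = 25L,
                          min_count = 5L), control)
  ld <- normalize_ld(ld)
  dif <- normalize_dif(dif)
  for (pair in ld)
    if (!all(pair %in% items)) stop("LD pair outside the analysis item set")
  for (d in dif)
    if (!d$item %in% items) stop("DIF item outside the analysis item set")

  prep <- prepare_cml_data(data, items, dif, collapse_null = collapse_null,
                           fixed_mode = !is.null(fixed_values))
  blocks <- build_blocks(prep$items, prep$ncat, ld)
  obs <- observed_counts(prep, blocks, ld, dif)
  parmap <- make_parmap(prep, ld, dif, obs, fixed_values = fixed_values,
                        min_count = ctrl$min_count)
  plevels <- profile_levels_list(prep)
  P <- nrow(prep$profiles)
  counts <- matrix(0, prep$rmax + 1L, P)
  tb <- table(factor(prep$r, levels = 0:prep$rmax),
              factor(prep$pidx, levels = seq_len(P)))
  counts <- matrix(as.numeric(tb), prep$rmax + 1L, P)
  s_list <- lapply(blocks, `[[`, "s")

  npar <- length(parmap$free)
  theta0 <- rep(0, npar)
  if (!is.null(start)) {
    sv <- if (inherits(start, "gllrm")) start$par_named else start
    hit <- match(parmap$names[parmap$free], names(sv))
    theta0[!is.na(hit)] <- sv[hit[!is.na(hit)]]
  }

  # The block log-weights are linear in the free parameters (the dependent
  # alpha is itself linear). Precompute the stacked affine map
  # W(theta) = W0 + Mmat %*% theta over (profile, block, cell), so each
  # likelihood/gradient evaluation is two small matrix products plus the
  # compiled ESF pass per profile.
  assemble_all <- function(theta) {
    pars <- unpack_params(theta, parmap, prep, ld, dif)
    unlist(lapply(seq_len(P), function(p)
      unlist(assemble_weights(blocks, pars$alpha, pars$lambda, pars$delta,
                              dif, prep$items, plevels[[p]]))))
  }
  W0 <- assemble_all(rep(0, npar))
  Mmat <- matrix(0, length(W0), npar)
  if (npar > 0L) for (j in seq_len(npar)) {
    ej <- rep(0, npar); ej[j] <- 1
    col <- assemble_all(ej) - W0
    col[!is.finite(col)] <- 0  # structurally dropped cells stay at -Inf
    Mmat[, j] <- col
  }
  ncells <- vapply(blocks, function(bl) nrow(bl$cells), 0L)
  # index ranges of each (profile, block) segment in the stacked vector
  seg <- vector("list", P)
  off <- 0L
  for (p in seq_len(P)) {
    seg[[p]] <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      seg[[p]][[b]] <- off + seq_len(ncells[b])
      off <- off + ncells[b]
    }
  }
  Ovec <- unlist(lapply(seq_len(P), function(p)
    lapply(seq_along(blocks), function(b) obs$O[[b]][, p])))
  obs_pos <- Ovec > 0
  use_profile <- vapply(seq_len(P), function(p) any(counts[, p] > 0), TRUE)

  # (negative) conditional log-likelihood and gradient, memoized
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) return(cache$val)
    Wvec <- if (npar > 0L) W0 + drop(Mmat %*% theta) else W0
    ll <- sum(Ovec[obs_pos] * Wvec[obs_pos])
    Dvec <- numeric(length(Wvec))
    for (p in seq_len(P)) {
      if (!use_profile[p]) next
      w_list <- lapply(seq_along(blocks), function(b) Wvec[seg[[p]][[b]]])
      res <- .cml_expected_cpp(s_list, w_list, counts[, p])
      ll <- ll - res$norm
      for (b in seq_along(blocks))
        Dvec[seg[[p]][[b]]] <- obs$O[[b]][, p] - res$M[[b]]
    }
    grad <- if (npar > 0L) drop(crossprod(Mmat, Dvec)) else numeric(0)
    cache$theta <- theta; cache$val <- list(ll = ll, grad = grad)
    cache$val
  }
  fn <- function(theta) -evaluate(theta)$ll
  gr <- function(theta) -evaluate(theta)$grad

  conv <- list(converged = TRUE, message = "")
  if (npar > 0L) {
    opt <- optim(theta0, fn, gr, method = "BFGS",
                 control = list(maxit = ctrl$maxit, reltol = 1e-12))
    theta <- opt$par
    # effective tolerance: per-observation max-norm, floored at the machine
    # precision of the objective (gradient steps below that cannot move it)
    gtol_eff <- max(ctrl$gtol * max(1, prep$n_used),
                    1e-10 * max(1, abs(fn(theta))))
    # Newton polish on the smooth concave conditional likelihood until the
    # gradient max-norm tolerance is met; also yields the information matrix.
    for (it in seq_len(ctrl$newton_steps)) {
      g <- gr(theta)
      if (max(abs(g)) < gtol_eff) break
      H <- optimHess(theta, fn, gr)
      step <- tryCatch(solve(H, g), error = function(e) g / max(abs(g)))
      f0 <- fn(theta); lam <- 1; improved <- FALSE
      while (lam >= 1e-6) {
        thn <- theta - lam * step
        if (fn(thn) <= f0) { improved <- TRUE; break }
        lam <- lam / 2
      }
      if (!improved) break  # at the numerical floor of the objective
      theta <- thn
    }
    g <- gr(theta)
    if (max(abs(g)) >= gtol_eff) {
      conv <- list(converged = FALSE,
                   message = sprintf("gradient max-norm %.2e above tolerance %.1e",
                                     max(abs(g)), ctrl$gtol))
      stop("CML estimation did not converge: ", conv$message,
           " (n used = ", prep$n_used, ", free parameters = ", npar, ")")
    }
  } else theta <- numeric(0)

  pars <- unpack_params(theta, parmap, prep, ld, dif)
  names(pars$alpha) <- prep$items
  ll <- evaluate(theta)$ll

  vcov_free <- NULL
  if (se && npar > 0L) {
    H <- optimHess(theta, fn, gr)
    vcov_free <- tryCatch(solve(H), error = function(e) {
      warning("observed information is singular; SEs unavailable")
      NULL
    })
  }

  par_named <- setNames(theta, parmap$names[parmap$free])
  fitstate <- list(s_list = s_list, W0 = W0, Mmat = Mmat, seg = seg,
                   counts = counts, use_profile = use_profile, theta = theta)
  model <- structure(list(
    items = prep$items, ncat = prep$ncat, collapse = prep$collapse,
    obs_cats = prep$obs_cats, ld = ld, dif = dif,
    alpha = pars$alpha, lambda = pars$lambda, delta = pars$delta,
    cov_levels = prep$cov_levels, profiles = prep$profiles,
    blocks = blocks, plevels = plevels,
    logLik = ll, df = npar,
    n_used = prep$n_used, n_extreme = prep$n_extreme,
    n_complete = prep$n_complete, rmax = prep$rmax,
    counts = counts, parmap = parmap, par_named = par_named,
    fitstate = fitstate, vcov_free = vcov_free, convergence = conv,
    flagged = parmap$names[parmap$fixed]),
    class = if (length(ld) + length(dif) == 0L) c("pcm", "gllrm") else "gllrm")
  model$se_table <- se_table(model)
  model
}

se_table <- function(model) {
  nm <- model$parmap$names[model$parmap$free]
  se <- rep(NA_real_, length(nm))
  if (!is.null(model$vcov_free)) {
    d <- diag(model$vcov_free)
    se[d >= 0] <- sqrt(pmax(d, 0))[d >= 0]
  }
  out <- data.frame(parameter = nm, estimate = unname(model$par_named),
                    se = se, flagged = FALSE, stringsAsFactors = FALSE)
  if (length(model$parmap$fixed)) {
    fixed_val <- vapply(model$parmap$fixed, function(e_i) {
      e <- model$parmap$entries[[e_i]]
      if (isTRUE(e$drop)) -Inf
      else if (!is.null(e$value) && !is.na(e$value)) e$value
      else 0
    }, 0)
    out <- rbind(out, data.frame(parameter = model$parmap$names[model$parmap$fixed],
                                 estimate = fixed_val, se = NA_real_,
                                 flagged = TRUE))
  }
  out
}

#' Fit the Partial Credit model by conditional maximum likelihood
#'
#' Shorthand for [gllrm_fit()] with no local-dependence and no DIF terms:
#' the polytomous Rasch model in which the total score is sufficient for the
#' person parameter.
#'
#' @inheritParams gllrm_fit
#' @return a fitted model of class `c("pcm", "gllrm")`.
#' @export
pcm_fit <- function(data, items = colnames(data$responses), start = NULL,
                    se = TRUE, control = list()) {
  gllrm_fit(data, items, ld = list(), dif = list(), start = start, se = se,
            control = control)
}

#' Free-parameter count of a fitted or hypothetical model
#'
#' For a model on k items with m_i + 1 categories each, the conditional
#' likelihood identifies `sum(m_i) - 1` item-category parameters, plus
#' `m_i * m_j` per local-dependence pair and `m_i * (G - 1)` per uniform DIF
#' term with a G-level covariate. For a fitted model the count excludes
#' interaction cells fixed at zero.
#'
#' @param x a fitted `gllrm`, or an integer vector of category counts
#'   (`m_i + 1` per item).
#' @param ld,dif when `x` is a category-count vector: lists describing LD
#'   pairs (vectors of two indices into `x`) and DIF terms
#'   (`list(item = index, nlevels = G)`).
#' @return integer free-parameter count.
#' @export
model_dof <- function(x, ld = list(), dif = list()) {
  if (inherits(x, "gllrm")) return(x$df)
  m <- as.integer(x) - 1L
  dof <- sum(m) - 1L
  for (pair in ld) dof <- dof + m[pair[1]] * m[pair[2]]
  for (d in dif) dof <- dof + m[d$item] * (d$nlevels - 1L)
  as.integer(dof)
}

#' @export
logLik.gllrm <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' @export
coef.gllrm <- function(object, ...) object$par_named

#' @export
print.gllrm <- function(x, ...) {
  kind <- if (inherits(x, "pcm")) "Partial Credit model (CML)"
          else "Graphical Log-linear Rasch Model (CML)"
  cat(kind, "\n")
  cat(sprintf("items: %s\n", paste(x$items, collapse = ", ")))
  if (length(x$ld))
    cat("LD pairs:", paste(vapply(x$ld, paste, "", collapse = "~"),
                           collapse = ", "), "\n")
  if (length(x$dif))
    cat("DIF terms:", paste(vapply(x$dif, function(d)
      paste0(d$item, "*", d$covariate), ""), collapse = ", "), "\n")
  cat(sprintf("n used (non-extreme complete cases): %d (+%d extreme)\n",
              x$n_used, x$n_extreme))
  cat(sprintf("conditional logLik: %.3f on %d free parameters\n", x$logLik, x$df))
  if (length(x$flagged))
    cat("flagged (zero-count, fixed at 0):", length(x$flagged), "cells\n")
  invisible(x)
}

#' Export fitted parameters as a tidy table
#'
#' One row per parameter (item-category, LD cell, DIF cell) with estimate
#' and standard error, suitable for CSV export and for re-instantiating a
#' fitted model.
#'
#' @param model a fitted `gllrm`.
#' @return a data frame.
#' @export
parameter_table <- function(model) model$se_table
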