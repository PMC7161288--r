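# Conditional quantities of a (fitted or constructed) model: elementary
# symmetric functions, pattern probabilities given the total score,
# item moments given the total score, and conditional pattern sampling.

#' Construct a model object from known parameters
#'
#' Builds the same object a fit produces, from user-supplied parameter
#' values, so that conditional probabilities, person scoring, and simulation
#' can be driven by a hypothetical (e.g. generating) model.
#'
#' @param alpha named list of item-category parameter vectors; each vector
#'   has length `m_i + 1` with first element 0.
#' @param ld list of LD pairs (two item names each).
#' @param lambda named list (`"itemA:itemB"`, sorted names) of interaction
#'   matrices of size `(m_i + 1) x (m_j + 1)` with zero first row/column.
#' @param dif list of DIF terms `list(item =, covariate =)`.
#' @param delta list (parallel to `dif`) of matrices `(m_i + 1) x G` with
#'   zero first row and zero reference-level (first) column.
#' @param cov_levels named list of covariate level vectors (first level =
#'   reference); required when `dif` is non-empty.
#' @return an object of class `gllrm` (unfitted: no data-dependent fields).
#' @export
rasch_model <- function(alpha, ld = list(), lambda = list(), dif = list(),
                        delta = list(), cov_levels = list()) {
  items <- names(alpha)
  if (is.null(items)) {
    items <- paste0("item", seq_along(alpha))
    names(alpha) <- items
  }
  ncat <- vapply(alpha, length, 0L)
  names(ncat) <- items
  for (i in seq_along(alpha))
    if (alpha[[i]][1] != 0) stop("alpha vectors must start at 0 (category 0)")
  ld <- normalize_ld(ld)
  dif <- normalize_dif(dif)
  if (length(ld)) {
    for (pair in ld) {
      key <- paste(pair, collapse = ":")
      if (is.null(lambda[[key]]))
        lambda[[key]] <- matrix(0, ncat[pair[1]], ncat[pair[2]])
      lam <- lambda[[key]]
      if (!all(dim(lam) == ncat[pair]) || any(lam[1, ] != 0) || any(lam[, 1] != 0))
        stop("lambda grid for ", key, " has wrong shape or non-zero corner")
    }
  }
  if (length(dif)) {
    if (!length(cov_levels)) stop("cov_levels required with DIF terms")
    if (length(delta) != length(dif)) stop("delta must parallel dif")
    for (t in seq_along(dif)) {
      G <- length(cov_levels[[dif[[t]]$covariate]])
      dm <- delta[[t]]
      if (!all(dim(dm) == c(ncat[dif[[t]]$item], G)) ||
          any(dm[1, ] != 0) || any(dm[, 1] != 0))
        stop("delta grid ", t, " has wrong shape or non-zero corners")
    }
    covs <- unique(vapply(dif, `[[`, "", "covariate"))
    cov_levels <- cov_levels[covs]
    profiles <- expand.grid(cov_levels, stringsAsFactors = FALSE)
  } else {
    cov_levels <- list()
    profiles <- data.frame(row.names = 1)
  }
  blocks <- build_blocks(items, ncat, ld)
  prep <- list(cov_levels = cov_levels, profiles = profiles)
  plevels <- profile_levels_list(prep)
  structure(list(items = items, ncat = ncat, collapse = NULL,
                 obs_cats = lapply(ncat, function(m) rep(TRUE, m)),
                 ld = ld, dif = dif, alpha = alpha, lambda = lambda,
                 delta = delta, cov_levels = cov_levels, profiles = profiles,
                 blocks = blocks, plevels = plevels,
                 rmax = sum(ncat - 1L),
                 df = model_dof(ncat,
                                lapply(ld, function(p) match(p, items)),
                                lapply(dif, function(d)
                                  list(item = match(d$item, items),
                                       nlevels = length(cov_levels[[d$covariate]])))),
                 logLik = NA_real_),
            class = if (length(ld) + length(dif) == 0L) c("pcm", "gllrm")
                    else "gllrm")
}

# per-profile list of block log-weight vectors
model_weights <- function(model) {
  lapply(seq_len(nrow(model$profiles)), function(p)
    assemble_weights(model$blocks, model$alpha, model$lambda, model$delta,
                     model$dif, model$items, model$plevels[[p]]))
}

# match a covariate profile (named list/character) to the model's profile row
match_profile <- function(model, profile) {
  if (nrow(model$profiles) == 1L) return(1L)
  if (is.null(profile))
    stop("model has DIF terms; a covariate profile is required")
  for (cv in names(model$cov_levels))
    if (is.null(profile[[cv]]))
      stop("profile is missing covariate ", cv)
  p <- 1L; mult <- 1L
  for (cv in names(model$cov_levels)) {
    li <- match(as.character(profile[[cv]]), model$cov_levels[[cv]])
    if (is.na(li)) stop("unknown level for covariate ", cv)
    p <- p + (li - 1L) * mult
    mult <- mult * length(model$cov_levels[[cv]])
  }
  p
}

#' Elementary symmetric functions of a Partial Credit model
#'
#' Returns `log gamma_r` for r = 0..sum(m_i), where `gamma_r` sums
#' `exp(sum_i alpha_i[y_i])` over all response patterns with total score r.
#' Computed by the log-space recursion over items; `log gamma_0 = 0` always.
#'
#' @param alpha list of item-category parameter vectors (first element 0).
#' @return numeric vector of length `sum(m_i) + 1`.
#' @export
esf_log <- function(alpha) {
  s_list <- lapply(alpha, function(a) 0:(length(a) - 1L))
  .esf_log_cpp(s_list, alpha)
}

# log normalizer per profile: log K_r(c) over blocks (equals esf_log for PCM)
model_esf <- function(model, profile_index = 1L) {
  w <- model_weights(model)[[profile_index]]
  .esf_log_cpp(lapply(model$blocks, `[[`, "s"), w)
}

#' Log-probability of a response pattern given its total score
#'
#' `log P(Y = y | R = r, C = c)` under the model: the sum of the pattern's
#' log-weights (item-category, LD, and DIF terms) minus the log normalizer
#' over all patterns with the same total score and covariate profile. For a
#' pure Partial Credit model the covariate profile is ignored.
#'
#' @param model a fitted or [rasch_model()] object.
#' @param pattern integer vector of responses (one per model item).
#' @param r total score; must equal `sum(pattern)`.
#' @param profile named covariate profile (list or character), required when
#'   the model has DIF terms.
#' @return log-probability (scalar).
#' @export
conditional_pattern_logprob <- function(model, pattern, r = sum(pattern),
                                        profile = NULL) {
  if (length(pattern) != length(model$items))
    stop("pattern length does not match the model item set")
  if (sum(pattern) != r) stop("pattern/score mismatch: sum(pattern) != r")
  p <- match_profile(model, profile)
  w <- model_weights(model)[[p]]
  logK <- .esf_log_cpp(lapply(model$blocks, `[[`, "s"), w)
  lp <- -logK[r + 1L]
  for (b in seq_along(model$blocks)) {
    bl <- model$blocks[[b]]
    cell <- 1L
    mult <- 1L
    for (jj in seq_along(bl$items)) {
      cell <- cell + pattern[bl$items[jj]] * mult
      mult <- mult * model$ncat[bl$items[jj]]
    }
    lp <- lp + w[[b]][cell]
  }
  lp
}

# Conditional item moments for every item and score, one covariate profile.
# Returns list(E, V, EY2, logK): E and V are k x (rmax + 1) matrices.
conditional_moments_profile <- function(model, profile_index = 1L) {
  w <- model_weights(model)[[profile_index]]
  post <- .block_posteriors_cpp(lapply(model$blocks, `[[`, "s"), w)
  k <- length(model$items)
  RR <- model$rmax + 1L
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
  V <- pmax(E2 - E^2, 0)
  list(E = E, V = V, logK = post$logK)
}

#' Conditional moments of an item given the total score
#'
#' Expected value and variance of item i's response among persons with total
#' score r (and covariate profile c, for models with DIF), the basis of item
#' characteristic curve tables and conditional fit residuals.
#'
#' @param model a fitted or [rasch_model()] object.
#' @param item item name.
#' @param r total score(s), 0..rmax.
#' @param profile covariate profile (required with DIF terms).
#' @return data frame with columns `r`, `expected`, `variance`.
#' @export
conditional_item_moments <- function(model, item, r = 0:model$rmax,
                                     profile = NULL) {
  i <- match(item, model$items)
  if (is.na(i)) stop("unknown item: ", item)
  if (any(r < 0 | r > model$rmax)) stop("score out of range")
  p <- match_profile(model, profile)
  mom <- conditional_moments_profile(model, p)
  data.frame(r = r, expected = mom$E[i, r + 1L], variance = mom$V[i, r + 1L])
}

#' Sample response patterns conditional on total scores
#'
#' Draws patterns from `P(Y | R = r, C = c)` under the model, the parametric
#' bootstrap engine behind the conditional item fit statistics.
#'
#' @param model a fitted or [rasch_model()] object.
#' @param r integer vector of total scores, one per draw.
#' @param profile_index covariate profile row (scalar) for all draws.
#' @return integer matrix (draws x items) of responses.
#' @export
sample_conditional_patterns <- function(model, r, profile_index = 1L) {
  w <- model_weights(model)[[profile_index]]
  cells <- .sample_conditional_cpp(lapply(model$blocks, `[[`, "s"), w,
                                   as.integer(r))
  out <- matrix(0L, length(r), length(model$items))
  colnames(out) <- model$items
  for (b in seq_along(model$blocks)) {
    bl <- model$blocks[[b]]
    for (jj in seq_along(bl$items))
      out[, bl$items[jj]] <- bl$cells[cells[, b], jj]
  }
  out
}
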