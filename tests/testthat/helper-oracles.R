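# Shared fixtures: brute-force enumeration oracles and small generating
# configurations used across test files.

# all response patterns for given category counts, as a matrix
all_patterns <- function(ncat) {
  as.matrix(expand.grid(lapply(ncat, function(m) 0:(m - 1L))))
}

# brute-force log weight of each pattern under alpha (+ optional LD lambda
# grids keyed "i:j" by item index, + DIF deltas at a given level index)
pattern_logweights <- function(pat, alpha, lambda = list(), delta = list()) {
  w <- numeric(nrow(pat))
  for (i in seq_along(alpha)) w <- w + alpha[[i]][pat[, i] + 1L]
  for (key in names(lambda)) {
    ij <- as.integer(strsplit(key, ":")[[1]])
    w <- w + lambda[[key]][cbind(pat[, ij[1]] + 1L, pat[, ij[2]] + 1L)]
  }
  for (d in delta) w <- w + d$grid[pat[, d$item] + 1L, d$level]
  w
}

# brute-force log gamma_r from enumeration
bf_esf <- function(alpha, lambda = list(), delta = list()) {
  ncat <- vapply(alpha, length, 0L)
  pat <- all_patterns(ncat)
  w <- pattern_logweights(pat, alpha, lambda, delta)
  r <- rowSums(pat)
  vapply(0:sum(ncat - 1L), function(rr) log(sum(exp(w[r == rr]))), 0)
}

# O(n^2) brute-force Goodman-Kruskal gamma
bf_gamma <- function(x, y) {
  C <- 0; D <- 0
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  (C - D) / (C + D)
}

# a small, well-behaved PCM generating setup (5 five-category items)
test_alpha <- function(k = 5, locs = seq(-0.4, 0.4, length.out = k),
                       off = c(-1.5, -0.5, 0.5, 1.5)) {
  alpha <- lapply(locs, function(L) c(0, -cumsum(L + off)))
  names(alpha) <- paste0("item", seq_len(k))
  alpha
}

null_pcm_config <- function(n, k = 5, trait_sd = 1.5,
                            covariates = list(sex = c(Male = .5, Female = .5))) {
  alpha <- test_alpha(k)
  scA <- sim_scale(names(alpha), alpha, trait_sd = trait_sd)
  filler <- test_alpha(2, locs = c(0, 0))
  names(filler) <- c("f1", "f2")
  scB <- sim_scale(c("f1", "f2"), filler, trait_sd = 1)
  sim_config(n = n, covariates = covariates,
             scales = list(a = scA, b = scB), trait_cor = 0)
}

# simulate a plain PCM data set (the scale of interest only)
sim_pcm_data <- function(n, seed, ...) {
  simulate_dataset(null_pcm_config(n, ...), seed = seed)$data
}

logsumexp_ref <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
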