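#' @useDynLib gllrm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimHess pnorm qnorm rnorm runif rbinom dnorm
#'   var sd median optimize uniroot p.adjust pchisq cor cor.test setNames
#'   complete.cases quantile
#' @importFrom utils head modifyList
NULL

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix, tolerating -Inf entries.
row_logsumexp <- function(m) {
  mx <- do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))
  out <- mx + log(rowSums(exp(m - mx)))
  out[mx == -Inf] <- -Inf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
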