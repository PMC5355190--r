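#' Two-occasion binomial removal sampling
#'
#' Simulates a trapping session: c1 ~ Binomial(n, p) animals are caught on
#' the first 24-hr occasion, removed from the available pool, and
#' c2 ~ Binomial(n - c1, p) are caught on the second. The same capture
#' probability applies on both occasions (no behavioural or time effect).
#'
#' @param n integer abundance (>= 0), vectorized.
#' @param p capture probability in [0, 1].
#' @return integer matrix with columns `c1`, `c2`; always c1 + c2 <= n.
#' @export
sampleCaptures <- function(n, p) {
  stopifnot(all(n >= 0), p >= 0, p <= 1)
  c1 <- rbinom(length(n), n, p)
  c2 <- rbinom(length(n), n - c1, p)
  cbind(c1 = c1, c2 = c2)
}

#' Log-likelihood of a two-occasion removal observation
#'
#' log Bin(c1; n, p) + log Bin(c2; n - c1, p). Observations with
#' c1 + c2 > n are impossible and return -Inf.
#'
#' @param c1,c2 occasion counts (vectorized).
#' @param n latent abundance.
#' @param p capture probability.
#' @return log-probability.
#' @export
captureLogLik <- function(c1, c2, n, p) {
  out <- dbinom(c1, n, p, log = TRUE) + dbinom(c2, n - c1, p, log = TRUE)
  out[c1 + c2 > n] <- -Inf
  out
}

#' Naive two-day density index
#'
#' The classical index of density: the total individuals marked over the
#' two occasions, c1 + c2. Always at or below the latent abundance; close
#' to it when capture probability is high (adult trappability in these
#' woodland populations typically catches over 70% of known individuals in
#' the first two days).
#'
#' @param c1,c2 occasion counts.
#' @return integer index.
#' @export
naiveAbundanceIndex <- function(c1, c2) {
  stopifnot(all(c1 >= 0), all(c2 >= 0))
  as.integer(c1 + c2)
}
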