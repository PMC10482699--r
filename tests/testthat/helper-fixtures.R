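# shared fixtures and independent oracles, built in code at test time

# small labelled count matrix
cmat <- function(values, taxa, samples) {
  matrix(values, nrow = length(taxa), byrow = TRUE,
         dimnames = list(taxa, samples))
}

# one cached default-config lab dataset (generation is the slow step; several
# test files interrogate the same ground truth)
lab_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_lab_dataset(sim_config(seed = 1))
    cache
  }
})

# independent beta-binomial log-likelihood (direct density sum, no reuse of
# package internals)
bb_loglik_oracle <- function(beta0, beta_g, phi, y, n, grp) {
  mu <- plogis(beta0 + beta_g * grp)
  a <- mu * (1 - phi) / phi
  b <- (1 - mu) * (1 - phi) / phi
  sum(lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b))
}

# hand-rolled Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# hand-rolled Bray-Curtis on two relative-abundance vectors
bc_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# fixed beta-binomial fixture: 8 samples, two arms
bb_fixture <- list(
  y = c(12, 30, 8, 22, 95, 160, 70, 120),
  n = c(1000, 1500, 900, 1200, 1100, 1600, 1000, 1300),
  grp = c(0, 0, 0, 0, 1, 1, 1, 1))
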