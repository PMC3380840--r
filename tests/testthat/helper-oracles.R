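# exhaustive-likelihood oracle: maximise the multinomial diplotype
# likelihood over the haplotype-frequency simplex (softmax parameters,
# quasi-Newton, many restarts); independent of the EM code path
oracle_phase <- function(geno, restarts = 30) {
  k <- ncol(geno)
  nh <- 2^k
  bit <- function(v) sum(v * 2^(seq_len(k) - 1)) + 1L  # haplotype index
  # per individual: list of (i, j, mult) compatible diplotypes
  dips <- lapply(seq_len(nrow(geno)), function(r) {
    g <- geno[r, ]
    het <- which(g == 1L)
    base <- integer(k); base[g == 2L] <- 1L
    if (!length(het)) return(cbind(i = bit(base), j = bit(base), mult = 1))
    picks <- as.matrix(expand.grid(rep(list(0:1), length(het))))
    out <- t(apply(picks, 1, function(p) {
      v1 <- base; v1[het] <- p
      v2 <- base; v2[het] <- 1L - p
      c(i = bit(v1), j = bit(v2))
    }))
    out <- out[out[, 1] <= out[, 2], , drop = FALSE]
    cbind(out, mult = 2)
  })
  loglik <- function(f) {
    sum(vapply(dips, function(d)
      log(sum(d[, "mult"] * f[d[, "i"]] * f[d[, "j"]])), numeric(1)))
  }
  best <- list(ll = -Inf, f = NULL)
  for (r in seq_len(restarts)) {
    x0 <- rnorm(nh)
    op <- optim(x0, function(x) {
      f <- exp(x - max(x)); f <- f / sum(f)
      -loglik(pmax(f, 1e-300))
    }, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    f <- exp(op$par - max(op$par)); f <- f / sum(f)
    if (-op$value > best$ll) best <- list(ll = -op$value, f = f)
  }
  best
}
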