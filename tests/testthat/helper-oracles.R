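# Independent oracles, deliberately coded apart from the package internals.

# dense ridge solve on the explicit normal equations, via QR of the
# augmented least-squares system [X; sqrt(k) I] -- a different route than
# the package's symmetric solve
oracle_ridge <- function(X, y, k) {
  Xa <- rbind(X, sqrt(k) * diag(ncol(X)))
  ya <- c(y, rep(0, ncol(X)))
  qr.coef(qr(Xa), ya)
}

# leave-one-out SSE by literally refitting n times
oracle_loo_sse <- function(data, y, positions, k) {
  n <- nrow(data)
  sum(vapply(seq_len(n), function(i) {
    m <- fit_ridge(data[-i, ], y = y[-i], positions = positions, k = k)
    (y[i] - predict_btr(m, data[i, ]))^2
  }, numeric(1)))
}

# auROC as the exhaustive pairwise-comparison probability
oracle_auroc <- function(scores, labels) {
  sp <- scores[labels > 0]
  sn <- scores[labels < 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# auPRC by naive per-threshold evaluation at every distinct score
oracle_auprc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  npos <- sum(labels > 0)
  for (i in seq_along(th)) {
    called <- scores >= th[i]
    prec[i] <- sum(labels[called] > 0) / sum(called)
    rec[i] <- sum(labels[called] > 0) / npos
  }
  sum(diff(c(0, rec)) * prec)
}

# first-order propagation checked against Monte-Carlo draws
oracle_mc_ratio_sd <- function(x1, sd1, x2, sd2, n = 1e5, seed = 1) {
  withr::with_seed(seed, {
    a <- rnorm(n, x1, sd1)
    b <- rnorm(n, x2, sd2)
    stats::sd(b / a)
  })
}

random_contexts <- function(n, seed) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    tibble::tibble(
      upstream = replicate(n, paste(sample(bases, 6, TRUE), collapse = "")),
      stop = sample(c("TAA", "TAG", "TGA"), n, TRUE),
      downstream = replicate(n, paste(sample(bases, 6, TRUE), collapse = ""))
    )
  })
}
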