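test_that("published models reproduce their printed norms, divisors and spot weights", {
  fs3 <- published_model("LINfs3")
  iter <- published_model("LINiter")
  expect_equal(fs3$weight_norm, 0.0063, tolerance = 0.02)
  expect_equal(iter$weight_norm, 0.0088, tolerance = 0.02)
  expect_equal(fs3$feature_divisor, 2)
  expect_equal(iter$feature_divisor, sqrt(13))

  tw3 <- tidy(fs3)
  expect_equal(tw3$weight[tw3$position == "stop" & tw3$base == "TGA"], 0.00229)
  twi <- tidy(iter)
  expect_equal(twi$weight[twi$position == "4" & twi$base == "C"], 0.00375)

  expect_error(published_model("LINfs5"), "published")
  expect_error(published_model("LIN"), "published")
})

test_that("LINfs3 scores the LDHB context as printed", {
  fs3 <- published_model("LINfs3")
  sc <- rtp_score(fs3, "AAAAGACCTG TGA CTAGTGAGCT")
  # hand sum of the four matched cells: TGA + C@+4 + T@+5 + A@+6
  expect_equal(sc$raw_sum, 0.00229 + 0.00351 + 0.00299 + 0.00306)
  expect_equal(sc$predicted_btr, 0.005925)
  expect_equal(sc$rtp, 0.01185 / 0.0126, tolerance = 0.005)
})

test_that("fit_ridge matches an independent dense QR oracle", {
  for (seed in 1:4) {
    train <- random_contexts(12, seed = seed)
    y <- withr::with_seed(seed, runif(12))
    for (pos in list(c(4, 5, 6), scc_positions())) {
      m <- fit_ridge(train, y = y, positions = pos, k = 1)
      X <- unit_normalize(encode_scc(train, positions = pos))
      active <- colSums(abs(X)) > 0
      w_oracle <- oracle_ridge(X[, active, drop = FALSE], y, 1)
      expect_equal(unname(m$weights[active]), unname(w_oracle),
                   tolerance = 1e-10)
      expect_true(all(m$weights[!active] == 0))
    }
  }
})

test_that("huge regularization shrinks all weights to nothing", {
  train <- random_contexts(10, seed = 3)
  y <- withr::with_seed(3, runif(10, 0, 5))
  m <- fit_ridge(train, y = y, k = 1e9)
  expect_lt(max(abs(m$weights)), 1e-6 * max(abs(y)))
})

test_that("weight norm is non-increasing in k and fit is permutation invariant", {
  train <- random_contexts(15, seed = 7)
  y <- withr::with_seed(7, runif(15))
  norms <- vapply(rtp_k_grid(), function(k) {
    fit_ridge(train, y = y, k = k)$weight_norm
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))

  perm <- withr::with_seed(8, sample(15))
  m1 <- fit_ridge(train, y = y, k = 2)
  m2 <- fit_ridge(train[perm, ], y = y[perm], k = 2)
  expect_equal(m1$weights, m2$weights)
})

test_that("fit_ridge validates its inputs", {
  train <- random_contexts(5, seed = 1)
  expect_error(fit_ridge(train, y = runif(5), k = 0), "positive")
  expect_error(fit_ridge(train, y = runif(5), k = -1), "positive")
  expect_error(fit_ridge(train[1, ], y = 1), "at least 2")
})

test_that("leave-one-out SSE equals the naive refit oracle and is zero on zero targets", {
  train <- random_contexts(8, seed = 11)
  y <- withr::with_seed(11, runif(8))
  for (k in c(0.1, 1.995, 50)) {
    expect_equal(as.numeric(loo_cv_sse(train, y = y, k = k)),
                 oracle_loo_sse(train, y, scc_positions(), k))
  }
  expect_equal(as.numeric(loo_cv_sse(train, y = rep(0, 8), k = 1)), 0)
  expect_error(loo_cv_sse(train[1:2, ], y = c(1, 2)), "at least 3")
})

test_that("the default k grid enumerates 10^(-3..3) in steps of 0.3", {
  g <- rtp_k_grid()
  expect_length(g, 21)
  expect_equal(g, 10^seq(-3, 3, by = 0.3))
  expect_equal(rtp_default_k(), 10^0.3)
  expect_equal(rtp_default_k(), 1.995, tolerance = 1e-3)
})

test_that("select_k returns the exhaustive grid argmin, smallest k on ties", {
  train <- gen_scc_dataset(30, noise_sd = 0, seed = 21)
  sel <- select_k(train)
  # oracle: evaluate every grid point independently
  sses <- vapply(rtp_k_grid(), function(k) {
    as.numeric(loo_cv_sse(train, k = k))
  }, numeric(1))
  expect_equal(sel$k, rtp_k_grid()[which.min(sses)])
  expect_equal(sel$sse, min(sses))

  expect_equal(select_k(train, grid = 7)$k, 7)
  expect_error(select_k(train, grid = numeric(0)), "empty")
  # exact ties go to the smallest k
  sel0 <- select_k(tibble::tibble(
    upstream = c("AAAAAA", "CCCCCC", "GGGGGG"),
    stop = "TGA", downstream = "TTTTTT",
    readthrough_pct = c(0, 0, 0)
  ), grid = c(10, 1, 0.1))
  expect_equal(sel0$k, 0.1)
})

test_that("predictions are the matched raw-weight sum over the feature divisor", {
  zero <- rtp_model(tibble::tibble(position = "stop", base = "TGA", weight = 0))
  ctxs <- random_contexts(5, seed = 2)
  expect_equal(predict_btr(zero, ctxs), rep(0, 5))

  single <- rtp_model(tibble::tibble(
    position = c("4", "stop"), base = c("C", "TGA"), weight = c(0.5, 0)
  ))
  expect_equal(predict_btr(single, "AAAAAA TGA CAAAAA"),
               0.5 / single$feature_divisor)
  expect_equal(predict_btr(single, "AAAAAA TGA GAAAAA"), 0)
})

test_that("rtp is scale invariant and propagates sign", {
  fs3 <- published_model("LINfs3")
  ctxs <- random_contexts(20, seed = 5)
  scaled <- tidy(fs3)
  scaled$weight <- scaled$weight * 10
  fs3x10 <- rtp_model(scaled, k = fs3$k)
  expect_equal(rtp_score(fs3, ctxs)$rtp, rtp_score(fs3x10, ctxs)$rtp)

  # a context matching only negative LINfs3 cells scores negative
  neg <- rtp_score(fs3, "AAAAAA TAG GCGAAA") # TAG, G@+4, C@+5, G@+6: all negative cells
  expect_lt(neg$rtp, 0)

  zero <- rtp_model(tibble::tibble(position = "stop", base = "TGA", weight = 0))
  expect_error(rtp_score(zero, ctxs), "zero weight norm")
})

test_that("models round-trip through JSON with norm verification", {
  m <- fit_ridge(published_table("table1"), positions = c(-6, 4, 5, 6, 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_rtp_model(m, path)
  back <- read_rtp_model(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$k, m$k)
  expect_equal(back$positions, m$positions)

  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$weight_norm <- doc$weight_norm * 2
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_rtp_model(path), "disagrees")
})

test_that("tidy output reconstructs an identically scoring model", {
  m <- fit_ridge(published_table("table1"))
  m2 <- rtp_model(tidy(m), k = m$k)
  ctxs <- random_contexts(10, seed = 6)
  expect_equal(rtp_score(m2, ctxs), rtp_score(m, ctxs))
  g <- glance(m)
  expect_equal(g$shortcut_divisor, m$weight_norm * m$feature_divisor)
})
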