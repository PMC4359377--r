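test_that("position importance is the per-block sum of squared coefficients", {
  zero <- rtp_model(dplyr::bind_rows(
    tidyr::expand_grid(position = as.character(scc_positions()),
                       base = c("A", "C", "G", "T"), weight = 0),
    tibble::tibble(position = "stop", base = "TGA", weight = 0)
  ))
  expect_true(all(position_importance(zero)$importance == 0))

  only5 <- rtp_model(dplyr::bind_rows(
    tidyr::expand_grid(position = as.character(scc_positions()),
                       base = c("A", "C", "G", "T"), weight = 0),
    tibble::tibble(position = "5", base = "T", weight = 0.3),
    tibble::tibble(position = "stop", base = "TGA", weight = 0.1)
  ))
  imp <- position_importance(only5)
  expect_equal(imp$importance[imp$position == 5], 0.3^2)
  expect_true(all(imp$importance[imp$position != 5] == 0))
  expect_false("stop" %in% imp$position)

  iter <- published_model("LINiter")
  impi <- position_importance(iter)
  expect_equal(impi$importance[impi$position == 4],
               0.00375^2 + 0.00037^2 + 0.00156^2 + 0.00067^2)
})

test_that("elimination runs 12 steps, never removes the stop, and shrinks by one", {
  train <- tibble::tibble(
    random_contexts(12, seed = 31),
    readthrough_pct = rep(1, 12) # constant targets: trace must still complete
  )
  trace <- run_elimination(train)
  expect_s3_class(trace, "elim_trace")
  expect_equal(trace$step, 0:12)
  expect_equal(trace$n_context_positions, 12:0)
  expect_true(all(!is.na(trace$removed_position[-1])))
  expect_equal(sort(trace$removed_position[-1]), sort(scc_positions()))
  for (i in 2:13) {
    expect_equal(
      sort(c(trace$positions[[i]], trace$removed_position[i])),
      sort(trace$positions[[i - 1]])
    )
  }
})

test_that("elimination recovers a signal planted at the stop-proximal codon", {
  w <- planted_scc_weights(positions = c(4, 5, 6), effect_sd = 0.02, seed = 41)
  train <- gen_scc_dataset(60, planted_weights = w, noise_sd = 1e-5, seed = 42)
  trace <- run_elimination(train)
  g <- pick_minima(trace)$global
  expect_equal(sort(g$positions[[1]]), c(4L, 5L, 6L))
  # the planted positions survive longest
  expect_equal(sort(tail(trace$removed_position, 3)), c(4L, 5L, 6L))
})

test_that("elimination is deterministic", {
  train <- gen_scc_dataset(25, seed = 51)
  t1 <- run_elimination(train, keep_models = FALSE)
  t2 <- run_elimination(train, keep_models = FALSE)
  expect_identical(t1, t2)
})

test_that("pick_minima finds global and interior local minima", {
  fake <- function(sse) {
    tibble::tibble(step = seq_along(sse) - 1, loo_sse = sse,
                   positions = list(1), n_context_positions = 0)
  }
  m <- pick_minima(fake(c(5, 3, 4, 2, 6)))
  expect_equal(m$global$step, 3)
  expect_equal(m$local$step, c(1, 3))

  dec <- pick_minima(fake(c(9, 7, 5, 3)))
  expect_equal(dec$global$step, 3)
  expect_equal(nrow(dec$local), 0)

  ush <- pick_minima(fake(c(5, 2, 6)))
  expect_equal(ush$global$step, 1)
  expect_equal(ush$local$step, 1)
})

test_that("logo matrix exports raw weights and reconstructs the model", {
  iter <- published_model("LINiter")
  logo <- logo_matrix(iter)
  expect_equal(dim(logo$positions), c(12, 4))
  expect_equal(logo$positions["-6", "T"], 0.00200)
  expect_equal(unname(logo$stop["TGA"]), 0.00243)

  zero <- fit_ridge(random_contexts(5, seed = 61), y = rep(0, 5), k = 1)
  expect_true(all(logo_matrix(zero)$positions == 0))

  # round-trip through the tidy layout reproduces identical scores
  back <- rtp_model(tidy(iter), k = iter$k)
  ctxs <- random_contexts(10, seed = 62)
  expect_equal(rtp_score(back, ctxs), rtp_score(iter, ctxs))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_logo_matrix(logo, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(tab), 51)
})

test_that("consensus of the published reduced model is UGA CUA", {
  fs3 <- published_model("LINfs3")
  cons <- consensus_motif(fs3, rna = TRUE)
  expect_equal(attr(cons, "consensus"), "UGA CUA")
  expect_false(any(cons$ambiguous))
  expect_equal(attr(consensus_motif(fs3), "consensus"), "TGA CTA")
})

test_that("consensus ties pick the lexicographically first base and are flagged", {
  tied <- rtp_model(dplyr::bind_rows(
    tibble::tibble(position = "4", base = c("A", "C", "G", "T"), weight = 0.2),
    tibble::tibble(position = "stop", base = "TGA", weight = 0.1)
  ))
  cons <- consensus_motif(tied)
  expect_equal(cons$base[cons$position == "4"], "A")
  expect_true(cons$ambiguous[cons$position == "4"])

  single <- rtp_model(dplyr::bind_rows(
    tibble::tibble(position = "7", base = "A", weight = 1),
    tibble::tibble(position = "stop", base = "TAA", weight = 0.5)
  ))
  expect_equal(attr(consensus_motif(single), "consensus"), "TAA A")
})
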