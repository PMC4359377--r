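#' Per-position importance of a fitted model
#'
#' The importance of a context position is the sum of squared regression
#' coefficients over its four base indicators. The stop codon is never a
#' removal candidate and is excluded.
#'
#' @param model An `rtp_model`.
#' @return Tibble with columns `position` (integer) and `importance`,
#'   one row per active context position.
#' @export
position_importance <- function(model) {
  stopifnot(inherits(model, "rtp_model"))
  tw <- tidy(model)
  tw <- tw[tw$position != "stop", ]
  out <- tw |>
    dplyr::mutate(position = as.integer(.data$position)) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(importance = sum(.data$weight^2), .groups = "drop") |>
    dplyr::arrange(.data$position)
  out
}

# tie-break for equal importances: drop the position farthest from the stop,
# upstream before downstream at equal distance
.removal_order_key <- function(positions) {
  dist <- ifelse(positions < 0, -positions, positions - 3L)
  order(dist, positions, decreasing = c(TRUE, FALSE), method = "radix")
}

#' Stepwise elimination of context positions
#'
#' Starting from all 12 context positions plus the stop, repeatedly (i)
#' selects `k` by leave-one-out cross-validation over `k_grid`, (ii) fits
#' the ridge model, (iii) records the loo-CV SSE, and (iv) removes the
#' context position with the minimum sum of squared regression coefficients,
#' until only the stop codon remains. Ties on importance are broken by
#' removing the position farthest from the stop, upstream before downstream.
#'
#' @inheritParams fit_ridge
#' @param k_grid Grid of regularization values re-optimized at every step.
#' @param keep_models Store the fitted model of each step (list column).
#' @return An `elim_trace`: a tibble with one row per model size, columns
#'   `step` (0 = full model), `removed_position` (NA for step 0),
#'   `n_context_positions`, `positions` (list column), `k`, `loo_sse`, and
#'   optionally `model`.
#' @export
#' @examples
#' \donttest{
#' train <- gen_scc_dataset(60, seed = 1)
#' trace <- run_elimination(train)
#' pick_minima(trace)
#' }
run_elimination <- function(data, y = "readthrough_pct", k_grid = rtp_k_grid(),
                            keep_models = TRUE) {
  yv <- .y_values(data, y)
  if (length(yv) < 3L) abort("elimination needs at least 3 training contexts")
  positions <- scc_positions()
  rows <- vector("list", 13L)
  removed <- NA_integer_
  for (step in 0:12) {
    sel <- select_k(data, y = yv, positions = positions, grid = k_grid)
    fit <- fit_ridge(data, y = yv, positions = positions, k = sel$k)
    rows[[step + 1L]] <- tibble::tibble(
      step = step,
      removed_position = removed,
      n_context_positions = length(positions),
      positions = list(positions),
      k = sel$k,
      loo_sse = sel$sse,
      model = if (keep_models) list(fit) else list(NULL)
    )
    if (step == 12L) break
    imp <- position_importance(fit)
    ord <- .removal_order_key(imp$position)
    cand <- imp[ord, ]
    removed <- cand$position[which.min(cand$importance)]
    positions <- setdiff(positions, removed)
  }
  out <- dplyr::bind_rows(rows)
  if (!keep_models) out$model <- NULL
  class(out) <- c("elim_trace", class(out))
  out
}

#' Locate error minima along an elimination trace
#'
#' The global minimum is the step with the smallest loo-CV SSE (earliest
#' step on ties). Local minima are interior steps strictly smaller than both
#' neighbors; the global minimum is also reported as local when interior.
#'
#' @param trace An `elim_trace` from [run_elimination()].
#' @return List with `global` (one-row tibble) and `local` (tibble of
#'   interior local minima, possibly empty).
#' @export
pick_minima <- function(trace) {
  stopifnot(is.data.frame(trace), all(c("step", "loo_sse") %in% names(trace)))
  sse <- trace$loo_sse
  n <- length(sse)
  gi <- which.min(sse)
  li <- if (n >= 3L) {
    which(sse[2:(n - 1L)] < sse[1:(n - 2L)] & sse[2:(n - 1L)] < sse[3:n]) + 1L
  } else {
    integer(0)
  }
  list(global = trace[gi, ], local = trace[li, ])
}

#' Signed-coefficient logo matrix
#'
#' Exports the raw regression weights of a model as a position-by-base
#' matrix of signed coefficients suitable for sequence-logo rendering
#' (positive weights drawn upright, negative inverted), with the stop
#' weights as a separate three-entry column.
#'
#' @param model An `rtp_model`.
#' @return List with `positions` (matrix, one row per active context
#'   position, columns A/C/G/T) and `stop` (named 3-vector TAA/TAG/TGA).
#' @export
logo_matrix <- function(model) {
  stopifnot(inherits(model, "rtp_model"))
  tw <- tidy(model)
  ctx <- tw[tw$position != "stop", ]
  mat <- matrix(0, nrow = length(model$positions), ncol = 4L,
                dimnames = list(.pos_label(model$positions), .bases))
  mat[cbind(ctx$position, ctx$base)] <- ctx$weight
  st <- tw[tw$position == "stop", ]
  list(positions = mat, stop = setNames(st$weight, st$base))
}

#' Write a logo matrix as TSV
#'
#' @param logo Output of [logo_matrix()].
#' @param path File path.
#' @export
write_logo_matrix <- function(logo, path) {
  pos_tbl <- tibble::as_tibble(logo$positions, rownames = "position")
  stop_tbl <- tibble::tibble(position = "stop",
                             base = names(logo$stop), weight = unname(logo$stop))
  readr::write_tsv(dplyr::bind_rows(
    tidyr::pivot_longer(pos_tbl, -"position", names_to = "base", values_to = "weight"),
    stop_tbl
  ), path)
  invisible(path)
}

#' High-readthrough consensus motif of a model
#'
#' For each active position, the base with the maximal regression weight;
#' for the stop, the stop codon with the maximal weight. Exact ties pick the
#' lexicographically first base and are flagged ambiguous.
#'
#' @param model An `rtp_model`.
#' @param rna Report the motif in the RNA alphabet (U instead of T).
#' @return Tibble with columns `position` (upstream positions, then "stop",
#'   then downstream), `base` and `ambiguous`; attribute `"consensus"` holds
#'   the motif as a single string with the stop set off by spaces.
#' @export
#' @examples
#' attr(consensus_motif(published_model("LINfs3"), rna = TRUE), "consensus")
consensus_motif <- function(model, rna = FALSE) {
  stopifnot(inherits(model, "rtp_model"))
  tw <- tidy(model)
  pick <- tw |>
    dplyr::group_by(.data$position) |>
    dplyr::arrange(.data$base, .by_group = TRUE) |>
    dplyr::summarise(
      base = .data$base[which.max(.data$weight)],
      ambiguous = sum(.data$weight == max(.data$weight)) > 1L,
      .groups = "drop"
    )
  ord <- c(.pos_label(sort(model$positions[model$positions < 0])), "stop",
           .pos_label(sort(model$positions[model$positions > 0])))
  pick <- pick[match(ord, pick$position), ]
  if (rna) pick$base <- chartr("T", "U", pick$base)
  non_stop <- pick$base[pick$position != "stop"]
  n_up <- sum(model$positions < 0)
  up <- paste(non_stop[seq_len(n_up)], collapse = "")
  dn <- paste(non_stop[seq_len(length(non_stop) - n_up) + n_up], collapse = "")
  stop_cd <- pick$base[pick$position == "stop"]
  attr(pick, "consensus") <- trimws(paste(up, stop_cd, dn))
  pick
}
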