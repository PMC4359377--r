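#' Default regularization strength and grid
#'
#' The default ridge regularization is `k = 10^0.3` (approximately 1.995),
#' the leave-one-out optimum on the original training contexts. The default
#' selection grid is `10^i` for `i = -3, -2.7, ..., 3` (step 0.3 in the
#' exponent, 21 values).
#'
#' @return `rtp_default_k()` a scalar; `rtp_k_grid()` a numeric vector of 21
#'   grid values.
#' @export
rtp_default_k <- function() 10^0.3

#' @rdname rtp_default_k
#' @export
rtp_k_grid <- function() 10^seq(-3, 3, by = 0.3)

# design matrix for a context tibble: indicator-encoded, unit-normalized
.design <- function(contexts, positions) {
  unit_normalize(encode_scc(contexts, positions = positions))
}

# stable symmetric solve of (X'X + kI) w = X'y
.ridge_solve <- function(X, y, k) {
  d <- ncol(X)
  A <- crossprod(X) + diag(k, d)
  drop(solve(A, crossprod(X, y)))
}

.y_values <- function(data, y) {
  if (is.character(y) && length(y) == 1L) {
    if (!y %in% names(data)) abort(sprintf("column '%s' not found", y))
    yv <- data[[y]]
  } else {
    yv <- y
  }
  if (!is.numeric(yv) || anyNA(yv)) abort("readthrough values must be numeric and non-missing")
  yv
}

#' Construct a readthrough-propensity model from raw weights
#'
#' Builds an `rtp_model` object from a tidy weight table -- the format
#' returned by [tidy()] on a fitted model and by `published_table("table2")`.
#' Norms are recomputed from the weights, so a model reconstructed from its
#' own tidy output scores identically.
#'
#' @param weights Tibble with columns `position` (character; context
#'   positions as "-6".."9" and "stop"), `base` (A/C/G/T, or TAA/TAG/TGA for
#'   the stop rows) and `weight`.
#' @param k Regularization strength the weights were obtained with.
#' @param y_units Unit of the training readthrough values ("percent" or
#'   "fraction"); affects predicted BTR only, never the normalized RTP score.
#' @return An object of class `rtp_model` with elements `weights` (named
#'   51-vector, canonical block order), `positions`, `k`, `weight_norm` (the
#'   Euclidean norm of the raw-weight stack) and `feature_divisor`
#'   (sqrt(number of active positions, stop included)).
#' @export
rtp_model <- function(weights, k = rtp_default_k(), y_units = "percent") {
  stopifnot(all(c("position", "base", "weight") %in% names(weights)))
  wfull <- setNames(numeric(51L), .vector_colnames())
  key <- ifelse(weights$position == "stop",
    paste0("stop_", weights$base),
    paste0(weights$position, "_", weights$base)
  )
  if (!all(key %in% names(wfull))) {
    abort(sprintf("unknown weight entries: %s",
                  paste(setdiff(key, names(wfull)), collapse = ", ")))
  }
  wfull[key] <- weights$weight
  positions <- sort(unique(as.integer(weights$position[weights$position != "stop"])))
  .new_rtp_model(wfull, positions, k, y_units = y_units)
}

.new_rtp_model <- function(weights, positions, k, y_units = "percent",
                           name = NULL, n_train = NA_integer_) {
  structure(
    list(
      weights = weights,
      positions = positions,
      k = k,
      weight_norm = sqrt(sum(weights^2)),
      feature_divisor = sqrt(length(positions) + 1L),
      y_units = y_units,
      name = name,
      n_train = n_train
    ),
    class = "rtp_model"
  )
}

#' Fit a ridge-regression readthrough-propensity model
#'
#' Fits the no-intercept ridge regression `w = (X'X + k I)^-1 X'y` on
#' unit-normalized indicator encodings of stop-codon contexts, where `y`
#' holds experimental basal readthrough values.
#'
#' @param data Context tibble (columns `upstream`, `stop`, `downstream`, or
#'   `scc`) with a readthrough column.
#' @param y Name of the readthrough column (default `"readthrough_pct"`) or
#'   a numeric vector.
#' @param positions Context positions to use; the stop is always included.
#' @param k Ridge regularization (> 0); see [rtp_default_k()].
#' @param y_units Unit label recorded in the model ("percent" or "fraction").
#' @return An `rtp_model` (see [rtp_model()]).
#' @export
#' @examples
#' train <- published_table("table1")
#' fit_ridge(train, positions = c(4, 5, 6))
fit_ridge <- function(data, y = "readthrough_pct", positions = scc_positions(),
                      k = rtp_default_k(), y_units = "percent") {
  yv <- .y_values(data, y)
  if (length(yv) < 2L) abort("need at least 2 training contexts")
  if (!is.numeric(k) || length(k) != 1L || k <= 0) abort("k must be a single positive number")
  X <- .design(data, positions)
  if (nrow(X) != length(yv)) abort("contexts and readthrough values differ in length")
  w <- .ridge_solve(X, yv, k)
  .new_rtp_model(setNames(w, colnames(X)), sort(unique(as.integer(positions))),
                 k, y_units = y_units, n_train = length(yv))
}

#' Leave-one-out cross-validation error of a ridge model
#'
#' Sum of squared deviations of held-out predictions from the known
#' readthrough values, where the prediction for context i comes from a model
#' fitted on all other contexts. Computed with the exact leave-one-out
#' identity for penalized linear smoothers, `e_i = (y_i - yhat_i)/(1 -
#' h_ii)`; it equals refitting n times from scratch.
#'
#' @inheritParams fit_ridge
#' @return The loo-CV SSE (scalar), with attribute `"predictions"`: a tibble
#'   of `y` and held-out `y_hat`, and attribute `"pearson"`: their
#'   correlation.
#' @export
loo_cv_sse <- function(data, y = "readthrough_pct", positions = scc_positions(),
                       k = rtp_default_k()) {
  yv <- .y_values(data, y)
  if (length(yv) < 3L) abort("leave-one-out needs at least 3 contexts")
  X <- .design(data, positions)
  A <- crossprod(X) + diag(k, ncol(X))
  H <- X %*% solve(A, t(X))
  h <- diag(H)
  fitted <- drop(H %*% yv)
  e_loo <- (yv - fitted) / (1 - h)
  preds <- yv - e_loo
  sse <- sum(e_loo^2)
  attr(sse, "predictions") <- tibble::tibble(y = yv, y_hat = preds)
  attr(sse, "pearson") <- if (stats::sd(preds) > 0 && stats::sd(yv) > 0) {
    cor(yv, preds)
  } else {
    NA_real_
  }
  sse
}

#' Select the ridge regularization by leave-one-out cross-validation
#'
#' Evaluates the loo-CV SSE over a grid of `k` values and returns the
#' minimizer; ties go to the smallest `k` evaluated.
#'
#' @inheritParams fit_ridge
#' @param grid Candidate `k` values; defaults to [rtp_k_grid()].
#' @return A list with `k` (selected), `sse` (its loo-CV SSE) and `results`
#'   (tibble of the full grid evaluation).
#' @export
select_k <- function(data, y = "readthrough_pct", positions = scc_positions(),
                     grid = rtp_k_grid()) {
  if (length(grid) == 0L) abort("empty k grid")
  grid <- sort(grid)
  sses <- purrr::map_dbl(grid, function(k) {
    as.numeric(loo_cv_sse(data, y = y, positions = positions, k = k))
  })
  best <- which(sses == min(sses))[1L] # sorted ascending: ties -> smallest k
  list(
    k = grid[best],
    sse = sses[best],
    results = tibble::tibble(k = grid, loo_sse = sses)
  )
}

# sum of matched raw weights for each context, under the model's positions
.raw_sum <- function(model, contexts) {
  V <- encode_scc(contexts, positions = model$positions)
  unname(drop(V %*% model$weights))
}

#' Predict basal readthrough and readthrough propensity
#'
#' `predict_btr()` returns the model-scale prediction `w.x` on the
#' unit-normalized feature vector, i.e. the sum of matched raw weights
#' divided by the feature divisor. `rtp_score()` additionally divides by the
#' Euclidean norm of the raw-weight stack, giving the dimensionless,
#' scale-free readthrough-propensity (RTP) score (equivalently: raw sum /
#' (weight norm x feature divisor)). RTP may be negative.
#'
#' @param model An `rtp_model`.
#' @param contexts Context tibble or character vector of context strings.
#' @return `predict_btr()`: numeric vector. `rtp_score()`: tibble with
#'   columns `scc`, `raw_sum`, `predicted_btr`, `rtp`.
#' @export
#' @examples
#' rtp_score(published_model("LINfs3"), "AAAAGACCTG TGA CTAGTGAGCT")
predict_btr <- function(model, contexts) {
  stopifnot(inherits(model, "rtp_model"))
  .raw_sum(model, contexts) / model$feature_divisor
}

#' @rdname predict_btr
#' @export
rtp_score <- function(model, contexts) {
  stopifnot(inherits(model, "rtp_model"))
  if (model$weight_norm <= 0) abort("model has zero weight norm; RTP is undefined")
  ctx <- .as_context_tbl(contexts)
  raw <- .raw_sum(model, ctx)
  tibble::tibble(
    scc = ctx$scc,
    raw_sum = raw,
    predicted_btr = raw / model$feature_divisor,
    rtp = raw / (model$weight_norm * model$feature_divisor)
  )
}

#' Published readthrough-propensity models
#'
#' The two published models bundled with the package: `LINiter` (all 12
#' context positions plus the stop; weight norm 0.0088, feature divisor
#' sqrt(13) ~ 3.6, combined RTP shortcut divisor 0.0317) and `LINfs3` (stop
#' plus positions +4..+6; weight norm 0.0063, divisor 2, shortcut 0.0126).
#' Both use `k = 10^0.3`. The intermediate `LIN` and `LINfs5` weights were
#' never published and are not available.
#'
#' @param name `"LINiter"` or `"LINfs3"`.
#' @return An `rtp_model`.
#' @export
#' @examples
#' glance(published_model("LINiter"))
published_model <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("LINiter", "LINfs3")) {
    abort("unknown model: published weights exist only for 'LINiter' and 'LINfs3'")
  }
  tab <- dplyr::filter(published_table("table2"), .data$model == name)
  m <- rtp_model(tab[c("position", "base", "weight")], k = rtp_default_k())
  m$name <- name
  m
}

#' @export
print.rtp_model <- function(x, ...) {
  cat("<rtp_model>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  positions:", paste(x$positions, collapse = " "), "+ stop\n")
  cat(sprintf("  k = %.4g, weight_norm = %.4g, feature_divisor = %.4g\n",
              x$k, x$weight_norm, x$feature_divisor))
  invisible(x)
}

#' Tidy and summarize readthrough-propensity models
#'
#' `tidy()` returns the active raw weights in long form (one row per
#' position/base, stop rows labelled `position = "stop"`); feeding the
#' result to [rtp_model()] reconstructs an identically scoring model.
#' `glance()` returns a one-row model summary.
#'
#' @param x An `rtp_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy rtp_model
#' @export
tidy.rtp_model <- function(x, ...) {
  nm <- names(x$weights)
  parts <- stringr::str_split_fixed(nm, "_", 2L)
  out <- tibble::tibble(position = parts[, 1L], base = parts[, 2L],
                        weight = unname(x$weights))
  active <- out$position == "stop" | out$position %in% .pos_label(x$positions)
  out[active, ]
}

#' @rdname tidy.rtp_model
#' @method glance rtp_model
#' @export
glance.rtp_model <- function(x, ...) {
  tibble::tibble(
    name = if (is.null(x$name)) NA_character_ else x$name,
    n_positions = length(x$positions) + 1L,
    k = x$k,
    weight_norm = x$weight_norm,
    feature_divisor = x$feature_divisor,
    shortcut_divisor = x$weight_norm * x$feature_divisor,
    n_train = x$n_train,
    y_units = x$y_units
  )
}

#' Serialize readthrough-propensity models as JSON
#'
#' The on-disk format mirrors the tidy weight layout: a JSON document with
#' the (position, base, weight) triples plus `k`, `positions` and the stored
#' norms. On load, norms are recomputed from the weights and checked.
#'
#' @param model An `rtp_model`.
#' @param path File path.
#' @export
write_rtp_model <- function(model, path) {
  stopifnot(inherits(model, "rtp_model"))
  doc <- list(
    type = "rtp_model",
    name = model$name,
    k = model$k,
    y_units = model$y_units,
    positions = model$positions,
    weight_norm = model$weight_norm,
    feature_divisor = model$feature_divisor,
    weights = tidy(model)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rtp_model
#' @export
read_rtp_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "rtp_model")) abort("not an rtp_model file")
  m <- rtp_model(tibble::as_tibble(doc$weights), k = doc$k,
                 y_units = if (is.null(doc$y_units)) "percent" else doc$y_units)
  if (!is.null(doc$weight_norm) &&
      abs(m$weight_norm - doc$weight_norm) > 1e-8 * max(1, doc$weight_norm)) {
    abort("stored weight_norm disagrees with recomputed norm; file corrupt?")
  }
  m$name <- doc$name
  m
}
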