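.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# canonical 300 column names: positions -15..-1, 20 amino acids each
.cterm_colnames <- function() {
  paste(rep(as.character(-15:-1), each = 20L), rep(.aa20, 15L), sep = "_")
}

#' Indicator-encode C-terminal peptides
#'
#' Encodes the last (up to) 15 residues of each peptide as binary indicators
#' over 15 C-terminal positions (-15..-1 from the terminus) x 20 amino
#' acids. Shorter peptides leave the leading blocks zero; the undefined
#' residue `'X'` (used for a recoded stop codon) leaves its block zero and
#' so contributes nothing to any score.
#'
#' @param peptides Character vector over the 20-letter amino-acid alphabet
#'   plus `X` (case-insensitive).
#' @return Numeric matrix, one row per peptide, 300 named columns.
#' @export
#' @examples
#' rowSums(encode_cterm(c("SKL", "XRL")))
encode_cterm <- function(peptides) {
  stopifnot(is.character(peptides), length(peptides) >= 1L)
  seqs <- toupper(gsub("\\s+", "", peptides))
  bad <- grepl(paste0("[^", paste(.aa20, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    abort(sprintf("illegal amino-acid character in: %s",
                  paste(unique(seqs[bad]), collapse = ", ")))
  }
  n <- length(seqs)
  m <- matrix(0, nrow = n, ncol = 300L, dimnames = list(NULL, .cterm_colnames()))
  tails <- substr(seqs, pmax(1L, nchar(seqs) - 14L), nchar(seqs))
  for (i in seq_len(n)) {
    aa <- strsplit(tails[i], "")[[1]]
    offs <- 15L - length(aa) + seq_along(aa) # 1..15 slot per residue
    hit <- match(aa, .aa20) # NA for 'X'
    keep <- !is.na(hit)
    m[i, (offs[keep] - 1L) * 20L + hit[keep]] <- 1
  }
  m
}

.pts1_labels <- function(data, label) {
  lv <- if (is.character(label) && length(label) == 1L) data[[label]] else label
  if (is.logical(lv)) lv <- ifelse(lv, 1, -1)
  if (!all(lv %in% c(-1, 1))) abort("labels must be +1 / -1 (or logical)")
  as.numeric(lv)
}

# deterministic stratified fold assignment: round-robin within class
.stratified_folds <- function(labels, folds) {
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) abort("every fold needs both classes; class too small")
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

# Platt-style sigmoid calibration of raw margin scores; slope constrained
# positive so the posterior is strictly increasing in the raw score
.platt_fit <- function(scores, labels) {
  np <- sum(labels > 0)
  nn <- sum(labels < 0)
  t <- ifelse(labels > 0, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    z <- exp(par[1L]) * (scores - par[2L])
    -sum(t * plogis(z, log.p = TRUE) + (1 - t) * plogis(-z, log.p = TRUE))
  }
  mid0 <- mean(c(mean(scores[labels > 0]), mean(scores[labels < 0])))
  sc <- stats::sd(scores)
  init <- c(log(1 / max(sc, 1e-6)), mid0)
  opt <- optim(init, nll, method = "BFGS", control = list(maxit = 500))
  list(slope = exp(opt$par[1L]), midpoint = opt$par[2L])
}

#' Fit a regularized least-squares classifier for PTS1 detection
#'
#' Trains ridge regression against +/-1 class labels (RLSC) on C-terminal
#' indicator vectors -- the same closed form `(X'X + kI) w = X'y` as the
#' readthrough-propensity models, unnormalized features. A monotone sigmoid
#' posterior map is calibrated on held-out cross-validation scores
#' (Platt-style) and the weights are then refitted on the full data.
#'
#' @param data Tibble with a peptide column and a label column (+1 =
#'   PTS1-positive, -1 = negative); both classes must be present.
#' @param peptide,label Column names (defaults `"peptide"`, `"label"`).
#' @param k Regularization; `NULL` selects it by `folds`-fold CV squared
#'   error over [rtp_k_grid()].
#' @param folds Folds used for k selection and calibration (default 5).
#' @return A `pts1_model`: list with `weights` (named 300-vector), `k`,
#'   `calibration` (slope, midpoint), `cv` (held-out scores used for
#'   calibration) and class counts.
#' @export
#' @examples
#' \donttest{
#' set <- gen_pts1_dataset(60, 120, seed = 1)
#' model <- fit_rlsc(set)
#' pts1_posterior(model, c("MAVSSKL", "MAVSSSI"))
#' }
fit_rlsc <- function(data, peptide = "peptide", label = "label", k = NULL,
                     folds = 5L) {
  y <- .pts1_labels(data, label)
  if (length(unique(y)) < 2L) abort("training needs both classes")
  X <- encode_cterm(data[[peptide]])
  # tiny classes cannot support held-out calibration: fall back to
  # calibrating on in-sample scores (fold 0 marks the degenerate case)
  folds <- min(folds, sum(y > 0), sum(y < 0))
  fold <- if (folds >= 2L) .stratified_folds(y, folds) else rep(0L, length(y))
  cv_scores <- function(kk) {
    if (folds < 2L) {
      return(drop(X %*% .ridge_solve(X, y, kk)))
    }
    s <- numeric(length(y))
    for (f in seq_len(folds)) {
      w <- .ridge_solve(X[fold != f, , drop = FALSE], y[fold != f], kk)
      s[fold == f] <- drop(X[fold == f, , drop = FALSE] %*% w)
    }
    s
  }
  if (is.null(k)) {
    grid <- rtp_k_grid()
    err <- purrr::map_dbl(grid, function(kk) sum((y - cv_scores(kk))^2))
    k <- grid[which.min(err)]
  }
  held <- cv_scores(k)
  cal <- .platt_fit(held, y)
  w <- .ridge_solve(X, y, k)
  structure(
    list(
      weights = setNames(w, colnames(X)),
      k = k,
      calibration = cal,
      cv = tibble::tibble(fold = fold, label = y, raw = held),
      n_pos = sum(y > 0),
      n_neg = sum(y < 0)
    ),
    class = "pts1_model"
  )
}

#' @export
print.pts1_model <- function(x, ...) {
  cat("<pts1_model>\n")
  cat(sprintf("  k = %.4g, trained on %d positives / %d negatives%s\n",
              x$k, x$n_pos, x$n_neg,
              if (x$n_neg > 3 * x$n_pos || x$n_pos > 3 * x$n_neg) " (imbalanced)" else ""))
  cat(sprintf("  calibration: slope %.4g, midpoint %.4g\n",
              x$calibration$slope, x$calibration$midpoint))
  invisible(x)
}

#' Score peptides with a PTS1 model
#'
#' `pts1_raw()` returns the raw RLSC margin score; `pts1_posterior()` maps
#' it through the fitted monotone sigmoid to a posterior probability of
#' peroxisomal targeting in [0, 1]. `pts1_score()` returns both as a tibble.
#'
#' @param model A `pts1_model`.
#' @param peptides Character vector of C-terminal peptides (`X` allowed).
#' @return Numeric vector (`pts1_raw`, `pts1_posterior`) or tibble
#'   (`pts1_score`).
#' @export
pts1_raw <- function(model, peptides) {
  stopifnot(inherits(model, "pts1_model"))
  drop(encode_cterm(peptides) %*% model$weights)
}

#' @rdname pts1_raw
#' @export
pts1_posterior <- function(model, peptides) {
  stopifnot(inherits(model, "pts1_model"))
  if (is.null(model$calibration)) abort("model is not calibrated")
  raw <- pts1_raw(model, peptides)
  plogis(model$calibration$slope * (raw - model$calibration$midpoint))
}

#' @rdname pts1_raw
#' @export
pts1_score <- function(model, peptides) {
  raw <- pts1_raw(model, peptides)
  tibble::tibble(
    peptide = peptides,
    raw = raw,
    posterior = plogis(model$calibration$slope * (raw - model$calibration$midpoint))
  )
}

#' Area under the ROC and precision/recall curves
#'
#' `auroc()` integrates the ROC curve by trapezoids over distinct score
#' thresholds (ties grouped, so it equals the pairwise-comparison
#' probability with half-credit for tied pairs). `auprc()` integrates
#' precision over recall increments (step integration).
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels +1 / -1 (or logical) true classes.
#' @return Scalar area.
#' @export
auroc <- function(scores, labels) {
  y <- .pts1_labels(tibble::tibble(), labels)
  stopifnot(length(scores) == length(y), any(y > 0), any(y < 0))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- as.numeric(y[ord] > 0)
  grp <- cumsum(!duplicated(s)) # distinct-threshold groups
  tp <- cumsum(pos)
  fp <- cumsum(1 - pos)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(1 - pos))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' @rdname auroc
#' @export
auprc <- function(scores, labels) {
  y <- .pts1_labels(tibble::tibble(), labels)
  stopifnot(length(scores) == length(y), any(y > 0), any(y < 0))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- as.numeric(y[ord] > 0)
  tp <- cumsum(pos)
  n_seen <- seq_along(pos)
  last <- which(!duplicated(cumsum(!duplicated(s)), fromLast = TRUE))
  precision <- tp[last] / n_seen[last]
  recall <- tp[last] / sum(pos)
  sum(diff(c(0, recall)) * precision)
}

#' Cross-validate a PTS1 classifier
#'
#' Stratified k-fold cross-validation of the RLSC: held-out raw scores are
#' pooled over folds and summarized as auROC and auPRC.
#'
#' @inheritParams fit_rlsc
#' @param folds Number of folds (>= 2); every fold contains both classes.
#' @param k Regularization (default [rtp_default_k()]).
#' @return List with `auROC`, `auPRC` and `scores` (tibble of fold, label,
#'   held-out raw score).
#' @export
cross_validate <- function(data, folds = 5L, k = rtp_default_k(),
                           peptide = "peptide", label = "label") {
  if (folds < 2L) abort("need at least 2 folds")
  y <- .pts1_labels(data, label)
  if (length(unique(y)) < 2L) abort("cross-validation needs both classes")
  X <- encode_cterm(data[[peptide]])
  fold <- .stratified_folds(y, folds)
  s <- numeric(length(y))
  for (f in seq_len(folds)) {
    w <- .ridge_solve(X[fold != f, , drop = FALSE], y[fold != f], k)
    s[fold == f] <- drop(X[fold == f, , drop = FALSE] %*% w)
  }
  list(
    auROC = auroc(s, y),
    auPRC = auprc(s, y),
    scores = tibble::tibble(fold = fold, label = y, raw = s)
  )
}

#' @rdname tidy.rtp_model
#' @method tidy pts1_model
#' @export
tidy.pts1_model <- function(x, ...) {
  parts <- stringr::str_split_fixed(names(x$weights), "_", 2L)
  tibble::tibble(position = as.integer(parts[, 1L]), aa = parts[, 2L],
                 weight = unname(x$weights))
}

#' @rdname tidy.rtp_model
#' @method glance pts1_model
#' @export
glance.pts1_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_pos = x$n_pos,
    n_neg = x$n_neg,
    slope = x$calibration$slope,
    midpoint = x$calibration$midpoint,
    cv_auROC = auroc(x$cv$raw, x$cv$label),
    cv_auPRC = auprc(x$cv$raw, x$cv$label)
  )
}

#' Serialize PTS1 models as JSON
#'
#' @param model A `pts1_model`.
#' @param path File path.
#' @export
write_pts1_model <- function(model, path) {
  stopifnot(inherits(model, "pts1_model"))
  doc <- list(
    type = "pts1_model",
    k = model$k,
    calibration = model$calibration,
    n_pos = model$n_pos,
    n_neg = model$n_neg,
    weights = tidy(model)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pts1_model
#' @export
read_pts1_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "pts1_model")) abort("not a pts1_model file")
  wfull <- setNames(numeric(300L), .cterm_colnames())
  key <- paste(doc$weights$position, doc$weights$aa, sep = "_")
  wfull[key] <- doc$weights$weight
  structure(
    list(
      weights = wfull,
      k = doc$k,
      calibration = as.list(doc$calibration),
      cv = NULL,
      n_pos = doc$n_pos,
      n_neg = doc$n_neg
    ),
    class = "pts1_model"
  )
}
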