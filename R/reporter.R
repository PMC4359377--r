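#' Reporter ratio with first-order error propagation
#'
#' The readthrough signal of a dual-reporter replicate is the luminescence /
#' fluorescence ratio `y = x2 / x1`; its SD follows from first-order
#' (Gaussian) propagation: `sd_y = sqrt(sd_x1^2 (x2/x1^2)^2 + sd_x2^2 /
#' x1^2)`.
#'
#' @param x1,x1_sd Blank-corrected fluorescence mean and SD (`x1 > 0`).
#' @param x2,x2_sd Blank-corrected luminescence mean and SD.
#' @return Tibble with columns `y` and `sd`.
#' @export
#' @examples
#' ratio_with_sd(2, 0.2, 1, 0.1)
ratio_with_sd <- function(x1, x1_sd, x2, x2_sd) {
  if (any(x1 <= 0)) abort("fluorescence signal x1 must be positive")
  if (any(c(x1_sd, x2_sd) < 0)) abort("SDs must be non-negative")
  y <- x2 / x1
  sd <- sqrt(x1_sd^2 * (x2 / x1^2)^2 + x2_sd^2 * (1 / x1)^2)
  tibble::tibble(y = y, sd = sd)
}

#' Normalize a reporter ratio to the no-stop control
#'
#' Expresses a construct's reporter ratio as percent of the no-stop control
#' ratio (`100 * y / y_c`), propagating both SDs through the ratio of
#' ratios.
#'
#' @param y,y_sd Construct ratio and SD.
#' @param control_y,control_sd Control ratio (> 0) and SD.
#' @return Tibble with columns `readthrough_pct` and `sd`.
#' @export
normalize_to_control <- function(y, y_sd, control_y, control_sd = 0) {
  if (any(control_y <= 0)) abort("control ratio must be positive")
  value <- 100 * y / control_y
  sd <- 100 * sqrt((y_sd / control_y)^2 + (y * control_sd / control_y^2)^2)
  tibble::tibble(readthrough_pct = value, sd = sd)
}

#' Inverse-variance weighted mean of replicate readthrough values
#'
#' Replicate values are combined with weights `w_i = 1 / sd_i^2`; the
#' weighted mean is `sum(y_i w_i) / sum(w_i)` with SD `sum(w_i)^-0.5`.
#' Replicates with zero SD would carry infinite weight and are rejected.
#'
#' @param values Replicate readthrough values.
#' @param sds Replicate SDs (all > 0).
#' @return Tibble with columns `mean` and `sd`.
#' @export
#' @examples
#' weighted_mean(c(1, 3), c(1, 0.5))
weighted_mean <- function(values, sds) {
  if (length(values) < 1L || length(values) != length(sds)) {
    abort("need matching non-empty values and sds")
  }
  if (any(sds <= 0)) abort("replicate SDs must be strictly positive (zero SD implies infinite weight)")
  w <- 1 / sds^2
  tibble::tibble(mean = sum(values * w) / sum(w), sd = sum(w)^-0.5)
}

#' Readthrough induction factor
#'
#' Fold-change of readthrough between treated and untreated estimates
#' (e.g. geneticin induction), with SD by first-order ratio propagation.
#'
#' @param treated,treated_sd Treated readthrough and SD.
#' @param untreated,untreated_sd Untreated readthrough (> 0) and SD.
#' @return Tibble with columns `factor` and `sd`.
#' @export
induction_factor <- function(treated, treated_sd, untreated, untreated_sd = 0) {
  if (any(untreated <= 0)) abort("untreated readthrough must be positive")
  f <- treated / untreated
  sd <- sqrt((treated_sd / untreated)^2 + (treated * untreated_sd / untreated^2)^2)
  tibble::tibble(factor = f, sd = sd)
}

#' Readthrough percentages from dual-reporter plate data
#'
#' Per replicate, subtracts blanks (if blank columns are present), forms the
#' luminescence/fluorescence ratio with propagated SD, combines replicates
#' by inverse-variance weighted mean, and normalizes every sample to the
#' no-stop control, which is set to 100%.
#'
#' @param plate Tibble with columns `sample_id`, `replicate`, `venus_mean`,
#'   `venus_sd`, `rluc_mean`, `rluc_sd`, optional `venus_blank`,
#'   `rluc_blank`.
#' @param control `sample_id` of the no-stop control (default `"pDRVL"`).
#' @return Tibble with `sample_id`, `readthrough_pct`, `sd`,
#'   `n_replicates`; the control row reads 100%.
#' @export
readthrough_from_plate <- function(plate, control = "pDRVL") {
  need <- c("sample_id", "replicate", "venus_mean", "venus_sd",
            "rluc_mean", "rluc_sd")
  if (!all(need %in% names(plate))) {
    abort(sprintf("plate table needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!control %in% plate$sample_id) abort(sprintf("control '%s' not on plate", control))
  venus <- plate$venus_mean - if ("venus_blank" %in% names(plate)) plate$venus_blank else 0
  rluc <- plate$rluc_mean - if ("rluc_blank" %in% names(plate)) plate$rluc_blank else 0
  ratios <- ratio_with_sd(venus, plate$venus_sd, rluc, plate$rluc_sd)
  per_sample <- tibble::tibble(sample_id = plate$sample_id,
                               y = ratios$y, sd = ratios$sd) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      wm = list(weighted_mean(.data$y, .data$sd)),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::unnest("wm")
  ctrl <- per_sample[per_sample$sample_id == control, ]
  norm <- normalize_to_control(per_sample$mean, per_sample$sd, ctrl$mean, ctrl$sd)
  tibble::tibble(
    sample_id = per_sample$sample_id,
    readthrough_pct = norm$readthrough_pct,
    sd = norm$sd,
    n_replicates = per_sample$n_replicates
  )
}
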