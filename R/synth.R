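#' Planted readthrough-propensity weights
#'
#' Draws a random raw-weight stack for synthetic training sets. Within each
#' position block (and the stop block) the base effects are centred to sum
#' to zero and a common gauge constant is added so that every block sums to
#' `block_sum`. Equal block sums make the weights identifiable: the
#' indicator design has one linear dependency per position block (the four
#' indicators of a block co-occur), so ridge regression can only recover
#' weights up to block-constant shifts; equal-block-sum weights are exactly
#' the representative it converges to as `k -> 0`. A positive `block_sum`
#' also keeps the planted responses positive, like readthrough percentages.
#'
#' @param positions Context positions that carry base effects; all blocks
#'   receive the gauge constant.
#' @param effect_sd SD of the per-base effects before centring.
#' @param block_sum Common sum of every block's weights.
#' @param seed Integer seed; the function is a pure function of its
#'   arguments.
#' @return Tidy weight tibble (`position`, `base`, `weight`) covering all 12
#'   context positions and the stop, suitable for [rtp_model()].
#' @export
planted_scc_weights <- function(positions = scc_positions(), effect_sd = 0.01,
                                block_sum = 0.2, seed = 1) {
  withr::local_seed(seed)
  rows <- purrr::map_dfr(scc_positions(), function(p) {
    eff <- if (p %in% positions) rnorm(4L, 0, effect_sd) else numeric(4L)
    eff <- eff - mean(eff)
    tibble::tibble(position = .pos_label(p), base = .bases,
                   weight = eff + block_sum / 4)
  })
  stop_eff <- rnorm(3L, 0, effect_sd)
  stop_eff <- stop_eff - mean(stop_eff)
  dplyr::bind_rows(
    rows,
    tibble::tibble(position = "stop", base = .stops,
                   weight = stop_eff + block_sum / 3)
  )
}

#' Synthetic stop-codon-context training sets
#'
#' Generates `n` contexts with every position (and the stop) drawn
#' uniformly, and responses from a planted linear model on the
#' unit-normalized indicator encoding plus Gaussian noise: `y = w.x + eps`.
#' With `noise_sd = 0` the responses equal the planted signal exactly.
#'
#' @param n Number of contexts (>= 2).
#' @param planted_weights Tidy weight tibble (see [planted_scc_weights()]);
#'   `NULL` uses `planted_scc_weights(seed = seed)`.
#' @param noise_sd Response noise SD (>= 0). The default, 0.004, is about
#'   40% of the planted signal SD under the default weights -- a moderate
#'   noise regime.
#' @param seed Integer seed.
#' @return Tibble with `context_id`, context columns, `signal` (noiseless
#'   response) and `readthrough_pct` (= signal + noise); attributes
#'   `"planted_model"` (an `rtp_model` built from the planted weights),
#'   `"noise_sd"`, `"seed"`.
#' @export
#' @examples
#' gen_scc_dataset(5, seed = 42)
gen_scc_dataset <- function(n, planted_weights = NULL, noise_sd = 0.004,
                            seed = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 2L) abort("need n >= 2 contexts")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (is.null(planted_weights)) planted_weights <- planted_scc_weights(seed = seed)
  model <- rtp_model(planted_weights, y_units = "synthetic")
  withr::local_seed(seed)
  n <- as.integer(n)
  up <- purrr::map_chr(seq_len(n), ~ paste(sample(.bases, 6L, replace = TRUE), collapse = ""))
  dn <- purrr::map_chr(seq_len(n), ~ paste(sample(.bases, 6L, replace = TRUE), collapse = ""))
  st <- sample(.stops, n, replace = TRUE)
  ctx <- tibble::tibble(
    context_id = sprintf("synth_%04d", seq_len(n)),
    upstream = up, stop = st, downstream = dn,
    scc = paste0(up, st, dn)
  )
  signal <- predict_btr(model, ctx)
  out <- dplyr::mutate(ctx, signal = signal,
                       readthrough_pct = signal + rnorm(n, 0, noise_sd))
  attr(out, "planted_model") <- model
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

.random_peptide <- function(len) {
  paste(sample(.aa20, len, replace = TRUE), collapse = "")
}

#' Synthetic labelled C-terminal peptide sets
#'
#' Positives end in one of the supplied PTS1-like tripeptide motifs
#' (sampled uniformly); negatives are random peptides whose terminal
#' tripeptide avoids every motif. Classes are separable by construction.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param motifs Terminal tripeptides marking positives; defaults to four
#'   canonical PTS1 variants.
#' @param length_range Peptide length range (uniform integer draw).
#' @param seed Integer seed.
#' @return Tibble with `peptide_id`, `peptide`, `label` (+1 / -1).
#' @export
#' @examples
#' gen_pts1_dataset(3, 3, seed = 7)
gen_pts1_dataset <- function(n_pos, n_neg, motifs = c("SKL", "SRL", "ARL", "AKL"),
                             length_range = c(8L, 15L), seed = 1) {
  if (n_pos < 1L || n_neg < 1L) abort("need at least one example per class")
  motifs <- toupper(motifs)
  if (any(nchar(motifs) != 3L)) abort("motifs must be tripeptides")
  if (length(unique(motifs)) >= 8000L) abort("motif list covers all tripeptides; no valid negatives")
  withr::local_seed(seed)
  lens <- function(n) sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  pos <- purrr::map_chr(lens(n_pos), function(l) {
    paste0(.random_peptide(max(0L, l - 3L)), sample(motifs, 1L))
  })
  neg <- purrr::map_chr(lens(n_neg), function(l) {
    for (i in 1:1000) {
      p <- .random_peptide(l)
      if (!substr(p, l - 2L, l) %in% motifs) return(p)
    }
    abort("could not generate a motif-free negative")
  })
  tibble::tibble(
    peptide_id = c(sprintf("pos_%04d", seq_len(n_pos)),
                   sprintf("neg_%04d", seq_len(n_neg))),
    peptide = c(pos, neg),
    label = rep(c(1, -1), c(n_pos, n_neg))
  )
}

.sense_codons <- function() setdiff(names(.CODONS), .stops)

# random CDS of n_aa sense codons (ATG first) plus a random stop
.random_cds <- function(n_aa) {
  paste0("ATG",
         paste(sample(.sense_codons(), n_aa - 1L, replace = TRUE), collapse = ""),
         sample(.stops, 1L))
}

#' Planted readthrough candidate mimicking a hidden-PTS1 transcript
#'
#' The default planted transcript carries the high-readthrough context motif
#' (stop TGA, downstream starting CTAG) and an 18-nt extension encoding six
#' residues ending in the PTS1 tripeptide SRL, terminated by an in-frame
#' stop -- a 7-residue readthrough extension once the recoded stop ('X') is
#' prefixed.
#'
#' @param id Transcript id.
#' @param n_aa Protein length in amino acids (>= 15).
#' @return One-row transcript tibble (call inside a seeded context for
#'   reproducibility).
#' @keywords internal
.planted_transcript <- function(id = "planted_1", n_aa = 30L) {
  ext <- "CTAGAAACAAGCAGACTG" # L E T S R L; starts CTA, +7 = G
  filler_len <- 300L - nchar(ext) - 3L
  filler <- paste(sample(.bases, filler_len, replace = TRUE), collapse = "")
  cds <- paste0("ATG",
                paste(sample(.sense_codons(), n_aa - 1L, replace = TRUE), collapse = ""),
                "TGA")
  tibble::tibble(id = id, cds = cds, downstream = paste0(ext, "TAA", filler))
}

#' Synthetic toy transcriptomes with planted readthrough candidates
#'
#' Builds `n_decoys` well-formed decoy transcripts (random codon usage,
#' 20-50 aa, random stop, 300 nt downstream) plus planted candidates
#' carrying the high-readthrough context motif and a PTS1-terminated
#' extension (see [gen_pts1_dataset()] motifs). Decoys are rejection-sampled
#' so that none carries the TGA-CTA context motif and none of their
#' C-terminal scan windows ends in a PTS1 motif; all records pass
#' [filter_transcripts()] by construction.
#'
#' @param n_decoys Number of decoys (>= 0).
#' @param n_planted Number of planted candidates (default 1).
#' @param avoid_motifs Terminal tripeptides decoys must avoid.
#' @param seed Integer seed.
#' @return Transcript tibble; attribute `"planted_ids"`.
#' @export
#' @examples
#' gen_transcriptome(3, seed = 3)
gen_transcriptome <- function(n_decoys, n_planted = 1L,
                              avoid_motifs = c("SKL", "SRL", "ARL", "AKL"),
                              seed = 1) {
  if (n_decoys < 0L) abort("n_decoys must be >= 0")
  withr::local_seed(seed)
  planted <- if (n_planted > 0L) {
    purrr::map_dfr(seq_len(n_planted), function(i) {
      .planted_transcript(sprintf("planted_%03d", i),
                          n_aa = sample(20:50, 1L))
    })
  } else {
    tibble::tibble(id = character(0), cds = character(0),
                   downstream = character(0))
  }
  decoys <- purrr::map_dfr(seq_len(n_decoys), function(i) {
    for (try in 1:1000) {
      n_aa <- sample(20:50, 1L)
      cds <- .random_cds(n_aa)
      down <- paste(sample(.bases, 300L, replace = TRUE), collapse = "")
      rec <- tibble::tibble(id = sprintf("decoy_%05d", i), cds = cds,
                            downstream = down)
      stop_cd <- substr(cds, nchar(cds) - 2L, nchar(cds))
      if (stop_cd == "TGA" && substr(down, 1L, 3L) == "CTA") next
      ext <- find_extension(rec)
      tail3 <- if (is.na(ext$extension_nt)) {
        protein <- sub("\\*$", "", translate_cds(cds))
        substr(protein, nchar(protein) - 2L, nchar(protein))
      } else {
        window <- paste0(sub("\\*$", "", translate_cds(cds)), ext$extension_aa)
        substr(window, nchar(window) - 2L, nchar(window))
      }
      if (tail3 %in% avoid_motifs) next
      return(rec)
    }
    abort("could not generate a motif-free decoy")
  })
  out <- dplyr::bind_rows(planted, decoys)
  attr(out, "planted_ids") <- planted$id
  out
}
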