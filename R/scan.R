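# standard genetic code, DNA codons; '*' marks stop
.codon_table <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  aa <- setNames(rep(NA_character_, 64L), codons)
  assign_aa <- function(aa_letter, cods) aa[cods] <<- aa_letter
  assign_aa("F", c("TTT", "TTC")); assign_aa("L", c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"))
  assign_aa("I", c("ATT", "ATC", "ATA")); assign_aa("M", "ATG")
  assign_aa("V", c("GTT", "GTC", "GTA", "GTG"))
  assign_aa("S", c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"))
  assign_aa("P", c("CCT", "CCC", "CCA", "CCG"))
  assign_aa("T", c("ACT", "ACC", "ACA", "ACG"))
  assign_aa("A", c("GCT", "GCC", "GCA", "GCG"))
  assign_aa("Y", c("TAT", "TAC")); assign_aa("*", c("TAA", "TAG", "TGA"))
  assign_aa("H", c("CAT", "CAC")); assign_aa("Q", c("CAA", "CAG"))
  assign_aa("N", c("AAT", "AAC")); assign_aa("K", c("AAA", "AAG"))
  assign_aa("D", c("GAT", "GAC")); assign_aa("E", c("GAA", "GAG"))
  assign_aa("C", c("TGT", "TGC")); assign_aa("W", "TGG")
  assign_aa("R", c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
  assign_aa("G", c("GGT", "GGC", "GGA", "GGG"))
  aa
}
.CODONS <- .codon_table()

.split_codons <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character(0))
  substring(nt, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
}

#' Translate a coding nucleotide string
#'
#' Standard-genetic-code translation of in-frame codons; stop codons
#' translate to `*`. Trailing incomplete codons are an error.
#'
#' @param nt Character vector of nucleotide strings (length divisible by 3).
#' @return Character vector of peptide strings.
#' @export
translate_cds <- function(nt) {
  nt <- .canon_nt(nt)
  .check_alphabet(nt, "coding sequence")
  if (any(nchar(nt) %% 3L != 0L)) abort("sequence length not divisible by 3")
  vapply(nt, function(s) paste(.CODONS[.split_codons(s)], collapse = ""), "",
         USE.NAMES = FALSE)
}

.as_transcript_tbl <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("id", "cds", "downstream")
  if (!all(need %in% names(records))) {
    abort("transcript records need columns id, cds, downstream")
  }
  tibble::as_tibble(records)
}

#' Filter transcript records for readthrough scanning
#'
#' Removes records that cannot be scanned: undetermined nucleotides
#' (non-ACGT) anywhere, CDS length not a multiple of 3 or terminal codon not
#' a stop ("incomplete"), protein shorter than 15 aa excluding the stop
#' ("short"), or fewer than 6 nt of downstream sequence (the +4..+9 context
#' cannot be assembled). Filtering is total: bad records are logged, never
#' errors.
#'
#' @param records Tibble with columns `id`, `cds` (including the stop
#'   codon), `downstream` (up to 300 nt after the stop).
#' @return The kept records, with attribute `"removal_log"`: a tibble of
#'   `id` and `reason` (accessible via [removal_log()]).
#' @export
filter_transcripts <- function(records) {
  rec <- .as_transcript_tbl(records)
  rec$cds <- .canon_nt(rec$cds)
  rec$downstream <- .canon_nt(rec$downstream)
  reason <- rep(NA_character_, nrow(rec))
  bad_nt <- grepl("[^ACGT]", rec$cds) | grepl("[^ACGT]", rec$downstream)
  reason[bad_nt] <- "undetermined"
  frame_ok <- nchar(rec$cds) %% 3L == 0L & nchar(rec$cds) >= 3L
  last_codon <- ifelse(frame_ok, substr(rec$cds, nchar(rec$cds) - 2L, nchar(rec$cds)), "")
  incomplete <- !frame_ok | !last_codon %in% .stops
  reason[is.na(reason) & incomplete] <- "incomplete"
  short <- nchar(rec$cds) / 3L - 1L < 15L
  reason[is.na(reason) & short] <- "short"
  reason[is.na(reason) & nchar(rec$downstream) < 6L] <- "short_downstream"
  kept <- rec[is.na(reason), ]
  attr(kept, "removal_log") <- tibble::tibble(
    id = rec$id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  kept
}

#' @rdname filter_transcripts
#' @param x A tibble returned by [filter_transcripts()] or
#'   [scan_transcriptome()].
#' @export
removal_log <- function(x) {
  lg <- attr(x, "removal_log")
  if (is.null(lg)) tibble::tibble(id = character(0), reason = character(0)) else lg
}

#' Aggregate transcripts with identical 3' termini
#'
#' Records whose terminal window -- the last 45 CDS nucleotides plus the
#' downstream sequence -- is identical are collapsed to one representative
#' (the lexicographically smallest id); all member ids are retained in
#' `aggregated_ids`. Idempotent.
#'
#' @param records Filtered transcript tibble.
#' @return Representative records with an `aggregated_ids` column
#'   (comma-separated member ids).
#' @export
dedupe_termini <- function(records) {
  rec <- .as_transcript_tbl(records)
  if ("aggregated_ids" %in% names(rec)) {
    members <- strsplit(rec$aggregated_ids, ",", fixed = TRUE)
  } else {
    members <- as.list(rec$id)
  }
  key <- paste0(
    substr(rec$cds, pmax(1L, nchar(rec$cds) - 44L), nchar(rec$cds)),
    "|", rec$downstream
  )
  rec$`..key` <- key
  rec$`..members` <- members
  out <- rec |>
    dplyr::group_by(.data$`..key`) |>
    dplyr::summarise(
      cds = .data$cds[order(.data$id)[1L]],
      downstream = .data$downstream[order(.data$id)[1L]],
      aggregated_ids = paste(sort(unique(unlist(.data$`..members`))), collapse = ","),
      id = sort(.data$id)[1L],
      .groups = "drop"
    ) |>
    dplyr::select("id", "cds", "downstream", "aggregated_ids", "..key") |>
    dplyr::select(-"..key") |>
    dplyr::arrange(.data$id)
  out
}

#' Detect readthrough extensions
#'
#' For each transcript, assembles the stop-codon context (last 9 CDS nt plus
#' the first 6 downstream nt) and scans the downstream sequence in frame for
#' the next stop codon. The extension runs from the first nucleotide after
#' the annotated stop up to, but excluding, that next stop; its translation
#' is prefixed with `'X'` for the unknowable amino acid inserted at the
#' recoded stop. Transcripts without an in-frame stop in the downstream
#' window have no extension (`extension_nt` is `NA`).
#'
#' @param records Filtered transcript tibble (every `downstream` >= 6 nt).
#' @return The records with added columns `upstream`, `stop`, `downstream_ctx`,
#'   `scc` (15-nt context), `extension_nt` and `extension_aa`.
#' @export
#' @examples
#' find_extension(tibble::tibble(
#'   id = "t1",
#'   cds = paste0("ATG", strrep("GCT", 15), "TGA"),
#'   downstream = "CTAGAAACAAGCAGACTGTAAGGGCC"
#' ))
find_extension <- function(records) {
  rec <- .as_transcript_tbl(records)
  rec$cds <- .canon_nt(rec$cds)
  rec$downstream <- .canon_nt(rec$downstream)
  if (any(nchar(rec$downstream) < 6L)) {
    abort("downstream too short to assemble the +4..+9 context; filter first")
  }
  n <- nchar(rec$cds)
  scc_text <- paste0(substr(rec$cds, n - 8L, n), substr(rec$downstream, 1L, 6L))
  ctx <- parse_scc(scc_text, flank = 6L)
  ext <- purrr::map(rec$downstream, function(d) {
    codons <- .split_codons(d)
    stop_at <- which(codons %in% .stops)
    if (length(stop_at) == 0L) {
      return(list(nt = NA_character_, aa = NA_character_))
    }
    first <- stop_at[1L]
    nt <- if (first == 1L) "" else paste(codons[seq_len(first - 1L)], collapse = "")
    list(nt = nt, aa = paste0("X", if (nzchar(nt)) translate_cds(nt) else ""))
  })
  dplyr::bind_cols(
    rec,
    tibble::tibble(
      upstream = ctx$upstream,
      stop = ctx$stop,
      downstream_ctx = ctx$downstream,
      scc = ctx$scc,
      extension_nt = purrr::map_chr(ext, "nt"),
      extension_aa = purrr::map_chr(ext, "aa")
    )
  )
}

#' Min-max scale scores to the unit interval
#'
#' `(x - min) / (max - min)`; a degenerate all-equal input maps to all
#' zeros. Used to make readthrough-propensity scores non-negative (RTP+)
#' before multiplication with PTS1 posteriors. The scaling is computed over
#' the scanned set, so ranks depend on the input universe.
#'
#' @param x Numeric vector.
#' @return Numeric vector in [0, 1].
#' @export
scale_rtp_unit <- function(x) {
  if (length(x) == 0L) abort("empty score vector")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Rank extension candidates by product score
#'
#' Multiplies the unit-scaled readthrough propensity (`rtp_plus`) with the
#' PTS1 posterior into `product_score`, sorts descending (ties by id), adds
#' 1-based ranks, and records the half-max rank: the first rank whose score
#' falls below 50% of the maximum.
#'
#' @param candidates Tibble with columns `id`, `rtp_plus`, `pts1_posterior`.
#' @return The ranked tibble with `product_score` and `rank`; attribute
#'   `"half_max_rank"`.
#' @export
rank_candidates <- function(candidates) {
  stopifnot(all(c("id", "rtp_plus", "pts1_posterior") %in% names(candidates)))
  out <- candidates |>
    dplyr::mutate(product_score = .data$rtp_plus * .data$pts1_posterior) |>
    dplyr::arrange(dplyr::desc(.data$product_score), .data$id) |>
    dplyr::mutate(rank = dplyr::row_number())
  half <- which(out$product_score < 0.5 * max(out$product_score))
  attr(out, "half_max_rank") <- if (length(half)) half[1L] else NA_integer_
  out
}

#' Scan a transcript set for PTS1-bearing readthrough extensions
#'
#' The full pipeline: filter, aggregate identical 3' termini, detect
#' readthrough extensions, score the stop-codon context with the
#' readthrough-propensity models, scale the ranking model's RTP to [0, 1]
#' across the scanned set (RTP+), score the extended C-terminus (last 15
#' residues of protein + extension, `'X'` at the recoded stop) with the PTS1
#' model, and rank by `RTP+ x PTS1`. Candidates without an extension get
#' PTS1 posterior 0 and hence product 0.
#'
#' @param records Transcript tibble (`id`, `cds`, `downstream`).
#' @param pts1_model A fitted [`pts1_model`][fit_rlsc].
#' @param rtp_models Named list of `rtp_model`s to score with; defaults to
#'   the published LINiter and LINfs3 models.
#' @param rank_by Name of the model whose RTP is scaled into `rtp_plus`
#'   (default `"LINiter"`).
#' @return A `readthrough_scan` tibble with columns `id`, `scc`,
#'   `extension_nt`, `extension_aa`, one `rtp_<model>` column per model,
#'   `rtp_plus`, `pts1_posterior`, `product_score`, `rank`,
#'   `aggregated_ids`; attributes `half_max_rank`, `removal_log`,
#'   `rank_model`.
#' @export
scan_transcriptome <- function(records, pts1_model,
                               rtp_models = list(
                                 LINiter = published_model("LINiter"),
                                 LINfs3 = published_model("LINfs3")
                               ),
                               rank_by = "LINiter") {
  if (!rank_by %in% names(rtp_models)) {
    abort("rank_by must name one of rtp_models")
  }
  kept <- filter_transcripts(records)
  log <- removal_log(kept)
  reps <- dedupe_termini(kept)
  cand <- find_extension(reps)
  ctx <- parse_scc(cand$scc)
  for (nm in names(rtp_models)) {
    cand[[paste0("rtp_", nm)]] <- rtp_score(rtp_models[[nm]], ctx)$rtp
  }
  cand$rtp_plus <- scale_rtp_unit(cand[[paste0("rtp_", rank_by)]])
  protein <- sub("\\*$", "", translate_cds(cand$cds))
  has_ext <- !is.na(cand$extension_nt)
  cterm <- paste0(protein, ifelse(has_ext, cand$extension_aa, ""))
  post <- numeric(nrow(cand))
  if (any(has_ext)) {
    post[has_ext] <- pts1_posterior(pts1_model, cterm[has_ext])
  }
  cand$pts1_posterior <- post
  out <- rank_candidates(cand)
  keep <- c("id", "scc", "extension_nt", "extension_aa",
            paste0("rtp_", names(rtp_models)), "rtp_plus",
            "pts1_posterior", "product_score", "rank", "aggregated_ids")
  res <- out[intersect(keep, names(out))]
  attr(res, "half_max_rank") <- attr(out, "half_max_rank")
  attr(res, "removal_log") <- log
  attr(res, "rank_model") <- rank_by
  class(res) <- c("readthrough_scan", class(res))
  res
}

#' Count transcripts matching a stop-codon-context motif
#'
#' Counts representatives whose stop codon and downstream context match a
#' pattern such as stop `TGA` followed by `CTA` (optionally `CTAG`).
#'
#' @param records Filtered (and typically deduplicated) transcript tibble,
#'   or any tibble with `stop` and `downstream`/`downstream_ctx` columns.
#' @param stop Stop triplet to match (3 ACGT characters), or `NULL` for any.
#' @param downstream_prefix Nucleotides required from +4 on (1-6 ACGT
#'   characters), or `NULL` for any.
#' @return Integer count.
#' @export
motif_count <- function(records, stop = NULL, downstream_prefix = NULL) {
  rec <- tibble::as_tibble(records)
  if (!"stop" %in% names(rec)) {
    rec <- find_extension(filter_transcripts(rec))
  }
  down <- if ("downstream_ctx" %in% names(rec)) rec$downstream_ctx else rec$downstream
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(stop)) {
    stop <- .canon_nt(stop)
    if (nchar(stop) != 3L || grepl("[^ACGT]", stop)) abort("malformed stop pattern")
    keep <- keep & rec$stop == stop
  }
  if (!is.null(downstream_prefix)) {
    pfx <- .canon_nt(downstream_prefix)
    if (nchar(pfx) < 1L || nchar(pfx) > 6L || grepl("[^ACGT]", pfx)) {
      abort("malformed downstream pattern")
    }
    keep <- keep & substr(down, 1L, nchar(pfx)) == pfx
  }
  sum(keep)
}

#' Read transcripts from FASTA with a declared CDS/downstream split
#'
#' Reads a FASTA of concatenated CDS + downstream sequence and splits each
#' record either at a per-transcript CDS length (companion table) or at a
#' fixed downstream length counted from the 3' end.
#'
#' @param path FASTA file.
#' @param cds_lengths Optional tibble (`id`, `cds_length`) or path to a TSV
#'   with those columns.
#' @param downstream_length Fixed downstream length used when `cds_lengths`
#'   is absent (default 300).
#' @return Transcript tibble (`id`, `cds`, `downstream`).
#' @export
read_transcript_fasta <- function(path, cds_lengths = NULL,
                                  downstream_length = 300L) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  full <- unname(as.character(seqs))
  if (!is.null(cds_lengths)) {
    if (is.character(cds_lengths)) {
      cds_lengths <- readr::read_tsv(cds_lengths, show_col_types = FALSE)
    }
    len <- cds_lengths$cds_length[match(ids, cds_lengths$id)]
    if (anyNA(len)) abort("cds_lengths missing for some FASTA records")
  } else {
    len <- pmax(0L, nchar(full) - as.integer(downstream_length))
  }
  tibble::tibble(
    id = ids,
    cds = substr(full, 1L, len),
    downstream = substr(full, len + 1L, nchar(full))
  )
}

#' Write transcripts to FASTA
#'
#' Writes `cds` and `downstream` concatenated, one record per transcript.
#'
#' @param records Transcript tibble.
#' @param path Output FASTA path.
#' @export
write_transcript_fasta <- function(records, path) {
  rec <- .as_transcript_tbl(records)
  lines <- as.vector(rbind(paste0(">", rec$id), paste0(rec$cds, rec$downstream)))
  writeLines(lines, path)
  invisible(path)
}
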