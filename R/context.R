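#' Stop-codon context positions
#'
#' The twelve nucleotide positions flanking the stop codon that enter the
#' readthrough-propensity models: six upstream (-6..-1) and six downstream
#' (+4..+9). The stop codon itself occupies positions +1..+3 and is always
#' modelled as a single 3-way categorical position; it is never part of this
#' vector.
#'
#' @return Integer vector `c(-6:-1, 4:9)` in canonical block order.
#' @export
#' @examples
#' scc_positions()
scc_positions <- function() {
  c(-6L:-1L, 4L:9L)
}

# canonical labels used in encodings, model weights and serialized files
.pos_label <- function(p) as.character(p)

.bases <- c("A", "C", "G", "T")
.stops <- c("TAA", "TAG", "TGA")

# canonical 51 column names: 12 blocks of 4 (A,C,G,T), then 3 stop indicators
.vector_colnames <- function() {
  c(
    paste(rep(.pos_label(scc_positions()), each = 4L), rep(.bases, 12L), sep = "_"),
    paste("stop", .stops, sep = "_")
  )
}

.canon_nt <- function(x) {
  x <- toupper(gsub("\\s+", "", x))
  chartr("U", "T", x)
}

.check_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf(
      "non-nucleotide character in %s: %s",
      what, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Parse stop-codon contexts
#'
#' Parses one or more stop-codon context (SCC) strings of the form used in
#' experimental tables -- a stop triplet centred in symmetric flanks, e.g.
#' `"AAAAGACCTG TGA CTAGTGAGCT"` (10-nt flanks). Whitespace is ignored, RNA
#' input (`U`) is canonicalized to DNA (`T`), and flanks wider than 6 nt are
#' trimmed symmetrically to the modelled -6..+9 window.
#'
#' @param text Character vector of context strings (flank + stop + flank).
#' @param flank Flank width in nucleotides declared by the input (>= 6).
#'   `NULL` (default) infers it from the string length.
#' @return A tibble with one row per context: `upstream` (6 nt, positions
#'   -6..-1), `stop` (the stop triplet), `downstream` (6 nt, +4..+9) and
#'   `scc` (the canonical 15-nt string).
#' @export
#' @examples
#' parse_scc("AAAAGACCTG TGA CTAGTGAGCT")
parse_scc <- function(text, flank = NULL) {
  stopifnot(is.character(text), length(text) >= 1L)
  seqs <- .canon_nt(text)
  .check_alphabet(seqs, "context")
  len <- nchar(seqs)
  if (is.null(flank)) {
    fl <- (len - 3L) / 2L
    if (any(fl != floor(fl))) {
      abort("cannot infer flank: context length minus the stop triplet is odd")
    }
    fl <- as.integer(fl)
  } else {
    fl <- rep_len(as.integer(flank), length(seqs))
    if (any(len != 2L * fl + 3L)) {
      abort("context length does not match the declared flank")
    }
  }
  if (any(fl < 6L)) {
    abort("insufficient flanks: at least 6 nucleotides are required on each side of the stop")
  }
  stop_cd <- substr(seqs, fl + 1L, fl + 3L)
  bad <- !stop_cd %in% .stops
  if (any(bad)) {
    abort(sprintf(
      "stop triplet not in {TAA, TAG, TGA}: %s",
      paste(unique(stop_cd[bad]), collapse = ", ")
    ))
  }
  up <- substr(seqs, fl - 5L, fl)
  down <- substr(seqs, fl + 4L, fl + 9L)
  tibble::tibble(
    upstream = up,
    stop = stop_cd,
    downstream = down,
    scc = paste0(up, stop_cd, down)
  )
}

# accept either a parsed context tibble or raw context strings
.as_context_tbl <- function(contexts) {
  if (is.character(contexts)) {
    return(parse_scc(contexts))
  }
  stopifnot(is.data.frame(contexts))
  if (!all(c("upstream", "stop", "downstream") %in% names(contexts))) {
    if ("scc" %in% names(contexts)) {
      return(parse_scc(contexts$scc))
    }
    abort("contexts must have columns upstream/stop/downstream or scc")
  }
  up <- .canon_nt(contexts$upstream)
  dn <- .canon_nt(contexts$downstream)
  st <- .canon_nt(contexts$stop)
  .check_alphabet(c(up, dn), "context")
  if (any(nchar(up) != 6L) || any(nchar(dn) != 6L)) {
    abort("upstream and downstream must each be exactly 6 nucleotides")
  }
  if (any(!st %in% .stops)) abort("stop triplet not in {TAA, TAG, TGA}")
  tibble::tibble(upstream = up, stop = st, downstream = dn,
                 scc = paste0(up, st, dn))
}

#' Indicator-encode stop-codon contexts
#'
#' Encodes contexts as 51-dimensional binary indicator vectors: 12 blocks of
#' 4 entries (bases A, C, G, T) for positions -6..-1 and +4..+9 in canonical
#' order, followed by 3 entries for the stop codon (TAA, TAG, TGA). Blocks
#' for positions outside `positions` are all-zero; the stop is always
#' encoded.
#'
#' @param contexts A context tibble (see [parse_scc()]) or character vector
#'   of context strings.
#' @param positions Integer subset of [scc_positions()] to encode; the stop
#'   indicator is always included and need not be listed. May be empty for a
#'   stop-only encoding.
#' @return A numeric matrix with one row per context and 51 named columns.
#' @export
#' @examples
#' v <- encode_scc("AAAAGACCTG TGA CTAGTGAGCT")
#' sum(v) # 13 active positions
encode_scc <- function(contexts, positions = scc_positions()) {
  ctx <- .as_context_tbl(contexts)
  positions <- sort(unique(as.integer(positions)))
  if (!all(positions %in% scc_positions())) {
    abort("positions must be a subset of scc_positions()")
  }
  n <- nrow(ctx)
  m <- matrix(0, nrow = n, ncol = 51L, dimnames = list(ctx$scc, .vector_colnames()))
  full <- paste0(ctx$upstream, ctx$downstream) # 12 context nucleotides in block order
  all_pos <- scc_positions()
  for (j in seq_along(all_pos)) {
    if (!all_pos[j] %in% positions) next
    base <- substr(full, j, j)
    col <- (j - 1L) * 4L + match(base, .bases)
    m[cbind(seq_len(n), col)] <- 1
  }
  m[cbind(seq_len(n), 48L + match(ctx$stop, .stops))] <- 1
  attr(m, "active_positions") <- positions
  m
}

#' Normalize indicator vectors to Euclidean unit length
#'
#' Divides each row by its Euclidean norm. For binary indicator vectors this
#' equals division by the square root of the number of active positions
#' (sqrt(13) for the full 15-nt context).
#'
#' @param v Numeric matrix of row vectors (or a single vector).
#' @return Matrix of the same shape with unit-norm rows.
#' @export
unit_normalize <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) abort("cannot normalize an all-zero vector")
  out <- v / nrm
  attr(out, "active_positions") <- attr(v, "active_positions")
  out
}

#' Decode a full indicator vector back to its context
#'
#' Inverse of [encode_scc()] for fully encoded (13-position) vectors; used
#' for round-trip checks of the canonical block layout.
#'
#' @param v A 51-entry binary vector (or one-row matrix).
#' @return A one-row context tibble.
#' @export
decode_scc <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 51L)
  blocks <- matrix(v[1:48], nrow = 4L) # one column per position
  hit <- apply(blocks, 2L, function(b) which(b == 1))
  if (!is.numeric(hit) || length(hit) != 12L) {
    abort("vector does not encode all 12 context positions")
  }
  nts <- .bases[hit]
  stop_cd <- .stops[which(v[49:51] == 1)]
  if (length(stop_cd) != 1L) abort("vector does not encode exactly one stop codon")
  tibble::tibble(
    upstream = paste(nts[1:6], collapse = ""),
    stop = stop_cd,
    downstream = paste(nts[7:12], collapse = ""),
    scc = paste0(paste(nts[1:6], collapse = ""), stop_cd, paste(nts[7:12], collapse = ""))
  )
}

#' Per-position nucleotide and stop-codon frequencies
#'
#' Tabulates, over a set of contexts, the frequency of each base at every
#' context position and of each stop codon, in the layout of a
#' position-frequency table.
#'
#' @param contexts Context tibble or character vector of context strings.
#' @return A tibble in long form with columns `position` (character; "-6"
#'   .. "-1", "4" .. "9", or "stop"), `base` (A/C/G/T or a stop triplet) and
#'   `freq`. Frequencies within each position sum to 1.
#' @export
base_frequencies <- function(contexts) {
  ctx <- .as_context_tbl(contexts)
  if (nrow(ctx) == 0L) abort("empty context list")
  full <- paste0(ctx$upstream, ctx$downstream)
  pos <- scc_positions()
  nt_rows <- purrr::map_dfr(seq_along(pos), function(j) {
    b <- factor(substr(full, j, j), levels = .bases)
    tibble::tibble(
      position = .pos_label(pos[j]),
      base = .bases,
      freq = as.numeric(table(b)) / nrow(ctx)
    )
  })
  st <- factor(ctx$stop, levels = .stops)
  stop_rows <- tibble::tibble(
    position = "stop",
    base = .stops,
    freq = as.numeric(table(st)) / nrow(ctx)
  )
  dplyr::bind_rows(nt_rows, stop_rows)
}

#' Read and write stop-codon context tables
#'
#' Context tables are TSV files with columns `context_id`, `scc_text`
#' (`"NNNNNNNNNN SSS NNNNNNNNNN"`, spaces optional), `readthrough_pct` and
#' `readthrough_sd`. `read_context_table()` parses `scc_text` and appends
#' the canonical context columns.
#'
#' @param path File path.
#' @param data For the writer: a tibble with at least `context_id` and
#'   either `scc_text` or parsed context columns.
#' @return `read_context_table()` returns a tibble with columns
#'   `context_id`, `scc_text`, `readthrough_pct`, `readthrough_sd`,
#'   `upstream`, `stop`, `downstream`, `scc`.
#' @export
read_context_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("context_id", "scc_text")
  if (!all(need %in% names(tab))) {
    abort("context table needs columns context_id and scc_text")
  }
  if ("readthrough_pct" %in% names(tab) &&
      any(tab$readthrough_pct < 0, na.rm = TRUE)) {
    abort("readthrough values must be non-negative")
  }
  dplyr::bind_cols(tab, parse_scc(tab$scc_text))
}

#' @rdname read_context_table
#' @export
write_context_table <- function(data, path) {
  if (!"scc_text" %in% names(data)) {
    ctx <- .as_context_tbl(data)
    data$scc_text <- paste(ctx$upstream, ctx$stop, ctx$downstream)
  }
  keep <- intersect(
    c("context_id", "scc_text", "readthrough_pct", "readthrough_sd"),
    names(data)
  )
  readr::write_tsv(data[keep], path)
  invisible(path)
}

#' Write a frequency table in wide position-by-base layout
#'
#' @param freqs Output of [base_frequencies()].
#' @param path File path.
#' @export
write_freq_table <- function(freqs, path) {
  wide <- tidyr::pivot_wider(freqs, names_from = "base", values_from = "freq")
  readr::write_tsv(wide, path)
  invisible(path)
}
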