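# small hand-built transcripts: cds always ends in a stop codon
.mk <- function(id, n_aa, stop = "TGA", down = strrep("A", 300)) {
  tibble::tibble(
    id = id,
    cds = paste0("ATG", strrep("GCT", n_aa - 1), stop),
    downstream = down
  )
}

test_that("filtering removes short, incomplete and undetermined records with reasons", {
  recs <- dplyr::bind_rows(
    .mk("ok", 20),
    .mk("short10", 10), # 10 aa protein
    tibble::tibble(id = "nostop", cds = paste0("ATG", strrep("GCT", 20)),
                   downstream = strrep("A", 300)),
    tibble::tibble(id = "frame", cds = paste0("ATG", strrep("GCT", 20), "TGAA"),
                   downstream = strrep("A", 300)),
    .mk("undet", 20, down = paste0("NNN", strrep("A", 297))),
    .mk("tiny_down", 20, down = "ACG")
  )
  kept <- filter_transcripts(recs)
  expect_equal(kept$id, "ok")
  log <- removal_log(kept)
  expect_equal(log$reason[log$id == "short10"], "short")
  expect_equal(log$reason[log$id == "nostop"], "incomplete")
  expect_equal(log$reason[log$id == "frame"], "incomplete")
  expect_equal(log$reason[log$id == "undet"], "undetermined")
  expect_equal(log$reason[log$id == "tiny_down"], "short_downstream")
})

test_that("identical 3' termini aggregate to one representative, and dedupe is idempotent", {
  a <- .mk("b_second", 30)
  b <- .mk("a_first", 30) # same terminal window, different id
  c <- .mk("c_diff", 30, down = paste0("C", strrep("A", 299)))
  d <- .mk("d_longcds", 40) # same -45..end window (GCT repeats), same downstream
  reps <- dedupe_termini(dplyr::bind_rows(a, b, c, d))
  expect_equal(nrow(reps), 2)
  merged <- reps[grepl("a_first", reps$aggregated_ids), ]
  expect_equal(merged$id, "a_first") # lexicographically smallest id
  expect_equal(merged$aggregated_ids, "a_first,b_second,d_longcds")
  expect_identical(dedupe_termini(reps), reps)
  # identical CDS but different downstream stays separate
  expect_true("c_diff" %in% reps$id)
})

test_that("dedupe preserves every kept id exactly once across aggregation lists", {
  tr <- gen_transcriptome(40, seed = 91)
  kept <- filter_transcripts(tr)
  reps <- dedupe_termini(kept)
  members <- unlist(strsplit(reps$aggregated_ids, ","))
  expect_setequal(members, kept$id)
  expect_equal(anyDuplicated(members), 0)
})

test_that("extensions run to the first in-frame stop, prefixed with X", {
  # immediate downstream stop: empty extension, peptide is just 'X'
  bg <- find_extension(.mk("bg", 20, stop = "TAA", down = "TAATTTGGGCCC"))
  expect_equal(bg$extension_nt, "")
  expect_equal(bg$extension_aa, "X")

  # 18 nt before the next in-frame stop: 7-residue extension
  ldhb_like <- find_extension(.mk("x", 20, down = "CTAGTGAGCTGGAGGCTGTAGCCC"))
  expect_equal(nchar(ldhb_like$extension_nt), 18)
  expect_equal(nchar(ldhb_like$extension_aa), 7)
  expect_equal(substr(ldhb_like$extension_aa, 1, 1), "X")
  expect_equal(ldhb_like$scc,
               paste0("GCTGCT", "TGA", "CTAGTG"))

  # no stop within the window: no extension
  none <- find_extension(.mk("none", 20, down = strrep("GGC", 100)))
  expect_true(is.na(none$extension_nt))
  expect_true(is.na(none$extension_aa))

  expect_error(find_extension(.mk("tiny", 20, down = "ACG")), "too short")
})

test_that("translation agrees with the Biostrings oracle on random codon strings", {
  skip_if_not_installed("Biostrings")
  withr::with_seed(92, {
    for (i in 1:10) {
      nt <- paste(sample(c("A", "C", "G", "T"), 3 * 30, TRUE), collapse = "")
      mine <- translate_cds(nt)
      oracle <- as.character(Biostrings::translate(
        Biostrings::DNAString(nt), if.fuzzy.codon = "error"
      ))
      expect_equal(mine, oracle)
    }
  })
})

test_that("unit scaling maps scores to [0,1] with a degenerate all-zero rule", {
  expect_equal(scale_rtp_unit(c(-1, 0, 3)), c(0, 0.25, 1))
  expect_equal(scale_rtp_unit(c(2, 2, 2)), c(0, 0, 0))
  withr::with_seed(93, {
    x <- rnorm(50)
    sc <- scale_rtp_unit(x)
    expect_equal(range(sc), c(0, 1))
  })
  expect_error(scale_rtp_unit(numeric(0)), "empty")
})

test_that("ranking is by descending product with id tie-break and half-max rank", {
  cand <- tibble::tibble(
    id = c("b", "a", "c", "d"),
    rtp_plus = c(0.5, 0.5, 1, 0.9),
    pts1_posterior = c(0.4, 0.4, 0.8, 0)
  )
  ranked <- rank_candidates(cand)
  expect_equal(ranked$id, c("c", "a", "b", "d"))
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$product_score[ranked$id == "d"], 0) # zero posterior kills rtp
  expect_equal(attr(ranked, "half_max_rank"), 2) # 0.2 < 0.4 = half of 0.8
})

test_that("the end-to-end scan ranks the planted LDHB-like candidate first", {
  pts1 <- fit_rlsc(gen_pts1_dataset(60, 120, seed = 94), k = rtp_default_k())
  tr <- gen_transcriptome(60, seed = 95)
  scan <- scan_transcriptome(tr, pts1)
  expect_s3_class(scan, "readthrough_scan")
  expect_equal(scan$id[1], "planted_001")
  expect_equal(substr(scan$scc[1], 7, 13), "TGACTAG") # planted context motif
  expect_match(scan$extension_aa[1], "SRL$")
  expect_true(all(scan$rtp_plus >= 0 & scan$rtp_plus <= 1))
  expect_true(all(scan$product_score >= 0 & scan$product_score <= 1))
  # product is zero exactly when a factor is zero
  zero <- scan$product_score == 0
  expect_equal(zero, scan$rtp_plus == 0 | scan$pts1_posterior == 0)
})

test_that("the scan pipeline is deterministic", {
  pts1 <- fit_rlsc(gen_pts1_dataset(40, 80, seed = 96), k = 1)
  tr <- gen_transcriptome(25, seed = 97)
  s1 <- scan_transcriptome(tr, pts1)
  s2 <- scan_transcriptome(tr, pts1)
  expect_identical(s1, s2)
})

test_that("motif counting matches hand counts and nests", {
  recs <- dplyr::bind_rows(
    .mk("m1", 20, stop = "TGA", down = paste0("CTAG", strrep("A", 296))),
    .mk("m2", 20, stop = "TGA", down = paste0("CTAT", strrep("A", 296))),
    .mk("m3", 20, stop = "TAA", down = paste0("CTAG", strrep("A", 296))),
    .mk("m4", 20, stop = "TGA", down = paste0("GGGG", strrep("A", 296))),
    .mk("m5", 20, stop = "TGA", down = paste0("CTAG", strrep("C", 296)))
  )
  n_cta <- motif_count(recs, stop = "TGA", downstream_prefix = "CTA")
  n_ctag <- motif_count(recs, stop = "TGA", downstream_prefix = "CTAG")
  expect_equal(n_cta, 3)
  expect_equal(n_ctag, 2)
  expect_lte(n_ctag, n_cta) # pattern nesting
  expect_equal(motif_count(recs, stop = "TTT"), 0) # not a stop: matches nothing
  expect_error(motif_count(recs, stop = "TG"), "malformed")
  expect_error(motif_count(recs, downstream_prefix = "CTAGAAA"), "malformed")
})

test_that("FASTA round-trips with a declared CDS/downstream split", {
  skip_if_not_installed("Biostrings")
  tr <- gen_transcriptome(5, seed = 98)
  path <- withr::local_tempfile(fileext = ".fa")
  write_transcript_fasta(tr, path)
  lens <- tibble::tibble(id = tr$id, cds_length = nchar(tr$cds))
  back <- read_transcript_fasta(path, cds_lengths = lens)
  expect_equal(back, tr, ignore_attr = TRUE)
  back2 <- read_transcript_fasta(path, downstream_length = 300)
  expect_equal(back2$cds, tr$cds)
})
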