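# Published experimental and model tables, transcribed verbatim.
# table1: dual-reporter readthrough of 18 stop-codon-context constructs
# (HeLa cells, +/-10 nt flanks). table2: raw ridge weights of the LINiter
# (all 12 context positions) and LINfs3 (stop and +4..+6) models.
# table3: per-position nucleotide and stop frequencies of the training
# contexts used for the iterative model.

.table1 <- function() {
  tab <- tibble::tribble(
    ~context_id,     ~scc_text,                  ~readthrough_pct, ~readthrough_sd,
    "ZNF-574",       "GATCAGTGGC TGA CTCTGCCCGA", 0.31, 0.020,
    "LDHB",          "AAAAGACCTG TGA CTAGTGAGCT", 1.55, 0.087,
    "PPP1R3F",       "ATTCTCCCAA TAA AGCTTTACAG", 0.18, 0.009,
    "LDHB [TGAT]",   "AAAAGACCTG TGA TTAGTGAGCT", 0.17, 0.009,
    "LDHB [TAA]",    "AAAAGACCTG TAA CTAGTGAGCT", 0.20, 0.009,
    "LDHB [TAAT]",   "AAAAGACCTG TAA TTAGTGAGCT", 0.17, 0.009,
    "LENG1",         "CCTTACTCAC TGA CTCCTGAGGG", 0.26, 0.009,
    "VASN",          "GCCCTACATC TAA GCCAGAGAGA", 0.12, 0.004,
    "MDH1",          "TTCCTCTGCC TGA CTAGACAATG", 2.91, 0.147,
    "PRDM10",        "CACCAAACCA TGA CTTCCACCCT", 0.13, 0.005,
    "FBXL20",        "CATCATCCTA TGA CAATGGAGGT", 0.10, 0.006,
    "THG1L",         "AGCCAGGCTT TGA CGGAAGAGTC", 0.15, 0.006,
    "EDEM3",         "GGATGAGCTA TGA CTTGCTAAAC", 0.66, 0.027,
    "EDN1",          "AGCACATTGG TGA CAGACCTTCG", 0.25, 0.008,
    "UBQLN1",        "CCAGCCATCA TAG CAGCATTTCT", 0.13, 0.009,
    "IRAK3",         "CAAAAAAGAA TAA ATTCTACCAG", 0.10, 0.007,
    "SLC3A1",        "TACCTCGTGT TAG GCACCTTTAT", 0.18, 0.008,
    "LEPRE1",        "GGATGAGCTA TGA CAGCGTCCAG", 0.27, 0.010
  )
  dplyr::bind_cols(tab, parse_scc(tab$scc_text))
}

.table2 <- function() {
  w <- function(model, position, A, C, G, TT) {
    tibble::tibble(
      model = model, position = position,
      base = c("A", "C", "G", "T"), weight = c(A, C, G, TT)
    )
  }
  liniter <- dplyr::bind_rows(
    w("LINiter", "-6", -0.00041, -0.00105,  0.00060,  0.00200),
    w("LINiter", "-5",  0.00130,  0.00164, -0.00077, -0.00103),
    w("LINiter", "-4", -0.00028,  0.00075, -0.00041,  0.00108),
    w("LINiter", "-3", -0.00073, -0.00004,  0.00193, -0.00002),
    w("LINiter", "-2", -0.00071,  0.00133, -0.00048,  0.00100),
    w("LINiter", "-1",  0.00016,  0.00109,  0.00043, -0.00054),
    w("LINiter",  "4", -0.00037,  0.00375, -0.00156, -0.00067),
    w("LINiter",  "5", -0.00068, -0.00097, -0.00008,  0.00287),
    w("LINiter",  "6",  0.00276, -0.00026, -0.00059, -0.00076),
    w("LINiter",  "7", -0.00020, -0.00062,  0.00245, -0.00049),
    w("LINiter",  "8",  0.00105, -0.00017, -0.00058,  0.00084),
    w("LINiter",  "9", -0.00081,  0.00148,  0.00014,  0.00032),
    tibble::tibble(
      model = "LINiter", position = "stop",
      base = c("TAA", "TAG", "TGA"),
      weight = c(-0.00026, -0.00103, 0.00243)
    )
  )
  linfs3 <- dplyr::bind_rows(
    w("LINfs3", "4",  0.00006,  0.00351, -0.00111, -0.00064),
    w("LINfs3", "5", -0.00071, -0.00056,  0.00010,  0.00299),
    w("LINfs3", "6",  0.00306,  0.00021, -0.00093, -0.00053),
    tibble::tibble(
      model = "LINfs3", position = "stop",
      base = c("TAA", "TAG", "TGA"),
      weight = c(0.00005, -0.00052, 0.00229)
    )
  )
  dplyr::bind_rows(liniter, linfs3)
}

.table3 <- function() {
  f <- function(position, A, C, G, U) {
    tibble::tibble(position = position, base = c("A", "C", "G", "T"),
                   freq = c(A, C, G, U))
  }
  dplyr::bind_rows(
    f("-6", 0.2892, 0.2530, 0.2651, 0.1928),
    f("-5", 0.3253, 0.2651, 0.1446, 0.2651),
    f("-4", 0.1566, 0.2289, 0.3494, 0.2651),
    f("-3", 0.2410, 0.3373, 0.2410, 0.1807),
    f("-2", 0.2651, 0.1807, 0.2048, 0.3494),
    f("-1", 0.2410, 0.2530, 0.2651, 0.2410),
    f("4",  0.2289, 0.3133, 0.3373, 0.1205),
    f("5",  0.2651, 0.2530, 0.1446, 0.3373),
    f("6",  0.2771, 0.2169, 0.2530, 0.2530),
    f("7",  0.2530, 0.3133, 0.2892, 0.1446),
    f("8",  0.3253, 0.1687, 0.2410, 0.2651),
    f("9",  0.1807, 0.2771, 0.2771, 0.2651),
    tibble::tibble(position = "stop", base = c("TAA", "TAG", "TGA"),
                   freq = c(0.1928, 0.3373, 0.4699))
  )
}

#' Bundled published tables
#'
#' Returns the experimental and model tables bundled with the package as
#' tidy tibbles:
#' \describe{
#'   \item{`table1`}{Dual-reporter basal readthrough of 18 stop-codon-context
#'     constructs measured in HeLa cells (`context_id`, `scc_text`,
#'     `readthrough_pct`, `readthrough_sd` plus parsed context columns).}
#'   \item{`table2`}{Raw ridge-regression weights of the published LINiter
#'     and LINfs3 readthrough-propensity models in long form (`model`,
#'     `position`, `base`, `weight`).}
#'   \item{`table3`}{Per-position nucleotide frequencies and stop-codon
#'     frequencies of the training contexts (`position`, `base`, `freq`).}
#' }
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A tibble (see Details).
#' @export
#' @examples
#' published_table("table1")
published_table <- function(name) {
  switch(match.arg(name, c("table1", "table2", "table3")),
    table1 = .table1(),
    table2 = .table2(),
    table3 = .table3()
  )
}
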