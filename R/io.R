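# Readers, writers and the shipped table fixtures.

#' Read a FASTA file of DNA sequences
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} returning plain
#' named character strings: order-preserving, upper-cased, RNA \code{U}
#' normalized to \code{T}. Duplicate identifiers and empty records are
#' rejected.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence record in ", path, call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Write aligned sequence pairs as two-record FASTA files
#'
#' @param pairs Named list of length-2 sequence vectors (or lists with
#'   \code{seq_a}, \code{seq_b}).
#' @param dir Output directory (created if needed); one file per pair.
#' @return Invisibly, the written paths.
#' @export
write_pair_fasta <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    path <- file.path(dir, paste0(nm, ".fa"))
    writeLines(c(paste0(">", nm, "_a"), p[[1]],
                 paste0(">", nm, "_b"), p[[2]]), path)
    path
  }, character(1))
  invisible(paths)
}

#' Write a data frame as TSV
#'
#' Tab-delimited, header row, no quoting or row names; undefined numeric
#' values serialize as the literal \code{NA}.
#'
#' @param x Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

FIXTURE_FILES <- c(
  table1 = "table1_catalog.tsv",
  table2 = "table2_cis_elements.tsv",
  table3 = "table3_paralog_pairs.tsv"
)

FIXTURE_MD5 <- c(
  table1 = "c5eb05cd5aa1019e25c25dd889a10c31",
  table2 = "cf056de4fc81f539c30b12fe138d5882",
  table3 = "fe3c0a10f4612eca3b2cbebe70a0b9a9"
)

#' Load a shipped reference table
#'
#' The package ships transcriptions of the three published reference tables
#' for the Brassica rapa ABC-transporter family: \code{table1} — the
#' 179-row gene catalog (locus, subfamily, chromosome, coordinates, protein
#' statistics); \code{table2} — the 13 common cis-regulatory elements with
#' their IUPAC signal sequences; \code{table3} — the 76 syntenic paralog
#' pairs with synonymous/non-synonymous site counts, Ka, Ks, Ka/Ks,
#' selection call and duplication time. En-dashes and thousands separators
#' in the printed originals were normalized. An MD5 checksum guards each
#' file against silent corruption.
#'
#' @param name One of \code{"table1"}, \code{"table2"}, \code{"table3"}.
#' @return Data frame (table1 passes through [load_catalog()] validation).
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "wgtfate",
                      mustWork = TRUE)
  digest <- unname(tools::md5sum(path))
  if (!identical(digest, FIXTURE_MD5[[name]])) {
    stop("fixture corruption: checksum mismatch for ", name, call. = FALSE)
  }
  switch(name,
    table1 = load_catalog(path),
    utils::read.delim(path, stringsAsFactors = FALSE)
  )
}

#' Consistency checks of the shipped reference tables
#'
#' Recomputes, from the shipped catalog and paralog-pair tables, every
#' quantity that is internally re-derivable — Ka/Ks ratios from the Ka and
#' Ks columns, selection calls from the recomputed ratio, synonymous-clock
#' duplication times from Ks, per-row site-count conservation, and the
#' catalog's headline statistics — and compares each against the printed
#' value.
#'
#' @param lambda_rate Synonymous clock rate.
#' @return Data frame with one row per check: \code{check}, \code{value},
#'   \code{expected}, \code{pass}.
#' @export
consistency_report <- function(lambda_rate = 1.5e-8) {
  t3 <- load_fixture("table3")
  t1 <- load_fixture("table1")
  cs <- summarize_catalog(t1)

  omega_hat <- omega_ratio(t3$ka, t3$ks)
  class_hat <- classify_selection(omega_hat)
  printed_class <- ifelse(class_hat == "positive",
                          "Positive selection", "Purify selection")
  time_hat <- duplication_time(t3$ks, lambda_rate)
  sn <- t3$s_sites + t3$n_sites

  row <- function(check, value, expected, pass) {
    data.frame(check = check, value = value, expected = expected,
               pass = pass)
  }
  rbind(
    row("omega recomputed within 0.001 (all 76 pairs)",
        max(abs(omega_hat - t3$omega)), 0.001,
        all(abs(omega_hat - t3$omega) <= 0.001)),
    row("selection calls match printed column",
        sum(printed_class == t3$selection), nrow(t3),
        all(printed_class == t3$selection)),
    row("positive-selection pairs", sum(class_hat == "positive"), 10,
        sum(class_hat == "positive") == 10),
    row("strong-purifying pairs (omega < 0.1)",
        sum(class_hat == "strong_purifying"), 22,
        sum(class_hat == "strong_purifying") == 22),
    row("duplication time within 0.01 MYA (all 76 pairs)",
        max(abs(time_hat - t3$time_mya)), 0.01,
        all(abs(time_hat - t3$time_mya) <= 0.01)),
    row("min duplication time (MYA)", min(time_hat), 3.45,
        abs(min(time_hat) - 3.45) <= 0.01),
    row("max duplication time (MYA)", max(time_hat), 42.2,
        abs(max(time_hat) - 42.2) <= 0.01),
    row("mean duplication time (MYA)", mean(time_hat), 15.13,
        abs(mean(time_hat) - 15.13) <= 0.01),
    row("S+N sites within rounding of a multiple of 3",
        max(abs(sn - 3 * round(sn / 3))), 0.1,
        all(abs(sn - 3 * round(sn / 3)) <= 0.1 + 1e-9)),
    row("catalog size", cs$n_genes, 179, cs$n_genes == 179),
    row("genes on chromosomes", cs$n_on_chromosomes, 173,
        cs$n_on_chromosomes == 173),
    row("largest chromosome count (A09)",
        unname(cs$chromosome_counts["A09"]), 26,
        cs$chromosome_counts[["A09"]] == 26),
    row("multi-exon genes", cs$n_multi_exon, 162, cs$n_multi_exon == 162),
    row("genes with >10 exons", cs$n_over_10_exons, 60,
        cs$n_over_10_exons == 60),
    row("protein length range",
        paste(cs$protein_length[["min"]], cs$protein_length[["max"]],
              sep = "-"),
        "118-5408",
        cs$protein_length[["min"]] == 118 &&
          cs$protein_length[["max"]] == 5408)
  )
}
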