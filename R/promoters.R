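# IUPAC degenerate cis-element scanning of promoter sequences, replacing a
# web signal-scan service with a local matcher.

IUPAC_CODES <- names(Biostrings::IUPAC_CODE_MAP)

check_signal <- function(signal) {
  if (!is.character(signal) || length(signal) != 1L || nchar(signal) == 0) {
    stop("motif signal must be a non-empty string", call. = FALSE)
  }
  letters <- strsplit(toupper(signal), "")[[1]]
  bad <- setdiff(letters, IUPAC_CODES)
  if (length(bad)) {
    stop("invalid IUPAC code in motif signal: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  toupper(signal)
}

#' Scan one sequence for a degenerate IUPAC motif
#'
#' Every window of the sequence matching the IUPAC pattern position-wise is
#' reported. With \code{both_strands = TRUE} (the default, matching how
#' promoter signal scans are usually run) the reverse complement of the
#' pattern is also matched and reported as a minus-strand hit; offsets always
#' refer to the given (plus-strand) sequence and are 0-based. Overlapping
#' occurrences are all reported. An \code{N} in the sequence is treated as an
#' unknown base and only matched by an \code{N} in the pattern.
#'
#' @param seq DNA string over \code{A,C,G,T,N} (case-insensitive).
#' @param signal IUPAC motif string, e.g. \code{"GRWAAW"}.
#' @param both_strands Scan the reverse strand too?
#' @return Data frame with columns \code{offset} (0-based start),
#'   \code{end} (0-based exclusive) and \code{strand} (\code{"+"}/\code{"-"}).
#' @examples
#' scan_motif("GATAAT", "GRWAAW")
#' @export
scan_motif <- function(seq, signal, both_strands = TRUE) {
  signal <- check_signal(signal)
  subject <- Biostrings::DNAString(toupper(seq))
  hits_for <- function(pat) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = "subject")
    IRanges::start(m) - 1L
  }
  fwd <- hits_for(signal)
  out <- data.frame(offset = fwd,
                    end = fwd + nchar(signal),
                    strand = rep("+", length(fwd)))
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(signal)))
    rev <- hits_for(rc)
    out <- rbind(out, data.frame(offset = rev, end = rev + nchar(signal),
                                 strand = rep("-", length(rev))))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Presence/absence of motifs across a promoter set
#'
#' Promoters containing assembly gaps (any \code{N}) are excluded from the
#' incidence matrix and listed, mirroring the usual exclusion of genes whose
#' upstream region is incompletely assembled.
#'
#' @param promoters Named character vector (or coercible) of promoter
#'   sequences, one per gene.
#' @param motifs Data frame with columns \code{element} and \code{signal}
#'   (as loaded by [load_fixture]\code{("table2")}) or a named character
#'   vector of signals.
#' @param both_strands Passed to [scan_motif()].
#' @return List with \code{incidence} (logical gene x motif matrix over
#'   included genes) and \code{excluded} (gene names with gaps).
#' @export
element_incidence <- function(promoters, motifs, both_strands = TRUE) {
  promoters <- vapply(promoters, toupper, character(1))
  if (is.null(names(promoters)) || anyNA(names(promoters))) {
    stop("promoters must be named by gene", call. = FALSE)
  }
  if (is.data.frame(motifs)) {
    signals <- stats::setNames(motifs$signal, motifs$element)
  } else {
    signals <- motifs
  }
  stopifnot(length(promoters) >= 1, length(signals) >= 1)
  gapped <- grepl("N", promoters, fixed = TRUE)
  excluded <- names(promoters)[gapped]
  kept <- promoters[!gapped]
  inc <- matrix(FALSE, nrow = length(kept), ncol = length(signals),
                dimnames = list(names(kept), names(signals)))
  for (g in names(kept)) {
    for (m in names(signals)) {
      inc[g, m] <- nrow(scan_motif(kept[[g]], signals[[m]],
                                   both_strands = both_strands)) > 0
    }
  }
  list(incidence = inc, excluded = excluded)
}

#' Common and unique cis-elements
#'
#' Splits motifs into those present in every included promoter (common) and
#' those present in exactly one (unique). "Common" is defined over included
#' genes only: promoters excluded for assembly gaps do not break
#' commonality.
#'
#' @param incidence Logical gene x motif matrix, or the list returned by
#'   [element_incidence()].
#' @return List with \code{common} (character vector of motif names) and
#'   \code{unique} (named character vector, motif -> its single gene).
#' @export
classify_elements <- function(incidence) {
  if (is.list(incidence) && !is.matrix(incidence)) {
    incidence <- incidence$incidence
  }
  stopifnot(is.matrix(incidence), nrow(incidence) >= 1)
  n_genes <- colSums(incidence)
  common <- colnames(incidence)[n_genes == nrow(incidence)]
  uniq_cols <- which(n_genes == 1)
  uniq <- vapply(uniq_cols, function(j) rownames(incidence)[incidence[, j]],
                 character(1))
  names(uniq) <- colnames(incidence)[uniq_cols]
  list(common = common, unique = uniq)
}
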