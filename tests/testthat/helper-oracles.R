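# Independent oracles used to cross-check the implementation. These are
# deliberately written differently from the package code paths.

oracle_code <- function() {
  stats::setNames(as.character(Biostrings::GENETIC_CODE)[1:64],
                  names(Biostrings::GENETIC_CODE))
}

# Site counting by direct enumeration of all 9 single-nucleotide mutants.
oracle_count_sites <- function(codon, code = oracle_code()) {
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos)),
                   function(b) {
                     m <- codon; substr(m, pos, pos) <- b; m
                   }, character(1))
    aas <- unname(code[muts])
    keep <- aas != "*"
    if (any(keep)) s <- s + sum(aas[keep] == aa) / sum(keep)
  }
  c(s = s, n = 3 - s)
}

# Recursive pathway enumerator: averages syn/nonsyn step counts over all
# orderings of single changes, excluding orderings through stop codons
# (falling back to all orderings when none survive).
oracle_pair_diff <- function(a, b, code = oracle_code()) {
  walk <- function(cur, remaining) {
    # returns a list of per-path c(sd, nd, valid)
    if (!length(remaining)) return(list(c(0, 0, TRUE)))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      step_syn <- as.numeric(code[[cur]] == code[[nxt]])
      ok <- code[[nxt]] != "*" || !length(setdiff(remaining, pos))
      # a stop is only disqualifying when it is an intermediate codon;
      # endpoints are sense by precondition so the last step is safe
      for (tail in walk(nxt, setdiff(remaining, pos))) {
        out[[length(out) + 1]] <- c(step_syn + tail[1],
                                    (1 - step_syn) + tail[2],
                                    ok && tail[3])
      }
    }
    out
  }
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  paths <- walk(a, diff_pos)
  m <- do.call(rbind, paths)
  use <- if (any(m[, 3] == 1)) m[m[, 3] == 1, , drop = FALSE] else m
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

# Naive regex-style IUPAC window matcher (forward strand, 0-based offsets).
oracle_scan_forward <- function(seq, signal) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
           W = "AT", S = "CG", K = "GT", M = "AC", B = "CGT", D = "AGT",
           H = "ACT", V = "ACG", N = "ACGTN")
  pat <- paste0(vapply(strsplit(toupper(signal), "")[[1]],
                       function(ch) paste0("[", map[[ch]], "]"),
                       character(1)), collapse = "")
  hits <- integer(0)
  L <- nchar(seq); w <- nchar(signal)
  if (w <= L) {
    for (i in seq_len(L - w + 1)) {
      if (grepl(paste0("^", pat, "$"), substr(seq, i, i + w - 1))) {
        hits <- c(hits, i - 1L)
      }
    }
  }
  hits
}

revcomp <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

sense_codons_list <- function(code = oracle_code()) {
  names(code)[code != "*"]
}
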