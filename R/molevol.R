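# Nei-Gojobori (1986) approximate Ka/Ks with Jukes-Cantor correction,
# selection-pressure classification and synonymous-clock dating.

BASES <- c("A", "C", "G", "T")

#' Standard nuclear genetic code
#'
#' Returns the codon to amino-acid map used throughout the package, a named
#' character vector of length 64 with stop codons encoded as \code{"*"}.
#' Alternative codes in the same format (e.g. other rows of
#' \code{Biostrings::getGeneticCode}) can be passed to every estimator.
#'
#' @return Named character vector mapping the 64 codons to one-letter amino
#'   acids.
#' @export
standard_genetic_code <- function() {
  as.character(Biostrings::GENETIC_CODE)[seq_len(64)] |>
    stats::setNames(names(Biostrings::GENETIC_CODE))
}

is_stop <- function(codon, code) unname(code[codon]) == "*"

check_codon <- function(codon, code, allow_stop = FALSE) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon)) {
    stop("invalid codon: ", deparse(codon), call. = FALSE)
  }
  if (!allow_stop && is_stop(codon, code)) {
    stop("stop codon not allowed here: ", codon, call. = FALSE)
  }
  invisible(codon)
}

# All single-nucleotide mutant codons of `codon` at position `pos`.
codon_mutants <- function(codon, pos) {
  ref <- substr(codon, pos, pos)
  vapply(setdiff(BASES, ref), function(b) {
    out <- codon
    substr(out, pos, pos) <- b
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Synonymous and non-synonymous site counts of one codon
#'
#' Fractional site counting of the Nei-Gojobori (1986) scheme: at each of the
#' three codon positions the synonymous fraction is the proportion of the
#' possible single-nucleotide changes that preserve the amino acid, with
#' changes that would create a stop codon removed from the denominator at
#' that position. The counts always satisfy \code{s + n == 3}.
#'
#' @param codon Three-letter DNA string over \code{A,C,G,T}; must be a sense
#'   codon.
#' @param code Genetic code as returned by [standard_genetic_code()].
#' @return Numeric vector \code{c(s = ..., n = ...)}.
#' @examples
#' count_sites("ATG")  # Met: every change is non-synonymous
#' count_sites("TTT")  # 1/3 synonymous site at the third position
#' @export
count_sites <- function(codon, code = standard_genetic_code()) {
  check_codon(codon, code)
  aa <- unname(code[codon])
  s <- 0
  for (pos in 1:3) {
    mut <- codon_mutants(codon, pos)
    mut_aa <- unname(code[mut])
    non_stop <- mut_aa != "*"
    if (any(non_stop)) {
      s <- s + sum(mut_aa[non_stop] == aa) / sum(non_stop)
    }
  }
  c(s = s, n = 3 - s)
}

#' Pathway-averaged substitution counts between two codons
#'
#' For codons differing at k positions, every one of the k! orderings of
#' single-nucleotide changes is walked and each step is scored as synonymous
#' or non-synonymous; the returned counts are means over the orderings whose
#' intermediate codons are all sense codons. If every ordering passes through
#' a stop codon (rare), all orderings are weighted equally instead.
#'
#' @param codon_a,codon_b Sense codons.
#' @param code Genetic code map.
#' @return Numeric vector \code{c(sd = ..., nd = ...)}; the two entries sum
#'   to the number of differing positions.
#' @examples
#' count_pair_differences("TTT", "GTA")
#' @export
count_pair_differences <- function(codon_a, codon_b,
                                   code = standard_genetic_code()) {
  check_codon(codon_a, code)
  check_codon(codon_b, code)
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))

  orderings <- permutations(diff_pos)
  step_counts <- lapply(orderings, function(ord) {
    cur <- codon_a
    sd <- nd <- 0
    valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop(nxt, code)) valid <- FALSE
      if (unname(code[cur]) == unname(code[nxt])) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, valid = valid)
  })
  valid <- vapply(step_counts, `[[`, logical(1), "valid")
  use <- if (any(valid)) step_counts[valid] else step_counts
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# All permutations of a small vector (k <= 3 here).
permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Proportion of observed differences per site, in \code{[0, 0.75)}.
#' @return Corrected substitutions per site, \code{-3/4 * log(1 - 4p/3)}.
#' @export
jc_correct <- function(p) {
  if (any(p < 0)) stop("p must be non-negative", call. = FALSE)
  if (any(p >= 0.75)) {
    stop("saturation: p >= 0.75, Jukes-Cantor distance undefined",
         call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Ka/Ks ratio with a division guard
#'
#' @param ka,ks Non-negative substitution rates per site.
#' @return \code{ka/ks}, or \code{NA_real_} when \code{ks == 0} (omega
#'   undefined rather than infinite).
#' @export
omega_ratio <- function(ka, ks) {
  if (any(c(ka, ks) < 0, na.rm = TRUE)) {
    stop("ka and ks must be non-negative", call. = FALSE)
  }
  ifelse(is.na(ka) | is.na(ks) | ks == 0, NA_real_, ka / ks)
}

#' Classify selection pressure from omega
#'
#' omega > 1 is called positive selection, omega == 1 neutral, omega < 1
#' purifying, and omega < 0.1 strong purifying (the threshold under which
#' paralog pairs are reported as under strong purifying selection).
#'
#' @param omega Numeric vector of Ka/Ks ratios; \code{NA} for undefined.
#' @return Character vector over \code{positive}, \code{neutral},
#'   \code{purifying}, \code{strong_purifying}, \code{undefined}.
#' @export
classify_selection <- function(omega) {
  out <- rep("undefined", length(omega))
  out[!is.na(omega) & omega > 1] <- "positive"
  out[!is.na(omega) & omega == 1] <- "neutral"
  out[!is.na(omega) & omega < 1] <- "purifying"
  out[!is.na(omega) & omega < 0.1] <- "strong_purifying"
  out
}

#' Date a duplication from Ks with a synonymous clock
#'
#' T = Ks / (2 lambda), reported in million years. The default clock is 1.5
#' synonymous substitutions per site per 10^8 years, the rate commonly used
#' for Brassica.
#'
#' @param ks Synonymous substitutions per site.
#' @param lambda_rate Synonymous substitution rate per site per year.
#' @return Duplication time in MYA.
#' @examples
#' duplication_time(0.2692)  # ~8.97 MYA
#' @export
duplication_time <- function(ks, lambda_rate = 1.5e-8) {
  stopifnot(lambda_rate > 0)
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be non-negative", call. = FALSE)
  ks / (2 * lambda_rate) / 1e6
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

#' Nei-Gojobori Ka/Ks estimate for one codon-aligned pair
#'
#' Implements the approximate NG86 method: fractional synonymous and
#' non-synonymous site counts averaged over the two sequences,
#' pathway-averaged difference counts, and Jukes-Cantor correction of the
#' per-site proportions. Codon columns containing a gap, an ambiguity
#' character, or a stop codon in either sequence are excluded from all
#' counts. Saturation (p >= 0.75) propagates as an \code{NA} rate with
#' selection class \code{undefined}.
#'
#' @param seq_a,seq_b Upper-case aligned DNA strings of equal length
#'   divisible by 3, over \code{A,C,G,T,-} (other letters are treated as
#'   ambiguities and exclude their codon column).
#' @param code Genetic code map.
#' @param lambda_rate Synonymous clock rate for [duplication_time()].
#' @return List with elements \code{s_sites}, \code{n_sites}, \code{sd},
#'   \code{nd}, \code{ka}, \code{ks}, \code{omega}, \code{selection_class},
#'   \code{duplication_time_mya}, \code{n_codons} (included) and
#'   \code{n_excluded}.
#' @export
kaks_ng86 <- function(seq_a, seq_b, code = standard_genetic_code(),
                      lambda_rate = 1.5e-8) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  included <- clean
  included[clean] <- !is_stop(ca[clean], code) & !is_stop(cb[clean], code)
  if (!any(included)) {
    stop("empty alignment: no included codons", call. = FALSE)
  }
  ca <- ca[included]; cb <- cb[included]

  site_tab <- vapply(unique(c(ca, cb)), count_sites, numeric(2), code = code)
  s_sites <- (sum(site_tab["s", ca]) + sum(site_tab["s", cb])) / 2
  n_sites <- (sum(site_tab["n", ca]) + sum(site_tab["n", cb])) / 2

  differing <- which(ca != cb)
  sd <- nd <- 0
  if (length(differing)) {
    keys <- paste(ca[differing], cb[differing])
    diff_tab <- vapply(unique(keys), function(k) {
      ab <- strsplit(k, " ")[[1]]
      count_pair_differences(ab[1], ab[2], code = code)
    }, numeric(2))
    sd <- sum(diff_tab["sd", keys])
    nd <- sum(diff_tab["nd", keys])
  }

  ps <- sd / s_sites
  pn <- nd / n_sites
  ks <- if (ps < 0.75) jc_correct(ps) else NA_real_
  ka <- if (pn < 0.75) jc_correct(pn) else NA_real_
  omega <- if (is.na(ka) || is.na(ks)) NA_real_ else omega_ratio(ka, ks)
  list(
    s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
    ka = ka, ks = ks, omega = omega,
    selection_class = classify_selection(omega),
    duplication_time_mya = if (is.na(ks)) NA_real_ else
      duplication_time(ks, lambda_rate),
    n_codons = length(ca), n_excluded = sum(!included)
  )
}

#' Batch Ka/Ks over a list of codon-aligned pairs
#'
#' @param pairs Named list; each element is a length-2 character vector (or
#'   list with elements \code{seq_a}, \code{seq_b}) holding one aligned pair.
#'   FASTA files of two records each, read with [read_fasta()], fit directly.
#' @inheritParams kaks_ng86
#' @return Data frame with one row per pair and columns \code{pair},
#'   \code{s_sites}, \code{n_sites}, \code{ka}, \code{ks}, \code{omega},
#'   \code{selection}, \code{time_mya}.
#' @export
kaks_batch <- function(pairs, code = standard_genetic_code(),
                       lambda_rate = 1.5e-8) {
  stopifnot(length(pairs) >= 1)
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    r <- kaks_ng86(p[[1]], p[[2]], code = code, lambda_rate = lambda_rate)
    data.frame(pair = nm, s_sites = r$s_sites, n_sites = r$n_sites,
               ka = r$ka, ks = r$ks, omega = r$omega,
               selection = r$selection_class, time_mya = r$duplication_time_mya)
  })
  do.call(rbind, rows)
}
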