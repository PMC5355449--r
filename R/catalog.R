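# Gene-family catalog: loading, summary statistics, domain-architecture
# topology, tandem-array detection.

VALID_SUBFAMILIES <- c(paste0("ABC", LETTERS[1:7]), "ABCI")

#' Load a gene-family catalog table
#'
#' Reads a tab-separated catalog with one row per family gene. Coordinates
#' are 1-based inclusive. Either separate \code{start}/\code{end} columns or
#' a single \code{position} column of the form \code{"start-end"} is
#' accepted (en-dashes are normalized).
#'
#' @param path TSV file with header; required columns: \code{gene},
#'   \code{locus}, \code{subfamily}, \code{chromosome}, coordinates (see
#'   above), \code{protein_length}, \code{exon_count}, \code{mw_kda},
#'   \code{pi}, \code{tm_count}.
#' @return Data frame of gene records, one per input row.
#' @export
load_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(tab)
  if (!all(c("start", "end") %in% names(tab))) {
    if (!"position" %in% names(tab)) {
      stop("catalog needs start/end columns or a position column",
           call. = FALSE)
    }
    pos <- gsub("–", "-", tab$position)
    parts <- strsplit(pos, "-", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      stop("malformed coordinate at row ", bad[1], ": ", tab$position[bad[1]],
           call. = FALSE)
    }
    tab$start <- as.integer(vapply(parts, `[`, character(1), 1))
    tab$end <- as.integer(vapply(parts, `[`, character(1), 2))
  }
  needed <- c("gene", "locus", "subfamily", "chromosome", "start", "end",
              "protein_length", "exon_count", "mw_kda", "pi", "tm_count")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!tab$subfamily %in% VALID_SUBFAMILIES)
  if (length(bad)) {
    stop("unknown subfamily at row ", bad[1], ": ", tab$subfamily[bad[1]],
         call. = FALSE)
  }
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$end < tab$start)
  if (length(bad)) {
    stop("malformed coordinates (end < start) at row ", bad[1], call. = FALSE)
  }
  bad <- which(tab$exon_count < 1 | tab$protein_length <= 0)
  if (length(bad)) {
    stop("invalid exon count or protein length at row ", bad[1],
         call. = FALSE)
  }
  tab[, needed]
}

#' Summary statistics of a gene-family catalog
#'
#' Reproduces the family-level descriptive statistics usually reported for a
#' plant gene-family survey: subfamily and chromosome counts, scaffold
#' (unanchored) genes, protein length / molecular weight / isoelectric point
#' ranges, exon statistics and the number of proteins with predicted
#' transmembrane helices.
#'
#' @param records Catalog data frame from [load_catalog()].
#' @return List of summary components.
#' @export
summarize_catalog <- function(records) {
  stopifnot(nrow(records) >= 1)
  on_chrom <- grepl("^A\\d{2}$", records$chromosome)
  exon_hist <- table(records$exon_count)
  list(
    n_genes = nrow(records),
    subfamily_counts = sort(table(records$subfamily), decreasing = TRUE),
    chromosome_counts = table(records$chromosome[on_chrom]),
    n_on_chromosomes = sum(on_chrom),
    n_on_scaffolds = sum(!on_chrom),
    protein_length = c(min = min(records$protein_length),
                       max = max(records$protein_length),
                       mean = mean(records$protein_length)),
    mw_range = range(records$mw_kda),
    pi_range = range(records$pi),
    exon_histogram = exon_hist,
    n_multi_exon = sum(records$exon_count > 1),
    n_over_10_exons = sum(records$exon_count > 10),
    n_with_tm = sum(records$tm_count > 0)
  )
}

#' Classify an ABC-protein domain architecture
#'
#' Full-size transporters carry two transmembrane domains (TMD) and two
#' nucleotide-binding domains (NBD); half-size transporters one of each.
#' Forward orientation is TMD before NBD (subfamilies A-D), reverse is NBD
#' before TMD (subfamily G). NBD-only proteins are soluble; single-domain
#' proteins are the heterogeneous prokaryotic-type subfamily. Non-canonical
#' architectures are mapped to the closest class by prefix with a warning.
#'
#' @param arch Character vector of domain labels over \code{"TMD"},
#'   \code{"NBD"}, in N- to C-terminal order.
#' @return One of \code{full_forward}, \code{full_reverse},
#'   \code{half_forward}, \code{half_reverse}, \code{soluble},
#'   \code{single_domain}.
#' @export
classify_topology <- function(arch) {
  if (length(arch) == 0) stop("empty domain architecture", call. = FALSE)
  if (!all(arch %in% c("TMD", "NBD"))) {
    stop("domain labels must be TMD or NBD", call. = FALSE)
  }
  key <- paste(arch, collapse = "-")
  canon <- c("TMD-NBD-TMD-NBD" = "full_forward",
             "NBD-TMD-NBD-TMD" = "full_reverse",
             "TMD-NBD" = "half_forward",
             "NBD-TMD" = "half_reverse")
  if (key %in% names(canon)) return(unname(canon[key]))
  if (length(arch) == 1) return("single_domain")
  if (all(arch == "NBD")) return("soluble")
  # nearest class by longest canonical prefix; a canonical pattern that is
  # entirely contained as a prefix (e.g. TMD-NBD inside TMD-NBD-NBD) beats a
  # partial match of the same length
  score <- vapply(names(canon), function(k) {
    ref <- strsplit(k, "-")[[1]]
    m <- min(length(ref), length(arch))
    agree <- arch[seq_len(m)] == ref[seq_len(m)]
    pref <- if (all(agree)) m else min(which(!agree)) - 1L
    pref + 0.5 * (pref == length(ref))
  }, numeric(1))
  best <- canon[[which.max(score)]]
  warning("non-canonical architecture ", key, " mapped to ", best,
          call. = FALSE)
  best
}

#' Detect tandem arrays of family genes
#'
#' A tandem array is a run of family members in the same or neighboring
#' intergenic regions of one chromosome. Two family genes are linked when at
#' most \code{max_intervening} non-family genes sit between them in the
#' genome gene order; arrays are the connected components of size >= 2.
#'
#' @param records Catalog data frame (needs \code{gene}, \code{chromosome},
#'   \code{start}).
#' @param genome_order Data frame of the whole-genome gene ranking with
#'   columns \code{gene}, \code{chromosome} and either \code{rank} (gene
#'   index along the chromosome) or \code{start} from which ranks are
#'   computed.
#' @param max_intervening Maximum number of non-family genes allowed between
#'   linked members (default 1: same or directly neighboring intergenic
#'   region).
#' @return Data frame with one row per tandem gene: \code{array_id},
#'   \code{chromosome}, \code{gene}, \code{rank}, members ordered by
#'   position. Zero rows when no arrays exist.
#' @export
detect_tandem_arrays <- function(records, genome_order, max_intervening = 1) {
  stopifnot(max_intervening >= 0)
  go <- genome_order
  if (!"rank" %in% names(go)) {
    if (!"start" %in% names(go)) {
      stop("genome_order needs a rank or start column", call. = FALSE)
    }
    go <- go[order(go$chromosome, go$start), ]
    go$rank <- stats::ave(seq_len(nrow(go)), go$chromosome,
                          FUN = seq_along)
  }
  missing <- setdiff(records$gene, go$gene)
  if (length(missing)) {
    stop("family genes missing from genome ranking: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  fam <- go[go$gene %in% records$gene, c("gene", "chromosome", "rank")]
  fam <- fam[order(fam$chromosome, fam$rank), ]
  out <- list()
  next_id <- 1L
  for (chr in unique(fam$chromosome)) {
    sub <- fam[fam$chromosome == chr, ]
    if (nrow(sub) < 2) next
    # link consecutive family genes with <= max_intervening non-family genes
    gaps <- diff(sub$rank) - 1L
    comp <- cumsum(c(1L, gaps > max_intervening))
    for (cc in unique(comp)) {
      members <- sub[comp == cc, ]
      if (nrow(members) >= 2) {
        members$array_id <- next_id
        out[[length(out) + 1L]] <- members
        next_id <- next_id + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(array_id = integer(), chromosome = character(),
                      gene = character(), rank = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("array_id", "chromosome", "gene", "rank")]
}
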