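# Seeded synthetic-data generators with planted ground truth, standing in
# for the external genome, synteny and RNA-seq resources so that every
# analysis stage is testable offline.

sense_codons <- function(code = standard_genetic_code()) {
  names(code)[code != "*"]
}

#' Simulate a codon-aligned sequence pair diverged under a known omega
#'
#' An ancestor of \code{n_codons} sense codons is drawn uniformly; each
#' descendant lineage then accumulates Poisson(t/2) proposed
#' single-nucleotide changes per codon (uniform position and base).
#' Proposals creating a stop codon are rejected. For \code{omega <= 1},
#' synonymous proposals are always accepted and non-synonymous ones with
#' probability \code{omega}; for \code{omega > 1} the rule is mirrored
#' (non-synonymous always accepted, synonymous with probability
#' \code{1/omega}) so that the realized rate ratio still equals
#' \code{omega}. The generator is deliberately simpler than the estimator's
#' assumptions — no transition/transversion bias (\code{kappa} is exposed
#' but defaults to 1) — so estimator bias stays interpretable.
#'
#' @param n_codons Number of codons.
#' @param omega True non-synonymous/synonymous rate ratio (>= 0).
#' @param t Expected proposed changes per codon along the whole tree (split
#'   evenly between the two lineages).
#' @param kappa Transition/transversion proposal bias (1 = unbiased).
#' @param seed Optional integer seed for reproducibility.
#' @param code Genetic code map.
#' @return List with \code{seq_a}, \code{seq_b} (aligned DNA strings),
#'   \code{omega_true} and \code{t}.
#' @export
simulate_codon_pair <- function(n_codons, omega, t, kappa = 1, seed = NULL,
                                code = standard_genetic_code()) {
  stopifnot(n_codons >= 1, omega >= 0, t >= 0, kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  sense <- sense_codons(code)
  ancestor <- sample(sense, n_codons, replace = TRUE)
  p_nonsyn <- min(1, omega)
  p_syn <- if (omega > 1) 1 / omega else 1

  transition <- c(A = "G", G = "A", C = "T", T = "C")
  evolve <- function(codons) {
    n_prop <- stats::rpois(length(codons), t / 2)
    for (i in which(n_prop > 0)) {
      cur <- codons[i]
      for (k in seq_len(n_prop[i])) {
        pos <- sample.int(3, 1)
        ref <- substr(cur, pos, pos)
        alts <- setdiff(BASES, ref)
        w <- ifelse(alts == transition[[ref]], kappa, 1)
        alt <- sample(alts, 1, prob = w)
        nxt <- cur
        substr(nxt, pos, pos) <- alt
        if (is_stop(nxt, code)) next  # stop-creating proposals rejected
        syn <- unname(code[cur]) == unname(code[nxt])
        p_accept <- if (syn) p_syn else p_nonsyn
        if (stats::runif(1) < p_accept) cur <- nxt
      }
      codons[i] <- cur
    }
    codons
  }

  list(seq_a = paste(evolve(ancestor), collapse = ""),
       seq_b = paste(evolve(ancestor), collapse = ""),
       omega_true = omega, t = t)
}

#' Simulate a genome gene order with planted tandem arrays
#'
#' Builds a per-chromosome gene ranking containing family and background
#' genes, planting a configurable set of tandem arrays (runs of family genes
#' with at most \code{max_intervening} background genes between members) and
#' scattering the remaining family genes far apart. Defaults mirror the
#' studied family: 179 family genes on 10 chromosomes of which 28 sit in 11
#' arrays.
#'
#' @param n_family Total family genes.
#' @param array_sizes Integer vector of planted array sizes (sum must not
#'   exceed \code{n_family}); the default's 11 arrays hold 28 genes.
#' @param n_chromosomes Number of chromosomes (named A01, A02, ...).
#' @param genes_per_chromosome Background ranking length per chromosome.
#' @param max_intervening Detection rule the plants must satisfy; planted
#'   members are separated by at most this many background genes, and
#'   distinct arrays/singletons by more.
#' @param seed Optional integer seed.
#' @return List with \code{genome_order} (gene, chromosome, rank, start,
#'   end), \code{records} (catalog-like data frame of the family genes) and
#'   \code{true_arrays} (array_id, gene) for the planted members.
#' @export
simulate_gene_table <- function(n_family = 179,
                                array_sizes = c(3, 3, 3, 3, 3, 3,
                                                2, 2, 2, 2, 2),
                                n_chromosomes = 10,
                                genes_per_chromosome = 400,
                                max_intervening = 1,
                                seed = NULL) {
  stopifnot(sum(array_sizes) <= n_family, all(array_sizes >= 2))
  if (!is.null(seed)) set.seed(seed)
  chroms <- sprintf("A%02d", seq_len(n_chromosomes))
  n_singleton <- n_family - sum(array_sizes)

  # slot layout per chromosome: ranks 1..genes_per_chromosome; we reserve
  # runs for arrays and isolated ranks for singletons, background elsewhere.
  placements <- list()  # per family gene: chromosome, rank, array_id (NA)
  array_id <- 0L
  # spread arrays round-robin over chromosomes, anchored at spaced offsets
  anchor <- stats::setNames(rep(10L, n_chromosomes), chroms)
  for (size in array_sizes) {
    array_id <- array_id + 1L
    chr <- chroms[(array_id - 1L) %% n_chromosomes + 1L]
    gaps <- sample(0:max_intervening, size - 1L, replace = TRUE)
    ranks <- anchor[[chr]] + cumsum(c(0L, gaps + 1L))
    placements[[length(placements) + 1L]] <-
      data.frame(chromosome = chr, rank = ranks, array_id = array_id)
    # next feature on this chromosome starts well past the detection window
    anchor[[chr]] <- max(ranks) + max_intervening + 5L
  }
  for (s in seq_len(n_singleton)) {
    chr <- chroms[(s - 1L) %% n_chromosomes + 1L]
    placements[[length(placements) + 1L]] <-
      data.frame(chromosome = chr, rank = anchor[[chr]], array_id = NA_integer_)
    anchor[[chr]] <- anchor[[chr]] + max_intervening + 5L
  }
  fam <- do.call(rbind, placements)
  if (any(anchor > genes_per_chromosome)) {
    stop("genes_per_chromosome too small for the requested layout",
         call. = FALSE)
  }
  fam <- fam[order(fam$chromosome, fam$rank), ]
  fam$gene <- sprintf("FAM%03d", seq_len(nrow(fam)))

  rows <- list()
  for (chr in chroms) {
    ranks <- seq_len(genes_per_chromosome)
    fam_chr <- fam[fam$chromosome == chr, ]
    gene <- sprintf("BG_%s_%03d", chr, ranks)
    gene[fam_chr$rank] <- fam_chr$gene
    start <- 1L + (ranks - 1L) * 3000L
    rows[[chr]] <- data.frame(gene = gene, chromosome = chr, rank = ranks,
                              start = start, end = start + 1999L)
  }
  genome_order <- do.call(rbind, rows)
  rownames(genome_order) <- NULL

  fam_coords <- genome_order[match(fam$gene, genome_order$gene), ]
  subfam <- sample(VALID_SUBFAMILIES, nrow(fam), replace = TRUE)
  records <- data.frame(
    gene = fam$gene, locus = paste0("Loc", fam$gene), subfamily = subfam,
    chromosome = fam$chromosome, start = fam_coords$start,
    end = fam_coords$end,
    protein_length = sample(118:1500, nrow(fam), replace = TRUE),
    exon_count = sample(1:30, nrow(fam), replace = TRUE),
    mw_kda = round(stats::runif(nrow(fam), 12, 250), 2),
    pi = round(stats::runif(nrow(fam), 4.5, 10.6), 2),
    tm_count = sample(0:15, nrow(fam), replace = TRUE)
  )
  true_arrays <- fam[!is.na(fam$array_id), c("array_id", "gene")]
  rownames(true_arrays) <- NULL
  list(genome_order = genome_order, records = records,
       true_arrays = true_arrays)
}

#' Simulate syntenic-group cohorts with known retention rates
#'
#' Every ancestral locus keeps a copy in each subgenome independently with
#' the cohort's per-subgenome Bernoulli rate. Default rates echo the focal
#' family's elevated retention against a more heavily fractionated
#' background.
#'
#' @param n_focal,n_background Number of ancestral loci per cohort.
#' @param focal_rates,background_rates Named numeric vectors (lf, mf1, mf2)
#'   of retention probabilities.
#' @param tandem_rate Probability that each side of a group is flagged as a
#'   tandem array (for collinearity-relation labelling).
#' @param seed Optional integer seed.
#' @return Groups data frame in the layout [copy_number_retention()] expects,
#'   with logical \code{ref_tandem}, \code{copy_tandem} columns.
#' @export
simulate_retention_cohorts <- function(n_focal = 179, n_background = 3580,
                                       focal_rates = c(lf = 0.70, mf1 = 0.46,
                                                       mf2 = 0.36),
                                       background_rates = c(lf = 0.55,
                                                            mf1 = 0.35,
                                                            mf2 = 0.28),
                                       tandem_rate = 0.15, seed = NULL) {
  stopifnot(all(focal_rates >= 0 & focal_rates <= 1),
            all(background_rates >= 0 & background_rates <= 1))
  if (!is.null(seed)) set.seed(seed)
  gen <- function(n, rates, cohort, prefix) {
    data.frame(
      ancestral_id = sprintf("%s%04d", prefix, seq_len(n)),
      lf = stats::rbinom(n, 1, rates[["lf"]]),
      mf1 = stats::rbinom(n, 1, rates[["mf1"]]),
      mf2 = stats::rbinom(n, 1, rates[["mf2"]]),
      ref_tandem = stats::runif(n) < tandem_rate,
      copy_tandem = stats::runif(n) < tandem_rate,
      cohort = cohort
    )
  }
  rbind(gen(n_focal, focal_rates, "focal", "FOC"),
        gen(n_background, background_rates, "background", "BG"))
}

#' Simulate an FPKM matrix of paralog pairs with planted fates
#'
#' Conserved/sub-functionalized pairs share a base log2-FPKM tissue profile
#' plus independent Gaussian noise; neo-functionalized pairs get independent
#' profiles, redrawn until the noiseless FPKM-scale correlation falls below
#' \code{neo_max_pcc} so the planted label is recoverable; pseudogenized
#' pairs have one member identically zero. The default census (27/40/9)
#' mirrors the fate split reported for the studied family, and the default
#' \code{noise_sd} is calibrated so conserved pairs keep an expected
#' FPKM-scale correlation around 0.85 (the scale on which pairs are
#' classified).
#'
#' @param n_conserved,n_neo,n_pseudo Pairs per planted fate.
#' @param tissues Condition labels.
#' @param profile_sd Spread of the base log2-FPKM profile across tissues.
#' @param noise_sd Per-member log2 noise (default 0.61: expected FPKM-scale
#'   correlation of a conserved pair is then about 0.85).
#' @param base_mean Mean log2 FPKM.
#' @param neo_max_pcc Upper bound on the noiseless FPKM-scale profile
#'   correlation of a neo pair (margin below the 0.6 classification
#'   threshold).
#' @param seed Optional integer seed.
#' @return List with \code{matrix} (gene x tissue FPKM), \code{pairs}
#'   (member_a, member_b, pair, true_fate).
#' @export
simulate_expression <- function(n_conserved = 27, n_neo = 40, n_pseudo = 9,
                                tissues = c("roots", "stems", "leaves",
                                            "flowers", "siliques"),
                                profile_sd = 2, noise_sd = 0.61,
                                base_mean = 3, neo_max_pcc = 0.3,
                                seed = NULL) {
  stopifnot(n_conserved >= 0, n_neo >= 0, n_pseudo >= 0,
            n_conserved + n_neo + n_pseudo >= 1)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(tissues)
  rows <- list(); meta <- list()
  add_pair <- function(a_expr, b_expr, fate) {
    i <- length(meta) + 1L
    a <- sprintf("GENE%03dA", i); b <- sprintf("GENE%03dB", i)
    rows[[a]] <<- a_expr
    rows[[b]] <<- b_expr
    meta[[i]] <<- data.frame(member_a = a, member_b = b,
                             pair = paste(a, b, sep = "_"), true_fate = fate)
  }
  fpkm <- function(log2_expr) pmax(2^log2_expr, 0)
  for (k in seq_len(n_conserved)) {
    base <- stats::rnorm(nt, base_mean, profile_sd)
    add_pair(fpkm(base + stats::rnorm(nt, 0, noise_sd)),
             fpkm(base + stats::rnorm(nt, 0, noise_sd)),
             "conserved_or_sub")
  }
  for (k in seq_len(n_neo)) {
    repeat {
      pa <- stats::rnorm(nt, base_mean, profile_sd)
      pb <- stats::rnorm(nt, base_mean, profile_sd)
      if (stats::cor(2^pa, 2^pb) < neo_max_pcc) break
    }
    add_pair(fpkm(pa + stats::rnorm(nt, 0, noise_sd)),
             fpkm(pb + stats::rnorm(nt, 0, noise_sd)),
             "neofunctionalized")
  }
  for (k in seq_len(n_pseudo)) {
    base <- stats::rnorm(nt, base_mean, profile_sd)
    add_pair(fpkm(base + stats::rnorm(nt, 0, noise_sd)),
             rep(0, nt),
             "pseudogenization")
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- tissues
  list(matrix = mat, pairs = do.call(rbind, meta))
}

#' Simulate a tissue-expression matrix with planted specificity
#'
#' Plants a chosen number of tissue-specific genes per tissue (expressed in
#' exactly that tissue), a chosen number of silent genes, and fills the rest
#' with broadly expressed genes; the defaults echo the tissue-specific and
#' not-detected counts reported for the studied family.
#'
#' @param n_genes Total genes.
#' @param specific_counts Named integer vector: tissue-specific genes per
#'   tissue.
#' @param n_silent Genes expressed nowhere.
#' @param seed Optional integer seed.
#' @return List with \code{matrix} and \code{truth} (per-gene planted class).
#' @export
simulate_tissue_matrix <- function(n_genes = 179,
                                   specific_counts = c(roots = 8, stems = 4,
                                                       leaves = 4,
                                                       flowers = 5,
                                                       siliques = 1),
                                   n_silent = 14, seed = NULL) {
  stopifnot(sum(specific_counts) + n_silent <= n_genes)
  if (!is.null(seed)) set.seed(seed)
  tissues <- names(specific_counts)
  nt <- length(tissues)
  mat <- matrix(0, nrow = n_genes, ncol = nt,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)), tissues))
  truth <- rep("broad", n_genes)
  i <- 1L
  for (tissue in tissues) {
    for (k in seq_len(specific_counts[[tissue]])) {
      mat[i, tissue] <- stats::rlnorm(1, 2, 0.5)
      truth[i] <- paste0("specific_", tissue)
      i <- i + 1L
    }
  }
  for (k in seq_len(n_silent)) {
    truth[i] <- "silent"
    i <- i + 1L
  }
  while (i <= n_genes) {
    mat[i, ] <- stats::rlnorm(nt, 2, 1)
    i <- i + 1L
  }
  list(matrix = mat, truth = stats::setNames(truth, rownames(mat)))
}

#' Simulate promoter sequences with planted motif occurrences
#'
#' Backgrounds are i.i.d. uniform ACGT of the standard 2,000 bp upstream
#' window; each requested plant writes a concrete instantiation of its
#' (possibly degenerate) signal at the recorded offset. When two plants for
#' the same gene would overlap, the later one is shifted deterministically
#' to the next free offset.
#'
#' @param genes Character vector of gene names.
#' @param plant Data frame with columns \code{gene}, \code{signal} and
#'   optionally \code{offset} (0-based; sampled when absent).
#' @param length Promoter length in bp.
#' @param seed Optional integer seed.
#' @return List with \code{promoters} (named character vector) and
#'   \code{plants} (gene, signal, offset, realized instance).
#' @export
simulate_promoters <- function(genes, plant = NULL, length = 2000,
                               seed = NULL) {
  stopifnot(length(genes) >= 1, length >= 1)
  if (!is.null(seed)) set.seed(seed)
  iupac <- Biostrings::IUPAC_CODE_MAP
  realize <- function(signal) {
    paste(vapply(strsplit(toupper(signal), "")[[1]], function(ch) {
      opts <- strsplit(iupac[[ch]], "")[[1]]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1)), collapse = "")
  }
  proms <- stats::setNames(
    vapply(genes, function(g)
      paste(sample(BASES, length, replace = TRUE), collapse = ""),
      character(1)),
    genes)
  plants_out <- NULL
  if (!is.null(plant) && nrow(plant) > 0) {
    check <- vapply(plant$signal, check_signal, character(1))
    occupied <- lapply(genes, function(g) integer(0))
    names(occupied) <- genes
    recs <- list()
    for (i in seq_len(nrow(plant))) {
      g <- plant$gene[i]
      if (!g %in% genes) stop("plant for unknown gene: ", g, call. = FALSE)
      sig <- toupper(plant$signal[i])
      w <- nchar(sig)
      if (w > length) stop("plant does not fit in promoter", call. = FALSE)
      off <- if (!is.null(plant$offset) && !is.na(plant$offset[i])) {
        as.integer(plant$offset[i])
      } else {
        sample.int(length - w + 1L, 1L) - 1L
      }
      # resolve collisions deterministically: slide right (wrapping) until
      # the window is free of previous plants
      win <- function(o) seq.int(o + 1L, o + w)
      tries <- 0L
      while (any(win(off) %in% occupied[[g]])) {
        off <- (off + 1L) %% (length - w + 1L)
        tries <- tries + 1L
        if (tries > length) stop("no free offset left in promoter ", g,
                                 call. = FALSE)
      }
      if (off + w > length) off <- length - w
      inst <- realize(sig)
      substr(proms[[g]], off + 1L, off + w) <- inst
      occupied[[g]] <- c(occupied[[g]], win(off))
      recs[[i]] <- data.frame(gene = g, signal = sig,
                              offset = as.integer(off), instance = inst)
    }
    plants_out <- do.call(rbind, recs)
  }
  list(promoters = proms, plants = plants_out)
}
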