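# Expression flags, paralog-pair correlation, duplicate-gene fate
# classification and comparative-Ct qPCR quantification.

check_expr_matrix <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (any(mat < 0, na.rm = TRUE)) {
    stop("expression values (FPKM) must be non-negative", call. = FALSE)
  }
  mat
}

#' Expressed-anywhere and expressed-everywhere flags
#'
#' @param mat Gene x condition FPKM matrix (genes in rows).
#' @param threshold A gene counts as expressed in a condition when its value
#'   exceeds this (default 0: any non-zero FPKM).
#' @return Data frame with logical columns \code{any_condition} and
#'   \code{all_conditions}, one row per gene.
#' @export
expressed_flags <- function(mat, threshold = 0) {
  mat <- check_expr_matrix(mat)
  data.frame(
    gene = rownames(mat),
    any_condition = apply(mat, 1, max) > threshold,
    all_conditions = apply(mat, 1, min) > threshold,
    row.names = NULL
  )
}

#' Tissue-specific genes
#'
#' A gene is specific to a tissue when that is the only condition in which it
#' is expressed above the threshold.
#'
#' @inheritParams expressed_flags
#' @return Named list (one element per condition) of gene-name vectors.
#' @export
tissue_specific <- function(mat, threshold = 0) {
  mat <- check_expr_matrix(mat)
  stopifnot(ncol(mat) >= 2)
  expressed <- mat > threshold
  one_only <- rowSums(expressed) == 1
  out <- lapply(colnames(mat), function(tissue) {
    rownames(mat)[one_only & expressed[, tissue]]
  })
  stats::setNames(out, colnames(mat))
}

#' Pearson correlation with a zero-variance guard
#'
#' Standard product-moment correlation; returns \code{NA_real_} instead of
#' raising when either vector has zero variance (a flat expression profile).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in \code{[-1, 1]}, or \code{NA_real_}.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Classify the evolutionary fate of a duplicate pair from expression
#'
#' Applies the expression-correlation fate rules for post-duplication gene
#' pairs: if either member is expressed in no condition the pair is called
#' \code{pseudogenization} (correlation not available); otherwise a Pearson
#' correlation above \code{pcc_threshold} indicates functional conservation
#' or sub-functionalization (one combined label, since expression alone
#' cannot separate them) and anything at or below the threshold — negative
#' or small positive correlation — indicates \code{neofunctionalized}.
#'
#' @param a,b FPKM vectors of the two pair members over the same conditions.
#' @param pcc_threshold Correlation threshold for the conserved/
#'   sub-functionalized call (default 0.6; exactly 0.6 is not above it).
#' @param expr_threshold Expression threshold as in [expressed_flags()].
#' @return List with \code{fate} (one of \code{conserved_or_sub},
#'   \code{neofunctionalized}, \code{pseudogenization}) and \code{pcc}
#'   (\code{NA} when not available).
#' @export
classify_fate <- function(a, b, pcc_threshold = 0.6, expr_threshold = 0) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (any(c(a, b) < 0)) stop("FPKM values must be non-negative",
                             call. = FALSE)
  if (max(a) <= expr_threshold || max(b) <= expr_threshold) {
    return(list(fate = "pseudogenization", pcc = NA_real_))
  }
  pcc <- pearson(a, b)
  if (is.na(pcc)) {
    warning("zero-variance expressed pair; correlation not available",
            call. = FALSE)
    return(list(fate = "neofunctionalized", pcc = NA_real_))
  }
  if (pcc > pcc_threshold) {
    list(fate = "conserved_or_sub", pcc = pcc)
  } else {
    list(fate = "neofunctionalized", pcc = pcc)
  }
}

#' Two-fold expression difference flag
#'
#' TRUE when the pair shows at least a two-fold expression difference
#' (|log2 ratio| >= 1) in every condition. A pseudocount keeps the ratio
#' finite when one member is silent.
#'
#' @inheritParams classify_fate
#' @param pseudocount Added to both members before taking the ratio
#'   (default 1).
#' @return Logical scalar.
#' @export
fold_difference_flag <- function(a, b, pseudocount = 1) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  all(abs(log2((a + pseudocount) / (b + pseudocount))) >= 1)
}

#' Fate census over a set of paralog pairs
#'
#' Classifies every pair, tallies the fates, and exports the per-condition
#' log2 FPKM ratio matrix used for heatmap display.
#'
#' @param mat Gene x condition FPKM matrix.
#' @param pairs Data frame with columns \code{member_a}, \code{member_b}
#'   (row names of \code{mat}) and optionally \code{pair} ids.
#' @inheritParams classify_fate
#' @param pseudocount Passed to [fold_difference_flag()] and the ratio
#'   matrix.
#' @return List with \code{per_pair} (pair, pcc, fate, fold_flag),
#'   \code{counts} (named: conserved_or_sub, neofunctionalized,
#'   pseudogenization) and \code{log2_ratio} (pair x condition matrix).
#' @export
fate_census <- function(mat, pairs, pcc_threshold = 0.6, expr_threshold = 0,
                        pseudocount = 1) {
  mat <- check_expr_matrix(mat)
  stopifnot(nrow(pairs) >= 1)
  if (is.null(pairs$pair)) {
    pairs$pair <- paste(pairs$member_a, pairs$member_b, sep = "_")
  }
  missing <- setdiff(c(pairs$member_a, pairs$member_b), rownames(mat))
  if (length(missing)) {
    stop("pair members absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  per <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- mat[pairs$member_a[i], ]
    b <- mat[pairs$member_b[i], ]
    cls <- classify_fate(a, b, pcc_threshold, expr_threshold)
    data.frame(pair = pairs$pair[i], pcc = cls$pcc, fate = cls$fate,
               fold_flag = fold_difference_flag(a, b, pseudocount))
  })
  per <- do.call(rbind, per)
  ratio <- t(vapply(seq_len(nrow(pairs)), function(i) {
    log2((mat[pairs$member_a[i], ] + pseudocount) /
         (mat[pairs$member_b[i], ] + pseudocount))
  }, numeric(ncol(mat))))
  rownames(ratio) <- pairs$pair
  fates <- c("conserved_or_sub", "neofunctionalized", "pseudogenization")
  counts <- vapply(fates, function(f) sum(per$fate == f), integer(1))
  list(per_pair = per, counts = counts, log2_ratio = ratio)
}

#' Relative expression by the comparative-Ct (2^-ddCt) method
#'
#' For every sample and target gene, dCt = Ct(target) - Ct(reference) within
#' the sample, ddCt subtracts the calibrator sample's dCt, and the relative
#' quantity is 2^-ddCt. The calibrator's own relative quantity is exactly 1.
#'
#' @param ct Data frame in long format with columns \code{sample},
#'   \code{gene}, \code{ct}.
#' @param reference_gene Internal-control gene present in every sample.
#' @param calibrator_sample Sample against which fold changes are expressed.
#' @return Data frame with columns \code{sample}, \code{gene}, \code{ddct},
#'   \code{rq} for every non-reference gene.
#' @export
ddct_relative_expression <- function(ct, reference_gene, calibrator_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  samples <- unique(ct$sample)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample not present: ", calibrator_sample, call. = FALSE)
  }
  ref_ct <- function(s) {
    v <- ct$ct[ct$sample == s & ct$gene == reference_gene]
    if (length(v) != 1) {
      stop("reference gene missing (or duplicated) in sample ", s,
           call. = FALSE)
    }
    v
  }
  refs <- vapply(samples, ref_ct, numeric(1))
  targets <- setdiff(unique(ct$gene), reference_gene)
  rows <- list()
  for (g in targets) {
    cal <- ct$ct[ct$sample == calibrator_sample & ct$gene == g]
    if (length(cal) != 1) next  # target not measured in the calibrator
    dct_cal <- cal - refs[[calibrator_sample]]
    for (s in samples) {
      v <- ct$ct[ct$sample == s & ct$gene == g]
      if (length(v) != 1) next
      ddct <- (v - refs[[s]]) - dct_cal
      rows[[length(rows) + 1L]] <-
        data.frame(sample = s, gene = g, ddct = ddct, rq = 2^(-ddct))
    }
  }
  do.call(rbind, rows)
}

#' Sign agreement of tissue and stress correlations
#'
#' Compares, pair by pair, whether the Pearson correlation across tissues
#' (R_T) and the correlation across stress time points (R_S) fall on the
#' same side of the classification threshold — i.e. whether the two assays
#' tell the same fate story.
#'
#' @param r_t,r_s Named numeric vectors of per-pair correlations (same
#'   pairs).
#' @param threshold Correlation threshold (default 0.6).
#' @return List with \code{per_pair} (pair, r_t, r_s, agree),
#'   \code{agreement_fraction} over pairs with both correlations defined,
#'   and \code{excluded} (pairs with a missing correlation).
#' @export
tissue_vs_stress_consistency <- function(r_t, r_s, threshold = 0.6) {
  stopifnot(length(r_t) == length(r_s))
  pair <- names(r_t)
  if (is.null(pair)) pair <- paste0("pair", seq_along(r_t))
  defined <- !is.na(r_t) & !is.na(r_s)
  agree <- (r_t > threshold) == (r_s > threshold)
  list(
    per_pair = data.frame(pair = pair[defined], r_t = r_t[defined],
                          r_s = r_s[defined], agree = agree[defined]),
    agreement_fraction = if (any(defined)) mean(agree[defined]) else NA_real_,
    excluded = pair[!defined]
  )
}
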