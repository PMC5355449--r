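# Post-polyploidy retention/fractionation analysis across subgenomes.

SUBGENOMES <- c("lf", "mf1", "mf2")

check_groups <- function(groups) {
  needed <- c("ancestral_id", SUBGENOMES, "cohort")
  missing <- setdiff(needed, names(groups))
  if (length(missing)) {
    stop("groups table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (sg in SUBGENOMES) {
    if (!all(groups[[sg]] %in% c(0, 1))) {
      stop("subgenome columns must be 0/1 presence flags", call. = FALSE)
    }
  }
  invisible(groups)
}

cohort_subset <- function(groups, cohort) {
  check_groups(groups)
  sub <- groups[groups$cohort == cohort, ]
  if (nrow(sub) == 0) stop("empty cohort: ", cohort, call. = FALSE)
  sub
}

#' Retention by homologous copy number
#'
#' For every ancestral locus the number of copies retained across the three
#' subgenomes (0-3) is tallied. Because a survey anchored on extant family
#' genes cannot observe fully lost loci, fractions are reported under both
#' conventions: over all groups, and over groups with at least one retained
#' copy.
#'
#' @param groups Data frame with columns \code{ancestral_id}, \code{lf},
#'   \code{mf1}, \code{mf2} (0/1 presence per subgenome) and \code{cohort}.
#' @param cohort Which cohort to tabulate (e.g. \code{"focal"} or
#'   \code{"background"}).
#' @return List with \code{counts} (copies 0-3),
#'   \code{fraction_incl_zero} and \code{fraction_excl_zero}.
#' @export
copy_number_retention <- function(groups, cohort = "focal") {
  sub <- cohort_subset(groups, cohort)
  copies <- rowSums(sub[, SUBGENOMES])
  counts <- vapply(0:3, function(k) sum(copies == k), integer(1))
  names(counts) <- as.character(0:3)
  retained <- counts[c("1", "2", "3")]
  list(
    counts = counts,
    fraction_incl_zero = counts / sum(counts),
    fraction_excl_zero = if (sum(retained) > 0) retained / sum(retained)
      else retained * NA_real_
  )
}

#' Retention per subgenome
#'
#' @inheritParams copy_number_retention
#' @return Named numeric vector: fraction of the cohort's ancestral loci with
#'   a retained copy in each of LF, MF1, MF2.
#' @export
subgenome_retention <- function(groups, cohort = "focal") {
  sub <- cohort_subset(groups, cohort)
  vapply(SUBGENOMES, function(sg) mean(sub[[sg]]), numeric(1))
}

two_prop_z <- function(x1, n1, x2, n2) {
  x1 <- unname(x1); x2 <- unname(x2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  c(diff = p1 - p2, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Compare retention between a focal family and background genes
#'
#' Per stratum (each subgenome, or each copy-number class) the retained
#' fractions of the two cohorts are compared with a two-proportion z-test
#' (unpooled difference, pooled standard error, two-sided p). Raw counts are
#' returned so any other test can be applied downstream.
#'
#' @param focal_groups,background_groups Groups tables as in
#'   [copy_number_retention()] (the \code{cohort} column is ignored here).
#' @param stratum \code{"subgenome"} (retained fraction per LF/MF1/MF2) or
#'   \code{"copy"} (fraction of loci in each copy-number class 1-3, over all
#'   loci).
#' @return Data frame with one row per stratum: counts, proportions,
#'   difference, z and two-sided p. Strata with a zero denominator get
#'   \code{NA} statistics and \code{degenerate = TRUE}.
#' @export
compare_retention <- function(focal_groups, background_groups,
                              stratum = c("subgenome", "copy")) {
  stratum <- match.arg(stratum)
  check_groups(focal_groups); check_groups(background_groups)
  if (nrow(focal_groups) == 0 || nrow(background_groups) == 0) {
    stop("empty cohort", call. = FALSE)
  }
  if (stratum == "subgenome") {
    strata <- SUBGENOMES
    xf <- vapply(strata, function(s) sum(focal_groups[[s]]), numeric(1))
    xb <- vapply(strata, function(s) sum(background_groups[[s]]), numeric(1))
    nf <- rep(nrow(focal_groups), 3)
    nb <- rep(nrow(background_groups), 3)
  } else {
    strata <- as.character(1:3)
    cf <- rowSums(focal_groups[, SUBGENOMES])
    cb <- rowSums(background_groups[, SUBGENOMES])
    xf <- vapply(1:3, function(k) sum(cf == k), numeric(1))
    xb <- vapply(1:3, function(k) sum(cb == k), numeric(1))
    nf <- rep(length(cf), 3)
    nb <- rep(length(cb), 3)
  }
  rows <- lapply(seq_along(strata), function(i) {
    degenerate <- nf[i] == 0 || nb[i] == 0
    stats <- if (degenerate) c(diff = NA_real_, z = NA_real_,
                               p_value = NA_real_)
             else two_prop_z(xf[i], nf[i], xb[i], nb[i])
    data.frame(stratum = strata[i], x_focal = xf[i], n_focal = nf[i],
               x_background = xb[i], n_background = nb[i],
               p_focal = xf[i] / nf[i], p_background = xb[i] / nb[i],
               diff = stats[["diff"]], z = stats[["z"]],
               p_value = stats[["p_value"]], degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Classify the collinearity relation of a syntenic group
#'
#' Labels the relation between the reference-genome locus and its retained
#' family copies by whether each side is a single gene or a tandem array:
#' single-to-single (SB_SA), tandem-to-tandem (TB_TA), single family copy to
#' reference tandem array (SB_TA), family tandem array to single reference
#' copy (TB_SA).
#'
#' @param ref_tandem,copy_tandem Logical vectors: is the reference locus /
#'   the retained family copy part of a tandem array? \code{NA} is rejected.
#' @return Character vector over \code{SB_SA}, \code{TB_TA}, \code{SB_TA},
#'   \code{TB_SA}.
#' @export
classify_collinearity <- function(ref_tandem, copy_tandem) {
  if (length(ref_tandem) != length(copy_tandem)) {
    stop("flag vectors must have equal length", call. = FALSE)
  }
  if (anyNA(ref_tandem) || anyNA(copy_tandem)) {
    stop("incomplete group: tandem flags must be set on both sides",
         call. = FALSE)
  }
  ifelse(copy_tandem,
         ifelse(ref_tandem, "TB_TA", "TB_SA"),
         ifelse(ref_tandem, "SB_TA", "SB_SA"))
}
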