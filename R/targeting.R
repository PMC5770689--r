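#' Classify secretory-pathway targeting
#'
#' A protein is counted as targeting the secretory pathway if it carries
#' a signal peptide OR at least one transmembrane domain (union; proteins
#' with both are counted once).
#'
#' @param has_signal_peptide,has_transmembrane Logical vectors.
#' @return Logical vector.
#' @export
classify_sp_targeting <- function(has_signal_peptide, has_transmembrane) {
  if (any(is.na(has_signal_peptide)) || any(is.na(has_transmembrane))) {
    stop("classify_sp_targeting: annotation flags must not be missing")
  }
  has_signal_peptide | has_transmembrane
}

# round half away from zero to `digits` decimals (base round() is
# round-half-even, which would print 33.75 as 33.8 only by accident)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise secretory-pathway targeting per group
#'
#' For each group: the number of proteins, the counts with a signal
#' peptide, with a transmembrane domain, with both, and the union
#' (SP-targeting), plus percentages rounded half-up to one decimal.
#' Groups may overlap (e.g. up-regulated within regulated), so the
#' assignment is a protein-to-group mapping, not a partition. The union
#' percentage is computed by inclusion-exclusion on the rounded SP, TM
#' and both percentages (pct_sp + pct_tm - pct_both), the convention
#' under which published one-decimal summary tables are internally
#' consistent; the exact fractions are also returned.
#'
#' @param annotations Data.frame with `protein_id`, `has_signal_peptide`,
#'   `has_transmembrane`.
#' @param groups Data.frame with `protein_id`, `group`; a protein may
#'   appear in several rows.
#' @return A data.frame with one row per group: `group`, `n`, `n_sp`,
#'   `n_tm`, `n_both`, `n_targeting`, `pct_sp`, `pct_tm`, `pct_both`,
#'   `pct_targeting`, and raw fractions `frac_sp`, `frac_tm`,
#'   `frac_targeting`. Percentages of an empty group are `NA`.
#' @export
summarize_targeting <- function(annotations, groups) {
  missing_ids <- setdiff(groups$protein_id, annotations$protein_id)
  if (length(missing_ids)) {
    stop("summarize_targeting: no annotation for protein(s) ",
         paste(head(missing_ids, 3L), collapse = ", "))
  }
  idx <- match(groups$protein_id, annotations$protein_id)
  sp <- annotations$has_signal_peptide[idx]
  tm <- annotations$has_transmembrane[idx]
  out <- lapply(unique(groups$group), function(g) {
    in_g <- groups$group == g
    n <- sum(in_g)
    n_sp <- sum(sp[in_g])
    n_tm <- sum(tm[in_g])
    n_both <- sum(sp[in_g] & tm[in_g])
    n_targ <- sum(classify_sp_targeting(sp[in_g], tm[in_g]))
    pct <- function(k) if (n > 0L) round_half_up(100 * k / n, 1L) else NA_real_
    pct_sp <- pct(n_sp); pct_tm <- pct(n_tm); pct_both <- pct(n_both)
    data.frame(group = g, n = n, n_sp = n_sp, n_tm = n_tm,
               n_both = n_both, n_targeting = n_targ,
               pct_sp = pct_sp, pct_tm = pct_tm, pct_both = pct_both,
               pct_targeting = if (n > 0L) {
                 round_half_up(pct_sp + pct_tm - pct_both, 1L)
               } else NA_real_,
               frac_sp = if (n > 0L) n_sp / n else NA_real_,
               frac_tm = if (n > 0L) n_tm / n else NA_real_,
               frac_targeting = if (n > 0L) n_targ / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Tests association between group membership and a binary trait
#' (e.g. regulated vs non-regulated x targeting vs not). The Yates
#' continuity correction is off by default.
#'
#' @param table A 2x2 matrix of non-negative counts.
#' @param continuity Apply the Yates continuity correction?
#' @return A list with `statistic`, `p_value`, `df`, and `expected`
#'   counts.
#' @export
chi_square_test <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("chi_square_test: need a 2x2 table")
  }
  if (any(table < 0) || sum(table) <= 0) {
    stop("chi_square_test: counts must be non-negative with positive total")
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0)) stop("chi_square_test: degenerate row margin (zero sum)")
  if (any(cs == 0)) stop("chi_square_test: degenerate column margin (zero sum)")
  ht <- suppressWarnings(chisq.test(table, correct = continuity))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter), expected = ht$expected)
}
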