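#' Orient label-swapped SILAC ratios
#'
#' In a label-swap design the isotope labels are reversed in half of the
#' biological replicates, so their measured ratios are wild-type/mutant
#' rather than mutant/wild-type. This negates the log2 ratios of swapped
#' replicates so that every column means log2(mutant/wt), and resets all
#' orientation flags to `"standard"`. Applying the function twice is a
#' no-op.
#'
#' @param quant A `protein_quant` table (see [protein_quant()]).
#' @return The oriented `protein_quant` table.
#' @export
orient_ratios <- function(quant) {
  orientation <- attr(quant, "orientation")
  if (is.null(orientation)) stop("orient_ratios: orientation attribute missing")
  if (!all(orientation %in% c("standard", "swapped"))) {
    stop("orient_ratios: unknown orientation value")
  }
  m <- quant_ratio_matrix(quant)
  m[, orientation == "swapped"] <- -m[, orientation == "swapped"]
  protein_quant(quant$protein_id, m, rep("standard", ncol(m)))
}

#' Filter proteins by replicate detection
#'
#' Keeps proteins quantified (non-missing) in at least `min_reps`
#' replicates; the rest are routed to the filtered set. The boundary is
#' inclusive: with four replicates and `min_reps = 3`, three present
#' values suffice.
#'
#' @param quant An oriented `protein_quant` table.
#' @param min_reps Minimum number of replicates with a present value.
#' @return A list with `kept` (a `protein_quant`) and `filtered`
#'   (data.frame `protein_id`, `n_detected`, `status = "filtered"`).
#' @export
filter_detected <- function(quant, min_reps = 3L) {
  m <- quant_ratio_matrix(quant)
  if (min_reps > ncol(m)) {
    stop("filter_detected: min_reps (", min_reps,
         ") exceeds replicate count (", ncol(m), ")")
  }
  n_det <- rowSums(!is.na(m))
  keep <- n_det >= min_reps
  kept <- protein_quant(quant$protein_id[keep], m[keep, , drop = FALSE],
                        attr(quant, "orientation"))
  filtered <- data.frame(protein_id = quant$protein_id[!keep],
                         n_detected = as.integer(n_det[!keep]),
                         status = if (any(!keep)) "filtered" else character(0),
                         stringsAsFactors = FALSE)
  list(kept = kept, filtered = filtered)
}

#' Per-protein one-sample t-test of oriented log2 ratios
#'
#' Each SILAC replicate yields one mutant/wt ratio per protein, so the
#' differential test is a two-sided one-sample t-test of the present
#' log2 ratios against 0, with `n_detected - 1` degrees of freedom.
#' Proteins with p below `alpha` are called `up` or `down` by the sign of
#' the mean log2 fold change, otherwise `ns`. Rows with fewer than two
#' present values, or with zero variance around a non-zero mean, cannot
#' be tested and are reported as `degenerate` with an undefined p (the
#' all-zero row is the exact null: t = 0, p = 1, `ns`). A
#' Benjamini-Hochberg FDR column is emitted as supplementary output but
#' does not drive the status call.
#'
#' @param quant A filtered, oriented `protein_quant` table.
#' @param alpha Significance threshold on the raw p-value.
#' @return A data.frame with columns `protein_id`, `n_detected`,
#'   `mean_log2fc`, `t_stat`, `p_value`, `bh_fdr`, `status`.
#' @export
test_differential <- function(quant, alpha = 0.05) {
  m <- quant_ratio_matrix(quant)
  n_det <- rowSums(!is.na(m))
  mean_fc <- rowMeans(m, na.rm = TRUE)
  mean_fc[n_det == 0L] <- NA_real_
  s <- apply(m, 1L, sd, na.rm = TRUE)
  t_stat <- rep(NA_real_, nrow(m))
  p <- rep(NA_real_, nrow(m))
  testable <- n_det >= 2L & !is.na(s) & s > 0
  t_stat[testable] <- mean_fc[testable] / (s[testable] / sqrt(n_det[testable]))
  p[testable] <- 2 * pt(-abs(t_stat[testable]), df = n_det[testable] - 1L)
  exact_null <- n_det >= 2L & !is.na(s) & s == 0 & mean_fc == 0
  t_stat[exact_null] <- 0
  p[exact_null] <- 1
  status <- rep("degenerate", nrow(m))
  decided <- !is.na(p)
  status[decided] <- ifelse(p[decided] < alpha,
                            ifelse(mean_fc[decided] > 0, "up", "down"),
                            "ns")
  bh <- rep(NA_real_, nrow(m))
  bh[decided] <- p.adjust(p[decided], method = "BH")
  data.frame(protein_id = quant$protein_id,
             n_detected = as.integer(n_det),
             mean_log2fc = mean_fc, t_stat = t_stat, p_value = p,
             bh_fdr = bh, status = status, stringsAsFactors = FALSE)
}

#' Volcano-plot coordinates
#'
#' One point per tested protein: x is the mean log2 fold change (a fold
#' change of 2 maps to x = 1) and y is -log10 of the p-value (p = 0.05
#' maps to y = -log10(0.05), about 1.301). Filtered and degenerate rows
#' are dropped.
#'
#' @param results Output of [test_differential()].
#' @return A data.frame with `protein_id`, `x`, `y`, `status`.
#' @export
volcano_coords <- function(results) {
  keep <- results$status %in% c("up", "down", "ns")
  data.frame(protein_id = results$protein_id[keep],
             x = results$mean_log2fc[keep],
             y = -log10(results$p_value[keep]),
             status = results$status[keep],
             stringsAsFactors = FALSE)
}

#' Summarise regulation calls
#'
#' @param results Output of [test_differential()].
#' @return A list with `n_tested` (up + down + ns), `n_up`, `n_down`.
#' @export
summarize_regulation <- function(results) {
  st <- results$status
  list(n_tested = sum(st %in% c("up", "down", "ns")),
       n_up = sum(st == "up"),
       n_down = sum(st == "down"))
}
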