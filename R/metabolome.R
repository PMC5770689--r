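#' Median-normalise a metabolite peak table
#'
#' Scales each sample so that all sample medians (taken over detected,
#' i.e. nonzero, metabolites) equal the global median of the sample
#' medians. Zeros (undetected) are preserved. The operation is
#' idempotent.
#'
#' @param peaks Long-format peak table: `metabolite`, `sample_id`,
#'   `intensity`, plus per-sample metadata columns.
#' @return The normalised peak table.
#' @export
median_normalize <- function(peaks) {
  if (any(peaks$intensity < 0)) {
    stop("median_normalize: negative intensities")
  }
  meds <- tapply(peaks$intensity, peaks$sample_id,
                 function(v) median(v[v > 0]))
  if (any(is.na(meds))) {
    stop("median_normalize: sample(s) with no detected metabolite: ",
         paste(head(names(meds)[is.na(meds)], 3L), collapse = ", "))
  }
  target <- median(meds)
  scale <- target / meds[peaks$sample_id]
  peaks$intensity <- peaks$intensity * as.numeric(scale)
  peaks
}

#' Presence/absence calls per genotype from intracellular samples
#'
#' A metabolite is detected in a genotype at a timepoint when at least
#' `min_fraction` of that genotype's cell-compartment replicates exceed
#' `threshold`. A genotype counts as (consistently) positive when it is
#' detected at every timepoint; the pattern (`both`, `wt-only`,
#' `mutant-only`, `neither`) is derived from the two genotype calls.
#' `consistent_across_timepoints` is true when the per-timepoint
#' patterns are identical.
#'
#' @param peaks Normalised long-format peak table.
#' @param threshold Detection threshold on normalised intensity; default
#'   half the smallest nonzero normalised intensity in the cell samples.
#' @param min_fraction Fraction of replicates that must exceed the
#'   threshold (default 1: all replicates, "consistently detected").
#' @return A data.frame: `metabolite`, `pattern`,
#'   `consistent_across_timepoints`.
#' @export
presence_calls <- function(peaks, threshold = NULL, min_fraction = 1.0) {
  cells <- peaks[peaks$compartment == "cell", , drop = FALSE]
  if (!nrow(cells)) stop("presence_calls: no cell-compartment samples")
  if (!all(cells$genotype %in% c("wt", "mutant"))) {
    stop("presence_calls: unknown genotype label: ",
         paste(setdiff(unique(cells$genotype), c("wt", "mutant")),
               collapse = ", "))
  }
  if (is.null(threshold)) {
    pos <- cells$intensity[cells$intensity > 0]
    threshold <- min(pos) * 0.5
  }
  pattern_of <- function(wt, mut) {
    if (wt && mut) "both"
    else if (wt) "wt-only"
    else if (mut) "mutant-only"
    else "neither"
  }
  tps <- sort(unique(cells$timepoint))
  mets <- unique(cells$metabolite)
  out <- lapply(mets, function(m) {
    sub <- cells[cells$metabolite == m, , drop = FALSE]
    det <- function(geno, tp) {
      v <- sub$intensity[sub$genotype == geno & sub$timepoint == tp]
      length(v) > 0L && mean(v > threshold) >= min_fraction
    }
    per_tp <- vapply(tps, function(tp) {
      pattern_of(det("wt", tp), det("mutant", tp))
    }, character(1))
    wt_all <- all(vapply(tps, det, logical(1), geno = "wt"))
    mut_all <- all(vapply(tps, det, logical(1), geno = "mutant"))
    data.frame(metabolite = m,
               pattern = pattern_of(wt_all, mut_all),
               consistent_across_timepoints = length(unique(per_tp)) == 1L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify medium metabolites as consumed or secreted
#'
#' Compares the mean conditioned-medium intensity of each metabolite,
#' per genotype, against the mean of the unconditioned-medium reference
#' samples. A relative decrease beyond `margin` is `consumed`, an
#' increase beyond `margin` is `secreted`, otherwise `unchanged`. A
#' metabolite absent from the unconditioned reference but present in
#' conditioned medium is `secreted`.
#'
#' @param peaks Normalised long-format peak table with `medium` and
#'   `unconditioned` compartment samples.
#' @param margin Relative margin (default 0.2, i.e. 20%).
#' @return A data.frame: `metabolite`, `genotype`, `class`, `ratio`
#'   (conditioned mean over unconditioned mean).
#' @export
uptake_secretion <- function(peaks, margin = 0.2) {
  uncond <- peaks[peaks$compartment == "unconditioned", , drop = FALSE]
  med <- peaks[peaks$compartment == "medium", , drop = FALSE]
  if (!nrow(uncond)) {
    stop("uptake_secretion: missing unconditioned-medium reference")
  }
  if (!nrow(med)) stop("uptake_secretion: no conditioned-medium samples")
  ref <- tapply(uncond$intensity, uncond$metabolite, mean)
  out <- list()
  for (g in unique(med$genotype)) {
    sub <- med[med$genotype == g, , drop = FALSE]
    cm <- tapply(sub$intensity, sub$metabolite, mean)
    mets <- names(cm)
    r <- as.numeric(cm) / as.numeric(ref[mets])
    r[is.na(ref[mets]) | ref[mets] == 0] <-
      ifelse(as.numeric(cm)[is.na(ref[mets]) | ref[mets] == 0] > 0, Inf, 1)
    cls <- ifelse(r < 1 - margin, "consumed",
                  ifelse(r > 1 + margin, "secreted", "unchanged"))
    out[[g]] <- data.frame(metabolite = mets, genotype = g, class = cls,
                           ratio = r, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
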