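#' Build variant-proportional protein feature profiles
#'
#' A protein translated from several mRNA variants contributes all its
#' variants, each down-weighted by 1/k (k = the number of included
#' variants), so the group analysis is not skewed by proteins with many
#' variants. Variants excluded by the minimum-UTR-length rule are
#' dropped before weighting (k is recomputed over the survivors, so
#' weights always sum to 1 per protein); proteins with no included
#' variant, or with no transcript at all, are excluded with a message.
#'
#' @param features Feature data.frame from [compute_features()].
#' @param protein_groups Data.frame with `protein_id`, `group`.
#' @return A data.frame with one row per included variant: `protein_id`,
#'   `group`, `transcript_id`, the feature columns, and `weight`.
#' @export
build_profiles <- function(features, protein_groups) {
  no_tx <- setdiff(protein_groups$protein_id, features$protein_id)
  if (length(no_tx)) {
    message("build_profiles: ", length(no_tx),
            " protein(s) without transcripts excluded")
  }
  inc <- features[!features$excluded, , drop = FALSE]
  k <- table(inc$protein_id)
  all_excl <- setdiff(intersect(protein_groups$protein_id,
                                features$protein_id), names(k))
  if (length(all_excl)) {
    message("build_profiles: ", length(all_excl),
            " protein(s) with no included variant excluded")
  }
  idx <- match(inc$protein_id, protein_groups$protein_id)
  keep <- !is.na(idx)
  inc <- inc[keep, , drop = FALSE]
  idx <- idx[keep]
  out <- data.frame(protein_id = inc$protein_id,
                    group = protein_groups$group[idx],
                    transcript_id = inc$transcript_id,
                    length = inc$length, gc_percent = inc$gc_percent,
                    delta_g = inc$delta_g, uorf_count = inc$uorf_count,
                    weight = 1 / as.numeric(k[inc$protein_id]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Bin assignment. For numeric features, `edges` is c(lower, cut1, ...,
# cutm, upper): values below `lower` are an error (they belong to
# variants excluded upstream); the first interior cut is left-closed on
# its upper side ([lower, cut1) then [cut1, ...]), subsequent cuts are
# right-closed ((..., cut_j] then (cut_j, ...]). With the default length
# edges c(13, 150, 550, Inf) this yields the bins [13,150), [150,550],
# (550, Inf). uORF counts use integer bins 0..7 and "8+" instead.
assign_bins <- function(x, edges) {
  lower <- edges[1L]
  cuts <- edges[-c(1L, length(edges))]
  if (any(x < lower)) {
    stop("assign_bins: value(s) below the support edge ", lower,
         "; exclude them upstream")
  }
  j <- rep(1L, length(x))
  if (length(cuts) >= 1L) j <- j + (x >= cuts[1L])
  if (length(cuts) >= 2L) {
    for (c_ in cuts[-1L]) j <- j + (x > c_)
  }
  j
}

bin_labels_from_edges <- function(edges) {
  cuts <- edges[-c(1L, length(edges))]
  labs <- sprintf("<%g", cuts[1L])
  if (length(cuts) >= 2L) {
    labs <- c(labs, sprintf("%g-%g", cuts[-length(cuts)], cuts[-1L]))
  }
  c(labs, sprintf(">%g", cuts[length(cuts)]))
}

default_edges <- function(feature_name) {
  switch(feature_name,
         length = c(13, 150, 550, Inf),
         NULL)
}

#' Weighted per-group histogram of a protein feature
#'
#' Each included variant contributes its protein weight to the bin
#' containing its feature value, so every group's total mass equals its
#' protein count. Lengths default to the bins [13,150), [150,550],
#' (550, Inf); uORF counts default to the integer bins 0..7 and "8 or
#' more".
#'
#' @param profiles Output of [build_profiles()].
#' @param feature_name One of the feature columns (`length`,
#'   `gc_percent`, `delta_g`, `uorf_count`).
#' @param edges For numeric features, ordered edges
#'   `c(lower, cuts..., upper)` (see Details in the source); ignored for
#'   `uorf_count` unless supplied.
#' @return A list of class `binned_feature`: `feature_name`,
#'   `bin_labels`, and `weighted_counts` (matrix, groups x bins).
#' @export
bin_feature <- function(profiles, feature_name, edges = NULL) {
  x <- profiles[[feature_name]]
  if (is.null(x)) stop("bin_feature: unknown feature '", feature_name, "'")
  if (any(is.na(x))) {
    stop("bin_feature: feature '", feature_name, "' has missing values")
  }
  if (feature_name == "uorf_count" && is.null(edges)) {
    j <- pmin(x, 8L) + 1L
    labs <- c(as.character(0:7), "8+")
  } else {
    if (is.null(edges)) edges <- default_edges(feature_name)
    if (is.null(edges)) {
      stop("bin_feature: no default edges for '", feature_name,
           "'; supply `edges`")
    }
    if (is.unsorted(edges, strictly = TRUE)) {
      stop("bin_feature: edges must be strictly increasing")
    }
    j <- assign_bins(x, edges)
    labs <- bin_labels_from_edges(edges)
  }
  groups <- sort(unique(profiles$group))
  counts <- matrix(0, nrow = length(groups), ncol = length(labs),
                   dimnames = list(groups, labs))
  for (r in seq_along(x)) {
    counts[profiles$group[r], j[r]] <- counts[profiles$group[r], j[r]] +
      profiles$weight[r]
  }
  structure(list(feature_name = feature_name, bin_labels = labs,
                 weighted_counts = counts),
            class = "binned_feature")
}

# Pearson chi-square statistic on a (possibly non-integer) count matrix;
# all-zero columns are dropped
pearson_chi2 <- function(counts) {
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - E)^2 / E)
}

#' Compare a binned feature between two protein groups
#'
#' Default method `"permutation"`: the Pearson chi-square statistic is
#' computed on the unrounded weighted per-group bin counts, and its null
#' distribution is built by shuffling group labels over proteins
#' (variants move with their protein); p = (1 + #\{perm >= obs\}) /
#' (1 + n_perm). Method `"chi-square-rounded"` rounds the weighted
#' counts half-up to integers and applies the ordinary chi-square test —
#' statistically improper for fractional weights, provided for
#' comparability with published summary-table practice.
#'
#' @param profiles Output of [build_profiles()], with exactly two
#'   distinct group labels.
#' @param feature_name Feature column to compare.
#' @param edges Optional bin edges, as in [bin_feature()].
#' @param method `"permutation"` or `"chi-square-rounded"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation null.
#' @return A list of class `binned_comparison`: `feature_name`,
#'   `bin_labels`, `weighted_counts`, `chi2_stat`, `p_value`, `method`,
#'   `n_perm`.
#' @export
compare_groups <- function(profiles, feature_name, edges = NULL,
                           method = c("permutation", "chi-square-rounded"),
                           n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  glev <- sort(unique(profiles$group))
  if (length(glev) != 2L) {
    stop("compare_groups: need exactly two groups, got ",
         length(glev))
  }
  binned <- bin_feature(profiles, feature_name, edges)
  counts <- binned$weighted_counts
  if (any(rowSums(counts) == 0)) {
    stop("compare_groups: a group has zero mass")
  }
  if (method == "chi-square-rounded") {
    rc <- round_half_up(counts, 0L)
    rc <- rc[, colSums(rc) > 0, drop = FALSE]
    ht <- suppressWarnings(chisq.test(rc, correct = FALSE))
    stat <- unname(ht$statistic)
    p <- unname(ht$p.value)
  } else {
    stat <- pearson_chi2(counts)
    # per-protein bin-mass matrix: permutations move whole proteins
    x <- profiles[[feature_name]]
    j <- if (feature_name == "uorf_count" && is.null(edges)) {
      pmin(x, 8L) + 1L
    } else {
      e <- if (is.null(edges)) default_edges(feature_name) else edges
      assign_bins(x, e)
    }
    # canonical protein order so the permutation stream is invariant to
    # input row order
    prots <- sort(unique(profiles$protein_id))
    P <- matrix(0, nrow = length(prots), ncol = ncol(counts),
                dimnames = list(prots, colnames(counts)))
    pi_ <- match(profiles$protein_id, prots)
    for (r in seq_along(j)) {
      P[pi_[r], j[r]] <- P[pi_[r], j[r]] + profiles$weight[r]
    }
    grp <- profiles$group[match(prots, profiles$protein_id)]
    n_a <- sum(grp == glev[1L])
    col_tot <- colSums(P)
    perm_ge <- 0L
    with_substream(seed, "compare_groups", {
      for (b in seq_len(n_perm)) {
        a_idx <- sample.int(length(prots), n_a)
        ca <- colSums(P[a_idx, , drop = FALSE])
        perm_counts <- rbind(ca, col_tot - ca)
        if (pearson_chi2(perm_counts) >= stat) perm_ge <- perm_ge + 1L
      }
    })
    p <- (1 + perm_ge) / (1 + n_perm)
  }
  structure(list(feature_name = feature_name,
                 bin_labels = binned$bin_labels,
                 weighted_counts = counts, chi2_stat = stat,
                 p_value = p, method = method,
                 n_perm = if (method == "permutation") n_perm else NA_integer_),
            class = "binned_comparison")
}
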