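#' Simple base-pair energy model for RNA folding
#'
#' A documented pair-energy model for the minimum-free-energy proxy:
#' each allowed pair contributes a fixed negative energy (GC -3, AU -2,
#' GU -1 by default, symmetric), and every pair must enclose at least
#' `min_hairpin` unpaired bases. This is not a nearest-neighbour
#' thermodynamic parameterisation: absolute values are model units, and
#' only within-run comparisons between groups are meaningful. The
#' folding backend behind [compute_features()] is pluggable, so an
#' external thermodynamic folder can be substituted.
#'
#' @param pair_energies Named numeric: energies (all < 0) for `GC`, `AU`,
#'   `GU`; applied symmetrically.
#' @param min_hairpin Minimum number of unpaired bases enclosed by any
#'   pair (default 3).
#' @param max_length Sequences longer than this are refused rather than
#'   silently truncated.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(pair_energies = c(GC = -3, AU = -2, GU = -1),
                         min_hairpin = 3L, max_length = 5000L) {
  need <- c("GC", "AU", "GU")
  if (!all(need %in% names(pair_energies))) {
    stop("energy_model: pair_energies must name GC, AU and GU")
  }
  if (any(pair_energies[need] >= 0)) {
    stop("energy_model: all pair energies must be negative")
  }
  if (min_hairpin < 0L) stop("energy_model: min_hairpin must be >= 0")
  structure(list(pair_energies = pair_energies[need],
                 min_hairpin = as.integer(min_hairpin),
                 max_length = as.integer(max_length)),
            class = "energy_model")
}

# 4x4 symmetric energy matrix over A,C,G,U; non-pairing entries 0
energy_matrix <- function(model) {
  m <- matrix(0, 4L, 4L, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U")))
  m["G", "C"] <- m["C", "G"] <- model$pair_energies[["GC"]]
  m["A", "U"] <- m["U", "A"] <- model$pair_energies[["AU"]]
  m["G", "U"] <- m["U", "G"] <- model$pair_energies[["GU"]]
  m
}

#' Minimum-free-energy fold of an RNA sequence
#'
#' Computes the minimum achievable sum of pair energies over all
#' pseudoknot-free (non-crossing) secondary structures respecting the
#' model's minimum hairpin size, by O(n^3) dynamic programming with a
#' deterministic traceback. An unpairable sequence returns 0 and an
#' all-dots structure; the reported energy always equals the sum of pair
#' energies of the reported structure.
#'
#' @param seq RNA (or DNA; T is read as U) sequence, length >= 1.
#' @param model An [energy_model()].
#' @return A list of class `fold_result`: `delta_g` (model units, <= 0)
#'   and `structure` (dot-bracket string of the same length as `seq`).
#' @export
mfe_fold <- function(seq, model = energy_model()) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n < 1L) stop("mfe_fold: empty sequence")
  if (n > model$max_length) {
    stop("mfe_fold: sequence length ", n, " exceeds the model cap of ",
         model$max_length, " nt")
  }
  res <- .mfe_fold_cpp(s, energy_matrix(model), model$min_hairpin)
  structure(list(delta_g = res$delta_g, structure = res$structure),
            class = "fold_result")
}

#' Exhaustive-enumeration folding oracle
#'
#' Recursively enumerates every valid non-crossing pairing (no
#' memoisation) and returns the minimum total energy with one optimal
#' structure. Exponential; guarded to sequences of at most 22 nt. Used
#' to validate [mfe_fold()].
#'
#' @inheritParams mfe_fold
#' @return A `fold_result` list (`delta_g`, `structure`).
#' @export
brute_force_mfe <- function(seq, model = energy_model()) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n < 1L) stop("brute_force_mfe: empty sequence")
  if (n > 22L) stop("brute_force_mfe: length guard (22 nt) exceeded")
  em <- energy_matrix(model)
  idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))  # N -> NA
  h <- model$min_hairpin
  pair_e <- function(i, k) {
    if (is.na(idx[i]) || is.na(idx[k])) return(0)
    em[idx[i], idx[k]]
  }
  rec <- function(i, j) {
    if (i >= j) return(list(e = 0, pairs = NULL))
    best <- rec(i + 1L, j)  # i unpaired
    ks <- if (i + h + 1L <= j) (i + h + 1L):j else integer(0)
    for (k in ks) {
      pe <- pair_e(i, k)
      if (pe < 0) {
        inner <- rec(i + 1L, k - 1L)
        outer <- rec(k + 1L, j)
        e <- pe + inner$e + outer$e
        if (e < best$e) {
          best <- list(e = e, pairs = rbind(c(i, k), inner$pairs,
                                            outer$pairs))
        }
      }
    }
    best
  }
  res <- if (n >= 2L) rec(1L, n) else list(e = 0, pairs = NULL)
  db <- rep(".", n)
  if (!is.null(res$pairs)) {
    db[res$pairs[, 1L]] <- "("
    db[res$pairs[, 2L]] <- ")"
  }
  structure(list(delta_g = res$e, structure = paste(db, collapse = "")),
            class = "fold_result")
}
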