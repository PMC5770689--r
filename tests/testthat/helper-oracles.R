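# Independent oracles used across tests. Deliberately naive: explicit
# loops and elementary checks, sharing no code path with the package.

# brute-force uORF scan: walk every transcript position and test the
# codon and context character by character
brute_scan_uorfs <- function(sequence, cds_start,
                             start_codons = c("AUG", "CUG", "GUG",
                                              "UUG", "ACG"),
                             minus3 = c("A", "G"), plus4 = "G") {
  s <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  hits <- integer(0)
  for (i in seq_along(s)) {
    if (i < 4) next                      # -3 context must exist
    if (i + 2 >= cds_start) next         # codon fully inside the UTR
    codon <- paste0(s[i], s[i + 1], s[i + 2])
    ok <- FALSE
    for (sc in start_codons) if (codon == sc) ok <- TRUE
    if (!ok) next
    if (!(s[i - 3] %in% minus3)) next
    if (i + 3 > length(s) || s[i + 3] != plus4) next
    hits <- c(hits, i)
  }
  hits
}

# parse a dot-bracket string into a 2-column matrix of pair indices
dotbracket_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  open <- integer(0)
  pairs <- NULL
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      stopifnot(length(open) > 0)
      j <- open[length(open)]
      open <- open[-length(open)]
      pairs <- rbind(pairs, c(j, i))
    }
  }
  stopifnot(length(open) == 0)
  pairs
}

# energy of a given structure under the default pair model
structure_energy <- function(seq, structure,
                             energies = c(GC = -3, AU = -2, GU = -1)) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  pairs <- dotbracket_pairs(structure)
  if (is.null(pairs)) return(0)
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    duo <- paste(sort(c(s[pairs[r, 1]], s[pairs[r, 2]])), collapse = "")
    e <- e + switch(duo, CG = energies[["GC"]], AU = energies[["AU"]],
                    GU = energies[["GU"]],
                    stop("invalid pair ", duo))
  }
  e
}

random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "")[[1]]), collapse = "")
}

# hand Pearson chi-square on a 2x2 table (formula oracle)
hand_chi2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  E <- outer(rs, cs) / n
  sum((tab - E)^2 / E)
}

# deterministic study whose differential calls equal the table3 fixture
# designation: first 72 proteins strongly up, next 8 strongly down, the
# rest exactly null
make_table3_study <- function(dir) {
  n <- 1240L
  ids <- sprintf("P%04d", seq_len(n))
  base <- c(0.8, 1.1, 0.9, 1.2)
  ratios <- matrix(0, n, 4L)
  for (i in 1:72) ratios[i, ] <- base
  for (i in 73:80) ratios[i, ] <- -base
  quant <- pulseUTR::protein_quant(ids, ratios, rep("standard", 4L))
  cfg <- pulseUTR::sim_config(seed = 1L, n_proteins = n)
  truth <- data.frame(protein_id = ids,
                      status = c(rep("up", 72), rep("down", 8),
                                 rep("null", n - 80)),
                      stringsAsFactors = FALSE)
  ann <- pulseUTR::gen_annotations(cfg, truth, mode = "table3")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pulseUTR::write_quant(quant, file.path(dir, "quant.tsv"))
  flags <- ann$annotations
  flags$has_signal_peptide <- as.integer(flags$has_signal_peptide)
  flags$has_transmembrane <- as.integer(flags$has_transmembrane)
  pulseUTR:::write_tsv_prov(flags, file.path(dir, "annotations.tsv"))
  invisible(dir)
}
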