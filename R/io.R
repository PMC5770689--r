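#' Read a nucleotide FASTA file
#'
#' Standard FASTA parsing (multi-line records joined); the description
#' after the first whitespace is preserved separately. Empty files,
#' duplicate identifiers and non-nucleotide characters are rejected with
#' named errors.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("read_fasta: empty FASTA file: ", path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("read_fasta: duplicate id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- as.character(set)
  for (i in seq_along(seqs)) {
    bad <- gsub("[ACGTUNacgtun]", "", seqs[i])
    if (nzchar(bad)) {
      stop("read_fasta: non-nucleotide character(s) in record '", id[i],
           "': ", substr(bad, 1L, 10L))
    }
  }
  data.frame(id = id, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param ids Character identifiers.
#' @param sequences Character sequences (written as-is).
#' @param path Output path.
#' @export
write_fasta <- function(ids, sequences, path) {
  set <- Biostrings::BStringSet(setNames(sequences, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# TSV with '#'-commented provenance header lines
write_tsv_prov <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pulseUTR %s",
                     as.character(utils::packageVersion("pulseUTR"))), con)
  for (nm in names(provenance)) {
    writeLines(sprintf("# %s: %s", nm, provenance[[nm]]), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  if (!file.exists(path)) stop("read_tsv_prov: no such file: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a protein quantification table to TSV
#'
#' Replicate label orientation is stored in a commented header line so
#' that a single file round-trips the full table.
#'
#' @param quant A `protein_quant` table.
#' @param path Output path.
#' @param provenance Optional named character vector of extra header
#'   fields.
#' @export
write_quant <- function(quant, path, provenance = character()) {
  prov <- c(orientation = paste(attr(quant, "orientation"), collapse = " "),
            provenance)
  write_tsv_prov(as.data.frame(quant), path, prov)
}

#' Read a protein quantification table from TSV
#'
#' @param path Path written by [write_quant()]. If the file lacks an
#'   orientation header, all replicates are assumed `standard`.
#' @return A `protein_quant` table.
#' @export
read_quant <- function(path) {
  if (!file.exists(path)) stop("read_quant: no such file: ", path)
  header <- grep("^#", readLines(path, n = 20L), value = TRUE)
  df <- read_tsv_prov(path)
  m <- as.matrix(df[, grep("^ratio_", names(df)), drop = FALSE])
  ol <- grep("^# orientation:", header, value = TRUE)
  orientation <- if (length(ol)) {
    strsplit(sub("^# orientation:\\s*", "", ol[1L]), "\\s+")[[1]]
  } else {
    rep("standard", ncol(m))
  }
  protein_quant(df$protein_id, m, orientation)
}

#' Write a synthetic study to a directory
#'
#' Emits every pipeline input as plain text: transcripts as FASTA
#' (uppercase RNA alphabet) plus an annotation TSV (`transcript_id`,
#' `protein_id`, `cds_start`, 1-based), the quantification table,
#' annotation flags (0/1), group assignment and peak/sample tables as
#' TSV with commented provenance headers, and the ground truth as JSON.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.character(study$config$seed)
  prov <- c(seed = seed)
  write_fasta(study$transcripts$transcript_id, study$transcripts$sequence,
              file.path(dir, "transcripts.fa"))
  write_tsv_prov(study$transcripts[, c("transcript_id", "protein_id",
                                       "cds_start")],
                 file.path(dir, "transcripts.tsv"), prov)
  write_quant(study$quant, file.path(dir, "quant.tsv"), prov)
  ann <- study$annotations
  ann$has_signal_peptide <- as.integer(ann$has_signal_peptide)
  ann$has_transmembrane <- as.integer(ann$has_transmembrane)
  write_tsv_prov(ann, file.path(dir, "annotations.tsv"), prov)
  write_tsv_prov(study$groups, file.path(dir, "groups.tsv"), prov)
  write_tsv_prov(study$peaks[, c("metabolite", "sample_id", "intensity")],
                 file.path(dir, "peaks.tsv"), prov)
  meta <- unique(study$peaks[, c("sample_id", "genotype", "compartment",
                                 "timepoint")])
  write_tsv_prov(meta, file.path(dir, "samples.tsv"), prov)
  jsonlite::write_json(
    list(truth = study$truth, planted_uorfs = study$planted_uorfs,
         seed = study$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read study inputs from a directory
#'
#' Counterpart of [write_study()]; reads whatever input files are
#' present. Missing optional components are returned as `NULL`.
#'
#' @param dir Directory containing the study files.
#' @return A list with `quant`, `transcripts`, `annotations`, `groups`,
#'   `peaks`.
#' @export
read_study <- function(dir) {
  need <- file.path(dir, "quant.tsv")
  if (!file.exists(need)) stop("read_study: missing file: ", need)
  quant <- read_quant(need)
  transcripts <- NULL
  fa_path <- file.path(dir, "transcripts.fa")
  ann_path <- file.path(dir, "transcripts.tsv")
  if (file.exists(fa_path) && file.exists(ann_path)) {
    fa <- read_fasta(fa_path)
    ann <- read_tsv_prov(ann_path)
    idx <- match(ann$transcript_id, fa$id)
    if (any(is.na(idx))) {
      stop("read_study: transcript(s) in annotation absent from FASTA: ",
           paste(head(ann$transcript_id[is.na(idx)], 3L), collapse = ", "))
    }
    transcripts <- data.frame(transcript_id = ann$transcript_id,
                              protein_id = ann$protein_id,
                              sequence = fa$sequence[idx],
                              cds_start = as.integer(ann$cds_start),
                              stringsAsFactors = FALSE)
  }
  read_if <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) read_tsv_prov(p) else NULL
  }
  annotations <- read_if("annotations.tsv")
  if (!is.null(annotations)) {
    annotations$has_signal_peptide <- annotations$has_signal_peptide == 1
    annotations$has_transmembrane <- annotations$has_transmembrane == 1
  }
  peaks <- read_if("peaks.tsv")
  meta <- read_if("samples.tsv")
  if (!is.null(peaks) && !is.null(meta)) {
    peaks <- merge(peaks, meta, by = "sample_id", sort = FALSE)
    peaks <- peaks[, c("metabolite", "sample_id", "intensity", "genotype",
                       "compartment", "timepoint")]
  }
  list(quant = quant, transcripts = transcripts,
       annotations = annotations, groups = read_if("groups.tsv"),
       peaks = peaks)
}
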