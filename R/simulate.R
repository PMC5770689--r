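#' Simulation configuration for a synthetic pulsed-labelling study
#'
#' Bundles every parameter of the synthetic-data generators. Defaults encode
#' the structure of a pulsed AHA-SILAC astrocyte study: 1240 quantified
#' proteins of which roughly 80 are regulated with a strong (90%) upward
#' bias, four biological replicates with the isotope labels swapped in two
#' of them, 5'-UTRs that are longer and carry more upstream open reading
#' frames (uORFs) in the regulated group, secretory-pathway annotation
#' frequencies matching the observed group marginals, and a metabolite
#' screen with one intracellular metabolite present only in the mutant.
#'
#' @param seed Master integer seed; fully determines all generator output.
#' @param n_proteins Number of quantified proteins.
#' @param frac_regulated Fraction of proteins regulated by genotype.
#' @param up_bias Probability that a regulated protein is up-regulated
#'   (mutant over wild type).
#' @param effect_log2 Magnitude of the planted log2 fold change.
#' @param noise_sd Log2-scale replicate standard deviation.
#' @param n_replicates Number of biological replicates (>= 2). Labels are
#'   swapped in the second half of the replicates.
#' @param missing_rate Probability that any single ratio is missing.
#' @param variants_per_protein_max Maximum mRNA variants per protein;
#'   variant counts follow a truncated geometric distribution.
#' @param utr_length_params Named list (`up`, `down`, `null`) of
#'   `c(meanlog, sdlog)` for log-normal 5'-UTR lengths, in nucleotides.
#' @param gc_fraction GC content of generated UTR sequence outside
#'   inserted motifs.
#' @param uorf_rate Named numeric (`up`, `down`, `null`): expected number
#'   of planted context-valid uORF starts per UTR (Poisson).
#' @param sp_tm_probs Named list (`up`, `down`, `null`) of
#'   `c(sp, tm, both)` probabilities for signal-peptide / transmembrane
#'   flags, with `both` the joint probability (overlap).
#' @param metabolite_params List controlling the metabolite generator:
#'   `n_background`, `n_replicates_cell`, `n_replicates_medium`,
#'   `timepoints` (hours), `meanlog`, `sdlog_metabolite`, `sdlog_replicate`,
#'   `flux_fold` (consumed/secreted fold versus unconditioned medium).
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_proteins = 100)
#' study <- simulate_study(cfg)
#' names(study)
sim_config <- function(seed = 1L,
                       n_proteins = 1240L,
                       frac_regulated = 80 / 1240,
                       up_bias = 0.9,
                       effect_log2 = 1,
                       noise_sd = 0.25,
                       n_replicates = 4L,
                       missing_rate = 0.1,
                       variants_per_protein_max = 4L,
                       utr_length_params = list(
                         up   = c(meanlog = log(450), sdlog = 0.70),
                         down = c(meanlog = log(133), sdlog = 0.55),
                         null = c(meanlog = log(180), sdlog = 0.80)
                       ),
                       gc_fraction = 0.6,
                       uorf_rate = c(up = 2.5, down = 0.5, null = 1.0),
                       sp_tm_probs = list(
                         up   = c(sp = 27 / 72, tm = 24 / 72, both = 13 / 72),
                         down = c(sp = 0, tm = 0, both = 0),
                         null = c(sp = 210 / 1160, tm = 153 / 1160,
                                  both = 84 / 1160)
                       ),
                       metabolite_params = list(
                         n_background = 20L,
                         n_replicates_cell = 3L,
                         n_replicates_medium = 2L,
                         timepoints = c(24, 72),
                         meanlog = log(1e6),
                         sdlog_metabolite = 0.5,
                         sdlog_replicate = 0.15,
                         flux_fold = 3
                       )) {
  cfg <- list(
    seed = seed, n_proteins = as.integer(n_proteins),
    frac_regulated = frac_regulated, up_bias = up_bias,
    effect_log2 = effect_log2, noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates), missing_rate = missing_rate,
    variants_per_protein_max = as.integer(variants_per_protein_max),
    utr_length_params = utr_length_params, gc_fraction = gc_fraction,
    uorf_rate = uorf_rate, sp_tm_probs = sp_tm_probs,
    metabolite_params = metabolite_params
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num <- c(cfg$seed, cfg$n_proteins, cfg$frac_regulated, cfg$up_bias,
           cfg$effect_log2, cfg$noise_sd, cfg$n_replicates,
           cfg$missing_rate, cfg$variants_per_protein_max,
           cfg$gc_fraction, cfg$uorf_rate)
  if (!all(is.finite(num))) {
    stop("sim_config: all numeric parameters must be finite")
  }
  fracs <- c(frac_regulated = cfg$frac_regulated, up_bias = cfg$up_bias,
             missing_rate = cfg$missing_rate, gc_fraction = cfg$gc_fraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop("sim_config: fractions outside [0,1]: ",
         paste(names(fracs)[bad], collapse = ", "))
  }
  if (cfg$n_replicates < 2L) stop("sim_config: n_replicates must be >= 2")
  if (cfg$n_proteins < 1L) stop("sim_config: n_proteins must be >= 1")
  if (cfg$variants_per_protein_max < 1L) {
    stop("sim_config: variants_per_protein_max must be >= 1")
  }
  for (g in c("up", "down", "null")) {
    p <- cfg$sp_tm_probs[[g]]
    if (is.null(p) || any(!is.finite(p)) || any(p < 0) || any(p[1:2] > 1) ||
        p[["both"]] > min(p[["sp"]], p[["tm"]]) + 1e-12 ||
        p[["sp"]] + p[["tm"]] - p[["both"]] > 1 + 1e-12) {
      stop("sim_config: invalid sp_tm_probs for group '", g, "'")
    }
    if (is.null(cfg$utr_length_params[[g]])) {
      stop("sim_config: utr_length_params missing group '", g, "'")
    }
  }
  invisible(cfg)
}

#' Generate a synthetic protein quantification table with ground truth
#'
#' Proteins are labelled regulated with probability `frac_regulated`;
#' regulated proteins are up with probability `up_bias`. Replicate log2
#' mutant/wild-type ratios are drawn around 0 (null) or around the signed
#' effect (regulated). The second half of the replicates is label-swapped:
#' its stored values are the ratios as measured under the reversed label
#' orientation (i.e. negated), to be corrected by [orient_ratios()].
#' Each cell is independently missing with probability `missing_rate`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `quant` (a `protein_quant` table) and `truth`
#'   (data.frame with `protein_id`, `status` in up/down/null).
#' @export
gen_proteome <- function(config) {
  validate_sim_config(config)
  with_substream(config$seed, "proteome", {
    n <- config$n_proteins
    k <- config$n_replicates
    ids <- sprintf("P%04d", seq_len(n))
    regulated <- runif(n) < config$frac_regulated
    up <- runif(n) < config$up_bias
    status <- ifelse(regulated, ifelse(up, "up", "down"), "null")
    mu <- ifelse(status == "up", config$effect_log2,
                 ifelse(status == "down", -config$effect_log2, 0))
    ratios <- matrix(rnorm(n * k, mean = rep(mu, k), sd = config$noise_sd),
                     nrow = n, ncol = k)
    orientation <- rep(c("standard", "swapped"), c(ceiling(k / 2), floor(k / 2)))
    swapped <- orientation == "swapped"
    ratios[, swapped] <- -ratios[, swapped]  # stored as measured
    miss <- matrix(runif(n * k) < config$missing_rate, nrow = n)
    ratios[miss] <- NA_real_
    quant <- protein_quant(ids, ratios, orientation)
    truth <- data.frame(protein_id = ids, status = status,
                        stringsAsFactors = FALSE)
    list(quant = quant, truth = truth)
  })
}

#' Construct a protein quantification table
#'
#' @param protein_id Character vector of protein identifiers.
#' @param ratios Numeric matrix (proteins x replicates) of log2 ratios;
#'   `NA` marks a missing (undetected) measurement.
#' @param orientation Character vector, one of `"standard"` or
#'   `"swapped"` per replicate column.
#' @return A `protein_quant` data.frame with an `orientation` attribute.
#' @export
protein_quant <- function(protein_id, ratios, orientation) {
  ratios <- as.matrix(ratios)
  if (ncol(ratios) < 2L) stop("protein_quant: need >= 2 replicates")
  if (length(orientation) != ncol(ratios)) {
    stop("protein_quant: orientation length must match replicate count")
  }
  if (!all(orientation %in% c("standard", "swapped"))) {
    stop("protein_quant: unknown orientation value; use standard/swapped")
  }
  if (any(is.infinite(ratios))) {
    stop("protein_quant: ratios must be finite or NA")
  }
  df <- data.frame(protein_id = as.character(protein_id),
                   ratios, stringsAsFactors = FALSE)
  names(df)[-1] <- sprintf("ratio_%d", seq_len(ncol(ratios)))
  rownames(df) <- NULL
  structure(df, orientation = orientation,
            class = c("protein_quant", "data.frame"))
}

quant_ratio_matrix <- function(quant) {
  as.matrix(quant[, grep("^ratio_", names(quant)), drop = FALSE])
}

#' Generate synthetic transcripts with planted uORFs
#'
#' Each protein receives 1..`variants_per_protein_max` mRNA variants
#' (truncated geometric). Each variant gets a 5'-UTR whose length is
#' log-normal with group-specific parameters (regulated-up UTRs longer),
#' i.i.d. nucleotides at the configured GC content, and
#' Poisson(`uorf_rate[group]`) planted uORF start motifs: a start codon
#' drawn from AUG/CUG/GUG/UUG/ACG with a purine written at -3 and a G at
#' +4, inserted by overwrite at non-overlapping positions at least 3 nt
#' from the 5' end. The main open reading frame starts with AUG directly
#' after the UTR; its first base is recorded as `cds_start` (1-based).
#'
#' @param config A [sim_config()] object.
#' @param truth Truth data.frame from [gen_proteome()].
#' @param rule The [uorf_rule()] whose codons are planted.
#' @return A list with `transcripts` (data.frame `transcript_id`,
#'   `protein_id`, `sequence`, `cds_start`) and `planted` (data.frame
#'   `transcript_id`, `position` of each planted start, 1-based).
#' @export
gen_transcripts <- function(config, truth, rule = uorf_rule()) {
  validate_sim_config(config)
  with_substream(config$seed, "transcripts", {
    n <- nrow(truth)
    kmax <- config$variants_per_protein_max
    n_var <- pmin(1L + rgeom(n, prob = 0.5), kmax)
    tx_id <- character(0)
    tx_prot <- character(0)
    tx_seq <- character(0)
    tx_cds <- integer(0)
    planted_tx <- character(0)
    planted_pos <- integer(0)
    for (i in seq_len(n)) {
      g <- truth$status[i]
      lp <- config$utr_length_params[[g]]
      for (v in seq_len(n_var[i])) {
        len <- max(1L, as.integer(round(rlnorm(1, lp[["meanlog"]],
                                               lp[["sdlog"]]))))
        utr <- random_rna(len, config$gc_fraction)
        n_plant <- rpois(1, config$uorf_rate[[g]])
        pos <- integer(0)
        if (n_plant > 0L) {
          pl <- plant_uorfs(utr, n_plant, rule)
          utr <- pl$seq
          pos <- pl$positions
        }
        cds_tail <- random_rna(30L, config$gc_fraction)
        full <- paste0(utr, "AUG", cds_tail, "UAA")
        id <- sprintf("%s.v%d", truth$protein_id[i], v)
        tx_id <- c(tx_id, id)
        tx_prot <- c(tx_prot, truth$protein_id[i])
        tx_seq <- c(tx_seq, full)
        tx_cds <- c(tx_cds, len + 1L)
        if (length(pos)) {
          planted_tx <- c(planted_tx, rep(id, length(pos)))
          planted_pos <- c(planted_pos, pos)
        }
      }
    }
    list(
      transcripts = data.frame(transcript_id = tx_id, protein_id = tx_prot,
                               sequence = tx_seq, cds_start = tx_cds,
                               stringsAsFactors = FALSE),
      planted = data.frame(transcript_id = planted_tx,
                           position = planted_pos,
                           stringsAsFactors = FALSE)
    )
  })
}

# i.i.d. RNA with P(G)=P(C)=gc/2
random_rna <- function(len, gc_fraction) {
  if (len < 1L) stop("random_rna: requested length < 1")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# Overwrite up to n_plant 7-nt uORF motifs (-3 purine | codon | +4 G) at
# non-overlapping positions; start index i satisfies 4 <= i <= len-3 so the
# whole context lies inside the UTR. Returns possibly fewer plants than
# requested when the UTR is too short.
plant_uorfs <- function(utr, n_plant, rule) {
  chars <- strsplit(utr, "")[[1]]
  len <- length(chars)
  candidates <- if (len >= 7L) seq(4L, len - 3L) else integer(0)
  chosen <- integer(0)
  while (length(chosen) < n_plant && length(candidates) > 0L) {
    i <- candidates[sample.int(length(candidates), 1L)]
    chosen <- c(chosen, i)
    candidates <- candidates[abs(candidates - i) > 6L]
  }
  for (i in chosen) {
    codon <- rule$start_codons[sample.int(length(rule$start_codons), 1L)]
    chars[i - 3L] <- rule$minus3_allowed[
      sample.int(length(rule$minus3_allowed), 1L)]
    chars[i:(i + 2L)] <- strsplit(codon, "")[[1]]
    chars[i + 3L] <- rule$plus4_required
  }
  list(seq = paste(chars, collapse = ""), positions = sort(chosen))
}

#' Generate signal-peptide / transmembrane annotation flags
#'
#' In `"stochastic"` mode flags are drawn per protein from the group's
#' configured joint Bernoulli probabilities (`sp`, `tm`, `both`). In
#' `"table3"` fixture mode the generator emits the exact observed group
#' marginals of a 1240-protein study: 237 signal peptides, 177
#' transmembrane domains, 97 with both overall; a designated up-regulated
#' subset of 72 with 27/24/13; and a down-regulated subset of 8 with all
#' flags false.
#'
#' @param config A [sim_config()] object.
#' @param truth Truth data.frame from [gen_proteome()].
#' @param mode `"stochastic"` or `"table3"`.
#' @return A list with `annotations` (data.frame `protein_id`,
#'   `has_signal_peptide`, `has_transmembrane`) and `groups` (data.frame
#'   `protein_id`, `group`): the group assignment under which the
#'   annotation marginals hold.
#' @export
gen_annotations <- function(config, truth, mode = c("stochastic", "table3")) {
  mode <- match.arg(mode)
  validate_sim_config(config)
  if (mode == "table3") {
    if (nrow(truth) != 1240L) {
      stop("gen_annotations: fixture 'table3' requires exactly 1240 ",
           "proteins, got ", nrow(truth))
    }
    ids <- truth$protein_id
    group <- rep("null", 1240L)
    group[1:72] <- "up"
    group[73:80] <- "down"
    sp <- logical(1240L)
    tm <- logical(1240L)
    # up subset of 72: 13 both, then SP-only to 27 SP, TM-only to 24 TM
    sp[1:13] <- TRUE; tm[1:13] <- TRUE
    sp[14:27] <- TRUE
    tm[28:38] <- TRUE
    # remaining 1160 null proteins: 84 both, 126 SP-only, 69 TM-only
    # (totals: 237 SP, 177 TM, 97 both over all 1240)
    sp[81:164] <- TRUE; tm[81:164] <- TRUE
    sp[165:290] <- TRUE
    tm[291:359] <- TRUE
    ann <- data.frame(protein_id = ids, has_signal_peptide = sp,
                      has_transmembrane = tm, stringsAsFactors = FALSE)
    groups <- data.frame(protein_id = ids, group = group,
                         stringsAsFactors = FALSE)
    return(list(annotations = ann, groups = groups))
  }
  with_substream(config$seed, "annotations", {
    n <- nrow(truth)
    u <- runif(n)
    sp <- logical(n)
    tm <- logical(n)
    for (g in c("up", "down", "null")) {
      idx <- truth$status == g
      p <- config$sp_tm_probs[[g]]
      p11 <- p[["both"]]
      p10 <- p[["sp"]] - p11
      p01 <- p[["tm"]] - p11
      sp[idx] <- u[idx] < p11 + p10
      tm[idx] <- u[idx] < p11 | (u[idx] >= p11 + p10 & u[idx] < p11 + p10 + p01)
    }
    list(
      annotations = data.frame(protein_id = truth$protein_id,
                               has_signal_peptide = sp,
                               has_transmembrane = tm,
                               stringsAsFactors = FALSE),
      groups = data.frame(protein_id = truth$protein_id,
                          group = truth$status, stringsAsFactors = FALSE)
    )
  })
}

#' Generate a synthetic metabolite peak table
#'
#' Emulates an LC-MS screen of astrocyte cultures: intracellular (cell)
#' and conditioned-medium samples for both genotypes at two timepoints,
#' plus unconditioned-medium reference samples. Intensities are
#' log-normal per metabolite. One planted metabolite
#' (`PPP_intermediate_synthetic`) is detected only in mutant cell samples,
#' at both timepoints. Medium samples carry metabolites planted lower
#' (consumed: glucose, pyruvate, glutamate, aspartate) or higher
#' (secreted: lactate, glutamine, cis-aconitate, alpha-ketoglutarate)
#' than the unconditioned reference, in both genotypes.
#'
#' @param config A [sim_config()] object.
#' @return A `peak_table` data.frame in long format with columns
#'   `metabolite`, `sample_id`, `intensity`, `genotype`, `compartment`,
#'   `timepoint`. Undetected is encoded as intensity 0.
#' @export
gen_metabolome <- function(config) {
  validate_sim_config(config)
  mp <- config$metabolite_params
  with_substream(config$seed, "metabolome", {
    consumed <- c("glucose", "pyruvate", "glutamate", "aspartate")
    secreted <- c("lactate", "glutamine", "cis-aconitate",
                  "alpha-ketoglutarate")
    background <- sprintf("M%03d", seq_len(mp$n_background))
    planted <- "PPP_intermediate_synthetic"
    mets <- c(background, consumed, secreted, planted)
    base <- setNames(rlnorm(length(mets), mp$meanlog, mp$sdlog_metabolite),
                     mets)

    samples <- rbind(
      expand.grid(genotype = c("wt", "mutant"), compartment = "cell",
                  timepoint = mp$timepoints,
                  rep = seq_len(mp$n_replicates_cell),
                  stringsAsFactors = FALSE),
      expand.grid(genotype = c("wt", "mutant"), compartment = "medium",
                  timepoint = mp$timepoints,
                  rep = seq_len(mp$n_replicates_medium),
                  stringsAsFactors = FALSE),
      expand.grid(genotype = "none", compartment = "unconditioned",
                  timepoint = 0,
                  rep = seq_len(mp$n_replicates_medium),
                  stringsAsFactors = FALSE)
    )
    samples$sample_id <- sprintf("%s_%s_t%g_r%d", samples$genotype,
                                 samples$compartment, samples$timepoint,
                                 samples$rep)

    rows <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      geno <- samples$genotype[s]
      comp <- samples$compartment[s]
      mu <- base
      if (comp == "cell") {
        if (geno == "wt") mu[planted] <- 0
      } else {
        mu[planted] <- 0
        if (comp == "medium") {
          mu[consumed] <- mu[consumed] / mp$flux_fold
          mu[secreted] <- mu[secreted] * mp$flux_fold
        }
      }
      noise <- rlnorm(length(mets), 0, mp$sdlog_replicate)
      rows[[s]] <- data.frame(
        metabolite = mets, sample_id = samples$sample_id[s],
        intensity = mu * noise,
        genotype = geno, compartment = comp,
        timepoint = samples$timepoint[s], stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    structure(tab, class = c("peak_table", "data.frame"))
  })
}

#' Generate a complete synthetic study
#'
#' Runs every generator under named substreams of the master seed, so the
#' full study is reproducible and each component is independent of the
#' others' draws.
#'
#' @param config A [sim_config()] object.
#' @param annotation_mode Passed to [gen_annotations()].
#' @param rule The [uorf_rule()] used for planting uORFs.
#' @return An object of class `synthetic_study`: a list with `quant`,
#'   `truth`, `transcripts`, `planted_uorfs`, `annotations`, `groups`,
#'   `peaks`, and the `config`.
#' @export
simulate_study <- function(config,
                           annotation_mode = c("stochastic", "table3"),
                           rule = uorf_rule()) {
  annotation_mode <- match.arg(annotation_mode)
  prot <- gen_proteome(config)
  tx <- gen_transcripts(config, prot$truth, rule)
  ann <- gen_annotations(config, prot$truth, annotation_mode)
  peaks <- gen_metabolome(config)
  structure(list(
    quant = prot$quant, truth = prot$truth,
    transcripts = tx$transcripts, planted_uorfs = tx$planted,
    annotations = ann$annotations, groups = ann$groups,
    peaks = peaks, config = config
  ), class = "synthetic_study")
}
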