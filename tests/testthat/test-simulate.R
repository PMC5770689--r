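test_that("generators are deterministic and substream-isolated", {
  cfg <- sim_config(seed = 11L, n_proteins = 80L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$quant, b$quant)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$peaks, b$peaks)
  # proteome draws do not depend on whether other generators ran
  solo <- gen_proteome(cfg)
  expect_identical(solo$quant, a$quant)
  expect_identical(gen_metabolome(cfg), a$peaks)
})

test_that("regulation labels follow the configured Bernoulli stream", {
  cfg <- sim_config(seed = 7L, n_proteins = 2000L, frac_regulated = 0.05)
  truth <- gen_proteome(cfg)$truth
  # independent re-draw of the same labelled stream
  redraw <- pulseUTR:::with_substream(7L, "proteome", {
    n <- 2000L
    regulated <- runif(n) < 0.05
    up <- runif(n) < cfg$up_bias
    ifelse(regulated, ifelse(up, "up", "down"), "null")
  })
  expect_identical(truth$status, redraw)
  expect_gt(sum(truth$status != "null"), 0)

  cfg0 <- sim_config(seed = 7L, n_proteins = 500L, frac_regulated = 0)
  expect_true(all(gen_proteome(cfg0)$truth$status == "null"))
})

test_that("quant tables encode swaps and missingness as specified", {
  cfg <- sim_config(seed = 3L, n_proteins = 400L, missing_rate = 0.2,
                    frac_regulated = 0)
  quant <- gen_proteome(cfg)$quant
  m <- pulseUTR:::quant_ratio_matrix(quant)
  expect_identical(attr(quant, "orientation"),
                   c("standard", "standard", "swapped", "swapped"))
  # missing cells are NA, never zero-filled
  expect_gt(sum(is.na(m)), 0)
  frac_missing <- mean(is.na(m))
  se <- sqrt(0.2 * 0.8 / length(m))
  expect_lt(abs(frac_missing - 0.2), 3 * se)
  expect_error(sim_config(noise_sd = Inf), "finite")
  expect_error(sim_config(missing_rate = 1.5), "fraction")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
})

test_that("every planted uORF is recovered by the scanner", {
  cfg <- sim_config(seed = 21L, n_proteins = 60L,
                    uorf_rate = c(up = 3, down = 1, null = 1.5))
  prot <- gen_proteome(cfg)
  tx <- gen_transcripts(cfg, prot$truth)
  expect_gt(nrow(tx$planted), 0)
  for (id in unique(tx$planted$transcript_id)) {
    rec <- tx$transcripts[tx$transcripts$transcript_id == id, ]
    found <- scan_uorfs(rec$sequence, rec$cds_start)$positions
    planted <- tx$planted$position[tx$planted$transcript_id == id]
    expect_true(all(planted %in% found),
                label = paste("planted positions recovered for", id))
  }
  # cds_start marks an AUG main start in every record
  starts <- substr(tx$transcripts$sequence, tx$transcripts$cds_start,
                   tx$transcripts$cds_start + 2L)
  expect_true(all(starts == "AUG"))
})

test_that("UTR composition follows the configured GC content", {
  cfg <- sim_config(seed = 5L, n_proteins = 40L, gc_fraction = 1,
                    uorf_rate = c(up = 0, down = 0, null = 0))
  tx <- gen_transcripts(cfg, gen_proteome(cfg)$truth)
  utrs <- substr(tx$transcripts$sequence, 1L, tx$transcripts$cds_start - 1L)
  gc <- vapply(utrs[nchar(utrs) > 0], gc_percent, numeric(1))
  expect_true(all(gc == 100))
  expect_identical(nrow(tx$planted), 0L)
})

test_that("table3 annotation fixture reproduces the printed marginals", {
  cfg <- sim_config(seed = 1L, n_proteins = 1240L)
  truth <- gen_proteome(cfg)$truth
  ann <- gen_annotations(cfg, truth, mode = "table3")
  flags <- ann$annotations
  expect_identical(nrow(flags), 1240L)
  expect_identical(sum(flags$has_signal_peptide), 237L)
  expect_identical(sum(flags$has_transmembrane), 177L)
  expect_identical(sum(flags$has_signal_peptide & flags$has_transmembrane),
                   97L)
  up <- flags[ann$groups$group == "up", ]
  expect_identical(sum(up$has_signal_peptide), 27L)
  expect_identical(sum(up$has_transmembrane), 24L)
  expect_identical(sum(up$has_signal_peptide & up$has_transmembrane), 13L)
  expect_identical(sum(classify_sp_targeting(up$has_signal_peptide,
                                             up$has_transmembrane)), 38L)
  down <- flags[ann$groups$group == "down", ]
  expect_identical(nrow(down), 8L)
  expect_false(any(down$has_signal_peptide | down$has_transmembrane))

  cfg_small <- sim_config(seed = 1L, n_proteins = 100L)
  truth_small <- gen_proteome(cfg_small)$truth
  expect_error(gen_annotations(cfg_small, truth_small, mode = "table3"),
               "1240")
})

test_that("stochastic annotation frequencies match configured probabilities", {
  cfg <- sim_config(seed = 13L, n_proteins = 5000L, frac_regulated = 0)
  truth <- gen_proteome(cfg)$truth
  ann <- gen_annotations(cfg, truth, mode = "stochastic")$annotations
  p <- cfg$sp_tm_probs$null
  n <- nrow(ann)
  for (obs_p in list(c(mean(ann$has_signal_peptide), p[["sp"]]),
                     c(mean(ann$has_transmembrane), p[["tm"]]),
                     c(mean(ann$has_signal_peptide & ann$has_transmembrane),
                       p[["both"]]))) {
    se <- sqrt(obs_p[2] * (1 - obs_p[2]) / n)
    expect_lt(abs(obs_p[1] - obs_p[2]), 3 * se)
  }
  cfg0 <- sim_config(seed = 13L, n_proteins = 200L, sp_tm_probs = list(
    up = c(sp = 0, tm = 0, both = 0), down = c(sp = 0, tm = 0, both = 0),
    null = c(sp = 0, tm = 0, both = 0)))
  ann0 <- gen_annotations(cfg0, gen_proteome(cfg0)$truth)$annotations
  expect_false(any(ann0$has_signal_peptide | ann0$has_transmembrane))
})

test_that("metabolome plants a mutant-only metabolite and flux shifts", {
  cfg <- sim_config(seed = 2L, n_proteins = 10L)
  peaks <- gen_metabolome(cfg)
  norm <- median_normalize(peaks)
  calls <- presence_calls(norm)
  planted <- calls[calls$metabolite == "PPP_intermediate_synthetic", ]
  expect_identical(planted$pattern, "mutant-only")
  expect_true(planted$consistent_across_timepoints)
  flux <- uptake_secretion(norm)
  for (g in c("wt", "mutant")) {
    sub <- flux[flux$genotype == g, ]
    expect_true(all(c("glucose", "pyruvate", "glutamate", "aspartate") %in%
                      sub$metabolite[sub$class == "consumed"]))
    expect_true(all(c("lactate", "glutamine", "cis-aconitate",
                      "alpha-ketoglutarate") %in%
                      sub$metabolite[sub$class == "secreted"]))
  }
})
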