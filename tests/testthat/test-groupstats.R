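fake_features <- function(protein_id, transcript_id, length,
                          uorf_count = 0L, gc = 50, dg = -5,
                          excluded = FALSE) {
  n <- length(transcript_id)
  excluded <- rep(excluded, length.out = n)
  uorf_count <- rep(uorf_count, length.out = n)
  gc <- rep(gc, length.out = n)
  dg <- rep(dg, length.out = n)
  data.frame(transcript_id = transcript_id, protein_id = protein_id,
             length = length, gc_percent = ifelse(excluded, NA, gc),
             delta_g = ifelse(excluded, NA, dg),
             uorf_count = ifelse(excluded, NA, uorf_count),
             excluded = excluded,
             reason = ifelse(excluded, "min_length", NA),
             stringsAsFactors = FALSE)
}

test_that("profiles weight variants proportionally per protein", {
  feats <- rbind(
    fake_features("A", c("A.1", "A.2"), c(100, 600)),
    fake_features("B", c("B.1", "B.2", "B.3"), c(10, 200, 300),
                  excluded = c(TRUE, FALSE, FALSE)),
    fake_features("C", "C.1", 250))
  groups <- data.frame(protein_id = c("A", "B", "C"),
                       group = c("regulated", "regulated", "non-regulated"))
  prof <- build_profiles(feats, groups)
  expect_equal(prof$weight[prof$protein_id == "A"], c(0.5, 0.5))
  # k recomputed after the min-length exclusion: 2 survivors
  expect_equal(prof$weight[prof$protein_id == "B"], c(0.5, 0.5))
  expect_equal(prof$weight[prof$protein_id == "C"], 1)
  # weights sum to 1 per protein
  expect_true(all(abs(tapply(prof$weight, prof$protein_id, sum) - 1) < 1e-12))
  # a protein whose variants are all excluded is dropped with a message
  feats2 <- rbind(feats, fake_features("D", "D.1", 5, excluded = TRUE))
  groups2 <- rbind(groups, data.frame(protein_id = "D", group = "regulated"))
  expect_message(prof2 <- build_profiles(feats2, groups2), "no included")
  expect_false("D" %in% prof2$protein_id)
  # a protein without any transcript is logged and excluded
  groups3 <- rbind(groups, data.frame(protein_id = "Z", group = "regulated"))
  expect_message(build_profiles(feats, groups3), "without transcripts")
})

test_that("binning follows the published length and uORF conventions", {
  feats <- rbind(fake_features("A", c("A.1", "A.2"), c(100, 600)),
                 fake_features("B", c("B.1", "B.2"), c(200, 200)))
  groups <- data.frame(protein_id = c("A", "B"), group = c("g1", "g2"))
  prof <- build_profiles(feats, groups)
  b <- bin_feature(prof, "length")
  expect_identical(b$bin_labels, c("<150", "150-550", ">550"))
  expect_equal(unname(b$weighted_counts["g1", ]), c(0.5, 0, 0.5))
  expect_equal(unname(b$weighted_counts["g2", ]), c(0, 1, 0))
  # boundary values: 150 and 550 fall in the middle bin, 551 above
  prof2 <- build_profiles(
    fake_features("C", c("C.1", "C.2", "C.3", "C.4"),
                  c(149, 150, 550, 551)),
    data.frame(protein_id = "C", group = "g"))
  b2 <- bin_feature(prof2, "length")
  expect_equal(unname(b2$weighted_counts["g", ]), c(0.25, 0.5, 0.25))
  # uORF counts: integer bins 0..7 then 8+
  prof3 <- build_profiles(
    fake_features("D", sprintf("D.%d", 1:3), c(200, 200, 200),
                  uorf_count = c(0L, 7L, 12L)),
    data.frame(protein_id = "D", group = "g"))
  b3 <- bin_feature(prof3, "uorf_count")
  expect_identical(b3$bin_labels, c(as.character(0:7), "8+"))
  expect_equal(unname(b3$weighted_counts["g", c("0", "7", "8+")]),
               c(1, 1, 1) / 3)
  # a value below the support edge is an upstream-exclusion bug
  prof_bad <- prof
  prof_bad$length[1] <- 5
  expect_error(bin_feature(prof_bad, "length"), "below the support")
})

test_that("weighted histograms match a per-variant accumulation loop", {
  set.seed(11)
  n <- 60
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:4, 1)
    fake_features(sprintf("P%02d", i), sprintf("P%02d.%d", i, seq_len(k)),
                  sample(13:900, k, replace = TRUE))
  }))
  groups <- data.frame(protein_id = sprintf("P%02d", seq_len(n)),
                       group = sample(c("reg", "non"), n, TRUE))
  prof <- build_profiles(feats, groups)
  b <- bin_feature(prof, "length")
  # independent accumulation
  acc <- matrix(0, 2, 3, dimnames = list(c("non", "reg"), NULL))
  for (r in seq_len(nrow(prof))) {
    len <- prof$length[r]
    bin <- if (len < 150) 1 else if (len <= 550) 2 else 3
    acc[prof$group[r], bin] <- acc[prof$group[r], bin] + prof$weight[r]
  }
  expect_equal(unname(b$weighted_counts), unname(acc))
  # conservation: per-group mass equals the protein count
  expect_equal(unname(rowSums(b$weighted_counts)),
               unname(as.numeric(table(groups$group))))
})

test_that("group comparison is null on identical distributions", {
  feats <- rbind(fake_features("A", "A.1", 100),
                 fake_features("B", "B.1", 100),
                 fake_features("C", "C.1", 600),
                 fake_features("D", "D.1", 600))
  groups <- data.frame(protein_id = c("A", "B", "C", "D"),
                       group = c("g1", "g2", "g1", "g2"))
  prof <- build_profiles(feats, groups)
  cmp <- compare_groups(prof, "length", n_perm = 200, seed = 4)
  expect_equal(cmp$chi2_stat, 0)
  expect_gt(cmp$p_value, 0.9)
})

test_that("permutation p-values are invariant to labels and order", {
  set.seed(5)
  n <- 40
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    fake_features(sprintf("P%02d", i), sprintf("P%02d.1", i),
                  sample(13:900, 1))
  }))
  groups <- data.frame(protein_id = sprintf("P%02d", seq_len(n)),
                       group = rep(c("a", "b"), each = n / 2))
  prof <- build_profiles(feats, groups)
  p1 <- compare_groups(prof, "length", n_perm = 500, seed = 7)
  # renaming groups
  groups2 <- groups
  groups2$group <- ifelse(groups$group == "a", "x", "y")
  p2 <- compare_groups(build_profiles(feats, groups2), "length",
                       n_perm = 500, seed = 7)
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$chi2_stat, p2$chi2_stat)
  # reordering proteins
  ord <- sample(n)
  p3 <- compare_groups(build_profiles(feats[ord, ], groups), "length",
                       n_perm = 500, seed = 7)
  expect_equal(p1$p_value, p3$p_value)
})

test_that("single-variant weighting reduces to unweighted chi-square", {
  set.seed(17)
  n <- 80
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    fake_features(sprintf("P%02d", i), sprintf("P%02d.1", i),
                  sample(c(60, 300, 700), 1))
  }))
  groups <- data.frame(protein_id = sprintf("P%02d", seq_len(n)),
                       group = rep(c("a", "b"), each = n / 2))
  prof <- build_profiles(feats, groups)
  cmp <- compare_groups(prof, "length", method = "chi-square-rounded")
  tab <- table(groups$group,
               cut(feats$length[match(groups$protein_id,
                                      feats$protein_id)],
                   c(0, 149.5, 550.5, Inf)))
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(cmp$chi2_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_value, unname(ref$p.value), tolerance = 1e-12)
  # permutation statistic equals the analytic statistic on the same counts
  cmp_p <- compare_groups(prof, "length", n_perm = 100, seed = 1)
  expect_equal(cmp_p$chi2_stat, cmp$chi2_stat, tolerance = 1e-12)
})

test_that("planted length shifts are detected by the permutation test", {
  set.seed(77)
  n <- 120
  mk_len <- function(g) {
    if (g == "reg") round(rlnorm(1, log(400), 0.5))
    else round(rlnorm(1, log(150), 0.5))
  }
  groups <- data.frame(protein_id = sprintf("P%03d", seq_len(n)),
                       group = rep(c("reg", "non"), each = n / 2))
  feats <- do.call(rbind, lapply(seq_len(n), function(i) {
    fake_features(groups$protein_id[i], sprintf("%s.1",
                                                groups$protein_id[i]),
                  max(13, mk_len(groups$group[i])))
  }))
  prof <- build_profiles(feats, groups)
  cmp <- compare_groups(prof, "length", n_perm = 500, seed = 3)
  expect_lt(cmp$p_value, 0.05)
})
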