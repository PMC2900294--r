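test_that("ROC endpoints and degenerate cases are exact", {
  r <- roc_auc(c(3, 4, 5), c(0, 1, 2))
  expect_equal(r$auc, 1.0)
  expect_equal(r$tpr_at_fpr10, 1.0)
  r2 <- roc_auc(rep(1, 10), rep(1, 7))
  expect_equal(r2$auc, 0.5)
  expect_equal(r2$fpr[1], 0)
  expect_equal(r2$tpr[length(r2$tpr)], 1)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
  expect_error(roc_auc(c(1, NA), c(0)), "non-finite")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair statistic", {
  set.seed(31)
  for (rep in 1:5) {
    pos <- round(rnorm(120, 0.4), 1)  # coarse rounding forces ties
    neg <- round(rnorm(80), 1)
    r <- roc_auc(pos, neg)
    expect_equal(r$auc, brute_mw_auc(pos, neg), tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
  }
})

test_that("AUC is invariant under increasing transforms and flips under swap", {
  set.seed(32)
  pos <- rnorm(60, 1)
  neg <- rnorm(60)
  a <- roc_auc(pos, neg)$auc
  expect_equal(roc_auc(exp(pos), exp(neg))$auc, a)
  expect_equal(roc_auc(5 * pos - 2, 5 * neg - 2)$auc, a)
  expect_equal(roc_auc(neg, pos)$auc, 1 - a)
})

test_that("pattern significance is calibrated, powered, and seeded", {
  # boundary: a constant PSFM gives p = 1
  g <- c(c1 = strrep("A", 3000))
  d <- data.frame(chrom = "c1", pos = seq(1200, 1800, by = 100),
                  confidence = 1)
  sig <- pattern_significance(d, g, n_sets = 50, seed = 1)
  expect_equal(unname(sig$p), rep(1, 4))
  expect_equal(unname(sig$delta_obs), rep(0, 4))
  # reproducible under a fixed seed; granularity 1/(1+n_sets)
  set.seed(33)
  g2 <- c(c1 = paste(sample(c("A", "C", "G", "T"), 30000, TRUE),
                     collapse = ""))
  d2 <- data.frame(chrom = "c1", pos = sort(sample(1500:28000, 80)),
                   confidence = 1)
  s1 <- pattern_significance(d2, g2, n_sets = 100, seed = 7)
  s2 <- pattern_significance(d2, g2, n_sets = 100, seed = 7)
  expect_identical(s1$p, s2$p)
  expect_true(all(s1$p >= 1 / 101 & s1$p <= 1))
  # planted oscillation attains the smallest attainable p
  spec <- generator_spec(genome_length = 50000, n_chromosomes = 1,
                         seed = 34L)
  sim <- simulate_genome(spec)
  s3 <- pattern_significance(sim$dyads, sim$genome, n_sets = 100,
                             seed = 2)
  expect_equal(unname(s3$p), rep(1 / 101, 4))
  expect_error(pattern_significance(d2, g2, n_sets = 0), "n_sets")
})

test_that("inter-dyad distances follow their definition and null", {
  d <- data.frame(chrom = "c1", pos = seq(0, 165 * 30, by = 165),
                  confidence = 1)
  h <- interdyad_histogram(d, max_dist = 300)
  expect_equal(h$count[h$distance == 165], 30L)
  expect_equal(sum(h$count), 30L)
  # no cross-chromosome distances
  d2 <- data.frame(chrom = rep(c("a", "b"), each = 2),
                   pos = c(0, 100, 5, 50), confidence = 1)
  h2 <- interdyad_histogram(d2, max_dist = 200)
  expect_equal(sum(h2$count), 2L)
  expect_equal(which(h2$count == 1), c(45L, 100L))
  expect_error(interdyad_histogram(data.frame(chrom = c("a", "b"),
                                              pos = c(1, 2),
                                              confidence = 1)),
               "at least 2")
  # Bernoulli placement matches the geometric pmf within multinomial error
  set.seed(35)
  pos <- which(stats::runif(1.7e6) < 1 / 165) - 1L
  db <- data.frame(chrom = "c1", pos = pos, confidence = 1)
  hb <- interdyad_histogram(db, max_dist = 700, mean_spacing = 165)
  expct <- pmax(hb$expected, 1e-12)
  chi2 <- sum((hb$count - expct)^2 / expct)
  # chi-square per bin should be ~1 under the null
  expect_lt(chi2 / nrow(hb), 1.5)
})

test_that("anchored profiles align, flip strands, and find planted offsets", {
  # a profile over one anchor is that anchor's own score trace
  fake_scores <- function(chrom, pos) sin(pos / 10)
  a1 <- data.frame(chrom = "c", pos = 100L, strand = "+")
  pr <- anchored_profile(fake_scores, a1, 20)
  expect_equal(pr$mean, sin((80:120) / 10))
  expect_equal(pr$n, rep(1L, 41))
  # constant scores give a flat profile
  prc <- anchored_profile(function(ch, p) rep(2, length(p)),
                          data.frame(chrom = "c", pos = c(10L, 50L)), 5)
  expect_equal(prc$mean, rep(2, 11))
  # minus-strand anchors are flipped
  a2 <- data.frame(chrom = "c", pos = c(100L, 100L),
                   strand = c("+", "-"))
  pr2 <- anchored_profile(fake_scores, a2, 10)
  fwd <- sin((90:110) / 10)
  expect_equal(pr2$mean, (fwd + rev(fwd)) / 2)
  expect_error(anchored_profile(fake_scores, a1[0, ], 10), "no anchors")

  # synthetic anchors at a fixed offset from planted dyads peak there
  world <- tiny_world()
  dyads <- world$dyads[world$dyads$chrom == "chr1", ]
  wins <- extract_windows(world$genome[["chr1"]], dyads$pos, 301)
  pats <- learn_patterns(wins[!is.na(wins)], 2)
  tr <- assemble_training_set(dyads, world$genome, pats, L = 110)
  fit <- train_linear(tr$X, tr$y)
  anchors <- data.frame(chrom = "chr1", pos = dyads$pos[5:40] - 30L,
                        strand = "+")
  prof <- anchored_profile(score_function(world$genome, fit, pats),
                           anchors, 60)
  expect_lte(abs(prof$offset[which.max(prof$mean)] - 30L), 1L)
})

test_that("windows are assigned to the variant that generated them", {
  spec <- generator_spec(seed = 36L)
  wins <- simulate_windows(spec, 400)
  mono <- lapply(stats::setNames(nm = c("A", "C", "G", "T")),
                 function(n) learn_pattern(wins, n))
  vars <- permuted_variants(mono)
  # windows from the canonical generator map to AGCT
  test_wins <- simulate_windows(generator_spec(seed = 37L), 60)
  got <- vapply(test_wins, assign_variant, character(1), variants = vars)
  expect_gt(mean(got == "AGCT"), 0.9)
  # windows from the reversed-profile generator (position-reversed windows,
  # i.e. the A curve moved onto T and C onto G) map to the
  # reverse-complement variant TCGA
  rev_wins <- vapply(test_wins, function(s) intToUtf8(rev(utf8ToInt(s))),
                     character(1), USE.NAMES = FALSE)
  got_rev <- vapply(rev_wins, assign_variant, character(1), variants = vars)
  expect_gt(mean(got_rev == "TCGA"), 0.9)
  # uniform random windows are predominantly no-match at threshold 0.2
  rnd <- random_windows(60, nchar(wins[1]), seed = 38,
                        probs = rep(0.25, 4))
  got_rnd <- vapply(rnd, assign_variant, character(1), variants = vars)
  expect_gt(mean(got_rnd == "no-match"), 0.5)
})

test_that("repeat fractions match a per-base brute-force check", {
  set.seed(39)
  dyads <- data.frame(chrom = "c1", pos = sort(sample(200:9800, 50)),
                      confidence = 1)
  s <- sort(sample(0:9900, 30))
  repeats <- data.frame(chrom = "c1", start = s,
                        end = s + sample(20:400, 30, TRUE))
  fr <- repeat_fraction(dyads, repeats, window = 200)
  # brute force: mark covered bases
  mask <- logical(11000)
  for (i in seq_len(nrow(repeats))) {
    mask[(repeats$start[i] + 1):repeats$end[i]] <- TRUE
  }
  want <- vapply(dyads$pos, function(p) {
    mean(mask[(p - 100 + 1):(p + 100)])
  }, numeric(1))
  expect_equal(fr, want, tolerance = 1e-12)

  part <- partition_by_repeat(dyads, repeats)
  expect_equal(nrow(part$low) + nrow(part$mid) + nrow(part$high),
               nrow(dyads))
  expect_true(all(attr(part, "fraction")[dyads$pos %in% part$high$pos] >
                    0.75))
  # no repeats at all: everything lands in the low subset
  none <- partition_by_repeat(dyads, repeats[0, ])
  expect_equal(nrow(none$low), nrow(dyads))
  # full coverage: everything high
  full <- partition_by_repeat(dyads,
                              data.frame(chrom = "c1", start = 0,
                                         end = 11000))
  expect_equal(nrow(full$high), nrow(dyads))
  expect_error(repeat_fraction(dyads,
                               data.frame(chrom = "c1", start = 5,
                                          end = 5)),
               "malformed")
})
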