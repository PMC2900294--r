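test_that("k-mer classes enumerate reverse-complement equivalence", {
  expect_equal(nrow(kmer_classes(1)), 2L)
  cl2 <- kmer_classes(2)
  expect_equal(nrow(cl2), 12L)
  expect_equal(sum(cl2$k == 2 & cl2$palindromic), 4L)
  expect_setequal(cl2$rep[cl2$palindromic & cl2$k == 2],
                  c("AT", "TA", "CG", "GC"))
  cl3 <- kmer_classes(3)
  expect_equal(nrow(cl3), 44L)
  # brute-force enumeration oracle: collapse all 4 + 16 + 64 k-mers
  all_kmers <- unlist(lapply(1:3, function(k) {
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1,
          paste, collapse = "")
  }))
  canon <- unique(pmin(all_kmers, reverse_complement(all_kmers)))
  expect_setequal(cl3$rep, canon)
  expect_true(all(cl3$rep <= cl3$partner))
  expect_error(kmer_classes(4), "k_max")
})

test_that("numeric representation counts overlapping matches at starts", {
  v <- numeric_representation("AAAAA", "AA")
  expect_equal(v, c(1, 1, 1, 1, 0))
  expect_equal(sum(v), 4)
  expect_equal(numeric_representation("CCCCC", "AA"), rep(0, 5))
  expect_error(numeric_representation("ACG", "ACGT"), "longer")
  # forward + revcomp representations sum to the double-strand brute count
  wins <- random_windows(40, 301, seed = 2)
  cl <- kmer_classes(3)
  ms <- c("A", "AA", "AT", cl$rep[sample.int(nrow(cl), 6)])
  for (w in wins[1:8]) {
    for (m in ms) {
      both <- sum(numeric_representation(w, m)) +
        sum(numeric_representation(reverse_complement(w), m))
      expect_equal(both, brute_count(w, m) +
                     brute_count(reverse_complement(w), m))
    }
  }
})

test_that("learned patterns are standardized and order-invariant", {
  wins <- random_windows(60, 61, seed = 3)
  p <- learn_pattern(wins, "AA")
  expect_equal(mean(p$values), 0, tolerance = 1e-9)
  expect_equal(mean(p$values^2), 1, tolerance = 1e-9)
  expect_equal(p$n_sequences, 60L)
  # permutation invariance
  p2 <- learn_pattern(wins[sample.int(60)], "AA")
  expect_equal(p2$values, p$values)
  # identical windows give the standardized single-window representation
  one <- rep(wins[1], 5)
  rep1 <- numeric_representation(wins[1], "AA") +
    numeric_representation(reverse_complement(wins[1]), "AA")
  p3 <- learn_pattern(one, "AA")
  expect_equal(p3$values, (rep1 - mean(rep1)) / sqrt(mean((rep1 - mean(rep1))^2)))
  expect_error(learn_pattern(paste(rep("A", 61), collapse = ""), "C"),
               "degenerate")
})

test_that("mirror identity holds exactly for every class", {
  wins <- random_windows(50, 41, seed = 4)
  W <- 41L
  cl <- kmer_classes(3)
  for (i in seq_len(nrow(cl))) {
    k <- cl$k[i]
    pm <- learn_pattern(wins, cl$rep[i])$values
    pr <- learn_pattern(wins, cl$partner[i])$values
    # P_revcomp(m)[x] = P_m[-x-(k-1)]: valid support reversed, tail equal
    expect_equal(pr[1:(W - k + 1)], rev(pm[1:(W - k + 1)]),
                 tolerance = 1e-9)
    if (k > 1) {
      expect_equal(pr[(W - k + 2):W], pm[(W - k + 2):W], tolerance = 1e-9)
    }
  }
})

test_that("learn_patterns agrees with single-kmer learning", {
  wins <- random_windows(30, 31, seed = 6)
  pats <- learn_patterns(wins, 3)
  expect_length(pats, 44L)
  expect_equal(attr(pats, "W"), 31L)
  for (nm in c("A", "AA", "AT", "CG", "AAC", "CAG")) {
    expect_equal(pats[[nm]]$values, learn_pattern(wins, nm)$values)
  }
})

test_that("reflect reverses values, preserves standardization, involutes", {
  wins <- random_windows(40, 41, seed = 7)
  p <- learn_pattern(wins, "AAC")
  r <- reflect(p)
  expect_equal(r$values, rev(p$values))
  expect_equal(reflect(r)$values, p$values)
  expect_equal(mean(r$values), 0, tolerance = 1e-12)
  # palindromic dinucleotide patterns are symmetric up to the 1-bp start
  # offset convention: reflect(p) equals p shifted by k-1 = 1 position
  p_at <- learn_pattern(random_windows(400, 61, seed = 9), "AT")
  refl <- reflect(p_at)$values
  expect_gt(cor(refl[2:61], p_at$values[1:60]), 0.999)
})

test_that("planted asymmetric ramp reflects element-wise", {
  ramp <- .standardize_for_test(seq(-1, 1, length.out = 21)^3)
  p <- structure(list(kmer = "A", k = 1L, W = 21L, values = ramp,
                      n_sequences = 1L, standardized = TRUE),
                 class = "nuc_pattern")
  expect_equal(reflect(p)$values, rev(ramp))
})

test_that("artifact interpolation removes localized bumps", {
  W <- 201L
  h <- (W - 1L) %/% 2L
  x <- seq(-h, h)
  smooth <- cos(2 * pi * x / 150)
  mk <- function(v) {
    structure(list(kmer = "A", k = 1L, W = W,
                   values = .standardize_for_test(v),
                   n_sequences = 1L, standardized = TRUE),
              class = "nuc_pattern")
  }
  # a pattern already linear inside the interval is a fixed point
  lin <- mk(0.01 * x)
  out <- interpolate_artifact(lin, centers = c(-80, 80), half_width = 15)
  expect_equal(out$values, lin$values, tolerance = 1e-9)
  # spike on a flat-ish background is removed
  spiky <- 0.01 * x
  spiky[x == -80] <- spiky[x == -80] + 5
  out2 <- interpolate_artifact(mk(spiky), centers = -80, half_width = 15)
  expect_lt(max(abs(diff(out2$values))), 0.1)
  # bumps at +/-80 on a smooth profile: interpolation restores correlation
  bumps <- 0.8 * exp(-(x - 80)^2 / 8) + 0.8 * exp(-(x + 80)^2 / 8)
  noisy <- mk(smooth + bumps)
  fixed <- interpolate_artifact(noisy)
  expect_gt(cor(fixed$values, smooth), cor(noisy$values, smooth))
  # interval must stay inside the pattern
  expect_error(interpolate_artifact(mk(smooth), centers = 95),
               "exceeds")
})

test_that("permuted variants assign curves per the maxima-order labels", {
  wins <- simulate_windows(generator_spec(seed = 31L), 300)
  mono <- lapply(stats::setNames(nm = c("A", "C", "G", "T")),
                 function(n) learn_pattern(wins, n))
  vars <- permuted_variants(mono)
  expect_named(vars, c("AGCT", "ACGT", "TGCA", "TCGA"))
  # AGCT is the identity assignment
  for (n in c("A", "C", "G", "T")) {
    expect_equal(vars$AGCT[[n]]$values, mono[[n]]$values)
    expect_equal(vars$AGCT[[n]]$kmer, n)
  }
  # TCGA swaps A<->T and C<->G curves
  expect_equal(vars$TCGA$A$values, mono$T$values)
  expect_equal(vars$TCGA$T$values, mono$A$values)
  expect_equal(vars$TCGA$C$values, mono$G$values)
  expect_equal(vars$TCGA$G$values, mono$C$values)
  # TGCA swaps only A<->T; ACGT only C<->G
  expect_equal(vars$TGCA$A$values, mono$T$values)
  expect_equal(vars$TGCA$C$values, mono$C$values)
  expect_equal(vars$ACGT$C$values, mono$G$values)
  expect_equal(vars$ACGT$A$values, mono$A$values)
  expect_error(permuted_variants(mono[c("A", "C")]), "must contain")
})

test_that("un-standardized mono curves sum to a constant per offset", {
  wins <- random_windows(80, 41, seed = 12)
  raw <- lapply(c("A", "C", "G", "T"), function(n) {
    learn_pattern(wins, n, standardize = FALSE)$values
  })
  sums <- Reduce(`+`, raw)
  # both strands contribute one base per offset each: total 2
  expect_equal(sums, rep(2, 41), tolerance = 1e-12)
})

test_that("patterns round-trip through the TSV + JSON bundle", {
  wins <- random_windows(25, 31, seed = 13)
  pats <- learn_patterns(wins, 2)
  dir <- withr::local_tempdir()
  write_patterns(pats, dir)
  back <- read_patterns(dir)
  expect_equal(names(back), names(pats))
  for (nm in names(pats)) {
    expect_equal(back[[nm]]$values, pats[[nm]]$values, tolerance = 1e-12)
  }
  expect_equal(attr(back, "k_max"), attr(pats, "k_max"))
})
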