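# Seeded synthetic genomes, dyads, windows and reads with the statistical
# structure the dyad model assumes: an i.i.d. background plus a planted
# per-offset nucleotide profile around each dyad, and full-length reads
# jittered around the true dyads.
#
# The planted profile mimics the qualitative shape of the nucleosome
# composition pattern: GC enriched in the core and AT in the linkers, the A
# curve ramping downward 5'->3' with T its mirror image, a G bump about
# 40 bp 5' of the dyad with the C bump mirrored 3', an optional 10-bp
# periodic component, and optional additive cut-site bumps at +/-80 bp
# emulating the MNase artifact. The profile is reverse-complement symmetric
# by construction: p_A(x) = p_T(-x) and p_C(x) = p_G(-x).

#' Create a synthetic-data generator specification
#'
#' All randomness downstream flows from `seed`: [simulate_genome()] seeds
#' with `seed`, [simulate_reads()] with `seed + 1`, [simulate_windows()]
#' with `seed + 2`.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_chromosomes Number of chromosomes (cross-validation needs >= 2).
#' @param gc Background GC fraction.
#' @param spacing `"fixed"` or `"geometric"` inter-dyad spacing.
#' @param mean_spacing Mean dyad-to-dyad distance in bp (nucleosome repeat
#'   length; default 165).
#' @param profile_halfwidth Planted-profile half-width in bp (default 150,
#'   i.e. a 301-bp profile).
#' @param ramp_amp Amplitude of the 5'->3' A/T ramp (probability units).
#' @param bump_amp Amplitude of the G/C bumps at `bump_center`.
#' @param bump_center Offset of the G bump 5' of the dyad (default 40).
#' @param bump_sd Gaussian width of the G/C bumps.
#' @param core_amp Amplitude of the GC-core / AT-linker trend.
#' @param period_amp Amplitude of the optional 10-bp periodic component
#'   (default 0 = off).
#' @param artifact_amp Amplitude of additive composition bumps at
#'   `+/- artifact_center` bp emulating MNase cut-site bias (default 0 =
#'   off).
#' @param artifact_center Offset of the artifact bumps (default 80).
#' @param effect Mixing weight of profile versus background in `[0, 1]`.
#' @param read_length_mean,read_length_sd Read-length model (defaults 156 /
#'   10; lengths are truncated at 100).
#' @param jitter_sd SD of the Gaussian dyad jitter of read midpoints.
#' @param depth Reads per dyad.
#' @param seed Mandatory RNG seed.
#' @return A `nuc_genspec` list.
#' @export
generator_spec <- function(genome_length = 2e5, n_chromosomes = 2L,
                           gc = 0.4, spacing = c("fixed", "geometric"),
                           mean_spacing = 165L, profile_halfwidth = 150L,
                           ramp_amp = 0.16, bump_amp = 0.20,
                           bump_center = 40L, bump_sd = 30,
                           core_amp = 0.10, period_amp = 0.05,
                           artifact_amp = 0, artifact_center = 80L,
                           effect = 1, read_length_mean = 156,
                           read_length_sd = 10, jitter_sd = 5,
                           depth = 20L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  spacing <- match.arg(spacing)
  if (profile_halfwidth > mean_spacing) {
    stop("planted profile wider than the mean dyad spacing")
  }
  spec <- structure(list(genome_length = as.integer(genome_length),
                         n_chromosomes = as.integer(n_chromosomes),
                         gc = gc, spacing = spacing,
                         mean_spacing = as.integer(mean_spacing),
                         profile_halfwidth = as.integer(profile_halfwidth),
                         ramp_amp = ramp_amp, bump_amp = bump_amp,
                         bump_center = as.integer(bump_center),
                         bump_sd = bump_sd, core_amp = core_amp,
                         period_amp = period_amp,
                         artifact_amp = artifact_amp,
                         artifact_center = as.integer(artifact_center),
                         effect = effect,
                         read_length_mean = read_length_mean,
                         read_length_sd = read_length_sd,
                         jitter_sd = jitter_sd, depth = as.integer(depth),
                         seed = as.integer(seed)),
                    class = "nuc_genspec")
  pr <- planted_profile(spec)
  if (any(pr <= 0) || any(pr >= 1) ||
      max(abs(colSums(pr) - 1)) > 1e-9) {
    stop("invalid spec: per-offset probabilities must lie in (0,1) and sum to 1")
  }
  spec
}

#' Planted per-offset nucleotide profile of a generator spec
#'
#' @param spec A `nuc_genspec`.
#' @return 4 x (2*halfwidth+1) matrix of probabilities, rows A, C, G, T;
#'   columns (offsets) sum to 1.
#' @export
planted_profile <- function(spec) {
  hw <- spec$profile_halfwidth
  x <- seq.int(-hw, hw)
  baseA <- (1 - spec$gc) / 2
  baseC <- spec$gc / 2
  core <- spec$core_amp * exp(-x^2 / (2 * (hw / 2)^2))
  fA <- -spec$ramp_amp * x / hw - core +
    spec$period_amp * sin(2 * pi * x / 10)
  fT <- rev(fA)
  fG <- spec$bump_amp * exp(-(x + spec$bump_center)^2 / (2 * spec$bump_sd^2)) +
    core
  fC <- rev(fG)
  if (spec$artifact_amp > 0) {
    art <- spec$artifact_amp *
      (exp(-(x + spec$artifact_center)^2 / (2 * 5^2)))
    fA <- fA + art
    fT <- fT + rev(art)
  }
  m <- rbind(A = baseA + fA, C = baseC + fC, G = baseC + fG, T = baseA + fT)
  m <- pmax(m, 1e-3)
  sweep(m, 2L, colSums(m), "/")
}

# Sample one base per column from a 4 x n probability matrix.
.sample_bases <- function(probs) {
  cp1 <- probs[1L, ]
  cp2 <- cp1 + probs[2L, ]
  cp3 <- cp2 + probs[3L, ]
  u <- stats::runif(ncol(probs))
  idx <- 1L + (u > cp1) + (u > cp2) + (u > cp3)
  c("A", "C", "G", "T")[idx]
}

.background_probs <- function(spec) {
  c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
    T = (1 - spec$gc) / 2)
}

#' Simulate a genome with planted dyad-centered composition
#'
#' Background bases are i.i.d. at the stated GC fraction. Around each
#' planted dyad, per-offset probabilities are mixed between the planted
#' profile and the background with weight `effect`. Where the profiles of
#' neighbouring dyads would overlap (the profile is wider than half the
#' spacing), each base follows the profile of its nearest dyad.
#'
#' @param spec A `nuc_genspec`.
#' @return List with `genome` (named character vector) and `dyads` (truth
#'   `data.frame` with `chrom`, `pos`, `confidence` = 1).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "nuc_genspec"))
  set.seed(spec$seed)
  len <- spec$genome_length
  hw <- spec$profile_halfwidth
  prof <- planted_profile(spec)
  bg <- .background_probs(spec)
  mix <- spec$effect * prof + (1 - spec$effect) * matrix(bg, 4L, ncol(prof))
  genome <- character(spec$n_chromosomes)
  names(genome) <- paste0("chr", seq_len(spec$n_chromosomes))
  dyad_list <- list()
  margin <- hw + 210L   # room for +/-L linker windows at chromosome ends
  for (ci in seq_len(spec$n_chromosomes)) {
    if (spec$spacing == "fixed") {
      pos <- seq.int(margin, len - margin - 1L, by = spec$mean_spacing)
    } else {
      gaps <- stats::rgeom(ceiling(2 * len / spec$mean_spacing),
                           prob = 1 / spec$mean_spacing) + 1L
      pos <- margin + cumsum(gaps)
      pos <- pos[pos < len - margin]
    }
    probs <- matrix(bg, 4L, len)
    if (length(pos) > 0L) {
      bounds <- c(-Inf, (pos[-length(pos)] + pos[-1L]) / 2, Inf)
      for (i in seq_along(pos)) {
        lo <- max(pos[i] - hw, ceiling(bounds[i]))
        hi <- min(pos[i] + hw, floor(bounds[i + 1L] - 1e-9), len - 1L)
        if (hi < lo) next
        probs[, (lo + 1L):(hi + 1L)] <-
          mix[, (lo - pos[i] + hw + 1L):(hi - pos[i] + hw + 1L)]
      }
    }
    genome[ci] <- paste(.sample_bases(probs), collapse = "")
    dyad_list[[ci]] <- data.frame(chrom = names(genome)[ci], pos = pos,
                                  confidence = 1,
                                  stringsAsFactors = FALSE)
  }
  list(genome = genome, dyads = as_dyadset(do.call(rbind, dyad_list)))
}

#' Simulate dyad-aligned windows directly from the planted profile
#'
#' Draws `n` windows of width `2*halfwidth + 1` whose per-offset base
#' probabilities are the planted profile mixed with background at the
#' stated effect size; used for clean parameter-recovery checks without the
#' neighbouring-nucleosome structure of a full genome.
#'
#' @param spec A `nuc_genspec`.
#' @param n Number of windows.
#' @return Character vector of `n` windows.
#' @export
simulate_windows <- function(spec, n) {
  stopifnot(inherits(spec, "nuc_genspec"))
  set.seed(spec$seed + 2L)
  prof <- planted_profile(spec)
  bg <- .background_probs(spec)
  mix <- spec$effect * prof + (1 - spec$effect) * matrix(bg, 4L, ncol(prof))
  vapply(seq_len(n),
         function(i) paste(.sample_bases(mix), collapse = ""),
         character(1))
}

#' Simulate full-length reads around true dyads
#'
#' Each dyad yields `depth` reads whose midpoint is the dyad plus rounded
#' Gaussian jitter and whose length is Normal(mean, sd) truncated at 100 bp;
#' reads are clipped to the contig. The triangle apex of a simulated read
#' falls on its (jittered) midpoint.
#'
#' @param dyads Truth dyad `data.frame`.
#' @param spec A `nuc_genspec`.
#' @return Read `data.frame` (`chrom`, `start`, `end`), sorted.
#' @export
simulate_reads <- function(dyads, spec) {
  stopifnot(inherits(spec, "nuc_genspec"))
  if (spec$depth < 1L) stop("depth must be >= 1")
  set.seed(spec$seed + 1L)
  n <- nrow(dyads) * spec$depth
  mid <- rep(dyads$pos, each = spec$depth) +
    round(stats::rnorm(n, 0, spec$jitter_sd))
  lens <- pmax(100L, round(stats::rnorm(n, spec$read_length_mean,
                                        spec$read_length_sd)))
  start <- mid - (lens - 1L) %/% 2L
  end <- start + lens
  reads <- data.frame(chrom = rep(dyads$chrom, each = spec$depth),
                      start = pmax(start, 0L),
                      end = pmin(end, spec$genome_length),
                      stringsAsFactors = FALSE)
  reads <- reads[reads$end > reads$start, , drop = FALSE]
  reads[order(reads$chrom, reads$start, reads$end), , drop = FALSE]
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `genome.fa`, `dyads.tsv` (truth), `reads.bed`, and `spec.json`;
#' the files round-trip through the package readers, and a spec re-read
#' from `spec.json` regenerates identical fixtures.
#'
#' @param spec A `nuc_genspec`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_fixtures <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(spec)
  reads <- simulate_reads(sim$dyads, spec)
  paths <- list(fasta = file.path(outdir, "genome.fa"),
                dyads = file.path(outdir, "dyads.tsv"),
                reads = file.path(outdir, "reads.bed"),
                spec = file.path(outdir, "spec.json"))
  write_fasta(sim$genome, paths$fasta)
  write_dyads(sim$dyads, paths$dyads)
  write_reads(reads, paths$reads)
  jsonlite::write_json(unclass(spec), paths$spec, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a generator spec back from `spec.json`
#'
#' @param path Path to a spec JSON written by [write_fixtures()].
#' @return A `nuc_genspec`.
#' @export
read_generator_spec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(generator_spec, vals)
}
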