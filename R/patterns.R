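# Position-specific k-mer patterns learned from dyad-aligned windows.
#
# A pattern P_m for a k-mer m is the per-offset average, over all training
# windows, of the indicator vectors of exact (possibly overlapping) matches
# of m on both strands, standardized to mean 0 / variance 1 (population
# moments). Matches are recorded at their start offset (leftmost base), and
# each strand is read in its own 5'->3' direction; this makes the patterns of
# reverse-complementary k-mers exact mirror images of one another:
#   P_revcomp(m)[x] = P_m[-x-(k-1)].

#' Reverse-complement equivalence classes of k-mers
#'
#' Double-stranded DNA makes a k-mer and its reverse complement
#' indistinguishable, so k-mers are grouped into classes represented by the
#' lexicographically smaller member. For k_max = 3 there are 2 + 10 + 32 = 44
#' classes.
#'
#' @param k_max Maximum k-mer length (1 to 3).
#' @return `data.frame` with columns `rep` (canonical k-mer), `partner`
#'   (its reverse complement), `k`, and `palindromic`, in deterministic order
#'   (k ascending, then `rep` lexicographic).
#' @export
kmer_classes <- function(k_max = 3L) {
  if (!is.numeric(k_max) || k_max < 1L || k_max > 3L) {
    stop("k_max must be 1, 2, or 3")
  }
  out <- lapply(seq_len(k_max), function(k) {
    kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1,
                               drop = FALSE],
                   1L, paste, collapse = "")
    rc <- reverse_complement(kmers)
    rep_ <- ifelse(kmers <= rc, kmers, rc)
    data.frame(rep = sort(unique(rep_)), k = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$partner <- reverse_complement(out$rep)
  out$palindromic <- out$rep == out$partner
  out[, c("rep", "partner", "k", "palindromic")]
}

#' Indicator vector of k-mer matches in a window
#'
#' Length-W numeric vector with a 1 added at the start offset of every exact
#' (possibly overlapping) match of `m`; the trailing k-1 entries are
#' structurally zero. The companion vector for the other strand is obtained
#' by calling this on `reverse_complement(w)`.
#'
#' @param w Window string of width W.
#' @param m k-mer to match.
#' @return Numeric vector of length W.
#' @export
numeric_representation <- function(w, m) {
  W <- nchar(w)
  k <- nchar(m)
  if (k > W) stop("k-mer longer than window")
  n <- W - k + 1L
  v <- as.numeric(substring(w, 1:n, k:W) == m)
  c(v, numeric(k - 1L))
}

.standardize <- function(v, what = "pattern") {
  mu <- mean(v)
  sd <- sqrt(mean((v - mu)^2))
  if (sd < 1e-12) stop("degenerate ", what, ": zero variance")
  (v - mu) / sd
}

.new_pattern <- function(values, kmer, n_sequences, standardized) {
  structure(list(kmer = kmer, k = nchar(kmer), W = length(values),
                 values = values, n_sequences = n_sequences,
                 standardized = standardized),
            class = "nuc_pattern")
}

#' @export
print.nuc_pattern <- function(x, ...) {
  cat(sprintf("<nuc_pattern %s: W=%d, n=%d, %s>\n", x$kmer, x$W,
              x$n_sequences,
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

#' Offsets of a pattern relative to the dyad
#'
#' @param p A `nuc_pattern`.
#' @return Integer vector from -(W-1)/2 to +(W-1)/2.
#' @export
pattern_offsets <- function(p) {
  h <- (p$W - 1L) %/% 2L
  seq.int(-h, h)
}

#' Learn the positional pattern of one k-mer from dyad-aligned windows
#'
#' Averages the forward- and reverse-strand indicator vectors (each strand
#' read in its own 5'->3' frame) over all windows, then standardizes to mean
#' 0 / variance 1.
#'
#' @param windows Character vector of equal-width, odd-width windows.
#' @param m k-mer (any of the 4^k raw k-mers, not only class representatives).
#' @param standardize Standardize the averaged pattern (default `TRUE`).
#' @return A `nuc_pattern`.
#' @export
learn_pattern <- function(windows, m, standardize = TRUE) {
  stopifnot(length(windows) >= 1L)
  W <- nchar(windows[[1L]])
  if (W %% 2L != 1L) stop("window width must be odd")
  k <- nchar(m)
  codes <- .encode_windows(windows)
  K <- .kmer_codes(codes, k)
  cc <- .kmer_to_code(m)
  cp <- .kmer_to_code(reverse_complement(m))
  nk <- ncol(K)
  f_m <- .col_code_counts(K, cc, 4L^k)
  f_p <- .col_code_counts(K, cp, 4L^k)
  avg <- c(f_m + rev(f_p), numeric(k - 1L)) / nrow(codes)
  vals <- if (standardize) .standardize(avg) else avg
  .new_pattern(vals, m, nrow(codes), standardize)
}

# Per-column count of a single k-mer code.
.col_code_counts <- function(K, code, n_codes) {
  colSums(K == code)
}

#' Learn the full set of class patterns for k-mers up to k_max
#'
#' One pattern per reverse-complement class (see [kmer_classes()]), learned
#' in a single vectorized pass over the encoded windows.
#'
#' @inheritParams learn_pattern
#' @param k_max Maximum k-mer length.
#' @return Named list of `nuc_pattern` objects keyed by class representative,
#'   with attributes `k_max` and `W`; class `nuc_patterns`.
#' @export
learn_patterns <- function(windows, k_max = 3L, standardize = TRUE) {
  stopifnot(length(windows) >= 1L)
  W <- nchar(windows[[1L]])
  if (W %% 2L != 1L) stop("window width must be odd")
  classes <- kmer_classes(k_max)
  codes <- .encode_windows(windows)
  n <- nrow(codes)
  pats <- vector("list", nrow(classes))
  names(pats) <- classes$rep
  for (k in seq_len(k_max)) {
    K <- .kmer_codes(codes, k)
    # counts[x, code]: occurrences of each k-mer code at each start column
    counts <- t(apply(K, 2L, tabulate, nbins = 4L^k))
    if (ncol(K) == 1L) counts <- matrix(counts, nrow = 1L)
    sel <- which(classes$k == k)
    for (i in sel) {
      cc <- .kmer_to_code(classes$rep[i])
      cp <- .kmer_to_code(classes$partner[i])
      avg <- c(counts[, cc] + rev(counts[, cp]), numeric(k - 1L)) / n
      vals <- if (standardize) .standardize(avg) else avg
      pats[[classes$rep[i]]] <- .new_pattern(vals, classes$rep[i], n,
                                             standardize)
    }
  }
  structure(pats, k_max = k_max, W = W, class = "nuc_patterns")
}

#' Reflect a pattern across the dyad axis
#'
#' Reverses the values along the offset axis; standardization is preserved.
#'
#' @param p A `nuc_pattern`.
#' @return The reflected `nuc_pattern`.
#' @export
reflect <- function(p) {
  stopifnot(inherits(p, "nuc_pattern"))
  p$values <- rev(p$values)
  p
}

#' Linearly interpolate a pattern across artifact regions
#'
#' Removes localized artifacts (such as the MNase cut-site composition bump
#' roughly 80 bp on either side of the dyad in fully sequenced read data) by
#' replacing values inside each `[center - half_width, center + half_width]`
#' interval with the straight line joining the boundary values, then
#' re-standardizing.
#'
#' @param p A `nuc_pattern`.
#' @param centers Offsets of the artifact centers (default `c(-80, 80)`).
#' @param half_width Half-width of each interpolation interval in bp
#'   (default 15, i.e. a 30-bp region).
#' @return The repaired, standardized `nuc_pattern`.
#' @export
interpolate_artifact <- function(p, centers = c(-80L, 80L), half_width = 15L) {
  stopifnot(inherits(p, "nuc_pattern"))
  h <- (p$W - 1L) %/% 2L
  v <- p$values
  for (ctr in centers) {
    lo <- ctr - half_width
    hi <- ctr + half_width
    if (lo < -h || hi > h) stop("interpolation interval exceeds pattern extent")
    i_lo <- lo + h + 1L
    i_hi <- hi + h + 1L
    v[i_lo:i_hi] <- seq(v[i_lo], v[i_hi], length.out = i_hi - i_lo + 1L)
  }
  p$values <- .standardize(v)
  p$standardized <- TRUE
  p
}

#' Build the four permuted mono-nucleotide pattern variants
#'
#' The canonical pattern is named AGCT after the 5'-to-3' order of the local
#' maxima of the four nucleotide curves. The variants permute which
#' nucleotide carries which curve while conforming to the same overall
#' AT-linker / GC-core shape: the curves, in their canonical maxima order
#' (A, G, C, T), are assigned to the letters of the variant label in order.
#' TGCA therefore swaps the A and T curves, ACGT swaps C and G, and TCGA
#' swaps both.
#'
#' @param mono_patterns Named list with elements `A`, `C`, `G`, `T`: the four
#'   learned mono-nucleotide patterns.
#' @return Named list of four variant sets (`AGCT`, `ACGT`, `TGCA`, `TCGA`),
#'   each a named list of patterns keyed by the nucleotide whose indicator is
#'   correlated against the assigned curve.
#' @export
permuted_variants <- function(mono_patterns) {
  if (!all(c("A", "C", "G", "T") %in% names(mono_patterns))) {
    stop("mono_patterns must contain A, C, G, and T")
  }
  shape_order <- c("A", "G", "C", "T")  # canonical 5'->3' maxima order
  labels <- c("AGCT", "ACGT", "TGCA", "TCGA")
  out <- lapply(labels, function(lab) {
    letters_ <- strsplit(lab, "")[[1L]]
    v <- vector("list", 4L)
    names(v) <- letters_
    for (i in 1:4) {
      p <- mono_patterns[[shape_order[i]]]
      p$kmer <- letters_[i]
      v[[letters_[i]]] <- p
    }
    v[c("A", "C", "G", "T")]
  })
  names(out) <- labels
  out
}

#' Write a pattern set as TSV files with a JSON sidecar
#'
#' Each pattern is written as a two-column TSV (`offset`, `value`); the
#' sidecar records the class table, W, n_sequences and standardization flag.
#'
#' @param patterns A `nuc_patterns` list.
#' @param dir Output directory (created if missing).
#' @export
write_patterns <- function(patterns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(patterns)) {
    p <- patterns[[nm]]
    utils::write.table(
      data.frame(offset = pattern_offsets(p), value = p$values),
      file.path(dir, paste0("pattern_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- list(kmers = names(patterns),
               k_max = attr(patterns, "k_max"),
               W = attr(patterns, "W"),
               n_sequences = patterns[[1L]]$n_sequences,
               standardized = patterns[[1L]]$standardized)
  jsonlite::write_json(meta, file.path(dir, "patterns.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a pattern set written by [write_patterns()]
#'
#' @param dir Directory containing `pattern_*.tsv` and `patterns.json`.
#' @return A `nuc_patterns` list.
#' @export
read_patterns <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "patterns.json"),
                              simplifyVector = TRUE)
  pats <- lapply(meta$kmers, function(nm) {
    d <- utils::read.table(file.path(dir, paste0("pattern_", nm, ".tsv")),
                           header = TRUE, sep = "\t")
    .new_pattern(d$value, nm, meta$n_sequences, meta$standardized)
  })
  names(pats) <- meta$kmers
  structure(pats, k_max = meta$k_max, W = meta$W, class = "nuc_patterns")
}
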