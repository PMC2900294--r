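# Correlation + count features of the dyad model.
#
# For each k-mer class, a window contributes three features: the correlation
# of its two-strand match-indicator vectors with the learned pattern
# (corr_fwd), the same correlation against the reflected pattern (corr_refl),
# and the total count of class occurrences on both strands. Each correlation
# term is normalized by W, so it is a Pearson coefficient of the indicator
# vector against the standardized pattern; the unnormalized sum used when the
# patterns were first described differs only by a constant scale that the SVM
# weights absorb. A zero-variance indicator vector (no occurrences, or a
# window made of one repeated base) contributes 0 - the count feature exists
# precisely to distinguish that case from a true lack of correlation.

#' Correlate a window with a pattern
#'
#' The forward-strand indicator vector of `p$kmer` in `w`, and the
#' reverse-strand indicator mapped back onto the forward axis (marking the
#' end offsets of `revcomp(p$kmer)` occurrences), are each standardized to
#' mean 0 / variance 1, dotted with `p$values`, divided by W, and summed.
#'
#' @param w Window string of width `p$W`.
#' @param p A standardized `nuc_pattern`.
#' @return Correlation value in `[-2, 2]`.
#' @export
correlate <- function(w, p) {
  stopifnot(inherits(p, "nuc_pattern"))
  W <- nchar(w)
  if (W != p$W) stop("window width does not match pattern width")
  k <- p$k
  n <- W - k + 1L
  kms_f <- substring(w, 1:n, k:W)
  i1 <- which(kms_f == p$kmer)                               # m starts in S
  i2 <- which(kms_f == reverse_complement(p$kmer)) + (k - 1L) # m' ends in S
  .corr_term(i1, p$values, W) + .corr_term(i2, p$values, W)
}

# Pearson term for a binary indicator with ones at `idx` against pattern
# values `pv` (any mean); zero-variance indicators contribute 0.
.corr_term <- function(idx, pv, W) {
  cnt <- length(idx)
  if (cnt == 0L || cnt == W) return(0)
  mu <- cnt / W
  sd <- sqrt(mu - mu^2)
  (sum(pv[idx]) - mu * sum(pv)) / (sd * W)
}

#' Count occurrences of a k-mer class on both strands of a window
#'
#' Overlapping occurrences of the class representative in `w` plus those in
#' `reverse_complement(w)`. Palindromic classes are counted once per strand
#' (both strands still summed).
#'
#' @param w Window string.
#' @param cls Either a single row of [kmer_classes()] or a k-mer string
#'   (taken as the class representative).
#' @return Non-negative integer count.
#' @export
count_kmer <- function(w, cls) {
  m <- if (is.character(cls)) cls else cls$rep
  k <- nchar(m)
  W <- nchar(w)
  n <- W - k + 1L
  kms_f <- substring(w, 1:n, k:W)
  sum(kms_f == m) + sum(kms_f == reverse_complement(m))
}

#' Feature names for a pattern set
#'
#' @param patterns A `nuc_patterns` list.
#' @return Character vector of length `3 * length(patterns)`.
#' @export
feature_names <- function(patterns) {
  as.vector(vapply(names(patterns),
                   function(nm) paste0(nm, c("_corr_fwd", "_corr_refl",
                                             "_count")),
                   character(3)))
}

#' Build the feature matrix for a set of windows
#'
#' Ordered concatenation, class by class (order of [kmer_classes()]), of
#' (corr_fwd, corr_refl, count). For k_max = 3 the dimension is
#' 44 classes x 3 = 132.
#'
#' @param windows Character vector of windows of width `attr(patterns, "W")`.
#' @param patterns A standardized `nuc_patterns` list covering all classes.
#' @return Numeric matrix, one row per window, with named columns.
#' @export
build_feature_matrix <- function(windows, patterns) {
  W <- attr(patterns, "W")
  k_max <- attr(patterns, "k_max")
  classes <- kmer_classes(k_max)
  if (!all(classes$rep %in% names(patterns))) {
    stop("pattern set is missing classes for k_max = ", k_max)
  }
  if (any(nchar(windows) != W)) stop("window width does not match patterns")
  codes <- .encode_windows(windows)
  n <- nrow(codes)
  X <- matrix(0, n, 3L * nrow(classes),
              dimnames = list(NULL, feature_names(patterns)))
  for (k in seq_len(k_max)) {
    K <- .kmer_codes(codes, k)
    nk <- ncol(K)
    sel <- which(classes$k == k)
    for (i in sel) {
      p <- patterns[[classes$rep[i]]]
      pv <- p$values
      pr <- rev(pv)
      cc <- .kmer_to_code(classes$rep[i])
      cp <- .kmer_to_code(classes$partner[i])
      M1 <- K == cc
      M2 <- if (cp == cc) M1 else K == cp
      n1 <- rowSums(M1)
      n2 <- rowSums(M2)
      # m matches at start offsets; m' occurrences marked at end offsets
      s1f <- M1 %*% pv[1:nk];      s1r <- M1 %*% pr[1:nk]
      s2f <- M2 %*% pv[k:W];       s2r <- M2 %*% pr[k:W]
      mu1 <- n1 / W; sd1 <- sqrt(pmax(mu1 - mu1^2, 0))
      mu2 <- n2 / W; sd2 <- sqrt(pmax(mu2 - mu2^2, 0))
      sp <- sum(pv)
      t1f <- ifelse(sd1 > 0, (s1f - mu1 * sp) / (sd1 * W), 0)
      t2f <- ifelse(sd2 > 0, (s2f - mu2 * sp) / (sd2 * W), 0)
      t1r <- ifelse(sd1 > 0, (s1r - mu1 * sp) / (sd1 * W), 0)
      t2r <- ifelse(sd2 > 0, (s2r - mu2 * sp) / (sd2 * W), 0)
      j <- 3L * (i - 1L)
      X[, j + 1L] <- t1f + t2f
      X[, j + 2L] <- t1r + t2r
      X[, j + 3L] <- n1 + n2
    }
  }
  X
}

#' Build the feature vector for a single window
#'
#' @inheritParams build_feature_matrix
#' @param w A single window string.
#' @return Named numeric vector of length `3 * number of classes`.
#' @export
build_features <- function(w, patterns) {
  drop(build_feature_matrix(w, patterns))
}
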