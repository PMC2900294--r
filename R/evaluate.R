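# Evaluation machinery: ROC/AUC, the empirical pattern-significance null,
# inter-dyad spacing against a geometric null, anchored score profiles,
# pattern-variant assignment, and repeat-content partitioning.

#' ROC curve and trapezoidal AUC for dyad-versus-linker scores
#'
#' The curve is swept from the maximum score down; tied scores contribute
#' diagonal segments, so the trapezoidal area equals the Mann-Whitney
#' statistic P(pos > neg) + 0.5 P(pos = neg). Perfectly separated scores
#' give AUC 1.0 and all-tied scores give 0.5. Also reports the true positive
#' rate at a 10% false positive rate, the operating point used when
#' comparing dyad models.
#'
#' @param pos_scores,neg_scores Numeric score vectors (finite, non-empty).
#' @return A `nuc_roc`: list with `auc`, `fpr`, `tpr`, `thresholds`,
#'   `tpr_at_fpr10`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score sets must be non-empty")
  }
  if (!all(is.finite(c(pos_scores, neg_scores)))) {
    stop("non-finite scores")
  }
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t) sum(pos_scores == t),
                            numeric(1))) / length(pos_scores))
  fpr <- c(0, cumsum(vapply(thr, function(t) sum(neg_scores == t),
                            numeric(1))) / length(neg_scores))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(auc = auc, fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, thr),
                 tpr_at_fpr10 = .tpr_at_fpr(fpr, tpr, 0.10),
                 n_pos = length(pos_scores), n_neg = length(neg_scores)),
            class = "nuc_roc")
}

#' @export
print.nuc_roc <- function(x, ...) {
  cat(sprintf("<nuc_roc: AUC=%.4f, TPR@FPR10=%.3f (%d pos, %d neg)>\n",
              x$auc, x$tpr_at_fpr10, x$n_pos, x$n_neg))
  invisible(x)
}

.tpr_at_fpr <- function(fpr, tpr, at) {
  stats::approx(fpr, tpr, xout = at, ties = max, rule = 2)$y
}

#' Position-specific frequency matrix of aligned windows
#'
#' Per-offset nucleotide frequencies across equal-width windows (forward
#' strand).
#'
#' @param windows Character vector of equal-width windows without N.
#' @return 4 x W matrix with rows A, C, G, T; columns sum to 1.
#' @export
psfm <- function(windows) {
  codes <- .encode_windows(windows)
  counts <- apply(codes, 2L, tabulate, nbins = 4L)
  m <- counts / nrow(codes)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# PSFM delta (max - min per nucleotide) for windows of `span` centered at
# 0-based positions `pos` on chromosome code vectors; positions whose window
# overruns or contains N are dropped. Returns NULL when no window survives.
.psfm_delta <- function(code_vecs, chrom, pos, span) {
  h <- (span - 1L) %/% 2L
  counts <- matrix(0, 4L, span)
  total <- 0L
  for (ch in unique(chrom)) {
    cv <- code_vecs[[ch]]
    p <- pos[chrom == ch]
    p <- p[p - h >= 0L & p + h < length(cv)]
    if (length(p) == 0L) next
    idx <- outer(p - h + 1L, 0:(span - 1L), "+")
    sub <- matrix(cv[idx], nrow = length(p))
    bad <- rowSums(is.na(sub)) > 0L
    sub <- sub[!bad, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (l in 1:4) counts[l, ] <- counts[l, ] + colSums(sub == l)
    total <- total + nrow(sub)
  }
  if (total == 0L) return(NULL)
  freq <- counts / total
  apply(freq, 1L, function(r) max(r) - min(r))
}

#' Empirical significance of the per-nucleotide pattern variation
#'
#' The observed statistic for each nucleotide is the difference between the
#' absolute maximum and minimum of its trace across the `span`-bp PSFM of
#' the dyad-aligned windows. The null distribution is built from `n_sets`
#' random sets, each the same size as the dyad set, obtained by jittering
#' every dyad to a uniformly random position within `jitter` bp in either
#' direction. Empirical p-values use the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_sets)`, so the attainable floor
#' is `1/(1 + n_sets)`.
#'
#' @param dyads Dyad `data.frame`.
#' @param genome Named character vector of chromosomes.
#' @param n_sets Number of random sets (>= 1). The original analysis used
#'   800,000; the default here is a desk-scale 1,000.
#' @param jitter Maximum displacement in bp (default 1000).
#' @param span Odd PSFM width in bp (default 151).
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `delta_obs` (named, A/C/G/T), `p` (named empirical
#'   p-values), `null` (n_sets x 4 matrix of null deltas), `n_sets`.
#' @export
pattern_significance <- function(dyads, genome, n_sets = 1000L,
                                 jitter = 1000L, span = 151L, seed = NULL) {
  if (n_sets < 1L) stop("n_sets must be >= 1")
  if (span %% 2L != 1L) stop("span must be odd")
  if (!is.null(seed)) set.seed(seed)
  code_vecs <- lapply(genome, .encode_seq)
  delta_obs <- .psfm_delta(code_vecs, dyads$chrom, dyads$pos, span)
  if (is.null(delta_obs)) stop("no valid dyad windows")
  names(delta_obs) <- c("A", "C", "G", "T")
  n <- nrow(dyads)
  offsets_pool <- c(-(jitter:1), 1:jitter)
  null <- matrix(NA_real_, n_sets, 4L,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  for (s in seq_len(n_sets)) {
    off <- sample(offsets_pool, n, replace = TRUE)
    d <- .psfm_delta(code_vecs, dyads$chrom, dyads$pos + off, span)
    if (!is.null(d)) null[s, ] <- d
  }
  ok <- stats::complete.cases(null)
  null <- null[ok, , drop = FALSE]
  p <- (1 + colSums(sweep(null, 2L, delta_obs, ">=") * 1)) / (1 + nrow(null))
  list(delta_obs = delta_obs, p = p, null = null, n_sets = nrow(null))
}

#' Inter-dyad distance histogram with a geometric reference
#'
#' Distances between successive positions on the same chromosome, overlaid
#' with the geometric probability mass expected if positions were placed at
#' random with the stated mean spacing.
#'
#' @param dyads Sorted dyad (or predicted local-maximum) `data.frame`.
#' @param max_dist Largest distance tabulated (default 500).
#' @param mean_spacing Mean spacing of the geometric reference (default 165,
#'   a typical nucleosome repeat length).
#' @return `data.frame` with `distance`, `count`, `expected` (geometric pmf
#'   scaled by the number of distances).
#' @export
interdyad_histogram <- function(dyads, max_dist = 500L, mean_spacing = 165) {
  dists <- unlist(lapply(split(dyads$pos, dyads$chrom), function(p) {
    if (length(p) < 2L) numeric(0) else diff(sort(p))
  }), use.names = FALSE)
  if (length(dists) == 0L) {
    stop("need at least 2 positions on some chromosome")
  }
  d <- seq_len(max_dist)
  count <- tabulate(dists[dists <= max_dist], nbins = max_dist)
  expected <- length(dists) * stats::dgeom(d - 1L, prob = 1 / mean_spacing)
  data.frame(distance = d, count = count, expected = expected)
}

#' Score function bound to a genome and model
#'
#' Convenience closure for [anchored_profile()].
#'
#' @inheritParams score_position
#' @return `function(chrom, pos)` returning dyad scores.
#' @export
score_function <- function(genome, model, patterns) {
  force(genome); force(model); force(patterns)
  function(chrom, pos) score_position(genome, chrom, pos, model, patterns)
}

#' Average score profile around a set of anchors
#'
#' Scores are computed at every offset around each anchor; minus-strand
#' anchors are flipped so that profiles align 5' to 3'. The mean is taken
#' per offset over the anchors with a valid score there.
#'
#' @param score_fn `function(chrom, pos)` returning scores (NA allowed),
#'   e.g. from [score_function()].
#' @param anchors `data.frame` with `chrom`, `pos`, and optionally `strand`
#'   ("+" / "-", default "+").
#' @param half_width Profile half-width in bp.
#' @return `data.frame` with `offset`, `mean`, `n` (anchors contributing).
#' @export
anchored_profile <- function(score_fn, anchors, half_width) {
  if (nrow(anchors) == 0L) stop("no anchors")
  if (is.null(anchors$strand)) anchors$strand <- "+"
  offs <- seq.int(-half_width, half_width)
  acc <- numeric(length(offs))
  cnt <- integer(length(offs))
  for (i in seq_len(nrow(anchors))) {
    sc <- score_fn(anchors$chrom[i], anchors$pos[i] + offs)
    if (anchors$strand[i] == "-") sc <- rev(sc)
    ok <- !is.na(sc)
    acc[ok] <- acc[ok] + sc[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  if (all(cnt == 0L)) stop("no valid anchors")
  data.frame(offset = offs, mean = ifelse(cnt > 0L, acc / cnt, NA_real_),
             n = cnt)
}

#' Assign a window to one of the four pattern variants
#'
#' Each variant set is scored as the sum of the four single-strand
#' mono-nucleotide correlations of the window against the variant's curves;
#' the window is assigned to the best variant if its score exceeds
#' `threshold`, and to `"no-match"` otherwise (ties are also no-match).
#' The correlation here reads only the query strand: folding in the reverse
#' strand (as the dyad-score features do) would make each variant
#' indistinguishable from its reverse-complement partner, because the mono
#' curves come in mirror pairs.
#'
#' @param w Window string.
#' @param variants Named list of four variant pattern sets from
#'   [permuted_variants()].
#' @param threshold Minimum summed correlation (default 0.2).
#' @return Character label: one of `names(variants)` or `"no-match"`.
#' @export
assign_variant <- function(w, variants, threshold = 0.2) {
  scores <- vapply(variants, function(v) {
    sum(vapply(v, function(p) .correlate_single(w, p), numeric(1)))
  }, numeric(1))
  best <- max(scores)
  if (best <= threshold || sum(scores == best) > 1L) return("no-match")
  names(scores)[which.max(scores)]
}

# Forward-strand-only pattern correlation (Pearson term of the query
# strand's indicator vector against the pattern).
.correlate_single <- function(w, p) {
  W <- nchar(w)
  if (W != p$W) stop("window width does not match pattern width")
  idx <- which(substring(w, 1:(W - p$k + 1L), p$k:W) == p$kmer)
  .corr_term(idx, p$values, W)
}

# Merge sorted intervals (data.frame start/end, half-open) per chromosome.
.merge_intervals <- function(iv) {
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  if (nrow(iv) <= 1L) return(iv)
  out_s <- iv$start[1L]; out_e <- iv$end[1L]
  ss <- ee <- numeric(0)
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= out_e) {
      out_e <- max(out_e, iv$end[i])
    } else {
      ss <- c(ss, out_s); ee <- c(ee, out_e)
      out_s <- iv$start[i]; out_e <- iv$end[i]
    }
  }
  data.frame(start = c(ss, out_s), end = c(ee, out_e))
}

#' Repeat-content fraction around each dyad
#'
#' Fraction of the `window` bases centered at each dyad (positions
#' `pos - window/2` to `pos + window/2 - 1`) covered by the repeat
#' intervals.
#'
#' @param dyads Dyad `data.frame`.
#' @param repeats `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open repeat intervals).
#' @param window Window width in bp (default 200).
#' @return Numeric vector of fractions in `[0, 1]`, one per dyad.
#' @export
repeat_fraction <- function(dyads, repeats, window = 200L) {
  if (any(repeats$end <= repeats$start)) stop("malformed repeat intervals")
  h <- window %/% 2L
  out <- numeric(nrow(dyads))
  for (ch in unique(dyads$chrom)) {
    sel <- dyads$chrom == ch
    iv <- repeats[repeats$chrom == ch, c("start", "end"), drop = FALSE]
    if (nrow(iv) == 0L) next
    iv <- .merge_intervals(iv)
    lo <- dyads$pos[sel] - h
    hi <- lo + window            # half-open [lo, hi)
    cov <- vapply(seq_along(lo), function(i) {
      sum(pmax(0, pmin(iv$end, hi[i]) - pmax(iv$start, lo[i])))
    }, numeric(1))
    out[sel] <- cov / window
  }
  out
}

#' Partition dyads by a per-dyad scalar
#'
#' Generic three-way split used for repeat-content and base-composition
#' partitions.
#'
#' @param dyads Dyad `data.frame`.
#' @param values Numeric vector, one value per dyad.
#' @param lo,hi Cut points: `values < lo` is "low", `values > hi` is "high",
#'   the remainder is "mid".
#' @return Named list of three dyad `data.frame`s (`low`, `mid`, `high`).
#' @export
partition_dyads <- function(dyads, values, lo, hi) {
  stopifnot(length(values) == nrow(dyads))
  list(low = dyads[values < lo, , drop = FALSE],
       mid = dyads[values >= lo & values <= hi, , drop = FALSE],
       high = dyads[values > hi, , drop = FALSE])
}

#' Partition dyads by local repeat content
#'
#' Splits a dyad set into "<25% repeat", intermediate, and ">75% repeat"
#' subsets according to the fraction of repeat-annotated bases in a 200-bp
#' window centered at each dyad.
#'
#' @inheritParams repeat_fraction
#' @param lo,hi Fraction cut points (default 0.25 / 0.75).
#' @return Named list (`low`, `mid`, `high`) of dyad `data.frame`s, with the
#'   computed fractions as attribute `fraction`.
#' @export
partition_by_repeat <- function(dyads, repeats, window = 200L, lo = 0.25,
                                hi = 0.75) {
  fr <- repeat_fraction(dyads, repeats, window)
  out <- partition_dyads(dyads, fr, lo, hi)
  attr(out, "fraction") <- fr
  out
}
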