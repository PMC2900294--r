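# Dyad calling from fully sequenced mapped reads.
#
# Each mapped read is represented on the genomic axis by a triangle of
# height 1 whose base is the read itself; the overlapping triangles are
# summed into a "dyad" trace, and all local maxima within centered windows
# of 141 nt are called dyad positions. The confidence of a call is the
# number of reads whose interval contains it.

#' Triangle-kernel dyad trace from mapped reads
#'
#' Each read `[start, end)` contributes a piecewise-linear kernel that is 0
#' at its first and last base, rises to 1 at the read midpoint, and is
#' evaluated at integer positions. Even-length reads place the apex at the
#' left of the two central positions.
#'
#' @param reads `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom Chromosome to build the trace for (defaults to the single
#'   chromosome present).
#' @param len Trace length in bp (defaults to the maximum read end).
#' @return Numeric vector of length `len`; element i is the trace at 0-based
#'   position i-1. Carries attribute `chrom`.
#' @export
triangle_trace <- function(reads, chrom = NULL, len = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(reads$chrom)
    if (length(chrom) != 1L) stop("specify `chrom`: multiple chromosomes")
  }
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  if (any(r$end <= r$start)) stop("zero-length read")
  if (is.null(len)) len <- max(r$end)
  trace <- numeric(len)
  for (i in seq_len(nrow(r))) {
    s <- r$start[i]
    e <- r$end[i] - 1L              # last covered base
    mid <- s + (r$end[i] - r$start[i] - 1L) %/% 2L
    x <- s:e
    v <- ifelse(x <= mid,
                if (mid > s) (x - s) / (mid - s) else 1,
                (e - x) / (e - mid))
    lo <- max(s, 0L)
    hi <- min(e, len - 1L)
    if (hi >= lo) {
      keep <- x >= lo & x <= hi
      trace[(lo + 1L):(hi + 1L)] <- trace[(lo + 1L):(hi + 1L)] + v[keep]
    }
  }
  attr(trace, "chrom") <- chrom
  trace
}

# Per-position read coverage (number of read intervals containing each
# position), as a length-`len` vector.
.read_coverage <- function(reads, chrom, len) {
  r <- reads[reads$chrom == chrom, , drop = FALSE]
  d <- numeric(len + 1L)
  s <- pmax(r$start, 0L) + 1L
  e <- pmin(r$end, len) + 1L
  for (i in seq_len(nrow(r))) {
    if (e[i] > s[i]) {
      d[s[i]] <- d[s[i]] + 1
      d[e[i]] <- d[e[i]] - 1
    }
  }
  cumsum(d)[seq_len(len)]
}

#' Call dyad positions as windowed local maxima of a trace
#'
#' A position is called when it achieves the maximum of the trace within a
#' centered window (default 141 nt) and the trace is positive there. Plateau
#' and exact ties are resolved to the leftmost position, so calls are always
#' at least `(window-1)/2 + 1` bp apart.
#'
#' @param trace Numeric trace (e.g. from [triangle_trace()]).
#' @param window Odd exclusion-window width in nt (default 141).
#' @param reads Optional read `data.frame`; when given, each call's
#'   confidence is the number of locally overlapping reads (reads whose
#'   interval contains the called position). Otherwise confidence = trace
#'   height.
#' @param positive_only Require trace > 0 at a call (default TRUE).
#' @return `data.frame` with `chrom`, `pos` (0-based), `height`,
#'   `confidence`.
#' @export
call_dyads <- function(trace, window = 141L, reads = NULL,
                       positive_only = TRUE) {
  if (length(trace) == 0L) stop("empty trace")
  if (window %% 2L != 1L) stop("window must be odd")
  chrom <- attr(trace, "chrom")
  if (is.null(chrom)) chrom <- "chr"
  h <- (window - 1L) %/% 2L
  x <- as.numeric(trace)
  xp <- c(rep(-Inf, h), x, rep(-Inf, h))
  rmax <- zoo::rollmax(xp, k = window, align = "center", fill = NULL)
  cand <- which(x == rmax)
  if (positive_only) cand <- cand[x[cand] > 0]
  # leftmost tie-break: drop any candidate within h of an accepted call
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last > h) {
      keep <- c(keep, i)
      last <- i
    }
  }
  pos <- keep - 1L
  conf <- if (!is.null(reads)) {
    cov <- .read_coverage(reads, chrom, length(trace))
    cov[keep]
  } else {
    x[keep]
  }
  data.frame(chrom = rep(chrom, length(pos)), pos = pos,
             height = x[keep], confidence = conf,
             stringsAsFactors = FALSE)
}

#' Highest-confidence fraction of a set of dyad calls
#'
#' @param calls `data.frame` from [call_dyads()] (needs `confidence`,
#'   `chrom`, `pos`).
#' @param f Fraction in (0, 1]; the top `ceiling(f * n)` calls are kept.
#' @return Dyad `data.frame` sorted by (chrom, pos). Ties at the cut are
#'   broken deterministically by (confidence desc, chrom, pos).
#' @export
top_fraction <- function(calls, f) {
  if (nrow(calls) == 0L) stop("empty call set")
  if (f <= 0 || f > 1) stop("f must be in (0, 1]")
  ord <- order(-calls$confidence, calls$chrom, calls$pos)
  keep <- calls[ord[seq_len(ceiling(f * nrow(calls)))], , drop = FALSE]
  keep <- keep[order(keep$chrom, keep$pos), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
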