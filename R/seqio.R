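# Sequence and interval I/O.
#
# Coordinate conventions used throughout the package:
#   * all genomic coordinates are 0-based;
#   * a dyad position is the coordinate of the central nucleotide;
#   * sequence windows are inclusive on both ends and always of odd width W,
#     with window offsets x running from -(W-1)/2 to +(W-1)/2 (x = 0 at the
#     queried position);
#   * read intervals are 0-based half-open [start, end).

#' Read a (possibly line-wrapped) multi-record FASTA file
#'
#' Sequences are folded to uppercase and any character outside `{A,C,G,T,N}`
#' is mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("empty FASTA record: ", paste(names(seqs)[empty], collapse = ", "))
  }
  gsub("[^ACGTN]", "N", seqs)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a dyad table
#'
#' Tab-delimited columns `chrom`, `pos`, `confidence` (header optional).
#' The result is sorted by (chrom, pos); duplicated (chrom, pos) records are
#' collapsed to the one with maximum confidence, with a warning.
#'
#' @param path Path to a tab-delimited dyad table.
#' @return `data.frame` with columns `chrom`, `pos` (0-based integer),
#'   `confidence`.
#' @export
read_dyads <- function(path) {
  if (!file.exists(path)) stop("dyad table not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first, fixed = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos", "confidence"))
  if (!is.numeric(d$pos) || any(d$pos != floor(d$pos))) {
    stop("dyad positions must be integers")
  }
  if (any(d$pos < 0)) stop("negative dyad position")
  d$pos <- as.integer(d$pos)
  as_dyadset(d)
}

#' Normalize a dyad data.frame into a sorted, deduplicated DyadSet
#'
#' @param d `data.frame` with columns `chrom`, `pos` and optionally
#'   `confidence` (defaults to 0).
#' @return Sorted, deduplicated dyad `data.frame`.
#' @export
as_dyadset <- function(d) {
  stopifnot(all(c("chrom", "pos") %in% names(d)))
  if (is.null(d$confidence)) d$confidence <- 0
  d <- d[, c("chrom", "pos", "confidence")]
  key <- paste(d$chrom, d$pos)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate dyad position(s) collapsed, ",
            "keeping maximum confidence")
    d <- d[order(key, -d$confidence), ]
    d <- d[!duplicated(paste(d$chrom, d$pos)), ]
  }
  d <- d[order(d$chrom, d$pos), ]
  rownames(d) <- NULL
  d
}

#' Write a dyad table
#'
#' @param dyads Dyad `data.frame` (`chrom`, `pos`, `confidence`).
#' @param path Output path.
#' @export
write_dyads <- function(dyads, path) {
  utils::write.table(dyads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read mapped-read intervals (BED3)
#'
#' @param path Path to a BED3 file (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("read table not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[, 1:3]
  names(d) <- c("chrom", "start", "end")
  if (any(d$end <= d$start)) stop("read intervals must satisfy end > start")
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write mapped-read intervals as BED3
#'
#' @param reads `data.frame` with `chrom`, `start`, `end`.
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  utils::write.table(reads[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a window of odd width centered at a position
#'
#' Returns `NULL` when the window would overrun the chromosome or contains
#' `N`; callers skip such positions rather than padding, which would distort
#' positional frequencies.
#'
#' @param seq Chromosome sequence (single uppercase string).
#' @param pos 0-based position of the central nucleotide.
#' @param W Odd window width.
#' @return Character string of length `W`, or `NULL`.
#' @export
extract_window <- function(seq, pos, W) {
  if (W %% 2L != 1L) stop("window width W must be odd")
  h <- (W - 1L) %/% 2L
  lo <- pos - h
  if (lo < 0L || pos + h >= nchar(seq)) return(NULL)
  w <- substr(seq, lo + 1L, pos + h + 1L)
  if (grepl("N", w, fixed = TRUE)) return(NULL)
  w
}

#' Extract windows for many positions at once
#'
#' @inheritParams extract_window
#' @param pos Integer vector of 0-based positions.
#' @return Character vector of length `length(pos)`; entries are `NA` where
#'   the window is not extractable.
#' @export
extract_windows <- function(seq, pos, W) {
  if (W %% 2L != 1L) stop("window width W must be odd")
  h <- (W - 1L) %/% 2L
  ok <- pos - h >= 0L & pos + h < nchar(seq)
  out <- rep(NA_character_, length(pos))
  if (any(ok)) {
    out[ok] <- substring(seq, pos[ok] - h + 1L, pos[ok] + h + 1L)
  }
  out[!is.na(out) & grepl("N", out, fixed = TRUE)] <- NA_character_
  out
}

#' Reverse complement of a DNA string
#'
#' @param s Character vector of sequences over `{A,C,G,T,N}`.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(s) {
  if (any(grepl("[^ACGTN]", s))) {
    stop("reverse_complement: sequence contains characters outside ACGTN")
  }
  vapply(chartr("ACGTN", "TGCAN", s), function(x) {
    intToUtf8(rev(utf8ToInt(x)))
  }, character(1), USE.NAMES = FALSE)
}

# Integer encoding A=1, C=2, G=3, T=4 (N and anything else -> NA), used by
# the vectorized pattern/feature kernels.
.BASE_CODE <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v
})

.encode_seq <- function(s) .BASE_CODE[utf8ToInt(s)]

# Encode equal-length windows into an n x W integer matrix.
.encode_windows <- function(windows) {
  W <- nchar(windows[[1L]])
  if (any(nchar(windows) != W)) stop("windows must share one width")
  m <- matrix(.BASE_CODE[utf8ToInt(paste(windows, collapse = ""))],
              nrow = length(windows), ncol = W, byrow = TRUE)
  if (anyNA(m)) stop("windows must not contain N")
  m
}

# k-mer integer codes (0-based base-4, value in 1..4^k) at each start
# position, as an n x (W-k+1) matrix computed from an encoded base matrix.
.kmer_codes <- function(codes, k) {
  W <- ncol(codes)
  out <- codes[, 1:(W - k + 1L), drop = FALSE] - 1L
  if (k > 1L) {
    for (j in 2:k) {
      out <- out * 4L + (codes[, j:(W - k + j), drop = FALSE] - 1L)
    }
  }
  out + 1L
}

.kmer_to_code <- function(m) {
  b <- .BASE_CODE[utf8ToInt(m)] - 1L
  sum(b * 4L^(rev(seq_along(b)) - 1L)) + 1L
}
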