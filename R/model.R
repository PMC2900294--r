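# Linear SVM dyad model: training-set assembly, weight fitting, position
# scoring, region scanning and leave-one-chromosome-out cross-validation.
#
# Defaults follow the final model: pattern width W = 301, k-mers up to
# length 3, negative (linker) examples at L = 110 bp on either side of each
# dyad, and an 11-bp moving average when smoothing score traces.

#' Assemble a labeled dyad-versus-linker training set
#'
#' One positive window per dyad, and two negatives at `pos - L` and
#' `pos + L`, giving twice as many negatives as positives. Windows that
#' overrun a chromosome or contain N are dropped; the mates of a dropped
#' window are kept.
#'
#' @param dyads Dyad `data.frame` (`chrom`, `pos`).
#' @param genome Named character vector of chromosome sequences.
#' @param patterns Standardized `nuc_patterns` used to featurize windows.
#' @param L Dyad-to-linker distance in bp (default 110).
#' @return List with feature matrix `X`, label vector `y` (+1 dyad,
#'   -1 linker), and counts `n_pos`, `n_neg`.
#' @export
assemble_training_set <- function(dyads, genome, patterns, L = 110L) {
  if (L < 0L) stop("L must be non-negative")
  W <- attr(patterns, "W")
  wins <- character(0)
  labs <- integer(0)
  for (chrom in unique(dyads$chrom)) {
    if (!chrom %in% names(genome)) next
    pos <- dyads$pos[dyads$chrom == chrom]
    cand <- c(pos, pos - L, pos + L)
    lab <- rep(c(1L, -1L, -1L), times = c(length(pos), length(pos),
                                          length(pos)))
    w <- extract_windows(genome[[chrom]], cand, W)
    keep <- !is.na(w)
    wins <- c(wins, w[keep])
    labs <- c(labs, lab[keep])
  }
  if (sum(labs == 1L) == 0L) stop("empty positive set")
  if (sum(labs == -1L) == 0L) stop("empty negative set")
  X <- build_feature_matrix(wins, patterns)
  list(X = X, y = labs, n_pos = sum(labs == 1L), n_neg = sum(labs == -1L))
}

#' Train the linear SVM weight vector
#'
#' Soft-margin linear SVM (hinge loss, L2 penalty, via libsvm). Features are
#' standardized per column with training-set statistics before fitting;
#' counts and correlations live on very different scales. The fit is
#' deterministic given fixed inputs. The returned object carries raw-space
#' weights, so the dyad score of a feature vector x is simply `w . x + bias`.
#'
#' @param X Feature matrix (rows = examples).
#' @param y Labels, +1 / -1; both classes must be present.
#' @param C Soft-margin regularization constant (default 1).
#' @param tolerance libsvm termination tolerance (default 1e-4).
#' @return A `nuc_svm` object with elements `w`, `bias`, `C`, and scaling
#'   metadata.
#' @export
train_linear <- function(X, y, C = 1, tolerance = 1e-4) {
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  if (!all(is.finite(X))) stop("non-finite feature values")
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2L, ctr)^2))  # population moments: the
  scl[scl < 1e-12] <- 1                       # scaling is then invariant
                                              # under dataset duplication
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  fit <- e1071::svm(Xs, factor(y, levels = c(-1L, 1L)), type = "C-classification",
                    kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  w_std <- drop(t(fit$coefs) %*% fit$SV)
  b_std <- -fit$rho
  # libsvm orients the decision function toward the class of the first
  # training example; flip so that positives score high.
  dec <- drop(Xs %*% w_std) + b_std
  if (stats::cor(dec, y) < 0) {
    w_std <- -w_std
    b_std <- -b_std
  }
  w_raw <- w_std / scl
  structure(list(w = w_raw, bias = b_std - sum(w_std * ctr / scl),
                 C = C, tolerance = tolerance,
                 center = ctr, scale = scl,
                 feature_names = colnames(X)),
            class = "nuc_svm")
}

#' @export
print.nuc_svm <- function(x, ...) {
  cat(sprintf("<nuc_svm: %d features, C=%g>\n", length(x$w), x$C))
  invisible(x)
}

#' Dyad scores for rows of a feature matrix
#'
#' @param object A `nuc_svm`.
#' @param X Feature matrix or single feature vector.
#' @param ... Unused.
#' @return Numeric score vector (`w . x + bias`).
#' @export
predict.nuc_svm <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  drop(X %*% object$w) + object$bias
}

#' Dyad score at one or more genomic positions
#'
#' A purely local scoring function: only the W bp centered at each position
#' are used. Positions whose window is not extractable get `NA`.
#'
#' @param genome Named character vector of chromosomes.
#' @param chrom Chromosome name.
#' @param pos Integer vector of 0-based positions.
#' @param model A `nuc_svm`.
#' @param patterns The `nuc_patterns` the model was trained with.
#' @return Numeric vector of scores (NA where not scorable).
#' @export
score_position <- function(genome, chrom, pos, model, patterns) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  W <- attr(patterns, "W")
  wins <- extract_windows(genome[[chrom]], pos, W)
  out <- rep(NA_real_, length(pos))
  ok <- !is.na(wins)
  if (any(ok)) {
    out[ok] <- predict(model, build_feature_matrix(wins[ok], patterns))
  }
  out
}

#' Scan a region into a per-position dyad score trace
#'
#' @inheritParams score_position
#' @param start,end 0-based half-open interval `[start, end)` to scan.
#' @param smooth Odd moving-average width (1 = no smoothing; 11 is the width
#'   used for final predictions). Missing flanks are excluded from the
#'   averaging denominator.
#' @return A `nuc_trace`: list with `chrom`, `start`, `scores` (raw),
#'   `smoothed`, `smooth`.
#' @export
scan_region <- function(genome, chrom, start, end, model, patterns,
                        smooth = 1L) {
  if (smooth %% 2L != 1L) stop("smoothing width must be odd")
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (start < 0L || end > nchar(genome[[chrom]]) || end <= start) {
    stop("interval outside chromosome")
  }
  pos <- seq.int(start, end - 1L)
  scores <- score_position(genome, chrom, pos, model, patterns)
  structure(list(chrom = chrom, start = start, scores = scores,
                 smoothed = moving_average(scores, smooth),
                 smooth = smooth),
            class = "nuc_trace")
}

#' Centered moving average with missing-aware denominator
#'
#' @param x Numeric vector (may contain NA).
#' @param width Odd window width.
#' @return Averaged vector of the same length; positions whose window holds
#'   no finite value are NA.
#' @export
moving_average <- function(x, width = 11L) {
  if (width %% 2L != 1L) stop("width must be odd")
  if (width == 1L) return(x)
  h <- (width - 1L) %/% 2L
  good <- !is.na(x)
  x0 <- ifelse(good, x, 0)
  cs <- cumsum(c(0, x0))
  cn <- cumsum(c(0, as.numeric(good)))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  ifelse(den > 0, num / den, NA_real_)
}

#' Leave-one-chromosome-out cross-validation
#'
#' For each chromosome c carrying dyads, the k-mer patterns and the SVM are
#' learned from the dyads of all other chromosomes, and evaluated on the
#' held-out positives of c versus their +/-L linkers. Nothing from the
#' evaluation chromosome influences pattern learning or weight fitting.
#'
#' @inheritParams assemble_training_set
#' @param k_max Maximum k-mer length (default 3).
#' @param W Pattern width (default 301).
#' @param C SVM regularization constant.
#' @return List with `per_chrom` (data.frame: chrom, n_pos, n_neg, auc,
#'   training_chroms), `composite` (AUC over pooled held-out scores), and
#'   `pooled` scores.
#' @export
loco_crossval <- function(dyads, genome, L = 110L, k_max = 3L, W = 301L,
                          C = 1) {
  chroms <- intersect(names(genome), unique(dyads$chrom))
  if (length(chroms) < 2L) stop("need dyads on at least 2 chromosomes")
  rows <- list()
  pooled_pos <- numeric(0)
  pooled_neg <- numeric(0)
  for (chrom in chroms) {
    train_d <- dyads[dyads$chrom != chrom, , drop = FALSE]
    test_d <- dyads[dyads$chrom == chrom, , drop = FALSE]
    if (nrow(test_d) == 0L || nrow(train_d) == 0L) {
      warning("skipping chromosome without dyads: ", chrom)
      next
    }
    train_wins <- unlist(lapply(unique(train_d$chrom), function(ch) {
      w <- extract_windows(genome[[ch]], train_d$pos[train_d$chrom == ch], W)
      w[!is.na(w)]
    }))
    pats <- learn_patterns(train_wins, k_max)
    tr <- assemble_training_set(train_d, genome, pats, L)
    fit <- train_linear(tr$X, tr$y, C)
    te <- assemble_training_set(test_d, genome, pats, L)
    sc <- predict(fit, te$X)
    roc <- roc_auc(sc[te$y == 1L], sc[te$y == -1L])
    pooled_pos <- c(pooled_pos, sc[te$y == 1L])
    pooled_neg <- c(pooled_neg, sc[te$y == -1L])
    rows[[chrom]] <- data.frame(chrom = chrom, n_pos = te$n_pos,
                                n_neg = te$n_neg, auc = roc$auc,
                                training_chroms = paste(sort(unique(
                                  train_d$chrom)), collapse = ","),
                                stringsAsFactors = FALSE)
  }
  per_chrom <- do.call(rbind, rows)
  rownames(per_chrom) <- NULL
  composite <- roc_auc(pooled_pos, pooled_neg)$auc
  list(per_chrom = per_chrom, composite = composite,
       pooled = list(pos = pooled_pos, neg = pooled_neg))
}

#' Save a model bundle (patterns + weights + metadata)
#'
#' @param model A `nuc_svm`.
#' @param patterns The `nuc_patterns` used to build its features.
#' @param dir Output directory.
#' @export
save_model <- function(model, patterns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patterns(patterns, file.path(dir, "patterns"))
  utils::write.table(
    data.frame(feature = model$feature_names, weight = model$w,
               center = model$center, scale = model$scale),
    file.path(dir, "weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(list(bias = model$bias, C = model$C,
                            tolerance = model$tolerance),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a model bundle written by [save_model()]
#'
#' @param dir Bundle directory.
#' @return List with elements `model` (`nuc_svm`) and `patterns`.
#' @export
load_model <- function(dir) {
  patterns <- read_patterns(file.path(dir, "patterns"))
  wt <- utils::read.table(file.path(dir, "weights.tsv"), header = TRUE,
                          sep = "\t")
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  model <- structure(list(w = stats::setNames(wt$weight, wt$feature),
                          bias = meta$bias, C = meta$C,
                          tolerance = meta$tolerance,
                          center = wt$center, scale = wt$scale,
                          feature_names = wt$feature),
                     class = "nuc_svm")
  list(model = model, patterns = patterns)
}
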