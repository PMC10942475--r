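# GC-aware normalization and regression-based motif activity: smooth
# quantile normalization within GC bins, a per-sample multivariate motif
# model, univariate per-motif models on peak log fold-changes, and binned
# motif enrichment with Simes aggregation.

#' Log-CPM transform of a peak count matrix
#'
#' \code{log2(count / colsum * 1e6 + 0.5)}, the variance-stabilizing
#' transform fed to the GC-aware normalization.
#'
#' @param counts Peaks x samples count matrix.
#' @return Matrix of log2 counts per million.
#' @export
log_cpm <- function(counts) {
  counts <- as.matrix(counts)
  cs <- colSums(counts)
  if (any(cs == 0)) stop("sample with zero total counts")
  log2(sweep(counts, 2, cs, "/") * 1e6 + 0.5)
}

#' Smooth quantile normalization within GC bins
#'
#' Peaks are assigned to \code{nbins} equal-occupancy GC bins. Within each
#' bin, values are quantile-normalized with a group-aware compromise: at
#' each quantile rank k, the reference is a weighted mix
#' \eqn{w_k q_k + (1 - w_k) q_{gk}} of the overall mean order statistic
#' \eqn{q_k} and the group-specific mean order statistic \eqn{q_{gk}}. The
#' weight \eqn{w_k = 1 - SSB_k / SST_k} (between-group over total sum of
#' squares across samples at that rank, clipped to [0, 1] and smoothed by a
#' running median over ranks) shrinks toward full quantile normalization
#' where groups agree and preserves group-specific quantiles where they
#' differ globally. Tied values receive the average of the implicated
#' reference values.
#'
#' @param logcpm Peaks x samples matrix (log scale, e.g.
#'   \code{\link{log_cpm}}).
#' @param gc Per-peak GC fractions.
#' @param groups Group labels per sample (>= 1 level).
#' @param nbins Number of equal-occupancy GC bins (default 10). Bins with
#'   fewer than 2 peaks are merged into their neighbor with a warning.
#' @param smooth_span Fraction of ranks used for the running-median window
#'   (default 0.05; window at least 3).
#' @return A \code{NormalizedMatrix}: the normalized matrix with
#'   attributes \code{gc_bin} (per-peak bin label) and \code{groups}.
#' @export
gc_smooth_quantile_normalize <- function(logcpm, gc, groups, nbins = 10L,
                                         smooth_span = 0.05) {
  logcpm <- as.matrix(logcpm)
  n <- nrow(logcpm)
  stopifnot(length(gc) == n, length(groups) == ncol(logcpm), nbins >= 1)
  groups <- as.factor(groups)
  bin <- .equal_occupancy_bins(gc, nbins)
  tab <- tabulate(bin, nbins = max(bin))
  if (any(tab > 0 & tab < 2)) {
    warning("GC bin(s) with < 2 peaks merged into neighboring bin")
    for (b in which(tab > 0 & tab < 2)) {
      nb <- if (b > 1) b - 1L else b + 1L
      bin[bin == b] <- nb
    }
  }
  out <- logcpm
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    out[idx, ] <- .qsmooth_block(logcpm[idx, , drop = FALSE], groups,
                                 smooth_span)
  }
  attr(out, "gc_bin") <- bin
  attr(out, "groups") <- groups
  out
}

.equal_occupancy_bins <- function(x, nbins) {
  n <- length(x)
  nbins <- min(as.integer(nbins), n)
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * nbins / n) + 1L)
}

.qsmooth_block <- function(x, groups, smooth_span) {
  k <- nrow(x)
  s <- ncol(x)
  if (k < 2) return(x)
  ord <- apply(x, 2, sort)              # k x s order statistics
  qk <- rowMeans(ord)
  glev <- levels(groups)
  qgk <- vapply(glev, function(g) {
    rowMeans(ord[, groups == g, drop = FALSE])
  }, numeric(k))
  ng <- as.vector(table(groups)[glev])
  ssb <- as.vector((qgk - qk)^2 %*% ng)
  sst <- rowSums((ord - qk)^2)
  w <- ifelse(sst > 0, 1 - ssb / sst, 1)
  w <- pmin(pmax(w, 0), 1)
  win <- max(3L, as.integer(round(smooth_span * k)))
  if (win %% 2L == 0L) win <- win + 1L
  if (win < k) w <- stats::runmed(w, win, endrule = "median")
  w <- pmin(pmax(w, 0), 1)
  out <- x
  for (j in seq_len(s)) {
    g <- which(glev == groups[j])
    ref <- w * qk + (1 - w) * qgk[, g]
    oj <- order(x[, j])
    val <- numeric(k)
    val[oj] <- ref
    out[, j] <- stats::ave(val, match(x[, j], x[, j]), FUN = mean)
  }
  out
}

#' Per-peak log fold-change between groups
#'
#' The difference of group mean normalized (log-scale) accessibilities,
#' group B minus group A. When tied values are present (which can break
#' downstream equal-count binning) and a positive \code{jitter_factor} is
#' given, uniform noise with amplitude \code{jitter_factor * max(|logFC|)}
#' is added under a fixed seed.
#'
#' @param norm Normalized peaks x samples matrix.
#' @param design Group labels with two levels; the second level is "B".
#' @param jitter_factor Relative jitter amplitude, default 0.001; set to 0
#'   to disable.
#' @param seed Seed for the jitter noise (default 1).
#' @return A \code{LogFCVector}: numeric vector with attribute
#'   \code{jittered}.
#' @export
peak_logfc <- function(norm, design, jitter_factor = 0.001, seed = 1L) {
  design <- as.factor(design)
  stopifnot(nlevels(design) == 2, length(design) == ncol(norm))
  a <- design == levels(design)[1]
  lfc <- rowMeans(norm[, !a, drop = FALSE]) -
    rowMeans(norm[, a, drop = FALSE])
  jittered <- FALSE
  if (jitter_factor > 0 && anyDuplicated(lfc)) {
    amp <- jitter_factor * max(abs(lfc))
    if (amp == 0) amp <- jitter_factor
    rng <- .local_rng(seed)
    lfc <- lfc + (rng$runif(length(lfc)) * 2 - 1) * amp
    jittered <- TRUE
  }
  attr(lfc, "jittered") <- jittered
  lfc
}

#' Per-sample multivariate motif activity model
#'
#' For each sample, ordinary least squares of the (column-centered)
#' normalized accessibility on the column-standardized motif match matrix
#' plus an intercept: all motifs compete as covariates, so highly similar
#' motifs share their credit. The returned activity scores are the
#' per-motif t-values (coefficient over standard error), which feed
#' moderated group comparison downstream. All-zero, duplicated, or
#' rank-deficient match columns are dropped with a message and reported in
#' the \code{dropped} attribute (their rows are \code{NA}).
#'
#' @param norm Normalized peaks x samples matrix.
#' @param matches Peaks x motifs indicator (or score) matrix.
#' @return Motifs x samples matrix of t-values with attribute
#'   \code{dropped}.
#' @export
mlm_sample_activities <- function(norm, matches) {
  norm <- as.matrix(norm)
  m <- as.matrix(matches)
  stopifnot(nrow(m) == nrow(norm))
  if (ncol(m) >= nrow(m)) stop("need fewer motifs than peaks")
  motif_ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
  keep <- which(apply(m, 2, stats::sd) > 0)
  dup <- keep[duplicated(lapply(keep, function(j) m[, j]))]
  if (length(dup) > 0) {
    message(length(dup), " duplicated match column(s) dropped")
    keep <- setdiff(keep, dup)
  }
  dropped <- setdiff(motif_ids, motif_ids[keep])
  xs <- scale(m[, keep, drop = FALSE])
  x <- cbind(1, xs)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- qr_x$pivot[-seq_len(qr_x$rank)]
    bad <- bad[bad > 1] - 1L
    message(length(bad), " rank-deficient match column(s) dropped")
    dropped <- union(dropped, motif_ids[keep][bad])
    keep <- keep[-bad]
    xs <- scale(m[, keep, drop = FALSE])
    x <- cbind(1, xs)
    qr_x <- qr(x)
  }
  y <- sweep(norm, 2, colMeans(norm))
  coef <- qr.coef(qr_x, y)
  resid <- y - x %*% coef
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(resid^2) / df
  xtx_inv_diag <- diag(chol2inv(chol(crossprod(x))))
  tvals <- coef / sqrt(outer(xtx_inv_diag, sigma2))
  if (any(sigma2 == 0)) {
    # perfectly fit response: t is sign(coef)*Inf, and 0 where coef is 0
    for (j in which(sigma2 == 0)) {
      tvals[, j] <- ifelse(abs(coef[, j]) < 1e-12, 0,
                           sign(coef[, j]) * Inf)
    }
  }
  out <- matrix(NA_real_, length(motif_ids), ncol(norm),
                dimnames = list(motif_ids, colnames(norm)))
  out[motif_ids[keep], ] <- tvals[-1, , drop = FALSE]
  cf <- matrix(NA_real_, length(motif_ids), ncol(norm),
               dimnames = dimnames(out))
  cf[motif_ids[keep], ] <- coef[-1, , drop = FALSE]
  attr(out, "coefficients") <- cf
  attr(out, "dropped") <- dropped
  out
}

#' Univariate per-motif regression of peak log fold-changes
#'
#' Per motif, a simple linear model of the per-peak logFC on the motif
#' predictor: the binary match indicator (\code{"binary"}), the match
#' score (\code{"scores"}), or the indicator with the peak GC fraction as a
#' covariate (\code{"binary+GC"}). A two-sided t-test on the motif slope
#' provides the p-value.
#'
#' @param logfc Per-peak log fold-change vector.
#' @param matches Peaks x motifs indicator matrix.
#' @param variant One of \code{"binary"}, \code{"scores"},
#'   \code{"binary+GC"}.
#' @param gc Per-peak GC fractions (required for \code{"binary+GC"}).
#' @param scores Peaks x motifs match-score matrix (required for
#'   \code{"scores"}).
#' @return Data frame with columns \code{motif}, \code{slope}, \code{t},
#'   \code{p} (NA and flagged for constant predictors) and an
#'   \code{effect} column equal to the slope for ranking.
#' @export
ulm_motif_test <- function(logfc, matches,
                           variant = c("binary", "scores", "binary+GC"),
                           gc = NULL, scores = NULL) {
  variant <- match.arg(variant)
  if (length(logfc) < 3) stop("need at least 3 peaks")
  m <- as.matrix(matches)
  stopifnot(nrow(m) == length(logfc))
  if (variant == "scores") {
    stopifnot(!is.null(scores), all(dim(scores) == dim(m)))
    pred_mat <- as.matrix(scores)
  } else {
    pred_mat <- m
  }
  if (variant == "binary+GC") {
    stopifnot(!is.null(gc), length(gc) == length(logfc))
  }
  motif_ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
  res <- lapply(seq_len(ncol(m)), function(j) {
    pred <- pred_mat[, j]
    if (stats::sd(pred) == 0) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    x <- if (variant == "binary+GC") cbind(1, pred, gc) else cbind(1, pred)
    fit <- stats::lm.fit(x, logfc)
    df <- length(logfc) - fit$rank
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(x)))
    se <- sqrt(s2 * xtx_inv[2, 2])
    slope <- fit$coefficients[2]
    tt <- slope / se
    c(slope, tt, 2 * stats::pt(-abs(tt), df))
  })
  res <- do.call(rbind, res)
  out <- data.frame(motif = motif_ids, slope = res[, 1], t = res[, 2],
                    p = res[, 3], effect = res[, 1],
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- motif_ids[is.na(res[, 1])]
  out
}

#' Binned motif enrichment along the log fold-change axis
#'
#' Peaks are sorted by logFC into \code{nbins} equal-count bins; the bin
#' whose range contains zero is the reference "zero bin". For every motif
#' and non-zero bin, over-representation of motif matches is assessed by a
#' one-sided Fisher exact test of the 2x2 table (motif presence x bin
#' membership), against either the zero bin (\code{"vsZero"}) or all other
#' bins (\code{"vsOthers"}). Log2 enrichments use +0.5 pseudocounts on all
#' cells. Per-motif bin p-values (not independent) are aggregated by
#' Simes' method.
#'
#' @param logfc Per-peak log fold-change vector (jittered upstream if tied).
#' @param matches Peaks x motifs indicator matrix.
#' @param mode \code{"vsOthers"} or \code{"vsZero"}.
#' @param nbins Odd number of bins >= 3 (default 9).
#' @return A \code{BinnedEnrichment} list: matrices \code{enrichment} and
#'   \code{p} (motifs x bins, zero-bin column NA), \code{bins} (range
#'   table), \code{zero_bin} index, and \code{simes} (named per-motif
#'   aggregated p).
#' @export
binned_enrichment <- function(logfc, matches,
                              mode = c("vsOthers", "vsZero"), nbins = 9L) {
  mode <- match.arg(mode)
  nbins <- as.integer(nbins)
  if (nbins < 3 || nbins %% 2L == 0L) stop("nbins must be odd and >= 3")
  m <- as.matrix(matches) > 0
  stopifnot(nrow(m) == length(logfc))
  bin <- .equal_occupancy_bins(logfc, nbins)
  rng <- vapply(seq_len(nbins), function(b) {
    range(logfc[bin == b])
  }, numeric(2))
  zero_bin <- which(rng[1, ] <= 0 & rng[2, ] >= 0)[1]
  if (is.na(zero_bin)) {
    zero_bin <- which.min(pmin(abs(rng[1, ]), abs(rng[2, ])))
  }
  motif_ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
  n_in_bin <- tabulate(bin, nbins)
  match_in_bin <- matrix(0, nbins, ncol(m))  # nbins x motifs
  for (b in seq_len(nbins)) {
    match_in_bin[b, ] <- colSums(m[bin == b, , drop = FALSE])
  }
  enr <- pmat <- matrix(NA_real_, ncol(m), nbins,
                        dimnames = list(motif_ids, NULL))
  for (b in setdiff(seq_len(nbins), zero_bin)) {
    comp <- if (mode == "vsZero") zero_bin else setdiff(seq_len(nbins), b)
    a <- match_in_bin[b, ]
    b2 <- n_in_bin[b] - a
    cc <- colSums(match_in_bin[comp, , drop = FALSE])
    dd <- sum(n_in_bin[comp]) - cc
    # one-sided Fisher exact (hypergeometric upper tail)
    pmat[, b] <- stats::phyper(a - 1, a + cc, b2 + dd, a + b2,
                               lower.tail = FALSE)
    enr[, b] <- log2(((a + 0.5) / (a + b2 + 1)) /
                       ((cc + 0.5) / (cc + dd + 1)))
    none <- a == 0 & cc == 0
    enr[none, b] <- 0
    pmat[none, b] <- 1
  }
  simes <- apply(pmat, 1, function(p) simes_aggregate(p[!is.na(p)]))
  list(enrichment = enr, p = pmat,
       bins = data.frame(bin = seq_len(nbins), lo = rng[1, ],
                         hi = rng[2, ], n = n_in_bin),
       zero_bin = zero_bin, simes = simes, mode = mode)
}
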