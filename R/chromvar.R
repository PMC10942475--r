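# Bias-corrected motif accessibility deviations: observed-vs-expected
# fragment counts summed over a motif's matched peaks, standardized against
# random background peak sets matched on GC content and mean accessibility.

#' Expected counts under the library-size model
#'
#' The expected count for peak i in sample j is the product of the peak and
#' sample marginals over the grand total,
#' \eqn{E_{ij} = (\sum_j X_{ij})(\sum_i X_{ij}) / \sum_{ij} X_{ij}},
#' i.e. each sample's library distributed over peaks according to the
#' average accessibility profile of all samples.
#'
#' @param counts Non-negative peaks x samples matrix with a positive grand
#'   total.
#' @param method Size-factor method; only \code{"libsize"} is implemented.
#' @return Matrix \code{E} of the same shape, with attribute
#'   \code{method}.
#' @export
expected_counts <- function(counts, method = c("libsize")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("grand total of counts is zero")
  e <- outer(rowSums(counts), colSums(counts)) / total
  dimnames(e) <- dimnames(counts)
  attr(e, "method") <- method
  e
}

#' Select background peak sets matched on GC and accessibility
#'
#' For every peak, the pool of plausible background peaks is its
#' \code{k_neighbors} nearest neighbors (itself included) in the space of
#' standardized (GC fraction, log1p mean count). Each background iteration
#' draws one pool member per peak uniformly at random, so a background peak
#' set preserves the foreground's joint GC/accessibility profile while
#' randomizing motif membership.
#'
#' @param gc Per-peak GC fractions.
#' @param mean_access Per-peak mean accessibility, conventionally
#'   \code{log1p(rowMeans(counts))}.
#' @param niter Number of background iterations (>= 1; 2000 recommended for
#'   reproducible differential results).
#' @param k_neighbors Pool size (default 25; tight pools keep the matched covariates close, which is what cancels covariate-linked technical bias); capped at the number of peaks.
#' @param seed Integer seed.
#' @return A \code{BackgroundSets} list: integer matrix \code{index}
#'   (peaks x niter) of background peak indices, plus \code{niter} and
#'   \code{k_neighbors}.
#' @export
select_background_peaks <- function(gc, mean_access, niter = 2000L,
                                    k_neighbors = 25L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(length(gc) == length(mean_access), niter >= 1, k_neighbors >= 1)
  n <- length(gc)
  k <- min(as.integer(k_neighbors), n)
  z <- cbind(.zscale(gc), .zscale(mean_access))
  pools <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d2 <- (z[, 1] - z[i, 1])^2 + (z[, 2] - z[i, 2])^2
    pools[i, ] <- order(d2)[seq_len(k)]
  }
  rng <- .local_rng(seed)
  pick <- rng$draw(function() {
    matrix(sample.int(k, n * niter, replace = TRUE), n, niter)
  })
  index <- matrix(pools[cbind(rep(seq_len(n), niter), as.vector(pick))],
                  n, niter)
  structure(list(index = index, niter = as.integer(niter),
                 k_neighbors = k),
            class = "BackgroundSets")
}

.zscale <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Motif accessibility deviations and z-scores
#'
#' For motif m and sample j, with \eqn{Y = \sum_{i \in m} X_{ij}} and
#' \eqn{E = \sum_{i \in m} E_{ij}}, the raw deviation is \eqn{(Y - E)/E}.
#' The same quantity computed on each background peak set (each matched
#' peak replaced by its sampled background peak) yields a null distribution
#' whose mean is subtracted (bias-corrected deviation) and whose standard
#' deviation standardizes the corrected deviation into a z-score. A zero
#' background SD yields z = 0 with a flag; a motif with no matched peaks
#' yields \code{NaN} scores and a flag.
#'
#' @param counts Peaks x samples count matrix.
#' @param expectation Matrix from \code{\link{expected_counts}}.
#' @param matches Peaks x motifs indicator matrix (dense or sparse; column
#'   names are motif ids).
#' @param background A \code{\link{select_background_peaks}} result.
#' @return List of three motifs x samples matrices: \code{raw},
#'   \code{deviations} (bias-corrected), \code{z}; plus \code{flagged},
#'   a character vector of motifs with degenerate backgrounds or zero
#'   matches.
#' @export
motif_deviations <- function(counts, expectation, matches, background) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), dim(expectation)),
            nrow(matches) == nrow(counts))
  m <- Matrix::Matrix(matches, sparse = TRUE)
  m <- methods::as(m, "dMatrix")
  mt <- Matrix::t(m)
  n_match <- Matrix::rowSums(mt)
  y <- as.matrix(mt %*% counts)
  e <- as.matrix(mt %*% expectation)
  raw <- (y - e) / e
  niter <- background$niter
  sum_d <- matrix(0, nrow(raw), ncol(raw))
  sum_d2 <- matrix(0, nrow(raw), ncol(raw))
  for (t in seq_len(niter)) {
    perm <- background$index[, t]
    yt <- as.matrix(mt %*% counts[perm, , drop = FALSE])
    et <- as.matrix(mt %*% expectation[perm, , drop = FALSE])
    dt <- (yt - et) / et
    sum_d <- sum_d + dt
    sum_d2 <- sum_d2 + dt * dt
  }
  mean_d <- sum_d / niter
  var_d <- pmax(sum_d2 / niter - mean_d^2, 0) * niter / max(1, niter - 1)
  sd_d <- sqrt(var_d)
  corrected <- raw - mean_d
  z <- corrected / sd_d
  zero_sd <- sd_d == 0 & is.finite(corrected)
  z[zero_sd] <- 0
  empty <- n_match == 0
  flagged <- character()
  if (any(zero_sd)) {
    flagged <- union(flagged, rownames(raw)[apply(zero_sd, 1, any)])
  }
  if (any(empty)) {
    raw[empty, ] <- NaN; corrected[empty, ] <- NaN; z[empty, ] <- NaN
    flagged <- union(flagged, rownames(raw)[empty])
  }
  dn <- list(colnames(matches), colnames(counts))
  dimnames(raw) <- dimnames(corrected) <- dimnames(z) <- dn
  list(raw = raw, deviations = corrected, z = z, flagged = flagged)
}

#' Normalize an activity matrix across samples
#'
#' \code{"center"} subtracts the per-sample (column) median;
#' \code{"scale"} additionally divides by the per-sample MAD (robust
#' choices, as activity-score distributions can be heavy-tailed and
#' shifted); \code{"quantile"} performs standard quantile normalization
#' across sample columns (ties receive the average of the implicated
#' reference values). Quantile normalization is the recommended default
#' ahead of moderated group comparison.
#'
#' @param act Motifs x samples matrix.
#' @param method One of \code{"none"}, \code{"center"}, \code{"scale"},
#'   \code{"quantile"}.
#' @return The normalized matrix, with attribute
#'   \code{normalization}.
#' @export
normalize_activity <- function(act,
                               method = c("quantile", "none", "center",
                                          "scale")) {
  method <- match.arg(method)
  act <- as.matrix(act)
  if (method %in% c("scale", "quantile") && nrow(act) < 2) {
    stop("scale/quantile normalization needs at least 2 motifs")
  }
  out <- switch(method,
    none = act,
    center = sweep(act, 2, apply(act, 2, stats::median, na.rm = TRUE)),
    scale = {
      med <- apply(act, 2, stats::median, na.rm = TRUE)
      mads <- apply(act, 2, stats::mad, na.rm = TRUE)
      if (any(mads == 0)) stop("constant sample column: MAD is zero")
      sweep(sweep(act, 2, med), 2, mads, "/")
    },
    quantile = limma::normalizeQuantiles(act, ties = TRUE)
  )
  dimnames(out) <- dimnames(act)
  attr(out, "normalization") <- method
  out
}
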