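#' Empirical-Bayes moderated two-group comparison of activity scores
#'
#' Fits, per motif, the two-group pooled-variance linear model to an
#' activity matrix (motifs x samples) and shrinks the residual variances
#' toward a common prior before computing t-statistics. The prior
#' \eqn{(d_0, s_0^2)} is estimated by matching moments of the log residual
#' variances (the scaled-F / digamma-trigamma closed form, via
#' \code{limma::fitFDist}); the moderated variance is
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} and the
#' moderated t has \eqn{d_0 + d_g} degrees of freedom.
#'
#' @param scores Numeric matrix, motifs x samples.
#' @param design Group labels (two levels) of length \code{ncol(scores)}.
#' @param prior_df Optional override of the prior degrees of freedom
#'   \eqn{d_0}; \code{0} disables moderation (ordinary pooled t),
#'   \code{Inf} forces full pooling to \eqn{s_0^2}.
#' @return A data frame (one row per motif) with columns \code{motif},
#'   \code{effect} (group B minus group A mean), \code{s2}, \code{df},
#'   \code{s2_post}, \code{t}, \code{df_total}, \code{p}, \code{fdr};
#'   attributes \code{prior_df} and \code{prior_var} carry the fitted prior.
#' @export
moderated_t_test <- function(scores, design, prior_df = NULL) {
  scores <- as.matrix(scores)
  design <- as.factor(design)
  if (nlevels(design) != 2) stop("design must have exactly two groups")
  if (length(design) != ncol(scores)) {
    stop("design length must match the number of samples")
  }
  ja <- design == levels(design)[1]
  jb <- design == levels(design)[2]
  na <- sum(ja); nb <- sum(jb)
  if (na < 1 || nb < 1) stop("both groups must be non-empty")
  ma <- rowMeans(scores[, ja, drop = FALSE])
  mb <- rowMeans(scores[, jb, drop = FALSE])
  effect <- mb - ma
  rss <- numeric(nrow(scores))
  if (na > 1) {
    rss <- rss + rowSums((scores[, ja, drop = FALSE] - ma)^2)
  }
  if (nb > 1) {
    rss <- rss + rowSums((scores[, jb, drop = FALSE] - mb)^2)
  }
  df <- na + nb - 2L
  s2 <- if (df > 0) rss / df else rep(NA_real_, nrow(scores))
  if (df > 0 && all(s2 == 0, na.rm = TRUE)) {
    stop("all residual variances are zero; cannot moderate")
  }
  if (nrow(scores) < 2 && is.null(prior_df)) {
    warning("single motif: no moderation possible, ordinary t returned")
    prior_df <- 0
  }
  if (is.null(prior_df)) {
    if (df == 0) stop("no residual degrees of freedom; supply prior_df")
    ok <- is.finite(s2) & s2 > 0
    fit <- limma::fitFDist(s2[ok], df1 = df)
    d0 <- fit$df2
    s02 <- fit$scale
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(prior_df) && prior_df == 0) 0 else mean(s2, na.rm = TRUE)
  }
  if (!is.finite(d0)) {
    s2_post <- rep(if (is.null(prior_df)) s02 else mean(s2, na.rm = TRUE),
                   length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    resid_term <- if (df > 0) df * s2 else 0
    s2_post <- (d0 * s02 + resid_term) / (d0 + df)
    df_total <- rep(d0 + df, length(s2))
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tt <- effect / se
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  out <- data.frame(motif = rownames(scores) %||% as.character(seq_len(nrow(scores))),
                    effect = effect, s2 = s2, df = df, s2_post = s2_post,
                    t = tt, df_total = df_total, p = p,
                    fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simes p-value aggregation
#'
#' Combines a vector of (possibly dependent) p-values into a single p-value
#' \eqn{\min_i n p_{(i)} / i}, valid under positive dependence. \code{NA}s
#' are dropped with a warning; an all-\code{NA} input returns \code{NA}.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return A single aggregated p-value.
#' @export
simes_aggregate <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (anyNA(pvals)) {
    warning("NA p-values dropped in Simes aggregation")
    pvals <- pvals[!is.na(pvals)]
    if (length(pvals) == 0) return(NA_real_)
  }
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  ps <- sort(pvals)
  min(1, min(n * ps / seq_len(n)))
}

#' Fisher's combination of two p-values
#'
#' \eqn{X = -2(\ln p_1 + \ln p_2)} referred to a chi-square distribution
#' with 4 degrees of freedom. Zero inputs are clamped to the smallest
#' positive double with a warning.
#'
#' @param p1,p2 P-values in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p1, p2) {
  p <- c(p1, p2)
  if (any(is.na(p))) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("zero p-value clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 4, lower.tail = FALSE)
}

#' Rank per-motif test results
#'
#' Results are sorted first by ascending uncorrected p-value, ties broken by
#' descending absolute effect size, remaining ties by motif id; motifs with
#' \code{NA} p-values are ranked last (among themselves by id). The returned
#' ranks are a permutation of \code{1..n}.
#'
#' @param result Data frame with columns \code{motif}, \code{p} and an
#'   effect-size column (\code{effect}, \code{t} or \code{statistic}; the
#'   first present is used).
#' @return The input data frame with a \code{rank} column added, sorted by
#'   rank.
#' @export
rank_results <- function(result) {
  stopifnot(is.data.frame(result), all(c("motif", "p") %in% names(result)))
  eff_col <- intersect(c("effect", "t", "statistic"), names(result))[1]
  eff <- if (is.na(eff_col)) rep(0, nrow(result)) else
    abs(result[[eff_col]])
  eff[is.na(eff)] <- 0
  p <- result$p
  ord <- order(is.na(p), p, -eff, result$motif)
  out <- result[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
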