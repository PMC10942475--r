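# Insertion-profile scores: per-motif aggregated Tn5 insertion profiles,
# the position-weighted insertion model, and the footprint-depth /
# flanking-accessibility two-part (BagFoot-like) test.

#' Aggregate Tn5 insertion profiles around motif matches
#'
#' Insertion events (both fragment ends) falling within
#' \code{[site_start - window, site_end + window)} are accumulated by
#' position relative to the site start (offset by the window), flipped for
#' minus-strand sites, and summed over all sites of a motif, separately per
#' sample. All sites of one motif must share a common length.
#'
#' @param frags A \code{FragmentSet} or list of them.
#' @param sites Data frame of motif match sites: \code{chrom},
#'   \code{start}, \code{end} (BED coordinates), \code{motif}, optional
#'   \code{strand} (\code{+}/\code{-}; default \code{+}). Sites should be
#'   pre-filtered to peaks.
#' @param window Flank width in bp on each side (default 200).
#' @return A named list of \code{InsertionProfile}s: each a list with
#'   \code{motif}, \code{counts} (positions x samples; position 1 is
#'   \code{-window} relative to the site start), \code{motif_len},
#'   \code{window}, \code{n_sites}. Motifs without sites are flagged via
#'   the \code{empty} attribute.
#' @export
motif_insertion_profiles <- function(frags, sites, window = 200L) {
  if (inherits(frags, "FragmentSet")) frags <- list(frags)
  stopifnot(all(c("chrom", "start", "end", "motif") %in% names(sites)))
  window <- as.integer(window)
  strand <- if (is.null(sites$strand)) rep("+", nrow(sites)) else
    as.character(sites$strand)
  ins <- lapply(frags, tn5_insertions)
  sample_ids <- vapply(frags, sample_id, "")
  profiles <- list()
  for (mo in unique(sites$motif)) {
    si <- which(sites$motif == mo)
    lens <- sites$end[si] - sites$start[si]
    if (length(unique(lens)) != 1) {
      stop("motif '", mo, "': sites have differing lengths")
    }
    lmot <- lens[1]
    plen <- lmot + 2L * window
    ext <- GenomicRanges::GRanges(
      sites$chrom[si],
      IRanges::IRanges(sites$start[si] - window + 1L,
                       sites$end[si] + window))
    counts <- matrix(0, plen, length(frags),
                     dimnames = list(NULL, sample_ids))
    for (j in seq_along(ins)) {
      ev <- ins[[j]]
      if (nrow(ev) == 0) next
      pts <- GenomicRanges::GRanges(ev$chrom,
                                    IRanges::IRanges(ev$pos + 1L,
                                                     ev$pos + 1L))
      hits <- GenomicRanges::findOverlaps(pts, ext)
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      rel <- ev$pos[qh] - (sites$start[si][sh] - window)
      minus <- strand[si][sh] == "-"
      rel[minus] <- plen - 1L - rel[minus]
      agg <- rowsum(ev$weight[qh], rel + 1L)
      counts[as.integer(rownames(agg)), j] <-
        counts[as.integer(rownames(agg)), j] + agg[, 1]
    }
    profiles[[mo]] <- list(motif = mo, counts = counts, motif_len = lmot,
                           window = window, n_sites = length(si))
  }
  empty <- setdiff(unique(sites$motif), names(profiles))
  attr(profiles, "empty") <- empty
  profiles
}

.running_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Position-weighted insertion-model activity scores
#'
#' For each motif, the global (across-sample) insertion profile is
#' smoothed by a centered running mean, symmetrized by averaging mirrored
#' positions about the profile center, and normalized to sum to one,
#' yielding a weight vector that emphasizes where the motif's insertions
#' concentrate. The per-sample activity score is the weight-averaged sum
#' of insertion counts; score matrices feed moderated group comparison.
#'
#' @param profiles Output of \code{\link{motif_insertion_profiles}}.
#' @param smooth_window Running-mean window in bp (odd, default 11).
#' @return Motifs x samples score matrix; motifs whose global profile is
#'   all zero get uniform weights and are recorded in the \code{flagged}
#'   attribute.
#' @export
insertion_model_scores <- function(profiles, smooth_window = 11L) {
  stopifnot(length(profiles) >= 1)
  flagged <- character()
  ns <- ncol(profiles[[1]]$counts)
  score_list <- lapply(profiles, function(pr) {
    glob <- rowSums(pr$counts)
    if (sum(glob) == 0) {
      flagged <<- c(flagged, pr$motif)
      w <- rep(1 / length(glob), length(glob))
    } else {
      sm <- .running_mean(glob, smooth_window)
      sym <- (sm + rev(sm)) / 2
      w <- sym / sum(sym)
    }
    colSums(pr$counts * w)
  })
  scores <- matrix(unlist(score_list), nrow = length(profiles),
                   ncol = ns, byrow = TRUE,
                   dimnames = list(names(profiles),
                                   colnames(profiles[[1]]$counts)))
  attr(scores, "flagged") <- flagged
  scores
}

#' Footprint depth and flanking accessibility summaries
#'
#' From each motif's insertion profile: \code{M}, insertions within the
#' match; \code{F20}, insertions in the 20 bp immediately flanking each
#' side; \code{F200}, insertions in the full 200 bp flanks. Per-bp rates
#' with a pseudocount c = 0.5 give, per motif and sample,
#' footprint depth \code{log2((F20/40 + c) / (M/motif_len + c))} (positive
#' when the match is protected) and flanking accessibility
#' \code{log2(F200/400 + c)}.
#'
#' @param profiles Output of \code{\link{motif_insertion_profiles}} with
#'   \code{window >= 200}.
#' @param pseudocount Per-bp rate pseudocount (default 0.5).
#' @return A \code{FootprintSummary}: list of two motifs x samples
#'   matrices, \code{depth} and \code{flank}.
#' @export
footprint_summaries <- function(profiles, pseudocount = 0.5) {
  stopifnot(length(profiles) >= 1)
  ns <- ncol(profiles[[1]]$counts)
  depth <- flank <- matrix(NA_real_, length(profiles), ns,
                           dimnames = list(names(profiles),
                                           colnames(profiles[[1]]$counts)))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    lmot <- pr$motif_len
    if (lmot <= 0) stop("motif length must be positive")
    wdw <- pr$window
    if (wdw < 200) stop("footprint summaries need window >= 200")
    plen <- nrow(pr$counts)
    motif_idx <- (wdw + 1L):(wdw + lmot)
    near_idx <- c((wdw - 19L):wdw, (wdw + lmot + 1L):(wdw + lmot + 20L))
    far_idx <- c((wdw - 199L):wdw,
                 (wdw + lmot + 1L):(wdw + lmot + 200L))
    m_cnt <- colSums(pr$counts[motif_idx, , drop = FALSE])
    f20 <- colSums(pr$counts[near_idx, , drop = FALSE])
    f200 <- colSums(pr$counts[far_idx, , drop = FALSE])
    depth[i, ] <- log2((f20 / 40 + pseudocount) /
                         (m_cnt / lmot + pseudocount))
    flank[i, ] <- log2(f200 / 400 + pseudocount)
  }
  structure(list(depth = depth, flank = flank),
            class = "FootprintSummary")
}

#' BagFoot-like two-part differential footprinting test
#'
#' Moderated two-group comparison (see \code{\link{moderated_t_test}}) run
#' separately on the footprint-depth and flanking-accessibility matrices;
#' the two per-motif p-values are combined with Fisher's method
#' (chi-square, 4 df) and BH-adjusted. A motif missing from either matrix
#' gets \code{NA} and is flagged.
#'
#' @param depths,flanks Motifs x samples matrices (as from
#'   \code{\link{footprint_summaries}}).
#' @param design Two-level group labels.
#' @return Data frame with \code{motif}, \code{effect} (depth effect),
#'   \code{p_depth}, \code{p_flank}, \code{p} (combined), \code{fdr}.
#' @export
bagfootlike_test <- function(depths, flanks, design) {
  fit_d <- moderated_t_test(depths, design)
  fit_f <- moderated_t_test(flanks, design)
  motifs <- union(fit_d$motif, fit_f$motif)
  pd <- fit_d$p[match(motifs, fit_d$motif)]
  pf <- fit_f$p[match(motifs, fit_f$motif)]
  eff <- fit_d$effect[match(motifs, fit_d$motif)]
  comb <- mapply(function(a, b) {
    if (is.na(a) || is.na(b)) NA_real_ else fisher_combine(a, b)
  }, pd, pf)
  out <- data.frame(motif = motifs, effect = eff, p_depth = pd,
                    p_flank = pf, p = comb,
                    fdr = stats::p.adjust(comb, "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- motifs[is.na(comb)]
  out
}
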