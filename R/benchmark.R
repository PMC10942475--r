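# Evaluation layer: motif-similarity clustering into archetypes, rank of
# the true motif, network/archetype AUC scores, precision/recall, the
# rank transform, method ranking with imputation, and rank-based method
# aggregation.

.ppm_ic <- function(mat) {
  # per-column information content in bits: 2 + sum p log2 p
  apply(mat, 2, function(p) {
    nz <- p > 0
    2 + sum(p[nz] * log2(p[nz]))
  })
}

.ppm_rc <- function(mat) {
  # reverse complement: reverse columns, swap A<->T and C<->G
  mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
}

.weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  if (sw == 0) return(NA_real_)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cov <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2)
  vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  cov / sqrt(vx * vy)
}

#' Similarity of two motif position probability matrices
#'
#' Over all ungapped alignment offsets with overlap of at least
#' \code{min(min_overlap, shorter motif length)} columns, and both
#' orientations of the second motif (as given and reverse-complemented),
#' computes the Pearson correlation of the flattened overlapping columns
#' with positions weighted by total information content (the weight of an
#' aligned column pair is the mean of the two columns' IC,
#' \code{2 + sum p log2 p} bits). Returns the maximum.
#'
#' @param a,b \code{MotifPPM} objects (lists with \code{id} and 4 x L
#'   \code{mat}).
#' @param min_overlap Minimum aligned columns (default 5, reduced for
#'   shorter motifs).
#' @return List with \code{similarity} (in [-1, 1]; 0 with a flag when
#'   all information weights vanish, -1 with a flag when no alignment
#'   satisfies the overlap constraint), \code{offset} (start of b relative
#'   to a), \code{rc} (orientation flag), \code{flagged}.
#' @export
motif_similarity <- function(a, b, min_overlap = 5L) {
  ma <- a$mat
  la <- ncol(ma)
  lb <- ncol(b$mat)
  need <- min(min_overlap, min(la, lb))
  best <- list(similarity = -1, offset = NA_integer_, rc = FALSE,
               flagged = TRUE)
  any_defined <- FALSE
  for (rc in c(FALSE, TRUE)) {
    mb <- if (rc) .ppm_rc(b$mat) else b$mat
    ic_a <- .ppm_ic(ma)
    ic_b <- .ppm_ic(mb)
    for (off in seq(-lb + need, la - need)) {
      ia <- max(1L, off + 1L):min(la, off + lb)
      ib <- ia - off
      if (length(ia) < need) next
      w <- rep((ic_a[ia] + ic_b[ib]) / 2, each = 4L)
      r <- .weighted_pearson(as.vector(ma[, ia]), as.vector(mb[, ib]), w)
      if (is.na(r)) { any_defined <- any_defined || FALSE; next }
      any_defined <- TRUE
      if (r > best$similarity) {
        best <- list(similarity = r, offset = off, rc = rc,
                     flagged = FALSE)
      }
    }
  }
  if (!any_defined && is.na(best$offset)) {
    # all weights zero (e.g. uniform PPM): similarity undefined
    best <- list(similarity = 0, offset = NA_integer_, rc = FALSE,
                 flagged = TRUE)
  }
  best
}

#' Pairwise motif similarity matrix
#'
#' @param ppms Named list of \code{MotifPPM}s.
#' @param min_overlap Passed to \code{\link{motif_similarity}}.
#' @return Symmetric motifs x motifs similarity matrix with unit diagonal.
#' @export
motif_similarity_matrix <- function(ppms, min_overlap = 5L) {
  n <- length(ppms)
  ids <- vapply(ppms, `[[`, "", "id")
  sim <- diag(1, n)
  dimnames(sim) <- list(ids, ids)
  if (n < 2) return(sim)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- motif_similarity(ppms[[i]], ppms[[j]], min_overlap)$similarity
      sim[i, j] <- sim[j, i] <- s
    }
  }
  sim
}

#' Cluster motifs into archetypes
#'
#' Complete-linkage hierarchical clustering on the distance
#' \code{1 - similarity}, cut at a fixed height. The conventional cut
#' heights are 0.45 for human motif collections and 0.35 for mouse (the
#' human collections carry more motifs).
#'
#' @param sim Symmetric similarity matrix (as from
#'   \code{\link{motif_similarity_matrix}}).
#' @param cut_height Dendrogram cut height in (0, 2); default 0.45.
#' @return Named integer vector of cluster labels.
#' @export
cluster_archetypes <- function(sim, cut_height = 0.45) {
  stopifnot(cut_height > 0, cut_height < 2)
  if (nrow(sim) == 1) {
    return(stats::setNames(1L, rownames(sim)))
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "complete")
  stats::cutree(hc, h = cut_height)
}

#' Best rank of any true motif
#'
#' @param ranked A ranked result (from \code{\link{rank_results}}).
#' @param true_motifs Character vector of true motif ids (the motif(s) of
#'   the perturbed TF).
#' @return The minimum rank attained by any true motif.
#' @export
true_motif_rank <- function(ranked, true_motifs) {
  hit <- ranked$motif %in% true_motifs
  if (!any(hit)) stop("no true motif present in the ranked results")
  min(ranked$rank[hit])
}

#' Normalized top-k membership AUC (network / archetype score)
#'
#' For k = 1..kmax, the proportion of the top-k ranked motifs that belong
#' to the member set (e.g. known physical interactors of the perturbed TF,
#' or motifs clustering with the true motif) defines a curve; its mean
#' (rectangle-rule AUC) is divided by the maximum theoretically attainable
#' AUC, \code{mean(pmin(k, n_members)/k)}, giving a score in [0, 1].
#'
#' @param ranked A ranked result (from \code{\link{rank_results}}).
#' @param members Character vector of member motif ids (non-empty).
#' @param kmax Curve depth (default 100, capped at the number of motifs).
#' @return Normalized AUC score in [0, 1].
#' @export
member_auc_score <- function(ranked, members, kmax = 100L) {
  stopifnot(length(members) > 0, kmax >= 1)
  kmax <- min(as.integer(kmax), nrow(ranked))
  in_set <- ranked$motif[order(ranked$rank)] %in% members
  k <- seq_len(kmax)
  prop <- cumsum(in_set[k]) / k
  auc <- mean(prop)
  auc_max <- mean(pmin(k, length(members)) / k)
  auc / auc_max
}

#' Precision and recall at an adjusted-p threshold
#'
#' The significant set S contains motifs with adjusted p <= alpha.
#' Positives are, by default, all motifs whose archetype cluster contains
#' a network member or true motif (set \code{expand_by_cluster = FALSE}
#' to count raw members only). Precision is |S and positives| / |S|
#' (\code{NA} when S is empty); recall counts only the true motifs,
#' |S and true| / |true|.
#'
#' @param results Data frame with \code{motif} and \code{fdr} (adjusted p)
#'   columns.
#' @param true_motifs Character vector of true motif ids.
#' @param network_members Character vector of network member ids
#'   (conventionally includes the true motifs).
#' @param clusters Named cluster labels (from
#'   \code{\link{cluster_archetypes}}); required when
#'   \code{expand_by_cluster} is \code{TRUE}.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param expand_by_cluster Expand positives to whole archetype clusters
#'   (default \code{TRUE}).
#' @return List with \code{precision}, \code{recall}, and the
#'   \code{positives} set used.
#' @export
precision_recall <- function(results, true_motifs, network_members,
                             clusters = NULL, alpha = 0.05,
                             expand_by_cluster = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  seed_set <- union(network_members, true_motifs)
  if (expand_by_cluster) {
    if (is.null(clusters)) stop("clusters required to expand positives")
    seed_cl <- unique(clusters[intersect(names(clusters), seed_set)])
    positives <- union(seed_set,
                       names(clusters)[clusters %in% seed_cl])
  } else {
    positives <- seed_set
  }
  sig <- results$motif[!is.na(results$fdr) & results$fdr <= alpha]
  precision <- if (length(sig) == 0) NA_real_ else
    length(intersect(sig, positives)) / length(sig)
  recall <- length(intersect(sig, true_motifs)) / length(true_motifs)
  list(precision = precision, recall = recall, positives = positives)
}

#' Transform a true-motif rank onto a bounded benefit scale
#'
#' \code{2 exp(-x) / (1 + exp(-x))} with \code{x = sqrt(rank)}
#' (equivalently \code{2 / (exp(sqrt(rank)) + 1)}): an inverse-logit-based
#' transform, strictly decreasing in rank, mapping rank 1 to about 0.538
#' and decaying toward 0, so that very poor ranks stop mattering.
#'
#' @param rank Integer rank(s) >= 1.
#' @return Transformed score(s) in (0, 0.538].
#' @export
rank_transform <- function(rank) {
  if (any(rank < 1)) stop("ranks must be >= 1")
  x <- sqrt(rank)
  2 * exp(-x) / (1 + exp(-x))
}

#' Rank methods across datasets with worst-case imputation
#'
#' Input metrics are methods x datasets matrices, one per metric; the
#' \code{rank} metric (rank of the true motif) is first transformed via
#' \code{\link{rank_transform}} so all metrics are benefit scores in
#' [0, 1]. Missing method/dataset cells are imputed, per dataset column,
#' with the worse (smaller) of that column's median and mean. Methods are
#' ordered by descending mean of all scores across metrics and datasets,
#' ties broken by method name; methods missing everywhere rank last and
#' are flagged.
#'
#' @param metrics Named list of methods x datasets numeric matrices; a
#'   matrix named \code{"rank"} holds raw true-motif ranks, all others are
#'   treated as benefit scores in [0, 1].
#' @return Data frame with \code{method}, \code{mean_score} and
#'   \code{rank}, best first; attribute \code{flagged} lists all-missing
#'   methods.
#' @export
rank_methods <- function(metrics) {
  stopifnot(is.list(metrics), length(metrics) >= 1)
  mats <- lapply(names(metrics), function(nm) {
    m <- as.matrix(metrics[[nm]])
    if (nm == "rank") {
      m[] <- ifelse(is.na(m), NA, rank_transform(pmax(m, 1)))
    }
    for (j in seq_len(ncol(m))) {
      if (anyNA(m[, j])) {
        fill <- min(stats::median(m[, j], na.rm = TRUE),
                    mean(m[, j], na.rm = TRUE))
        m[is.na(m[, j]), j] <- fill
      }
    }
    m
  })
  methods_ <- rownames(as.matrix(metrics[[1]]))
  all_missing <- methods_[apply(
    do.call(cbind, lapply(metrics, as.matrix)), 1,
    function(r) all(is.na(r)))]
  score <- rowMeans(do.call(cbind, mats), na.rm = TRUE)
  score[methods_ %in% all_missing] <- -Inf
  ord <- order(-score, methods_)
  out <- data.frame(method = methods_[ord], mean_score = score[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "flagged") <- all_missing
  out
}

#' Rank-based aggregation of several methods' motif rankings
#'
#' Per motif, the test statistic is the sum of its ranks across methods;
#' the aggregate p-value is the probability that independently uniform
#' ranks give a sum at most as small. The null distribution is computed by
#' exact convolution when \code{n_motifs * n_methods <= 1e4} and by
#' seeded Monte-Carlo otherwise.
#'
#' @param per_method_ranks Motifs x methods integer matrix; every column
#'   must be a permutation of \code{1..n_motifs}.
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed Seed for the Monte-Carlo path (default 1).
#' @return Data frame with \code{motif}, \code{rank_sum}, \code{p},
#'   \code{fdr}.
#' @export
aggregate_method_ranks <- function(per_method_ranks, n_mc = 1e5L,
                                   seed = 1L) {
  r <- as.matrix(per_method_ranks)
  n <- nrow(r)
  k <- ncol(r)
  if (k < 2) stop("need at least 2 methods")
  for (j in seq_len(k)) {
    if (!identical(sort(r[, j]), seq_len(n) * 1L) &&
        !isTRUE(all.equal(sort(as.numeric(r[, j])), as.numeric(seq_len(n))))) {
      stop("column ", j, " is not a permutation of 1..n")
    }
  }
  tsum <- rowSums(r)
  if (n * k <= 1e4) {
    # exact convolution of k iid uniform{1..n} variables
    pmf <- rep(1 / n, n)
    dist <- pmf
    for (i in seq_len(k - 1)) {
      dist <- stats::convolve(dist, rev(pmf), type = "open")
    }
    # dist[s] = P(sum = s + k - 1)
    cdf <- cumsum(dist)
    p <- cdf[tsum - k + 1]
    p <- pmin(pmax(p, 0), 1)
  } else {
    rng <- .local_rng(seed)
    sims <- rng$draw(function() {
      matrix(sample.int(n, n_mc * k, replace = TRUE), n_mc, k)
    })
    sim_sum <- rowSums(sims)
    p <- vapply(tsum, function(t0) mean(sim_sum <= t0), 0)
  }
  out <- data.frame(motif = rownames(r) %||% as.character(seq_len(n)),
                    rank_sum = tsum, p = p,
                    fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out
}
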