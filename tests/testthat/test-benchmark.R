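test_that("motif similarity handles identity, reverse complement and degeneracy", {
  a <- consensus_ppm("a", "AAACCGCT")
  expect_equal(motif_similarity(a, a)$similarity, 1, tolerance = 1e-12)
  expect_equal(motif_similarity(a, a)$offset, 0)

  rc_mat <- a$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(a$mat)))]
  rownames(rc_mat) <- c("A", "C", "G", "T")
  b <- list(id = "b", mat = rc_mat)
  sb <- motif_similarity(a, b)
  expect_equal(sb$similarity, 1, tolerance = 1e-12)
  expect_true(sb$rc)

  unif <- list(id = "u", mat = matrix(0.25, 4, 6,
                                      dimnames = list(c("A", "C", "G", "T"),
                                                      NULL)))
  su <- motif_similarity(unif, a)
  expect_equal(su$similarity, 0)
  expect_true(su$flagged)

  # shifted copy is recovered at the right offset
  shifted <- list(id = "s", mat = a$mat[, 3:8])
  ss <- motif_similarity(a, shifted)
  expect_equal(ss$similarity, 1, tolerance = 1e-12)
  expect_equal(ss$offset, 2)
})

test_that("archetype clustering cuts complete-linkage trees at fixed heights", {
  sim <- matrix(c(1, 0.8, 0.8, 1), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  cl <- cluster_archetypes(sim, 0.45)
  expect_equal(cl[["x"]], cl[["y"]])

  sim0 <- diag(1, 3)
  dimnames(sim0) <- list(letters[1:3], letters[1:3])
  expect_equal(length(unique(cluster_archetypes(sim0, 0.45))), 3)
  # extreme cuts: singletons vs one cluster
  set.seed(40)
  ppms <- lapply(1:6, function(i) {
    consensus_ppm(paste0("m", i),
                  paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                        collapse = ""))
  })
  names(ppms) <- paste0("m", 1:6)
  sm <- motif_similarity_matrix(ppms)
  expect_equal(length(unique(cluster_archetypes(sm, 1e-6))), 6)
  expect_equal(length(unique(cluster_archetypes(sm, 1.999))), 1)
  expect_equal(unname(cluster_archetypes(sim[1, 1, drop = FALSE], 0.45)),
               1L)
})

test_that("true-motif rank takes the best rank over the truth set", {
  ranked <- data.frame(motif = c("m1", "m2", "m3", "m4"),
                       p = c(0.01, 0.02, 0.03, 0.04),
                       effect = 1, rank = 1:4)
  expect_equal(true_motif_rank(ranked, "m3"), 3)
  expect_equal(true_motif_rank(ranked, c("m4", "m2")), 2)
  expect_error(true_motif_rank(ranked, "m99"), "no true motif")
})

test_that("member AUC score matches the worked example and brute force", {
  ranked <- data.frame(motif = c("A", "x", "B", "y"),
                       p = 1:4 / 10, effect = 1, rank = 1:4)
  expect_equal(member_auc_score(ranked, c("A", "B"), kmax = 4),
               0.8421053, tolerance = 1e-6)
  all_first <- data.frame(motif = c("A", "B", "x", "y"),
                          p = 1:4 / 10, effect = 1, rank = 1:4)
  expect_equal(member_auc_score(all_first, c("A", "B"), kmax = 4), 1)
  expect_equal(member_auc_score(ranked, "zzz", kmax = 4), 0)

  set.seed(41)
  for (r in 1:20) {
    n <- sample(20:500, 1)
    ids <- paste0("m", 1:n)
    rk <- data.frame(motif = sample(ids), p = sort(runif(n)), effect = 1,
                     rank = 1:n)
    members <- sample(ids, sample(3:15, 1))
    kmax <- min(100, n)
    prop <- vapply(seq_len(kmax), function(k) {
      mean(rk$motif[1:k] %in% members)
    }, 0)
    propmax <- vapply(seq_len(kmax), function(k) {
      min(k, length(members)) / k
    }, 0)
    expect_equal(member_auc_score(rk, members),
                 mean(prop) / mean(propmax), tolerance = 1e-12)
  }
})

test_that("precision and recall use archetype-expanded positives", {
  res <- data.frame(motif = paste0("m", 1:6),
                    fdr = c(0.01, 0.02, 0.04, 0.2, 0.9, NA))
  clusters <- setNames(c(1, 1, 2, 3, 3, 4), paste0("m", 1:6))
  pr <- precision_recall(res, true_motifs = "m1",
                         network_members = c("m1", "m2"),
                         clusters = clusters)
  # significant: m1, m2, m3; positives: cluster 1 = {m1, m2}
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 1)

  none <- transform(res, fdr = pmax(fdr, 0.5))
  pr0 <- precision_recall(none, "m1", c("m1", "m2"), clusters)
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)

  # raw-members-only variant shrinks the positive set
  pr_raw <- precision_recall(res, "m1", c("m1", "m2"), clusters,
                             expand_by_cluster = FALSE)
  expect_equal(pr_raw$positives, c("m1", "m2"))
})

test_that("the rank transform is the stated inverse-logit decay", {
  expect_equal(rank_transform(1), 0.5378828, tolerance = 1e-6)
  expect_equal(rank_transform(4), 0.2384058, tolerance = 1e-6)
  expect_equal(rank_transform(9), 2 / (exp(3) + 1), tolerance = 1e-12)
  v <- rank_transform(1:50)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 0.538))
  expect_error(rank_transform(0), ">= 1")
})

test_that("method ranking transforms, imputes worst-case and orders", {
  rank_mat <- matrix(c(1, 4), 2, 1,
                     dimnames = list(c("good", "bad"), "d1"))
  out <- rank_methods(list(rank = rank_mat))
  expect_equal(out$method, c("good", "bad"))

  # missing cell imputed with the worse of column median and mean
  score3 <- matrix(c(0.0, 0.2, 1.0, NA), 2, 2,
                   dimnames = list(c("m1", "m2"), c("d1", "d2")))
  out3 <- rank_methods(list(net = score3))
  # d2 column has single value 1.0; imputed 1.0; m1 mean (0+1)/2, m2 (0.2+1)/2
  expect_equal(out3$method, c("m2", "m1"))

  # skewed column: median 0.6, mean 0.7 -> the worse (0.6) is imputed
  skew <- matrix(c(0.1, 0.9, 0.8, 0.7, NA, 0.5, 0.6, 1.0), 4, 2,
                 dimnames = list(c("a", "b", "c", "d"), c("d1", "d2")))
  out_skew <- rank_methods(list(net = skew))
  a_score <- out_skew$mean_score[out_skew$method == "a"]
  expect_equal(a_score, mean(c(0.1, 0.6)))

  # all cells equal: ties broken by method name
  eq <- matrix(0.5, 3, 1, dimnames = list(c("zeta", "alpha", "mid"), "d"))
  expect_equal(rank_methods(list(net = eq))$method,
               c("alpha", "mid", "zeta"))
})

test_that("rank-sum aggregation uses the exact convolution when feasible", {
  n <- 10
  ranks <- cbind(a = 1:10, b = c(1, 3:10, 2), c = c(1, 2, 4:10, 3))
  rownames(ranks) <- paste0("m", 1:10)
  res <- aggregate_method_ranks(ranks)
  expect_equal(res$p[1], 1 / 1000, tolerance = 1e-9)  # T = 3, best possible
  mid <- which.min(abs(res$rank_sum - (3 * 11 / 2)))
  expect_lt(abs(res$p[mid] - 0.5), 0.15)
  expect_error(aggregate_method_ranks(ranks[, 1, drop = FALSE]),
               "2 methods")
  bad <- ranks; bad[1, 1] <- 5
  expect_error(aggregate_method_ranks(bad), "permutation")

  # exact branch against direct enumeration for 2 methods, n = 6
  set.seed(42)
  two <- cbind(sample.int(6), sample.int(6))
  rownames(two) <- paste0("m", 1:6)
  res2 <- aggregate_method_ranks(two)
  grid <- expand.grid(1:6, 1:6)
  for (i in 1:6) {
    pref <- mean(rowSums(grid) <= res2$rank_sum[i])
    expect_equal(res2$p[i], pref, tolerance = 1e-9)
  }
})

test_that("network-style scores correlate with better true-motif ranks", {
  set.seed(43)
  n <- 60
  ids <- paste0("m", 1:n)
  members <- paste0("m", 1:8)
  true_ranks <- numeric(30)
  net_scores <- numeric(30)
  for (s in 1:30) {
    # methods of varying quality: members pulled toward the top
    quality <- runif(1)
    score <- runif(n) - quality * (ids %in% members)
    rk <- data.frame(motif = ids[order(score)], p = sort(runif(n)),
                     effect = 1, rank = 1:n)
    true_ranks[s] <- true_motif_rank(rk, "m1")
    net_scores[s] <- member_auc_score(rk, members, kmax = 50)
  }
  expect_gt(cor(-true_ranks, net_scores, method = "spearman"), 0)
})
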