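toy_scenario <- function(enrichment, log2fc) {
  structure(data.frame(enrichment = enrichment, log2fc = log2fc),
            name = "toy", class = c("BindingScenario", "data.frame"))
}

test_that("fold-changes are assigned by quantile matching to the reference", {
  sc <- toy_scenario(c(2, 5, 9), c(-0.5, -1, -2))
  # identical target -> each peak gets its own reference fold-change
  expect_equal(quantile_match_fold_changes(c(2, 5, 9), sc),
               c(-0.5, -1, -2))
  # single reference peak -> everything maps to it
  sc1 <- toy_scenario(c(3, 3), c(-1.5, -1.5))
  expect_equal(quantile_match_fold_changes(c(0, 10, 20), sc1),
               rep(-1.5, 3))
  # interpolated map with the nearest-reference tie rule (lower index)
  sc2 <- toy_scenario(c(0, 10), c(-0.1, -2))
  expect_equal(quantile_match_fold_changes(c(1, 5, 9), sc2),
               c(-0.1, -0.1, -2))
  expect_equal(quantile_match_fold_changes(numeric(), sc2), numeric())
})

test_that("perturbation strength converts fold-changes to retention fractions", {
  eff <- effective_fraction(-2, 0.5)
  expect_equal(eff$fraction, 0.5)
  expect_equal(eff$group, "B")
  expect_equal(effective_fraction(3, 0)$fraction, 1)
  expect_equal(effective_fraction(0, 2)$fraction, 1)
  expect_equal(effective_fraction(1.5, 1)$group, "A")
  v <- effective_fraction(c(-1, 2), 1)
  expect_equal(v$fraction, c(0.5, 0.25))
  expect_equal(v$group, c("B", "A"))
})

test_that("downsampling retains ceil(n0 * fraction) fragments per peak", {
  pk <- data.frame(chrom = "c", start = 0L, end = 1000L)
  fr <- fragment_set(rep("c", 10), 0:9 * 50L, 0:9 * 50L + 60L,
                     sample_id = "s1")
  out <- downsample_fragments(fr, pk, fractions = 0.5, seed = 3)
  expect_equal(nrow(out), 5)
  expect_equal(attr(out, "retained")$ns, 5L)

  out1 <- downsample_fragments(fr, pk, fractions = 1, seed = 3)
  expect_equal(as.data.frame(out1), as.data.frame(fr))

  fr3 <- fragment_set(rep("c", 3), c(0L, 100L, 200L),
                      c(90L, 190L, 290L), sample_id = "s1")
  out3 <- downsample_fragments(fr3, pk, fractions = 0.9, seed = 3)
  expect_equal(nrow(out3), 3)  # min(ceil(2.7), 3) = 3

  expect_error(downsample_fragments(fr, pk, fractions = 0.5),
               "seed")
})

test_that("downsampling is seed-reproducible and count-deterministic", {
  pk <- data.frame(chrom = "c", start = c(0L, 2000L),
                   end = c(1000L, 3000L))
  set.seed(9)
  st <- c(sample(0:900, 200, TRUE), sample(2000:2900, 200, TRUE))
  fr <- fragment_set(rep("c", 400), st, st + 80L, sample_id = "s1")
  a <- downsample_fragments(fr, pk, fractions = c(0.4, 0.7), seed = 11)
  b <- downsample_fragments(fr, pk, fractions = c(0.4, 0.7), seed = 11)
  c_ <- downsample_fragments(fr, pk, fractions = c(0.4, 0.7), seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(attr(a, "retained")$ns, attr(c_, "retained")$ns)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
  expect_true(nrow(a) <= nrow(fr))
})

test_that("fragments overlapping two perturbed peaks are resolved once", {
  pk <- data.frame(chrom = "c", start = c(0L, 90L), end = c(100L, 200L))
  # fragment [80, 130): 20 bp in peak 1, 40 bp in peak 2 -> peak 2
  fr <- fragment_set("c", 80L, 130L, sample_id = "s1")
  out <- downsample_fragments(fr, pk, fractions = c(1, 1e-9), seed = 1)
  expect_equal(nrow(out), 1)  # ns = ceil(1 * 1e-9) = 1, still kept
  ret <- attr(out, "retained")
  expect_equal(ret$n0, c(0L, 1L))
})

test_that("composition bias resampling follows the density-ratio rule", {
  set.seed(2)
  n <- 4000
  fr <- fragment_set(rep("c", n), rep(0L, n),
                     sample(30:119, n, TRUE), sample_id = "s1",
                     gc = runif(n))
  # target equal to the empirical distribution -> identity
  b_unif <- bias_spec("gc", target = rep(0.5, 2), breaks = c(0, 0.5, 1))
  emp <- tabulate(findInterval(fr$gc, c(0, 0.5, 1), rightmost.closed = TRUE),
                  2) / n
  b_emp <- bias_spec("gc", target = emp, breaks = c(0, 0.5, 1))
  out_id <- apply_composition_bias(fr, b_emp, seed = 5)
  expect_equal(nrow(out_id), n)

  # degenerate length target keeps only NF fragments
  n2 <- 1000
  fr2 <- fragment_set(rep("c", n2), rep(0L, n2),
                      sample(c(60L, 200L, 400L, 700L), n2, TRUE))
  bfl <- bias_spec("fragment_length", target = c(1, 0, 0, 0))
  out_nf <- apply_composition_bias(fr2, bfl, seed = 5)
  expect_true(all(fragment_lengths(out_nf) <= 120))

  # 2-bin target (0.75, 0.25) on uniform empirical -> retention ratio 3:1
  b34 <- bias_spec("gc", target = c(0.75, 0.25), breaks = c(0, 0.5, 1))
  out34 <- apply_composition_bias(fr, b34, seed = 5)
  lo <- sum(out34$gc <= 0.5)
  hi <- sum(out34$gc > 0.5)
  expect_gt(lo / hi, 2.5)
  expect_lt(lo / hi, 3.6)
})

test_that("biased output converges to the reachable target distribution", {
  set.seed(13)
  n <- 4e4
  cls_ranges <- rbind(c(30, 120), c(121, 300), c(301, 500), c(501, 800))
  cls <- sample.int(4, n, TRUE, prob = c(0.55, 0.30, 0.10, 0.05))
  len <- cls_ranges[cls, 1] +
    floor(runif(n) * (cls_ranges[cls, 2] - cls_ranges[cls, 1] + 1))
  fr <- fragment_set(rep("c", n), rep(0L, n), as.integer(len))
  target <- c(0.40, 0.38, 0.14, 0.08)
  out <- apply_composition_bias(fr, bias_spec("fragment_length", target),
                                seed = 21)
  obs <- table(classify_fragments(out, "length_class"))
  gof <- chisq.test(obs, p = target)
  expect_gt(gof$p.value, 0.01)
})

test_that("the composed two-group simulation honors its boundary contracts", {
  b <- generate_fixture(small_spec(seed = 17, strength = 0))
  sc <- binding_scenario("activation")
  # p = 0 -> byte-identical fragment sets
  sim0 <- simulate_two_group_dataset(b$baseline_fragments, b$chip_peaks,
                                     sc, p = 0, seed = 4)
  for (j in seq_along(sim0$samples)) {
    expect_identical(as.data.frame(sim0$samples[[j]]),
                     as.data.frame(b$baseline_fragments[[j]]))
  }
  expect_equal(sim0$groups, rep(c("A", "B"), each = 3))
  # stronger perturbation removes at least as much everywhere
  sim1 <- simulate_two_group_dataset(b$baseline_fragments, b$chip_peaks,
                                     sc, p = 1, seed = 4)
  sim3 <- simulate_two_group_dataset(b$baseline_fragments, b$chip_peaks,
                                     sc, p = 3, seed = 4)
  expect_true(all(sim3$truth$peaks$fraction <= sim1$truth$peaks$fraction))
  cnt0 <- count_overlaps(b$baseline_fragments, b$peaks)
  cnt1 <- count_overlaps(sim1$samples, b$peaks)
  expect_true(all(cnt1 <= cnt0))
  expect_error(
    simulate_two_group_dataset(b$baseline_fragments, b$chip_peaks, sc,
                               p = 1),
    "seed")
})

test_that("realized between-group log-ratio approaches p * log2FC", {
  # one perturbed region with a constant reference fold-change of -1
  sc <- toy_scenario(c(1, 2), c(-1, -1))
  pk <- data.frame(chrom = "c", start = 0L, end = 5000L, score = 1.5)
  n0 <- 2000
  mk <- function(sid, seed) {
    set.seed(seed)
    st <- sample(0:4900, n0, TRUE)
    fragment_set(rep("c", n0), st, st + 80L, sample_id = sid)
  }
  baseline <- list(mk("a1", 1), mk("a2", 2), mk("b1", 3), mk("b2", 4))
  for (p in c(0.5, 1)) {
    sim <- simulate_two_group_dataset(baseline, pk, sc, p = p, seed = 31)
    cnt <- count_overlaps(sim$samples, pk)
    ratio <- log2(mean(cnt[1, 3:4]) / mean(cnt[1, 1:2]))
    expect_lt(abs(ratio - (-p)), 0.1)
  }
})
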