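test_that("fragment files parse with lengths, weights and sample filtering", {
  path <- write_fragment_lines(c("chr1\t100\t200", "chr1\t150\t260"))
  fr <- read_fragments(path, sample_id = "s1")
  expect_s3_class(fr, "FragmentSet")
  expect_equal(nrow(fr), 2)
  expect_equal(fragment_lengths(fr), c(100, 110))

  empty <- write_fragment_lines(character())
  expect_equal(nrow(read_fragments(empty)), 0)

  # weights carried vs expanded
  path5 <- write_fragment_lines(c("chr1\t10\t60\ts1\t3", "chr1\t20\t80\ts2\t1"))
  fr5 <- read_fragments(path5, sample_id = "s1")
  expect_equal(fr5$weight, 3L)
  fr5e <- read_fragments(path5, sample_id = "s1", expand_counts = TRUE)
  expect_equal(nrow(fr5e), 3)
  expect_true(all(fr5e$weight == 1L))
})

test_that("invalid fragment records are rejected or raise parse errors", {
  path <- write_fragment_lines(c("chr1\t100\t200", "chr1\t200\t100"))
  expect_message(fr <- read_fragments(path), "1 fragment record")
  expect_equal(nrow(fr), 1)
  expect_equal(attr(fr, "n_rejected"), 1)

  bad <- write_fragment_lines(c("chr1\t100\t200", "chr1\tnope\t300"))
  expect_error(read_fragments(bad), "line 2")
  short <- write_fragment_lines(c("chr1\t100"))
  expect_error(read_fragments(short), "line 1")
})

test_that("fragment write/read round trip preserves intervals", {
  fr <- fragment_set(c("chr1", "chr2", "chr1"), c(0L, 5L, 100L),
                     c(50L, 80L, 220L), weight = c(1L, 2L, 1L),
                     sample_id = "sA")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fragments(fr, path)
  back <- read_fragments(path, sample_id = "sA")
  expect_equal(back$chrom, fr$chrom)
  expect_equal(back$start, fr$start)
  expect_equal(back$end, fr$end)
  expect_equal(back$weight, fr$weight)
})

test_that("peak merging and fixed-width resizing follow the midpoint rule", {
  p1 <- data.frame(chrom = "chr1", start = 100L, end = 250L)
  p2 <- data.frame(chrom = "chr1", start = 200L, end = 400L)
  out <- resize_and_merge_peaks(list(p1, p2), width = 300)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 400L)

  single <- data.frame(chrom = "chr1", start = 0L, end = 300L)
  expect_equal(resize_and_merge_peaks(single, 300)[, c("start", "end")],
               data.frame(start = 0L, end = 300L))

  disj <- data.frame(chrom = "chr1", start = c(0L, 500L),
                     end = c(100L, 600L))
  out2 <- resize_and_merge_peaks(disj, 150)
  expect_equal(out2$start, c(0L, 475L))   # [-25,125) clipped at 0
  expect_equal(out2$end, c(125L, 625L))

  expect_error(resize_and_merge_peaks(list(), 300), "no peak sets")
})

test_that("resizing preserves midpoints within 1 bp away from clipping", {
  set.seed(41)
  starts <- sample.int(10000, 50) + 500L
  peaks <- data.frame(chrom = "chrX", start = starts,
                      end = starts + sample(50:400, 50, replace = TRUE))
  out <- resize_and_merge_peaks(peaks, 301)
  merged <- GenomicRanges::reduce(GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end)))
  mid_in <- (GenomicRanges::start(merged) - 1 +
               GenomicRanges::end(merged)) %/% 2
  mid_out <- (out$start + out$end) %/% 2
  expect_true(all(abs(sort(mid_out) - sort(mid_in)) <= 1))
})

test_that("overlap counting matches a brute-force double loop", {
  fr1 <- fragment_set("chr1", 150L, 160L, sample_id = "s1")
  peaks <- data.frame(chrom = "chr1", start = c(100L, 300L),
                      end = c(200L, 400L))
  expect_equal(unname(count_overlaps(fr1, peaks)[, 1]), c(1L, 0L))
  spanning <- fragment_set("chr1", 190L, 310L, sample_id = "s1")
  expect_equal(unname(count_overlaps(spanning, peaks)[, 1]), c(1L, 1L))
  none <- fragment_set(sample_id = "s1")
  expect_equal(unname(count_overlaps(list(none, none), peaks)),
               matrix(0L, 2, 2))

  set.seed(7)
  n <- 500
  frs <- lapply(1:2, function(j) {
    st <- sample.int(5000, n)
    fragment_set(sample(c("c1", "c2"), n, TRUE), st,
                 st + sample(20:600, n, TRUE),
                 weight = sample(1:3, n, TRUE),
                 sample_id = paste0("s", j))
  })
  ps <- sample.int(5000, 40)
  pk <- data.frame(chrom = sample(c("c1", "c2", "c3"), 40, TRUE),
                   start = ps, end = ps + 300L)
  got <- count_overlaps(frs, pk)
  brute <- matrix(0L, nrow(pk), 2)
  for (j in 1:2) {
    fr <- frs[[j]]
    for (i in seq_len(nrow(pk))) {
      for (k in seq_len(nrow(fr))) {
        if (fr$chrom[k] == pk$chrom[i] && fr$start[k] < pk$end[i] &&
            fr$end[k] > pk$start[i]) {
          brute[i, j] <- brute[i, j] + fr$weight[k]
        }
      }
    }
  }
  expect_equal(unname(got), brute)
})

test_that("fragment length classes partition at the fixed thresholds", {
  fr <- fragment_set(rep("c", 6), rep(0L, 6),
                     c(120L, 121L, 300L, 301L, 500L, 501L))
  expect_equal(as.character(classify_fragments(fr, "length_class")),
               c("NF", "mono", "mono", "di", "di", "multi"))

  fr2 <- fragment_set(rep("c", 4), rep(100L, 4),
                      100L + c(29L, 30L, 120L, 121L))
  kept <- classify_fragments(fr2, "nucleosome_free")
  expect_equal(fragment_lengths(kept), c(30, 120))

  expect_equal(nrow(classify_fragments(fragment_set(), "nucleosome_free")), 0)
  # partition: every fragment gets exactly one class
  set.seed(1)
  frr <- fragment_set(rep("c", 200), rep(0L, 200),
                      sample(1:900, 200, TRUE))
  cls <- classify_fragments(frr, "length_class")
  expect_false(anyNA(cls))
})

test_that("Tn5 insertion events sit at (shifted) fragment endpoints", {
  fr <- fragment_set("chr1", 100L, 200L)
  ev <- tn5_insertions(fr)
  expect_equal(sort(ev$pos), c(100, 199))
  ev2 <- tn5_insertions(fr, shift_plus = 4L, shift_minus = 5L)
  expect_equal(sort(ev2$pos), c(104, 194))

  two <- fragment_set(rep("chr1", 2), rep(100L, 2), rep(200L, 2))
  ev3 <- tn5_insertions(two)
  expect_equal(as.integer(table(ev3$pos)), c(2L, 2L))

  near0 <- fragment_set("chr1", 1L, 50L)
  expect_message(ev4 <- tn5_insertions(near0, shift_plus = -3L),
                 "dropped")
  expect_equal(nrow(ev4), 1)
})

test_that("JASPAR and MEME motif parsing normalizes probabilities", {
  jaspar <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 test",
               "A [ 8 0 0 ]",
               "C [ 0 8 0 ]",
               "G [ 0 0 0 ]",
               "T [ 0 0 0 ]"), jaspar)
  expect_warning(ppms <- read_ppm(jaspar, "jaspar"), "all-zero")
  m <- ppms[["M1"]]$mat
  expect_equal(m[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(m[, 3]), rep(0.25, 4))
  expect_equal(unname(m[, 2]), c(0, 1, 0, 0))
  expect_true(all(abs(colSums(m) - 1) < 1e-9))

  meme <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF MX", "letter-probability matrix: alength= 4 w= 2",
               " 0.25 0.25 0.25 0.25", " 0.97 0.01 0.01 0.01"), meme)
  pm <- read_ppm(meme, "meme")
  expect_equal(unname(pm[["MX"]]$mat[, 2]), c(0.97, 0.01, 0.01, 0.01))

  # write -> read round trip
  out <- withr::local_tempfile(fileext = ".jaspar")
  write_ppm_jaspar(pm, out)
  back <- read_ppm(out, "jaspar")
  expect_equal(back[["MX"]]$mat, pm[["MX"]]$mat, tolerance = 1e-6)
})

test_that("matrix and count table round trips preserve values and names", {
  set.seed(5)
  m <- matrix(rpois(60, 2), 10, 6,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:6)))
  path <- withr::local_tempfile(fileext = ".mtx")
  write_matrix_mtx(m, path)
  back <- as.matrix(read_matrix_mtx(path))
  expect_equal(unname(back), unname(m))
  expect_equal(dimnames(back), dimnames(m))

  pk <- data.frame(chrom = "c1", start = 0:9 * 100L, end = 0:9 * 100L + 50L)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(m, pk, cpath)
  rt <- read_counts_tsv(cpath)
  expect_equal(unname(rt$counts), unname(m))
  expect_equal(rt$peaks$start, pk$start)
})
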