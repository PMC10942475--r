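# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

small_spec <- function(seed, ...) {
  fixture_spec(n_peaks = 400L, n_motifs = 30L, n_per_group = 3L,
               seed = seed, ...)
}

# moderate shift of the GC distribution toward higher GC, mimicking a
# reference GC content profile differing from the baseline Beta(9, 11)
make_gc_bias <- function(shape1 = 10, shape2 = 10) {
  br <- seq(0, 1, length.out = 21)
  mids <- (br[-1] + br[-length(br)]) / 2
  d <- stats::dbeta(mids, shape1, shape2)
  bias_spec("gc", target = d / sum(d), breaks = br)
}

# shift of the fragment-length mixture toward nucleosome-containing
# fragments, relative to the baseline weights (0.55, 0.30, 0.10, 0.05)
make_fl_bias <- function(probs = c(0.40, 0.38, 0.14, 0.08)) {
  bias_spec("fragment_length", target = probs / sum(probs))
}

# biases applied to group B only (first n samples untouched)
group_b_biases <- function(bias, n_per_group = 3L) {
  c(rep(list(NULL), n_per_group), rep(list(bias), n_per_group))
}

# a deterministic PPM from a consensus string, with `soft` probability
# spread over the other bases
consensus_ppm <- function(id, consensus, soft = 0.05) {
  bases <- c("A", "C", "G", "T")
  mat <- vapply(strsplit(consensus, "")[[1]], function(b) {
    p <- rep(soft / 3, 4)
    p[match(b, bases)] <- 1 - soft
    p
  }, numeric(4))
  rownames(mat) <- bases
  list(id = id, mat = mat)
}

write_fragment_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
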