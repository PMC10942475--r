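# Fully synthetic fixtures: peaks, motifs, matches, fragments and ChIP
# truth with the statistical structure the inference methods assume, so
# every analysis is exercisable without external downloads.

#' Specification of a synthetic fixture
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 2000 fixed-width peaks on one synthetic contig, 100 motifs, two
#' groups of 3 samples, negative-binomial baseline counts with peak-specific
#' means, the four-class ATAC fragment-length mixture, Beta-distributed
#' peak GC with a mild GC-motif association, sparse pairwise motif
#' co-occurrence, and an imperfect ChIP/motif overlap (70% of the perturbed
#' motif's matched peaks are ChIP peaks, and 10% of the ChIP set is
#' off-motif).
#'
#' @param n_peaks,n_motifs,n_per_group,peak_width Fixture dimensions.
#' @param gc_shape1,gc_shape2 Beta parameters of per-peak GC (mean 0.45).
#' @param nb_mean_log,nb_mean_sdlog Log-normal parameters of peak-specific
#'   NB means (fragments per peak per sample).
#' @param nb_size Negative-binomial size (1/dispersion).
#' @param lib_sdlog Log-normal spread of per-sample library size factors.
#' @param fl_weights Mixture weights over fragment-length classes
#'   (NF, mono, di, multi).
#' @param fl_ranges 4 x 2 matrix of class length ranges in bp.
#' @param prevalence_range Per-motif match prevalence range.
#' @param gc_association SD of per-motif GC slopes on the match logit
#'   (0 removes GC-motif association).
#' @param cooccurrence_boost Logit boost for paired motif co-occurrence;
#'   about \code{n_motifs/10} motif pairs are linked.
#' @param ppm_length_range,ppm_conc Motif model length range and Dirichlet
#'   concentration of PPM columns (small = informative).
#' @param perturbed_motif Motif id to perturb (default the first motif).
#' @param scenario Scenario name for \code{\link{binding_scenario}}.
#' @param strength Perturbation strength p (default 1).
#' @param chip_frac_matched Fraction of the perturbed motif's matched peaks
#'   that are ChIP peaks (default 0.7).
#' @param chip_frac_offmotif Fraction of the ChIP set drawn from unmatched
#'   peaks (default 0.1).
#' @param seed Integer seed (required).
#' @return A \code{FixtureSpec} list.
#' @export
fixture_spec <- function(n_peaks = 2000L, n_motifs = 100L,
                         n_per_group = 3L, peak_width = 300L,
                         gc_shape1 = 9, gc_shape2 = 11,
                         nb_mean_log = log(20), nb_mean_sdlog = 0.6,
                         nb_size = 5, lib_sdlog = 0.15,
                         fl_weights = c(NF = 0.55, mono = 0.30,
                                        di = 0.10, multi = 0.05),
                         fl_ranges = rbind(c(30, 120), c(121, 300),
                                           c(301, 500), c(501, 800)),
                         prevalence_range = c(0.03, 0.15),
                         gc_association = 1,
                         cooccurrence_boost = 1.5,
                         ppm_length_range = c(8L, 14L), ppm_conc = 0.3,
                         perturbed_motif = NULL,
                         scenario = "activation", strength = 1,
                         chip_frac_matched = 0.7,
                         chip_frac_offmotif = 0.1, seed = NULL) {
  stopifnot(n_per_group >= 1,
            abs(sum(fl_weights) - 1) < 1e-8, all(fl_weights >= 0),
            strength >= 0)
  as.list(environment())
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Generate a synthetic fixture bundle
#'
#' Lays \code{n_peaks} fixed-width peaks with gaps on one synthetic contig;
#' draws per-peak GC from a Beta distribution; samples motif matches as
#' Bernoulli with a logit linear in (standardized) GC plus pairwise
#' co-occurrence boosts; samples PPMs column-wise from a Dirichlet;
#' draws baseline counts from a negative binomial with peak-specific means
#' and per-sample library factors; realizes each counted fragment with a
#' length from the class mixture and a midpoint inside the peak (plus a
#' per-fragment GC annotation tracking the peak GC); selects ChIP peaks as
#' a fraction of the perturbed motif's matched peaks plus off-motif peaks
#' with log-normal enrichment scores; and finally applies the
#' semi-simulated perturbation at the requested strength.
#'
#' @param spec A \code{\link{fixture_spec}} with a non-\code{NULL}
#'   \code{seed}.
#' @return A \code{FixtureBundle} list: \code{peaks} (with \code{gc}),
#'   \code{matches} (sparse indicator), \code{scores} (match scores),
#'   \code{ppms}, \code{fragments} (list of perturbed
#'   \code{FragmentSet}s), \code{baseline_counts}, \code{groups},
#'   \code{sample_ids}, \code{chip_peaks}, \code{truth}, \code{spec}.
#' @export
generate_fixture <- function(spec = fixture_spec(seed = 1L)) {
  if (is.null(spec$seed)) stop("a seed is required")
  rng <- .local_rng(spec$seed)
  rng$draw(function() .generate_fixture_impl(spec))
}

.generate_fixture_impl <- function(spec) {
  np <- spec$n_peaks
  nm <- spec$n_motifs
  ns <- 2L * spec$n_per_group
  width <- spec$peak_width
  gap <- 600L
  starts <- 1000L + (seq_len(np) - 1L) * (width + gap)
  peaks <- data.frame(chrom = "chrSim", start = starts,
                      end = starts + width, stringsAsFactors = FALSE)
  peaks$gc <- stats::rbeta(np, spec$gc_shape1, spec$gc_shape2)

  # motif matches: Bernoulli, logit linear in standardized GC, plus
  # co-occurrence boosts from a sparse set of motif pairs
  motif_ids <- sprintf("M%03d", seq_len(nm))
  prev <- stats::runif(nm, spec$prevalence_range[1],
                       spec$prevalence_range[2])
  slopes <- stats::rnorm(nm, 0, spec$gc_association)
  zgc <- .zscale(peaks$gc)
  n_pairs <- floor(nm / 10)
  partner <- rep(NA_integer_, nm)
  if (n_pairs > 0 && nm >= 4) {
    pr <- matrix(sample.int(nm, 2L * n_pairs), ncol = 2)
    partner[pmax(pr[, 1], pr[, 2])] <- pmin(pr[, 1], pr[, 2])
  }
  matches <- matrix(0L, np, nm, dimnames = list(peak_names(peaks),
                                                motif_ids))
  for (m in seq_len(nm)) {
    eta <- stats::qlogis(prev[m]) + slopes[m] * zgc
    if (!is.na(partner[m])) {
      eta <- eta + spec$cooccurrence_boost * matches[, partner[m]]
    }
    matches[, m] <- stats::rbinom(np, 1L, stats::plogis(eta))
  }
  scores <- matrix(0, np, nm, dimnames = dimnames(matches))
  nz <- matches > 0
  scores[nz] <- stats::runif(sum(nz), 0.5, 1)

  ppms <- lapply(seq_len(nm), function(m) {
    len <- sample(seq(spec$ppm_length_range[1], spec$ppm_length_range[2]),
                  1)
    mat <- vapply(seq_len(len), function(i) {
      .rdirichlet1(rep(spec$ppm_conc, 4))
    }, numeric(4))
    rownames(mat) <- c("A", "C", "G", "T")
    list(id = motif_ids[m], mat = mat)
  })
  names(ppms) <- motif_ids

  # baseline counts: NB with peak-specific means, per-sample library factors
  mu <- stats::rlnorm(np, spec$nb_mean_log, spec$nb_mean_sdlog)
  libf <- stats::rlnorm(ns, 0, spec$lib_sdlog)
  sample_ids <- sprintf("s%d", seq_len(ns))
  groups <- rep(c("A", "B"), each = spec$n_per_group)
  counts <- matrix(0L, np, ns, dimnames = list(peak_names(peaks),
                                               sample_ids))
  for (j in seq_len(ns)) {
    counts[, j] <- stats::rnbinom(np, mu = mu * libf[j],
                                  size = spec$nb_size)
  }

  # realize fragments: class mixture lengths, midpoints inside the peak
  fragments <- vector("list", ns)
  for (j in seq_len(ns)) {
    idx <- rep.int(seq_len(np), counts[, j])
    nfr <- length(idx)
    cls <- sample.int(4L, nfr, replace = TRUE, prob = spec$fl_weights)
    lo <- spec$fl_ranges[cls, 1]
    hi <- spec$fl_ranges[cls, 2]
    len <- lo + floor(stats::runif(nfr) * (hi - lo + 1))
    mid <- peaks$start[idx] + floor(stats::runif(nfr) * width)
    fstart <- pmax(mid - len %/% 2, 0)
    fgc <- pmin(pmax(peaks$gc[idx] + stats::rnorm(nfr, 0, 0.04), 0.01),
                0.99)
    fragments[[j]] <- fragment_set(rep("chrSim", nfr), fstart,
                                   fstart + len, sample_id = sample_ids[j],
                                   gc = fgc)
  }

  # ChIP peaks of the perturbed motif: most matched peaks, some off-motif
  perturbed <- spec$perturbed_motif %||% motif_ids[1]
  matched_idx <- which(matches[, perturbed] > 0)
  n_on <- max(2L, round(spec$chip_frac_matched * length(matched_idx)))
  on_idx <- sort(sample(matched_idx, min(n_on, length(matched_idx))))
  n_off <- round(spec$chip_frac_offmotif * length(on_idx) /
                   max(1e-9, 1 - spec$chip_frac_offmotif))
  off_pool <- setdiff(seq_len(np), matched_idx)
  off_idx <- sort(sample(off_pool, min(n_off, length(off_pool))))
  chip_idx <- sort(c(on_idx, off_idx))
  chip_peaks <- peaks[chip_idx, c("chrom", "start", "end")]
  chip_peaks$score <- stats::rlnorm(length(chip_idx), 2, 0.8)
  rownames(chip_peaks) <- NULL

  scen <- binding_scenario(spec$scenario)
  sim <- simulate_two_group_dataset(fragments, chip_peaks, scen,
                                    p = spec$strength, seed = spec$seed)
  truth <- sim$truth
  truth$perturbed_motif <- perturbed
  truth$chip_peak_index <- chip_idx
  truth$spec <- spec[setdiff(names(spec), c("fl_ranges"))]

  list(peaks = peaks,
       matches = Matrix::Matrix(matches, sparse = TRUE),
       scores = scores, ppms = ppms, fragments = sim$samples,
       baseline_fragments = fragments, baseline_counts = counts,
       groups = groups, sample_ids = sample_ids,
       chip_peaks = chip_peaks, truth = truth, spec = spec)
}

#' Permute group labels of a fixture (null resample)
#'
#' Produces a label-permuted copy of the bundle for type-I-error suites;
#' no data are regenerated and group sizes are preserved. The truth
#' manifest is marked null.
#'
#' @param bundle A \code{\link{generate_fixture}} bundle.
#' @param seed Integer seed.
#' @return The bundle with permuted \code{groups} and
#'   \code{truth$null = TRUE}.
#' @export
generate_null_resample <- function(bundle, seed) {
  rng <- .local_rng(seed)
  perm <- rng$sample(seq_along(bundle$groups), length(bundle$groups))
  bundle$groups <- bundle$groups[perm]
  bundle$truth$null <- TRUE
  bundle$truth$label_permutation <- perm
  bundle
}

#' Write a fixture bundle to disk
#'
#' Emits exactly the plain-text formats the package consumes: one
#' fragments TSV per sample, peaks BED, a peak GC TSV, the match matrix as
#' MatrixMarket with name sidecars, motifs in JASPAR format, ChIP peaks
#' BED (enrichment in the score column) and a JSON truth manifest.
#'
#' @param bundle A \code{\link{generate_fixture}} bundle.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (j in seq_along(bundle$fragments)) {
    sid <- sample_id(bundle$fragments[[j]])
    p <- file.path(dir, paste0("fragments_", sid, ".tsv"))
    write_fragments(bundle$fragments[[j]], p)
    paths[[paste0("fragments_", sid)]] <- p
  }
  paths$peaks <- write_peaks_bed(bundle$peaks, file.path(dir, "peaks.bed"))
  gc_df <- data.frame(peak = peak_names(bundle$peaks),
                      gc = bundle$peaks$gc)
  utils::write.table(gc_df, file.path(dir, "peaks_gc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$gc <- file.path(dir, "peaks_gc.tsv")
  paths$matches <- write_matrix_mtx(bundle$matches,
                                    file.path(dir, "matches.mtx"))
  paths$motifs <- write_ppm_jaspar(bundle$ppms,
                                   file.path(dir, "motifs.jaspar"))
  paths$chip <- write_peaks_bed(bundle$chip_peaks,
                                file.path(dir, "chip_peaks.bed"))
  manifest <- bundle$truth
  manifest$groups <- bundle$groups
  manifest$sample_ids <- bundle$sample_ids
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$truth <- file.path(dir, "truth.json")
  invisible(paths)
}
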