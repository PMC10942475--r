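# Semi-simulation: plant a TF-specific accessibility perturbation into
# baseline fragment data by downsampling fragments over the TF's ChIP-seq
# peaks, following a differential-binding scenario, with optional
# GC/fragment-length technical biases.

#' Load a differential-binding scenario
#'
#' A scenario is a table of reference ChIP-seq peaks with their enrichment
#' over input and the log2 fold-change observed between conditions. Two
#' synthetic scenario libraries ship with the package, emulating the two
#' canonical shapes: \code{"activation"} (high-occupancy peaks most
#' affected, as for ligand-based receptor activation) and
#' \code{"haploinsufficiency"} (TF dosage halved; low-occupancy peaks most
#' affected). Users may instead supply their own TSV with columns
#' \code{enrichment} and \code{log2fc}.
#'
#' @param name \code{"activation"}, \code{"haploinsufficiency"}, or a path
#'   to a scenario TSV.
#' @return A \code{BindingScenario}: data frame with columns
#'   \code{enrichment} and \code{log2fc} and a \code{name} attribute.
#' @export
binding_scenario <- function(name = c("activation", "haploinsufficiency")) {
  if (file.exists(name[1])) {
    path <- name[1]
    label <- sub("\\.tsv$", "", basename(path))
  } else {
    label <- match.arg(name)
    path <- system.file("extdata",
                        paste0("scenario_", label, "_synthetic.tsv"),
                        package = "tfatac", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("enrichment", "log2fc") %in% names(df)),
            nrow(df) >= 2, all(is.finite(df$enrichment)))
  structure(df[, c("enrichment", "log2fc")], name = label,
            class = c("BindingScenario", "data.frame"))
}

#' Assign fold-changes to target peaks by quantile matching
#'
#' Target ChIP-peak enrichments are quantile-normalized onto the reference
#' enrichment distribution of the scenario (rank-based, linear interpolation
#' between order statistics), and each mapped value receives the log2
#' fold-change of the reference peak with the nearest enrichment (ties go to
#' the lower reference index).
#'
#' @param target_enrich Numeric vector of enrichment scores of the peaks to
#'   perturb.
#' @param scenario A \code{\link{binding_scenario}}.
#' @return Numeric vector of per-peak log2 fold-changes, same length as
#'   \code{target_enrich}.
#' @export
quantile_match_fold_changes <- function(target_enrich, scenario) {
  if (length(target_enrich) == 0) return(numeric())
  stopifnot(all(is.finite(target_enrich)))
  ref_e <- scenario$enrichment
  ref_fc <- scenario$log2fc
  n <- length(target_enrich)
  probs <- if (n == 1) 0.5 else
    (rank(target_enrich, ties.method = "average") - 1) / (n - 1)
  mapped <- stats::quantile(ref_e, probs = probs, type = 7, names = FALSE)
  idx <- vapply(mapped, function(v) which.min(abs(ref_e - v)), 0L)
  ref_fc[idx]
}

#' Effective retention fraction for a perturbed peak
#'
#' The planted per-peak log2 fold-change, scaled by the perturbation
#' strength \code{p}, is realized as a retention fraction
#' \eqn{2^{-p |log2FC|}} applied to the downsampled group. The group is
#' determined by the sign of the fold-change: negative log2FC downsamples
#' group B (so the realized B-vs-A log fold-change is negative), positive
#' downsamples group A. \code{p = 0} gives fraction 1, i.e. the original
#' data.
#'
#' @param log2fc Planted log2 fold-change (real).
#' @param p Perturbation strength (non-negative).
#' @return List with \code{fraction} in (0, 1] and \code{group}
#'   (\code{"A"} or \code{"B"}); vectorized over \code{log2fc}.
#' @export
effective_fraction <- function(log2fc, p) {
  stopifnot(p >= 0, is.finite(p))
  list(fraction = 2^(-p * abs(log2fc)),
       group = ifelse(log2fc < 0, "B", "A"))
}

#' Downsample fragments over perturbed peaks
#'
#' For each perturbed peak i, the fragments of the sample overlapping it
#' (n0) are downsampled uniformly at random without replacement to
#' \eqn{n_s = \min\{\lceil n_0 \cdot fraction_i \rceil, n_0\}}. Fragments
#' outside all perturbed peaks pass through unchanged. A fragment
#' overlapping several perturbed peaks is assigned once, to the peak with
#' the largest overlap (ties to the lower peak index). Fragment weights > 1
#' are expanded before sampling so the formula operates on fragment events.
#'
#' @param frags A \code{FragmentSet} belonging to the group being
#'   downsampled.
#' @param chip_peaks Peak data frame of the perturbed ChIP peaks.
#' @param fractions Numeric vector of retention fractions, one per ChIP
#'   peak.
#' @param seed Integer seed (required for reproducibility).
#' @return A downsampled \code{FragmentSet}; attribute \code{retained}
#'   holds the per-peak (n0, ns) table.
#' @export
downsample_fragments <- function(frags, chip_peaks, fractions, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  .validate_peaks(chip_peaks)
  stopifnot(length(fractions) == nrow(chip_peaks),
            all(fractions > 0 & fractions <= 1))
  if (nrow(frags) == 0 || all(fractions == 1)) {
    attr(frags, "retained") <- NULL
    return(frags)
  }
  if (any(frags$weight > 1)) {
    frags <- .fragment_subset(frags, rep.int(seq_len(nrow(frags)),
                                             frags$weight))
    frags$weight <- 1L
  }
  fr_gr <- .as_gr(frags)
  pk_gr <- .as_gr(chip_peaks)
  hits <- GenomicRanges::findOverlaps(fr_gr, pk_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  assigned <- rep(NA_integer_, nrow(frags))
  if (length(qh) > 0) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      fr_gr[qh], pk_gr[sh]))
    # largest overlap wins; ties -> lower peak index
    ord <- order(qh, -ov, sh)
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- sh[ord][first]
  }
  rng <- .local_rng(seed)
  keep <- rep(TRUE, nrow(frags))
  retained <- data.frame(peak = seq_len(nrow(chip_peaks)),
                         n0 = 0L, ns = 0L)
  for (i in sort(unique(assigned[!is.na(assigned)]))) {
    members <- which(assigned == i)
    n0 <- length(members)
    ns <- min(ceiling(n0 * fractions[i]), n0)
    retained$n0[i] <- n0
    retained$ns[i] <- as.integer(ns)
    if (ns < n0) {
      drop <- members[rng$sample(seq_len(n0), n0 - ns)]
      keep[drop] <- FALSE
    }
  }
  out <- .fragment_subset(frags, which(keep))
  attr(out, "retained") <- retained
  out
}

# Seeded RNG scoped to the call: callers get reproducibility without
# clobbering the global .Random.seed.
.local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  state <- get(".Random.seed", envir = globalenv())
  restore <- function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  use <- function(f) {
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      restore()
    })
    f()
  }
  list(
    sample = function(x, size) use(function() sample(x, size)),
    runif = function(n) use(function() stats::runif(n)),
    draw = function(f) use(f)
  )
}

#' Composition-bias specification
#'
#' Describes a target distribution over a fragment attribute used to inject
#' sample-wise technical bias: either a binned density over GC fraction
#' (bins covering [0, 1]) or sampling probabilities over the four
#' fragment-length classes (NF, mono, di, multi).
#'
#' @param kind \code{"gc"} or \code{"fragment_length"}.
#' @param target For \code{"gc"}: numeric vector of bin masses (must sum to
#'   1) over \code{breaks}; for \code{"fragment_length"}: probabilities for
#'   (NF, mono, di, multi), summing to 1.
#' @param breaks For \code{"gc"}: bin breakpoints covering [0, 1]
#'   (default 20 equal bins).
#' @return A \code{BiasSpec} list.
#' @export
bias_spec <- function(kind = c("gc", "fragment_length"), target,
                      breaks = seq(0, 1, length.out = 21)) {
  kind <- match.arg(kind)
  stopifnot(abs(sum(target) - 1) < 1e-8, all(target >= 0))
  if (kind == "gc") {
    stopifnot(length(target) == length(breaks) - 1,
              abs(breaks[1]) < 1e-12,
              abs(breaks[length(breaks)] - 1) < 1e-12)
  } else {
    stopifnot(length(target) == 4)
  }
  structure(list(kind = kind, target = target, breaks = breaks),
            class = "BiasSpec")
}

#' Subsample fragments toward a target attribute distribution
#'
#' Fragments are kept with acceptance probability proportional to
#' target density / empirical density of the biased attribute (GC content
#' or fragment-length class), normalized so the maximum acceptance
#' probability is 1. The empirical density is a histogram over the bias
#' bins/classes. Target mass on empirically empty bins is unreachable and
#' triggers a warning.
#'
#' @param frags A \code{FragmentSet}; for GC bias it must carry a
#'   \code{gc} column.
#' @param bias A \code{\link{bias_spec}}.
#' @param seed Integer seed.
#' @return The subsampled \code{FragmentSet}.
#' @export
apply_composition_bias <- function(frags, bias, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(inherits(bias, "BiasSpec"))
  if (nrow(frags) == 0) return(frags)
  if (bias$kind == "gc") {
    if (is.null(frags$gc)) stop("gc bias requires per-fragment gc values")
    bin <- findInterval(frags$gc, bias$breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    nbin <- length(bias$breaks) - 1L
  } else {
    bin <- as.integer(classify_fragments(frags, "length_class"))
    nbin <- 4L
  }
  emp <- tabulate(bin, nbins = nbin) / nrow(frags)
  unreachable <- bias$target > 0 & emp == 0
  if (any(unreachable)) {
    warning("target mass ", signif(sum(bias$target[unreachable]), 3),
            " on empirically empty bins is unreachable")
  }
  ratio <- ifelse(emp > 0, bias$target / emp, 0)
  if (all(ratio == 0)) stop("target distribution has no reachable mass")
  accept <- ratio / max(ratio)
  rng <- .local_rng(seed)
  u <- rng$runif(nrow(frags))
  .fragment_subset(frags, which(u <= accept[bin]))
}

#' Simulate a perturbed two-group dataset
#'
#' Composes the full semi-simulation: fold-change assignment by quantile
#' matching against the scenario, conversion to retention fractions at
#' perturbation strength \code{p}, per-sample downsampling of fragments
#' overlapping the ChIP peaks of the perturbed group, and optional
#' per-sample composition biases. Baseline samples are split into two
#' groups (first half A, second half B unless \code{groups} is given).
#'
#' @param baseline List of \code{FragmentSet}s (>= 2 samples).
#' @param chip_peaks ChIP peak data frame with a \code{score} column
#'   holding enrichment over input.
#' @param scenario A \code{\link{binding_scenario}}.
#' @param p Perturbation strength (>= 0); 0 reproduces the baseline.
#' @param biases Optional list (one element per sample) of
#'   \code{\link{bias_spec}} objects or \code{NULL}s.
#' @param seed Integer seed.
#' @param groups Optional explicit \code{"A"}/\code{"B"} assignment per
#'   sample.
#' @return List with \code{samples} (list of perturbed \code{FragmentSet}s),
#'   \code{groups}, and \code{truth}: a manifest recording the scenario,
#'   strength, seed, per-peak log2 fold-changes, fractions, downsampled
#'   group, and the number of perturbed fragments.
#' @export
simulate_two_group_dataset <- function(baseline, chip_peaks, scenario,
                                       p, biases = NULL, seed,
                                       groups = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(length(baseline) >= 2)
  .validate_peaks(chip_peaks)
  if (is.null(chip_peaks$score)) {
    stop("chip_peaks must carry enrichment scores in the 'score' column")
  }
  ns <- length(baseline)
  if (is.null(groups)) {
    groups <- rep(c("A", "B"), c(ceiling(ns / 2), floor(ns / 2)))
  }
  stopifnot(length(groups) == ns, all(groups %in% c("A", "B")))
  log2fc <- quantile_match_fold_changes(chip_peaks$score, scenario)
  eff <- effective_fraction(log2fc, p)
  samples <- vector("list", ns)
  n_perturbed <- 0L
  for (j in seq_len(ns)) {
    fr <- baseline[[j]]
    # only peaks whose downsampled group matches this sample shrink here
    frac_j <- ifelse(eff$group == groups[j], eff$fraction, 1)
    fr <- downsample_fragments(fr, chip_peaks, frac_j, seed = seed + j)
    ret <- attr(fr, "retained")
    if (!is.null(ret)) n_perturbed <- n_perturbed + sum(ret$n0 - ret$ns)
    if (!is.null(biases) && !is.null(biases[[j]])) {
      fr <- apply_composition_bias(fr, biases[[j]], seed = seed + 1000L + j)
    }
    samples[[j]] <- fr
  }
  truth <- list(scenario = attr(scenario, "name"), strength = p,
                seed = seed, groups = groups,
                peaks = data.frame(chip_peaks[, c("chrom", "start", "end")],
                                   enrichment = chip_peaks$score,
                                   log2fc = log2fc,
                                   fraction = eff$fraction,
                                   group_downsampled = eff$group),
                n_fragments_removed = n_perturbed,
                zero_perturbed = n_perturbed == 0L)
  list(samples = samples, groups = groups, truth = truth)
}
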