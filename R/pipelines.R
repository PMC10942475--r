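# End-to-end convenience pipelines combining the activity scores with the
# moderated group comparison, as recommended: background-corrected motif
# z-scores with quantile normalization, and the GC-aware multivariate
# regression route.

#' Peak count matrix of a fixture bundle
#'
#' @param bundle A \code{\link{generate_fixture}} bundle.
#' @param which \code{"perturbed"} (default) or \code{"baseline"}
#'   fragments.
#' @return Peaks x samples count matrix.
#' @export
fixture_counts <- function(bundle, which = c("perturbed", "baseline")) {
  which <- match.arg(which)
  frs <- if (which == "perturbed") bundle$fragments else
    bundle$baseline_fragments
  count_overlaps(frs, bundle$peaks)
}

#' Motif z-score pipeline with moderated group comparison
#'
#' Computes library-size expected counts, GC/accessibility-matched
#' background peak sets, bias-corrected motif deviations and z-scores,
#' normalizes the z-scores across samples (quantile normalization by
#' default) and performs the moderated two-group comparison, returning
#' per-motif results ranked by p-value then absolute effect.
#'
#' @param counts Peaks x samples count matrix.
#' @param gc Per-peak GC fractions.
#' @param matches Peaks x motifs indicator matrix.
#' @param groups Two-level group labels per sample.
#' @param niter Background iterations (default 2000; tests and
#'   simulations use fewer, see the vignette).
#' @param seed Integer seed for background sampling.
#' @param normalize Normalization for the z-score matrix
#'   (default \code{"quantile"}).
#' @return Ranked per-motif data frame (see \code{\link{rank_results}});
#'   attribute \code{activity} holds the normalized z-score matrix.
#' @export
chromvar_pipeline <- function(counts, gc, matches, groups,
                              niter = 2000L, seed,
                              normalize = "quantile") {
  e <- expected_counts(counts)
  bg <- select_background_peaks(gc, log1p(rowMeans(counts)),
                                niter = niter, seed = seed)
  dev <- motif_deviations(counts, e, matches, bg)
  z <- normalize_activity(dev$z, normalize)
  fit <- moderated_t_test(z, groups)
  out <- rank_results(fit)
  attr(out, "activity") <- z
  out
}

#' GC smooth-quantile + multivariate regression pipeline
#'
#' Log-CPM transforms the counts, applies smooth quantile normalization
#' within GC bins, fits the per-sample multivariate motif model, and runs
#' the moderated two-group comparison on the per-motif t-values.
#'
#' @inheritParams chromvar_pipeline
#' @param nbins Number of GC bins (default 10).
#' @return Ranked per-motif data frame; attribute \code{activity} holds
#'   the motif x sample t-value matrix.
#' @export
mlm_pipeline <- function(counts, gc, matches, groups, nbins = 10L) {
  norm <- gc_smooth_quantile_normalize(log_cpm(counts), gc, groups,
                                       nbins = nbins)
  act <- mlm_sample_activities(norm, matches)
  ok <- !apply(is.na(act), 1, any)
  fit <- moderated_t_test(act[ok, , drop = FALSE], groups)
  out <- rank_results(fit)
  attr(out, "activity") <- act
  out
}
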