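# Peaks are plain data frames with BED-style 0-based half-open coordinates
# (columns chrom/start/end plus optional gc, score). IRanges/GenomicRanges
# do the interval arithmetic internally (converted to 1-based closed).

.as_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

.validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) > 0 && any(peaks$start >= peaks$end)) {
    stop("peaks must satisfy start < end")
  }
  peaks
}

#' Merge peak sets and resize to a fixed width
#'
#' Consensus peaks are obtained by union-merging overlapping or adjacent
#' intervals across all input peak sets, then resizing each merged interval
#' to a common width anchored at its midpoint: with \code{mid =
#' floor((start + end) / 2)}, the resized interval is
#' \code{[mid - floor(width/2), mid - floor(width/2) + width)}. Resized peaks
#' that newly overlap are deliberately not re-merged (fixed-width
#' convention). Resized intervals are clipped at 0 and, when
#' \code{chrom_lengths} is supplied, at the contig end.
#'
#' @param peak_sets A single peak data frame or a list of them
#'   (chrom/start/end, BED coordinates).
#' @param width Target peak width in bp (default 300).
#' @param chrom_lengths Optional named vector of contig lengths for clipping.
#' @return A peak data frame of merged, resized peaks sorted by coordinate.
#' @export
resize_and_merge_peaks <- function(peak_sets, width = 300L,
                                   chrom_lengths = NULL) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (length(peak_sets) == 0) stop("no peak sets supplied")
  stopifnot(width > 0)
  all_peaks <- do.call(rbind, lapply(peak_sets, function(p) {
    .validate_peaks(p)[, c("chrom", "start", "end")]
  }))
  if (nrow(all_peaks) == 0) stop("no peaks in input")
  merged <- GenomicRanges::reduce(.as_gr(all_peaks))
  ms <- GenomicRanges::start(merged) - 1L  # back to BED
  me <- GenomicRanges::end(merged)
  mid <- (ms + me) %/% 2L
  new_start <- mid - width %/% 2L
  new_end <- new_start + as.integer(width)
  new_start <- pmax(new_start, 0L)
  chrom <- as.character(GenomicRanges::seqnames(merged))
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[chrom])
    new_end <- ifelse(is.na(lim), new_end, pmin(new_end, lim))
  }
  out <- data.frame(chrom = chrom, start = new_start, end = new_end,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count fragments overlapping peaks
#'
#' Builds the peaks x samples count matrix: entry (i, j) is the number of
#' fragments of sample j overlapping peak i by at least 1 bp (weights
#' counted as multiplicities). A fragment overlapping k peaks increments each
#' of the k counts. Chromosomes present in fragments but absent from the
#' peak set contribute nothing.
#'
#' @param fragments A \code{FragmentSet} or list of them (one per sample).
#' @param peaks Peak data frame (BED coordinates).
#' @return Integer matrix peaks x samples; column names are sample ids,
#'   row names \code{chrom:start-end}.
#' @export
count_overlaps <- function(fragments, peaks) {
  if (inherits(fragments, "FragmentSet")) fragments <- list(fragments)
  .validate_peaks(peaks)
  pk_gr <- .as_gr(peaks)
  counts <- matrix(0L, nrow = nrow(peaks), ncol = length(fragments))
  colnames(counts) <- vapply(fragments, sample_id, "")
  rownames(counts) <- peak_names(peaks)
  for (j in seq_along(fragments)) {
    fr <- fragments[[j]]
    if (nrow(fr) == 0) next
    hits <- GenomicRanges::findOverlaps(.as_gr(fr), pk_gr)
    if (length(hits) == 0) next
    w <- fr$weight[S4Vectors::queryHits(hits)]
    agg <- rowsum(w, S4Vectors::subjectHits(hits))
    counts[as.integer(rownames(agg)), j] <- as.integer(agg[, 1])
  }
  counts
}

#' Canonical peak names
#' @param peaks Peak data frame.
#' @return Character vector \code{chrom:start-end}.
#' @export
peak_names <- function(peaks) {
  sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
}

#' Read a BED3+ peak file
#'
#' @param path BED file; column 4 (name) is ignored, column 5 is kept as
#'   \code{score} when present.
#' @return Peak data frame (chrom/start/end and optional score).
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 5) out$score <- as.numeric(df[[5]])
  .validate_peaks(out)
}

#' Write peaks as BED
#'
#' @param peaks Peak data frame; an optional \code{score} column is written
#'   to BED column 5 (with peak names in column 4).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  .validate_peaks(peaks)
  df <- data.frame(peaks$chrom, peaks$start, peaks$end)
  if (!is.null(peaks$score)) {
    df$name <- peak_names(peaks)
    df$score <- peaks$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a count matrix as TSV (peaks as rows with coordinates)
#' @param counts Matrix peaks x samples.
#' @param peaks Matching peak data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_counts_tsv <- function(counts, peaks, path) {
  stopifnot(nrow(counts) == nrow(peaks))
  df <- cbind(peaks[, c("chrom", "start", "end")], as.data.frame(counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV written by \code{write_counts_tsv}
#' @param path Input path.
#' @return List with \code{peaks} (data frame) and \code{counts} (matrix).
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  peaks <- df[, c("chrom", "start", "end")]
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(counts) <- peak_names(peaks)
  list(peaks = peaks, counts = counts)
}

#' Write a sparse matrix as MatrixMarket with name sidecars
#'
#' Writes \code{<path>} in MTX format plus \code{<path>.rownames} and
#' \code{<path>.colnames} (one name per line).
#'
#' @param m Matrix (dense or sparse) with dimnames.
#' @param path Output path (conventionally \code{.mtx}).
#' @return \code{path}, invisibly.
#' @export
write_matrix_mtx <- function(m, path) {
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "dMatrix")
  sm <- methods::as(methods::as(sm, "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sm, path)
  writeLines(rownames(m), paste0(path, ".rownames"))
  writeLines(colnames(m), paste0(path, ".colnames"))
  invisible(path)
}

#' Read a MatrixMarket matrix with name sidecars
#' @param path Path written by \code{\link{write_matrix_mtx}}.
#' @return A sparse \code{Matrix} with dimnames restored.
#' @export
read_matrix_mtx <- function(path) {
  m <- Matrix::readMM(path)
  # pattern/logical MTX (written for indicator matrices) -> numeric 0/1
  m <- methods::as(1 * m, "CsparseMatrix")
  rn <- paste0(path, ".rownames")
  cn <- paste0(path, ".colnames")
  if (file.exists(rn)) rownames(m) <- readLines(rn)
  if (file.exists(cn)) colnames(m) <- readLines(cn)
  m
}
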