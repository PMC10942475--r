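#' Construct a FragmentSet
#'
#' A FragmentSet holds the sequenced fragments of one ATAC-seq sample as
#' BED-style intervals (0-based, half-open). Each fragment corresponds to a
#' pair of Tn5 insertion events; an integer \code{weight} carries duplicate
#' multiplicities when a fragment file provides a count column.
#'
#' @param chrom Character vector of contig names.
#' @param start,end Integer vectors; 0-based half-open coordinates with
#'   \code{start < end}.
#' @param weight Integer multiplicities (recycled), default 1.
#' @param sample_id Sample identifier string.
#' @param gc Optional numeric vector of per-fragment GC fractions in
#'   \eqn{[0,1]}; used by composition-bias resampling on synthetic data where
#'   fragment sequence is not materialized.
#' @return An object of class \code{FragmentSet}: a data frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{weight} (and \code{gc} when
#'   supplied), plus a \code{sample_id} attribute.
#' @export
fragment_set <- function(chrom = character(), start = integer(),
                         end = integer(), weight = 1L,
                         sample_id = "sample", gc = NULL) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  start <- as.integer(start)
  end <- as.integer(end)
  if (n > 0 && any(start < 0 | start >= end)) {
    stop("fragments must satisfy 0 <= start < end")
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   weight = as.integer(rep_len(weight, n)),
                   stringsAsFactors = FALSE)
  if (!is.null(gc)) {
    stopifnot(length(gc) == n)
    if (n > 0 && any(gc < 0 | gc > 1)) stop("gc fractions must lie in [0,1]")
    df$gc <- as.numeric(gc)
  }
  structure(df, sample_id = sample_id,
            class = c("FragmentSet", "data.frame"))
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet '%s': %d fragments (%d events incl. weights)\n",
              sample_id(x), nrow(x), sum(x$weight)))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Sample identifier of a FragmentSet
#' @param x A \code{FragmentSet}.
#' @return The sample id string.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' Fragment lengths in bp
#' @param frags A \code{FragmentSet}.
#' @return Integer vector \code{end - start}.
#' @export
fragment_lengths <- function(frags) frags$end - frags$start

.fragment_subset <- function(frags, idx) {
  out <- as.data.frame(frags)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sample_id = sample_id(frags),
            class = c("FragmentSet", "data.frame"))
}

#' Read an ATAC fragment file
#'
#' Parses a (optionally gzip-compressed) tab-separated fragment file with
#' columns chrom, start, end and optional 4th (sample/barcode) and 5th
#' (duplicate count) columns. Coordinates are taken as 0-based half-open,
#' 10x-style, i.e. already Tn5-shifted.
#'
#' Records with \code{start >= end} are rejected; the number of rejects is
#' reported via \code{message()} and stored in the \code{n_rejected}
#' attribute. A malformed line (fewer than 3 fields, or non-numeric
#' coordinates) aborts with its line number.
#'
#' @param path Path to the fragment file.
#' @param sample_id Sample to extract when a 4th column is present; when the
#'   file has no sample column all fragments are returned under this id
#'   (default: file base name).
#' @param expand_counts If \code{TRUE}, a 5th duplicate-count column is
#'   expanded into that many identical fragments; otherwise counts are carried
#'   as integer weights.
#' @return A \code{\link{fragment_set}}.
#' @export
read_fragments <- function(path, sample_id = NULL, expand_counts = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  default_id <- if (is.null(sample_id)) {
    sub("\\.(tsv|bed|txt)(\\.gz)?$", "", basename(path))
  } else {
    sample_id
  }
  if (length(lines) == 0) {
    return(fragment_set(sample_id = default_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed fragment record (fewer than 3 fields) at line ",
         which(nf < 3)[1])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed fragment coordinates at line ", bad[1])
  }
  samp <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  wt <- if (all(nf >= 5)) {
    w <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    if (anyNA(w)) stop("malformed count column at line ", which(is.na(w))[1])
    w
  } else {
    rep(1L, length(chrom))
  }
  if (!is.null(samp) && !is.null(sample_id)) {
    keep <- samp == sample_id
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    wt <- wt[keep]
  }
  ok <- start >= 0 & start < end
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(n_rejected, " fragment record(s) with start >= end rejected")
  }
  chrom <- chrom[ok]; start <- start[ok]; end <- end[ok]; wt <- wt[ok]
  if (expand_counts && length(wt) > 0 && any(wt > 1)) {
    idx <- rep.int(seq_along(wt), wt)
    chrom <- chrom[idx]; start <- start[idx]; end <- end[idx]
    wt <- rep(1L, length(idx))
  }
  out <- fragment_set(chrom, start, end, wt, sample_id = default_id)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a FragmentSet as a fragments TSV
#'
#' Emits chrom, start, end, sample, count columns (BED-style coordinates),
#' the format \code{\link{read_fragments}} consumes.
#'
#' @param frags A \code{FragmentSet}.
#' @param path Output path; \code{.gz} suffix triggers gzip compression.
#' @return \code{path}, invisibly.
#' @export
write_fragments <- function(frags, path) {
  df <- data.frame(frags$chrom, frags$start, frags$end,
                   rep(sample_id(frags), nrow(frags)), frags$weight)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Classify or filter fragments by length
#'
#' \code{mode = "length_class"} assigns each fragment to one of the four
#' nucleosome-occupancy classes by fixed length thresholds
#' (0,120] = \code{NF}, (120,300] = \code{mono}, (300,500] = \code{di},
#' (500,Inf) = \code{multi}. \code{mode = "nucleosome_free"} returns the
#' subset of fragments with lengths in [30, 120] bp, the nucleosome-free
#' filtering rule.
#'
#' @param frags A \code{FragmentSet}.
#' @param mode \code{"length_class"} or \code{"nucleosome_free"}.
#' @return A factor of class labels, or a filtered \code{FragmentSet}.
#' @export
classify_fragments <- function(frags,
                               mode = c("length_class", "nucleosome_free")) {
  mode <- match.arg(mode)
  len <- fragment_lengths(frags)
  if (mode == "length_class") {
    cls <- cut(len, breaks = c(0, 120, 300, 500, Inf),
               labels = c("NF", "mono", "di", "multi"), right = TRUE)
    return(cls)
  }
  .fragment_subset(frags, which(len >= 30 & len <= 120))
}

#' Tn5 insertion events of a fragment set
#'
#' Each fragment marks two transposition events: one at each end. With
#' pre-shifted (10x-style) fragment files the default shifts of (0, 0) are
#' appropriate; for unshifted files the +4/-5 convention can be requested.
#' The two 0-based insertion points of a fragment \code{[start, end)} are
#' \code{start + shift_plus} and \code{end - 1 - shift_minus}.
#'
#' @param frags A \code{FragmentSet}.
#' @param shift_plus,shift_minus Integer shifts applied to the left and right
#'   fragment ends, default 0.
#' @return A data frame with columns \code{chrom}, \code{pos} (0-based
#'   insertion point) and \code{weight}; positions shifted below 0 are dropped
#'   (count reported via \code{message()} and the \code{n_dropped} attribute).
#' @export
tn5_insertions <- function(frags, shift_plus = 0L, shift_minus = 0L) {
  n <- nrow(frags)
  pos <- c(frags$start + as.integer(shift_plus),
           frags$end - 1L - as.integer(shift_minus))
  out <- data.frame(chrom = rep(frags$chrom, 2L), pos = pos,
                    weight = rep(frags$weight, 2L),
                    stringsAsFactors = FALSE)
  neg <- out$pos < 0
  n_dropped <- sum(neg)
  if (n_dropped > 0) {
    message(n_dropped, " shifted insertion position(s) < 0 dropped")
    out <- out[!neg, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped") <- n_dropped
  out
}
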