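#' Read motif position probability matrices
#'
#' Supports JASPAR raw-count/probability text (\code{>id name} header
#' followed by four \code{A [ ... ]} style rows) and MEME minimal format.
#' Columns are normalized to probabilities; an all-zero column becomes the
#' uniform distribution (0.25 each) with a warning.
#'
#' @param path Motif file path.
#' @param format \code{"jaspar"} or \code{"meme"}.
#' @return A named list of \code{MotifPPM} objects: each a list with
#'   \code{id} and \code{mat}, a 4 x L probability matrix with rows
#'   A, C, G, T (columns sum to 1).
#' @export
read_ppm <- function(path, format = c("jaspar", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "jaspar") .parse_jaspar(lines) else .parse_meme(lines)
}

.normalize_ppm <- function(mat, id) {
  if (nrow(mat) != 4) stop("motif '", id, "': matrix must have 4 rows")
  cs <- colSums(mat)
  zero <- cs == 0
  if (any(zero)) {
    warning("motif '", id, "': ", sum(zero),
            " all-zero column(s) set to uniform probabilities")
    mat[, zero] <- 0.25
    cs[zero] <- 1
  }
  mat <- sweep(mat, 2, cs, "/")
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  mat
}

.parse_jaspar <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no JASPAR motif headers ('>') found")
  bounds <- c(headers, length(lines) + 1L)
  motifs <- list()
  for (i in seq_along(headers)) {
    id <- strsplit(sub("^>\\s*", "", lines[headers[i]]), "\\s+")[[1]][1]
    block <- lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4) {
      stop("motif '", id, "': expected 4 base rows, found ", length(block))
    }
    rows <- lapply(block, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
      ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("motif '", id, "': rows have unequal lengths")
    }
    mat <- do.call(rbind, rows)
    motifs[[id]] <- list(id = id, mat = .normalize_ppm(mat, id))
  }
  motifs
}

.parse_meme <- function(lines) {
  motif_idx <- grep("^MOTIF\\b", lines)
  if (length(motif_idx) == 0) stop("no MEME 'MOTIF' records found")
  motifs <- list()
  for (i in seq_along(motif_idx)) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[motif_idx[i]])),
                   "\\s+")[[1]][1]
    lp <- grep("^letter-probability matrix", lines)
    lp <- lp[lp > motif_idx[i]][1]
    if (is.na(lp)) stop("motif '", id, "': missing letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp]))
    block <- lines[(lp + 1L):(lp + w)]
    mat <- t(vapply(block, function(ln) {
      v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
      if (length(v) != 4) stop("motif '", id, "': alphabet length != 4")
      v
    }, numeric(4)))
    motifs[[id]] <- list(id = id, mat = .normalize_ppm(t(mat), id))
  }
  motifs
}

#' Write motifs in JASPAR text format
#'
#' @param ppms List of \code{MotifPPM} objects (as from \code{\link{read_ppm}}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ppm_jaspar <- function(ppms, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (m in ppms) {
    writeLines(paste0(">", m$id), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(m$mat[b, ], digits = 6),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
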