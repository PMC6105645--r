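#' Genomic intervals
#'
#' All coordinates in this package are 0-based, half-open (`[start, end)`),
#' matching BED/bedGraph/narrowPeak on disk. 1-based coordinates appear only
#' in human-readable reports.
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open bounds; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param name free-text label per interval.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`.
#' @export
gintervals <- function(chrom, start, end, strand = ".", name = ".") {
  n <- length(start)
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  validate_gintervals(x)
  x
}

#' @noRd
validate_gintervals <- function(x) {
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop_ftc("interval coordinates must be integers")
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad)) {
    stop_ftc("invalid interval at row %d: start=%s end=%s (need 0 <= start < end)",
             bad[1], x$start[bad[1]], x$end[bad[1]])
  }
  if (!all(x$strand %in% c("+", "-", "."))) {
    stop_ftc("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

#' Read a BED file (3 or 6 columns)
#'
#' BED is already 0-based half-open, so coordinates are taken verbatim.
#'
#' @param path BED file path.
#' @return An interval `data.frame` as from [gintervals()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_ftc("no such file: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(gintervals(character(), integer(), integer()))
  }
  if (ncol(dt) < 3) stop_ftc("BED needs >= 3 columns: %s", path)
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  if (any(is.na(start)) || any(is.na(end)) ||
      !is_wholenumber(start) || !is_wholenumber(end)) {
    stop_ftc("non-integer coordinates in BED: %s", path)
  }
  gintervals(
    chrom = dt[[1]], start = start, end = end,
    strand = if (ncol(dt) >= 6) dt[[6]] else ".",
    name = if (ncol(dt) >= 4) as.character(dt[[4]]) else "."
  )
}

#' Write intervals as 6-column BED
#'
#' @param x interval `data.frame`.
#' @param path output path.
#' @param score numeric vector for column 5 (default 0).
#' @export
write_bed <- function(x, path, score = 0) {
  validate_gintervals(x)
  out <- data.table::data.table(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$name, score = rep_len(score, nrow(x)), strand = x$strand
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated, no header, columns: gene_id, chrom, strand (+/-), tss
#' (0-based position of the first transcribed base).
#'
#' @param path file path.
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop_ftc("no such file: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1:3))
  if (ncol(dt) < 4) stop_ftc("TSS table needs 4 columns: %s", path)
  tss <- suppressWarnings(as.numeric(dt[[4]]))
  if (any(is.na(tss)) || !is_wholenumber(tss) || any(tss < 0)) {
    stop_ftc("non-integer or negative TSS position in %s", path)
  }
  if (!all(dt[[3]] %in% c("+", "-"))) {
    stop_ftc("TSS strand must be '+' or '-' in %s", path)
  }
  data.frame(gene_id = dt[[1]], chrom = dt[[2]], strand = dt[[3]],
             tss = as.integer(tss), stringsAsFactors = FALSE)
}

#' Write a TSS table (inverse of [read_tss_table()])
#' @param tss `data.frame` with `gene_id`, `chrom`, `strand`, `tss`.
#' @param path output path.
#' @export
write_tss_table <- function(tss, path) {
  data.table::fwrite(tss[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file (name, length)
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  sizes <- as.integer(dt[[2]])
  if (any(is.na(sizes)) || any(sizes <= 0)) {
    stop_ftc("chromosome lengths must be positive integers: %s", path)
  }
  stats::setNames(sizes, dt[[1]])
}

#' Overlap pairs between two interval sets (>= 1 bp)
#'
#' @param query,subject interval `data.frame`s.
#' @return two-column integer `data.frame` (`query`, `subject`) of row
#'   indices of overlapping pairs.
#' @export
interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query = integer(), subject = integer()))
  }
  res <- list()
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    # convert 0-based half-open to IRanges 1-based closed
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    res[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                            subject = si[S4Vectors::subjectHits(hits)])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(query = integer(), subject = integer())
  else out[order(out$query, out$subject), , drop = FALSE]
}
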