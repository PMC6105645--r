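#' Peak tables and ENCODE narrowPeak I/O
#'
#' Peaks are data.frames with columns `chrom`, `start`, `end`, `name`,
#' `score`, `strand`, `fold_enrichment`, `neg_log10_p`, `neg_log10_q`,
#' `summit_offset` — the ten columns of ENCODE narrowPeak (BED6+4), with
#' the summit stored as an offset from `start`.
#'
#' @param chrom,start,end,strand interval fields (0-based half-open).
#' @param name peak label.
#' @param score integer display score (0-1000).
#' @param fold_enrichment observed/expected ratio at the summit window.
#' @param neg_log10_p,neg_log10_q -log10 of the Poisson p-value and BH
#'   q-value.
#' @param summit_offset summit position relative to `start`,
#'   `0 <= summit_offset < end - start`.
#' @return peak `data.frame`.
#' @export
peaks_df <- function(chrom, start, end, name, score = 0L, strand = ".",
                     fold_enrichment = 0, neg_log10_p = 0, neg_log10_q = 0,
                     summit_offset = 0L) {
  n <- length(chrom)
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), name = as.character(name),
                  score = rep_len(as.integer(score), n),
                  strand = rep_len(as.character(strand), n),
                  fold_enrichment = rep_len(as.numeric(fold_enrichment), n),
                  neg_log10_p = rep_len(as.numeric(neg_log10_p), n),
                  neg_log10_q = rep_len(as.numeric(neg_log10_q), n),
                  summit_offset = rep_len(as.integer(summit_offset), n),
                  stringsAsFactors = FALSE)
  validate_peaks(x)
  x
}

#' @noRd
validate_peaks <- function(x) {
  validate_gintervals(x[, c("chrom", "start", "end", "strand", "name")])
  bad <- which(x$summit_offset < 0 | x$summit_offset >= x$end - x$start)
  if (length(bad)) {
    stop_ftc("peak %s: summit_offset %d outside [0, width)",
             x$name[bad[1]], x$summit_offset[bad[1]])
  }
  if (any(x$fold_enrichment < 0) || any(x$neg_log10_p < 0) ||
      any(x$neg_log10_q < 0)) {
    stop_ftc("narrowPeak statistics must be >= 0")
  }
  invisible(x)
}

#' Write peaks in ENCODE narrowPeak format
#' @param peaks peak `data.frame` (see [peaks_df()]).
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  num <- function(v) formatC(v, digits = 17, format = "g")
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, peaks$strand, num(peaks$fold_enrichment),
                   num(peaks$neg_log10_p), num(peaks$neg_log10_q),
                   peaks$summit_offset)
  writeLines(lines, path)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#' @param path narrowPeak path.
#' @return peak `data.frame`.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop_ftc("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(peaks_df(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 10)) {
    stop_ftc("narrowPeak line %d has %d columns, expected 10",
             which(ncols != 10)[1], ncols[ncols != 10][1])
  }
  m <- do.call(rbind, fields)
  peaks_df(chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
           name = m[, 4], score = as.integer(m[, 5]), strand = m[, 6],
           fold_enrichment = as.numeric(m[, 7]),
           neg_log10_p = as.numeric(m[, 8]), neg_log10_q = as.numeric(m[, 9]),
           summit_offset = as.integer(m[, 10]))
}
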