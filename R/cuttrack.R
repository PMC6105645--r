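#' Cut-count tracks
#'
#' A cut track holds, per chromosome, a dense non-negative integer vector of
#' transposase insertion (cut) counts, strand-pooled. It stands in for the
#' processed alignment data the footprinting pipeline consumes.
#'
#' @param counts named list of non-negative integer vectors, one per
#'   chromosome.
#' @param sizes named integer vector of chromosome lengths; defaults to the
#'   vector lengths of `counts`.
#' @return an object of class `cut_track`.
#' @export
cut_track <- function(counts, sizes = NULL) {
  if (is.null(sizes)) sizes <- vapply(counts, length, numeric(1))
  sizes <- stats::setNames(as.integer(sizes), names(counts))
  for (ch in names(counts)) {
    v <- counts[[ch]]
    if (any(v < 0)) stop_ftc("negative cut counts on %s", ch)
    if (length(v) != sizes[[ch]]) {
      stop_ftc("%s: vector length %d != declared length %d",
               ch, length(v), sizes[[ch]])
    }
    counts[[ch]] <- as.numeric(v)
  }
  structure(list(counts = counts, sizes = sizes), class = "cut_track")
}

#' @export
print.cut_track <- function(x, ...) {
  cat(sprintf("<cut_track> %d chromosome(s), %.0f total cuts\n",
              length(x$counts), sum(vapply(x$counts, sum, numeric(1)))))
  invisible(x)
}

#' Read a bedGraph file into a dense cut track
#'
#' Positions absent from the file are 0. Intervals must be non-overlapping
#' per chromosome, carry non-negative integer values, and lie within the
#' declared chromosome lengths.
#'
#' @param path bedGraph path.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return a `cut_track`.
#' @export
read_cut_track <- function(path, chrom_sizes) {
  if (!file.exists(path)) stop_ftc("no such file: %s", path)
  counts <- lapply(chrom_sizes, function(n) numeric(n))
  names(counts) <- names(chrom_sizes)
  info <- file.info(path)
  if (info$size > 0) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (nrow(dt) > 0) {
      if (ncol(dt) < 4) stop_ftc("bedGraph needs 4 columns: %s", path)
      val <- as.numeric(dt[[4]])
      if (any(val < 0) || !is_wholenumber(val)) {
        stop_ftc("bedGraph values must be non-negative integers: %s", path)
      }
      for (ch in unique(dt[[1]])) {
        if (!ch %in% names(chrom_sizes)) {
          stop_ftc("bedGraph chromosome '%s' absent from chrom sizes", ch)
        }
        sel <- dt[[1]] == ch
        s <- dt[[2]][sel]; e <- dt[[3]][sel]; v <- val[sel]
        if (any(s < 0) || any(e > chrom_sizes[[ch]]) || any(s >= e)) {
          stop_ftc("bedGraph interval out of bounds on %s", ch)
        }
        o <- order(s)
        if (any(s[o][-1] < e[o][-length(e)])) {
          stop_ftc("overlapping bedGraph intervals on %s", ch)
        }
        len <- e - s
        pos <- sequence(len) + rep(s, len)   # 1-based indices into the vector
        counts[[ch]][pos] <- rep(v, len)
      }
    }
  }
  cut_track(counts, chrom_sizes)
}

#' Write a cut track as bedGraph
#'
#' Zero runs are omitted; constant nonzero runs are collapsed into single
#' intervals, so `read_cut_track(write_cut_track(x))` is the identity.
#'
#' @param track a `cut_track`.
#' @param path output path.
#' @export
write_cut_track <- function(track, path) {
  pieces <- list()
  for (ch in names(track$counts)) {
    r <- rle(track$counts[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      pieces[[ch]] <- data.table::data.table(
        chrom = ch, start = starts[keep], end = ends[keep],
        value = r$values[keep])
    }
  }
  if (length(pieces)) {
    data.table::fwrite(data.table::rbindlist(pieces), path, sep = "\t",
                       col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}
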