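#' Position weight matrices
#'
#' A PWM is stored as a list with a 4 x W probability matrix (rows A, C, G,
#' T; columns are motif positions), a background base distribution, and the
#' TF name. Every column sums to 1 and every entry is strictly positive
#' (guaranteed by the pseudocount or probability floor applied on read).
#'
#' @param tf_name transcription factor name.
#' @param probs 4 x W numeric matrix of per-position base probabilities,
#'   rows in A, C, G, T order.
#' @param background length-4 base background, sums to 1 (default uniform).
#' @return an object of class `pwm`.
#' @export
new_pwm <- function(tf_name, probs, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop_ftc("PWM '%s': probs must have 4 rows", tf_name)
  if (ncol(probs) < 1) stop_ftc("PWM '%s': width must be >= 1", tf_name)
  if (any(probs <= 0)) stop_ftc("PWM '%s': probabilities must be > 0", tf_name)
  csums <- colSums(probs)
  if (any(abs(csums - 1) > 1e-6)) {
    stop_ftc("PWM '%s': column %d sums to %.8f, not 1",
             tf_name, which.max(abs(csums - 1)), csums[which.max(abs(csums - 1))])
  }
  if (!is_prob_vector(background)) stop_ftc("PWM '%s': bad background", tf_name)
  rownames(probs) <- DNA_BASES
  structure(list(tf_name = tf_name, width = ncol(probs), probs = probs,
                 background = stats::setNames(as.numeric(background), DNA_BASES)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, IC %.2f bits\n", x$tf_name, x$width,
              information_content(x)$total))
  print(round(x$probs, 3))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-probability base per column,
#' alphabetical tie-break).
#' @param pwm a `pwm` object.
#' @return character consensus string.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM.
#' @param pwm a `pwm` object.
#' @return a `pwm` scoring the reverse-complement motif.
#' @export
pwm_revcomp <- function(pwm) {
  rc <- pwm$probs[c("T", "G", "C", "A"), rev(seq_len(pwm$width)), drop = FALSE]
  new_pwm(pwm$tf_name, rc, pwm$background[c("T", "G", "C", "A")])
}

#' Read PWMs from JASPAR or Cis-BP text
#'
#' JASPAR records are count matrices (`>id name` header, then four
#' `A [ ... ]` base rows); counts are converted to probabilities with a
#' uniform Laplace pseudocount of 0.25 per base. Cis-BP records are
#' probability matrices (positions as rows, bases as columns under a
#' `Pos A C G T` header); probabilities are floored at 1e-4 and
#' renormalized.
#'
#' @param path file path.
#' @param dialect `"jaspar"` or `"cisbp"`.
#' @param pseudocount per-base pseudocount added to JASPAR counts.
#' @param background length-4 background distribution for all records.
#' @return named list of `pwm` objects.
#' @export
read_pwms <- function(path, dialect = c("jaspar", "cisbp"),
                      pseudocount = 0.25, background = rep(0.25, 4)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_ftc("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "jaspar") {
    parse_jaspar(lines, pseudocount, background)
  } else {
    parse_cisbp(lines, background)
  }
}

#' @noRd
parse_jaspar <- function(lines, pseudocount, background) {
  heads <- grep("^>", lines)
  if (!length(heads)) stop_ftc("no JASPAR records found ('>' headers)")
  bounds <- c(heads, length(lines) + 1L)
  pwms <- list()
  for (i in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    name <- if (length(toks) >= 2) toks[2] else toks[1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4) {
      stop_ftc("record '%s': expected 4 base rows, found %d", name, length(body))
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (any(is.na(v))) stop_ftc("record '%s': non-numeric counts", name)
      v
    })
    w <- unique(vapply(rows, length, integer(1)))
    if (length(w) != 1) stop_ftc("record '%s': unequal row lengths", name)
    counts <- do.call(rbind, rows)
    if (any(counts < 0)) stop_ftc("record '%s': negative counts", name)
    probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
    pwms[[name]] <- new_pwm(name, probs, background)
  }
  pwms
}

#' @noRd
parse_cisbp <- function(lines, background, floor = 1e-4) {
  # records start at an optional ">name" or at a "Pos A C G T" header
  starts <- grep("^(>|Pos\\b)", lines)
  if (!length(starts)) stop_ftc("no Cis-BP records found")
  pwms <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    name <- NULL
    if (grepl("^>", lines[i])) {
      name <- sub("^>\\s*", "", lines[i])
      i <- i + 1L
    }
    if (i > length(lines) || !grepl("^Pos\\b", lines[i])) {
      stop_ftc("Cis-BP record '%s': missing 'Pos A C G T' header", name %||% "?")
    }
    i <- i + 1L
    rows <- list()
    while (i <= length(lines) && !grepl("^(>|Pos\\b)", lines[i])) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(v) != 5 || any(is.na(v))) {
        stop_ftc("Cis-BP record '%s': malformed row '%s'", name %||% "?", lines[i])
      }
      rows[[length(rows) + 1L]] <- v[2:5]
      i <- i + 1L
    }
    if (!length(rows)) stop_ftc("Cis-BP record '%s': empty matrix", name %||% "?")
    k <- k + 1L
    name <- name %||% sprintf("cisbp_%d", k)
    probs <- t(do.call(rbind, rows))     # positions as rows on disk
    if (any(probs < 0)) stop_ftc("Cis-BP record '%s': negative probabilities", name)
    probs <- pmax(probs, floor)
    probs <- sweep(probs, 2, colSums(probs), "/")
    pwms[[name]] <- new_pwm(name, probs, background)
  }
  pwms
}

#' Write PWMs as JASPAR PFM text
#'
#' Probabilities are emitted as integer counts out of 100 per column
#' (largest-remainder rounding so columns sum exactly to 100).
#'
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @export
write_jaspar_pfms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    counts <- apply(p$probs, 2, function(col) {
      raw <- col * 100
      fl <- floor(raw)
      rem <- 100 - sum(fl)
      if (rem > 0) {
        ord <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
        fl[ord] <- fl[ord] + 1
      }
      fl
    })
    writeLines(sprintf(">%s %s", p$tf_name, p$tf_name), con)
    for (b in seq_len(4)) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(counts[b, ], collapse = " ")), con)
    }
  }
  invisible(path)
}
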