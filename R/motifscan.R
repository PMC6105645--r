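#' Information content of a PWM
#'
#' Per column c: `sum_b p_bc * log2(p_bc / bg_b)` (Kullback-Leibler
#' divergence from the background, in bits); the total is the motif's
#' specificity and is what the 8-bit profile filter is applied to.
#'
#' @param pwm a `pwm` object.
#' @return list with `per_column` (numeric vector) and `total` (bits).
#' @export
information_content <- function(pwm) {
  per_col <- colSums(pwm$probs * log2(pwm$probs / pwm$background))
  list(per_column = unname(per_col), total = sum(per_col))
}

#' @noRd
pwm_log_odds_matrix <- function(pwm) {
  lo <- log2(pwm$probs / pwm$background)
  rbind(lo, N = 0)                      # N bases contribute 0
}

#' @noRd
pwm_score_range <- function(pwm) {
  lo <- log2(pwm$probs / pwm$background)
  c(min = sum(apply(lo, 2, min)), max = sum(apply(lo, 2, max)))
}

#' Log2-odds score of one sequence under a PWM
#'
#' `-` strand scores the reverse complement of the sequence. `N` bases
#' contribute 0.
#'
#' @param seq DNA string of exactly the PWM width (ACGTN alphabet).
#' @param pwm a `pwm` object.
#' @param strand `"+"` or `"-"`.
#' @return log2-odds score.
#' @export
log_odds <- function(seq, pwm, strand = "+") {
  if (nchar(seq) != pwm$width) {
    stop_ftc("sequence length %d != PWM width %d", nchar(seq), pwm$width)
  }
  if (strand == "-") seq <- revcomp(seq)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c(DNA_BASES, "N"))
  if (any(is.na(idx))) stop_ftc("non-ACGTN base in sequence")
  lo <- pwm_log_odds_matrix(pwm)
  sum(lo[cbind(idx, seq_len(pwm$width))])
}

#' Min-max normalized ("relative") score of one sequence
#' @inheritParams log_odds
#' @return relative score in [0, 1].
#' @export
pwm_rel_score <- function(seq, pwm, strand = "+") {
  r <- pwm_score_range(pwm)
  unname((log_odds(seq, pwm, strand) - r["min"]) / (r["max"] - r["min"]))
}

#' Score every window of a coded sequence against a log-odds matrix.
#' @noRd
score_windows <- function(idx, lo, W) {
  n <- length(idx) - W + 1L
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(W)) sc <- sc + lo[idx[j:(j + n - 1L)], j]
  sc
}

#' Scan regions of a genome for PWM matches on both strands
#'
#' Every window whose min-max relative score reaches `rel_threshold` on
#' either strand is a candidate hit; overlapping same-TF hits are greedily
#' pruned keeping the higher raw score (leftmost, then `+` strand, on
#' ties). Windows containing `N` receive 0 contribution at those positions.
#'
#' @param regions interval `data.frame` to scan.
#' @param genome named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param pwm a `pwm` object.
#' @param rel_threshold relative-score cutoff (oPOSSUM-style "matrix score
#'   threshold"; default 0.90).
#' @return motif-site `data.frame`, sorted by coordinate, with columns
#'   `chrom`, `start`, `end`, `strand`, `tf`, `score`, `rel_score`.
#' @export
scan_pwm <- function(regions, genome, pwm, rel_threshold = 0.90) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  W <- pwm$width
  rng <- pwm_score_range(pwm)
  span <- rng["max"] - rng["min"]
  lo_f <- pwm_log_odds_matrix(pwm)
  lo_r <- pwm_log_odds_matrix(pwm_revcomp(pwm))
  hits <- list()
  for (ri in seq_len(nrow(regions))) {
    ch <- regions$chrom[ri]
    if (!ch %in% names(genome)) stop_ftc("chromosome '%s' not in genome", ch)
    if (regions$start[ri] < 0 || regions$end[ri] > nchar(genome[[ch]])) {
      stop_ftc("region %d outside genome bounds on %s", ri, ch)
    }
    seq <- substr(genome[[ch]], regions$start[ri] + 1L, regions$end[ri])
    idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
                 c(DNA_BASES, "N"))
    if (any(is.na(idx))) stop_ftc("non-ACGTN base in region %d", ri)
    if (length(idx) < W) next
    for (str in c("+", "-")) {
      sc <- score_windows(idx, if (str == "+") lo_f else lo_r, W)
      rel <- (sc - rng["min"]) / span
      keep <- which(rel >= rel_threshold)
      if (length(keep)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = regions$start[ri] + keep - 1L,
          end = regions$start[ri] + keep - 1L + W, strand = str,
          tf = pwm$tf_name, score = sc[keep], rel_score = rel[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(), tf = character(),
                      score = numeric(), rel_score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  sites <- unique(do.call(rbind, hits))   # regions may overlap; dedupe
  prune_overlaps(sites)
}

#' Greedy per-TF overlap pruning: accept hits in decreasing score order
#' (leftmost, then `+` strand, on ties), rejecting any hit that overlaps an
#' accepted one on the same chromosome.
#' @noRd
prune_overlaps <- function(sites) {
  # scores are quantized for ordering only, so ties break by position even
  # when two summation orders differ in the last float bit
  o <- order(-round(sites$score, 9), sites$start, sites$strand != "+")
  sites <- sites[o, , drop = FALSE]
  kept <- logical(nrow(sites))
  acc <- list()
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]
    a <- acc[[ch]]
    if (is.null(a) ||
        !any(sites$start[i] < a[, 2] & sites$end[i] > a[, 1])) {
      kept[i] <- TRUE
      acc[[ch]] <- rbind(a, c(sites$start[i], sites$end[i]))
    }
  }
  out <- sites[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a PWM panel by total information content
#' @param pwms list of `pwm` objects.
#' @param min_ic_bits minimum total specificity in bits (default 8).
#' @return the PWMs passing the filter (excluded ones reported via message).
#' @export
filter_pwms_ic <- function(pwms, min_ic_bits = 8) {
  ic <- vapply(pwms, function(p) information_content(p)$total, numeric(1))
  drop <- names(pwms)[ic < min_ic_bits]
  if (length(drop)) {
    message("excluding low-IC PWMs (< ", min_ic_bits, " bits): ",
            paste(drop, collapse = ", "))
  }
  pwms[ic >= min_ic_bits]
}
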