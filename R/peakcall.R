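#' Peak-calling parameters
#'
#' A deliberately simplified MACS-style caller for cut-count tracks:
#' sliding windows are tested against a local Poisson background (the
#' maximum of the genome-wide rate and local means over each background
#' width), p-values are Benjamini-Hochberg corrected over all tested
#' windows in the run, and significant windows are merged into peaks.
#'
#' @param window window width in bp.
#' @param step step between window starts in bp (must be <= window).
#' @param local_bg_widths widths in bp of the centered local-background
#'   windows.
#' @param q_threshold BH FDR bound (the MACS `-q` contract; default 0.01).
#' @param merge_gap significant windows closer than this are merged.
#' @return an object of class `peakcall_params`.
#' @export
peakcall_params <- function(window = 300, step = 100,
                            local_bg_widths = c(1000, 10000),
                            q_threshold = 0.01, merge_gap = 100) {
  if (step > window) stop_ftc("step must be <= window")
  if (q_threshold <= 0 || q_threshold >= 1) stop_ftc("q_threshold in (0,1)")
  structure(list(window = as.integer(window), step = as.integer(step),
                 local_bg_widths = as.integer(local_bg_widths),
                 q_threshold = q_threshold, merge_gap = as.integer(merge_gap)),
            class = "peakcall_params")
}

#' Upper-tail Poisson probability P(X >= q | lambda)
#' @param q observed count (vectorized).
#' @param lambda Poisson mean (vectorized).
#' @return numeric vector of tail probabilities.
#' @export
poisson_upper_tail <- function(q, lambda) {
  stats::ppois(q - 1, lambda, lower.tail = FALSE)
}

#' Mean of a vector over centered windows of width w at given centers,
#' clipped at the chromosome ends (mean over the bases actually covered).
#' @noRd
centered_means <- function(cs, centers, w, n) {
  lo <- pmax(0L, as.integer(round(centers - w / 2)))
  hi <- pmin(n, lo + as.integer(w))
  lo <- pmin(lo, hi - 1L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Call peaks on a cut track
#'
#' For each window, `lambda_local = max(genome rate, local rates) * window`;
#' `p = P(X >= observed | lambda_local)` (upper-tail Poisson); BH over all
#' windows; windows with `q <= q_threshold` are merged when at most
#' `merge_gap` bp apart. The summit is the leftmost per-base maximum inside
#' the merged peak; fold enrichment is observed/expected in the significant
#' window containing the summit (highest such ratio when several do).
#'
#' @param track a `cut_track`.
#' @param params a `peakcall_params`.
#' @return peak `data.frame` (see [peaks_df()]), sorted and disjoint.
#' @export
call_peaks <- function(track, params = peakcall_params()) {
  stopifnot(inherits(track, "cut_track"))
  w <- params$window
  for (ch in names(track$counts)) {
    if (w > track$sizes[[ch]]) {
      stop_ftc("window %d bp exceeds chromosome %s (%d bp)", w, ch,
               track$sizes[[ch]])
    }
  }
  genome_rate <- sum(vapply(track$counts, sum, numeric(1))) /
    sum(track$sizes)
  tested <- list()
  for (ch in names(track$counts)) {
    x <- track$counts[[ch]]
    n <- length(x)
    starts <- seq.int(0L, n - w, by = params$step)
    cs <- c(0, cumsum(x))
    obs <- cs[starts + w + 1L] - cs[starts + 1L]
    centers <- starts + w / 2
    rate <- rep(genome_rate, length(starts))
    for (bgw in params$local_bg_widths) {
      rate <- pmax(rate, centered_means(cs, centers, bgw, n))
    }
    lambda <- rate * w
    tested[[ch]] <- data.frame(chrom = ch, start = starts, obs = obs,
                               lambda = lambda,
                               p = poisson_upper_tail(obs, lambda),
                               stringsAsFactors = FALSE)
  }
  all_w <- do.call(rbind, tested)
  all_w$q <- stats::p.adjust(all_w$p, method = "BH")
  sig <- all_w[all_w$q <= params$q_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(peaks_df(character(), integer(), integer(), character()))
  }
  out <- list()
  pk <- 0L
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    ends <- s$start + w
    grp <- cumsum(c(1L, as.integer(s$start[-1] - cummax(ends[-nrow(s)])
                                   > params$merge_gap)))
    x <- track$counts[[ch]]
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      ps <- min(m$start); pe <- max(m$start) + w
      seg <- x[(ps + 1L):pe]
      summit <- which.max(seg) - 1L      # leftmost maximum
      spos <- ps + summit
      holds <- m$start <= spos & spos < m$start + w
      if (!any(holds)) {
        # summit fell in a sub-threshold gap between merged windows;
        # use the member window nearest the summit
        holds <- seq_len(nrow(m)) == which.min(abs(m$start + w / 2 - spos))
      }
      fold <- max(m$obs[holds] / m$lambda[holds])
      pk <- pk + 1L
      out[[pk]] <- data.frame(
        chrom = ch, start = ps, end = pe, name = sprintf("peak_%d", pk),
        p = min(m$p), q = min(m$q), fold = fold, summit = summit,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  # cap -log10 at 320 to keep values finite when p underflows
  nl <- function(p) pmin(320, -log10(pmax(p, 1e-320)))
  peaks_df(chrom = res$chrom, start = res$start, end = res$end,
           name = res$name,
           score = pmin(1000L, as.integer(round(10 * nl(res$q)))),
           strand = ".", fold_enrichment = res$fold,
           neg_log10_p = nl(res$p), neg_log10_q = nl(res$q),
           summit_offset = res$summit)
}
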