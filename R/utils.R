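# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
stop_ftc <- function(...) stop(sprintf(...), call. = FALSE)

#' Pairwise log(exp(a) + exp(b)) without overflow.
#' @noRd
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  # if both are -Inf the result is -Inf, not NaN
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

#' Reverse-complement a DNA string (ACGTN alphabet).
#' @noRd
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

#' Check a numeric vector sums to 1 within tol.
#' @noRd
is_prob_vector <- function(p, tol = 1e-6) {
  is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) <= tol
}

#' Integer-valued check tolerant of numeric storage.
#' @noRd
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

#' Derive a child RNG seed from a base seed and a stream label,
#' kept below 2^31 so it is always a valid R integer seed.
#' @noRd
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}
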