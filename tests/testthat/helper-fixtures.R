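# shared fixtures and oracles, built in code at test time

# small desk-scale synthetic configuration for module tests
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 120, n_enhancers = 60,
         gene_body_length = 2000, chrom_length = 8e5),
    list(...))
  do.call(synthetic_config, args)
}

# one-age configuration sized for co-occupancy replicates: 1000 promoter
# regions, scaled down from the default two-age dataset to keep 50-replicate
# suites inside their time budgets
calib_config <- function(seed, rho_co) {
  synthetic_config(seed = seed, n_genes = 1000, n_enhancers = 0,
                   gene_body_length = 1000, chrom_length = 3.4e6,
                   ages = "P0", focal_bind = c(P0 = 0.3), rho_co = rho_co)
}

# end-to-end co-occupancy replicate: simulate -> footprint every panel TF
# (coordinates mode) -> occupancy -> enrichment vs the background null
cooccupancy_replicate <- function(config, age = config$ages[1]) {
  truth <- design_truth(config)
  track <- simulate_cut_track(truth, config, age)
  calls <- lapply(
    stats::setNames(nm = tf_panel(config)),
    function(tf) {
      st <- truth$sites[truth$sites$tf == tf,
                        c("chrom", "start", "end", "strand", "rel_score")]
      posterior_calls(fit_centipede(build_cut_matrix(st, track)))
    })
  occ <- assign_footprints(calls, truth$regions)$occupancy
  stat <- cooccupancy_rate(occ, config$focal, config$partner)
  null <- background_null(occ, config$focal, config$background_tfs)
  enr <- enrichment_summary(stat, null)
  list(truth = truth, calls = calls, occupancy = occ, stat = stat,
       null = null, enr = enr)
}

tf_panel <- function(config) {
  c(config$focal, config$partner, config$background_tfs)
}

# rank-based AUROC (probability a positive outranks a negative)
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# independent hypergeometric-summation oracle for the one-sided Fisher test
fisher_oracle <- function(fg_hit, fg_n, bg_hit, bg_n) {
  m <- fg_hit + bg_hit
  n <- (fg_n - fg_hit) + (bg_n - bg_hit)
  k <- fg_n
  xs <- fg_hit:min(m, k)
  sum(stats::dhyper(xs, m, n, k))
}

# independent Poisson upper-tail oracle by direct term summation
poisson_tail_oracle <- function(q, lambda) {
  if (q <= 0) return(1)
  x <- q
  term <- stats::dpois(x, lambda)
  total <- term
  repeat {
    x <- x + 1
    term <- stats::dpois(x, lambda)
    total <- total + term
    if (term < total * 1e-16 || x > q + 10000) break
  }
  total
}

# independent exhaustive scan oracle: score every window on both strands
# with log_odds(), threshold, then greedy-prune by descending score
scan_oracle <- function(regions, genome, pwm, rel_threshold) {
  W <- pwm$width
  hits <- list()
  for (ri in seq_len(nrow(regions))) {
    seq <- substr(genome[[regions$chrom[ri]]], regions$start[ri] + 1,
                  regions$end[ri])
    if (nchar(seq) < W) next
    for (i in 0:(nchar(seq) - W)) {
      w <- substr(seq, i + 1, i + W)
      for (str in c("+", "-")) {
        rel <- pwm_rel_score(w, pwm, str)
        if (rel >= rel_threshold) {
          hits[[length(hits) + 1]] <- data.frame(
            chrom = regions$chrom[ri], start = regions$start[ri] + i,
            end = regions$start[ri] + i + W, strand = str,
            score = log_odds(w, pwm, str), rel_score = rel,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), rel_score = numeric()))
  }
  h <- unique(do.call(rbind, hits))
  h <- h[order(-round(h$score, 9), h$start, h$strand != "+"), , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    acc <- h[keep & h$chrom == h$chrom[i], , drop = FALSE]
    if (!nrow(acc) || !any(h$start[i] < acc$end & h$end[i] > acc$start)) {
      keep[i] <- TRUE
    }
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# uniform random PWM of a given width
random_pwm <- function(name, W, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(4 * W, 1), 4, W)
  new_pwm(name, sweep(m, 2, colSums(m), "/"))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
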