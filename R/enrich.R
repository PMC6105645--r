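#' oPOSSUM-style promoter motif over-representation
#'
#' For each PWM passing the specificity filter, promoters (default
#' -1000/+300 around the TSS — the over-representation window, distinct
#' from the footprinting module's -2000/+300) of the foreground and
#' background gene sets are scanned at the relative-score threshold. Two
#' statistics are reported per TF: a nucleotide-rate Z-score,
#' `z = (fg_hits - fg_nt * bg_rate) / sqrt(fg_nt * bg_rate * (1 - bg_rate))`
#' with `bg_rate` the background hits-per-nucleotide, and a one-sided
#' Fisher exact test on the 2x2 gene-hit table. Results are sorted by
#' descending z with a flag at the z >= 10 reporting cutoff.
#'
#' @param fg_genes,bg_genes character vectors of gene ids (foreground must
#'   be non-empty; sets are disjointified by dropping fg genes from bg).
#' @param tss TSS table covering both sets.
#' @param genome named character vector (or `DNAStringSet`) of sequences.
#' @param pwms list of `pwm` objects.
#' @param up,down promoter extent in bp (defaults 1000/300).
#' @param rel_threshold matrix score threshold (default 0.90).
#' @param min_ic_bits minimum PWM specificity in bits (default 8).
#' @return `data.frame` with one row per retained TF: `tf`, `fg_hits`,
#'   `fg_nt`, `bg_hits`, `bg_nt`, `bg_rate`, `z`, `fg_gene_frac`,
#'   `bg_gene_frac`, `fisher_p`, `pass_z10`; sorted by descending `z`.
#' @export
enrich_promoters <- function(fg_genes, bg_genes, tss, genome, pwms,
                             up = 1000, down = 300, rel_threshold = 0.90,
                             min_ic_bits = 8) {
  if (!length(fg_genes)) stop_ftc("empty foreground gene set")
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  bg_genes <- setdiff(bg_genes, fg_genes)
  if (!length(bg_genes)) stop_ftc("empty background gene set")
  missing <- setdiff(c(fg_genes, bg_genes), tss$gene_id)
  if (length(missing)) {
    stop_ftc("gene(s) absent from the TSS table: %s",
             paste(utils::head(missing, 3), collapse = ", "))
  }
  pwms <- filter_pwms_ic(pwms, min_ic_bits)
  if (!length(pwms)) stop_ftc("no PWM passes the %g-bit filter", min_ic_bits)
  sizes <- vapply(genome, nchar, numeric(1))
  proms <- function(genes) {
    make_promoters(tss[tss$gene_id %in% genes, , drop = FALSE],
                   up = up, down = down, chrom_sizes = sizes)
  }
  fg_prom <- proms(fg_genes); bg_prom <- proms(bg_genes)
  fg_nt <- sum(fg_prom$end - fg_prom$start)
  bg_nt <- sum(bg_prom$end - bg_prom$start)
  rows <- lapply(pwms, function(pwm) {
    fg_sites <- scan_pwm(fg_prom, genome, pwm, rel_threshold)
    bg_sites <- scan_pwm(bg_prom, genome, pwm, rel_threshold)
    genes_hit <- function(prom, sites) {
      if (nrow(sites) == 0) return(character(0))
      ov <- interval_overlaps(sites, prom)
      sub("_prom$", "", unique(prom$name[ov$subject]))
    }
    fg_hit_genes <- genes_hit(fg_prom, fg_sites)
    bg_hit_genes <- genes_hit(bg_prom, bg_sites)
    bg_rate <- nrow(bg_sites) / bg_nt
    z <- if (bg_rate > 0 && bg_rate < 1) {
      (nrow(fg_sites) - fg_nt * bg_rate) /
        sqrt(fg_nt * bg_rate * (1 - bg_rate))
    } else NA_real_
    data.frame(
      tf = pwm$tf_name, fg_hits = nrow(fg_sites), fg_nt = fg_nt,
      bg_hits = nrow(bg_sites), bg_nt = bg_nt, bg_rate = bg_rate, z = z,
      fg_gene_frac = length(fg_hit_genes) / length(fg_genes),
      bg_gene_frac = length(bg_hit_genes) / length(bg_genes),
      fisher_p = fisher_onesided(length(fg_hit_genes), length(fg_genes),
                                 length(bg_hit_genes), length(bg_genes)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$z), , drop = FALSE]
  out$pass_z10 <- !is.na(out$z) & out$z >= 10
  rownames(out) <- NULL
  out
}

#' One-sided (over-representation) Fisher exact p-value for the 2x2 table
#' of genes with >= 1 hit in foreground vs background: the hypergeometric
#' upper tail P(X >= fg_hit).
#' @param fg_hit,fg_n hit genes / total genes, foreground.
#' @param bg_hit,bg_n hit genes / total genes, background.
#' @return p-value in (0, 1].
#' @export
fisher_onesided <- function(fg_hit, fg_n, bg_hit, bg_n) {
  stats::phyper(fg_hit - 1, m = fg_hit + bg_hit,
                n = (fg_n - fg_hit) + (bg_n - bg_hit), k = fg_n,
                lower.tail = FALSE)
}
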