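#' Configuration for the synthetic cortex-like ATAC dataset
#'
#' The generator emulates the statistical structure the co-occupancy
#' analysis runs on: a single synthetic chromosome tiled with gene
#' "cassettes" (a promoter window followed by a gene body), a subset of
#' bodies carrying an intragenic enhancer; a TF panel of one focal factor
#' (KLF6-like), one partner (STAT3-like) and ~10 background factors; motif
#' instances planted in regulatory regions with presence decoupled from
#' binding; and cut tracks for two "ages" in which bound sites show central
#' cut depletion with flanking enrichment inside accessibility peaks.
#'
#' Joint binding is planted at the region level: a configurable fraction of
#' focal-bound regions is flagged "growth-relevant", and there the partner
#' binds with probability `rho_co` instead of its marginal rate.
#'
#' @param n_genes number of genes (one promoter each).
#' @param promoter_up,promoter_down promoter extent upstream/downstream of
#'   the TSS in bp (defaults 2000/300).
#' @param gene_body_length gene body length in bp downstream of the promoter.
#' @param n_enhancers number of intragenic enhancers (at most one per gene).
#' @param enhancer_width enhancer width in bp.
#' @param chrom,chrom_length synthetic chromosome name and length.
#' @param focal,partner,background_tfs TF panel names.
#' @param motif_width motif width in bp (all TFs).
#' @param ages labels of the conditions to simulate.
#' @param focal_bind named per-age marginal binding probability of the focal
#'   TF at a sited region (default P0 0.3, adult 0.15 — the adult halves the
#'   newborn rate, mirroring the reported age decline in focal footprints).
#' @param partner_bind,background_bind marginal binding probabilities of the
#'   partner and background TFs (age-invariant defaults 0.05).
#' @param site_presence_prob probability a TF has a motif instance planted
#'   in a given region.
#' @param co_subset_frac fraction of focal-bound regions (at the first age)
#'   designated growth-relevant.
#' @param rho_co probability the partner binds (given a planted site) in a
#'   growth-relevant, focal-bound region.
#' @param background_cut_rate expected cuts/bp outside peaks.
#' @param peak_fold accessibility fold inside regulatory regions.
#' @param footprint_depletion multiplicative cut-rate dip over the cores of
#'   bound motifs (< 1).
#' @param flank_boost multiplicative rise over the +/- `flank_width` bp
#'   flanks of bound motifs (> 1).
#' @param flank_width flank width in bp.
#' @param nb_dispersion negative-binomial overdispersion of per-base counts
#'   (variance = mu + dispersion * mu^2; 0 gives Poisson).
#' @param seed integer master seed; all randomness derives from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 680,
                             promoter_up = 2000, promoter_down = 300,
                             gene_body_length = 3000,
                             n_enhancers = 340, enhancer_width = 1000,
                             chrom = "chrS", chrom_length = 4e6,
                             focal = "KLF6L", partner = "STAT3L",
                             background_tfs = sprintf("BG%02d", 1:10),
                             motif_width = 12,
                             ages = c("P0", "adult"),
                             focal_bind = c(P0 = 0.3, adult = 0.15),
                             partner_bind = 0.05,
                             background_bind = 0.05,
                             site_presence_prob = 0.5,
                             co_subset_frac = 0.6,
                             rho_co = 0.6,
                             background_cut_rate = 0.2,
                             peak_fold = 8,
                             footprint_depletion = 0.2,
                             flank_boost = 2.0,
                             flank_width = 10,
                             nb_dispersion = 0.25,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$focal_bind, partner_bind, background_bind,
             site_presence_prob, co_subset_frac, rho_co)
  if (any(probs < 0 | probs > 1)) stop_ftc("probabilities must lie in [0, 1]")
  if (!(footprint_depletion < 1 && flank_boost > 1)) {
    stop_ftc("need footprint_depletion < 1 < flank_boost")
  }
  panel <- c(focal, partner, background_tfs)
  if (anyDuplicated(panel)) stop_ftc("TF panel names must be unique")
  if (n_enhancers > n_genes) stop_ftc("at most one enhancer per gene")
  if (motif_width >= enhancer_width - 2 * 104) {
    stop_ftc("motif width too large for the enhancer width")
  }
  if (n_enhancers > 0 && enhancer_width > gene_body_length) {
    stop_ftc("enhancers must fit inside gene bodies")
  }
  if (!all(ages %in% names(cfg$focal_bind))) {
    stop_ftc("focal_bind must name every age")
  }
  cassette <- promoter_up + promoter_down + gene_body_length
  if (n_genes * cassette > chrom_length) {
    stop_ftc("regions do not fit: %d genes x %d bp > chromosome %d bp",
             n_genes, cassette, chrom_length)
  }
  structure(cfg, class = "synthetic_config")
}

#' @noRd
tf_panel_names <- function(config) {
  c(config$focal, config$partner, config$background_tfs)
}

#' @noRd
tf_bind_prob <- function(config, tf, age) {
  if (tf == config$focal) unname(config$focal_bind[[age]])
  else if (tf == config$partner) config$partner_bind
  else config$background_bind
}

#' Deterministic synthetic PWMs for the TF panel
#'
#' Each TF gets a random consensus of the configured width; consensus bases
#' carry probability 0.85 and the others 0.05 (total IC about 1.15 bits per
#' column, comfortably above the 8-bit specificity filter at width 12).
#'
#' @param config a `synthetic_config`.
#' @return named list of `pwm` objects.
#' @export
synthetic_pwms <- function(config) {
  set.seed(derive_seed(config$seed, "pwms"))
  pwms <- list()
  for (tf in tf_panel_names(config)) {
    cons <- sample.int(4, config$motif_width, replace = TRUE)
    probs <- matrix(0.05, 4, config$motif_width)
    probs[cbind(cons, seq_len(config$motif_width))] <- 0.85
    pwms[[tf]] <- new_pwm(tf, probs)
  }
  pwms
}

# margin kept between a motif core and the region edge so the default
# footprint window (core +/- 100 bp) stays inside the flat peak plateau
SITE_EDGE_MARGIN <- 104L

# slot spacing keeping neighbouring sites >= W + 113 bp apart, so one
# site's footprint window (+/- 100 bp) never covers another site's
# perturbed zone (core +/- 10 bp flanks)
site_slot_spacing <- function(W) 2L * W + 112L

#' Draw the planted truth: annotation, motif instances, bound labels
#'
#' Gene cassettes are placed along the chromosome with randomized spacing
#' (no overlaps by construction); each TF gets at most one planted motif
#' instance per regulatory region (presence probability
#' `site_presence_prob`), positioned so its footprint window stays inside
#' the region; bound labels are then drawn per age: the focal and background
#' TFs independently at their marginal rates, the partner at `rho_co` in
#' growth-relevant focal-bound regions and at its marginal rate elsewhere.
#'
#' @param config a `synthetic_config`.
#' @return an object of class `synthetic_truth`: list with `config`, `tss`,
#'   `gene_spans`, `regions` (with a `growth_relevant` flag), `sites`, and
#'   `bound` (site x age logical matrix).
#' @export
design_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "truth"))
  n <- config$n_genes
  prom_w <- config$promoter_up + config$promoter_down
  cassette <- prom_w + config$gene_body_length
  free <- config$chrom_length - n * cassette
  gaps <- stats::runif(n + 1)
  gaps <- floor(free * gaps / sum(gaps))
  cass_start <- cumsum(c(0, rep(cassette, n - 1))) + cumsum(gaps[seq_len(n)])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # promoter always occupies [c, c + prom_w); the TSS position making that
  # true depends on strand (see make_promoters for the formulas)
  tss_pos <- ifelse(strand == "+", cass_start + config$promoter_up,
                    cass_start + config$promoter_down - 1L)
  gene_id <- sprintf("gene%04d", seq_len(n))
  tss <- data.frame(gene_id = gene_id, chrom = config$chrom, strand = strand,
                    tss = as.integer(tss_pos), stringsAsFactors = FALSE)
  gene_spans <- gintervals(config$chrom, cass_start, cass_start + cassette,
                           strand, gene_id)
  promoters <- make_promoters(tss, up = config$promoter_up,
                              down = config$promoter_down,
                              chrom_sizes = stats::setNames(config$chrom_length,
                                                            config$chrom))
  regions <- data.frame(
    region_id = promoters$name, kind = "promoter", chrom = promoters$chrom,
    start = promoters$start, end = promoters$end, gene_id = gene_id,
    stringsAsFactors = FALSE)
  if (config$n_enhancers > 0) {
    enh_genes <- sort(sample.int(n, config$n_enhancers))
    body_start <- cass_start[enh_genes] + prom_w
    off_max <- config$gene_body_length - config$enhancer_width
    if (off_max < 0) stop_ftc("enhancer wider than gene body")
    es <- body_start + floor(stats::runif(config$n_enhancers) * (off_max + 1))
    regions <- rbind(regions, data.frame(
      region_id = sprintf("%s_enh", gene_id[enh_genes]), kind = "enhancer",
      chrom = config$chrom, start = as.integer(es),
      end = as.integer(es + config$enhancer_width),
      gene_id = gene_id[enh_genes], stringsAsFactors = FALSE))
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL

  pwms <- synthetic_pwms(config)
  sites <- plant_sites(config, regions, pwms)
  labels <- draw_bound_labels(config, regions, sites)

  structure(list(config = config, pwms = pwms, tss = tss,
                 gene_spans = gene_spans,
                 regions = cbind(regions,
                                 growth_relevant = labels$growth_relevant),
                 sites = sites, bound = labels$bound),
            class = "synthetic_truth")
}

#' One planted motif instance per (region, TF) pair with presence
#' probability `site_presence_prob`; cores never overlap within a region
#' (sites occupy distinct 2W-wide slots with W of random jitter, so
#' neighbours stay >= W apart by construction).
#' @noRd
plant_sites <- function(config, regions, pwms) {
  W <- config$motif_width
  tfs <- tf_panel_names(config)
  nR <- nrow(regions); nT <- length(tfs)
  sp <- site_slot_spacing(W)
  lo <- regions$start + SITE_EDGE_MARGIN
  hi <- regions$end - SITE_EDGE_MARGIN - W     # max allowed start
  nslots <- pmax(0L, (hi - lo - W + 1L) %/% sp + 1L)
  pres <- matrix(stats::runif(nR * nT) < config$site_presence_prob, nR, nT)
  reg_idx <- integer(0); tf_idx <- integer(0); pos <- integer(0)
  for (ri in which(rowSums(pres) > 0)) {
    tfi <- which(pres[ri, ])
    if (length(tfi) > nslots[ri]) {
      # random truncation so no TF is systematically favoured in small regions
      tfi <- sort(sample(tfi, nslots[ri]))
    }
    if (!length(tfi)) next
    slots <- sample.int(nslots[ri], length(tfi))
    jitter <- floor(stats::runif(length(tfi)) * W)
    reg_idx <- c(reg_idx, rep.int(ri, length(tfi)))
    tf_idx <- c(tf_idx, tfi)
    pos <- c(pos, lo[ri] + (slots - 1L) * sp + jitter)
  }
  if (!length(pos)) stop_ftc("no sites planted; enlarge the configuration")
  sites <- data.frame(
    tf = tfs[tf_idx], region_id = regions$region_id[reg_idx],
    chrom = regions$chrom[reg_idx], start = as.integer(pos),
    end = as.integer(pos + W),
    strand = sample(c("+", "-"), length(pos), replace = TRUE),
    seq = NA_character_, rel_score = NA_real_, stringsAsFactors = FALSE)
  # draw each site's 12-mer from its PWM columns; score it in index space
  for (tf in tfs) {
    rows <- which(sites$tf == tf)
    if (!length(rows)) next
    p <- pwms[[tf]]
    lo_m <- log2(p$probs / p$background)
    draw <- vapply(seq_len(W), function(j) {
      sample.int(4, length(rows), replace = TRUE, prob = p$probs[, j])
    }, integer(length(rows)))
    draw <- matrix(draw, nrow = length(rows))
    sc <- rowSums(matrix(lo_m[cbind(as.vector(draw),
                                    rep(seq_len(W), each = length(rows)))],
                         nrow = length(rows)))
    rng <- pwm_score_range(p)
    sites$rel_score[rows] <- (sc - rng["min"]) / (rng["max"] - rng["min"])
    sites$seq[rows] <- apply(matrix(DNA_BASES[draw], nrow = length(rows)),
                             1, paste, collapse = "")
  }
  sites <- sites[order(sites$start, sites$tf), , drop = FALSE]
  sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  sites[, c("site_id", "tf", "region_id", "chrom", "start", "end",
            "strand", "seq", "rel_score")]
}

#' @noRd
draw_bound_labels <- function(config, regions, sites) {
  ages <- config$ages
  bound <- matrix(FALSE, nrow(sites), length(ages),
                  dimnames = list(sites$site_id, ages))
  focal_rows <- sites$tf == config$focal
  partner_rows <- sites$tf == config$partner
  # focal + background TFs: independent marginals per age
  for (age in ages) {
    for (tf in c(config$focal, config$background_tfs)) {
      rows <- sites$tf == tf
      p <- tf_bind_prob(config, tf, age)
      bound[rows, age] <- stats::runif(sum(rows)) < p
    }
  }
  # growth-relevant flag: a fixed fraction of regions focal-bound at age 1
  fb_regions <- unique(sites$region_id[focal_rows & bound[, ages[1]]])
  n_gr <- round(config$co_subset_frac * length(fb_regions))
  gr <- sort(sample(fb_regions, n_gr))
  growth_relevant <- regions$region_id %in% gr
  # partner: rho_co in growth-relevant focal-bound regions, marginal elsewhere
  for (age in ages) {
    fb_age <- unique(sites$region_id[focal_rows & bound[, age]])
    elevated <- partner_rows & sites$region_id %in% intersect(gr, fb_age)
    p <- ifelse(elevated[partner_rows], config$rho_co, config$partner_bind)
    bound[partner_rows, age] <- stats::runif(sum(partner_rows)) < p
  }
  list(bound = bound, growth_relevant = growth_relevant)
}

#' Planted sites of one TF with bound labels for one age
#' @param truth a `synthetic_truth`.
#' @param tf TF name.
#' @param age age label.
#' @return sites `data.frame` with a logical `bound` column.
#' @export
truth_sites <- function(truth, tf, age) {
  sel <- truth$sites$tf == tf
  out <- truth$sites[sel, , drop = FALSE]
  out$bound <- truth$bound[sel, age]
  rownames(out) <- NULL
  out
}

#' Per-region planted occupancy table for one age
#'
#' A TF occupies a region when it has at least one bound planted site there.
#' @param truth a `synthetic_truth`.
#' @param age age label.
#' @return `data.frame` (`region_id`, `tf`), one row per occupied pair.
#' @export
truth_occupancy <- function(truth, age) {
  sel <- truth$bound[, age]
  occ <- unique(truth$sites[sel, c("region_id", "tf")])
  rownames(occ) <- NULL
  occ
}

#' Simulate a cut track for one age
#'
#' Per-base counts are negative binomial with mean `background_cut_rate`,
#' times `peak_fold` inside regulatory regions, times `footprint_depletion`
#' over the cores of bound motif instances and `flank_boost` over their
#' flanks. Unbound instances leave the accessibility profile unmodified.
#'
#' @param truth a `synthetic_truth`.
#' @param config its `synthetic_config`.
#' @param age age label (must be in `config$ages`).
#' @param seed RNG seed; defaults to a stream derived from `config$seed`
#'   and the age label.
#' @return a `cut_track`.
#' @export
simulate_cut_track <- function(truth, config = truth$config, age,
                               seed = NULL) {
  if (!age %in% config$ages) stop_ftc("unknown age '%s'", age)
  set.seed(seed %||% derive_seed(config$seed, paste0("track_", age)))
  L <- config$chrom_length
  mu <- rep(config$background_cut_rate, L)
  for (ri in seq_len(nrow(truth$regions))) {
    mu[(truth$regions$start[ri] + 1L):truth$regions$end[ri]] <-
      config$background_cut_rate * config$peak_fold
  }
  b <- truth$sites[truth$bound[, age], , drop = FALSE]
  fw <- config$flank_width
  for (i in seq_len(nrow(b))) {
    core <- (b$start[i] + 1L):b$end[i]
    mu[core] <- mu[core] * config$footprint_depletion
    fl <- c((b$start[i] - fw + 1L):b$start[i], (b$end[i] + 1L):(b$end[i] + fw))
    fl <- fl[fl >= 1 & fl <= L]
    mu[fl] <- mu[fl] * config$flank_boost
  }
  counts <- if (config$nb_dispersion < 1e-12) {
    stats::rpois(L, mu)
  } else {
    stats::rnbinom(L, size = 1 / config$nb_dispersion, mu = mu)
  }
  cut_track(stats::setNames(list(counts), config$chrom),
            stats::setNames(L, config$chrom))
}

#' Synthetic genome sequence with planted motif instances
#'
#' Random uniform background sequence; each planted site's drawn motif
#' sequence is embedded at its coordinates (reverse-complemented for minus
#' strand sites).
#'
#' @param truth a `synthetic_truth`.
#' @param config its `synthetic_config`.
#' @return named character vector of length 1 (the chromosome sequence).
#' @export
synth_genome <- function(truth, config = truth$config) {
  set.seed(derive_seed(config$seed, "genome"))
  bases <- sample(DNA_BASES, config$chrom_length, replace = TRUE)
  for (i in seq_len(nrow(truth$sites))) {
    s <- truth$sites$seq[i]
    if (truth$sites$strand[i] == "-") s <- revcomp(s)
    bases[(truth$sites$start[i] + 1L):truth$sites$end[i]] <-
      strsplit(s, "", fixed = TRUE)[[1]]
  }
  stats::setNames(paste(bases, collapse = ""), config$chrom)
}

#' Write the synthetic dataset to disk
#'
#' Emits, under `outdir`: `cuts_<age>.bedGraph` per simulated age,
#' `tss.tsv`, `enhancers.bed`, `regions.bed`, `motifs.jaspar`,
#' `chrom.sizes`, a `truth_sites.tsv` table of planted sites with bound
#' labels, and optionally `genome.fa`. Regenerating with the same config
#' and seed yields byte-identical files.
#'
#' @param truth a `synthetic_truth`.
#' @param tracks named list (age -> `cut_track`).
#' @param outdir output directory (created if missing).
#' @param write_fasta also emit the synthetic genome FASTA.
#' @return named character vector of the paths written.
#' @export
emit_dataset <- function(truth, tracks, outdir, write_fasta = FALSE) {
  config <- truth$config
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop_ftc("cannot create output directory %s", outdir)
  paths <- c()
  for (age in names(tracks)) {
    p <- file.path(outdir, sprintf("cuts_%s.bedGraph", age))
    write_cut_track(tracks[[age]], p)
    paths[paste0("cuts_", age)] <- p
  }
  paths["tss"] <- file.path(outdir, "tss.tsv")
  write_tss_table(truth$tss, paths["tss"])
  enh <- truth$regions[truth$regions$kind == "enhancer", , drop = FALSE]
  paths["enhancers"] <- file.path(outdir, "enhancers.bed")
  write_bed(gintervals(enh$chrom, enh$start, enh$end, ".", enh$region_id),
            paths["enhancers"])
  paths["regions"] <- file.path(outdir, "regions.bed")
  write_bed(gintervals(truth$regions$chrom, truth$regions$start,
                       truth$regions$end, ".",
                       paste(truth$regions$region_id, truth$regions$kind,
                             truth$regions$gene_id, sep = "|")),
            paths["regions"])
  paths["pwms"] <- file.path(outdir, "motifs.jaspar")
  write_jaspar_pfms(truth$pwms, paths["pwms"])
  paths["chrom_sizes"] <- file.path(outdir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", config$chrom, config$chrom_length),
             paths["chrom_sizes"])
  tt <- truth$sites
  for (age in config$ages) tt[[paste0("bound_", age)]] <- truth$bound[, age]
  paths["truth"] <- file.path(outdir, "truth_sites.tsv")
  data.table::fwrite(tt, paths["truth"], sep = "\t")
  if (write_fasta) {
    g <- synth_genome(truth, config)
    paths["genome"] <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g), paths["genome"])
  }
  paths
}
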