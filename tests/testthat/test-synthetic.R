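test_that("truth generation is deterministic and structurally sound", {
  cfg <- small_config(seed = 3)
  t1 <- design_truth(cfg)
  t2 <- design_truth(cfg)
  expect_identical(t1$sites, t2$sites)
  expect_identical(t1$bound, t2$bound)
  expect_identical(t1$regions, t2$regions)

  # every planted site lies inside exactly one regulatory region
  ov <- interval_overlaps(
    t1$sites, t1$regions[, c("chrom", "start", "end")])
  expect_equal(nrow(ov), nrow(t1$sites))
  expect_true(all(t1$sites$start[ov$query] >= t1$regions$start[ov$subject] &
                  t1$sites$end[ov$query] <= t1$regions$end[ov$subject]))
  # regions never overlap each other
  self <- interval_overlaps(t1$regions[, c("chrom", "start", "end")],
                            t1$regions[, c("chrom", "start", "end")])
  expect_true(all(self$query == self$subject))
  # promoters are 2300 bp at the defaults
  prom <- t1$regions[t1$regions$kind == "promoter", ]
  expect_true(all(prom$end - prom$start == 2300))
})

test_that("degenerate probabilities give the degenerate co-occupancy", {
  cfg <- small_config(seed = 5, ages = "P0", focal_bind = c(P0 = 1),
                      partner_bind = 1, background_bind = 1, rho_co = 1)
  truth <- design_truth(cfg)
  occ <- truth_occupancy(truth, "P0")
  stat <- cooccupancy_rate(occ, cfg$focal, cfg$partner)
  sited <- split(truth$sites$tf, truth$sites$region_id)
  with_f <- vapply(sited, function(s) cfg$focal %in% s, logical(1))
  with_fp <- vapply(sited, function(s) all(c(cfg$focal, cfg$partner) %in% s),
                    logical(1))
  expect_equal(stat$n_focal_regions, sum(with_f))
  expect_equal(stat$rate, 100 * sum(with_fp) / sum(with_f))
})

test_that("rho_co at the partner marginal makes the partner look background", {
  # LLN check over ~2000 regions: planted co-occupancy of the partner
  # matches the background TFs' within binomial error
  cfg <- synthetic_config(seed = 8, n_genes = 2000, n_enhancers = 0,
                          gene_body_length = 300, chrom_length = 5.6e6,
                          ages = "P0", focal_bind = c(P0 = 0.5),
                          partner_bind = 0.1, background_bind = 0.1,
                          rho_co = 0.1)
  truth <- design_truth(cfg)
  occ <- truth_occupancy(truth, "P0")
  partner_rate <- cooccupancy_rate(occ, cfg$focal, cfg$partner)$rate
  bg_rates <- vapply(cfg$background_tfs, function(tf) {
    cooccupancy_rate(occ, cfg$focal, tf)$rate
  }, numeric(1))
  # expected rate = presence 0.5 * bind 0.1 = 5%; binomial SE over ~500
  # focal regions is ~1 percentage point
  expect_lt(abs(partner_rate - mean(bg_rates)), 3)
})

test_that("cut simulation realizes the configured accessibility structure", {
  cfg <- small_config(seed = 9, n_genes = 300, n_enhancers = 150,
                      chrom_length = 1.8e6, partner_bind = 0.15,
                      background_bind = 0.15)
  truth <- design_truth(cfg)
  expect_identical(simulate_cut_track(truth, cfg, "P0"),
                   simulate_cut_track(truth, cfg, "P0"))
  zero <- small_config(seed = 9, background_cut_rate = 0)
  tz <- simulate_cut_track(design_truth(zero), zero, "P0")
  expect_true(all(tz$counts[[1]] == 0))

  track <- simulate_cut_track(truth, cfg, "P0")
  x <- track$counts[[1]]
  in_reg <- logical(length(x))
  for (i in seq_len(nrow(truth$regions))) {
    in_reg[(truth$regions$start[i] + 1):truth$regions$end[i]] <- TRUE
  }
  # exclude the +/-(flank+core) neighbourhoods of all planted sites so the
  # moment check sees only unmodified plateau
  perturbed <- logical(length(x))
  for (i in seq_len(nrow(truth$sites))) {
    perturbed[(truth$sites$start[i] - 9):(truth$sites$end[i] + 10)] <- TRUE
  }
  ratio <- mean(x[in_reg & !perturbed]) / mean(x[!in_reg])
  expect_lt(abs(ratio - cfg$peak_fold) / cfg$peak_fold, 0.1)

  # bound cores are depleted relative to unbound cores (>= 200 sites each)
  core_mean <- function(rows) {
    mean(vapply(rows, function(i) {
      mean(x[(truth$sites$start[i] + 1):truth$sites$end[i]])
    }, numeric(1)))
  }
  b <- which(truth$bound[, "P0"]); u <- which(!truth$bound[, "P0"])
  expect_gt(length(b), 200)
  expect_gt(length(u), 200)
  expect_lt(core_mean(b), core_mean(u))
})

test_that("emitted datasets round-trip and regenerate byte-identically", {
  cfg <- small_config(seed = 4, n_genes = 40, n_enhancers = 20,
                      chrom_length = 3e5)
  truth <- design_truth(cfg)
  tracks <- lapply(stats::setNames(nm = cfg$ages), function(a) {
    simulate_cut_track(truth, cfg, a)
  })
  d1 <- withr::local_tempdir()
  p1 <- emit_dataset(truth, tracks, d1, write_fasta = TRUE)

  sizes <- read_chrom_sizes(p1[["chrom_sizes"]])
  expect_equal(read_cut_track(p1[["cuts_P0"]], sizes), tracks$P0)
  tss_back <- read_tss_table(p1[["tss"]])
  expect_equal(tss_back, truth$tss)
  enh_back <- read_bed(p1[["enhancers"]])
  enh <- truth$regions[truth$regions$kind == "enhancer", ]
  expect_equal(enh_back$start, enh$start)
  expect_equal(enh_back$end, enh$end)
  tt <- read.delim(p1[["truth"]])
  expect_equal(nrow(tt), nrow(truth$sites))

  d2 <- withr::local_tempdir()
  p2 <- emit_dataset(design_truth(cfg), tracks, d2, write_fasta = TRUE)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", 2e7), readBin(p2[[k]], "raw", 2e7),
                     label = paste("bytes of", k))
  }
})

test_that("the synthetic genome carries the planted motif instances", {
  cfg <- small_config(seed = 6, n_genes = 30, n_enhancers = 10,
                      chrom_length = 2.5e5)
  truth <- design_truth(cfg)
  g <- synth_genome(truth, cfg)
  for (i in sample(nrow(truth$sites), 25)) {
    s <- truth$sites[i, ]
    emb <- substr(g[[s$chrom]], s$start + 1, s$end)
    expect_equal(if (s$strand == "+") emb else ftcooc:::revcomp(emb), s$seq)
  }
})
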