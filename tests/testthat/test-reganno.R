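test_that("promoter windows follow the -up/+down rule on both strands", {
  tss <- data.frame(gene_id = c("geneA", "geneB", "geneC"),
                    chrom = "chr1", strand = c("+", "-", "+"),
                    tss = c(10000L, 10000L, 100L))
  pr <- make_promoters(tss, chrom_sizes = c(chr1 = 50000L))
  expect_equal(pr$start, c(8000, 9701, 0))
  expect_equal(pr$end, c(10300, 12001, 400))
  expect_equal(pr$end[2] - pr$start[2], 2300)
  expect_equal(pr$name, c("geneA_prom", "geneB_prom", "geneC_prom"))
  # clipping at the right edge too
  pr2 <- make_promoters(data.frame(gene_id = "d", chrom = "chr1",
                                   strand = "-", tss = 49900L),
                        chrom_sizes = c(chr1 = 50000L))
  expect_equal(pr2$end, 50000)
})

test_that("enhancers attach by gene containment with a nearest-TSS fallback", {
  spans <- gintervals("chr1", c(1000, 4000, 4500), c(3000, 9000, 9500),
                      "+", c("g1", "g2", "g3"))
  tss <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                    strand = "+", tss = c(1000L, 4000L, 4500L))
  cis <- gintervals("chr1", c(2000, 4600, 20000, 500000),
                    c(2400, 4900, 20400, 500400))
  suppressMessages(
    enh <- attach_enhancers(cis, spans, tss, max_tss_dist = 1e5))
  # element 1 inside g1 only
  expect_equal(enh$gene_id[enh$start == 2000], "g1")
  # element 2 inside both g2 and g3
  expect_setequal(enh$gene_id[enh$start == 4600], c("g2", "g3"))
  # element 3 inside no gene, nearest TSS (g3, 4500) within 100 kb
  expect_equal(enh$gene_id[enh$start == 20000], "g3")
  # element 4 is 495 kb from every TSS: dropped
  expect_false(any(enh$start == 500000))
  expect_true(all(enh$kind == "enhancer"))
})

make_call <- function(chrom, start, end, bound = TRUE) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = "+", bound = bound, stringsAsFactors = FALSE)
}

test_that("gene categories implement the two-category scheme", {
  regions <- data.frame(
    region_id = c("g1_prom", "g1_enh", "g2_prom", "g3_prom"),
    kind = c("promoter", "enhancer", "promoter", "promoter"),
    chrom = "chr1", start = c(0L, 5000L, 10000L, 20000L),
    end = c(2300L, 5500L, 12300L, 22300L),
    gene_id = c("g1", "g1", "g2", "g3"), stringsAsFactors = FALSE)
  # focal in g1's promoter, partner in g1's enhancer (different regions of
  # the same gene): gene-level union makes g1 focal_and_partner
  calls <- list(F = make_call("chr1", 100, 112),
                P = make_call("chr1", 5100, 5112))
  res <- assign_footprints(calls, regions, focal = "F", partner = "P")
  cat1 <- res$gene_category
  expect_equal(cat1$category[cat1$gene_id == "g1"], "focal_and_partner")
  expect_equal(cat1$category[cat1$gene_id == "g2"], "other")
  # region-level co-presence is NOT claimed for g1 (different regions)
  stat <- cooccupancy_rate(res$occupancy, "F", "P")
  expect_equal(stat$n_focal_regions, 1)
  expect_equal(stat$n_co_regions, 0)

  # focal only in g2
  calls2 <- list(F = make_call("chr1", c(100, 10100), c(112, 10112)),
                 P = make_call("chr1", 5100, 5112))
  res2 <- assign_footprints(calls2, regions, focal = "F", partner = "P")
  expect_equal(res2$gene_category$category,
               c("focal_and_partner", "focal_only", "other"))

  # counting conservation: focal_only + focal_and_partner = genes with a
  # focal-footprinted region
  occ <- res2$occupancy
  focal_genes <- unique(regions$gene_id[
    regions$region_id %in% occ$region_id[occ$tf == "F"]])
  n_cat <- table(res2$gene_category$category)
  expect_equal(unname(n_cat["focal_only"] + n_cat["focal_and_partner"]),
               length(focal_genes))

  # no bound calls: everything "other", occupancy empty
  calls3 <- list(F = make_call("chr1", 100, 112, bound = FALSE))
  res3 <- assign_footprints(calls3, regions, focal = "F", partner = "P")
  expect_equal(nrow(res3$occupancy), 0)
  expect_true(all(res3$gene_category$category == "other"))

  # calls on unknown chromosomes are ignored with a warning
  calls4 <- list(F = make_call("chrX", 100, 112))
  expect_warning(res4 <- assign_footprints(calls4, regions, "F", "P"),
                 "absent")
  expect_equal(nrow(res4$occupancy), 0)
})

test_that("occupancy grows monotonically with added bound calls", {
  regions <- data.frame(region_id = sprintf("r%d", 1:5), kind = "promoter",
                        chrom = "chr1", start = (0:4) * 1000L,
                        end = (0:4) * 1000L + 500L,
                        gene_id = sprintf("g%d", 1:5),
                        stringsAsFactors = FALSE)
  calls <- list(F = make_call("chr1", c(10, 1010), c(22, 1022)))
  occ1 <- assign_footprints(calls, regions)$occupancy
  calls$F <- rbind(calls$F, make_call("chr1", 2010, 2022))
  occ2 <- assign_footprints(calls, regions)$occupancy
  expect_true(all(paste(occ1$region_id, occ1$tf) %in%
                  paste(occ2$region_id, occ2$tf)))
})

test_that("perfect calls reproduce the planted joint-binding table exactly", {
  cfg <- small_config(seed = 44, n_genes = 80, n_enhancers = 40,
                      chrom_length = 6e5)
  truth <- design_truth(cfg)
  calls <- lapply(stats::setNames(nm = tf_panel(cfg)), function(tf) {
    st <- truth_sites(truth, tf, "P0")
    data.frame(chrom = st$chrom, start = st$start, end = st$end,
               strand = st$strand, bound = st$bound)
  })
  res <- assign_footprints(calls, truth$regions,
                           focal = cfg$focal, partner = cfg$partner)
  # occupancy == planted occupancy
  planted <- truth_occupancy(truth, "P0")
  expect_equal(res$occupancy[, c("region_id", "tf")],
               planted[order(planted$region_id, planted$tf), ],
               ignore_attr = TRUE)
  # gene categories match the planted labels computed independently
  r2g <- truth$regions[, c("region_id", "gene_id")]
  pl <- merge(planted, r2g, by = "region_id")
  want <- vapply(unique(truth$regions$gene_id), function(g) {
    tfs <- pl$tf[pl$gene_id == g]
    if (cfg$focal %in% tfs && cfg$partner %in% tfs) "focal_and_partner"
    else if (cfg$focal %in% tfs) "focal_only" else "other"
  }, character(1))
  got <- stats::setNames(res$gene_category$category,
                         res$gene_category$gene_id)
  expect_equal(got[names(want)], want)
})
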