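#' Build promoter regions around TSSs
#'
#' Plus strand: `[tss - up, tss + down)`; minus strand:
#' `[tss - down + 1, tss + up + 1)` — `up` bp upstream and `down` bp
#' downstream of the TSS in the gene's reading direction, width
#' `up + down` unless clipped at a chromosome edge.
#'
#' @param tss TSS `data.frame` (`gene_id`, `chrom`, `strand`, `tss`).
#' @param up,down promoter extent in bp (defaults 2000/300).
#' @param chrom_sizes optional named lengths used to clip at edges.
#' @return interval `data.frame` with `name = <gene_id>_prom`.
#' @export
make_promoters <- function(tss, up = 2000, down = 300, chrom_sizes = NULL) {
  start <- ifelse(tss$strand == "+", tss$tss - up, tss$tss - down + 1)
  end <- ifelse(tss$strand == "+", tss$tss + down, tss$tss + up + 1)
  start <- pmax(start, 0)
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, chrom_sizes[tss$chrom])
  }
  gintervals(tss$chrom, start, end, tss$strand,
             paste0(tss$gene_id, "_prom"))
}

#' Turn cis-elements into enhancer regions assigned to genes
#'
#' Each element becomes an enhancer assigned to every gene whose span
#' contains it; elements inside no gene are assigned to the nearest TSS
#' within `max_tss_dist` bp, else dropped (with a message).
#'
#' @param cis_elements interval `data.frame` of candidate elements.
#' @param gene_spans interval `data.frame` of gene spans (`name` =
#'   gene id).
#' @param tss optional TSS table for the nearest-TSS fallback.
#' @param max_tss_dist fallback distance bound in bp (default 1e5).
#' @return `data.frame` (`region_id`, `kind`, `chrom`, `start`, `end`,
#'   `gene_id`), one row per (element, gene) assignment.
#' @export
attach_enhancers <- function(cis_elements, gene_spans, tss = NULL,
                             max_tss_dist = 1e5) {
  if (nrow(cis_elements) == 0) {
    return(data.frame(region_id = character(), kind = character(),
                      chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  ov <- interval_overlaps(cis_elements, gene_spans)
  # containment, not mere overlap
  contained <- ov[cis_elements$start[ov$query] >= gene_spans$start[ov$subject] &
                  cis_elements$end[ov$query] <= gene_spans$end[ov$subject], ,
                  drop = FALSE]
  rows <- list()
  if (nrow(contained)) {
    rows[["contained"]] <- data.frame(
      element = contained$query,
      gene_id = gene_spans$name[contained$subject], stringsAsFactors = FALSE)
  }
  orphan <- setdiff(seq_len(nrow(cis_elements)), unique(contained$query))
  dropped <- 0L
  if (length(orphan) && !is.null(tss) && nrow(tss)) {
    for (i in orphan) {
      same <- which(tss$chrom == cis_elements$chrom[i])
      if (!length(same)) { dropped <- dropped + 1L; next }
      d <- ifelse(tss$tss[same] < cis_elements$start[i],
                  cis_elements$start[i] - tss$tss[same],
                  pmax(0, tss$tss[same] - cis_elements$end[i] + 1))
      j <- same[which.min(d)]
      if (min(d) <= max_tss_dist) {
        rows[[paste0("orphan", i)]] <- data.frame(
          element = i, gene_id = tss$gene_id[j], stringsAsFactors = FALSE)
      } else dropped <- dropped + 1L
    }
  } else {
    dropped <- length(orphan)
  }
  if (dropped) message(dropped, " cis-element(s) dropped: no containing gene",
                       " and no TSS within ", max_tss_dist, " bp")
  asg <- do.call(rbind, rows)
  if (is.null(asg)) {
    return(attach_enhancers(cis_elements[0, , drop = FALSE], gene_spans))
  }
  nm <- cis_elements$name
  nm[is.na(nm) | nm == "."] <- sprintf("enh%04d", which(is.na(nm) | nm == "."))
  out <- data.frame(region_id = nm[asg$element], kind = "enhancer",
                    chrom = cis_elements$chrom[asg$element],
                    start = cis_elements$start[asg$element],
                    end = cis_elements$end[asg$element],
                    gene_id = asg$gene_id, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign footprint calls to regions and categorize genes
#'
#' A bound call joins every region it overlaps by at least 1 bp. Gene
#' categories follow the two-category scheme: `focal_and_partner` when both
#' TFs are footprinted anywhere in the gene's promoter/enhancer regions
#' (gene-level union, irrespective of binding distance), else `focal_only`
#' when any region holds a focal footprint, else `other`. Region-level
#' co-presence is what the co-occupancy statistics consume.
#'
#' @param calls named list (TF -> calls `data.frame` with `chrom`, `start`,
#'   `end` and logical `bound`).
#' @param regions regions `data.frame` (`region_id`, `kind`, `chrom`,
#'   `start`, `end`, `gene_id`).
#' @param focal,partner TF names for gene categorization (optional; when
#'   omitted only occupancy is returned).
#' @return list with `occupancy` (long `data.frame`: `region_id`, `kind`,
#'   `tf`) and, when focal/partner are given, `gene_category`
#'   (`gene_id`, `category`).
#' @export
assign_footprints <- function(calls, regions, focal = NULL, partner = NULL) {
  occ <- list()
  reg_iv <- regions[, c("chrom", "start", "end")]
  reg_iv$strand <- "."; reg_iv$name <- regions$region_id
  for (tf in names(calls)) {
    b <- calls[[tf]][calls[[tf]]$bound, , drop = FALSE]
    if (nrow(b) == 0) next
    miss <- !b$chrom %in% regions$chrom
    if (any(miss)) {
      warning(sum(miss), " bound call(s) for ", tf,
              " on chromosomes absent from the regions; ignored")
      b <- b[!miss, , drop = FALSE]
    }
    if (nrow(b) == 0) next
    ov <- interval_overlaps(b, reg_iv)
    if (nrow(ov)) {
      occ[[tf]] <- data.frame(region_id = regions$region_id[unique(ov$subject)],
                              tf = tf, stringsAsFactors = FALSE)
    }
  }
  occupancy <- do.call(rbind, occ)
  if (is.null(occupancy)) {
    occupancy <- data.frame(region_id = character(), tf = character(),
                            stringsAsFactors = FALSE)
  }
  occupancy <- merge(occupancy,
                     unique(regions[, c("region_id", "kind")]),
                     by = "region_id", sort = TRUE)[, c("region_id", "kind", "tf")]
  occupancy <- occupancy[order(occupancy$region_id, occupancy$tf), ,
                         drop = FALSE]
  rownames(occupancy) <- NULL
  res <- list(occupancy = occupancy)
  if (!is.null(focal) && !is.null(partner)) {
    res$gene_category <- categorize_genes(occupancy, regions, focal, partner)
  }
  res
}

#' @noRd
categorize_genes <- function(occupancy, regions, focal, partner) {
  r2g <- unique(regions[, c("region_id", "gene_id")])
  hit <- merge(occupancy, r2g, by = "region_id")
  genes <- unique(regions$gene_id)
  focal_genes <- unique(hit$gene_id[hit$tf == focal])
  partner_genes <- unique(hit$gene_id[hit$tf == partner])
  category <- rep("other", length(genes))
  category[genes %in% focal_genes] <- "focal_only"
  category[genes %in% focal_genes & genes %in% partner_genes] <-
    "focal_and_partner"
  out <- data.frame(gene_id = genes, category = category,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}
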