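#' Co-occupancy rate of a focal TF with a partner
#'
#' Over regulatory regions containing at least one focal footprint, the
#' percentage also containing at least one partner footprint.
#'
#' @param occupancy long `data.frame` (`region_id`, `tf`), one row per
#'   occupied pair (as from [assign_footprints()]).
#' @param focal,partner TF names.
#' @return an object of class `cooccupancy_stat`: `focal`, `partner`,
#'   `n_focal_regions`, `n_co_regions`, `rate` (percent; `NA` with
#'   `undefined = TRUE` when no focal regions exist).
#' @export
cooccupancy_rate <- function(occupancy, focal, partner) {
  focal_regions <- unique(occupancy$region_id[occupancy$tf == focal])
  partner_regions <- unique(occupancy$region_id[occupancy$tf == partner])
  n_focal <- length(focal_regions)
  n_co <- length(intersect(focal_regions, partner_regions))
  structure(list(focal = focal, partner = partner,
                 n_focal_regions = n_focal, n_co_regions = n_co,
                 rate = if (n_focal == 0) NA_real_ else 100 * n_co / n_focal,
                 undefined = n_focal == 0),
            class = "cooccupancy_stat")
}

#' Background-TF null for the co-occupancy rate
#'
#' The focal TF's co-occupancy rate with each TF of a background panel,
#' summarized by the mean and sample SD (n - 1 denominator) over the panel.
#' Panel TFs footprinted in no region are excluded (with a message); the
#' panel must retain at least two members.
#'
#' @param occupancy long occupancy `data.frame`.
#' @param focal focal TF name (must not be in the panel).
#' @param panel character vector of background TF names (>= 2).
#' @return an object of class `background_null`: `panel`, `rates`
#'   (named, percent), `mean`, `sd`.
#' @export
background_null <- function(occupancy, focal, panel) {
  if (length(panel) < 2) stop_ftc("background panel needs >= 2 TFs")
  if (focal %in% panel) stop_ftc("focal TF must not be in the background panel")
  present <- panel[panel %in% occupancy$tf]
  if (length(drop <- setdiff(panel, present))) {
    message("panel TF(s) with no footprinted region excluded: ",
            paste(drop, collapse = ", "))
  }
  if (length(present) < 2) stop_ftc("background panel shrank below 2 TFs")
  rates <- vapply(present, function(tf) {
    cooccupancy_rate(occupancy, focal, tf)$rate
  }, numeric(1))
  structure(list(panel = present, rates = rates,
                 mean = mean(rates), sd = stats::sd(rates)),
            class = "background_null")
}

#' Fold and z enrichment of a co-occupancy rate over the background null
#'
#' `fold = rate / mean`; `z = (rate - mean) / sd`. Undefined inputs
#' (zero mean for fold, zero sd for z, undefined rate) propagate as `NA`
#' with flags — never silent zeros. No rounding is applied.
#'
#' @param stat a `cooccupancy_stat`.
#' @param null a `background_null`.
#' @return an object of class `enrichment_summary`: `fold`, `z`,
#'   `fold_undefined`, `z_undefined`, plus the inputs' headline numbers.
#' @export
enrichment_summary <- function(stat, null) {
  rate_ok <- !isTRUE(stat$undefined) && is.finite(stat$rate)
  fold_ok <- rate_ok && is.finite(null$mean) && null$mean > 0
  z_ok <- rate_ok && is.finite(null$sd) && null$sd > 0
  structure(list(
    rate = stat$rate, null_mean = null$mean, null_sd = null$sd,
    fold = if (fold_ok) stat$rate / null$mean else NA_real_,
    z = if (z_ok) (stat$rate - null$mean) / null$sd else NA_real_,
    fold_undefined = !fold_ok, z_undefined = !z_ok),
    class = "enrichment_summary")
}

#' Age contrast of focal footprinting and co-occupancy
#'
#' Percentage decline in focal-footprinted genes,
#' `100 * (young - old) / young`, and the drop in co-occupied genes. When
#' integer co-occupied gene counts are not supplied they are derived as
#' `n_genes * rate / 100`; both the unrounded figures and nearest-integer
#' roundings are reported.
#'
#' @param young,old per-age lists with `n_genes_focal` (count of genes with
#'   focal footprints), `co_rate` (partner co-occupancy, percent), and
#'   optionally `n_co_genes` (integer co-occupied gene count).
#' @return an object of class `age_contrast` with per-age counts,
#'   `pct_decline_focal_genes` (+ `_rounded`) and `pct_drop_co_genes`
#'   (+ `_rounded`); `NA` with `undefined = TRUE` when young counts are 0.
#' @export
age_contrast <- function(young, old) {
  co_genes <- function(a) a$n_co_genes %||% (a$n_genes_focal * a$co_rate / 100)
  yc <- co_genes(young); oc <- co_genes(old)
  decl_ok <- young$n_genes_focal > 0
  drop_ok <- yc > 0
  decline <- if (decl_ok) {
    100 * (young$n_genes_focal - old$n_genes_focal) / young$n_genes_focal
  } else NA_real_
  drop <- if (drop_ok) 100 * (yc - oc) / yc else NA_real_
  structure(list(
    young = list(n_genes_focal = young$n_genes_focal,
                 co_rate = young$co_rate, n_co_genes = yc,
                 n_co_genes_rounded = round(yc)),
    old = list(n_genes_focal = old$n_genes_focal, co_rate = old$co_rate,
               n_co_genes = oc, n_co_genes_rounded = round(oc)),
    pct_decline_focal_genes = decline,
    pct_decline_focal_genes_rounded = round(decline),
    pct_drop_co_genes = drop,
    pct_drop_co_genes_rounded = round(drop),
    undefined = !(decl_ok && drop_ok)),
    class = "age_contrast")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf(paste0("<enrichment_summary> rate %.3f%% vs background ",
                     "%.3f%% (SD %.3f): fold %.2f, z %.2f\n"),
              x$rate, x$null_mean, x$null_sd, x$fold, x$z))
  invisible(x)
}
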