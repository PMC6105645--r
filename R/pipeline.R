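#' Default pipeline configuration
#'
#' One block per stage; paper-derived defaults (peak q 0.01, promoter
#' -2000/+300, relative score 0.90, 8-bit specificity, posterior 0.99)
#' sit in their stage blocks and every remaining value is an invented
#' desk-scale default.
#'
#' @param seed global seed.
#' @param synthetic named list of overrides for [synthetic_config()].
#' @param site_mode `"coordinates"` (sites taken from the planted truth) or
#'   `"fasta"` (PWM scanning of peak sequence on the synthetic genome).
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, synthetic = list(),
                                    site_mode = c("coordinates", "fasta")) {
  list(
    seed = as.integer(seed),
    synthetic = synthetic,
    sites = list(mode = match.arg(site_mode), rel_threshold = 0.90),
    peakcall = list(window = 300, step = 100, q_threshold = 0.01,
                    merge_gap = 100),
    footprint = list(L = 100, posterior_threshold = 0.99)
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the blocks of
#'   [default_pipeline_config()]; missing values take the defaults.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = user$seed %||% 1L)
  for (blk in c("synthetic", "sites", "peakcall", "footprint")) {
    base[[blk]] <- utils::modifyList(base[[blk]], user[[blk]] %||% list())
  }
  base
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> peak calling -> site definition -> footprinting ->
#' promoter/enhancer annotation -> co-occupancy enrichment -> report.
#' Every stage is a pure function of (config, seed); rerunning with the
#' same config yields a byte-identical report JSON.
#'
#' @param config nested list as from [default_pipeline_config()].
#' @param outdir output directory for intermediate files and the report.
#' @param quiet suppress progress messages.
#' @return the report (list), invisibly also written to
#'   `<outdir>/report.json`.
#' @export
run_all <- function(config, outdir, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[ftcooc] ", sprintf(...))
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  scfg <- do.call(synthetic_config,
                  c(config$synthetic, list(seed = config$seed)))
  say("simulate: %d genes, %d enhancers, %s ages",
      scfg$n_genes, scfg$n_enhancers, paste(scfg$ages, collapse = "/"))
  truth <- design_truth(scfg)
  tracks <- lapply(stats::setNames(scfg$ages, scfg$ages), function(a) {
    simulate_cut_track(truth, scfg, a)
  })
  emit_dataset(truth, tracks, file.path(outdir, "data"),
               write_fasta = config$sites$mode == "fasta")
  genome <- if (config$sites$mode == "fasta") synth_genome(truth, scfg)

  pk_par <- peakcall_params(
    window = config$peakcall$window %||% 300,
    step = config$peakcall$step %||% 100,
    q_threshold = config$peakcall$q_threshold %||% 0.01,
    merge_gap = config$peakcall$merge_gap %||% 100)
  tfs <- tf_panel_names(scfg)
  panel <- scfg$background_tfs
  per_age <- list()
  for (age in scfg$ages) {
    say("age %s: peak calling", age)
    peaks <- call_peaks(tracks[[age]], pk_par)
    write_narrowpeak(peaks, file.path(outdir, sprintf("peaks_%s.narrowPeak",
                                                      age)))
    say("age %s: %d peaks; footprinting %d TFs", age, nrow(peaks),
        length(tfs))
    calls <- list()
    for (tf in tfs) {
      sites <- if (config$sites$mode == "fasta") {
        scan_pwm(peaks, genome, truth$pwms[[tf]],
                 rel_threshold = config$sites$rel_threshold %||% 0.90)
      } else {
        truth$sites[truth$sites$tf == tf,
                    c("chrom", "start", "end", "strand", "rel_score"),
                    drop = FALSE]
      }
      if (nrow(sites) == 0) next
      cm <- build_cut_matrix(sites, tracks[[age]],
                             L = config$footprint$L %||% 100)
      fit <- fit_centipede(cm)
      calls[[tf]] <- posterior_calls(
        fit, threshold = config$footprint$posterior_threshold %||% 0.99)
    }
    asg <- assign_footprints(calls, truth$regions,
                             focal = scfg$focal, partner = scfg$partner)
    stat <- cooccupancy_rate(asg$occupancy, scfg$focal, scfg$partner)
    null <- tryCatch(background_null(asg$occupancy, scfg$focal, panel),
                     error = function(e) NULL)
    enr <- if (!is.null(null)) enrichment_summary(stat, null)
    cat_tab <- table(asg$gene_category$category)
    n_focal_genes <- sum(cat_tab[c("focal_only", "focal_and_partner")],
                         na.rm = TRUE)
    per_age[[age]] <- list(
      n_peaks = nrow(peaks),
      n_focal_regions = stat$n_focal_regions,
      n_co_regions = stat$n_co_regions,
      co_rate_pct = stat$rate,
      null_mean_pct = null$mean, null_sd_pct = null$sd,
      fold = enr$fold, z = enr$z,
      n_focal_genes = unname(n_focal_genes),
      n_co_genes = unname(cat_tab["focal_and_partner"] %|NA|% 0))
    calls_path <- file.path(outdir, sprintf("calls_%s.tsv", age))
    data.table::fwrite(
      data.table::rbindlist(calls, idcol = "tf"), calls_path, sep = "\t")
  }
  report <- list(
    package = "ftcooc",
    seed = config$seed,
    parameters = list(synthetic = scfg[setdiff(names(scfg), "seed")],
                      sites = config$sites, peakcall = config$peakcall,
                      footprint = config$footprint),
    ages = per_age)
  if (length(scfg$ages) >= 2) {
    y <- per_age[[scfg$ages[1]]]; o <- per_age[[scfg$ages[2]]]
    report$age_contrast <- unclass(age_contrast(
      list(n_genes_focal = y$n_focal_genes, co_rate = y$co_rate_pct,
           n_co_genes = y$n_co_genes),
      list(n_genes_focal = o$n_focal_genes, co_rate = o$co_rate_pct,
           n_co_genes = o$n_co_genes)))
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done in %.1f s; report at %s", as.numeric(Sys.time() - t0, "secs"),
      file.path(outdir, "report.json"))
  invisible(report)
}

#' @noRd
`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
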