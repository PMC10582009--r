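#' Pipeline run configuration
#'
#' Bundles input paths and stage parameters for [run_pipeline()].
#' Defaults are the analysis defaults throughout the package: 50 kb
#' windows with a 10 kb step and Z > 5 for the selection scan, the
#' strict [roh_params()] set, r = 1.04 cM/Mb with 7-year generations for
#' ROH dating, and alpha = 0.05 indicator gating.
#'
#' @param vcf,sheet,mask,gff input file paths (mask/gff optional).
#' @param outdir output directory for stage tables.
#' @param scan_pops two population labels for the spatial F_ST scan
#'   (default: the two largest populations).
#' @param window_bp,step_bp scan window and step (bp).
#' @param z_cut outlier Z-score threshold.
#' @param estimator F_ST estimator.
#' @param roh [roh_params()].
#' @param timing [roh_timing_params()].
#' @param thresholds [indicator_thresholds()].
#' @param autosomal_bp genome size for F_ROH (default: sum of the last
#'   observed position per chromosome).
#' @param ne optional named vector of externally estimated Ne values per
#'   population (e.g. LD-based), classified by [classify_ne()].
#' @param callable_bp callable genome size per sample for
#'   heterozygosity (default: `autosomal_bp`).
#' @param seed RNG seed for any resampling.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, sheet, mask = NULL, gff = NULL,
                       outdir = "erosure_out", scan_pops = NULL,
                       window_bp = 50000, step_bp = 10000, z_cut = 5,
                       estimator = "weir-cockerham",
                       roh = roh_params(), timing = roh_timing_params(),
                       thresholds = indicator_thresholds(),
                       autosomal_bp = NULL, ne = NULL,
                       callable_bp = NULL, seed = 1) {
  structure(list(vcf = vcf, sheet = sheet, mask = mask, gff = gff,
                 outdir = outdir, scan_pops = scan_pops,
                 window_bp = window_bp, step_bp = step_bp, z_cut = z_cut,
                 estimator = estimator, roh = roh, timing = timing,
                 thresholds = thresholds, autosomal_bp = autosomal_bp,
                 ne = ne, callable_bp = callable_bp, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments
#'   (nested `roh`, `timing` and `thresholds` blocks map onto
#'   [roh_params()], [roh_timing_params()] and
#'   [indicator_thresholds()]).
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$roh)) y$roh <- do.call(roh_params, y$roh)
  if (!is.null(y$timing)) y$timing <- do.call(roh_timing_params, y$timing)
  if (!is.null(y$thresholds))
    y$thresholds <- do.call(indicator_thresholds, y$thresholds)
  y$schema_version <- NULL
  do.call(run_config, y)
}

stage_msg <- function(...) message("[erosure] ", ...)

#' Run the full genomic-erosion pipeline
#'
#' Executes read -> complete-case filter -> diversity (heterozygosity,
#' windowed pi) -> ROH (+ F_ROH and dating) -> load (counts, normalised
#' totals, realised load, R_xy) -> windowed F_ST scan (+ Z(F_ST),
#' outlier genes) -> indicators, writing one TSV per stage and
#' returning a machine-readable report. The orchestrator adds no
#' computation of its own.
#'
#' @param cfg a [run_config()].
#' @return list of class `run_report`: parameters, per-stage row counts,
#'   stage tables and indicator statuses.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  sheet <- read_sample_sheet(cfg$sheet)
  mask <- if (!is.null(cfg$mask)) read_bed_mask(cfg$mask) else NULL

  stage_msg("reading genotypes from ", cfg$vcf)
  gm <- read_genotypes(cfg$vcf, sheet, mask)
  gm <- complete_case_filter(gm)
  stage_msg(length(gm$pos), " complete-case biallelic sites, ",
            length(gm$sample_ids), " samples")

  chroms <- unique(gm$chrom)
  auto_bp <- cfg$autosomal_bp %||%
    sum(vapply(chroms, function(ch) max(gm$pos[gm$chrom == ch]),
               numeric(1)))
  call_bp <- cfg$callable_bp %||% auto_bp
  pops <- names(sort(table(gm$populations), decreasing = TRUE))
  scan_pops <- cfg$scan_pops %||% pops[1:2]

  stage_msg("diversity")
  het <- heterozygosity_per_kb(gm, call_bp)
  het_tab <- data.frame(sample_id = gm$sample_ids,
                        population = gm$populations,
                        cohort = gm$cohorts, het_per_kb = het)
  write_track_tsv(het_tab, file.path(cfg$outdir, "heterozygosity.tsv"))
  pi_tracks <- lapply(pops[table(gm$populations)[pops] >= 2],
                      function(p) pi_windows(gm, p, cfg$window_bp))
  names(pi_tracks) <- pops[table(gm$populations)[pops] >= 2]
  for (p in names(pi_tracks))
    write_track_tsv(pi_tracks[[p]],
                    file.path(cfg$outdir, paste0("pi_", p, ".tsv")))

  stage_msg("ROH calling")
  segs <- call_roh(gm, cfg$roh)
  write_track_tsv(segs, file.path(cfg$outdir, "roh_segments.tsv"))
  fr <- froh(segs, auto_bp, samples = gm$sample_ids)
  fr2 <- froh(segs, auto_bp, samples = gm$sample_ids, min_length_mb = 2)
  froh_tab <- data.frame(sample_id = gm$sample_ids,
                         population = gm$populations,
                         cohort = gm$cohorts,
                         froh_100kb = fr[gm$sample_ids],
                         froh_2mb = fr2[gm$sample_ids])
  write_track_tsv(froh_tab, file.path(cfg$outdir, "froh.tsv"))
  dating <- if (nrow(segs)) roh_age(segs$length_mb, cfg$timing) else NULL

  stage_msg("genetic load")
  load_tab <- NULL; rxy_res <- list()
  has_load <- any(gm$impact %in% LOAD_CATEGORIES &
                    !is.na(gm$ancestral_is_ref))
  if (has_load) {
    load_tab <- normalized_total_load(load_counts(gm))
    for (cat in c("HIGH", "MODERATE")) {
      rl <- try(realised_load(gm, cat), silent = TRUE)
      if (!inherits(rl, "try-error"))
        load_tab[[paste0(cat, "_realised")]] <- rl[load_tab$sample_id]
    }
    write_track_tsv(load_tab, file.path(cfg$outdir, "load.tsv"))
    # block jackknife needs enough blocks; cut finer than chromosomes
    # when the assembly is small
    n_blocks <- max(10L, length(chroms))
    for (cat in c("HIGH", "MODERATE")) {
      r <- try(rxy(gm, scan_pops[1], scan_pops[2], cat,
                   blocks = n_blocks), silent = TRUE)
      if (!inherits(r, "try-error")) rxy_res[[cat]] <- r
    }
  } else stage_msg("no orientable annotated sites; load stage skipped")

  stage_msg("F_ST scan ", scan_pops[1], " vs ", scan_pops[2])
  scan <- fst_windows(gm, scan_pops[1], scan_pops[2], cfg$window_bp,
                      cfg$step_bp, cfg$estimator)
  scan_z <- zfst(scan, cfg$z_cut)
  write_track_tsv(scan_z, file.path(cfg$outdir, "fst_scan.tsv"))
  genes <- if (!is.null(cfg$gff)) read_gene_models(cfg$gff) else NULL
  outlier_genes <- if (!is.null(genes)) intersect_genes(scan_z, genes)
                   else NULL
  if (!is.null(outlier_genes))
    write_track_tsv(outlier_genes,
                    file.path(cfg$outdir, "outlier_genes.tsv"))

  stage_msg("indicators")
  indicators <- list()
  cohorts <- sort(unique(gm$cohorts))
  if (length(cohorts) >= 2) {
    t1 <- cohorts[1]; t2 <- cohorts[length(cohorts)]
    yrs <- diff(range(gm$years))
    for (p in unique(gm$populations)) {
      i1 <- gm$populations == p & gm$cohorts == t1
      i2 <- gm$populations == p & gm$cohorts == t2
      if (sum(i1) >= 2 && sum(i2) >= 2 && yrs > 0) {
        ih <- try(classify_delta_h(het[i1], het[i2], yrs,
                                   name = paste0("deltaHET_", p),
                                   thresholds = cfg$thresholds),
                  silent = TRUE)
        if (!inherits(ih, "try-error"))
          indicators[[paste0("deltaHET_", p)]] <- ih
        # F_ROH can be identically 0 in a cohort; skip when untestable
        ifr <- try(classify_delta_h(fr[i1], fr[i2], yrs,
                                    direction = "loss-when-increasing",
                                    name = paste0("deltaFROH_", p),
                                    thresholds = cfg$thresholds),
                   silent = TRUE)
        if (!inherits(ifr, "try-error"))
          indicators[[paste0("deltaFROH_", p)]] <- ifr
      }
    }
    # between-population indicator: scan pops at the two cohorts
    gm1 <- subset_samples(gm, gm$cohorts == t1)
    gm2 <- subset_samples(gm, gm$cohorts == t2)
    enough <- function(g) all(table(factor(g$populations,
                                           scan_pops))[scan_pops] >= 2)
    if (enough(gm1) && enough(gm2)) {
      tr1 <- fst_windows(gm1, scan_pops[1], scan_pops[2], cfg$window_bp)
      tr2 <- fst_windows(gm2, scan_pops[1], scan_pops[2], cfg$window_bp)
      ind <- try(classify_delta_fst(tr1, tr2,
                                    thresholds = cfg$thresholds),
                 silent = TRUE)
      if (!inherits(ind, "try-error")) indicators$deltaFST <- ind
    }
  }
  if (!is.null(cfg$ne))
    for (p in names(cfg$ne))
      indicators[[paste0("Ne_", p)]] <-
        structure(list(indicator = paste0("Ne_", p), ne = cfg$ne[[p]],
                       status = classify_ne(cfg$ne[[p]],
                                            cfg$thresholds)),
                  class = "indicator_report")

  statuses <- vapply(indicators, function(x) x$status, character(1))
  report <- list(
    parameters = cfg,
    n_sites = length(gm$pos), n_samples = length(gm$sample_ids),
    stage_rows = c(heterozygosity = nrow(het_tab),
                   roh_segments = nrow(segs),
                   load = if (is.null(load_tab)) 0L else nrow(load_tab),
                   scan_windows = nrow(scan_z),
                   outlier_windows = sum(scan_z$outlier),
                   outlier_genes = if (is.null(outlier_genes)) 0L
                                   else nrow(outlier_genes)),
    heterozygosity = het_tab, pi = pi_tracks, roh = segs,
    froh = froh_tab, roh_dating = dating, load = load_tab,
    rxy = rxy_res, scan = scan_z, outlier_genes = outlier_genes,
    indicators = indicators, indicator_status = statuses)
  class(report) <- "run_report"
  jsonlite::write_json(
    list(n_sites = report$n_sites, n_samples = report$n_samples,
         stage_rows = as.list(report$stage_rows),
         indicator_status = as.list(statuses)),
    file.path(cfg$outdir, "report.json"), auto_unbox = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("erosure run:", x$n_samples, "samples,", x$n_sites, "sites\n")
  print(x$stage_rows)
  if (length(x$indicator_status)) {
    cat("indicators:\n")
    for (n in names(x$indicator_status))
      cat("  ", n, ":", x$indicator_status[[n]], "\n")
  }
  invisible(x)
}
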