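#' Configuration for the cohort simulator
#'
#' Defaults describe the monitoring design the package targets: two
#' diverged populations (Balding-Nichols F = 0.10) of 30 diploids each,
#' sampled at two time points 40 years apart (1980 and 2020, 7-year
#' generations), 50,000 independent biallelic coding SNPs on 5
#' chromosomes of 50 Mb, with ancestral allele frequencies
#' Uniform(0.05, 0.95) and an impact mix of 70% synonymous, 25%
#' moderate (missense-class) and 5% high (protein-truncating) variants.
#'
#' @param n_pops number of populations.
#' @param pop_names population labels.
#' @param n_per_pop diploid samples per population per time point.
#' @param n_sites number of biallelic sites.
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param F Balding-Nichols divergence per population (scalar or
#'   per-population vector), in `[0, 1)`.
#' @param impact_mix named proportions for SYNONYMOUS / MODERATE / HIGH
#'   (must sum to 1).
#' @param category_multiplier named list mapping an impact category to a
#'   per-population vector of derived-frequency multipliers (drives a
#'   true R_xy different from 1); default none.
#' @param ancestral_freq_range range of the ancestral derived-allele
#'   frequency distribution.
#' @param prob_ref_ancestral probability that the reference allele is
#'   the ancestral one at a site.
#' @param timepoints sampling years (1 or 2 values; two time points
#'   simulate temporal change).
#' @param drift_ne effective size driving Wright-Fisher drift between
#'   time points (ignored when `annual_het_change` is set).
#' @param annual_het_change programmed percent change per year in
#'   expected heterozygosity between the time points (negative = loss);
#'   `NULL` for pure drift.
#' @param generation_time years per generation.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2, pop_names = NULL, n_per_pop = 30,
                       n_sites = 50000, n_chrom = 5, chrom_length = 5e7,
                       F = 0.10,
                       impact_mix = c(SYNONYMOUS = 0.70, MODERATE = 0.25,
                                      HIGH = 0.05),
                       category_multiplier = list(),
                       ancestral_freq_range = c(0.05, 0.95),
                       prob_ref_ancestral = 0.8,
                       timepoints = c(1980, 2020),
                       drift_ne = 500, annual_het_change = NULL,
                       generation_time = 7, seed = 1) {
  if (is.null(pop_names))
    pop_names <- c("North", "South", "Transition",
                   paste0("pop", seq_len(max(0, n_pops - 3)) + 3))[
                     seq_len(n_pops)]
  if (abs(sum(impact_mix) - 1) > 1e-8)
    stop("impact_mix proportions must sum to 1")
  if (any(F < 0 | F >= 1)) stop("F must be in [0, 1)")
  if (n_per_pop < 1 || n_sites < 1 || n_chrom < 1)
    stop("all counts must be positive")
  F <- rep_len(F, n_pops)
  structure(list(n_pops = n_pops, pop_names = pop_names,
                 n_per_pop = n_per_pop, n_sites = n_sites,
                 n_chrom = n_chrom, chrom_length = chrom_length,
                 F = F, impact_mix = impact_mix,
                 category_multiplier = category_multiplier,
                 ancestral_freq_range = ancestral_freq_range,
                 prob_ref_ancestral = prob_ref_ancestral,
                 timepoints = sort(timepoints),
                 drift_ne = drift_ne,
                 annual_het_change = annual_het_change,
                 generation_time = generation_time, seed = seed),
            class = "sim_config")
}

# deterministic heterozygosity scaling: move p so that p'(1-p') equals
# factor * p(1-p), staying on p's side of 1/2
scale_het <- function(p, factor) {
  target <- pmin(pmax(factor * p * (1 - p), 0), 0.25)
  root <- sqrt(1 - 4 * target)
  ifelse(p <= 0.5, (1 - root) / 2, (1 + root) / 2)
}

# Wright-Fisher drift: g generations of binomial resampling at size 2Ne
drift_freq <- function(p, ne, generations) {
  for (i in seq_len(generations))
    p <- stats::rbinom(length(p), 2 * ne, p) / (2 * ne)
  p
}

#' Simulate diverged population cohorts
#'
#' Balding-Nichols model: each population's derived-allele frequency at
#' a site is Beta-distributed around the ancestral frequency with
#' divergence parameter F; genotypes are Binomial(2, p). With two time
#' points the later cohort's frequencies either drift (Wright-Fisher at
#' `drift_ne`) or follow a programmed annual heterozygosity change.
#' Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `gm` (a [genotype_matrix()]) and `truth`
#'   (ancestral and per-population frequencies, planted-tract slot,
#'   programmed change, seed).
#' @export
simulate_cohorts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_sites
  # chromosome layout and positions
  per_chrom <- diff(round(seq(0, S, length.out = cfg$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(n)
    sort(sample.int(cfg$chrom_length, n))))
  # ancestral state and derived frequency
  pd <- stats::runif(S, cfg$ancestral_freq_range[1],
                     cfg$ancestral_freq_range[2])
  anc_is_ref <- stats::runif(S) < cfg$prob_ref_ancestral
  impact <- sample(names(cfg$impact_mix), S, replace = TRUE,
                   prob = cfg$impact_mix)
  # per-population derived frequencies at time point 1
  pop_freq <- matrix(NA_real_, S, cfg$n_pops,
                     dimnames = list(NULL, cfg$pop_names))
  for (k in seq_len(cfg$n_pops)) {
    Fk <- cfg$F[k]
    pk <- if (Fk > 0)
      stats::rbeta(S, pd * (1 - Fk) / Fk, (1 - pd) * (1 - Fk) / Fk)
    else pd
    for (cat in names(cfg$category_multiplier)) {
      m <- rep_len(cfg$category_multiplier[[cat]], cfg$n_pops)[k]
      sel <- impact == cat
      pk[sel] <- pmin(pk[sel] * m, 0.999)
    }
    pop_freq[, k] <- pk
  }
  # time point 2 frequencies
  two_tp <- length(cfg$timepoints) == 2
  pop_freq_t2 <- NULL
  if (two_tp) {
    years <- diff(cfg$timepoints)
    pop_freq_t2 <- pop_freq
    if (!is.null(cfg$annual_het_change)) {
      factor <- max(0, 1 + cfg$annual_het_change / 100 * years)
      for (k in seq_len(cfg$n_pops))
        pop_freq_t2[, k] <- scale_het(pop_freq[, k], factor)
    } else if (!is.null(cfg$drift_ne)) {
      g <- max(1L, round(years / cfg$generation_time))
      for (k in seq_len(cfg$n_pops))
        pop_freq_t2[, k] <- drift_freq(pop_freq[, k], cfg$drift_ne, g)
    }
  }
  # genotypes: alt-allele dosage (alt is derived iff ancestral is ref)
  draw_cohort <- function(freq_mat, year) {
    mats <- lapply(seq_len(cfg$n_pops), function(k) {
      pderived <- freq_mat[, k]
      palt <- ifelse(anc_is_ref, pderived, 1 - pderived)
      m <- matrix(stats::rbinom(cfg$n_per_pop * S, 2,
                                rep(palt, each = cfg$n_per_pop)),
                  nrow = cfg$n_per_pop)
      m
    })
    geno <- do.call(rbind, mats)
    ids <- paste0(rep(cfg$pop_names, each = cfg$n_per_pop), "_", year,
                  "_", sprintf("%02d", seq_len(cfg$n_per_pop)))
    list(geno = geno, ids = ids,
         pops = rep(cfg$pop_names, each = cfg$n_per_pop),
         years = rep(year, cfg$n_pops * cfg$n_per_pop))
  }
  c1 <- draw_cohort(pop_freq, cfg$timepoints[1])
  if (two_tp) {
    c2 <- draw_cohort(pop_freq_t2, cfg$timepoints[2])
    geno <- rbind(c1$geno, c2$geno)
    ids <- c(c1$ids, c2$ids); pops <- c(c1$pops, c2$pops)
    yrs <- c(c1$years, c2$years)
  } else {
    geno <- c1$geno; ids <- c1$ids; pops <- c1$pops; yrs <- c1$years
  }
  gm <- genotype_matrix(geno, chrom = chrom, pos = pos,
                        sample_ids = ids, populations = pops,
                        years = yrs, ancestral_is_ref = anc_is_ref,
                        impact = impact)
  truth <- list(ancestral_freq = pd, pop_freq_t1 = pop_freq,
                pop_freq_t2 = pop_freq_t2,
                ancestral_is_ref = anc_is_ref, impact = impact,
                category_multiplier = cfg$category_multiplier,
                annual_het_change = cfg$annual_het_change,
                timepoints = cfg$timepoints, seed = cfg$seed,
                planted_tracts = NULL)
  list(gm = gm, truth = truth)
}

#' Plant homozygous tracts (ROH) into simulated genotypes
#'
#' Overwrites genotypes inside randomly placed, non-overlapping tracts
#' with the homozygote of the sample's population-major allele, until
#' each target sample reaches its target genome fraction (realised
#' fraction within about 10% of target). Tract coordinates are returned
#' as ground truth.
#'
#' @param gm a [genotype_matrix()].
#' @param target_fraction per-sample genome fraction to cover (<= 0.9).
#' @param tract_mb tract-length range in Mb (drawn uniformly).
#' @param samples sample ids to plant into (default: all).
#' @param seed RNG seed.
#' @return list with `gm` (modified) and `tracts` (data.frame
#'   sample_id, chrom, start, end).
#' @export
plant_roh <- function(gm, target_fraction, tract_mb = c(1, 3),
                      samples = gm$sample_ids, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (target_fraction > 0.9) stop("target fraction > 0.9 is infeasible")
  set.seed(seed)
  chroms <- unique(gm$chrom)
  chrom_len <- vapply(chroms, function(ch)
    max(gm$pos[gm$chrom == ch]), numeric(1))
  genome_bp <- sum(chrom_len)
  # population-major alt-allele homozygote per population x site
  major <- lapply(unique(gm$populations), function(p) {
    g <- gm$genotypes[gm$populations == p, , drop = FALSE]
    called <- g != -1L
    alt <- colSums(g == 1L) + 2 * colSums(g == 2L)
    ifelse(alt > colSums(called), 2L, 0L)   # alt freq > 0.5 ?
  })
  names(major) <- unique(gm$populations)
  tracts <- list(); k <- 0L
  if (target_fraction > 0) for (sid in samples) {
    si <- match(sid, gm$sample_ids)
    if (is.na(si)) stop("unknown sample id: ", sid)
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
    covered <- 0
    guard <- 0L
    while (covered < target_fraction * genome_bp) {
      guard <- guard + 1L
      if (guard > 10000L) stop("cannot place tracts (fraction too high?)")
      L <- round(stats::runif(1, tract_mb[1], tract_mb[2]) * 1e6)
      remaining <- target_fraction * genome_bp - covered
      if (remaining < 1e5) break       # within a rounding sliver of target
      L <- min(L, max(round(remaining), 1e5))
      ch <- sample(chroms, 1, prob = chrom_len)
      if (L >= chrom_len[ch]) next
      s <- sample.int(chrom_len[ch] - L, 1)
      e <- s + L - 1
      ov <- placed$chrom == ch & placed$start <= e & placed$end >= s
      if (any(ov)) next
      placed <- rbind(placed, data.frame(chrom = ch, start = s, end = e))
      covered <- covered + L
      sel <- gm$chrom == ch & gm$pos >= s & gm$pos <= e
      gm$genotypes[si, sel] <- major[[gm$populations[si]]][sel]
      k <- k + 1L
      tracts[[k]] <- data.frame(sample_id = sid, chrom = ch,
                                start = s, end = e,
                                stringsAsFactors = FALSE)
    }
  }
  tracts <- if (k) do.call(rbind, tracts) else
    data.frame(sample_id = character(), chrom = character(),
               start = numeric(), end = numeric())
  list(gm = gm, tracts = tracts)
}

#' Write a simulated fixture directory
#'
#' Emits the files the pipeline reads: a VCF with AA/ANN INFO entries, a
#' sample sheet TSV, an (empty by default) BED mask, a toy GFF3 tiling
#' gene models across the genome, and a truth JSON.
#'
#' @param gm a [genotype_matrix()].
#' @param truth truth list from [simulate_cohorts()] / [plant_roh()];
#'   large per-site vectors are summarised, scalars and planted tracts
#'   are written verbatim.
#' @param outdir output directory (created if needed).
#' @param gene_every place one toy gene every this many bp.
#' @return named vector of written paths, invisibly.
#' @export
write_fixture <- function(gm, truth, outdir, gene_every = 1e6) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(outdir, "sim.vcf"),
             sheet = file.path(outdir, "samples.tsv"),
             mask = file.path(outdir, "mask.bed"),
             gff = file.path(outdir, "genes.gff3"),
             truth = file.path(outdir, "truth.json"))
  write_vcf(gm, paths["vcf"])
  sheet <- data.frame(sample_id = gm$sample_ids,
                      population = gm$populations,
                      year = gm$years, cohort = gm$cohorts)
  utils::write.table(sheet, paths["sheet"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.create(paths["mask"])
  # toy genes tiling each chromosome
  gff <- c("##gff-version 3")
  gi <- 0L
  for (ch in unique(gm$chrom)) {
    mx <- max(gm$pos[gm$chrom == ch])
    starts <- seq(1, mx, by = gene_every)
    for (s in starts) {
      gi <- gi + 1L
      gff <- c(gff, paste(ch, "sim", "gene", s,
                          min(s + round(gene_every / 2), mx), ".", "+",
                          ".", paste0("ID=gene", gi), sep = "\t"))
    }
  }
  writeLines(gff, paths["gff"])
  tr <- truth
  if (length(tr$ancestral_freq) > 10)
    tr$ancestral_freq <- list(n = length(tr$ancestral_freq),
                              mean = mean(tr$ancestral_freq))
  if (length(tr$ancestral_is_ref) > 10)
    tr$ancestral_is_ref <- list(n = length(tr$ancestral_is_ref),
                                fraction_ref = mean(tr$ancestral_is_ref))
  if (length(tr$impact) > 10)
    tr$impact <- as.list(table(tr$impact))
  tr$pop_freq_t1 <- tr$pop_freq_t2 <- NULL
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
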