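test_that("the simulator is deterministic for a fixed seed", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 4, n_sites = 500,
                    n_chrom = 2, chrom_length = 1e6, seed = 21)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a$gm, b$gm)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohorts(sim_config(n_pops = 2, n_per_pop = 4,
                                   n_sites = 500, n_chrom = 2,
                                   chrom_length = 1e6, seed = 22))
  expect_false(identical(a$gm$genotypes, c$gm$genotypes))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(impact_mix = c(SYNONYMOUS = 0.5,
                                         MODERATE = 0.4, HIGH = 0.3)),
               "sum to 1")
  expect_error(sim_config(F = 1), "F must be")
  expect_error(sim_config(n_sites = 0), "positive")
})

test_that("simulated heterozygosity matches the 2p(1-p) expectation", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 20, n_sites = 20000,
                    n_chrom = 2, chrom_length = 1e7, F = 0,
                    timepoints = 1980, seed = 33)
  sim <- simulate_cohorts(cfg)
  p <- sim$truth$pop_freq_t1[, 1]
  expected <- mean(2 * p * (1 - p))
  observed <- mean(sim$gm$genotypes == 1L)
  se <- sqrt(expected * (1 - expected) /
               (length(p) * cfg$n_per_pop))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("Balding-Nichols divergence is recovered by the F_ST estimator", {
  # no-divergence limit
  sim0 <- simulate_cohorts(sim_config(n_pops = 2, n_per_pop = 30,
                                      n_sites = 50000, F = 0,
                                      timepoints = 1980, seed = 41))
  expect_lt(abs(fst_genomewide(sim0$gm, "North", "South")), 0.01)
  # F = 0.10
  sim1 <- simulate_cohorts(sim_config(n_pops = 2, n_per_pop = 30,
                                      n_sites = 50000, F = 0.10,
                                      timepoints = 1980, seed = 42))
  expect_lt(abs(fst_genomewide(sim1$gm, "North", "South") - 0.10), 0.01)
})

test_that("a programmed annual heterozygosity change is recovered end to end", {
  cfg <- sim_config(n_pops = 1, n_per_pop = 15, n_sites = 50000,
                    n_chrom = 2, chrom_length = 2e7,
                    timepoints = c(1980, 2020),
                    annual_het_change = -0.5, seed = 55)
  sim <- simulate_cohorts(cfg)
  gm <- sim$gm
  het <- heterozygosity_per_kb(gm, 1e6)
  h1 <- mean(het[gm$cohorts == "1980"])
  h2 <- mean(het[gm$cohorts == "2020"])
  est <- annual_change(h1, h2, 40)
  expect_lt(abs(est - (-0.5)) / 0.5, 0.20)
})

test_that("category frequency multipliers drive R_xy away from 1", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 15, n_sites = 20000,
                    n_chrom = 5, chrom_length = 5e6, F = 0.02,
                    category_multiplier = list(HIGH = c(1.5, 1)),
                    timepoints = 1980, seed = 60)
  sim <- simulate_cohorts(cfg)
  r <- rxy(sim$gm, "North", "South", "HIGH")
  expect_gt(r$ratio, 1.2)
  expect_gt(r$ci[1], 1)
})

test_that("planting tracts respects the target fraction and records truth", {
  sim <- simulate_cohorts(sim_config(n_pops = 1, n_per_pop = 3,
                                     n_sites = 5000, n_chrom = 2,
                                     chrom_length = 1e7,
                                     timepoints = 1980, seed = 70))
  # target 0: unchanged
  un <- plant_roh(sim$gm, target_fraction = 0, seed = 1)
  expect_identical(un$gm$genotypes, sim$gm$genotypes)
  expect_equal(nrow(un$tracts), 0L)

  pl <- plant_roh(sim$gm, target_fraction = 0.10, tract_mb = c(0.5, 1),
                  seed = 2)
  genome_bp <- sum(tapply(sim$gm$pos, sim$gm$chrom, max))
  for (sid in sim$gm$sample_ids) {
    tr <- pl$tracts[pl$tracts$sample_id == sid, ]
    frac <- sum(tr$end - tr$start + 1) / genome_bp
    expect_gte(frac, 0.09)
    expect_lte(frac, 0.11)     # realised within ~10% of target
    si <- match(sid, pl$gm$sample_ids)
    for (j in seq_len(nrow(tr))) {
      sel <- pl$gm$chrom == tr$chrom[j] & pl$gm$pos >= tr$start[j] &
        pl$gm$pos <= tr$end[j]
      expect_true(all(pl$gm$genotypes[si, sel] %in% c(0L, 2L)))
    }
  }
  expect_error(plant_roh(sim$gm, 0.95), "infeasible")
})

test_that("fixtures round-trip through the readers and the truth JSON parses", {
  sim <- simulate_cohorts(sim_config(n_pops = 2, n_per_pop = 3,
                                     n_sites = 300, n_chrom = 2,
                                     chrom_length = 2e6, seed = 77))
  outdir <- withr::local_tempdir()
  paths <- write_fixture(sim$gm, sim$truth, outdir)
  expect_true(all(file.exists(paths)))
  sheet <- read_sample_sheet(paths["sheet"])
  mask <- read_bed_mask(paths["mask"])
  back <- read_genotypes(paths["vcf"], sheet, mask)
  expect_identical(back$genotypes, sim$gm$genotypes)
  expect_identical(back$impact, sim$gm$impact)
  genes <- read_gene_models(paths["gff"])
  expect_gt(nrow(genes), 0)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$seed, 77)
  expect_equal(sort(names(truth$impact)),
               c("HIGH", "MODERATE", "SYNONYMOUS"))
})
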