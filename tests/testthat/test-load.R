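# fixture: 4 HIGH sites, sample s1 carries derived alleles at 2 of them;
# one extra HIGH site fixed hom-derived everywhere (must be excluded);
# 2 SYNONYMOUS sites for normalisation.
load_fixture <- function() {
  #           s1  s2  s3  s4
  sites <- cbind(
    c(1L, 0L, 0L, 0L),   # HIGH, s1 carrier
    c(2L, 0L, 1L, 0L),   # HIGH, s1 + s3 carriers
    c(0L, 1L, 0L, 0L),   # HIGH, s2 carrier
    c(0L, 0L, 0L, 1L),   # HIGH, s4 carrier
    c(2L, 2L, 2L, 2L),   # HIGH, fixed hom-derived -> removed
    c(1L, 1L, 0L, 2L),   # SYN
    c(0L, 1L, 1L, 0L))   # SYN
  toy_gm(sites, impact = c(rep("HIGH", 5), rep("SYNONYMOUS", 2)),
         populations = c("X", "X", "Y", "Y"))
}

test_that("carrier counts exclude fixed sites and unannotated categories", {
  gm <- load_fixture()
  counts <- load_counts(gm)
  expect_equal(counts$HIGH, c(2L, 1L, 1L, 1L))
  expect_equal(counts$SYNONYMOUS, c(1L, 2L, 1L, 1L))
  # sample order invariance
  perm <- sample(seq_along(gm$sample_ids))
  counts_p <- load_counts(subset_samples(gm, perm))
  expect_equal(counts_p$HIGH[match(counts$sample_id, counts_p$sample_id)],
               counts$HIGH)
  # allele-count mode counts dosage
  expect_equal(load_counts(gm, mode = "alleles")$HIGH, c(3L, 1L, 1L, 1L))
  expect_error(load_counts(toy_gm(matrix(0L, 2, 2))), "annotated")
})

test_that("normalised totals divide by the sample's synonymous count", {
  gm <- load_fixture()
  norm <- normalized_total_load(load_counts(gm))
  expect_equal(norm$HIGH_norm, c(2 / 1, 1 / 2, 1 / 1, 1 / 1))

  tab <- data.frame(sample_id = c("a", "b"), population = "P",
                    HIGH = c(10L, 7L), MODERATE = c(100L, 41L),
                    SYNONYMOUS = c(1000L, 350L))
  class(tab) <- c("load_table", "data.frame")
  n <- normalized_total_load(tab)
  expect_equal(n$HIGH_norm, c(0.01, 0.02))
  expect_equal(n$MODERATE_norm[2], 41 / 350, tolerance = 1e-12)

  tab$SYNONYMOUS[1] <- 0L
  expect_warning(n0 <- normalized_total_load(tab), "synonymous")
  expect_true(is.na(n0$HIGH_norm[1]))
})

test_that("realised load is homozygous-derived over twice segregating sites", {
  # 10 segregating HIGH sites; s1 hom-derived at 3, het at the rest
  g <- matrix(0L, nrow = 3, ncol = 10)
  g[1, 1:3] <- 2L; g[1, 4:10] <- 1L
  g[2, ] <- 1L                       # keeps every site segregating
  gm <- toy_gm(g, impact = "HIGH", populations = c("X", "X", "Y"))
  rl <- realised_load(gm, "HIGH")
  expect_equal(unname(rl["s1"]), 3 / 20)
  expect_equal(unname(rl["s2"]), 0)        # het everywhere
  # hom-derived at every segregating site reaches the 0.5 bound
  g2 <- rbind(rep(2L, 6), rep(1L, 6))
  rl2 <- realised_load(toy_gm(g2, impact = "HIGH"), "HIGH")
  expect_equal(unname(rl2["s1"]), 0.5)
  expect_error(realised_load(toy_gm(matrix(0L, 2, 3), impact = "HIGH"),
                             "HIGH"), "segregating")
})

# R_xy fixture over 4 chromosomes: per chromosome one HIGH and one SYN
# site; HIGH derived frequencies in X are double those in Y, SYN equal.
rxy_fixture <- function() {
  dos <- function(f) {        # 5 diploids with exact dosage sum 10*f
    out <- integer(5)
    left <- round(10 * f)
    for (i in 1:5) { out[i] <- min(2L, left); left <- left - out[i] }
    out
  }
  fY <- c(0.1, 0.2, 0.3, 0.1); fX <- 2 * fY
  fS <- c(0.2, 0.3, 0.4, 0.5)
  cols <- list(); impact <- character(); chrom <- character()
  pos <- integer()
  for (i in 1:4) {
    cols <- c(cols, list(c(dos(fX[i]), dos(fY[i]))),
              list(c(dos(fS[i]), dos(fS[i]))))
    impact <- c(impact, "HIGH", "SYNONYMOUS")
    chrom <- c(chrom, rep(paste0("chr", i), 2))
    pos <- c(pos, 1000L, 2000L)
  }
  toy_gm(do.call(cbind, cols), pos = pos, chrom = chrom,
         populations = rep(c("X", "Y"), each = 5), impact = impact)
}

test_that("R_xy is 1 for identical frequencies and reciprocal by construction", {
  # identical derived-allele frequencies in X and Y at every site
  half <- cbind(c(1L, 1L, 0L, 0L), c(2L, 0L, 1L, 1L), c(1L, 0L, 1L, 0L),
                c(0L, 1L, 0L, 1L), c(2L, 1L, 1L, 2L), c(1L, 1L, 1L, 1L))
  g <- rbind(half, half)     # population Y mirrors X exactly
  gm <- toy_gm(g, pos = c(1e3, 2e3, 1e3, 2e3, 1e3, 2e3),
               chrom = rep(c("c1", "c2", "c3"), each = 2),
               populations = rep(c("X", "Y"), each = 4),
               impact = rep(c("HIGH", "SYNONYMOUS"), 3))
  r <- rxy(gm, "X", "Y", "HIGH")
  expect_equal(r$ratio, 1, tolerance = 1e-12)
  expect_true(r$ci[1] <= r$ratio && r$ratio <= r$ci[2])

  gm2 <- rxy_fixture()
  fwd <- rxy(gm2, "X", "Y", "HIGH", blocks = 4)
  rev <- rxy(gm2, "Y", "X", "HIGH", blocks = 4)
  expect_equal(fwd$ratio * rev$ratio, 1, tolerance = 1e-12)
})

test_that("R_xy matches the brute-force sum on the doubled-frequency fixture", {
  gm <- rxy_fixture()
  # frozen spreadsheet-style evaluation:
  # num = sum fX (1 - fY) = .2*.9 + .4*.8 + .6*.7 + .2*.9 = 1.10
  # den = sum fY (1 - fX) = .1*.8 + .2*.6 + .3*.4 + .1*.8 = 0.40
  # neutral ratio = 1  =>  R_xy = 2.75
  r <- rxy(gm, "X", "Y", "HIGH", blocks = 4)
  expect_equal(r$ratio, 2.75, tolerance = 1e-12)
  expect_equal(r$n_blocks, 4L)
  expect_error(rxy(gm, "X", "Y", "HIGH", blocks = 2), "blocks")
})

test_that("jackknife interval covers 1 under no category-specific shift", {
  hits <- 0L
  for (s in 1:100) {
    # 20 chromosomes give the block jackknife enough blocks for its
    # normal-theory interval to be trustworthy
    sim <- simulate_cohorts(sim_config(n_pops = 2, n_per_pop = 8,
                                       n_sites = 3000, n_chrom = 20,
                                       chrom_length = 1e6, F = 0.05,
                                       timepoints = 1980, seed = 1000 + s))
    r <- rxy(sim$gm, "North", "South", "HIGH")
    if (r$ci[1] <= 1 && 1 <= r$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})
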