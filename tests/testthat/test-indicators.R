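test_that("annual change is the linear annualised percent difference", {
  expect_equal(annual_change(0.3, 0.3, 40), 0)
  expect_equal(annual_change(0.30, 0.27, 40), -0.25)
  expect_equal(annual_change(0.1, 0.2, 100), 1.0)
  expect_error(annual_change(0, 0.1, 10), "positive")
  expect_error(annual_change(0.1, 0.2, 0), "positive")
})

test_that("delta-H classification gates on significance then bands the loss rate", {
  set.seed(31)
  base <- rnorm(20, 10, 0.05)
  # large but non-significant difference (huge spread) -> Acceptable
  noisy1 <- rnorm(10, 10, 8); noisy2 <- rnorm(10, 9, 8)
  r <- classify_delta_h(noisy1, noisy2, years = 40)
  expect_equal(r$status, "Acceptable")

  # significant losses at programmed annual rates hit the stated bands
  r_warn <- classify_delta_h(base, base * (1 - 0.002 * 40), 40)
  expect_equal(r_warn$status, "Warning")      # 0.2 %/yr loss
  r_alarm <- classify_delta_h(base, base * (1 - 0.004 * 40), 40)
  expect_equal(r_alarm$status, "Alarm")       # 0.4 %/yr loss
  r_ok <- classify_delta_h(base, base * (1 - 0.0004 * 40), 40)
  expect_equal(r_ok$status, "Acceptable")     # 0.04 %/yr loss

  # F_ROH direction: an increase is the loss
  r_froh <- classify_delta_h(base, base * (1 + 0.004 * 40), 40,
                             direction = "loss-when-increasing")
  expect_equal(r_froh$status, "Alarm")
  # and a significant gain in heterozygosity is not an alarm
  r_gain <- classify_delta_h(base, base * (1 + 0.004 * 40), 40)
  expect_equal(r_gain$status, "Acceptable")

  expect_true(all(c("t_p", "wilcoxon_p", "concordant") %in%
                    names(r_warn)))
  expect_error(classify_delta_h(1, c(1, 2), 10), "samples")
})

test_that("the annual-loss truth table over band boundaries is exact", {
  # significance is guaranteed (tiny spread), loss rate programmed exactly
  base <- rep(c(9.999, 10.001), 10)
  for (case in list(list(0.049, "Acceptable"), list(0.05, "Acceptable"),
                    list(0.051, "Warning"), list(0.299, "Warning"),
                    list(0.3, "Warning"), list(0.301, "Alarm"),
                    list(1, "Alarm"))) {
    rate <- case[[1]]
    t2 <- base * (1 - rate / 100 * 40)
    r <- classify_delta_h(base, t2, 40)
    expect_lt(r$t_p, 0.05)
    expect_equal(r$loss_pct_per_year, rate, tolerance = 1e-8)
    expect_equal(r$status, case[[2]])
  }
})

test_that("Ne classification matches the stated thresholds and is monotone", {
  expect_equal(classify_ne(600), "Acceptable")
  expect_equal(classify_ne(120), "Warning")
  expect_equal(classify_ne(30), "Alarm")
  # boundary cases: 500 is Acceptable, 50 falls to Alarm
  expect_equal(classify_ne(500), "Acceptable")
  expect_equal(classify_ne(499.999), "Warning")
  expect_equal(classify_ne(50.001), "Warning")
  expect_equal(classify_ne(50), "Alarm")
  expect_error(classify_ne(0), "positive")
  # monotone: status never improves as ne decreases
  rank <- c(Acceptable = 3, Warning = 2, Alarm = 1)
  ne_grid <- sort(c(10^seq(0, 4, length.out = 40), 50, 500),
                  decreasing = TRUE)
  st <- rank[classify_ne(ne_grid)]
  expect_true(all(diff(st) <= 0))
})

test_that("F_ST converts to island-model migrant numbers", {
  expect_equal(fst_to_migrants(0.2), 1.0)
  expect_equal(fst_to_migrants(0.05), 4.75)
  expect_lt(fst_to_migrants(0.999), 0.001)   # Nm -> 0 as F_ST -> 1
  expect_error(fst_to_migrants(0), "in \\(0, 1\\)")
  expect_error(fst_to_migrants(1), "in \\(0, 1\\)")
})

test_that("delta-F_ST classification follows extinction, significance and Nm bands", {
  tr <- function(values) {
    d <- data.frame(chrom = "chr1",
                    start = (seq_along(values) - 1L) * 50000L,
                    end = seq_along(values) * 50000L,
                    n_sites = 10L, value = values)
    class(d) <- c("diversity_track", "data.frame")
    d
  }
  v1 <- seq(0.041, 0.059, length.out = 20)   # mean exactly 0.05

  # extinction dominates everything
  r_ext <- classify_delta_fst(tr(v1), tr(v1 + 0.05),
                              populations_maintained = FALSE)
  expect_equal(r_ext$status, "Alarm")

  # no significant change -> Acceptable
  set.seed(8)
  jitter <- rnorm(20, 0, 1e-4)
  r_ns <- classify_delta_fst(tr(v1), tr(v1 + jitter))
  expect_equal(r_ns$status, "Acceptable")

  # mean F_ST 0.05 -> 0.10: Nm 4.75 -> 2.25, -52.6% migration -> Alarm
  r_alarm <- classify_delta_fst(tr(v1), tr(v1 + 0.05))
  expect_equal(r_alarm$nm_t1, 4.75, tolerance = 1e-6)
  expect_equal(r_alarm$nm_t2, 2.25, tolerance = 1e-6)
  expect_equal(r_alarm$nm_change_pct, -52.63158, tolerance = 1e-5)
  expect_equal(r_alarm$status, "Alarm")

  # moderate significant decrease in migration -> Warning band
  v2 <- v1 * 1.28                             # mean 0.064, Nm 3.656 (-23%)
  r31 <- classify_delta_fst(tr(v1), tr(v1 * 1.32))  # Nm -26.6%
  expect_equal(r31$status, "Warning")

  # significant increase in migration >= 100% -> Alarm
  r_up <- classify_delta_fst(tr(v1), tr(v1 * 0.45)) # Nm +130%
  expect_equal(r_up$status, "Alarm")

  expect_error(classify_delta_fst(tr(v1[1:5]), tr(v1[1:5] + 0.01)),
               "10 shared")
})
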