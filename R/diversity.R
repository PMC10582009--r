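#' Per-sample heterozygosity per kilobase
#'
#' Direct count of heterozygous calls per sample, scaled to a rate per
#' 1,000 bp of callable sequence.
#'
#' @param gm a [genotype_matrix()].
#' @param callable_bp callable bases per sample: a single number applied
#'   to all samples, or a vector named by (or ordered as) the samples.
#' @return named numeric vector, heterozygous sites per kb.
#' @export
heterozygosity_per_kb <- function(gm, callable_bp) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(callable_bp <= 0)) stop("callable_bp must be positive")
  n_samp <- nrow(gm$genotypes)
  cb <- rep_len(as.numeric(callable_bp), n_samp)
  if (!is.null(names(callable_bp)) && length(callable_bp) == n_samp)
    cb <- as.numeric(callable_bp[gm$sample_ids])
  het <- rowSums(gm$genotypes == 1L)
  stats::setNames(1000 * het / cb, gm$sample_ids)
}

# tile [0, ceiling(max_pos / window) * window) in half-open 0-based windows
tile_windows <- function(chrom, pos, window_bp) {
  out <- lapply(unique(chrom), function(ch) {
    mx <- max(pos[chrom == ch])
    starts <- seq(0L, mx - 1L, by = window_bp)
    data.frame(chrom = ch, start = starts, end = starts + window_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# sliding half-open 0-based windows covering positions on each chromosome
slide_windows <- function(chrom, pos, window_bp, step_bp) {
  out <- lapply(unique(chrom), function(ch) {
    mx <- max(pos[chrom == ch])
    starts <- seq(0L, max(0L, mx - 1L), by = step_bp)
    data.frame(chrom = ch, start = starts, end = starts + window_bp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# indices of sites in each window (1-based pos vs half-open 0-based window)
window_site_index <- function(chrom, pos, windows) {
  lapply(seq_len(nrow(windows)), function(i) {
    which(chrom == windows$chrom[i] &
            pos > windows$start[i] & pos <= windows$end[i])
  })
}

#' Windowed nucleotide diversity
#'
#' Per-site diversity is the expected pairwise difference among called
#' allele copies, `2 * c_ref * c_alt / (n * (n - 1))`; window values sum
#' the per-site contributions and divide by window length (or by supplied
#' per-window callable bases).
#'
#' @param gm a [genotype_matrix()].
#' @param population population label to compute within (>= 2 samples).
#' @param window_bp non-overlapping window size in bp (default 50 kb).
#' @param callable_bp optional per-window callable bases (recycled);
#'   default uses the full window length as denominator.
#' @return data.frame (class `diversity_track`) with columns chrom,
#'   start, end (half-open, 0-based), n_sites, value.
#' @export
pi_windows <- function(gm, population, window_bp = 50000,
                       callable_bp = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sel <- gm$populations == population
  if (sum(sel) < 2) stop("population '", population, "' has < 2 samples")
  g <- gm$genotypes[sel, , drop = FALSE]
  called <- g != -1L
  n <- 2 * colSums(called)
  c_alt <- colSums((g == 1L)) + 2 * colSums(g == 2L)
  c_ref <- n - c_alt
  pi_site <- ifelse(n >= 2, 2 * c_ref * c_alt / (n * (n - 1)), 0)
  win <- tile_windows(gm$chrom, gm$pos, window_bp)
  idx <- window_site_index(gm$chrom, gm$pos, win)
  win$n_sites <- vapply(idx, length, integer(1))
  denom <- if (is.null(callable_bp)) window_bp
           else rep_len(callable_bp, nrow(win))
  win$value <- vapply(idx, function(i) sum(pi_site[i]), numeric(1)) / denom
  attr(win, "population") <- population
  attr(win, "statistic") <- "pi"
  class(win) <- c("diversity_track", "data.frame")
  win
}

# Weir-Cockerham per-site variance components for two populations.
# Inputs are vectors over sites: diploid sample sizes n1/n2 (called),
# alt-allele frequencies p1/p2, observed het frequencies h1/h2.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Hudson per-site numerator/denominator (allele-count form), for the
# ratio-of-averages estimator. n1/n2 are allele (not diploid) counts.
hudson_components <- function(n1, n2, p1, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

# per-site frequency summaries for one population's genotype submatrix
pop_site_stats <- function(g) {
  called <- g != -1L
  n <- colSums(called)                       # diploid individuals called
  alt <- colSums(g == 1L) + 2 * colSums(g == 2L)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(g == 1L) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Windowed F_ST between two populations
#'
#' Weir-Cockerham variance components `a`, `b`, `c` are computed per site
#' from genotype counts; the window value is the weighted ratio
#' `sum(a) / sum(a + b + c)`. The Hudson option uses the allele-frequency
#' ratio-of-averages estimator. Negative values are retained. Windows
#' with no informative site get `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB distinct population labels, each with >= 2 samples.
#' @param window_bp window size in bp (default 50 kb).
#' @param step_bp step in bp (default = `window_bp`, i.e. non-overlapping;
#'   set 10 kb for the sliding selection scan). Must be <= `window_bp`.
#' @param estimator "weir-cockerham" (default) or "hudson".
#' @return data.frame (class `diversity_track`) with columns chrom,
#'   start, end, n_sites, value.
#' @export
fst_windows <- function(gm, popA, popB, window_bp = 50000,
                        step_bp = window_bp,
                        estimator = c("weir-cockerham", "hudson")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  estimator <- match.arg(estimator)
  if (identical(popA, popB)) stop("popA and popB must differ")
  if (step_bp > window_bp) stop("step_bp must be <= window_bp")
  sA <- gm$populations == popA
  sB <- gm$populations == popB
  if (sum(sA) < 2 || sum(sB) < 2)
    stop("both populations need >= 2 samples")
  stA <- pop_site_stats(gm$genotypes[sA, , drop = FALSE])
  stB <- pop_site_stats(gm$genotypes[sB, , drop = FALSE])
  info <- stA$n >= 1 & stB$n >= 1
  if (estimator == "weir-cockerham") {
    comp <- wc_components(stA$n, stB$n, stA$p, stB$p, stA$h, stB$h)
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    comp <- hudson_components(2 * stA$n, 2 * stB$n, stA$p, stB$p)
    num <- comp$num
    den <- comp$den
  }
  num[!info] <- NA_real_
  den[!info] <- NA_real_
  win <- slide_windows(gm$chrom, gm$pos, window_bp, step_bp)
  idx <- window_site_index(gm$chrom, gm$pos, win)
  win$n_sites <- vapply(idx, function(i) sum(info[i]), integer(1))
  win$value <- vapply(idx, function(i) {
    i <- i[info[i]]
    if (!length(i)) return(NA_real_)
    s <- sum(den[i])
    if (s == 0) return(NA_real_)
    sum(num[i]) / s
  }, numeric(1))
  attr(win, "populations") <- c(popA, popB)
  attr(win, "statistic") <- paste0("fst_", estimator)
  class(win) <- c("diversity_track", "data.frame")
  win
}

#' Genome-wide weighted F_ST
#'
#' The same per-site components as [fst_windows()], pooled over all
#' informative sites (one ratio of sums).
#'
#' @inheritParams fst_windows
#' @return a single numeric value.
#' @export
fst_genomewide <- function(gm, popA, popB,
                           estimator = c("weir-cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  if (identical(popA, popB)) stop("popA and popB must differ")
  sA <- gm$populations == popA
  sB <- gm$populations == popB
  if (sum(sA) < 2 || sum(sB) < 2)
    stop("both populations need >= 2 samples")
  stA <- pop_site_stats(gm$genotypes[sA, , drop = FALSE])
  stB <- pop_site_stats(gm$genotypes[sB, , drop = FALSE])
  info <- stA$n >= 1 & stB$n >= 1
  if (estimator == "weir-cockerham") {
    comp <- wc_components(stA$n, stB$n, stA$p, stB$p, stA$h, stB$h)
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    comp <- hudson_components(2 * stA$n, 2 * stB$n, stA$p, stB$p)
    num <- comp$num
    den <- comp$den
  }
  sum(num[info]) / sum(den[info])
}

#' @export
print.diversity_track <- function(x, ...) {
  cat(sprintf("diversity_track (%s): %d windows, %d with data\n",
              attr(x, "statistic") %||% "?", nrow(x),
              sum(!is.na(x$value))))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
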