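#' Parameters for scanning-window ROH detection
#'
#' Defaults follow the strict PLINK-style parameterisation used for
#' conservative ROH calling: 100-SNP scanning windows allowing at most
#' 1 heterozygous and 5 missing calls, a 5% homozygous-window fraction
#' to flag a SNP, and segment filters of >= 25 SNPs, >= 100 kb span,
#' >= 1 SNP per 50 kb, <= 1,000 kb between neighbouring SNPs and
#' <= 750 heterozygous calls per segment.
#'
#' @param window_snp scanning window size in SNPs.
#' @param window_het max heterozygous calls for a homozygous window.
#' @param window_missing max missing calls for a homozygous window.
#' @param window_threshold min fraction of homozygous windows covering a
#'   SNP for the SNP to be in a homozygous segment.
#' @param min_snp minimum SNPs per emitted segment.
#' @param min_kb minimum segment span in kb.
#' @param density_kb_per_snp maximum kb per SNP (density filter).
#' @param max_gap_kb split candidate runs at inter-SNP gaps above this.
#' @param max_het_in_segment maximum heterozygous calls per segment.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 100, window_het = 1,
                       window_missing = 5, window_threshold = 0.05,
                       min_snp = 25, min_kb = 100,
                       density_kb_per_snp = 50, max_gap_kb = 1000,
                       max_het_in_segment = 750) {
  p <- list(window_snp = window_snp, window_het = window_het,
            window_missing = window_missing,
            window_threshold = window_threshold,
            min_snp = min_snp, min_kb = min_kb,
            density_kb_per_snp = density_kb_per_snp,
            max_gap_kb = max_gap_kb,
            max_het_in_segment = max_het_in_segment)
  if (any(unlist(p) <= 0)) stop("all ROH parameters must be positive")
  if (p$window_threshold > 1) stop("window_threshold must be in (0,1]")
  structure(p, class = "roh_params")
}

# per-SNP pass flag for one sample on one chromosome.
# g: genotype codes at the chromosome's SNPs, in position order.
roh_pass_snps <- function(g, params) {
  S <- length(g)
  W <- params$window_snp
  n_win <- S - W + 1L
  if (n_win < 1L) return(logical(S))
  het <- as.integer(g == 1L)
  mis <- as.integer(g == -1L)
  csh <- c(0L, cumsum(het))
  csm <- c(0L, cumsum(mis))
  j <- seq_len(n_win)                     # window j covers SNPs j..j+W-1
  hom_win <- (csh[j + W] - csh[j]) <= params$window_het &
             (csm[j + W] - csm[j]) <= params$window_missing
  csw <- c(0L, cumsum(as.integer(hom_win)))
  idx <- seq_len(S)
  lo <- pmax(1L, idx - W + 1L)            # first window covering SNP
  hi <- pmin(idx, n_win)                  # last window covering SNP
  covered <- hi >= lo
  frac <- rep(0, S)
  frac[covered] <- (csw[hi[covered] + 1L] - csw[lo[covered]]) /
    (hi[covered] - lo[covered] + 1L)
  covered & frac >= params$window_threshold
}

# maximal runs of TRUE in a logical vector -> matrix of (start, end) indices
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Call runs of homozygosity
#'
#' Scanning-window ROH detection per sample per chromosome: (1) each
#' window of `window_snp` consecutive SNPs is homozygous iff it has at
#' most `window_het` heterozygous and `window_missing` missing calls;
#' (2) a SNP is flagged iff at least `window_threshold` of the
#' fully-fitting windows covering it are homozygous; (3) maximal runs of
#' flagged SNPs are split at inter-SNP gaps above `max_gap_kb`; (4) a
#' run is emitted iff it satisfies the span, SNP-count, density and
#' heterozygote-count filters. Segment boundaries are the outermost
#' flagged SNP positions.
#'
#' @param gm a [genotype_matrix()] (positions sorted per chromosome).
#' @param params a [roh_params()] object.
#' @return data.frame (class `roh_segments`) with columns sample_id,
#'   chrom, start, end (1-based inclusive), length_kb, length_mb,
#'   n_snps, n_het.
#' @export
call_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  res <- list(); k <- 0L
  for (ch in unique(gm$chrom)) {
    sel <- which(gm$chrom == ch)
    pos <- gm$pos[sel]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions not sorted on chromosome ", ch)
    for (si in seq_along(gm$sample_ids)) {
      g <- gm$genotypes[si, sel]
      pass <- roh_pass_snps(g, params)
      if (!any(pass)) next
      runs <- true_runs(pass)
      for (ri in seq_len(nrow(runs))) {
        a <- runs[ri, 1]; b <- runs[ri, 2]
        # split at gaps > max_gap_kb
        ii <- a:b
        gaps <- which(diff(pos[ii]) > params$max_gap_kb * 1000)
        cut_start <- c(a, a + gaps)
        cut_end <- c(a + gaps - 1L, b)
        for (ci in seq_along(cut_start)) {
          s <- cut_start[ci]; e <- cut_end[ci]
          n_snps <- e - s + 1L
          span_bp <- pos[e] - pos[s] + 1L
          n_het <- sum(g[s:e] == 1L)
          if (span_bp < params$min_kb * 1000) next
          if (n_snps < params$min_snp) next
          if (span_bp / 1000 / n_snps > params$density_kb_per_snp) next
          if (n_het > params$max_het_in_segment) next
          k <- k + 1L
          res[[k]] <- data.frame(
            sample_id = gm$sample_ids[si], chrom = ch,
            start = pos[s], end = pos[e],
            length_kb = span_bp / 1000, length_mb = span_bp / 1e6,
            n_snps = n_snps, n_het = n_het,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (k) do.call(rbind, res) else
    data.frame(sample_id = character(), chrom = character(),
               start = integer(), end = integer(),
               length_kb = numeric(), length_mb = numeric(),
               n_snps = integer(), n_het = integer())
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Fraction of the autosomal genome covered by ROH per sample,
#' optionally restricted to segments above a length threshold.
#'
#' @param segments output of [call_roh()].
#' @param autosomal_bp total autosomal genome length in bp.
#' @param samples sample ids to report (default: those present in
#'   `segments`); samples without segments get 0.
#' @param min_length_mb only count segments at least this long
#'   (e.g. 0.1 for ROH >= 100 kb, 2 for ROH >= 2 Mb).
#' @return named numeric vector of F_ROH values in `[0, 1]`.
#' @export
froh <- function(segments, autosomal_bp, samples = NULL,
                 min_length_mb = 0) {
  if (autosomal_bp <= 0) stop("autosomal_bp must be positive")
  if (is.null(samples)) samples <- sort(unique(segments$sample_id))
  seg <- segments[segments$length_mb >= min_length_mb, , drop = FALSE]
  # overlap check per sample+chromosome (the caller never emits overlaps)
  if (nrow(seg)) {
    sp <- split(seg, paste(seg$sample_id, seg$chrom))
    for (x in sp) {
      x <- x[order(x$start), , drop = FALSE]
      if (nrow(x) > 1 && any(x$start[-1] <= x$end[-nrow(x)]))
        stop("overlapping ROH segments for sample ", x$sample_id[1])
    }
  }
  tot <- tapply(as.numeric(seg$end - seg$start + 1), seg$sample_id, sum)
  out <- stats::setNames(rep(0, length(samples)), samples)
  hit <- intersect(names(tot), samples)
  out[hit] <- tot[hit] / autosomal_bp
  out
}

#' Parameters for dating inbreeding from ROH length
#'
#' @param r recombination rate in cM/Mb (default 1.04, a red-deer
#'   estimate used for cervids lacking a linkage map).
#' @param generation_time generation time in years (default 7).
#' @return list of class `roh_timing_params`.
#' @export
roh_timing_params <- function(r = 1.04, generation_time = 7) {
  if (r <= 0 || generation_time <= 0)
    stop("r and generation_time must be positive")
  structure(list(r = r, generation_time = generation_time),
            class = "roh_timing_params")
}

#' Date inbreeding events from ROH length
#'
#' The expected age of the inbreeding event generating a ROH of length
#' L Mb is `g = 100 / (2 r L)` generations, with `r` the recombination
#' rate in cM/Mb; years are `g` times the generation time. Values are
#' reported unrounded.
#'
#' @param length_mb ROH length(s) in Mb (positive).
#' @param timing a [roh_timing_params()] object.
#' @return data.frame with columns length_mb, generations, years.
#' @export
roh_age <- function(length_mb, timing = roh_timing_params()) {
  if (any(length_mb <= 0)) stop("length_mb must be positive")
  g <- 100 / (2 * timing$r * length_mb)
  data.frame(length_mb = length_mb, generations = g,
             years = g * timing$generation_time)
}
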