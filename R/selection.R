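#' Z-transform a windowed F_ST track and flag outlier windows
#'
#' `z = (fst - mean) / sd` with mean and (sample, n-1) standard deviation
#' computed over all non-missing windows. Outliers are windows with
#' `z > threshold_sd` (one-sided upper, the default) or
#' `|z| > threshold_sd` when `two_sided = TRUE`. Missing windows are
#' excluded from the moments and can never be outliers.
#'
#' @param track a `diversity_track` from [fst_windows()].
#' @param threshold_sd Z-score cut-off (default 5).
#' @param two_sided flag both tails instead of the upper tail only.
#' @return the track (class `fst_window_track`) with added columns z and
#'   outlier, and attributes mu_fst / sigma_fst.
#' @export
zfst <- function(track, threshold_sd = 5, two_sided = FALSE) {
  v <- track$value
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("need >= 2 non-missing windows")
  mu <- mean(v[ok])
  sigma <- stats::sd(v[ok])
  if (sigma == 0) stop("degenerate track: zero variance in window F_ST")
  track$z <- (v - mu) / sigma
  track$outlier <- !is.na(track$z) &
    (if (two_sided) abs(track$z) else track$z) > threshold_sd
  attr(track, "mu_fst") <- mu
  attr(track, "sigma_fst") <- sigma
  attr(track, "threshold_sd") <- threshold_sd
  class(track) <- unique(c("fst_window_track", class(track)))
  track
}

#' Intersect outlier windows with gene models
#'
#' Reports each gene whose span overlaps at least one outlier window by
#' at least 1 bp, deduplicated and sorted by chromosome then start.
#' Windows are half-open 0-based; gene spans are compared on the same
#' half-open convention (a gene starting exactly at a window's end does
#' not overlap it).
#'
#' @param outliers an `fst_window_track` from [zfst()] (only rows with
#'   `outlier == TRUE` are used), or any window data.frame with chrom,
#'   start, end.
#' @param genes gene models from [read_gene_models()].
#' @return data.frame gene_id, chrom, start, end, n_hit_windows.
#' @export
intersect_genes <- function(outliers, genes) {
  win <- if (!is.null(outliers$outlier))
    outliers[outliers$outlier, , drop = FALSE] else outliers
  if (!nrow(win) || !nrow(genes))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_hit_windows = integer()))
  hits <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    same <- win$chrom == genes$chrom[i]
    hits[i] <- sum(same & genes$start[i] < win$end &
                     genes$end[i] > win$start)
  }
  out <- genes[hits > 0, c("gene_id", "chrom", "start", "end"),
               drop = FALSE]
  out$n_hit_windows <- hits[hits > 0]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
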