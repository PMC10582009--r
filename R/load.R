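# categories that enter load accounting
LOAD_CATEGORIES <- c("HIGH", "MODERATE", "SYNONYMOUS")

# sites usable for load statistics: annotated in a load category,
# orientable (ancestral allele known) and not fixed hom-derived in every
# sample with a call.
load_site_filter <- function(gm) {
  d <- derived_dosage(gm)
  usable <- gm$impact %in% LOAD_CATEGORIES & !is.na(gm$ancestral_is_ref)
  n_called <- colSums(!is.na(d))
  fixed <- n_called > 0 & colSums(d == 2, na.rm = TRUE) == n_called
  list(dosage = d, keep = usable & n_called > 0 & !fixed)
}

#' Per-sample impact-category carrier counts
#'
#' After removing sites fixed homozygous-derived in all individuals,
#' counts per sample and category the sites carrying at least one
#' derived allele (`mode = "sites"`, the default) or the summed derived
#' allele dosage (`mode = "alleles"`). OTHER/UNANNOTATED sites and sites
#' without ancestral orientation are ignored.
#'
#' @param gm a [genotype_matrix()] with impacts and ancestral orientation.
#' @param mode "sites" or "alleles".
#' @return data.frame (class `load_table`) with one row per sample and
#'   columns sample_id, population, HIGH, MODERATE, SYNONYMOUS.
#' @export
load_counts <- function(gm, mode = c("sites", "alleles")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mode <- match.arg(mode)
  f <- load_site_filter(gm)
  if (!any(gm$impact %in% LOAD_CATEGORIES))
    stop("no annotated (HIGH/MODERATE/SYNONYMOUS) sites")
  d <- f$dosage[, f$keep, drop = FALSE]
  imp <- gm$impact[f$keep]
  out <- data.frame(sample_id = gm$sample_ids,
                    population = gm$populations,
                    stringsAsFactors = FALSE)
  for (cat in LOAD_CATEGORIES) {
    dc <- d[, imp == cat, drop = FALSE]
    out[[cat]] <- if (mode == "sites")
      rowSums(dc >= 1, na.rm = TRUE) else rowSums(dc, na.rm = TRUE)
  }
  class(out) <- c("load_table", "data.frame")
  out
}

#' Synonymous-normalised total load
#'
#' Divides each sample's HIGH and MODERATE counts by its SYNONYMOUS
#' count, correcting for mapping/annotation bias. Samples with a zero
#' synonymous count get `NA` values.
#'
#' @param counts a `load_table` from [load_counts()].
#' @return the table with added columns HIGH_norm, MODERATE_norm.
#' @export
normalized_total_load <- function(counts) {
  stopifnot(inherits(counts, "load_table"))
  syn <- counts$SYNONYMOUS
  zero <- syn == 0
  if (any(zero))
    warning("synonymous count 0 for: ",
            paste(counts$sample_id[zero], collapse = ", "),
            "; normalised values set to NA")
  counts$HIGH_norm <- ifelse(zero, NA_real_, counts$HIGH / syn)
  counts$MODERATE_norm <- ifelse(zero, NA_real_, counts$MODERATE / syn)
  counts
}

#' Per-sample realised load
#'
#' Number of sites of a category where the sample is homozygous-derived,
#' divided by twice the number of segregating sites of that category
#' (segregation assessed over all samples after fixed-site removal).
#' Bounded in `[0, 0.5]`.
#'
#' @param gm a [genotype_matrix()].
#' @param category one of "HIGH", "MODERATE", "SYNONYMOUS".
#' @return named numeric vector per sample.
#' @export
realised_load <- function(gm, category) {
  stopifnot(inherits(gm, "genotype_matrix"))
  category <- match.arg(category, LOAD_CATEGORIES)
  f <- load_site_filter(gm)
  keep <- f$keep & gm$impact == category
  d <- f$dosage[, keep, drop = FALSE]
  ac <- colSums(d, na.rm = TRUE)
  nmax <- 2 * colSums(!is.na(d))
  segregating <- ac > 0 & ac < nmax
  n_seg <- sum(segregating)
  if (n_seg == 0)
    stop("no segregating sites in category ", category)
  hom <- rowSums(d[, segregating, drop = FALSE] == 2, na.rm = TRUE)
  stats::setNames(hom / (2 * n_seg), gm$sample_ids)
}

# contiguous genomic block index per site: `blocks` blocks spread over
# chromosomes proportionally to their site counts (order-preserving).
site_blocks <- function(chrom, pos, blocks = NULL) {
  chroms <- unique(chrom)
  if (is.null(blocks)) return(match(chrom, chroms))
  n <- length(chrom)
  # cut the site sequence (already grouped/sorted per chromosome) into
  # `blocks` contiguous, nearly equal chunks
  ceiling(seq_along(chrom) / n * blocks)
}

#' R_xy: relative derived-allele frequency ratio between populations
#'
#' For sites of a category with derived-allele frequencies f_X and f_Y,
#' `L(X not Y) = sum f_X (1 - f_Y)` and `L(Y not X) = sum f_Y (1 - f_X)`;
#' the raw ratio `L(X not Y) / L(Y not X)` is divided by the same ratio
#' on neutral (default synonymous) sites. A ratio of 1 means no frequency
#' difference; < 1 a deficit and > 1 an excess in X relative to Y.
#' Uncertainty by delete-one block jackknife over contiguous genomic
#' blocks (default one block per chromosome).
#'
#' @param gm a [genotype_matrix()].
#' @param popX,popY population labels.
#' @param category variant category of interest ("HIGH" or "MODERATE").
#' @param neutral_category normalising category (default "SYNONYMOUS");
#'   `NULL` for the unnormalised ratio.
#' @param blocks number of contiguous genomic blocks for the jackknife;
#'   default `NULL` uses one block per chromosome.
#' @return list of class `rxy_result`: category, ratio, se, ci (95%),
#'   n_blocks, n_sites.
#' @export
rxy <- function(gm, popX, popY, category,
                neutral_category = "SYNONYMOUS", blocks = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  category <- match.arg(category, LOAD_CATEGORIES)
  selX <- gm$populations == popX
  selY <- gm$populations == popY
  if (!any(selX) || !any(selY)) stop("both populations must be non-empty")
  f <- load_site_filter(gm)
  d <- f$dosage
  fX <- colMeans(d[selX, , drop = FALSE], na.rm = TRUE) / 2
  fY <- colMeans(d[selY, , drop = FALSE], na.rm = TRUE) / 2
  ok <- f$keep & !is.na(fX) & !is.na(fY)
  blk <- site_blocks(gm$chrom, gm$pos, blocks)

  ratio_on <- function(use) {
    num <- sum(fX[use] * (1 - fY[use]))
    den <- sum(fY[use] * (1 - fX[use]))
    if (den == 0 || num == 0) return(NA_real_)
    num / den
  }
  full_ratio <- function(drop_block = NULL) {
    use <- ok & gm$impact == category
    if (!is.null(drop_block)) use <- use & blk != drop_block
    r <- ratio_on(use)
    if (!is.null(neutral_category)) {
      usen <- ok & gm$impact == neutral_category
      if (!is.null(drop_block)) usen <- usen & blk != drop_block
      rn <- ratio_on(usen)
      r <- r / rn
    }
    r
  }
  point <- full_ratio()
  if (is.na(point)) stop("R_xy undefined: zero numerator or denominator")

  used_blocks <- unique(blk[ok & (gm$impact == category |
    (!is.null(neutral_category) & gm$impact == neutral_category))])
  if (length(used_blocks) < 3)
    stop("fewer than 3 non-empty jackknife blocks")
  loo <- vapply(used_blocks, full_ratio, numeric(1))
  loo <- loo[!is.na(loo)]
  B <- length(loo)
  if (B < 3) stop("fewer than 3 non-empty jackknife blocks")
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  structure(list(category = category, popX = popX, popY = popY,
                 ratio = point, se = se,
                 ci = c(point - 1.96 * se, point + 1.96 * se),
                 n_blocks = B,
                 n_sites = sum(ok & gm$impact == category)),
            class = "rxy_result")
}

#' @export
print.rxy_result <- function(x, ...) {
  cat(sprintf(
    "R_xy (%s, %s vs %s): %.4f (95%% CI %.4f-%.4f; SE %.4f; %d blocks, %d sites)\n",
    x$category, x$popX, x$popY, x$ratio, x$ci[1], x$ci[2], x$se,
    x$n_blocks, x$n_sites))
  invisible(x)
}
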