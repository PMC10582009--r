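#' Impact category levels, from most to least severe
#'
#' Severity order used when several annotations hit one site:
#' HIGH > MODERATE > SYNONYMOUS > OTHER > UNANNOTATED.
#' @export
IMPACT_LEVELS <- c("HIGH", "MODERATE", "SYNONYMOUS", "OTHER", "UNANNOTATED")

#' Construct a genotype matrix
#'
#' The central in-memory container: biallelic sites for a set of samples,
#' with per-sample population/cohort metadata and per-site annotation.
#' Genotypes are coded 0 (hom-reference), 1 (heterozygous), 2 (hom-alternate)
#' and -1 (missing).
#'
#' @param genotypes integer matrix, samples in rows, sites in columns.
#' @param chrom character vector of per-site chromosome ids.
#' @param pos integer vector of 1-based per-site positions, strictly
#'   increasing within each chromosome.
#' @param sample_ids character vector of unique sample identifiers
#'   (row names of `genotypes`).
#' @param populations per-sample population labels.
#' @param years per-sample sampling years (integer CE).
#' @param cohorts optional per-sample cohort tags (e.g. "1980",
#'   "2019/2020"); defaults to `as.character(years)`.
#' @param ancestral_is_ref per-site logical: TRUE when the reference allele
#'   is the ancestral (outgroup) allele, NA when orientation is unknown.
#' @param impact per-site impact category, one of [IMPACT_LEVELS].
#' @param ref,alt optional per-site allele characters (defaults "A"/"C").
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, chrom, pos, sample_ids,
                            populations, years, cohorts = NULL,
                            ancestral_is_ref = NA, impact = "UNANNOTATED",
                            ref = NULL, alt = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  n_samp <- nrow(genotypes)
  n_site <- ncol(genotypes)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != n_site || length(pos) != n_site)
    stop("chrom/pos length must equal the number of sites")
  if (length(sample_ids) != n_samp)
    stop("sample_ids length must equal the number of samples")
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique")
  if (length(populations) != n_samp || length(years) != n_samp)
    stop("every sample needs a population label and a year")
  if (any(is.na(populations)) || any(is.na(years)))
    stop("every sample needs a population label and a year")
  bad <- setdiff(unique(as.vector(genotypes)), c(-1L, 0L, 1L, 2L))
  if (length(bad))
    stop("genotype codes restricted to {-1,0,1,2}; found: ",
         paste(bad, collapse = ", "))
  impact <- rep_len(as.character(impact), n_site)
  if (!all(impact %in% IMPACT_LEVELS))
    stop("impact must be one of: ", paste(IMPACT_LEVELS, collapse = ", "))
  ancestral_is_ref <- rep_len(as.logical(ancestral_is_ref), n_site)
  if (is.null(cohorts)) cohorts <- as.character(years)
  if (is.null(ref)) ref <- rep("A", n_site)
  if (is.null(alt)) alt <- rep("C", n_site)
  # positions strictly increasing within each chromosome
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(genotypes) <- sample_ids
  structure(
    list(sample_ids = as.character(sample_ids),
         populations = as.character(populations),
         years = as.integer(years),
         cohorts = as.character(cohorts),
         chrom = chrom, pos = pos,
         genotypes = genotypes,
         ancestral_is_ref = ancestral_is_ref,
         impact = impact,
         ref = as.character(rep_len(ref, n_site)),
         alt = as.character(rep_len(alt, n_site))),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$pos), "sites on", length(unique(x$chrom)),
      "chromosome(s)\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(table(x$populations)),
                    table(x$populations)), collapse = ", "), "\n")
  cat("  cohorts:    ",
      paste(sort(unique(x$cohorts)), collapse = ", "), "\n")
  imp <- table(factor(x$impact, IMPACT_LEVELS))
  cat("  impact:     ",
      paste(sprintf("%s %d", names(imp), imp), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  g <- object$genotypes
  out <- list(
    n_samples = nrow(g), n_sites = ncol(g),
    missing_rate = mean(g == -1L),
    het_rate = mean(g == 1L),
    populations = table(object$populations),
    impact = table(factor(object$impact, IMPACT_LEVELS)))
  class(out) <- "summary.genotype_matrix"
  out
}

#' @export
print.summary.genotype_matrix <- function(x, ...) {
  cat(sprintf("%d samples x %d sites; missing %.4f; het %.4f\n",
              x$n_samples, x$n_sites, x$missing_rate, x$het_rate))
  print(x$populations); print(x$impact)
  invisible(x)
}

#' Subset sites of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over sites; order preserved.
#' @return a `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, keep) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$chrom <- gm$chrom[keep]
  gm$pos <- gm$pos[keep]
  gm$genotypes <- gm$genotypes[, keep, drop = FALSE]
  gm$ancestral_is_ref <- gm$ancestral_is_ref[keep]
  gm$impact <- gm$impact[keep]
  gm$ref <- gm$ref[keep]
  gm$alt <- gm$alt[keep]
  gm
}

#' Subset samples of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param keep logical/integer index over samples, or sample ids.
#' @return a `genotype_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(gm, keep) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.character(keep)) {
    miss <- setdiff(keep, gm$sample_ids)
    if (length(miss)) stop("unknown sample id(s): ",
                           paste(miss, collapse = ", "))
    keep <- match(keep, gm$sample_ids)
  }
  gm$sample_ids <- gm$sample_ids[keep]
  gm$populations <- gm$populations[keep]
  gm$years <- gm$years[keep]
  gm$cohorts <- gm$cohorts[keep]
  gm$genotypes <- gm$genotypes[keep, , drop = FALSE]
  gm
}

#' Drop sites with any missing genotype call
#'
#' Keeps only sites called in every sample (the complete-case SNP set used
#' for all cross-population comparisons); site order is preserved.
#'
#' @param gm a [genotype_matrix()].
#' @return a `genotype_matrix` with no `-1` codes (possibly zero sites).
#' @export
complete_case_filter <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- colSums(gm$genotypes == -1L) == 0L
  if (all(keep)) return(gm)
  subset_sites(gm, keep)
}

# derived-allele dosage per sample x site; NA where missing or unoriented
derived_dosage <- function(gm) {
  g <- gm$genotypes
  d <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  ori <- gm$ancestral_is_ref
  fwd <- which(!is.na(ori) & ori)
  rev <- which(!is.na(ori) & !ori)
  if (length(fwd)) d[, fwd] <- g[, fwd]
  if (length(rev)) d[, rev] <- 2 - g[, rev]
  d[g == -1L] <- NA_real_
  d
}
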