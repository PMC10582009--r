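# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles re-derive each quantity by direct enumeration
# and never call the package's own computational path.

# quick genotype_matrix builder: `geno` is sites-in-columns (samples x
# sites) and metadata defaults are filled in.
toy_gm <- function(geno, pos = NULL, chrom = NULL, populations = NULL,
                   years = NULL, impact = "UNANNOTATED",
                   ancestral_is_ref = TRUE) {
  geno <- as.matrix(geno)
  n_samp <- nrow(geno); n_site <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(n_site) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", n_site)
  if (is.null(populations))
    populations <- rep(c("A", "B"), each = ceiling(n_samp / 2))[seq_len(n_samp)]
  if (is.null(years)) years <- rep(2000L, n_samp)
  genotype_matrix(geno, chrom = chrom, pos = pos,
                  sample_ids = paste0("s", seq_len(n_samp)),
                  populations = rep_len(populations, n_samp),
                  years = rep_len(years, n_samp),
                  impact = impact, ancestral_is_ref = ancestral_is_ref)
}

# exhaustive per-site average pairwise allele difference, summed over
# sites (the definition of nucleotide diversity, computed by literally
# enumerating every pair of called allele copies)
pi_pairwise_oracle <- function(geno_pop) {
  total <- 0
  for (j in seq_len(ncol(geno_pop))) {
    alleles <- unlist(lapply(geno_pop[, j], function(g) {
      if (g == -1) NULL
      else if (g == 0) c(0, 0)
      else if (g == 1) c(0, 1)
      else c(1, 1)
    }))
    n <- length(alleles)
    if (n < 2) next
    diff <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      pairs <- pairs + 1
      if (alleles[a] != alleles[b]) diff <- diff + 1
    }
    total <- total + diff / pairs
  }
  total
}

# brute-force ROH caller for one sample on one chromosome: enumerates
# every scanning window and every candidate run directly.
brute_roh <- function(g, pos, params) {
  S <- length(g)
  W <- params$window_snp
  pass <- logical(S)
  n_win <- S - W + 1L
  if (n_win >= 1) {
    hom_win <- logical(n_win)
    for (j in seq_len(n_win)) {
      w <- g[j:(j + W - 1)]
      hom_win[j] <- sum(w == 1) <= params$window_het &&
        sum(w == -1) <= params$window_missing
    }
    for (i in seq_len(S)) {
      cov <- which(seq_len(n_win) <= i & seq_len(n_win) + W - 1 >= i)
      if (length(cov))
        pass[i] <- mean(hom_win[cov]) >= params$window_threshold
    }
  }
  segs <- list(); k <- 0
  i <- 1
  while (i <= S) {
    if (!pass[i]) { i <- i + 1; next }
    j <- i
    while (j < S && pass[j + 1]) j <- j + 1
    # split the run i..j at gaps
    s <- i
    for (q in i:j) {
      end_piece <- q == j || (pos[q + 1] - pos[q]) > params$max_gap_kb * 1000
      if (end_piece) {
        n_snps <- q - s + 1
        span <- pos[q] - pos[s] + 1
        n_het <- sum(g[s:q] == 1)
        if (span >= params$min_kb * 1000 && n_snps >= params$min_snp &&
            span / 1000 / n_snps <= params$density_kb_per_snp &&
            n_het <= params$max_het_in_segment) {
          k <- k + 1
          segs[[k]] <- data.frame(start = pos[s], end = pos[q],
                                  n_snps = n_snps, n_het = n_het)
        }
        s <- q + 1
      }
    }
    i <- j + 1
  }
  if (k) do.call(rbind, segs)
  else data.frame(start = integer(), end = integer(),
                  n_snps = integer(), n_het = integer())
}

# base-level Jaccard between two interval sets on one genome
interval_jaccard <- function(a, b) {
  cover <- function(x, grid_chrom, grid_pos) {
    hit <- logical(length(grid_pos))
    for (i in seq_len(nrow(x)))
      hit <- hit | (grid_chrom == x$chrom[i] & grid_pos >= x$start[i] &
                      grid_pos <= x$end[i])
    hit
  }
  chroms <- unique(c(a$chrom, b$chrom))
  inter <- 0; uni <- 0
  for (ch in chroms) {
    xa <- a[a$chrom == ch, , drop = FALSE]
    xb <- b[b$chrom == ch, , drop = FALSE]
    pts <- sort(unique(c(xa$start, xa$end + 1, xb$start, xb$end + 1)))
    if (length(pts) < 2) next
    seg_start <- pts[-length(pts)]
    seg_len <- diff(pts)
    ina <- inb <- logical(length(seg_start))
    for (i in seq_len(nrow(xa)))
      ina <- ina | (seg_start >= xa$start[i] & seg_start <= xa$end[i])
    for (i in seq_len(nrow(xb)))
      inb <- inb | (seg_start >= xb$start[i] & seg_start <= xb$end[i])
    inter <- inter + sum(seg_len[ina & inb])
    uni <- uni + sum(seg_len[ina | inb])
  }
  if (uni == 0) return(NA_real_)
  inter / uni
}

# write a small hand-enumerable VCF used by the io tests
write_toy_vcf <- function(path, with_unknown_sample = FALSE) {
  samples <- c("m1", "m2", if (with_unknown_sample) "ghost")
  gts <- function(...) paste(c(...), collapse = "\t")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
    '##INFO=<ID=ANN,Number=.,Type=String,Description="ann">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    # record 1: plain biallelic
    gts("chr1", 100, ".", "A", "C", ".", "PASS",
        "AA=A;ANN=C|synonymous_variant|", "GT", "0/0", "0/1",
        if (with_unknown_sample) "0/0"),
    # record 2: inside the mask interval [150, 250)
    gts("chr1", 200, ".", "G", "T", ".", "PASS", "AA=G", "GT",
        "1/1", "0/0", if (with_unknown_sample) "0/0"),
    # record 3: tri-allelic, must be dropped
    gts("chr1", 300, ".", "A", "C,T", ".", "PASS", ".", "GT",
        "0/1", "0/2", if (with_unknown_sample) "0/0"),
    # record 4: HIGH impact, alt ancestral
    gts("chr1", 400, ".", "T", "G", ".", "PASS",
        "AA=G;ANN=G|stop_gained|", "GT", "1/1", "0/1",
        if (with_unknown_sample) "0/0"),
    # record 5: missing call present
    gts("chr1", 500, ".", "C", "G", ".", "PASS", ".", "GT",
        "./.", "0/0", if (with_unknown_sample) "0/0"))
  writeLines(lines, path)
  path
}

toy_sheet <- function(path) {
  writeLines(c("sample_id\tpopulation\tyear\tcohort",
               "m1\tNorth\t1980\t1980",
               "m2\tSouth\t2020\t2019/2020"), path)
  path
}
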