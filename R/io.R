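#' Read a sample sheet
#'
#' Tab-separated file with header columns `sample_id`, `population`,
#' `year` and optionally `cohort`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns sample_id, population, year, cohort.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("sample_id", "population", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("sample sheet has duplicated sample_id values")
  if (is.null(df$cohort)) df$cohort <- as.character(df$year)
  df$year <- as.integer(df$year)
  df[c("sample_id", "population", "year", "cohort")]
}

#' Read a BED3 mask
#'
#' Intervals are BED-native half-open 0-based and are kept that way in
#' memory; they are sorted and merged per chromosome on read.
#'
#' @param path path to a BED3 file (may be empty or absent columns > 3 are
#'   ignored); `NULL` yields an empty mask.
#' @param label mask label, e.g. "repeat", "cpg" or "exclude-scaffold".
#' @return data.frame with columns chrom, start, end, label
#'   (class `genomic_mask`).
#' @export
read_bed_mask <- function(path = NULL, label = "repeat") {
  if (is.null(path) || !file.size(path)) {
    m <- data.frame(chrom = character(), start = integer(),
                    end = integer(), label = character())
    class(m) <- c("genomic_mask", "data.frame")
    return(m)
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  m <- data.frame(chrom = as.character(df[[1]]),
                  start = as.integer(df[[2]]),
                  end = as.integer(df[[3]]),
                  label = label, stringsAsFactors = FALSE)
  if (any(m$end < m$start)) stop("mask interval with negative length")
  m <- merge_mask(m)
  class(m) <- c("genomic_mask", "data.frame")
  m
}

# sort and merge overlapping/adjacent intervals within each chromosome
merge_mask <- function(m) {
  if (!nrow(m)) return(m)
  m <- m[order(m$chrom, m$start, m$end), , drop = FALSE]
  out <- vector("list", length(unique(m$chrom)))
  i <- 0L
  for (ch in unique(m$chrom)) {
    x <- m[m$chrom == ch, , drop = FALSE]
    s <- x$start; e <- x$end
    ks <- s[1]; ke <- e[1]; rs <- c(); re <- c()
    for (j in seq_along(s)[-1]) {
      if (s[j] <= ke) ke <- max(ke, e[j])
      else { rs <- c(rs, ks); re <- c(re, ke); ks <- s[j]; ke <- e[j] }
    }
    rs <- c(rs, ks); re <- c(re, ke)
    i <- i + 1L
    out[[i]] <- data.frame(chrom = ch, start = rs, end = re,
                           label = x$label[1], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene`-type features (1-based inclusive coordinates, as in
#' GFF3), taking the gene id from the `ID=` attribute.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns gene_id, chrom, start, end, strand.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) stop("malformed GFF3 line (fewer than 9 fields)")
  f <- do.call(rbind, f)
  keep <- f[, 3] == "gene"
  f <- f[keep, , drop = FALSE]
  ids <- sub("^.*ID=([^;]+).*$", "\\1", f[, 9])
  g <- data.frame(gene_id = ids, chrom = f[, 1],
                  start = as.integer(f[, 4]), end = as.integer(f[, 5]),
                  strand = f[, 7], stringsAsFactors = FALSE)
  if (any(g$start > g$end)) stop("gene model with start > end")
  g
}

#' Map a SnpEff-style ANN string to an impact category
#'
#' Stop-gained, splice-donor/acceptor and start-lost effects are HIGH
#' (protein-truncating); missense-class effects MODERATE; synonymous
#' effects SYNONYMOUS; intergenic/intronic and other non-coding effects
#' OTHER (excluded from load accounting downstream). When several
#' annotations are present (comma-separated ANN entries or
#' ampersand-joined effects) the most severe category wins.
#'
#' @param ann_text character vector of ANN annotation strings (the value
#'   of the `ANN=` INFO key, or a bare effect term). Empty or NA entries
#'   yield UNANNOTATED.
#' @return character vector of categories in [IMPACT_LEVELS].
#' @export
parse_impact <- function(ann_text) {
  high <- c("stop_gained", "splice_donor_variant", "splice_acceptor_variant",
            "start_lost")
  moderate <- c("missense_variant", "inframe_insertion", "inframe_deletion",
                "disruptive_inframe_insertion", "disruptive_inframe_deletion")
  synonymous <- c("synonymous_variant", "stop_retained_variant",
                  "start_retained_variant")
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return("UNANNOTATED")
    entries <- unlist(strsplit(s, ",", fixed = TRUE))
    effects <- unlist(lapply(entries, function(e) {
      fields <- strsplit(e, "|", fixed = TRUE)[[1]]
      eff <- if (length(fields) >= 2) fields[2] else fields[1]
      strsplit(eff, "&", fixed = TRUE)[[1]]
    }))
    if (any(effects %in% high)) return("HIGH")
    if (any(effects %in% moderate)) return("MODERATE")
    if (any(effects %in% synonymous)) return("SYNONYMOUS")
    "OTHER"
  }
  vapply(ann_text, one, character(1), USE.NAMES = FALSE)
}

# TRUE for sites falling inside a half-open 0-based mask interval
site_in_mask <- function(chrom, pos, mask) {
  hit <- logical(length(pos))
  if (is.null(mask) || !nrow(mask)) return(hit)
  p0 <- pos - 1L                       # convert to 0-based
  for (ch in unique(mask$chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    iv <- mask[mask$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(iv)))
      hit[sel] <- hit[sel] | (p0[sel] >= iv$start[j] & p0[sel] < iv$end[j])
  }
  hit
}

#' Apply a genomic mask to a genotype matrix
#'
#' Removes sites whose position falls inside any mask interval. Applying
#' the same mask twice is a no-op.
#'
#' @param gm a [genotype_matrix()].
#' @param mask a mask from [read_bed_mask()] (or NULL for no masking).
#' @return the masked `genotype_matrix`.
#' @export
apply_mask <- function(gm, mask) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hit <- site_in_mask(gm$chrom, gm$pos, mask)
  if (!any(hit)) return(gm)
  subset_sites(gm, !hit)
}

#' Read genotypes from a VCF file
#'
#' Builds a [genotype_matrix()] from a (possibly gzipped) VCF v4.2 file:
#' multi-allelic records are dropped, masked sites removed, `ANN=` INFO
#' entries mapped to impact categories and `AA=` entries (ancestral
#' allele) to derived-allele orientation.
#'
#' @param vcf_path path to the VCF file.
#' @param sheet sample sheet from [read_sample_sheet()]; every VCF sample
#'   must be present.
#' @param mask optional mask from [read_bed_mask()].
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, sheet, mask = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- v@fix[, "INFO"]
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, sheet$sample_id)
  if (length(unknown))
    stop("VCF sample(s) absent from sample sheet: ",
         paste(unknown, collapse = ", "))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  keep <- keep & !site_in_mask(chrom, pos, mask)
  idx <- which(keep)
  if (!length(idx)) stop("no biallelic SNPs left after filtering")

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[idx, , drop = FALSE]
  gt_chr <- gsub("|", "/", gt, fixed = TRUE)
  code <- match(gt_chr, c("0/0", "0/1", "1/0", "1/1")) # -> 1..4
  codes <- c(0L, 1L, 1L, 2L)[code]
  missing <- is.na(gt_chr) | gt_chr %in% c("./.", ".")
  codes[missing] <- -1L
  bad <- which(is.na(codes))
  if (length(bad)) {
    b <- arrayInd(bad[1], dim(gt_chr))
    stop(sprintf("malformed genotype '%s' at %s:%d (sample %s)",
                 gt[bad[1]], chrom[idx][b[1]], pos[idx][b[1]],
                 colnames(gt)[b[2]]))
  }
  geno <- matrix(codes, nrow = nrow(gt), ncol = ncol(gt))
  geno <- t(geno)                       # samples x sites
  rownames(geno) <- samples

  inf <- info[idx]
  ann <- ifelse(grepl("(^|;)ANN=", inf),
                sub("^(.*;)?ANN=([^;]*).*$", "\\2", inf), "")
  aa <- ifelse(grepl("(^|;)AA=", inf),
               sub("^(.*;)?AA=([^;]*).*$", "\\2", inf), NA_character_)
  anc_is_ref <- ifelse(is.na(aa), NA, aa == ref[idx])

  srows <- sheet[match(samples, sheet$sample_id), ]
  genotype_matrix(geno, chrom = chrom[idx], pos = pos[idx],
                  sample_ids = samples,
                  populations = srows$population, years = srows$year,
                  cohorts = srows$cohort,
                  ancestral_is_ref = anc_is_ref,
                  impact = parse_impact(ann),
                  ref = ref[idx], alt = alt[idx])
}

#' Write a genotype matrix to a VCF v4.2 file
#'
#' Emits one biallelic record per site with `AA=` (ancestral allele, when
#' orientation is known) and `ANN=` (an effect term that round-trips
#' through [parse_impact()]) INFO entries. Reading the file back with
#' [read_genotypes()] reproduces genotypes, positions and impacts.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  eff <- c(HIGH = "stop_gained", MODERATE = "missense_variant",
           SYNONYMOUS = "synonymous_variant", OTHER = "intergenic_region")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=erosure",
           paste0("##contig=<ID=", unique(gm$chrom), ">"),
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
           '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotation">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  n_site <- length(gm$pos)
  aa <- ifelse(is.na(gm$ancestral_is_ref), NA,
               ifelse(gm$ancestral_is_ref, gm$ref, gm$alt))
  info <- rep("", n_site)
  has_aa <- !is.na(aa)
  info[has_aa] <- paste0("AA=", aa[has_aa])
  has_ann <- gm$impact != "UNANNOTATED"
  annstr <- paste0("ANN=", gm$alt, "|", eff[gm$impact], "|")
  info[has_ann] <- ifelse(has_aa[has_ann],
                          paste0(info[has_ann], ";", annstr[has_ann]),
                          annstr[has_ann])
  info[!nzchar(info)] <- "."
  gt_map <- c("./.", "0/0", "0/1", "1/1")   # codes -1,0,1,2 -> index+2
  gt <- matrix(gt_map[gm$genotypes + 2L], nrow = nrow(gm$genotypes))
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS",
                info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a window track as TSV
#'
#' @param track a track data.frame (e.g. from [pi_windows()] or
#'   [fst_windows()]).
#' @param path output path; a commented header line starting with '#'
#'   names the columns.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(track), collapse = "\t")), con)
  utils::write.table(track, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
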