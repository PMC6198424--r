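# Readers/writers for the formats the pipeline touches: PLINK PED/MAP,
# VCF (via VariantAnnotation), breed TSV, BED/TSV region reports.
# Internal coordinates are 1-based inclusive; BED export converts to
# 0-based half-open.

#' Construct a genotype dataset
#'
#' @param G Integer matrix, samples x SNPs; entries 0/1/2 count the
#'   "counted" allele, `NA` = missing.
#' @param map SNP map data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based), sorted by (chrom, pos), positions strictly increasing
#'   within chromosome.
#' @param samples Character vector of sample ids (rows of `G`).
#' @param breed Breed label per sample.
#' @param coding Free-text note recording which allele is counted.
#' @return Object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(G, map, samples, breed, coding = "") {
  stopifnot(nrow(G) == length(samples), ncol(G) == nrow(map),
            length(breed) == length(samples))
  .check_map(map)
  structure(list(G = G, map = map, samples = samples,
                 breed = breed, coding = coding),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs, breeds: %s\n",
              nrow(x$G), ncol(x$G),
              paste(sprintf("%s (n=%d)", names(table(x$breed)),
                            as.integer(table(x$breed))), collapse = ", ")))
  invisible(x)
}

.check_map <- function(map) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(map$snp_id)) stop("duplicate snp_ids in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("map positions not strictly increasing within chromosome ", ch)
  }
  invisible(map)
}

.read_breeds <- function(path) {
  b <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("sample_id", "breed") %in% names(b)))
    stop("breed file must have columns sample_id and breed")
  b
}

.match_breeds <- function(samples, breeds) {
  miss <- setdiff(samples, breeds$sample_id)
  if (length(miss))
    stop("samples missing from breed file: ", paste(miss, collapse = ", "))
  breeds$breed[match(samples, breeds$sample_id)]
}

# order map (and return permutation) by chromosome then position
.map_order <- function(map) order(map$chrom, map$pos)

#' Read unphased genotypes from PLINK PED/MAP or VCF
#'
#' The counted allele (genotype code 2) is the first ALT allele for VCF
#' input and the lexicographically smaller of the two observed alleles
#' for PED input; the convention is recorded in the returned dataset and
#' every downstream statistic is invariant under flipping it.
#'
#' @param ped,map Paths to a PLINK PED and MAP file (text, whitespace
#'   separated). Supply either these or `vcf`.
#' @param vcf Path to a VCF file (plain or bgzipped); biallelic SNVs only.
#' @param breeds Path to a TSV with header `sample_id<TAB>breed`.
#' @param drop_nonautosomal Drop markers whose chromosome matches
#'   `c("X","Y","MT","0")` (sex chromosomes / unplaced), mirroring array
#'   pre-filtering.
#' @return A [genotype_dataset()], SNPs sorted by (chrom, pos).
#' @export
read_genotypes <- function(ped = NULL, map = NULL, vcf = NULL, breeds,
                           drop_nonautosomal = FALSE) {
  if (!is.null(vcf)) {
    ds <- .read_genotypes_vcf(vcf, breeds)
  } else {
    if (is.null(ped) || is.null(map)) stop("supply ped+map or vcf")
    ds <- .read_genotypes_ped(ped, map, breeds)
  }
  if (drop_nonautosomal) {
    keep <- !toupper(ds$map$chrom) %in% c("X", "Y", "MT", "0")
    ds$G <- ds$G[, keep, drop = FALSE]
    ds$map <- ds$map[keep, , drop = FALSE]
  }
  ds
}

.read_genotypes_ped <- function(ped_path, map_path, breeds_path) {
  mp <- utils::read.table(map_path, header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "snp_id", "cm", "pos"))
  ped <- data.table::fread(ped_path, header = FALSE, data.table = FALSE,
                           colClasses = "character")
  n_snp <- nrow(mp)
  if (ncol(ped) != 6 + 2 * n_snp)
    stop("PED column count does not match MAP (", n_snp, " SNPs)")
  samples <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_snp), drop = FALSE])
  G <- matrix(NA_integer_, nrow = length(samples), ncol = n_snp)
  counted <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    obs <- sort(setdiff(unique(al), "0"))
    if (length(obs) > 2) stop("more than 2 alleles at ", mp$snp_id[j])
    counted[j] <- if (length(obs)) obs[1] else NA_character_
    g <- (a1[, j] == counted[j]) + (a2[, j] == counted[j])
    g[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    G[, j] <- as.integer(g)
  }
  map <- data.frame(snp_id = mp$snp_id, chrom = as.character(mp$chrom),
                    pos = as.integer(mp$pos), stringsAsFactors = FALSE)
  ord <- .map_order(map)
  breed <- .match_breeds(samples, .read_breeds(breeds_path))
  rownames(G) <- samples
  genotype_dataset(G[, ord, drop = FALSE], map[ord, , drop = FALSE],
                   samples, breed,
                   coding = "counted allele = lexicographically smaller PED allele")
}

.read_gt_matrix <- function(vcf_path) {
  v <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  if (any(S4Vectors::elementNROWS(alt) != 1))
    stop("only biallelic records are supported")
  gt <- VariantAnnotation::geno(v)$GT   # variants x samples, character
  map <- data.frame(snp_id = names(rr),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    stringsAsFactors = FALSE)
  list(gt = gt, map = map, samples = colnames(gt))
}

.read_genotypes_vcf <- function(vcf_path, breeds_path) {
  x <- .read_gt_matrix(vcf_path)
  gt <- gsub("|", "/", x$gt, fixed = TRUE)
  G <- matrix(NA_integer_, nrow = length(x$samples), ncol = nrow(x$map))
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  G[] <- t(matrix(codes[gt], nrow = nrow(gt)))
  ord <- .map_order(x$map)
  breed <- .match_breeds(x$samples, .read_breeds(breeds_path))
  rownames(G) <- x$samples
  genotype_dataset(G[, ord, drop = FALSE], x$map[ord, , drop = FALSE],
                   x$samples, breed, coding = "counted allele = first ALT")
}

#' Read phased haplotypes from a VCF
#'
#' Every GT field must be phased (`|` separator) and non-missing; any
#' violation is reported with its record coordinates.
#'
#' @param vcf Path to a phased VCF.
#' @param breeds Path to a breed TSV (`sample_id<TAB>breed`).
#' @return A `haplotype_set` with two haplotype rows per sample, left
#'   allele first.
#' @export
read_haplotypes <- function(vcf, breeds) {
  x <- .read_gt_matrix(vcf)
  bad <- which(!grepl("^[01]\\|[01]$", x$gt))
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(x$gt))
    stop(sprintf("unphased or missing GT '%s' at %s:%d (sample %s)",
                 x$gt[bad[1]], x$map$chrom[ij[1]], x$map$pos[ij[1]],
                 x$samples[ij[2]]))
  }
  left <- matrix(as.integer(substr(x$gt, 1, 1)), nrow = nrow(x$gt))
  right <- matrix(as.integer(substr(x$gt, 3, 3)), nrow = nrow(x$gt))
  n_s <- length(x$samples)
  H <- matrix(0L, nrow = 2L * n_s, ncol = nrow(x$map))
  H[seq(1, 2 * n_s, by = 2), ] <- t(left)
  H[seq(2, 2 * n_s, by = 2), ] <- t(right)
  ord <- .map_order(x$map)
  breed <- .match_breeds(x$samples, .read_breeds(breeds))
  hs <- list(haps = H[, ord, drop = FALSE], map = x$map[ord, , drop = FALSE],
             samples = x$samples, breed = breed,
             hap_sample = rep(seq_len(n_s), each = 2L))
  rownames(hs$haps) <- sprintf("%s_h%d", x$samples[hs$hap_sample],
                               rep(1:2, n_s))
  class(hs) <- "haplotype_set"
  hs
}

#' Write a haplotype set as a phased VCF
#'
#' Alleles are written as REF=A, ALT=G with GT `a|b`; the simulated '1'
#' allele maps to ALT.
#'
#' @param hs A `haplotype_set`.
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_phased_vcf <- function(hs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(hs$map$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", hs$samples), collapse = "\t")),
             con)
  odd <- seq(1, nrow(hs$haps), by = 2)
  gt <- matrix(paste(hs$haps[odd, , drop = FALSE],
                     hs$haps[odd + 1, , drop = FALSE], sep = "|"),
               nrow = length(odd))
  lines <- paste(hs$map$chrom, hs$map$pos, hs$map$snp_id, "A", "G",
                 ".", "PASS", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write the sample-to-breed mapping as TSV
#'
#' @param hs A `haplotype_set` or `genotype_dataset`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_breeds_tsv <- function(hs, path) {
  utils::write.table(data.frame(sample_id = hs$samples, breed = hs$breed),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write selection regions as BED or TSV
#'
#' TSV output mirrors the reporting convention of FST-scan tables:
#' `START`, `END`, `SIZE` (= END - START) and the +/- pad columns. BED
#' output converts the internal 1-based inclusive interval to 0-based
#' half-open.
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` and
#'   optionally `breed`, `score`.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @param pad Pad (bp) used for the TSV's START-pad / END+pad columns.
#' @return The path, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed"),
                          pad = 25000) {
  format <- match.arg(format)
  if (is.null(regions$breed)) regions$breed <- NA_character_
  if (is.null(regions$score)) regions$score <- NA_real_
  if (format == "bed") {
    df <- data.frame(chrom = regions$chrom,
                     start = regions$start - 1L,
                     end = regions$end,
                     name = regions$breed,
                     score = regions$score)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tname\tscore", con)
    if (nrow(df) > 0)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(BREED = regions$breed, CHR = regions$chrom,
                     START = regions$start, END = regions$end,
                     SIZE = regions$end - regions$start,
                     START_PAD = pmax(1, regions$start - pad),
                     END_PAD = regions$end + pad,
                     SCORE = regions$score)
    names(df)[6:7] <- c(sprintf("START-%dkb", pad %/% 1000),
                        sprintf("END+%dkb", pad %/% 1000))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
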