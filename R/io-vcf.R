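#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gz), keeps biallelic SNP records only,
#' codes genotypes as alt-allele dosages and applies minor-allele-frequency
#' and missingness filters. Variants are returned sorted by (chrom, pos).
#'
#' @param path Path to a VCF file.
#' @param maf_min Minimum minor allele frequency (computed from non-missing
#'   dosages); variants strictly below it are dropped. Default 0.
#' @param missing_max Maximum fraction of missing genotype calls per variant.
#'   Default 1 (no filter).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, maf_min = 0, missing_max = 1) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("failed to parse VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) fixm <- t(fixm)       # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path, call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF has no sample genotype columns: ", path, call. = FALSE)

  # biallelic SNPs only: single-base REF and single-base ALT without commas
  snp <- nchar(fix$REF) == 1L & !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$ALT) == 1L & fix$ALT %in% c("A", "C", "G", "T") &
    fix$REF %in% c("A", "C", "G", "T")
  if (!any(snp)) stop("no biallelic SNP records in VCF: ", path, call. = FALSE)
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]

  dos <- parse_gt_dosage(gt)          # variants x samples
  miss <- rowMeans(is.na(dos))
  af <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[!is.finite(maf)] <- 0
  keep <- maf >= maf_min & miss <= missing_max
  if (!any(keep))
    stop("no variants survive filters (maf_min=", maf_min,
         ", missing_max=", missing_max, ")", call. = FALSE)
  fix <- fix[keep, , drop = FALSE]
  dos <- dos[keep, , drop = FALSE]

  ids <- fix$ID
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dos <- dos[ord, , drop = FALSE]
  rownames(variants) <- NULL
  genotype_matrix(t(dos), variants)
}

# "0/1", "0|1", "./." (and haploid "0"/"1") -> alt-allele count
parse_gt_dosage <- function(gt) {
  core <- sub(":.*$", "", gt)
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2,
           "0" = 0, "1" = 1)
  dos <- matrix(lut[core], nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  dos
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Minimal VCF 4.2 writer used for simulator output and round-trip checks;
#' genotypes are emitted as unphased GT calls, missing dosages as `./.`.
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  v <- G$variants
  gt_code <- c("0/0", "0/1", "1/1")
  dos <- t(G$dosages)                          # variants x samples
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[dos[ok] + 1L]
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT", gt)
  header <- c("##fileformat=VCFv4.2",
              "##source=dyneqtl",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", G$accessions), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
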