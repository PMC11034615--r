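#' Construct a genotype matrix object
#'
#' Container for a dosage-coded biallelic SNP panel: an accessions x variants
#' matrix of alt-allele counts in `{0, 1, 2, NA}` plus per-variant metadata.
#'
#' @param dosages Numeric matrix, accessions in rows, variants in columns.
#'   Row names are accession ids, column names variant ids.
#' @param variants `data.frame` with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; `maf` and `missing_frac` are recomputed here.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `accessions`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages))
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(rownames(dosages)))
    stop("dosages must carry accession ids as row names", call. = FALSE)
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate accession ids in genotype matrix", call. = FALSE)
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids", call. = FALSE)
  if (any(variants$pos < 1)) stop("variant positions must be >= 1", call. = FALSE)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  colnames(dosages) <- variants$id
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$maf <- variant_maf(dosages)
  variants$missing_frac <- colMeans(is.na(dosages))
  obj <- list(dosages = dosages, variants = variants,
              accessions = rownames(dosages))
  class(obj) <- "genotype_matrix"
  obj
}

variant_maf <- function(dosages) {
  af <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d variants on %d chromosome(s)\n",
              length(x$accessions), nrow(x$variants),
              length(unique(x$variants$chrom))))
  cat(sprintf("  MAF range %.3f-%.3f; %.2f%% missing calls\n",
              min(x$variants$maf), max(x$variants$maf),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param accessions,variants Character vectors of ids (or logical/integer
#'   indices) selecting rows/columns; `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, accessions = NULL, variants = NULL) {
  d <- x$dosages
  v <- x$variants
  if (!is.null(accessions)) d <- d[accessions, , drop = FALSE]
  if (!is.null(variants)) {
    idx <- if (is.character(variants)) match(variants, v$id) else variants
    d <- d[, idx, drop = FALSE]
    v <- v[idx, , drop = FALSE]
  }
  genotype_matrix(d, v)
}

# Mean-impute missing calls per variant (used at association/kinship time
# only; the raw matrix keeps its missingness).
impute_dosages <- function(dosages) {
  if (!anyNA(dosages)) return(dosages)
  mu <- colMeans(dosages, na.rm = TRUE)
  idx <- which(is.na(dosages), arr.ind = TRUE)
  dosages[idx] <- mu[idx[, 2]]
  dosages
}

# Squared dosage correlation between one variant and a set of variants,
# on mean-imputed dosages. Returns 0 where either side is monomorphic.
dosage_r2 <- function(dosages, lead, others) {
  x <- impute_dosages(dosages[, c(lead, others), drop = FALSE])
  sds <- apply(x, 2, sd)
  if (sds[1] == 0) return(setNames(rep(0, length(others)), others))
  r <- suppressWarnings(cor(x[, 1], x[, -1, drop = FALSE]))[1, ]
  r[!is.finite(r)] <- 0
  setNames(r^2, others)
}
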