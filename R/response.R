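#' Expression filter: which genes count as expressed per condition
#'
#' A gene is expressed in a condition iff its mean FPKM across the panel is
#' strictly greater than `min_mean_fpkm` (default 0.1; a mean of exactly 0.1
#' is excluded). Also derives the common / normal-only / stress-only split of
#' the expressed universe.
#'
#' @param normal,stress Expression matrices (genes x accessions) sharing a
#'   gene universe and accession panel.
#' @param min_mean_fpkm Strict lower bound on the per-condition mean.
#' @return List of gene-id sets: `expressed_normal`, `expressed_stress`,
#'   `common`, `normal_only`, `stress_only`.
#' @export
filter_expressed <- function(normal, stress, min_mean_fpkm = 0.1) {
  check_paired(normal, stress)
  en <- rownames(normal)[rowMeans(normal) > min_mean_fpkm]
  es <- rownames(stress)[rowMeans(stress) > min_mean_fpkm]
  list(expressed_normal = en,
       expressed_stress = es,
       common = intersect(en, es),
       normal_only = setdiff(en, es),
       stress_only = setdiff(es, en))
}

check_paired <- function(normal, stress) {
  if (!identical(rownames(normal), rownames(stress)))
    stop("expression matrices must share the same gene universe/order",
         call. = FALSE)
  if (length(intersect(colnames(normal), colnames(stress))) == 0L)
    stop("no accessions shared between condition matrices", call. = FALSE)
  if (!identical(colnames(normal), colnames(stress)))
    stop("accession columns must be aligned; run align_panel() first",
         call. = FALSE)
  invisible(TRUE)
}

#' Per-accession response profiles (paired log2 fold changes)
#'
#' For each gene and accession, `log2FC = log2((stress + pseudocount) /
#' (normal + pseudocount))`, comparing the same accession across conditions.
#' Accessions at or above `fc_threshold` count as up-responders, at or below
#' `-fc_threshold` as down-responders (boundary inclusive).
#'
#' @param normal,stress Aligned expression matrices.
#' @param pseudocount Added to both sides of the ratio; keeps log2FC finite
#'   for zero FPKM. Default 0.5.
#' @param fc_threshold Count threshold on |log2FC|. Default 2.
#' @return List: `log2fc` (genes x accessions matrix) and `counts`
#'   (data.frame `gene_id`, `up_count`, `down_count`, `n_accessions`).
#' @export
compute_response <- function(normal, stress, pseudocount = 0.5,
                             fc_threshold = 2) {
  check_paired(normal, stress)
  if (any(normal < 0) || any(stress < 0))
    stop("negative expression values", call. = FALSE)
  lfc <- log2((stress + pseudocount) / (normal + pseudocount))
  counts <- data.frame(gene_id = rownames(lfc),
                       up_count = rowSums(lfc >= fc_threshold),
                       down_count = rowSums(lfc <= -fc_threshold),
                       n_accessions = ncol(lfc),
                       stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(log2fc = lfc, counts = counts)
}

#' Classify population-level differential response
#'
#' With `t = floor(deg_min_fraction * N)` (N = panel size): a gene is
#' `salt_inducible` iff `up_count > t` and `down_count <= t`;
#' `salt_repressed` iff the reverse; `responsive_variable` iff both counts
#' exceed `t`; otherwise `non_DEG`. Inducible and repressed genes are further
#' placed into prevalence classes by their dominant count `n`, with band
#' edges at the rounded counts `round(0.5 N)` and `round(0.9 N)`: class A for
#' `t < n <= round(0.5N)`, B up to `round(0.9N)`, C up to `N` (at N = 202 and
#' a 10% floor this is the published 20 < n <= 101 / 101 < n <= 182 /
#' 182 < n <= 202 banding; the rounded edge is what puts n = 182 in class B).
#'
#' @param counts The `counts` data.frame from [compute_response()] (columns
#'   `gene_id`, `up_count`, `down_count`, `n_accessions`).
#' @param deg_min_fraction Prevalence floor as a fraction of the panel.
#' @return data.frame: `gene_id`, `category`, `prevalence_class` (`A`/`B`/`C`
#'   or `none`), `up_count`, `down_count`.
#' @export
classify_degs <- function(counts, deg_min_fraction = 0.1) {
  N <- counts$n_accessions
  t0 <- floor(deg_min_fraction * N)
  up <- counts$up_count
  dn <- counts$down_count
  category <- rep("non_DEG", nrow(counts))
  category[up > t0 & dn <= t0] <- "salt_inducible"
  category[dn > t0 & up <= t0] <- "salt_repressed"
  category[up > t0 & dn > t0] <- "responsive_variable"

  dominant <- pmax(up, dn)
  edgeA <- round(0.5 * N)
  edgeB <- round(0.9 * N)
  prevalence_class <- rep("none", nrow(counts))
  directional <- category %in% c("salt_inducible", "salt_repressed")
  prevalence_class[directional & dominant > t0 & dominant <= edgeA] <- "A"
  prevalence_class[directional & dominant > edgeA & dominant <= edgeB] <- "B"
  prevalence_class[directional & dominant > edgeB & dominant <= N] <- "C"

  data.frame(gene_id = counts$gene_id, category = category,
             prevalence_class = prevalence_class,
             up_count = up, down_count = dn, stringsAsFactors = FALSE)
}

#' Summarize DEG categories
#'
#' @param degs Output of [classify_degs()].
#' @return data.frame of counts and percentages per (category,
#'   prevalence_class).
#' @export
summarize_degs <- function(degs) {
  tab <- as.data.frame(table(category = degs$category,
                             prevalence_class = degs$prevalence_class),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "n_genes"
  tab$percent <- round(100 * tab$n_genes / nrow(degs), 2)
  rownames(tab) <- NULL
  tab[order(-tab$n_genes), ]
}
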