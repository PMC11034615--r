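#' Clump association results into independent peaks
#'
#' Greedy lead-SNP clumping for one response (gene or trait) in one
#' condition: the most significant remaining variant below the threshold
#' becomes a lead, and every remaining significant variant within
#' `clump_window_bp` of it on the same chromosome OR in LD with it
#' (dosage r-squared >= `clump_r2`) is absorbed into its peak; repeat until
#' no significant variant remains. Ties on p are broken by (chrom, pos), so
#' the decomposition does not depend on input order.
#'
#' @param results `data.frame` of association results for one response
#'   (columns `variant_id`, `chrom`, `pos`, `p`; `beta`, `se`, `r2` carried
#'   through if present).
#' @param G The [genotype_matrix()] (for LD between lead and candidates).
#' @param p_threshold Significance threshold; variants with `p` strictly
#'   below it seed/join peaks.
#' @param clump_window_bp,clump_r2 Absorption rules (either suffices).
#' @return `data.frame` of peaks ordered by `lead_p`: `lead_variant`,
#'   `chrom`, `pos`, `lead_p`, `lead_beta`, `lead_r2`, `n_members`,
#'   `span_start`, `span_end`, `members` (comma-joined ids).
#' @export
clump_peaks <- function(results, G, p_threshold,
                        clump_window_bp = 200000, clump_r2 = 0.2) {
  cols <- c("variant_id", "chrom", "pos", "p")
  stopifnot(all(cols %in% names(results)))
  sig <- results[results$p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty_peaks())
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  peaks <- list()
  while (nrow(sig) > 0L) {
    lead <- sig[1L, ]
    near <- sig$chrom == lead$chrom & abs(sig$pos - lead$pos) <= clump_window_bp
    linked <- rep(FALSE, nrow(sig))
    if (any(!near)) {
      r2 <- dosage_r2(G$dosages, lead$variant_id, sig$variant_id[!near])
      linked[!near] <- r2 >= clump_r2
    }
    member <- near | linked
    mem <- sig[member, , drop = FALSE]
    on_chrom <- mem[mem$chrom == lead$chrom, , drop = FALSE]
    peaks[[length(peaks) + 1L]] <- data.frame(
      lead_variant = lead$variant_id, chrom = lead$chrom, pos = lead$pos,
      lead_p = lead$p,
      lead_beta = if ("beta" %in% names(lead)) lead$beta else NA_real_,
      lead_r2 = if ("r2" %in% names(lead)) lead$r2 else NA_real_,
      n_members = nrow(mem),
      span_start = min(on_chrom$pos), span_end = max(on_chrom$pos),
      members = paste(mem$variant_id, collapse = ","),
      stringsAsFactors = FALSE)
    sig <- sig[!member, , drop = FALSE]
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$lead_p, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_peaks <- function() {
  data.frame(lead_variant = character(), chrom = character(), pos = integer(),
             lead_p = numeric(), lead_beta = numeric(), lead_r2 = numeric(),
             n_members = integer(), span_start = integer(),
             span_end = integer(), members = character(),
             stringsAsFactors = FALSE)
}

#' Classify peaks as cis or trans relative to their gene
#'
#' A peak is cis iff its lead variant lies on the gene's chromosome and the
#' distance from the lead position to the gene interval `[start, end]` is at
#' most `cis_window_bp` (boundary inclusive; distance 0 inside the gene
#' body). Leads farther away or on a different chromosome are trans. Strand
#' is ignored.
#'
#' @param peaks Peak `data.frame` from [clump_peaks()] (needs `chrom`, `pos`).
#' @param gene One row of an annotation `data.frame` (`chrom`, `start`,
#'   `end`), or `NULL`/missing coordinates to flag unclassifiable.
#' @param cis_window_bp Window size. Default 200,000.
#' @return `peaks` with a `cis_flag` column: `"cis"`, `"trans"`, or
#'   `"unclassified"` when the gene has no annotation.
#' @export
classify_cis_trans <- function(peaks, gene, cis_window_bp = 200000) {
  if (nrow(peaks) == 0L) {
    peaks$cis_flag <- character(0)
    return(peaks)
  }
  if (is.null(gene) || nrow(gene) == 0L || is.na(gene$chrom[1])) {
    peaks$cis_flag <- "unclassified"
    return(peaks)
  }
  d <- gene_distance(peaks$chrom, peaks$pos, gene$chrom[1], gene$start[1],
                     gene$end[1])
  peaks$cis_flag <- ifelse(is.finite(d) & d <= cis_window_bp, "cis", "trans")
  peaks
}

# distance from point positions to a gene interval; Inf across chromosomes
gene_distance <- function(chrom, pos, gchrom, gstart, gend) {
  d <- pmax(0, pmax(gstart - pos, pos - gend))
  d[chrom != gchrom] <- Inf
  d
}

#' Match one gene's peaks across conditions into static/dynamic categories
#'
#' A peak is static iff the other condition has a peak for the same gene
#' whose lead lies within `match_window_bp` (same chromosome) or whose lead
#' is in LD with it (dosage r-squared >= `clump_r2`). Matching is 1-to-1
#' greedy by ascending combined lead p, so two stress peaks cannot both claim
#' one normal peak. Unmatched peaks are dynamic, labelled with the condition
#' they were detected in.
#'
#' @param peaks_normal,peaks_stress Peak data.frames ([clump_peaks()] output)
#'   for the same gene.
#' @param G [genotype_matrix()] for lead-lead LD; `NULL` restricts matching
#'   to the distance rule.
#' @param match_window_bp,clump_r2 Matching rules.
#' @return List of the two data.frames with an added `category` column
#'   (`static`, `dynamic_normal_only`, `dynamic_stress_only`).
#' @export
match_conditions <- function(peaks_normal, peaks_stress, G = NULL,
                             match_window_bp = 200000, clump_r2 = 0.2) {
  pn <- peaks_normal
  ps <- peaks_stress
  pn$category <- rep("dynamic_normal_only", nrow(pn))
  ps$category <- rep("dynamic_stress_only", nrow(ps))
  if (nrow(pn) > 0L && nrow(ps) > 0L) {
    cand <- expand.grid(i = seq_len(nrow(pn)), j = seq_len(nrow(ps)))
    near <- pn$chrom[cand$i] == ps$chrom[cand$j] &
      abs(pn$pos[cand$i] - ps$pos[cand$j]) <= match_window_bp
    if (!is.null(G) && any(!near)) {
      far <- which(!near)
      for (k in far) {
        r2 <- dosage_r2(G$dosages, pn$lead_variant[cand$i[k]],
                        ps$lead_variant[cand$j[k]])
        near[k] <- r2 >= clump_r2
      }
    }
    cand <- cand[near, , drop = FALSE]
    if (nrow(cand) > 0L) {
      cand$combined <- log(pn$lead_p[cand$i]) + log(ps$lead_p[cand$j])
      cand <- cand[order(cand$combined), , drop = FALSE]
      used_i <- used_j <- logical(0)
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (i %in% used_i || j %in% used_j) next
        pn$category[i] <- "static"
        ps$category[j] <- "static"
        used_i <- c(used_i, i); used_j <- c(used_j, j)
      }
    }
  }
  list(normal = pn, stress = ps)
}

#' Build the per-gene eQTL catalogue
#'
#' Runs clumping, cis/trans classification and condition matching for every
#' gene, then rolls results up into eGene records: per-condition peak counts,
#' regulatory class (`cis_only` / `trans_only` / `both` / `none`), exclusion
#' of genes with more than `max_peaks_per_egene` peaks in either condition,
#' and the condition category (`static` when the gene is an eGene in both
#' conditions, `neGene` normal-only, `reGene` stress-only).
#'
#' @param scan_normal,scan_stress Full association results (all genes) for
#'   the two conditions, as returned by [association_scan()].
#' @param G [genotype_matrix()].
#' @param annotation Gene annotation `data.frame`.
#' @param cfg [analysis_config()]; `eqtl_p_threshold = NULL` resolves to
#'   `1 / n_variants_tested` of the scans.
#' @return List of class `eqtl_catalog`: `peaks` (one data.frame, columns
#'   incl. `gene_id`, `condition`, `cis_flag`, `category`), `egenes`
#'   (per-gene roll-up), `summary` (counts by condition/cis/category),
#'   `p_threshold`.
#' @export
build_egene_records <- function(scan_normal, scan_stress, G, annotation,
                                cfg = analysis_config()) {
  thr <- cfg$eqtl_p_threshold
  if (is.null(thr)) {
    m <- attr(scan_normal, "n_variants_tested")
    if (is.null(m)) m <- length(unique(scan_normal$variant_id))
    thr <- 1 / m
  }
  genes <- union(unique(scan_normal$response_id), unique(scan_stress$response_id))
  ann_idx <- split(seq_len(nrow(annotation)), annotation$gene_id)
  by_gene_n <- split(scan_normal, scan_normal$response_id)
  by_gene_s <- split(scan_stress, scan_stress$response_id)

  peak_rows <- vector("list", length(genes))
  names(peak_rows) <- genes
  for (g in genes) {
    pn <- clump_one(by_gene_n[[g]], G, thr, cfg)
    ps <- clump_one(by_gene_s[[g]], G, thr, cfg)
    if (nrow(pn) == 0L && nrow(ps) == 0L) next
    gene_ann <- annotation[ann_idx[[g]], , drop = FALSE]
    pn <- classify_cis_trans(pn, gene_ann, cfg$cis_window_bp)
    ps <- classify_cis_trans(ps, gene_ann, cfg$cis_window_bp)
    mm <- match_conditions(pn, ps, G, cfg$match_window_bp, cfg$clump_r2)
    add_id <- function(p, cond) {
      if (nrow(p) == 0L) return(NULL)
      cbind(gene_id = g, condition = cond, p,
            stringsAsFactors = FALSE)
    }
    peak_rows[[g]] <- rbind(add_id(mm$normal, "normal"),
                            add_id(mm$stress, "stress"))
  }
  peaks <- do.call(rbind, peak_rows)
  if (is.null(peaks))
    peaks <- cbind(gene_id = character(), condition = character(),
                   empty_peaks(), cis_flag = character(),
                   category = character())
  rownames(peaks) <- NULL

  egenes <- roll_up_egenes(peaks, genes, cfg$max_peaks_per_egene)
  summary <- summarize_catalog(peaks, egenes)
  structure(list(peaks = peaks, egenes = egenes, summary = summary,
                 p_threshold = thr), class = "eqtl_catalog")
}

clump_one <- function(res, G, thr, cfg) {
  if (is.null(res)) return(empty_peaks())
  clump_peaks(res, G, thr, cfg$clump_window_bp, cfg$clump_r2)
}

roll_up_egenes <- function(peaks, genes, max_peaks) {
  cnt <- function(g, cond) sum(peaks$gene_id == g & peaks$condition == cond)
  reg_class <- function(g, cond) {
    fl <- peaks$cis_flag[peaks$gene_id == g & peaks$condition == cond]
    fl <- fl[fl != "unclassified"]
    if (!length(fl)) return("none")
    if (all(fl == "cis")) return("cis_only")
    if (all(fl == "trans")) return("trans_only")
    "both"
  }
  rows <- lapply(genes, function(g) {
    nn <- cnt(g, "normal"); ns <- cnt(g, "stress")
    if (nn == 0L && ns == 0L) return(NULL)
    excluded <- (nn > max_peaks) || (ns > max_peaks)
    cond_cat <- if (nn > 0L && ns > 0L) "static"
                else if (nn > 0L) "neGene" else "reGene"
    data.frame(gene_id = g, n_peaks_normal = nn, n_peaks_stress = ns,
               excluded = excluded,
               regulatory_class_normal = reg_class(g, "normal"),
               regulatory_class_stress = reg_class(g, "stress"),
               condition_category = cond_cat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), n_peaks_normal = integer(),
                      n_peaks_stress = integer(), excluded = logical(),
                      regulatory_class_normal = character(),
                      regulatory_class_stress = character(),
                      condition_category = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

summarize_catalog <- function(peaks, egenes) {
  if (nrow(peaks) == 0L) return(data.frame())
  kept <- egenes$gene_id[!egenes$excluded]
  pk <- peaks[peaks$gene_id %in% kept, , drop = FALSE]
  tab <- as.data.frame(table(condition = pk$condition, cis_flag = pk$cis_flag,
                             category = pk$category), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[4] <- "n_peaks"
  rownames(tab) <- NULL
  tab
}

#' Scan for trans-eQTL hotspot windows
#'
#' Tiles the genome into fixed windows and counts, per window and condition,
#' the number of distinct eGenes whose trans lead falls inside. Enrichment is
#' a Poisson upper tail against the genome-wide mean count per window;
#' windows passing a Bonferroni-corrected alpha are reported. The underlying
#' criterion is exploratory — a hotspot call here flags a window for
#' inspection, not a validated regulatory hub.
#'
#' @param peaks Peak table (from [build_egene_records()]`$peaks`) —
#'   trans peaks are selected internally.
#' @param chrom_lengths Named vector of chromosome lengths (bp). Defaults to
#'   the maximum observed lead position per chromosome.
#' @param window_bp Tile size. Default 1e6.
#' @param alpha Family-wise error target before Bonferroni. Default 0.05.
#' @return `data.frame`: `condition`, `chrom`, `start`, `end`,
#'   `n_target_egenes`, `p_enrichment`.
#' @export
detect_hotspots <- function(peaks, chrom_lengths = NULL, window_bp = 1e6,
                            alpha = 0.05) {
  tp <- peaks[peaks$cis_flag == "trans", , drop = FALSE]
  if (nrow(tp) == 0L)
    return(data.frame(condition = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_target_egenes = integer(), p_enrichment = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(tp$pos, tp$chrom, max)
  wins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = window_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp - 1, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  n_windows <- nrow(wins)
  out <- list()
  for (cond in unique(tp$condition)) {
    pc <- tp[tp$condition == cond, , drop = FALSE]
    counts <- vapply(seq_len(n_windows), function(i) {
      inw <- pc$chrom == wins$chrom[i] & pc$pos >= wins$start[i] &
        pc$pos <= wins$end[i]
      length(unique(pc$gene_id[inw]))
    }, integer(1))
    rate <- sum(counts) / n_windows
    pval <- ppois(counts - 1L, rate, lower.tail = FALSE)
    hit <- pval < alpha / n_windows
    if (any(hit))
      out[[cond]] <- data.frame(condition = cond, wins[hit, , drop = FALSE],
                                n_target_egenes = counts[hit],
                                p_enrichment = pval[hit],
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(condition = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_target_egenes = integer(), p_enrichment = numeric(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
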