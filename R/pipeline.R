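#' Run the full discovery pipeline on a dataset bundle
#'
#' Executes the whole inference chain on aligned inputs: expression
#' filtering, population-level response classification, kinship-aware eQTL
#' scans in both conditions, peak clumping and the static/dynamic eGene
#' catalogue, mixed-model GWAS per trait, locus definition, per-candidate
#' colocalization, and evidence triangulation. Works directly on the bundle
#' returned by [simulate_dataset()] or on one assembled from
#' [read_vcf()]/[read_tables()] output with the same element names.
#'
#' @param dataset List with `genotypes`, `expression` (list `normal`,
#'   `stress`), `annotation`, `phenotypes` (optional), and optionally
#'   `truth` (its `nonsyn` table feeds the triangulation when no explicit
#'   `nonsyn` is given).
#' @param cfg [analysis_config()].
#' @param nonsyn Optional variant-consequence table (`gene_id` column).
#' @param coloc_condition Which condition's eQTL statistics are colocalized
#'   against the GWAS. Default `"stress"`.
#' @return List of class `dyneqtl_result`: `expressed`, `response`, `degs`,
#'   `kinship`, `scans` (`normal`, `stress`, `gwas`), `catalog`, `hotspots`,
#'   `loci`, `coloc`, `candidates`, `cfg`.
#' @export
run_pipeline <- function(dataset, cfg = analysis_config(), nonsyn = NULL,
                         coloc_condition = "stress") {
  G <- dataset$genotypes
  al <- align_panel(genotypes = G, expression = dataset$expression,
                    phenotypes = dataset$phenotypes)
  G <- al$genotypes
  expr <- al$expression
  phen <- al$phenotypes
  ann <- dataset$annotation

  # --- expression filter and response classification --------------------
  expressed <- filter_expressed(expr$normal, expr$stress, cfg$min_mean_fpkm)
  deg_universe <- union(expressed$expressed_normal, expressed$expressed_stress)
  response <- compute_response(expr$normal[deg_universe, , drop = FALSE],
                               expr$stress[deg_universe, , drop = FALSE],
                               pseudocount = cfg$pseudocount,
                               fc_threshold = cfg$fc_threshold)
  degs <- classify_degs(response$counts, cfg$deg_min_fraction)

  # --- eQTL scans (mixed model per gene, EMMAX-style) -------------------
  K <- compute_kinship(G)
  scan_cond <- function(cond) {
    genes <- expressed[[paste0("expressed_", cond)]]
    if (!length(genes)) return(NULL)
    association_scan(expr[[cond]][genes, , drop = FALSE], G, K = K,
                     mode = "mlm", maf_min = cfg$maf_min,
                     rank_normalize = cfg$rank_normalize, loco = cfg$loco)
  }
  scan_normal <- scan_cond("normal")
  scan_stress <- scan_cond("stress")
  catalog <- build_egene_records(scan_normal, scan_stress, G, ann, cfg)
  hotspots <- detect_hotspots(catalog$peaks, window_bp = cfg$hotspot_window_bp)

  # --- GWAS, loci, colocalization, triangulation ------------------------
  loci <- data.frame(locus_id = character(), traits = character(),
                     lead_variant = character(), chrom = character(),
                     pos = integer(), lead_p = numeric(), start = numeric(),
                     end = numeric(), n_candidate_genes = integer(),
                     candidate_genes = character(), stringsAsFactors = FALSE)
  gwas <- NULL
  coloc_by_gene <- list()
  candidates <- NULL
  if (!is.null(phen) && ncol(phen) > 0L) {
    gwas_list <- lapply(colnames(phen), function(tr) {
      y <- phen[[tr]]
      names(y) <- rownames(phen)
      keep <- names(y)[is.finite(y)]
      if (length(keep) < 10L) return(NULL)
      Gi <- if (length(keep) == length(y)) G else subset_genotypes(G, keep)
      Ki <- if (length(keep) == length(y)) K else compute_kinship(Gi)
      res <- association_scan(rbind(y[keep]), Gi, K = Ki, mode = "mlm",
                              maf_min = cfg$maf_min, loco = cfg$loco)
      res$response_id <- tr
      attr_n <- attr(res, "n_variants_tested")
      attr(res, "n_variants_tested") <- attr_n
      res
    })
    gwas_list <- Filter(Negate(is.null), gwas_list)
    if (length(gwas_list)) {
      n_tested <- attr(gwas_list[[1]], "n_variants_tested")
      gwas <- do.call(rbind, gwas_list)
      attr(gwas, "n_variants_tested") <- n_tested
      loci <- define_gwas_loci(gwas, G, ann, cfg)
    }
    if (nrow(loci) > 0L) {
      eqtl_scan <- if (coloc_condition == "stress") scan_stress else scan_normal
      for (i in seq_len(nrow(loci))) {
        reg_var <- G$variants$id[G$variants$chrom == loci$chrom[i] &
                                   G$variants$pos >= loci$start[i] &
                                   G$variants$pos <= loci$end[i]]
        traits_i <- strsplit(loci$traits[i], ",", fixed = TRUE)[[1]]
        gsub_rows <- gwas[gwas$variant_id %in% reg_var &
                            gwas$response_id %in% traits_i, , drop = FALSE]
        # colocalize against the trait with the strongest lead in the region
        lead_tr <- gsub_rows$response_id[which.min(gsub_rows$p)]
        gwas_region <- gsub_rows[gsub_rows$response_id == lead_tr, , drop = FALSE]
        genes_i <- strsplit(loci$candidate_genes[i], ",", fixed = TRUE)[[1]]
        for (g in genes_i) {
          eq <- eqtl_scan[eqtl_scan$response_id == g &
                            eqtl_scan$variant_id %in% reg_var, , drop = FALSE]
          if (nrow(eq) < 2L) next
          cres <- tryCatch(
            coloc_abf(gwas_region, eq, priors = cfg$coloc_priors,
                      effect_prior_sd_trait = cfg$effect_prior_sd,
                      effect_prior_sd_expr = cfg$effect_prior_sd),
            error = function(e) NULL)
          if (!is.null(cres)) coloc_by_gene[[g]] <- cres
        }
      }
      if (is.null(nonsyn) && !is.null(dataset$truth))
        nonsyn <- dataset$truth$nonsyn
      candidates <- triangulate(loci, degs, catalog$egenes,
                                coloc = coloc_by_gene, nonsyn = nonsyn,
                                cfg = cfg)
    }
  }

  structure(list(expressed = expressed, response = response, degs = degs,
                 kinship = K,
                 scans = list(normal = scan_normal, stress = scan_stress,
                              gwas = gwas),
                 catalog = catalog, hotspots = hotspots, loci = loci,
                 coloc = coloc_by_gene, candidates = candidates, cfg = cfg),
            class = "dyneqtl_result")
}

#' @export
print.dyneqtl_result <- function(x, ...) {
  cat("dyneqtl pipeline result\n")
  cat(sprintf("  expressed genes: %d normal / %d stress (%d common)\n",
              length(x$expressed$expressed_normal),
              length(x$expressed$expressed_stress),
              length(x$expressed$common)))
  cat(sprintf("  DEGs: %d of %d profiled genes\n",
              sum(x$degs$category != "non_DEG"), nrow(x$degs)))
  cat(sprintf("  eQTL peaks: %d (threshold %.3g); eGenes: %d\n",
              nrow(x$catalog$peaks), x$catalog$p_threshold,
              nrow(x$catalog$egenes)))
  cat(sprintf("  GWAS loci: %d; colocalized genes: %d; candidates ranked: %d\n",
              nrow(x$loci), length(x$coloc),
              if (is.null(x$candidates)) 0L else nrow(x$candidates)))
  invisible(x)
}

#' Write the principal pipeline tables to a directory
#'
#' @param result A `dyneqtl_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$cfg
  write_result_tsv(result$degs, file.path(dir, "degs.tsv"), cfg)
  write_result_tsv(result$catalog$peaks, file.path(dir, "eqtl_peaks.tsv"), cfg)
  write_result_tsv(result$catalog$egenes, file.path(dir, "egenes.tsv"), cfg)
  if (nrow(result$loci)) write_result_tsv(result$loci,
                                          file.path(dir, "gwas_loci.tsv"), cfg)
  if (!is.null(result$candidates))
    write_result_tsv(result$candidates, file.path(dir, "candidates.tsv"), cfg)
  if (length(result$coloc)) {
    cl <- do.call(rbind, lapply(names(result$coloc), function(g) {
      pp <- result$coloc[[g]]$pp
      data.frame(gene_id = g, t(pp), n_variants = result$coloc[[g]]$n_variants,
                 stringsAsFactors = FALSE)
    }))
    write_result_tsv(cl, file.path(dir, "coloc.tsv"), cfg)
  }
  invisible(dir)
}
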