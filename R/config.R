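#' Analysis configuration
#'
#' Bundles the thresholds and window sizes used across the pipeline. The
#' defaults encode the published analysis constants for this study design: a
#' 200 kb cis window, a fold-change threshold of 2 (log2 scale), a minimum
#' response prevalence of 10% of the panel for calling a gene differentially
#' expressed, exclusion of genes with more than 15 independent peaks, and a
#' colocalization posterior cut-off of 0.7.
#'
#' @param cis_window_bp Distance (bp) from a gene interval within which a lead
#'   variant is called cis; inclusive boundary. Default 200,000.
#' @param eqtl_p_threshold Per-test eQTL significance threshold. `NULL` (the
#'   default) means "compute as 1/m at scan time", m being the number of
#'   tested variants.
#' @param gwas_p_threshold GWAS significance threshold. `NULL` means Bonferroni
#'   0.05/m at scan time.
#' @param fc_threshold Per-accession |log2 fold change| needed to count an
#'   accession as responding. Default 2.
#' @param deg_min_fraction Fraction of the panel that must respond (in the
#'   dominant direction) before a gene is a DEG; the count threshold is
#'   `floor(deg_min_fraction * N)` and the comparison is strict (`>`).
#'   Default 0.1.
#' @param min_mean_fpkm Expression filter: a gene is "expressed" in a condition
#'   iff its mean FPKM across accessions is strictly greater than this.
#'   Default 0.1.
#' @param pseudocount Added to both conditions before the log2 ratio so that
#'   zero FPKM values give finite fold changes. Default 0.5.
#' @param max_peaks_per_egene eGenes with more peaks than this in either
#'   condition are excluded from category counts. Default 15.
#' @param clump_r2 Dosage r-squared with the lead above which a significant
#'   variant is absorbed into the lead's peak (and above which two leads in
#'   different conditions are matched). Default 0.2.
#' @param clump_window_bp Distance from the lead within which significant
#'   variants are absorbed regardless of LD. Default 200,000.
#' @param match_window_bp Lead-to-lead distance within which peaks of the same
#'   gene in the two conditions are matched as static. Default 200,000.
#' @param hotspot_window_bp Window size used to tile the genome when scanning
#'   for trans-eQTL hotspots. Default 1e6.
#' @param maf_min Minor-allele-frequency floor for tested variants.
#' @param missing_max Maximum per-variant missing-genotype fraction on read.
#' @param n_pcs Number of genotype principal components used as covariates in
#'   `ols_pcs` mode.
#' @param coloc_priors Named vector `c(p1=, p2=, p12=)` of per-variant prior
#'   probabilities of association with study 1 only, study 2 only, and both.
#' @param coloc_pp_threshold Posterior mass required on the configured
#'   hypothesis for a colocalization pass. Default 0.7.
#' @param coloc_hypothesis Which posterior is compared to the threshold;
#'   `"PP4"` (one shared variant, the default) or `"PP3"` (two distinct
#'   variants — reported for comparability, but a pass on PP3 argues against
#'   colocalization and triggers a warning).
#' @param effect_prior_sd Prior standard deviation of the (standardized) effect
#'   size used in the approximate Bayes factors, for both studies.
#' @param rank_normalize Whether expression responses are transformed to
#'   normal scores per gene before eQTL scanning.
#' @param loco Use leave-one-chromosome-out kinship in the mixed-model scans
#'   (removes proximal contamination; standard practice). Default `TRUE`.
#' @param rng_seed Seed recorded in output headers.
#'
#' @return A list of class `dyneqtl_config`.
#' @export
analysis_config <- function(cis_window_bp = 200000L,
                            eqtl_p_threshold = NULL,
                            gwas_p_threshold = NULL,
                            fc_threshold = 2,
                            deg_min_fraction = 0.1,
                            min_mean_fpkm = 0.1,
                            pseudocount = 0.5,
                            max_peaks_per_egene = 15L,
                            clump_r2 = 0.2,
                            clump_window_bp = 200000L,
                            match_window_bp = 200000L,
                            hotspot_window_bp = 1e6,
                            maf_min = 0.05,
                            missing_max = 0.1,
                            n_pcs = 5L,
                            coloc_priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                            coloc_pp_threshold = 0.7,
                            coloc_hypothesis = c("PP4", "PP3"),
                            effect_prior_sd = 0.15,
                            rank_normalize = TRUE,
                            loco = TRUE,
                            rng_seed = 1L) {
  coloc_hypothesis <- match.arg(coloc_hypothesis)
  cfg <- list(
    cis_window_bp = as.integer(cis_window_bp),
    eqtl_p_threshold = eqtl_p_threshold,
    gwas_p_threshold = gwas_p_threshold,
    fc_threshold = fc_threshold,
    deg_min_fraction = deg_min_fraction,
    min_mean_fpkm = min_mean_fpkm,
    pseudocount = pseudocount,
    max_peaks_per_egene = as.integer(max_peaks_per_egene),
    clump_r2 = clump_r2,
    clump_window_bp = as.numeric(clump_window_bp),
    match_window_bp = as.numeric(match_window_bp),
    hotspot_window_bp = as.numeric(hotspot_window_bp),
    maf_min = maf_min,
    missing_max = missing_max,
    n_pcs = as.integer(n_pcs),
    coloc_priors = coloc_priors,
    coloc_pp_threshold = coloc_pp_threshold,
    coloc_hypothesis = coloc_hypothesis,
    effect_prior_sd = effect_prior_sd,
    rank_normalize = isTRUE(rank_normalize),
    loco = isTRUE(loco),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "dyneqtl_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("cis_window_bp", "fc_threshold", "pseudocount", "max_peaks_per_egene",
           "clump_window_bp", "match_window_bp", "hotspot_window_bp",
           "effect_prior_sd")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a single positive number", call. = FALSE)
  }
  for (f in c("eqtl_p_threshold", "gwas_p_threshold")) {
    v <- cfg[[f]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0 || v > 1))
      stop("config field '", f, "' must be NULL or in (0, 1]", call. = FALSE)
  }
  if (cfg$deg_min_fraction <= 0 || cfg$deg_min_fraction >= 1)
    stop("deg_min_fraction must lie in (0, 1)", call. = FALSE)
  if (cfg$clump_r2 <= 0 || cfg$clump_r2 > 1)
    stop("clump_r2 must lie in (0, 1]", call. = FALSE)
  if (cfg$coloc_pp_threshold <= 0 || cfg$coloc_pp_threshold > 1)
    stop("coloc_pp_threshold must lie in (0, 1]", call. = FALSE)
  pr <- cfg$coloc_priors
  if (!all(c("p1", "p2", "p12") %in% names(pr)) || any(pr <= 0) || sum(pr) >= 1)
    stop("coloc_priors must name positive p1, p2, p12 with sum < 1", call. = FALSE)
  invisible(cfg)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Fields present in the file override `analysis_config()` defaults; unknown
#' fields are an error so that typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A `dyneqtl_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(vals$coloc_priors)) vals$coloc_priors <- unlist(vals$coloc_priors)
  do.call(analysis_config, vals)
}

#' @export
print.dyneqtl_config <- function(x, ...) {
  cat("dyneqtl analysis configuration\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-22s %s\n", f,
                if (is.null(v)) "(set at scan time)" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  # small rolling hash; only used to stamp output files
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
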