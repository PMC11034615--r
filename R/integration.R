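#' Define GWAS loci and their candidate-gene windows
#'
#' Clumps significant trait associations with the same rule as the eQTL
#' peaks, extends each peak's span by `cis_window_bp` on both sides, and
#' lists annotated genes overlapping the region. Loci from different traits
#' whose leads fall within `match_window_bp` of each other are merged and
#' labelled with all supporting traits.
#'
#' @param gwas_results Association results for one or more traits
#'   ([association_scan()] output; `response_id` = trait).
#' @param G [genotype_matrix()].
#' @param annotation Gene annotation `data.frame`.
#' @param cfg [analysis_config()]; `gwas_p_threshold = NULL` resolves to
#'   Bonferroni `0.05 / n_variants_tested`.
#' @return `data.frame`: `locus_id`, `traits` (comma-joined), `lead_variant`,
#'   `chrom`, `pos`, `lead_p`, `start`, `end`, `n_candidate_genes`,
#'   `candidate_genes` (comma-joined gene ids). Empty (not an error) when no
#'   variant is significant.
#' @export
define_gwas_loci <- function(gwas_results, G, annotation,
                             cfg = analysis_config()) {
  thr <- cfg$gwas_p_threshold
  if (is.null(thr)) {
    m <- attr(gwas_results, "n_variants_tested")
    if (is.null(m)) m <- length(unique(gwas_results$variant_id))
    thr <- 0.05 / m
  }
  per_trait <- split(gwas_results, gwas_results$response_id)
  loci <- list()
  for (trait in names(per_trait)) {
    pk <- clump_peaks(per_trait[[trait]], G, thr,
                      cfg$clump_window_bp, cfg$clump_r2)
    if (nrow(pk) == 0L) next
    pk$trait <- trait
    loci[[trait]] <- pk
  }
  loci <- do.call(rbind, loci)
  if (is.null(loci) || nrow(loci) == 0L)
    return(data.frame(locus_id = character(), traits = character(),
                      lead_variant = character(), chrom = character(),
                      pos = integer(), lead_p = numeric(), start = numeric(),
                      end = numeric(), n_candidate_genes = integer(),
                      candidate_genes = character(), stringsAsFactors = FALSE))
  loci <- loci[order(loci$lead_p), , drop = FALSE]

  # merge cross-trait loci with nearby leads (keep the most significant lead)
  merged <- list()
  for (i in seq_len(nrow(loci))) {
    placed <- FALSE
    for (k in seq_along(merged)) {
      m <- merged[[k]]
      if (m$chrom == loci$chrom[i] &&
          abs(m$pos - loci$pos[i]) <= cfg$match_window_bp) {
        merged[[k]]$traits <- union(m$traits, loci$trait[i])
        merged[[k]]$span_start <- min(m$span_start, loci$span_start[i])
        merged[[k]]$span_end <- max(m$span_end, loci$span_end[i])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      merged[[length(merged) + 1L]] <-
        list(chrom = loci$chrom[i], pos = loci$pos[i],
             lead_variant = loci$lead_variant[i], lead_p = loci$lead_p[i],
             span_start = loci$span_start[i], span_end = loci$span_end[i],
             traits = loci$trait[i])
  }
  rows <- lapply(seq_along(merged), function(k) {
    m <- merged[[k]]
    start <- max(1, m$span_start - cfg$cis_window_bp)
    end <- m$span_end + cfg$cis_window_bp
    genes <- annotation$gene_id[annotation$chrom == m$chrom &
                                  annotation$end >= start &
                                  annotation$start <= end]
    data.frame(locus_id = sprintf("locus_%02d", k),
               traits = paste(sort(m$traits), collapse = ","),
               lead_variant = m$lead_variant, chrom = m$chrom, pos = m$pos,
               lead_p = m$lead_p, start = start, end = end,
               n_candidate_genes = length(genes),
               candidate_genes = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Colocalization of a trait and an expression signal by approximate Bayes
#' factors
#'
#' For each variant shared between the two studies, the approximate Bayes
#' factor against the null is `sqrt(1 - r) * exp(z^2 r / 2)` with
#' `z = beta/se` and `r = W / (W + se^2)`, `W` being the prior effect
#' variance. Evidence is combined over the five hypotheses — H0 no
#' association, H1 trait only, H2 expression only, H3 two distinct causal
#' variants, H4 one shared causal variant — with per-variant priors
#' `(p1, p2, p12)`, and posteriors are normalized.
#'
#' @param gwas_region,eqtl_region `data.frame`s with `variant_id`, `beta`,
#'   `se` covering the region (intersected by variant id; non-finite `se`
#'   rows are dropped).
#' @param priors Named vector `c(p1=, p2=, p12=)`.
#' @param effect_prior_sd_trait,effect_prior_sd_expr Prior SD of effect sizes
#'   in the two studies.
#' @return List of class `coloc_result`: `pp` (named PP0..PP4, summing to 1),
#'   `n_variants`, `priors`, `lead_variant` (largest joint ABF).
#' @export
coloc_abf <- function(gwas_region, eqtl_region,
                      priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                      effect_prior_sd_trait = 0.15,
                      effect_prior_sd_expr = 0.15) {
  g <- gwas_region[is.finite(gwas_region$se) & gwas_region$se > 0, , drop = FALSE]
  e <- eqtl_region[is.finite(eqtl_region$se) & eqtl_region$se > 0, , drop = FALSE]
  shared <- intersect(g$variant_id, e$variant_id)
  if (length(shared) < 2L)
    stop("fewer than 2 shared variants between studies", call. = FALSE)
  g <- g[match(shared, g$variant_id), ]
  e <- e[match(shared, e$variant_id), ]

  labf1 <- log_abf(g$beta, g$se, effect_prior_sd_trait)
  labf2 <- log_abf(e$beta, e$se, effect_prior_sd_expr)

  lp1 <- log(priors[["p1"]]); lp2 <- log(priors[["p2"]])
  lp12 <- log(priors[["p12"]])
  lH0 <- 0
  lH1 <- lp1 + logsumexp(labf1)
  lH2 <- lp2 + logsumexp(labf2)
  lH4 <- lp12 + logsumexp(labf1 + labf2)
  # H3: sum over ordered pairs i != j = (sum_i)(sum_j) - sum_{i==j}
  l_all <- logsumexp(labf1) + logsumexp(labf2)
  l_same <- logsumexp(labf1 + labf2)
  diff <- l_same - l_all
  lH3 <- if (diff >= 0) -Inf else lp1 + lp2 + l_all + log1p(-exp(diff))

  lh <- c(PP0 = lH0, PP1 = lH1, PP2 = lH2, PP3 = lH3, PP4 = lH4)
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_variants = length(shared), priors = priors,
                 lead_variant = shared[which.max(labf1 + labf2)]),
            class = "coloc_result")
}

log_abf <- function(beta, se, prior_sd) {
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log1p(-r) + z^2 * r)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc over %d shared variants: %s\n", x$n_variants,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " ")))
  invisible(x)
}

#' Gene-set enrichment of one set within another
#'
#' Builds the 2x2 table (in/out of `query` x in/out of `target`) over the
#' `universe` and tests it by chi-square (df = 1, no continuity correction)
#' or a hypergeometric upper tail. Fold enrichment is observed overlap over
#' the overlap expected under independence.
#'
#' @param query,target Character vectors of gene ids, subsets of `universe`.
#' @param universe Background gene universe (nonempty).
#' @param method `"chi_square"` (default) or `"hypergeometric"`.
#' @return List: `statistic` (chi-square value; `NA` for hypergeometric),
#'   `p`, `fold_enrichment`, `overlap`, `expected`, `table`.
#' @export
gene_set_enrichment <- function(query, target, universe,
                                method = c("chi_square", "hypergeometric")) {
  method <- match.arg(method)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  target <- intersect(unique(target), universe)
  N <- length(universe)
  a <- length(intersect(query, target))
  b <- length(query) - a
  cc <- length(target) - a
  d <- N - a - b - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(query = c("in", "out"),
                                target = c("in", "out")))
  expected <- length(query) * length(target) / N
  fold <- if (expected > 0) a / expected else NA_real_
  if (method == "chi_square") {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic)
    p <- unname(ct$p.value)
  } else {
    stat <- NA_real_
    p <- phyper(a - 1, length(target), N - length(target), length(query),
                lower.tail = FALSE)
  }
  list(statistic = stat, p = p, fold_enrichment = fold, overlap = a,
       expected = expected, table = tab)
}

#' Group accessions by haplotype at defining variants and compare traits
#'
#' Accessions are grouped by their exact dosage pattern at the defining
#' variants (e.g. promoter and exon SNPs of a candidate gene); accessions
#' missing a call at any defining site are set aside. Groups smaller than
#' `min_group` are dropped as outliers and reported. Every retained pair of
#' groups is compared per trait with a two-sample t-test (Welch by default).
#'
#' @param G [genotype_matrix()].
#' @param defining_variants Variant ids present in `G`.
#' @param phenotypes Phenotype `data.frame` (accessions in rows).
#' @param traits Trait column names to compare; default all.
#' @param min_group Minimum group size. Default 5.
#' @param pooled_var Use the pooled-variance (classical Student) t-test
#'   instead of Welch.
#' @return List: `groups` (`haplotype`, `pattern`, `n`, per-trait mean/sd),
#'   `tests` (pairwise t-test table), `outliers` (excluded accessions and
#'   why), `assignments` (accession -> haplotype).
#' @export
haplotype_compare <- function(G, defining_variants, phenotypes, traits = NULL,
                              min_group = 5L, pooled_var = FALSE) {
  missing_v <- setdiff(defining_variants, G$variants$id)
  if (length(missing_v))
    stop("defining variant(s) not in genotype matrix: ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  if (is.null(traits)) traits <- colnames(phenotypes)
  common <- intersect(G$accessions, rownames(phenotypes))
  dos <- G$dosages[common, defining_variants, drop = FALSE]
  has_na <- rowSums(is.na(dos)) > 0
  pattern <- apply(dos, 1, paste, collapse = "/")
  pattern[has_na] <- NA

  outliers <- data.frame(accession = common[has_na],
                         reason = rep("missing_genotype", sum(has_na)),
                         stringsAsFactors = FALSE)
  ok <- !has_na
  tab <- sort(table(pattern[ok]), decreasing = TRUE)
  small <- names(tab)[tab < min_group]
  if (length(small)) {
    drop_acc <- common[ok][pattern[ok] %in% small]
    outliers <- rbind(outliers,
                      data.frame(accession = drop_acc,
                                 reason = rep("rare_haplotype",
                                              length(drop_acc)),
                                 stringsAsFactors = FALSE))
    ok <- ok & !(pattern %in% small)
  }
  kept <- names(tab)[tab >= min_group]
  hap_names <- setNames(paste0("Hap", seq_along(kept)), kept)
  assignments <- data.frame(accession = common[ok],
                            haplotype = hap_names[pattern[ok]],
                            stringsAsFactors = FALSE)

  groups <- do.call(rbind, lapply(kept, function(pt) {
    acc <- common[ok][pattern[ok] == pt]
    row <- data.frame(haplotype = hap_names[[pt]], pattern = pt,
                      n = length(acc), stringsAsFactors = FALSE)
    for (tr in traits) {
      v <- phenotypes[acc, tr]
      row[[paste0(tr, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(tr, "_sd")]] <- sd(v, na.rm = TRUE)
    }
    row
  }))
  rownames(groups) <- NULL

  tests <- NULL
  if (length(kept) >= 2L) {
    pairs <- utils::combn(seq_along(kept), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      acc_i <- common[ok][pattern[ok] == kept[i]]
      acc_j <- common[ok][pattern[ok] == kept[j]]
      do.call(rbind, lapply(traits, function(tr) {
        vi <- phenotypes[acc_i, tr]; vj <- phenotypes[acc_j, tr]
        tt <- tryCatch(t.test(vi, vj, var.equal = pooled_var),
                       error = function(err) NULL)
        data.frame(group1 = hap_names[[kept[i]]], group2 = hap_names[[kept[j]]],
                   trait = tr,
                   mean1 = mean(vi, na.rm = TRUE), mean2 = mean(vj, na.rm = TRUE),
                   t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                   p = if (is.null(tt)) NA_real_ else tt$p.value,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(tests) <- NULL
  }
  list(groups = groups, tests = tests, outliers = outliers,
       assignments = assignments)
}

#' Triangulate candidate genes across evidence sets
#'
#' For every candidate gene of every GWAS locus, sets the evidence flags —
#' differential response (DEG), stress-only eGene (reGene), colocalization
#' pass, presence of a non-synonymous variant — and ranks genes by the number
#' of satisfied flags (ties: shared-variant posterior, then locus lead p).
#' The colocalization pass compares the configured posterior (PP4 by default)
#' to `coloc_pp_threshold`; when PP3 instead passes, a warning is emitted,
#' since mass on "two distinct variants" argues against a shared one.
#'
#' @param loci Output of [define_gwas_loci()].
#' @param degs Output of [classify_degs()].
#' @param egenes The `egenes` roll-up from [build_egene_records()].
#' @param coloc Named list of `coloc_result`s keyed by gene id (or `NULL`).
#' @param nonsyn `data.frame` with a `gene_id` column (genes carrying a
#'   non-synonymous variant), or `NULL`.
#' @param cfg [analysis_config()].
#' @return `data.frame` of class `candidate_report`: one row per
#'   (locus, gene) with flags `in_DEG`, `deg_category`, `in_reGene`,
#'   `coloc_pass`, `coloc_pp3`, `coloc_pp4`, `has_nonsyn_variant`,
#'   `rank_score`, ordered best-first.
#' @export
triangulate <- function(loci, degs, egenes, coloc = NULL, nonsyn = NULL,
                        cfg = analysis_config()) {
  if (nrow(loci) == 0L)
    return(data.frame(locus_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  deg_cat <- setNames(degs$category, degs$gene_id)
  egene_cat <- setNames(egenes$condition_category, egenes$gene_id)
  egene_excl <- setNames(egenes$excluded, egenes$gene_id)
  nonsyn_genes <- if (is.null(nonsyn)) character(0) else unique(nonsyn$gene_id)

  rows <- list()
  for (i in seq_len(nrow(loci))) {
    genes <- strsplit(loci$candidate_genes[i], ",", fixed = TRUE)[[1]]
    genes <- genes[nzchar(genes)]
    for (g in genes) {
      cat_g <- unname(deg_cat[match(g, names(deg_cat))])
      in_deg <- !is.na(cat_g) && cat_g != "non_DEG"
      ecat <- unname(egene_cat[match(g, names(egene_cat))])
      in_regene <- !is.na(ecat) && ecat == "reGene" &&
        !isTRUE(unname(egene_excl[match(g, names(egene_excl))]))
      pp3 <- pp4 <- NA_real_
      cres <- coloc[[g]]
      if (!is.null(cres)) {
        pp3 <- unname(cres$pp[["PP3"]])
        pp4 <- unname(cres$pp[["PP4"]])
      }
      pass_pp <- if (cfg$coloc_hypothesis == "PP4") pp4 else pp3
      coloc_pass <- !is.na(pass_pp) && pass_pp >= cfg$coloc_pp_threshold
      if (cfg$coloc_hypothesis == "PP4" && !is.na(pp3) &&
          pp3 >= cfg$coloc_pp_threshold)
        warning("gene ", g, ": PP3 (two distinct variants) exceeds the ",
                "threshold — evidence against a shared causal variant",
                call. = FALSE)
      has_ns <- g %in% nonsyn_genes
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loci$locus_id[i], gene_id = g,
        traits = loci$traits[i], lead_p = loci$lead_p[i],
        in_DEG = in_deg, deg_category = cat_g, in_reGene = in_regene,
        coloc_pass = coloc_pass, coloc_pp3 = pp3, coloc_pp4 = pp4,
        has_nonsyn_variant = has_ns,
        rank_score = sum(in_deg, in_regene, coloc_pass, has_ns),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  tie_pp <- ifelse(is.na(out$coloc_pp4), -1, out$coloc_pp4)
  out <- out[order(-out$rank_score, -tie_pp, out$lead_p, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' Narrow a candidate report by successive evidence requirements
#'
#' Applies flag requirements cumulatively, returning the surviving gene count
#' at each stage; adding a requirement can only shrink the set (monotone
#' narrowing).
#'
#' @param report A `candidate_report` from [triangulate()].
#' @param require Character vector of flag columns, applied left to right
#'   (e.g. `c("has_nonsyn_variant", "in_DEG", "in_reGene")`).
#' @return List: `stages` (`data.frame` of requirement and surviving count)
#'   and `final` (the narrowed report).
#' @export
narrow_candidates <- function(report,
                              require = c("has_nonsyn_variant", "in_DEG",
                                          "in_reGene")) {
  cur <- report
  stages <- data.frame(requirement = c("(none)", require),
                       n_genes = NA_integer_, stringsAsFactors = FALSE)
  stages$n_genes[1] <- length(unique(cur$gene_id))
  for (k in seq_along(require)) {
    fl <- require[k]
    if (!fl %in% names(cur)) stop("unknown flag: ", fl, call. = FALSE)
    cur <- cur[which(cur[[fl]]), , drop = FALSE]
    stages$n_genes[k + 1] <- length(unique(cur$gene_id))
  }
  list(stages = stages, final = cur)
}
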