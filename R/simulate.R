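#' Simulation specification
#'
#' Parameters of the synthetic diversity panel. Defaults emulate the study
#' design the pipeline targets, at desk scale: 202 accessions in two
#' subpopulations (139/63, the indica/japonica split), strong
#' allele-frequency divergence (Balding-Nichols F = 0.3), SNPs in LD blocks
#' with adjacent-pair r-squared about 0.8, log-normal expression noise, and
#' planted cis/trans effects in the three condition categories plus
#' fold-change response genes in the three prevalence classes. One planted
#' trait QTL shares its causal variant with a planted stress-only cis effect
#' of a planted salt-inducible gene, so the full discovery chain has a known
#' answer.
#'
#' @param n_accessions Panel size. Default 202.
#' @param subpop_fraction Fraction of accessions in subpopulation 1.
#'   Default 139/202.
#' @param fst_like_divergence Balding-Nichols F controlling subpopulation
#'   allele-frequency divergence; 0 gives an unstructured panel.
#' @param n_snps,n_chromosomes,snp_spacing_bp Marker panel: `n_snps` spread
#'   evenly over `n_chromosomes` at `snp_spacing_bp` intervals.
#' @param block_length_snps,within_block_r2 LD structure: adjacent SNPs within
#'   a block are generated by a neighbour-copying process calibrated so their
#'   dosage r-squared is about `within_block_r2`.
#' @param maf_min Minimum empirical minor allele frequency; failing variant
#'   columns are resampled.
#' @param n_genes,gene_length_bp Genes placed evenly along the chromosomes.
#' @param n_static_cis,n_dynamic_cis_stress_only,n_dynamic_cis_normal_only
#'   Planted cis effects per condition category.
#' @param n_trans Planted static trans effects (causal variant on another
#'   chromosome).
#' @param cis_pve,trans_pve Length-2 ranges (or scalars) of the variance in
#'   log expression explained by a planted variant; drawn uniformly per gene.
#' @param n_response_per_class Planted salt-inducible and salt-repressed genes
#'   per prevalence class (A, B, C).
#' @param n_variable Planted responsive-variable genes (both directions).
#' @param n_condition_specific Genes expressed in only one condition (half
#'   normal-only, half stress-only; mean FPKM below the expression filter in
#'   the other condition).
#' @param response_shift_log2 Range of the per-responder |log2 fold change|
#'   shift; the lower end sits above `fc_threshold` so planted responders
#'   clear the calling threshold despite noise.
#' @param fc_threshold log2 fold-change threshold the planted responses are
#'   designed against. Default 2.
#' @param expr_noise_sd SD of the accession-level log-normal expression noise
#'   (natural-log scale). Default 0.4.
#' @param baseline_log_mean,baseline_log_sd Distribution of gene baseline
#'   log expression (natural-log FPKM scale).
#' @param trait_heritability Total genetic fraction of trait variance,
#'   in `[0, 1)`; 0 gives genotype-independent traits.
#' @param qtl_pve Variance fraction of the planted trait QTL (capped at the
#'   heritability).
#' @param coloc_pair If `TRUE`, the trait QTL variant is the causal variant of
#'   a planted stress-only cis-eQTL whose gene is also planted salt-inducible
#'   (class C).
#' @param nonsyn_fraction Fraction of genes assigned a synthetic
#'   non-synonymous variant in the consequence table.
#' @param rng_seed Master seed; all three generator stages derive their
#'   streams from it, so identical (spec, seed) gives bit-identical output.
#'
#' @return A list of class `sim_spec`.
#' @export
simulation_spec <- function(n_accessions = 202L,
                            subpop_fraction = 139 / 202,
                            fst_like_divergence = 0.3,
                            n_snps = 2000L,
                            n_chromosomes = 5L,
                            snp_spacing_bp = 10000L,
                            block_length_snps = 20L,
                            within_block_r2 = 0.8,
                            maf_min = 0.05,
                            n_genes = 150L,
                            gene_length_bp = 3000L,
                            n_static_cis = 10L,
                            n_dynamic_cis_stress_only = 10L,
                            n_dynamic_cis_normal_only = 10L,
                            n_trans = 10L,
                            cis_pve = c(0.2, 0.3),
                            trans_pve = c(0.05, 0.15),
                            n_response_per_class = 5L,
                            n_variable = 5L,
                            n_condition_specific = 10L,
                            response_shift_log2 = c(3.5, 5.5),
                            fc_threshold = 2,
                            expr_noise_sd = 0.4,
                            baseline_log_mean = log(5),
                            baseline_log_sd = 1.2,
                            trait_heritability = 0.5,
                            qtl_pve = 0.25,
                            coloc_pair = TRUE,
                            nonsyn_fraction = 0.3,
                            rng_seed = 1L) {
  spec <- as.list(environment())
  spec$n_accessions <- as.integer(n_accessions)
  spec$n_snps <- as.integer(n_snps)
  spec$n_chromosomes <- as.integer(n_chromosomes)
  spec$block_length_snps <- as.integer(block_length_snps)
  spec$n_genes <- as.integer(n_genes)
  spec$rng_seed <- as.integer(rng_seed)
  if (length(spec$cis_pve) == 1L) spec$cis_pve <- rep(spec$cis_pve, 2L)
  if (length(spec$trans_pve) == 1L) spec$trans_pve <- rep(spec$trans_pve, 2L)
  class(spec) <- "sim_spec"
  validate_sim_spec(spec)
  spec
}

validate_sim_spec <- function(spec) {
  with(spec, {
    if (n_accessions < 4L) stop("n_accessions too small", call. = FALSE)
    if (subpop_fraction <= 0 || subpop_fraction >= 1)
      stop("subpop_fraction must lie in (0, 1)", call. = FALSE)
    if (fst_like_divergence < 0 || fst_like_divergence >= 1)
      stop("fst_like_divergence must lie in [0, 1)", call. = FALSE)
    if (within_block_r2 <= 0 || within_block_r2 > 1)
      stop("within_block_r2 must lie in (0, 1]", call. = FALSE)
    if (block_length_snps > ceiling(n_snps / n_chromosomes))
      stop("block_length_snps exceeds per-chromosome SNP count", call. = FALSE)
    if (trait_heritability < 0 || trait_heritability >= 1)
      stop("trait_heritability must lie in [0, 1)", call. = FALSE)
    if (any(c(cis_pve, trans_pve) <= 0) || any(c(cis_pve, trans_pve) >= 1))
      stop("planted PVE values must lie in (0, 1)", call. = FALSE)
    planted <- n_static_cis + n_dynamic_cis_stress_only +
      n_dynamic_cis_normal_only + n_trans + 6L * n_response_per_class +
      n_variable + n_condition_specific
    if (planted > n_genes)
      stop("planted gene roles (", planted, ") exceed n_genes (", n_genes, ")",
           call. = FALSE)
  })
  invisible(spec)
}

# chromosome/block layout shared by the genotype and expression generators
sim_layout <- function(spec) {
  per_chr <- diff(round(seq(0, spec$n_snps, length.out = spec$n_chromosomes + 1L)))
  chrom <- rep(paste0("chr", seq_len(spec$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(m) spec$snp_spacing_bp * seq_len(m)))
  block <- unlist(lapply(seq_along(per_chr), function(ci) {
    b <- ceiling(seq_len(per_chr[ci]) / spec$block_length_snps)
    paste0(ci, "_", b)
  }))
  list(chrom = chrom, pos = as.integer(pos), block = block, per_chr = per_chr,
       chrom_len = as.integer(per_chr * spec$snp_spacing_bp))
}

#' Simulate structured genotypes
#'
#' Two subpopulations with Balding-Nichols allele-frequency divergence; within
#' each LD block, haplotype alleles are generated by a neighbour-copying
#' process (copy the previous SNP's allele with probability
#' `sqrt(within_block_r2)`, else redraw from the block's subpopulation
#' frequency), which gives adjacent-pair dosage r-squared of about
#' `within_block_r2` while preserving marginal frequencies. Variant columns
#' whose empirical MAF falls below `maf_min` are resampled.
#'
#' @param spec A [simulation_spec()].
#' @return A [genotype_matrix()] with an `attr(, "subpop")` integer vector
#'   recording the planted subpopulation of each accession.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_accessions
  lay <- sim_layout(spec)
  m <- spec$n_snps
  n1 <- round(n * spec$subpop_fraction)
  subpop <- rep(c(1L, 2L), c(n1, n - n1))
  hap_pop <- rep(subpop, each = 2L)
  copy_p <- sqrt(spec$within_block_r2)
  FST <- spec$fst_like_divergence

  H <- matrix(0L, nrow = 2L * n, ncol = m)
  freqs <- matrix(0, nrow = 2L, ncol = m)   # per-subpop allele freq per variant
  for (bl in unique(lay$block)) {
    cols <- which(lay$block == bl)
    p0 <- runif(1, 0.15, 0.85)
    pk <- if (FST > 0)
      rbeta(2L, p0 * (1 - FST) / FST, (1 - p0) * (1 - FST) / FST)
    else rep(p0, 2L)
    pk <- pmin(pmax(pk, 0.1), 0.9)
    freqs[, cols] <- pk
    prow <- pk[hap_pop]
    L <- length(cols)
    D <- matrix(rbinom(2L * n * L, 1L, rep(prow, L)), nrow = 2L * n)
    cp <- matrix(runif(2L * n * L) < copy_p, nrow = 2L * n)
    Hb <- D
    if (L > 1L) for (j in 2:L)
      Hb[, j] <- ifelse(cp[, j], Hb[, j - 1L], D[, j])
    H[, cols] <- Hb
  }
  dos <- H[seq(1L, 2L * n, 2L), , drop = FALSE] +
         H[seq(2L, 2L * n, 2L), , drop = FALSE]

  # enforce the MAF floor by resampling failing columns (LD for that column
  # is sacrificed; with frequencies clamped to [0.1, 0.9] this is rare)
  maf <- variant_maf(dos)
  for (it in seq_len(50L)) {
    bad <- which(maf < spec$maf_min)
    if (!length(bad)) break
    for (j in bad) {
      prow <- freqs[hap_pop, j]
      dos[, j] <- rbinom(n, 1L, freqs[subpop, j]) + rbinom(n, 1L, freqs[subpop, j])
    }
    maf <- variant_maf(dos)
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  variants <- data.frame(id = sprintf("snp_%05d", seq_len(m)),
                         chrom = lay$chrom, pos = lay$pos,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  rownames(dos) <- sprintf("acc_%03d", seq_len(n))
  G <- genotype_matrix(dos, variants)
  attr(G, "subpop") <- subpop
  G
}

# evenly spaced gene placement; strand alternates, which downstream code
# ignores for cis distance
sim_annotation <- function(spec, lay) {
  per_chr_genes <- diff(round(seq(0, spec$n_genes,
                                  length.out = spec$n_chromosomes + 1L)))
  rows <- do.call(rbind, lapply(seq_len(spec$n_chromosomes), function(ci) {
    k <- per_chr_genes[ci]
    if (k == 0L) return(NULL)
    start <- floor(lay$chrom_len[ci] * (seq_len(k) - 0.5) / k)
    data.frame(chrom = paste0("chr", ci), start = start,
               end = start + spec$gene_length_bp - 1L,
               stringsAsFactors = FALSE)
  }))
  data.frame(gene_id = sprintf("gene_%04d", seq_len(nrow(rows))),
             chrom = rows$chrom, start = rows$start, end = rows$end,
             strand = rep(c("+", "-"), length.out = nrow(rows)),
             stringsAsFactors = FALSE)
}

#' Simulate paired-condition expression with planted effects
#'
#' Builds genes x accessions FPKM-like matrices for the normal and stress
#' conditions as `exp(baseline + planted genetic effect + response shift +
#' noise)` on the natural-log scale. Planted cis variants sit within 50 kb of
#' their gene; trans variants on a different chromosome. Dynamic cis effects
#' have a nonzero effect in exactly one condition. Planted response genes
#' shift a Bernoulli(`target prevalence`) subset of accessions by a log2 fold
#' change drawn from `response_shift_log2` (up for inducible, down for
#' repressed, either way for variable). Effect sizes are calibrated so the
#' planted variant explains the drawn PVE of the gene's log-expression
#' variance given its total non-genetic variance.
#'
#' @param genotypes A [genotype_matrix()] from [simulate_genotypes()].
#' @param spec The same [simulation_spec()].
#' @return List: `normal` and `stress` expression matrices (genes x
#'   accessions, `attr(, "condition")` set), `annotation` (the generated gene
#'   coordinates), and `truth` (a `truth_table` list: `planted_cis`,
#'   `planted_trans`, `planted_response`, `nonsyn`; trait entries are filled
#'   in by [simulate_traits()]).
#' @export
simulate_expression <- function(genotypes, spec) {
  stopifnot(inherits(spec, "sim_spec"), inherits(genotypes, "genotype_matrix"))
  set.seed(spec$rng_seed + 1000L)
  n <- length(genotypes$accessions)
  lay <- sim_layout(spec)
  ann <- sim_annotation(spec, lay)
  ng <- nrow(ann)
  vtab <- genotypes$variants

  # ---- assign planted roles to disjoint gene sets (coloc gene excepted) ----
  pool <- sample(ann$gene_id)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  g_static  <- take(spec$n_static_cis)
  g_dstress <- take(spec$n_dynamic_cis_stress_only)
  g_dnormal <- take(spec$n_dynamic_cis_normal_only)
  g_trans   <- take(spec$n_trans)
  nr <- spec$n_response_per_class
  g_ind <- list(A = take(nr), B = take(nr), C = take(nr))
  g_rep <- list(A = take(nr), B = take(nr), C = take(nr))
  g_var <- take(spec$n_variable)
  ncs <- spec$n_condition_specific
  g_normal_only <- take(floor(ncs / 2))
  g_stress_only <- take(ncs - floor(ncs / 2))

  coloc_gene <- NA_character_
  if (isTRUE(spec$coloc_pair) && spec$n_dynamic_cis_stress_only > 0L) {
    # one gene carries both a stress-only cis effect and a class-C inducible
    # response: the planted analogue of a stress-responsive causal gene
    coloc_gene <- g_dstress[1L]
    g_ind$C <- c(g_ind$C, coloc_gene)
  }

  # ---- response plan ---------------------------------------------------
  band <- list(A = c(0.1, 0.5), B = c(0.5, 0.9), C = c(0.9, 1.0))
  resp <- list()
  for (cl in c("A", "B", "C")) {
    for (g in g_ind[[cl]])
      resp[[g]] <- list(class = "inducible", prev_class = cl,
                        up = runif(1, band[[cl]][1], band[[cl]][2]), down = 0)
    for (g in g_rep[[cl]])
      resp[[g]] <- list(class = "repressed", prev_class = cl, up = 0,
                        down = runif(1, band[[cl]][1], band[[cl]][2]))
  }
  for (g in g_var)
    resp[[g]] <- list(class = "variable", prev_class = NA_character_,
                      up = runif(1, 0.15, 0.35), down = runif(1, 0.15, 0.35))

  # analytic variance of the stress-side shift, used to calibrate PVE
  shift_mu <- mean(spec$response_shift_log2) * log(2)
  shift_var_unit <- (diff(spec$response_shift_log2) * log(2))^2 / 12
  shift_var <- function(g) {
    r <- resp[[g]]
    if (is.null(r)) return(0)
    p <- r$up + r$down
    p * (shift_mu^2 + shift_var_unit) - (p * shift_mu * (r$up - r$down) / max(p, 1e-12))^2
  }

  # ---- planted variant choice and effect sizes -------------------------
  pick_cis_variant <- function(g) {
    a <- ann[ann$gene_id == g, ]
    same <- which(vtab$chrom == a$chrom)
    d <- pmax(0, pmax(a$start - vtab$pos[same], vtab$pos[same] - a$end))
    near <- same[d <= 50000]
    if (!length(near)) near <- same[which.min(d)]
    sample(rep(near, 2L), 1L)       # rep() guards length-1 sample() behaviour
  }
  pick_trans_variant <- function(g) {
    a <- ann[ann$gene_id == g, ]
    other <- which(vtab$chrom != a$chrom)
    sample(other, 1L)
  }
  effect_size <- function(vidx, pve_range, extra_var) {
    pve <- runif(1, pve_range[1], pve_range[2])
    vx <- var(genotypes$dosages[, vidx])
    s2 <- spec$expr_noise_sd^2 + extra_var
    list(beta = sample(c(-1, 1), 1L) * sqrt(pve / (1 - pve) * s2 / vx),
         pve = pve)
  }

  cis_rows <- list()
  add_cis <- function(g, kind) {
    vidx <- pick_cis_variant(g)
    ef <- effect_size(vidx, spec$cis_pve, shift_var(g))
    data.frame(gene_id = g, variant_id = vtab$id[vidx],
               beta_normal = if (kind == "stress_only") 0 else ef$beta,
               beta_stress = if (kind == "normal_only") 0 else ef$beta,
               category = switch(kind, static = "static",
                                 stress_only = "dynamic_stress_only",
                                 normal_only = "dynamic_normal_only"),
               pve = ef$pve, stringsAsFactors = FALSE)
  }
  for (g in g_static)  cis_rows[[g]] <- add_cis(g, "static")
  for (g in g_dstress) cis_rows[[g]] <- add_cis(g, "stress_only")
  for (g in g_dnormal) cis_rows[[g]] <- add_cis(g, "normal_only")
  planted_cis <- do.call(rbind, cis_rows)
  rownames(planted_cis) <- NULL

  trans_rows <- lapply(g_trans, function(g) {
    vidx <- pick_trans_variant(g)
    ef <- effect_size(vidx, spec$trans_pve, shift_var(g))
    data.frame(gene_id = g, variant_id = vtab$id[vidx],
               beta_normal = ef$beta, beta_stress = ef$beta,
               category = "static", pve = ef$pve, stringsAsFactors = FALSE)
  })
  planted_trans <- do.call(rbind, trans_rows)

  # ---- assemble log expression -----------------------------------------
  base <- rnorm(ng, spec$baseline_log_mean, spec$baseline_log_sd)
  names(base) <- ann$gene_id
  base[c(g_normal_only, g_stress_only)] <- spec$baseline_log_mean
  # planted response genes are modelled as well-expressed: a repressed gene
  # starting near the pseudocount scale could never show its planted
  # fold change through the (stress + 0.5)/(normal + 0.5) ratio
  base[names(resp)] <- pmax(base[names(resp)], log(8))
  base_n <- base
  base_s <- base
  base_n[g_stress_only] <- log(0.005)   # mean FPKM far below the 0.1 filter
  base_s[g_normal_only] <- log(0.005)

  Ln <- matrix(base_n, nrow = ng, ncol = n)
  Ls <- matrix(base_s, nrow = ng, ncol = n)
  rownames(Ln) <- rownames(Ls) <- ann$gene_id

  add_effect <- function(tab) {
    for (i in seq_len(NROW(tab))) {
      x <- genotypes$dosages[, tab$variant_id[i]]
      xc <- x - mean(x)
      g <- tab$gene_id[i]
      Ln[g, ] <<- Ln[g, ] + tab$beta_normal[i] * xc
      Ls[g, ] <<- Ls[g, ] + tab$beta_stress[i] * xc
    }
  }
  if (NROW(planted_cis)) add_effect(planted_cis)
  if (NROW(planted_trans)) add_effect(planted_trans)

  resp_rows <- list()
  for (g in names(resp)) {
    r <- resp[[g]]
    u <- runif(n)
    up <- u < r$up
    down <- !up & u < (r$up + r$down)
    mag <- runif(n, spec$response_shift_log2[1], spec$response_shift_log2[2]) * log(2)
    Ls[g, ] <- Ls[g, ] + ifelse(up, mag, ifelse(down, -mag, 0))
    resp_rows[[g]] <- data.frame(gene_id = g, class = r$class,
                                 prevalence_class = r$prev_class,
                                 target_prevalence = r$up + r$down,
                                 stringsAsFactors = FALSE)
  }
  planted_response <- do.call(rbind, resp_rows)
  rownames(planted_response) <- NULL

  Ln <- Ln + matrix(rnorm(ng * n, 0, spec$expr_noise_sd), ng, n)
  Ls <- Ls + matrix(rnorm(ng * n, 0, spec$expr_noise_sd), ng, n)
  normal <- exp(Ln); stress <- exp(Ls)
  colnames(normal) <- colnames(stress) <- genotypes$accessions
  attr(normal, "condition") <- "normal"
  attr(stress, "condition") <- "stress"

  # ---- synthetic non-synonymous consequence table ----------------------
  nonsyn_genes <- ann$gene_id[runif(ng) < spec$nonsyn_fraction]
  if (!is.na(coloc_gene)) nonsyn_genes <- union(nonsyn_genes, coloc_gene)
  nonsyn <- do.call(rbind, lapply(nonsyn_genes, function(g) {
    a <- ann[ann$gene_id == g, ]
    same <- which(vtab$chrom == a$chrom)
    d <- pmax(0, pmax(a$start - vtab$pos[same], vtab$pos[same] - a$end))
    data.frame(gene_id = g, variant_id = vtab$id[same[which.min(d)]],
               consequence = "nonsynonymous", stringsAsFactors = FALSE)
  }))

  cond_specific <- data.frame(
    gene_id = c(g_normal_only, g_stress_only),
    expressed_in = rep(c("normal", "stress"),
                       c(length(g_normal_only), length(g_stress_only))),
    stringsAsFactors = FALSE)

  truth <- structure(list(planted_cis = planted_cis,
                          planted_trans = planted_trans,
                          planted_response = planted_response,
                          condition_specific = cond_specific,
                          planted_qtl = NULL, coloc_pair = NULL,
                          coloc_gene = coloc_gene, nonsyn = nonsyn),
                     class = "truth_table")
  list(normal = normal, stress = stress, annotation = ann, truth = truth)
}

#' Simulate phenotypes with a planted QTL and polygenic background
#'
#' Traits are built as `QTL effect + kinship-structured polygenic background +
#' noise`, scaled so the genetic fraction of variance is approximately
#' `trait_heritability` and the QTL alone explains `qtl_pve`. With
#' `coloc_pair` set in the spec, the QTL variant is the shared causal variant
#' recorded in the truth table. Three traits are produced: `SR` (survival
#' rate; carries the planted QTL with positive sign), `DLR` (dead-leaf rate;
#' same QTL, opposite sign) and `STL` (salt-tolerance level; a noisy rescaling
#' of SR).
#'
#' @param genotypes A [genotype_matrix()].
#' @param truth The `truth_table` from [simulate_expression()]; updated in the
#'   returned value with `planted_qtl` and `coloc_pair`.
#' @param spec The [simulation_spec()].
#' @return List with `phenotypes` (data.frame, accessions in rows) and the
#'   updated `truth`.
#' @export
simulate_traits <- function(genotypes, truth, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$rng_seed + 2000L)
  n <- length(genotypes$accessions)
  h2 <- spec$trait_heritability
  pve_q <- min(spec$qtl_pve, h2)

  qtl_variant <- NA_character_
  if (h2 > 0 && pve_q > 0) {
    qtl_variant <- if (!is.null(truth$coloc_gene) && !is.na(truth$coloc_gene)) {
      truth$planted_cis$variant_id[truth$planted_cis$gene_id == truth$coloc_gene]
    } else sample(genotypes$variants$id, 1L)
  }

  poly_bg <- function() {
    if (h2 - pve_q <= 0) return(rep(0, n))
    K <- compute_kinship(genotypes)
    ev <- eigen(K$values, symmetric = TRUE)
    g0 <- as.numeric(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n)))
    if (!is.na(qtl_variant)) {
      # keep the background orthogonal to the planted QTL so the QTL's
      # marginal variance share equals its target PVE
      x <- genotypes$dosages[, qtl_variant]
      g0 <- g0 - x * (cov(g0, x) / var(x))
    }
    g0 / sd(g0) * sqrt(h2 - pve_q)
  }
  qtl_term <- function(sign) {
    if (is.na(qtl_variant)) return(list(x = rep(0, n), beta = 0))
    x <- genotypes$dosages[, qtl_variant]
    xc <- x - mean(x)
    beta <- sign * sqrt(pve_q / var(x))
    list(x = beta * xc, beta = beta)
  }
  qt <- qtl_term(+1)
  SR <- qt$x + poly_bg() + rnorm(n, 0, sqrt(1 - h2))
  DLR <- -qt$x + poly_bg() + rnorm(n, 0, sqrt(1 - h2))
  STL <- 0.8 * SR + rnorm(n, 0, sqrt(1 - 0.64))
  phen <- data.frame(SR = SR, DLR = DLR, STL = STL,
                     row.names = genotypes$accessions)

  if (!is.na(qtl_variant)) {
    truth$planted_qtl <- data.frame(trait = "SR", variant_id = qtl_variant,
                                    beta = qt$beta, pve = pve_q,
                                    stringsAsFactors = FALSE)
    if (!is.null(truth$coloc_gene) && !is.na(truth$coloc_gene))
      truth$coloc_pair <- data.frame(trait = "SR", gene_id = truth$coloc_gene,
                                     shared_variant_id = qtl_variant,
                                     stringsAsFactors = FALSE)
  }
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_expression()] and [simulate_traits()] under one spec.
#'
#' @param spec A [simulation_spec()].
#' @return List: `genotypes`, `expression` (list `normal`, `stress`),
#'   `annotation`, `phenotypes`, `truth`, `spec`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  G <- simulate_genotypes(spec)
  ex <- simulate_expression(G, spec)
  tr <- simulate_traits(G, ex$truth, spec)
  list(genotypes = G,
       expression = list(normal = ex$normal, stress = ex$stress),
       annotation = ex$annotation,
       phenotypes = tr$phenotypes,
       truth = tr$truth,
       spec = spec)
}

#' Write a simulated dataset to disk in the pipeline's input dialects
#'
#' Emits a plain-text VCF, two expression TSVs, a BED6 annotation, a phenotype
#' TSV and the truth tables as TSVs, all readable back by the `core_io`
#' readers.
#'
#' @param ds Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(ds$genotypes, file.path(dir, "genotypes.vcf"))
  for (cond in c("normal", "stress")) {
    m <- ds$expression[[cond]]
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    data.table::fwrite(df, file.path(dir, paste0("expression_", cond, ".tsv")),
                       sep = "\t")
  }
  ann <- ds$annotation
  bed <- data.frame(ann$chrom, ann$start - 1L, ann$end, ann$gene_id, 0L,
                    ann$strand)
  data.table::fwrite(bed, file.path(dir, "genes.bed"), sep = "\t",
                     col.names = FALSE)
  ph <- data.frame(accession = rownames(ds$phenotypes), ds$phenotypes,
                   check.names = FALSE)
  data.table::fwrite(ph, file.path(dir, "phenotypes.tsv"), sep = "\t")
  for (nm in c("planted_cis", "planted_trans", "planted_response",
               "condition_specific", "planted_qtl", "coloc_pair", "nonsyn")) {
    tab <- ds$truth[[nm]]
    if (!is.null(tab))
      data.table::fwrite(tab, file.path(dir, paste0("truth_", nm, ".tsv")),
                         sep = "\t")
  }
  invisible(dir)
}
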