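test_that("a lone significant variant defines a lead +/- 200 kb region", {
  pos <- 28351660L
  dos <- matrix(rbinom(40, 2, 0.5), 20, 2,
                dimnames = list(sprintf("a%02d", 1:20), c("vq", "v2")))
  while (any(apply(dos, 2, sd) == 0))
    dos <- matrix(rbinom(40, 2, 0.5), 20, 2,
                  dimnames = list(sprintf("a%02d", 1:20), c("vq", "v2")))
  G <- genotype_matrix(dos, data.frame(id = c("vq", "v2"), chrom = "chr5",
                                       pos = c(pos, 5000000L),
                                       ref = "A", alt = "T"))
  ann <- data.frame(gene_id = c("gin", "gout"), chrom = "chr5",
                    start = c(28300000, 29000000),
                    end = c(28310000, 29010000), strand = "+",
                    stringsAsFactors = FALSE)
  res <- data.frame(response_id = "SR", variant_id = c("vq", "v2"),
                    chrom = "chr5", pos = c(pos, 5000000L),
                    beta = 1, se = 1, stat = 1, p = c(1e-10, 0.5),
                    stringsAsFactors = FALSE)
  attr(res, "n_variants_tested") <- 2L
  loci <- define_gwas_loci(res, G, ann, analysis_config())
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, pos - 200000)
  expect_equal(loci$end, pos + 200000)
  expect_equal(loci$candidate_genes, "gin")

  # two traits sharing the lead merge into one locus naming both
  res2 <- rbind(res, transform(res, response_id = "DLR"))
  attr(res2, "n_variants_tested") <- 2L
  loci2 <- define_gwas_loci(res2, G, ann, analysis_config())
  expect_equal(nrow(loci2), 1L)
  expect_equal(loci2$traits, "DLR,SR")

  # nothing significant: empty result, not an error
  res3 <- transform(res, p = 0.9)
  attr(res3, "n_variants_tested") <- 2L
  expect_equal(nrow(define_gwas_loci(res3, G, ann, analysis_config())), 0L)
})

test_that("colocalization posteriors match brute-force enumeration", {
  set.seed(51)
  for (i in 1:25) {
    m <- sample(2:4, 1)
    b1 <- rnorm(m, 0, 0.5); se1 <- runif(m, 0.05, 0.3)
    b2 <- rnorm(m, 0, 0.5); se2 <- runif(m, 0.05, 0.3)
    ids <- paste0("v", seq_len(m))
    cres <- coloc_abf(data.frame(variant_id = ids, beta = b1, se = se1),
                      data.frame(variant_id = ids, beta = b2, se = se2))
    oracle <- coloc_enum_oracle(b1, se1, b2, se2)
    expect_equal(unname(cres$pp), unname(oracle), tolerance = 1e-8)
    expect_equal(sum(cres$pp), 1, tolerance = 1e-8)
  }
})

test_that("a null region puts the posterior mass on no-association", {
  ids <- paste0("v", 1:10)
  null_df <- data.frame(variant_id = ids, beta = 0, se = 0.2)
  cres <- coloc_abf(null_df, null_df)
  expect_equal(names(which.max(cres$pp)), "PP0")
  expect_error(coloc_abf(null_df[1, ], null_df[1, ]), "fewer than 2")
  # non-finite standard errors are dropped, not fatal
  bad <- null_df
  bad$se[1] <- NA
  expect_equal(coloc_abf(bad, null_df)$n_variants, 9L)
})

test_that("strengthening a shared signal never lowers the shared posterior", {
  set.seed(52)
  ids <- paste0("v", 1:6)
  base1 <- data.frame(variant_id = ids, beta = rnorm(6, 0, 0.1), se = 0.1)
  base2 <- data.frame(variant_id = ids, beta = rnorm(6, 0, 0.1), se = 0.1)
  pp4 <- sapply(seq(0, 1.2, by = 0.2), function(boost) {
    g <- base1; e <- base2
    g$beta[3] <- g$beta[3] + boost
    e$beta[3] <- e$beta[3] + boost
    coloc_abf(g, e)$pp[["PP4"]]
  })
  expect_true(all(diff(pp4) >= -1e-12))
})

test_that("shared-causal regions are called PP4-first in most seeds", {
  wins <- 0L
  for (seed in 1:40) {
    reg <- sim_coloc_region(seed, shared = TRUE)
    cres <- coloc_abf(reg$gwas, reg$eqtl)
    wins <- wins + (names(which.max(cres$pp)) == "PP4")
  }
  expect_gte(wins / 40, 0.8)
  # distinct causal variants lean away from the shared hypothesis
  distinct_pp4 <- sapply(1:10, function(seed) {
    reg <- sim_coloc_region(seed + 100, shared = FALSE)
    coloc_abf(reg$gwas, reg$eqtl)$pp[["PP4"]]
  })
  shared_pp4 <- sapply(1:10, function(seed) {
    reg <- sim_coloc_region(seed + 100, shared = TRUE)
    coloc_abf(reg$gwas, reg$eqtl)$pp[["PP4"]]
  })
  expect_gt(mean(shared_pp4), mean(distinct_pp4))
})

test_that("enrichment statistics match the closed-form 2x2 computation", {
  # table (a,b,c,d) = (30,10,20,40): chi2 = N(ad-bc)^2 / row/col products
  universe <- paste0("g", 1:100)
  query <- universe[1:40]                 # a + b
  target <- universe[c(1:30, 41:60)]      # a = 30, c = 20
  en <- gene_set_enrichment(query, target, universe)
  chi_hand <- 100 * (30 * 40 - 10 * 20)^2 / (40 * 60 * 50 * 50)
  expect_equal(en$statistic, chi_hand, tolerance = 1e-10)
  expect_equal(en$p, pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(en$overlap, 30)
  expect_equal(en$fold_enrichment, 30 / (40 * 50 / 100), tolerance = 1e-12)

  hy <- gene_set_enrichment(query, target, universe, "hypergeometric")
  expect_equal(hy$p, phyper(29, 50, 50, 40, lower.tail = FALSE),
               tolerance = 1e-12)

  # constructed 3x enrichment
  u2 <- paste0("u", 1:1000)
  q2 <- u2[1:100]
  t2 <- c(u2[1:30], u2[101:171])          # expected overlap 10.1 -> use exact
  en2 <- gene_set_enrichment(q2, u2[c(1:30, 101:170)], u2)
  expect_equal(en2$fold_enrichment, 30 / (100 * 100 / 1000), tolerance = 1e-12)

  expect_error(gene_set_enrichment(q2, t2, character(0)), "empty universe")
})

test_that("chi-square and hypergeometric agree on enrichment direction", {
  set.seed(53)
  for (i in 1:20) {
    u <- paste0("g", 1:300)
    q <- sample(u, sample(30:120, 1))
    t <- sample(u, sample(30:120, 1))
    en <- gene_set_enrichment(q, t, u)
    hy <- gene_set_enrichment(q, t, u, "hypergeometric")
    if (en$fold_enrichment > 1) expect_lt(hy$p, 0.975)
    if (en$fold_enrichment < 1) expect_gt(hy$p, 0.025)
  }
})

test_that("haplotype grouping drops rare patterns and compares traits", {
  set.seed(54)
  n <- 202
  acc <- sprintf("acc_%03d", 1:n)
  hap <- c(rep(0L, 49), rep(2L, 149), rep(1L, 4))   # 4 rare heterozygotes
  dos <- cbind(v_prom = hap, v_exon = hap)
  rownames(dos) <- acc
  G <- genotype_matrix(dos, data.frame(id = c("v_prom", "v_exon"),
                                       chrom = "chr5",
                                       pos = c(28500000L, 28505479L),
                                       ref = "A", alt = "T"))
  shift <- ifelse(hap == 0, 1, 0)                    # 1-sd trait shift
  ph <- data.frame(SR = shift + rnorm(n), row.names = acc)
  hp <- haplotype_compare(G, c("v_prom", "v_exon"), ph, min_group = 5)
  expect_equal(nrow(hp$groups), 2L)
  expect_setequal(hp$groups$n, c(49L, 149L))
  expect_equal(nrow(hp$outliers), 4L)                # the rare pattern is out
  expect_equal(unique(hp$outliers$reason), "rare_haplotype")
  expect_lt(hp$tests$p[1], 0.01)

  # a planted 1-sd shift at these group sizes is detected almost always
  det <- sapply(1:30, function(s) {
    set.seed(1000 + s)
    ph2 <- data.frame(SR = shift + rnorm(n), row.names = acc)
    haplotype_compare(G, "v_exon", ph2, min_group = 5)$tests$p[1] < 0.01
  })
  expect_gte(mean(det), 0.95)

  # all accessions identical: one group, no tests
  G1 <- genotype_matrix(matrix(2L, n, 1, dimnames = list(acc, "v1")),
                        data.frame(id = "v1", chrom = "chr1", pos = 1L,
                                   ref = "A", alt = "T"))
  hp1 <- haplotype_compare(G1, "v1", ph, min_group = 5)
  expect_equal(nrow(hp1$groups), 1L)
  expect_null(hp1$tests)
  expect_error(haplotype_compare(G1, "nope", ph), "not in genotype")
})

test_that("triangulation ranks by evidence flags and narrows monotonically", {
  # constructed locus: 97 candidates, 31 with a non-synonymous variant,
  # 4 of those also DEG + reGene
  genes <- sprintf("cand_%02d", 1:97)
  loci <- data.frame(locus_id = "locus_01", traits = "SR",
                     lead_variant = "vq", chrom = "chr5", pos = 28351660L,
                     lead_p = 1e-10, start = 28151660, end = 28551660,
                     n_candidate_genes = 97L,
                     candidate_genes = paste(genes, collapse = ","),
                     stringsAsFactors = FALSE)
  ns_genes <- genes[1:31]
  core4 <- genes[1:4]
  degs <- data.frame(gene_id = genes,
                     category = ifelse(genes %in% core4, "salt_inducible",
                                       "non_DEG"),
                     prevalence_class = "none", up_count = 0, down_count = 0,
                     stringsAsFactors = FALSE)
  egenes <- data.frame(gene_id = core4, n_peaks_normal = 0L,
                       n_peaks_stress = 1L, excluded = FALSE,
                       regulatory_class_normal = "none",
                       regulatory_class_stress = "cis_only",
                       condition_category = "reGene", stringsAsFactors = FALSE)
  nonsyn <- data.frame(gene_id = ns_genes, variant_id = "vx",
                       stringsAsFactors = FALSE)
  rep_out <- triangulate(loci, degs, egenes, coloc = NULL, nonsyn = nonsyn,
                         cfg = analysis_config())
  expect_equal(nrow(rep_out), 97L)
  expect_true(all(rep_out$gene_id[1:4] %in% core4))
  expect_equal(rep_out$rank_score[1:4], rep(3, 4))

  nr <- narrow_candidates(rep_out, c("has_nonsyn_variant", "in_DEG",
                                     "in_reGene"))
  expect_equal(nr$stages$n_genes, c(97L, 31L, 4L, 4L))
  expect_true(all(diff(nr$stages$n_genes) <= 0))   # monotone narrowing
  expect_setequal(nr$final$gene_id, core4)
})

test_that("the full pipeline ranks the planted colocalizing gene first", {
  st <- default_study(1)
  res <- st$res
  expect_gt(nrow(res$loci), 0L)
  expect_equal(res$candidates$gene_id[1], st$ds$truth$coloc_gene)
  pp <- res$coloc[[st$ds$truth$coloc_gene]]$pp
  expect_equal(sum(pp), 1, tolerance = 1e-6)
  expect_gte(pp[["PP4"]], 0.7)
})
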