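mk_results <- function(G, idx, p) {
  v <- G$variants[idx, ]
  data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos, p = p,
             beta = 1, se = 1, r2 = 0.1, stringsAsFactors = FALSE)
}

test_that("clumping groups significant variants by window or LD", {
  G <- tiny_genotypes(40, 60, seed = 41, spacing = 10000L)

  # one significant variant: one single-member peak
  r1 <- mk_results(G, 5, 1e-8)
  pk1 <- clump_peaks(r1, G, p_threshold = 1e-5)
  expect_equal(nrow(pk1), 1L)
  expect_equal(pk1$lead_variant, "v0005")
  expect_equal(pk1$span_start, pk1$span_end)

  # two significant variants 10 kb apart within a 200 kb window: one peak
  r2 <- mk_results(G, c(5, 6), c(1e-8, 1e-6))
  pk2 <- clump_peaks(r2, G, p_threshold = 1e-5)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$n_members, 2L)

  # an identical (r2 = 1) variant outside the window is absorbed by LD
  d <- G$dosages
  d[, 40] <- d[, 5]                           # 350 kb away, perfect LD
  Gl <- genotype_matrix(d, G$variants)
  r3 <- mk_results(Gl, c(5, 40), c(1e-8, 1e-7))
  pk3 <- clump_peaks(r3, Gl, p_threshold = 1e-5, clump_window_bp = 200000,
                     clump_r2 = 0.2)
  expect_equal(nrow(pk3), 1L)

  # without LD, 350 kb apart: two peaks, ordered by lead p
  r4 <- mk_results(G, c(5, 40), c(1e-6, 1e-8))
  pk4 <- clump_peaks(r4, G, p_threshold = 1e-5)
  expect_equal(pk4$lead_variant, c("v0040", "v0005"))

  expect_equal(nrow(clump_peaks(mk_results(G, 5, 0.5), G, 1e-5)), 0L)
})

test_that("clumping is invariant to input order under equal p-values", {
  G <- tiny_genotypes(40, 30, seed = 42)
  r <- mk_results(G, c(25, 3, 14), rep(1e-9, 3))   # equal p, far apart
  pk_a <- clump_peaks(r, G, 1e-5)
  pk_b <- clump_peaks(r[c(3, 1, 2), ], G, 1e-5)
  expect_equal(pk_a, pk_b)
  # tie broken by (chrom, pos): first lead is the smallest position
  expect_equal(pk_a$lead_variant[1], "v0003")
})

test_that("independent planted causal variants yield separate peaks", {
  hits <- 0L
  for (seed in 1:8) {
    set.seed(seed + 400)
    n <- 150
    G1 <- tiny_genotypes(n, 40, seed = seed + 400, chrom = "chr1")
    G2 <- tiny_genotypes(n, 40, seed = seed + 500, chrom = "chr2")
    v <- rbind(G1$variants, G2$variants)
    v$id <- sprintf("v%04d", seq_len(80))
    G <- genotype_matrix(cbind(G1$dosages, G2$dosages), v)
    y <- scale(G$dosages[, 10])[, 1] + scale(G$dosages[, 60])[, 1] + rnorm(n)
    names(y) <- G$accessions
    res <- association_scan(rbind(g = y), G, mode = "ols_pcs", n_pcs = 0)
    pk <- clump_peaks(res, G, p_threshold = 1e-5)
    ok <- nrow(pk) == 2L &&
      setequal(pk$chrom, c("chr1", "chr2")) &&
      all(abs(pk$pos - ifelse(pk$chrom == "chr1", 100000, 200000)) <= 100000)
    hits <- hits + ok
  }
  expect_gte(hits / 8, 0.9)
})

test_that("cis/trans classification uses an inclusive 200 kb interval rule", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 1000000,
                     end = 1010000, strand = "+")
  mk_peak <- function(chrom, pos)
    data.frame(lead_variant = "v", chrom = chrom, pos = pos, lead_p = 1e-9,
               lead_beta = 1, lead_r2 = 0.1, n_members = 1L,
               span_start = pos, span_end = pos, members = "v",
               stringsAsFactors = FALSE)
  expect_equal(classify_cis_trans(mk_peak("chr1", 1005000), gene)$cis_flag,
               "cis")                               # inside the gene body
  expect_equal(classify_cis_trans(mk_peak("chr1", 1210000), gene)$cis_flag,
               "cis")                               # exactly 200,000 bp away
  expect_equal(classify_cis_trans(mk_peak("chr1", 1210001), gene)$cis_flag,
               "trans")
  expect_equal(classify_cis_trans(mk_peak("chr1", 800000), gene)$cis_flag,
               "cis")                               # upstream side
  expect_equal(classify_cis_trans(mk_peak("chr2", 1005000), gene)$cis_flag,
               "trans")                             # other chromosome
  expect_equal(classify_cis_trans(mk_peak("chr1", 1005000), NULL)$cis_flag,
               "unclassified")
})

test_that("condition matching is 1-to-1 and labels unmatched peaks dynamic", {
  mk_peak <- function(pos, p)
    data.frame(lead_variant = paste0("v", pos), chrom = "chr1", pos = pos,
               lead_p = p, lead_beta = 1, lead_r2 = 0.1, n_members = 1L,
               span_start = pos, span_end = pos, members = paste0("v", pos),
               stringsAsFactors = FALSE)
  pn <- rbind(mk_peak(100000, 1e-9), mk_peak(2000000, 1e-8))
  mm <- match_conditions(pn, pn)
  expect_true(all(mm$normal$category == "static"))
  expect_true(all(mm$stress$category == "static"))

  mm2 <- match_conditions(pn[0, ], pn)
  expect_true(all(mm2$stress$category == "dynamic_stress_only"))

  # two stress peaks within the window of one normal peak: only one matches
  ps <- rbind(mk_peak(90000, 1e-12), mk_peak(150000, 1e-7))
  mm3 <- match_conditions(pn[1, , drop = FALSE], ps)
  expect_equal(mm3$stress$category, c("static", "dynamic_stress_only"))
  expect_equal(mm3$normal$category, "static")

  # swapping the condition arguments swaps the dynamic labels
  mm4 <- match_conditions(ps, pn[1, , drop = FALSE])
  expect_equal(mm4$normal$category, c("static", "dynamic_normal_only"))
})

test_that("eGene roll-up applies the peak cap and condition categories", {
  n <- 60
  G <- tiny_genotypes(n, 80, seed = 44, spacing = 1000000L)  # 1 Mb apart
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    start = c(1000000, 5000000), end = c(1003000, 5003000),
                    strand = "+", stringsAsFactors = FALSE)
  sc <- function(gene, idx, p) {
    v <- G$variants[idx, ]
    data.frame(response_id = gene, variant_id = v$id, chrom = v$chrom,
               pos = v$pos, beta = 1, se = 1, stat = 1, p = p, r2 = 0.1,
               stringsAsFactors = FALSE)
  }
  # gA: 16 scattered independent peaks under stress -> excluded
  # gB: one cis peak under stress only -> reGene, cis_only
  scan_s <- rbind(sc("gA", seq(1, 76, by = 5), rep(1e-9, 16)),
                  sc("gB", 5, 1e-9))
  scan_n <- sc("gA", 1, 0.9)   # nothing significant under normal
  attr(scan_n, "n_variants_tested") <- 80L
  attr(scan_s, "n_variants_tested") <- 80L
  cat_out <- build_egene_records(scan_n, scan_s, G, ann,
                                 analysis_config(eqtl_p_threshold = 1e-5))
  eg <- cat_out$egenes
  expect_true(eg$excluded[eg$gene_id == "gA"])
  expect_equal(eg$n_peaks_stress[eg$gene_id == "gA"], 16L)
  gB <- eg[eg$gene_id == "gB", ]
  expect_false(gB$excluded)
  expect_equal(gB$condition_category, "reGene")
  expect_equal(gB$regulatory_class_stress, "cis_only")
  expect_equal(gB$regulatory_class_normal, "none")
})

test_that("catalog bookkeeping partitions hold on a full synthetic run", {
  res <- default_study(1)$res
  pk <- res$catalog$peaks
  # cis/trans is a partition of classified peaks
  expect_true(all(pk$cis_flag %in% c("cis", "trans")))
  expect_equal(sum(pk$cis_flag == "cis") + sum(pk$cis_flag == "trans"),
               nrow(pk))
  # static + dynamic is a partition
  expect_true(all(pk$category %in% c("static", "dynamic_normal_only",
                                     "dynamic_stress_only")))
  expect_equal(sum(pk$category == "static") +
                 sum(pk$category != "static"), nrow(pk))
  # static peaks pair up across conditions within each gene
  st_n <- pk[pk$category == "static" & pk$condition == "normal", ]
  st_s <- pk[pk$category == "static" & pk$condition == "stress", ]
  expect_equal(table(st_n$gene_id), table(st_s$gene_id))
  # lead p is minimal within each peak's members and below threshold
  expect_true(all(pk$lead_p < res$catalog$p_threshold))
  # cis lead variance explained exceeds trans on average (cis-favoring spec)
  expect_gt(mean(pk$lead_r2[pk$cis_flag == "cis"]),
            mean(pk$lead_r2[pk$cis_flag == "trans"]))
})

test_that("planted condition categories are recovered across the catalog", {
  st <- default_study(1)
  eg <- st$res$catalog$egenes
  tr <- st$ds$truth
  truth_cat <- c(static = "static", dynamic_stress_only = "reGene",
                 dynamic_normal_only = "neGene")
  got <- eg$condition_category[match(tr$planted_cis$gene_id, eg$gene_id)]
  got[is.na(got)] <- "none"
  expect_gte(mean(got == truth_cat[tr$planted_cis$category]), 0.8)
})

test_that("hotspot detection reports planted hubs and nothing under the null", {
  expect_equal(nrow(detect_hotspots(data.frame(
    gene_id = character(), condition = character(), chrom = character(),
    pos = integer(), cis_flag = character(), stringsAsFactors = FALSE))), 0L)

  # uniform scatter: one lead per window, no enrichment anywhere
  flat <- data.frame(gene_id = paste0("g", 1:40), condition = "stress",
                     chrom = "chr1", pos = seq(5e5, 39.5e6, by = 1e6),
                     cis_flag = "trans", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_hotspots(flat, chrom_lengths = c(chr1 = 4e7))), 0L)

  # a hub window controlling 20 genes against a sparse background
  hub <- data.frame(gene_id = paste0("h", 1:20), condition = "stress",
                    chrom = "chr1", pos = 10200000 + (1:20) * 1000,
                    cis_flag = "trans", stringsAsFactors = FALSE)
  hs <- detect_hotspots(rbind(flat, hub), chrom_lengths = c(chr1 = 4e7))
  expect_equal(nrow(hs), 1L)
  expect_true(hs$start <= 10200000 && hs$end >= 10221000)
  expect_equal(hs$n_target_egenes, 21L)
})
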