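# Fixtures are built in code at test time; expensive shared objects are
# computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# write VCF body lines (already tab-joined) with a standard header
write_test_vcf <- function(body_lines, samples, path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

vcf_line <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# small random genotype panel with iid variants (one chromosome)
tiny_genotypes <- function(n, m, seed = 1, chrom = "chr1",
                           spacing = 10000L, freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.2, 0.8)
  dos <- sapply(freq, function(p) rbinom(n, 2, p))
  while (any(apply(dos, 2, sd) == 0)) {
    j <- which(apply(dos, 2, sd) == 0)
    dos[, j] <- sapply(freq[j], function(p) rbinom(n, 2, p))
  }
  rownames(dos) <- sprintf("acc_%03d", seq_len(n))
  genotype_matrix(dos, data.frame(id = sprintf("v%04d", seq_len(m)),
                                  chrom = chrom,
                                  pos = spacing * seq_len(m),
                                  ref = "A", alt = "T",
                                  stringsAsFactors = FALSE))
}

# brute-force colocalization oracle: enumerate every causal-variant
# configuration (none / variant i per study) and sum prior-weighted ABFs
coloc_enum_oracle <- function(b1, se1, b2, se2,
                              priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
                              sd1 = 0.15, sd2 = 0.15) {
  bf <- function(b, se, w) {
    r <- w^2 / (w^2 + se^2)
    sqrt(1 - r) * exp((b / se)^2 * r / 2)
  }
  m <- length(b1)
  bf1 <- bf(b1, se1, sd1)
  bf2 <- bf(b2, se2, sd2)
  s <- c(H0 = 0, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (c1 in 0:m) for (c2 in 0:m) {
    w <- 1
    if (c1 > 0) w <- w * priors[["p1"]] * bf1[c1]
    if (c2 > 0) w <- w * priors[["p2"]] * bf2[c2]
    if (c1 > 0 && c2 > 0 && c1 == c2)
      w <- priors[["p12"]] * bf1[c1] * bf2[c2]
    h <- if (c1 == 0 && c2 == 0) "H0"
         else if (c2 == 0) "H1"
         else if (c1 == 0) "H2"
         else if (c1 != c2) "H3" else "H4"
    s[h] <- s[h] + w
  }
  setNames(s / sum(s), c("PP0", "PP1", "PP2", "PP3", "PP4"))
}

# per-variant marginal OLS summary statistics for a region (used to build
# colocalization inputs independently of association_scan)
marginal_stats <- function(y, dos) {
  t(apply(dos, 2, function(x) {
    fit <- summary(lm(y ~ x))$coefficients
    if (nrow(fit) < 2) return(c(beta = 0, se = Inf))
    c(beta = fit[2, 1], se = fit[2, 2])
  }))
}

# one LD block with a shared (or distinct) causal variant in two studies
sim_coloc_region <- function(seed, shared = TRUE, n = 200, m = 25,
                             b = 0.45) {
  set.seed(seed)
  p <- runif(1, 0.25, 0.75)
  H <- matrix(rbinom(2 * n * m, 1, p), nrow = 2 * n)
  cp <- matrix(runif(2 * n * m) < sqrt(0.8), nrow = 2 * n)
  for (j in 2:m) H[, j] <- ifelse(cp[, j], H[, j - 1], H[, j])
  dos <- H[seq(1, 2 * n, 2), ] + H[seq(2, 2 * n, 2), ]
  colnames(dos) <- sprintf("v%02d", seq_len(m))
  i1 <- sample(m, 1)
  i2 <- if (shared) i1 else sample(setdiff(seq_len(m), i1), 1)
  y1 <- b * scale(dos[, i1])[, 1] + rnorm(n)
  y2 <- b * scale(dos[, i2])[, 1] + rnorm(n)
  s1 <- marginal_stats(y1, dos)
  s2 <- marginal_stats(y2, dos)
  list(gwas = data.frame(variant_id = colnames(dos), beta = s1[, 1],
                         se = s1[, 2], stringsAsFactors = FALSE),
       eqtl = data.frame(variant_id = colnames(dos), beta = s2[, 1],
                         se = s2[, 2], stringsAsFactors = FALSE),
       causal = c(i1, i2))
}

# the default synthetic study analysed with the desk-scale configuration
# (eQTL threshold Bonferroni 0.05/m; see the methods vignette)
desk_config <- function(spec) {
  analysis_config(eqtl_p_threshold = 0.05 / spec$n_snps)
}

default_study <- function(seed = 1) {
  cached(paste0("study_", seed), {
    spec <- simulation_spec(rng_seed = seed)
    ds <- simulate_dataset(spec)
    res <- run_pipeline(ds, desk_config(spec))
    list(spec = spec, ds = ds, res = res)
  })
}
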