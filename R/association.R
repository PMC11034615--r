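#' Genetic relatedness (kinship) matrix
#'
#' `K = Z Z' / m`, where `Z` is the accessions x variants dosage matrix with
#' each polymorphic variant standardized to mean 0 and variance 1 (monomorphic
#' variants are skipped, missing dosages mean-imputed for this computation
#' only). The diagonal then averages about 1.
#'
#' @param G A [genotype_matrix()].
#' @return List of class `kinship_matrix`: `values` (symmetric n x n matrix
#'   with accession dimnames), `n_variants` used.
#' @export
compute_kinship <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (length(G$accessions) < 2L) stop("need >= 2 accessions", call. = FALSE)
  X <- impute_dosages(G$dosages)
  Z <- standardize_pop(X)
  poly <- !is.na(Z[1, ])
  if (!any(poly)) stop("all variants are monomorphic", call. = FALSE)
  Z <- Z[, poly, drop = FALSE]
  K <- tcrossprod(Z) / sum(poly)
  dimnames(K) <- list(G$accessions, G$accessions)
  structure(list(values = K, n_variants = sum(poly)), class = "kinship_matrix")
}

# center and scale columns to population variance 1 (divide by the
# root mean squared deviation, not the sample sd); monomorphic columns
# become all-NA and are dropped by callers
standardize_pop <- function(X) {
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(X^2) - mu^2)
  sd_pop[sd_pop == 0] <- NA_real_
  sweep(sweep(X, 2, mu), 2, sd_pop, `/`)
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d accessions from %d variants; mean diagonal %.3f\n",
              nrow(x$values), x$n_variants, mean(diag(x$values))))
  invisible(x)
}

#' Principal components of the genotype panel
#'
#' Top-k eigenvectors of the kinship matrix scaled by the square root of
#' their eigenvalues. Signs are fixed deterministically (the loading of
#' largest magnitude in each component is made positive). When the leading
#' eigenvalue gap is negligible the scores carry no structure signal and the
#' result is flagged.
#'
#' @param G A [genotype_matrix()] (or a precomputed `kinship_matrix`).
#' @param k Number of components, `0 < k < n`.
#' @param gap_tol Relative eigenvalue gap below which `attr(, "no_structure")`
#'   is set.
#' @return n x k score matrix with accession row names, eigenvalues in
#'   `attr(, "eigenvalues")`.
#' @export
compute_pcs <- function(G, k = 5L, gap_tol = 1e-6) {
  K <- if (inherits(G, "kinship_matrix")) G else compute_kinship(G)
  n <- nrow(K$values)
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  if (k >= n) stop("k must be smaller than the number of accessions", call. = FALSE)
  ev <- eigen(K$values, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(V, 2, sqrt(lam[seq_len(k)]), `*`)
  dimnames(scores) <- list(rownames(K$values), paste0("PC", seq_len(k)))
  attr(scores, "eigenvalues") <- ev$values
  attr(scores, "no_structure") <-
    (ev$values[1] - ev$values[min(2L, n)]) < gap_tol * max(abs(ev$values[1]), 1)
  scores
}

# restricted log-likelihood of the variance-ratio parameter delta = se2/sg2
# in the rotated model; lam are kinship eigenvalues, yt/Wt the rotated
# response and design. Full constants kept so refits reproduce the value.
reml_ll <- function(delta, lam, yt, Wt, WtW_logdet) {
  n <- length(yt)
  q <- ncol(Wt)
  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  Ws <- Wt * sw
  ys <- yt * sw
  fit <- lm.fit(Ws, ys)
  rss <- sum(fit$residuals^2)
  sg2 <- rss / (n - q)
  XtX <- crossprod(Ws)
  ld <- determinant(XtX, logarithm = TRUE)$modulus[1]
  -0.5 * ((n - q) * log(2 * pi * sg2) + (n - q) + sum(log(lam + delta)) +
            ld - WtW_logdet)
}

#' Restricted likelihood of the mixed-model variance ratio
#'
#' Profile REML log-likelihood at a given `delta = sigma_e^2 / sigma_g^2` for
#' the model `y = W alpha + u + e`, `u ~ N(0, sigma_g^2 K)`. Exposed so the
#' optimum returned by [fit_null_mlm()] can be audited against a grid.
#'
#' @param delta Variance ratio (> 0).
#' @param y Response vector.
#' @param K `kinship_matrix` (or plain symmetric matrix).
#' @param covariates Optional covariate matrix; an intercept is always added.
#' @return Scalar restricted log-likelihood.
#' @export
mlm_reml_loglik <- function(delta, y, K, covariates = NULL) {
  Km <- if (inherits(K, "kinship_matrix")) K$values else K
  n <- length(y)
  W <- cbind(`(Intercept)` = rep(1, n), covariates)
  ev <- eigen(Km, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  yt <- drop(crossprod(ev$vectors, y))
  Wt <- crossprod(ev$vectors, W)
  WtW_logdet <- determinant(crossprod(W), logarithm = TRUE)$modulus[1]
  reml_ll(delta, lam, yt, Wt, WtW_logdet)
}

#' Fit the null mixed model for one response
#'
#' Model: `y = W alpha + u + e` with `u ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`. The kinship is eigendecomposed once, the model is
#' rotated to independence, and the restricted likelihood is maximized over
#' `log(delta)` on `[-10, 10]` (a coarse grid locates the basin, golden-
#' section polishing finds the optimum). The returned rotation is reused by
#' [association_scan()] so each variant test costs one weighted regression.
#'
#' @param y Named response vector (finite values; length >= 10 after dropping
#'   missing).
#' @param K A `kinship_matrix` from [compute_kinship()], or a plain matrix.
#' @param covariates Optional numeric covariate matrix (rows = accessions); an
#'   intercept is always included.
#' @param eigen_K Optional precomputed `eigen()` of the kinship, to share
#'   across responses.
#' @return List of class `null_mlm`: `delta`, `sigma_g2`, `sigma_e2`,
#'   `log_likelihood`, `rotation` (eigenvectors/eigenvalues), `W`
#'   (rotated design), `n`, `q`.
#' @export
fit_null_mlm <- function(y, K, covariates = NULL, eigen_K = NULL) {
  Km <- if (inherits(K, "kinship_matrix")) K$values else K
  if (anyNA(y)) stop("y must be free of missing values (subset first)",
                     call. = FALSE)
  n <- length(y)
  if (n < 10L) stop("need n >= 10 observations", call. = FALSE)
  if (sd(y) == 0) stop("response is constant", call. = FALSE)
  if (nrow(Km) != n) stop("kinship/response dimension mismatch", call. = FALSE)
  ev <- if (is.null(eigen_K)) eigen(Km, symmetric = TRUE) else eigen_K
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("kinship matrix is not positive semidefinite", call. = FALSE)
  lam <- pmax(ev$values, 0)
  W <- cbind(`(Intercept)` = rep(1, n), covariates)
  yt <- drop(crossprod(ev$vectors, y))
  Wt <- crossprod(ev$vectors, W)
  WtW_logdet <- determinant(crossprod(W), logarithm = TRUE)$modulus[1]

  f <- function(ld) reml_ll(exp(ld), lam, yt, Wt, WtW_logdet)
  grid <- seq(-10, 10, length.out = 128L)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(f, interval = c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.4)
  ld_hat <- if (opt$objective >= vals[i]) opt$maximum else grid[i]
  ll <- max(opt$objective, vals[i])
  delta <- exp(ld_hat)

  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  fit <- lm.fit(Wt * sw, yt * sw)
  sg2 <- sum(fit$residuals^2) / (n - ncol(Wt))
  structure(list(delta = delta, sigma_g2 = sg2, sigma_e2 = delta * sg2,
                 log_likelihood = ll,
                 rotation = list(vectors = ev$vectors, values = lam),
                 W = W, n = n, q = ncol(W)),
            class = "null_mlm")
}

# inverse-normal (rank) transform per row
rank_normalize_rows <- function(m) {
  t(apply(m, 1, function(v) qnorm((rank(v) - 0.5) / length(v))))
}

#' Single-variant association scan
#'
#' Tests every variant against one or many responses with a generalized-
#' least-squares Wald test. In `mlm` mode the kinship random effect is handled
#' EMMAX-style: the variance ratio is estimated once per response under the
#' null ([fit_null_mlm()]) and held fixed across variants, each test then
#' being a weighted regression in the eigenrotated model. In `ols_pcs` mode
#' structure is handled by including the top genotype principal components as
#' fixed covariates. With `K = I` (or zero PCs) both modes reduce exactly to
#' ordinary least squares.
#'
#' @param responses Numeric matrix, responses in rows and accessions in
#'   columns (a single named vector is accepted), or an expression matrix.
#' @param G A [genotype_matrix()] aligned to the same accessions.
#' @param K `kinship_matrix`; required for `mode = "mlm"`.
#' @param covariates Optional numeric covariate matrix (accessions in rows).
#' @param mode `"mlm"` (default) or `"ols_pcs"`.
#' @param n_pcs Number of PCs added as covariates in `ols_pcs` mode.
#' @param maf_min Variants with MAF below this are skipped (reported in
#'   `attr(, "skipped")`).
#' @param loco Leave-one-chromosome-out kinship (mlm mode only): each
#'   chromosome's variants are tested against a kinship rebuilt from the
#'   other chromosomes, removing proximal contamination (a variant helping to
#'   define the random effect it is tested against absorbs part of its own
#'   signal and deflates the null). The LOCO kinship is derived from `G`
#'   itself; a supplied `K` is only used for the non-LOCO path.
#' @param rank_normalize Transform each response to normal scores first
#'   (recommended for FPKM-scale expression).
#' @param p_max If set, only rows with `p <= p_max` are returned (the scan
#'   still tests everything); `NULL` returns all tests.
#' @return `data.frame` with columns `response_id`, `variant_id`, `chrom`,
#'   `pos`, `beta`, `se`, `stat` (squared Wald t), `p`, `r2` (variance
#'   explained: squared partial correlation after structure/covariate
#'   adjustment), and attributes `n_variants_tested`, `skipped`.
#' @export
association_scan <- function(responses, G, K = NULL, covariates = NULL,
                             mode = c("mlm", "ols_pcs"), n_pcs = 5L,
                             maf_min = 0.05, rank_normalize = FALSE,
                             loco = FALSE, p_max = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(dim(responses))) {
    responses <- matrix(responses, nrow = 1L,
                        dimnames = list("response", names(responses)))
  }
  if (is.null(colnames(responses)) ||
      !identical(colnames(responses), G$accessions))
    stop("responses must carry accession columns aligned to the genotypes",
         call. = FALSE)
  n <- length(G$accessions)
  maf <- G$variants$maf
  sds0 <- apply(impute_dosages(G$dosages), 2, sd)
  usable <- maf >= maf_min & sds0 > 0
  skipped <- data.frame(variant_id = G$variants$id[!usable],
                        reason = ifelse(sds0[!usable] == 0, "monomorphic",
                                        "maf_below_threshold"),
                        stringsAsFactors = FALSE)
  X <- impute_dosages(G$dosages)[, usable, drop = FALSE]
  vinfo <- G$variants[usable, , drop = FALSE]
  m <- ncol(X)
  if (m == 0L) stop("no testable variants after MAF filter", call. = FALSE)

  W <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (mode == "mlm") {
    if (loco) {
      # leave-one-chromosome-out kinship pieces from the full variant set
      Xk <- impute_dosages(G$dosages)
      Z <- standardize_pop(Xk)
      poly <- !is.na(Z[1, ])
      Z <- Z[, poly, drop = FALSE]
      kchr <- G$variants$chrom[poly]
      ZZ_all <- tcrossprod(Z)
      m_all <- ncol(Z)
      groups <- lapply(unique(vinfo$chrom), function(ch) {
        Zc <- Z[, kchr == ch, drop = FALSE]
        Kc <- (ZZ_all - tcrossprod(Zc)) / (m_all - ncol(Zc))
        ev <- eigen(Kc, symmetric = TRUE)
        ev$values <- pmax(ev$values, 0)
        list(cols = which(vinfo$chrom == ch), Km = Kc, ev = ev)
      })
    } else {
      if (is.null(K)) K <- compute_kinship(G)
      Km <- if (inherits(K, "kinship_matrix")) K$values else K
      ev <- eigen(Km, symmetric = TRUE)
      ev$values <- pmax(ev$values, 0)
      groups <- list(list(cols = seq_len(m), Km = Km, ev = ev))
    }
  } else {
    pcs <- if (n_pcs > 0L) compute_pcs(G, k = n_pcs) else NULL
    W <- cbind(`(Intercept)` = rep(1, n), covariates, pcs)
    groups <- list(list(cols = seq_len(m), Km = NULL, ev = NULL))
  }
  for (gi in seq_along(groups)) {
    if (!is.null(groups[[gi]]$ev))
      groups[[gi]]$Xt <- crossprod(groups[[gi]]$ev$vectors,
                                   X[, groups[[gi]]$cols, drop = FALSE])
    else groups[[gi]]$Xt <- X[, groups[[gi]]$cols, drop = FALSE]
  }

  if (rank_normalize) {
    cn <- colnames(responses)
    responses <- rank_normalize_rows(responses)
    colnames(responses) <- cn
  }

  out <- vector("list", nrow(responses) * length(groups))
  resp_ids <- rownames(responses)
  if (is.null(resp_ids)) resp_ids <- paste0("response_", seq_len(nrow(responses)))
  k_out <- 0L
  for (r in seq_len(nrow(responses))) {
    y <- responses[r, ]
    if (sd(y) == 0) next
    for (grp in groups) {
      if (mode == "mlm") {
        null_fit <- fit_null_mlm(y, grp$Km, covariates = covariates,
                                 eigen_K = grp$ev)
        sw <- sqrt(1 / (grp$ev$values + null_fit$delta))
        ys <- drop(crossprod(grp$ev$vectors, y)) * sw
        Ws <- crossprod(grp$ev$vectors, W) * sw
        Xs <- grp$Xt * sw
      } else {
        ys <- y
        Ws <- W
        Xs <- grp$Xt
      }
      res <- gls_scan_one(ys, Ws, Xs)
      vi <- vinfo[grp$cols, , drop = FALSE]
      if (!is.null(p_max)) {
        keep <- res$p <= p_max
        res <- lapply(res, `[`, keep)
        vi <- vi[keep, , drop = FALSE]
      }
      if (!length(res$beta)) next
      k_out <- k_out + 1L
      out[[k_out]] <- data.frame(response_id = resp_ids[r], variant_id = vi$id,
                                 chrom = vi$chrom, pos = vi$pos,
                                 beta = res$beta, se = res$se, stat = res$stat,
                                 p = res$p, r2 = res$r2,
                                 stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(response_id = character(), variant_id = character(),
                      chrom = character(), pos = integer(), beta = numeric(),
                      se = numeric(), stat = numeric(), p = numeric(),
                      r2 = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_variants_tested") <- m
  attr(res, "skipped") <- skipped
  res
}

# whitened single-variant regressions: ys response, Ws design (always
# includes intercept), Xs variant columns; all already on the whitened scale
gls_scan_one <- function(ys, Ws, Xs) {
  n <- length(ys)
  q <- ncol(Ws)
  qrW <- qr(Ws)
  yr <- qr.resid(qrW, ys)
  Xr <- qr.resid(qrW, Xs)
  xx <- colSums(Xr^2)
  xy <- drop(crossprod(Xr, yr))
  yy <- sum(yr^2)
  df <- n - q - 1L
  ok <- xx > n * .Machine$double.eps
  beta <- ifelse(ok, xy / xx, 0)
  rss <- pmax(yy - beta * xy, 0)
  sigma2 <- rss / df
  se <- ifelse(ok, sqrt(sigma2 / xx), NA_real_)
  tstat <- ifelse(ok & se > 0, beta / se, 0)
  p <- 2 * pt(-abs(tstat), df)
  r2 <- ifelse(ok & yy > 0, xy^2 / (xx * yy), 0)
  list(beta = beta, se = se, stat = tstat^2, p = p, r2 = r2)
}
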