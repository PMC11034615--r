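#' Read an expression matrix (genes x accessions TSV)
#'
#' First column holds gene ids, remaining columns one accession each, values
#' on an FPKM-like nonnegative scale. Replicate columns sharing an accession
#' id (duplicate header names) are averaged on read, so downstream stages see
#' one value per accession.
#'
#' @param path TSV path.
#' @param condition Label attached to the matrix (e.g. `"normal"`, `"stress"`).
#' @return Numeric matrix, genes in rows (row names = gene ids), accessions in
#'   columns, with attribute `condition`.
#' @export
read_expression_matrix <- function(path, condition = NA_character_) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  genes <- as.character(dt[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene id in ", path, ": ",
         genes[duplicated(genes)][1], call. = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  accs <- hdr[-1]
  if (length(accs) != ncol(m))
    stop("header/body column mismatch in ", path, call. = FALSE)
  rownames(m) <- genes
  if (anyDuplicated(accs)) {           # replicate columns: average per accession
    uniq <- unique(accs)
    m <- vapply(uniq, function(a) rowMeans(m[, accs == a, drop = FALSE]),
                numeric(nrow(m)))
    accs <- uniq
  }
  colnames(m) <- accs
  if (any(m < 0, na.rm = TRUE))
    stop("negative expression values in ", path, call. = FALSE)
  attr(m, "condition") <- condition
  m
}

#' Read gene annotation from BED6 or GFF3
#'
#' Coordinates are converted to the package's internal convention: 1-based,
#' inclusive. BED input (0-based, half-open) is shifted on read via
#' `rtracklayer`; GFF3 is taken as-is, restricted to `gene` features when the
#' file distinguishes feature types.
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", , drop = FALSE]
  id <- if (!is.null(df$gene_id)) df$gene_id
        else if (!is.null(df$ID)) df$ID
        else if (!is.null(df$Name)) df$Name
        else df$name
  if (is.null(id)) stop("cannot find gene ids in annotation: ", path, call. = FALSE)
  ann <- data.frame(gene_id = as.character(id),
                    chrom = as.character(df$seqnames),
                    start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("duplicated gene id in annotation: ",
         ann$gene_id[duplicated(ann$gene_id)][1], call. = FALSE)
  if (any(ann$start > ann$end)) stop("annotation has start > end", call. = FALSE)
  rownames(ann) <- NULL
  ann
}

#' Read a phenotype table (accessions x traits TSV)
#'
#' @param path TSV with accession ids in the first column and one numeric
#'   trait per remaining column; missing values permitted.
#' @return `data.frame` with row names = accession ids.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids))
    stop("duplicated accession id in phenotypes: ",
         ids[duplicated(ids)][1], call. = FALSE)
  ph <- dt[, -1, drop = FALSE]
  ph[] <- lapply(ph, as.numeric)
  rownames(ph) <- ids
  ph
}

#' Align accession panels across inputs
#'
#' Intersects the accession sets of all supplied objects and returns each one
#' restricted to the common panel in canonical (sorted) order, so the result
#' does not depend on input file order and re-aligning is a no-op.
#'
#' @param genotypes A [genotype_matrix()], or `NULL`.
#' @param expression Named list of expression matrices (accessions in
#'   columns), or `NULL`.
#' @param phenotypes Phenotype `data.frame` (accessions in rows), or `NULL`.
#' @return List with the aligned `genotypes`, `expression`, `phenotypes` and
#'   the common `accessions` vector.
#' @export
align_panel <- function(genotypes = NULL, expression = NULL, phenotypes = NULL) {
  sets <- list()
  if (!is.null(genotypes)) sets <- c(sets, list(genotypes$accessions))
  if (!is.null(expression))
    sets <- c(sets, lapply(expression, colnames))
  if (!is.null(phenotypes)) sets <- c(sets, list(rownames(phenotypes)))
  if (!length(sets)) stop("nothing to align", call. = FALSE)
  common <- Reduce(intersect, sets)
  if (length(common) == 0L)
    stop("no accessions shared across inputs", call. = FALSE)
  common <- sort(common)
  if (!is.null(genotypes)) genotypes <- subset_genotypes(genotypes, common)
  if (!is.null(expression))
    expression <- lapply(expression, function(m) {
      cond <- attr(m, "condition")
      m <- m[, common, drop = FALSE]
      attr(m, "condition") <- cond
      m
    })
  if (!is.null(phenotypes)) phenotypes <- phenotypes[common, , drop = FALSE]
  list(genotypes = genotypes, expression = expression,
       phenotypes = phenotypes, accessions = common)
}

#' Read the full tabular input bundle
#'
#' Reads the two condition expression matrices, the gene annotation and the
#' phenotype table, intersects accession panels, and reports genes that lack
#' annotation (they stay in the expression matrices — response classification
#' does not need coordinates — but are excluded from cis/trans calls).
#'
#' @param expr_normal_path,expr_stress_path TSV expression matrices.
#' @param annot_path BED6/GFF3 annotation.
#' @param pheno_path TSV phenotype table, or `NULL`.
#' @return List: `expression` (named list `normal`, `stress`), `annotation`,
#'   `phenotypes`, `accessions`, `unplaced_genes`.
#' @export
read_tables <- function(expr_normal_path, expr_stress_path, annot_path,
                        pheno_path = NULL) {
  expr <- list(normal = read_expression_matrix(expr_normal_path, "normal"),
               stress = read_expression_matrix(expr_stress_path, "stress"))
  ann <- read_gene_annotation(annot_path)
  ph <- if (is.null(pheno_path)) NULL else read_phenotypes(pheno_path)
  al <- align_panel(expression = expr, phenotypes = ph)
  genes <- union(rownames(expr$normal), rownames(expr$stress))
  unplaced <- setdiff(genes, ann$gene_id)
  if (length(unplaced))
    message(length(unplaced), " expressed gene(s) lack annotation and are ",
            "excluded from cis/trans classification")
  list(expression = al$expression, annotation = ann, phenotypes = al$phenotypes,
       accessions = al$accessions, unplaced_genes = unplaced)
}

#' Write a result table as TSV with a provenance header
#'
#' Prepends a `#` comment line recording the configuration hash and seed so
#' every output can be traced to the run that produced it.
#'
#' @param x `data.frame` to write.
#' @param path Output path.
#' @param cfg Optional `dyneqtl_config`.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, cfg = NULL) {
  hdr <- sprintf("# dyneqtl%s%s",
                 if (is.null(cfg)) "" else paste0(" config=", config_hash(cfg)),
                 if (is.null(cfg)) "" else paste0(" seed=", cfg$rng_seed))
  writeLines(hdr, path)
  suppressWarnings(data.table::fwrite(x, path, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}
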