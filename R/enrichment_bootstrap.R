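# Chromosome-level enrichment of gene features against a bootstrap null of
# equally sized random gene sets. For each chromosome with n_c genes, random
# sets of n_c genes are drawn without replacement from the whole genome,
# the mean feature value of each set forms the null distribution, and the
# chromosome's observed mean is placed on that null as a CDF value in [0,1]
# (near 0 = depleted, near 1 = enriched).

#' The standard gene-feature catalogue
#'
#' The 17 chromosome-level features evaluated by [enrichment_matrix()]:
#' per-gene physical-interaction counts (all / intra- / inter-chromosomal),
#' genetic-interaction counts split by chromosome partition and score sign,
#' protein-complex membership, and binary stress up-regulation under four
#' conditions (glycerol, lactate, ethanol, oxidative/oxaloacetate stress).
#'
#' @return data.frame with columns `feature_id`, `source` (which input table
#'   feeds the feature: `pi`, `gi`, `complexes`, `expr`), `partition`
#'   (`intra`/`inter`/`all`), `sign` (`pos`/`neg`/`all`), `condition`.
#' @export
default_feature_specs <- function() {
  data.frame(
    feature_id = c("PI_mean", "PI_intra", "PI_inter",
                   "GI", "GI_pos", "GI_neg",
                   "GI_intra", "GI_intra_pos", "GI_intra_neg",
                   "GI_inter", "GI_inter_pos", "GI_inter_neg",
                   "Complex_member",
                   "Expr_GLY", "Expr_LAC", "Expr_ETOH", "Expr_OXD"),
    source = c(rep("pi", 3), rep("gi", 9), "complexes", rep("expr", 4)),
    partition = c("all", "intra", "inter",
                  "all", "all", "all", "intra", "intra", "intra",
                  "inter", "inter", "inter", rep("all", 5)),
    sign = c(rep("all", 4), "pos", "neg", "all", "pos", "neg",
             "all", "pos", "neg", rep("all", 5)),
    condition = c(rep(NA_character_, 13), "GLY", "LAC", "ETOH", "OXD"),
    stringsAsFactors = FALSE)
}

#' Per-gene feature values for one feature
#'
#' Every gene of the genome map gets a value (0 when absent from the
#' source). For interaction features the value is the number of retained
#' pairs involving the gene whose partner lies on the same chromosome
#' (`intra`), a different chromosome (`inter`), or any (`all`), restricted
#' by score sign for the genetic variants (pos: score > 0; neg: score < 0).
#' Complex membership gives the 0/1 indicator; expression features give the
#' 0/1 up-regulation flag of the requested condition. Feature values are
#' defined once with respect to each gene's true chromosome; resampling
#' never redefines intra/inter.
#'
#' @param map a [genome_map()].
#' @param source an [interaction_table()], [expression_flags()] or
#'   [complex_membership()] matching `spec$source`.
#' @param spec one row of [default_feature_specs()] (data.frame or list).
#' @return Named numeric vector over all genes of `map`.
#' @export
gene_feature_vector <- function(map, source, spec) {
  genes <- map$genes$gene
  values <- stats::setNames(numeric(length(genes)), genes)
  spec <- as.list(spec)
  if (spec$source %in% c("pi", "gi")) {
    if (!inherits(source, "interaction_table")) {
      stopf("feature '%s' needs an interaction table", spec$feature_id)
    }
    if (spec$source == "gi" && interaction_kind(source) != "genetic") {
      stopf("feature '%s' needs a genetic interaction table", spec$feature_id)
    }
    tab <- as.data.frame(source)
    known <- tab$gene_a %in% genes & tab$gene_b %in% genes
    if (any(!known)) {
      msgf("ignored %d pair(s) with gene(s) absent from the genome map",
           sum(!known))
      tab <- tab[known, , drop = FALSE]
    }
    if (spec$sign != "all") {
      if (spec$sign == "pos") tab <- tab[tab$score > 0, , drop = FALSE]
      if (spec$sign == "neg") tab <- tab[tab$score < 0, , drop = FALSE]
    }
    if (nrow(tab) > 0) {
      chrom <- stats::setNames(map$genes$chrom, genes)
      same <- chrom[tab$gene_a] == chrom[tab$gene_b]
      if (spec$partition == "intra") tab <- tab[same, , drop = FALSE]
      if (spec$partition == "inter") tab <- tab[!same, , drop = FALSE]
    }
    if (nrow(tab) > 0) {
      cnt <- table(c(tab$gene_a, tab$gene_b))
      values[names(cnt)] <- as.numeric(cnt)
    }
  } else if (spec$source == "complexes") {
    if (!inherits(source, "complex_membership")) {
      stopf("feature '%s' needs a complex membership table", spec$feature_id)
    }
    inmap <- unique(source$gene)
    out <- setdiff(inmap, genes)
    if (length(out) > 0) {
      msgf("ignored %d complex gene(s) absent from the genome map", length(out))
    }
    values[genes %in% inmap] <- 1
  } else if (spec$source == "expr") {
    if (!inherits(source, "expression_flags")) {
      stopf("feature '%s' needs expression flags", spec$feature_id)
    }
    sub <- source[source$condition == spec$condition, , drop = FALSE]
    out <- setdiff(sub$gene, genes)
    if (length(out) > 0) {
      msgf("ignored %d flagged gene(s) absent from the genome map", length(out))
      sub <- sub[sub$gene %in% genes, , drop = FALSE]
    }
    values[sub$gene] <- sub$flag
  } else {
    stopf("unknown feature source '%s'", spec$source)
  }
  values
}

#' Bootstrap null distribution for a chromosome-sized gene set
#'
#' Each replicate draws `set_size` genes without replacement from the full
#' gene universe and records the mean of their feature values; the null mean
#' and sd are taken over the replicates. This is the null against which a
#' chromosome's observed mean is placed.
#'
#' @param values named numeric vector of per-gene feature values (the
#'   universe), as from [gene_feature_vector()].
#' @param set_size number of genes per random set (a chromosome's n_c).
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @param keep_samples retain the replicate means (needed for
#'   `method = "empirical"` in [cdf_value()]).
#' @return List of class `null_distribution` with `reps`, `set_size`,
#'   `null_mean`, `null_sd`, `samples` (or `NULL`), `seed`.
#' @export
bootstrap_null <- function(values, set_size, reps = 10000L, seed = 1L,
                           keep_samples = TRUE) {
  n <- length(values)
  if (set_size > n) stopf("set_size (%d) exceeds gene universe (%d)", set_size, n)
  if (set_size < 1 || reps < 1) stopf("set_size and reps must be >= 1")
  values <- unname(values)
  samples <- with_seed(seed, {
    vapply(seq_len(reps),
           function(r) mean(values[sample.int(n, set_size)]),
           numeric(1))
  })
  structure(list(reps = as.integer(reps), set_size = as.integer(set_size),
                 null_mean = mean(samples), null_sd = stats::sd(samples),
                 samples = if (keep_samples) samples else NULL,
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' CDF value of an observed mean on a bootstrap null
#'
#' `method = "normal"` evaluates the normal CDF at the standardized observed
#' mean, `pnorm((actual - null_mean) / null_sd)`; `method = "empirical"`
#' uses the proportion of replicate means below the observed value, counting
#' ties at half weight. A degenerate null (`null_sd = 0`) gives 0.5 when the
#' observed mean equals the null mean, else 0 or 1 by sign.
#'
#' @param actual_mean observed mean feature value of the chromosome's genes.
#' @param null a [bootstrap_null()] result.
#' @param method `"normal"` or `"empirical"`.
#' @return CDF value in `[0, 1]`.
#' @export
cdf_value <- function(actual_mean, null, method = c("normal", "empirical")) {
  method <- match.arg(method)
  if (is.na(null$null_sd) || null$null_sd == 0) {
    d <- actual_mean - null$null_mean
    return(if (d == 0) 0.5 else if (d > 0) 1 else 0)
  }
  if (method == "normal") {
    stats::pnorm((actual_mean - null$null_mean) / null$null_sd)
  } else {
    if (is.null(null$samples)) stopf("empirical method needs retained samples")
    (sum(null$samples < actual_mean) +
       0.5 * sum(null$samples == actual_mean)) / null$reps
  }
}

#' Chromosome x feature enrichment matrix of CDF values
#'
#' For every chromosome and every computable feature, compares the mean
#' feature value of the chromosome's genes to a [bootstrap_null()] of
#' equally sized random gene sets and records the [cdf_value()]. The
#' observed statistic is the mean over the chromosome's genes; since the
#' chromosome's sum is its mean times n_c and every null replicate has the
#' same set size, `statistic = "sum"` rescales both sides by n_c and yields
#' the identical CDF replicate-for-replicate.
#'
#' One shared `seed` governs the whole matrix; each (chromosome, feature)
#' cell uses a deterministically derived substream, so the full heatmap is
#' reproducible and individual cells can be recomputed in isolation.
#'
#' @param map a [genome_map()].
#' @param sources named list with any of `gi`, `pi`, `complexes`, `expr`;
#'   features whose source is missing are skipped with a warning.
#' @param specs feature catalogue (default [default_feature_specs()]).
#' @param reps bootstrap replicates per cell.
#' @param seed master seed.
#' @param method CDF method, `"normal"` or `"empirical"`.
#' @param statistic `"mean"` or `"sum"` per-chromosome statistic.
#' @param aneuploidy_f optional [aneuploidy_frequency()] result appended as
#'   an `Aneup_freq` column (raw f, not a CDF).
#' @return List of class `enrichment_matrix` with `cdf` (chromosome x
#'   feature matrix), `long` (data.frame: chrom, feature, actual, null_mean,
#'   null_sd, cdf), `seed`, `method`, `reps`.
#' @export
enrichment_matrix <- function(map, sources, specs = default_feature_specs(),
                              reps = 10000L, seed = 1L,
                              method = c("normal", "empirical"),
                              statistic = c("mean", "sum"),
                              aneuploidy_f = NULL) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  chroms <- map$chromosomes$chrom
  n_c <- genes_per_chromosome(map)
  have <- specs$source %in% names(sources)
  if (any(!have)) {
    warnf("skipping feature(s) without a source table: %s",
          paste(specs$feature_id[!have], collapse = ", "))
    specs <- specs[have, , drop = FALSE]
  }
  if (nrow(specs) == 0) stopf("no computable features")
  vectors <- lapply(seq_len(nrow(specs)), function(i) {
    gene_feature_vector(map, sources[[specs$source[i]]], specs[i, ])
  })
  names(vectors) <- specs$feature_id
  enrichment_cdf(map, vectors, reps = reps, seed = seed, method = method,
                 statistic = statistic, aneuploidy_f = aneuploidy_f)
}

#' Chromosome x feature CDF matrix from precomputed feature vectors
#'
#' The core engine behind [enrichment_matrix()], usable directly with any
#' named list of per-gene value vectors (e.g. for calibration experiments
#' where feature values are assigned independently of chromosome).
#'
#' @param map a [genome_map()].
#' @param vectors named list of numeric vectors, each named by gene and
#'   covering every gene of `map` (as from [gene_feature_vector()]).
#' @inheritParams enrichment_matrix
#' @return An `enrichment_matrix` object; see [enrichment_matrix()].
#' @export
enrichment_cdf <- function(map, vectors, reps = 10000L, seed = 1L,
                           method = c("normal", "empirical"),
                           statistic = c("mean", "sum"),
                           aneuploidy_f = NULL) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  chroms <- map$chromosomes$chrom
  n_c <- genes_per_chromosome(map)
  genes <- map$genes$gene
  for (nm in names(vectors)) {
    if (!all(genes %in% names(vectors[[nm]]))) {
      stopf("feature vector '%s' does not cover every gene of the map", nm)
    }
    vectors[[nm]] <- vectors[[nm]][genes]
  }
  if (any(n_c == 0)) {
    warnf("chromosome(s) without genes flagged with NA rows: %s",
          paste(names(n_c)[n_c == 0], collapse = ", "))
  }
  cdf <- matrix(NA_real_, length(chroms), length(vectors),
                dimnames = list(chroms, names(vectors)))
  long <- vector("list", length(chroms) * length(vectors))
  idx <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    if (n_c[[ch]] == 0) next
    on_ch <- map$genes$chrom == ch
    for (fi in seq_along(vectors)) {
      v <- vectors[[fi]]
      null <- bootstrap_null(v, n_c[[ch]], reps = reps,
                             seed = derive_seed(seed, ci, fi),
                             keep_samples = (method == "empirical"))
      actual <- mean(v[on_ch])
      # the CDF is computed on the mean scale: the sum statistic is the mean
      # times the fixed set size, a positive rescaling of both sides, so the
      # CDF is identical and only the reported magnitudes change
      cdf[ci, fi] <- cdf_value(actual, null, method)
      if (statistic == "sum") {
        k <- null$set_size
        actual <- actual * k
        null$null_mean <- null$null_mean * k
        null$null_sd <- null$null_sd * k
      }
      idx <- idx + 1L
      long[[idx]] <- data.frame(chrom = ch, feature = names(vectors)[fi],
                                actual = actual, null_mean = null$null_mean,
                                null_sd = null$null_sd, cdf = cdf[ci, fi])
    }
  }
  long <- do.call(rbind, long[seq_len(idx)])
  if (!is.null(aneuploidy_f)) {
    f <- aneuploidy_f$f[match(chroms, aneuploidy_f$chrom)]
    cdf <- cbind(cdf, Aneup_freq = f)
  }
  structure(list(cdf = cdf, long = long, seed = as.integer(seed),
                 method = method, reps = as.integer(reps)),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d chromosomes x %d columns (reps = %d, method = %s)\n",
              nrow(x$cdf), ncol(x$cdf), x$reps, x$method))
  invisible(x)
}

#' Correlation-clustered heatmap ordering
#'
#' Hierarchical ordering of rows and columns by average-linkage
#' agglomeration on the distance 1 - Pearson correlation, as used to arrange
#' the enrichment heatmap. Zero-variance rows or columns have no defined
#' correlation and are assigned the maximal distance 2, with a warning.
#'
#' @param mat numeric matrix (e.g. the `cdf` element of an
#'   [enrichment_matrix()]), or the `enrichment_matrix` itself.
#' @return List with `row_order` and `col_order` (character vectors of
#'   dimnames in leaf order) and the two `hclust` trees.
#' @export
cluster_heatmap_order <- function(mat) {
  if (inherits(mat, "enrichment_matrix")) mat <- mat$cdf
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) stopf("need >= 2 rows and columns")
  cor_dist <- function(m) {
    sds <- apply(m, 1, stats::sd)
    if (any(is.na(sds)) || any(sds == 0)) {
      warnf("zero-variance row/column assigned maximal distance")
    }
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- -1
    stats::as.dist(1 - cc)
  }
  hr <- stats::hclust(cor_dist(mat), method = "average")
  hc <- stats::hclust(cor_dist(t(mat)), method = "average")
  list(row_order = rownames(mat)[hr$order],
       col_order = colnames(mat)[hc$order],
       row_tree = hr, col_tree = hc)
}

#' Write an enrichment matrix (long and wide) as TSV
#'
#' @param em an [enrichment_matrix()].
#' @param prefix output path prefix; writes `<prefix>.long.tsv`,
#'   `<prefix>.matrix.tsv` and, when the matrix is clusterable,
#'   `<prefix>.order.tsv` with the clustered row/column orders.
#' @return Named vector of written paths, invisibly.
#' @export
write_enrichment_matrix <- function(em, prefix) {
  p_long <- paste0(prefix, ".long.tsv")
  p_wide <- paste0(prefix, ".matrix.tsv")
  utils::write.table(em$long, p_long, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wide <- data.frame(chrom = rownames(em$cdf), em$cdf, check.names = FALSE)
  utils::write.table(wide, p_wide, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(long = p_long, matrix = p_wide)
  ok <- stats::complete.cases(em$cdf)
  if (sum(ok) >= 2 && ncol(em$cdf) >= 2) {
    ord <- suppressWarnings(cluster_heatmap_order(em$cdf[ok, , drop = FALSE]))
    p_ord <- paste0(prefix, ".order.tsv")
    n <- max(length(ord$row_order), length(ord$col_order))
    utils::write.table(
      data.frame(rank = seq_len(n),
                 row = c(ord$row_order, rep("", n - length(ord$row_order))),
                 column = c(ord$col_order, rep("", n - length(ord$col_order)))),
      p_ord, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, order = p_ord)
  }
  invisible(paths)
}
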