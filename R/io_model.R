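# Domain types and tab-delimited readers/writers for every input the
# pipeline touches. All files are TSV, UTF-8, with a header row; lines
# starting with '#' are comments (the genome-map section markers
# "#chromosomes" / "#genes" excepted).

# ---------------------------------------------------------------------------
# GenomeMap

#' Construct a genome map
#'
#' A genome map holds the chromosome complement (ids and lengths) and the
#' gene coordinates used throughout the pipeline: chromosome lengths are the
#' x-axis of the size-frequency correlation, and the per-chromosome gene
#' counts are the set sizes drawn by the bootstrap null.
#'
#' @param chromosomes data.frame with columns `chrom` (unique ids) and
#'   `length` (bp, positive integers).
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand`. Coordinates are 1-based inclusive; `strand` is `+` or `-` and
#'   is retained for format fidelity only (no statistic uses it).
#' @return An object of class `genome_map`: a list with elements
#'   `chromosomes` and `genes`, genes sorted by (chromosome, start).
#' @examples
#' gm <- genome_map(
#'   data.frame(chrom = c("chrA", "chrB"), length = c(1e5, 5e4)),
#'   data.frame(gene = c("g1", "g2"), chrom = c("chrA", "chrB"),
#'              start = c(100, 200), end = c(900, 700), strand = "+"))
#' genes_per_chromosome(gm)
#' @export
genome_map <- function(chromosomes, genes) {
  chromosomes <- as.data.frame(chromosomes)
  genes <- as.data.frame(genes)
  need_c <- c("chrom", "length")
  need_g <- c("gene", "chrom", "start", "end", "strand")
  if (!all(need_c %in% names(chromosomes))) {
    stopf("chromosomes needs columns: %s", paste(need_c, collapse = ", "))
  }
  if (nrow(genes) > 0 && !all(need_g %in% names(genes))) {
    stopf("genes needs columns: %s", paste(need_g, collapse = ", "))
  }
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom)) {
    stopf("duplicated chromosome ids: %s",
          paste(unique(chromosomes$chrom[duplicated(chromosomes$chrom)]),
                collapse = ", "))
  }
  if (any(chromosomes$length <= 0) || any(chromosomes$length != round(chromosomes$length))) {
    stopf("chromosome lengths must be positive integers")
  }
  chromosomes$length <- as.integer(round(chromosomes$length))
  if (nrow(genes) == 0) {
    genes <- data.frame(gene = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  } else {
    genes$gene <- as.character(genes$gene)
    genes$chrom <- as.character(genes$chrom)
    bad <- !genes$chrom %in% chromosomes$chrom
    if (any(bad)) {
      stopf("gene row %d cites unknown chromosome '%s'",
            which(bad)[1], genes$chrom[which(bad)[1]])
    }
    if (anyDuplicated(genes$gene)) {
      stopf("duplicated gene ids: %s",
            paste(unique(genes$gene[duplicated(genes$gene)]), collapse = ", "))
    }
    for (col in c("start", "end")) {
      v <- genes[[col]]
      if (!is.numeric(v) || any(is.na(v)) || any(v != round(v))) {
        stopf("non-integer gene coordinate in column '%s'", col)
      }
      genes[[col]] <- as.integer(round(v))
    }
    len <- chromosomes$length[match(genes$chrom, chromosomes$chrom)]
    if (any(genes$start < 1) || any(genes$end < genes$start) || any(genes$end > len)) {
      i <- which(genes$start < 1 | genes$end < genes$start | genes$end > len)[1]
      stopf("gene '%s' has coordinates outside 1..chromosome length", genes$gene[i])
    }
    if (!all(genes$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
    ord <- order(match(genes$chrom, chromosomes$chrom), genes$start)
    genes <- genes[ord, need_g, drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(chromosomes = chromosomes[, need_c], genes = genes),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes (%.2f Mb), %d genes\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$genes)))
  invisible(x)
}

#' Chromosome lengths of a genome map
#' @param map a [genome_map()].
#' @return Named integer vector of lengths in bp.
#' @export
chromosome_lengths <- function(map) {
  stats::setNames(map$chromosomes$length, map$chromosomes$chrom)
}

#' Number of genes per chromosome
#'
#' The per-chromosome gene counts n_c; chromosomes without genes get 0.
#' These are the set sizes used by [bootstrap_null()].
#' @inheritParams chromosome_lengths
#' @return Named integer vector.
#' @export
genes_per_chromosome <- function(map) {
  n <- table(factor(map$genes$chrom, levels = map$chromosomes$chrom))
  stats::setNames(as.integer(n), map$chromosomes$chrom)
}

#' Read a genome map from a two-section TSV
#'
#' The file has a `#chromosomes` section (columns `chrom`, `length`)
#' followed by a `#genes` section (columns `gene`, `chrom`, `start`, `end`,
#' `strand`). Other `#` lines are comments.
#'
#' @param path path to the file.
#' @return A [genome_map()].
#' @export
load_genome_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  i_chr <- which(trimws(lines) == "#chromosomes")
  i_gen <- which(trimws(lines) == "#genes")
  if (length(i_chr) != 1 || length(i_gen) != 1 || i_gen <= i_chr) {
    stopf("'%s' is not a two-section genome map (#chromosomes then #genes)", path)
  }
  strip <- function(x) x[!startsWith(trimws(x), "#") & nzchar(trimws(x))]
  chr_txt <- strip(lines[(i_chr + 1):(i_gen - 1)])
  gen_txt <- if (i_gen < length(lines)) strip(lines[(i_gen + 1):length(lines)]) else character()
  chroms <- utils::read.table(text = chr_txt, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, quote = "")
  genes <- if (length(gen_txt) > 1) {
    utils::read.table(text = gen_txt, header = TRUE, sep = "\t",
                      colClasses = c("character", "character", "character",
                                     "character", "character"),
                      stringsAsFactors = FALSE, quote = "")
  } else {
    data.frame(gene = character(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  }
  if (nrow(genes) > 0) {
    for (col in c("start", "end")) {
      v <- suppressWarnings(as.numeric(genes[[col]]))
      bad <- is.na(v) | v != round(v)
      if (any(bad)) {
        stopf("non-integer coordinate '%s' in gene row %d of '%s'",
              genes[[col]][which(bad)[1]], which(bad)[1], path)
      }
      genes[[col]] <- as.integer(v)
    }
    unknown <- !genes$chrom %in% chroms$chrom
    if (any(unknown)) {
      stopf("gene row %d of '%s' cites unknown chromosome '%s'",
            which(unknown)[1], path, genes$chrom[which(unknown)[1]])
    }
  }
  genome_map(chroms, genes)
}

#' Write a genome map to the two-section TSV dialect
#' @param map a [genome_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_map <- function(map, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#chromosomes", con)
  utils::write.table(map$chromosomes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("#genes", con)
  utils::write.table(map$genes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CopyNumberMatrix

# Per-strain mode of copies; ties broken toward the smaller value.
infer_baseline_ploidy <- function(copies) {
  apply(copies, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_integer_)
    tab <- table(x)
    as.integer(names(tab)[which.max(tab)])  # names sorted ascending; first max wins
  })
}

#' Construct a strain x chromosome copy-number matrix
#'
#' @param copies integer matrix, strains in rows (rownames) and chromosomes
#'   in columns (colnames); `NA` marks missing calls.
#' @param baseline_ploidy integer vector of per-strain baseline ploidies
#'   (recycled), or `NULL` to infer each strain's baseline as the mode of its
#'   chromosome copies with ties broken toward the smaller value.
#' @return Object of class `copy_number_matrix`: list with `strains`,
#'   `chromosomes`, `copies`, `baseline_ploidy`.
#' @export
copy_number_matrix <- function(copies, baseline_ploidy = NULL) {
  copies <- as.matrix(copies)
  if (is.null(rownames(copies)) || is.null(colnames(copies))) {
    stopf("copies must have strain rownames and chromosome colnames")
  }
  storage.mode(copies) <- "integer"
  if (any(copies < 0, na.rm = TRUE)) stopf("negative copy number")
  if (is.null(baseline_ploidy)) {
    baseline_ploidy <- infer_baseline_ploidy(copies)
  } else {
    baseline_ploidy <- as.integer(rep_len(baseline_ploidy, nrow(copies)))
  }
  if (any(baseline_ploidy < 1, na.rm = TRUE)) stopf("baseline ploidy must be >= 1")
  names(baseline_ploidy) <- rownames(copies)
  structure(list(strains = rownames(copies), chromosomes = colnames(copies),
                 copies = copies, baseline_ploidy = baseline_ploidy),
            class = "copy_number_matrix")
}

#' @export
print.copy_number_matrix <- function(x, ...) {
  cat(sprintf("copy_number_matrix: %d strains x %d chromosomes (%d missing cells)\n",
              length(x$strains), length(x$chromosomes), sum(is.na(x$copies))))
  invisible(x)
}

#' Read a strain x chromosome copy-number TSV
#'
#' First column `strain`, an optional `ploidy` column, then one column per
#' chromosome. Shaped like published panel-wide chromosome copy-number calls.
#' When `ploidy` is absent the baseline is inferred per strain as the mode of
#' its copies (ties toward the smaller value).
#'
#' @param path path to the TSV.
#' @return A [copy_number_matrix()].
#' @export
load_copy_number_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#", quote = "")
  if (length(unique(nf)) != 1) stopf("ragged rows in '%s'", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1] != "strain") stopf("first column of '%s' must be 'strain'", path)
  ploidy <- NULL
  if ("ploidy" %in% names(df)) {
    ploidy <- as.integer(df$ploidy)
    df$ploidy <- NULL
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$strain
  if (any(m < 0, na.rm = TRUE)) stopf("negative copy number in '%s'", path)
  copy_number_matrix(m, baseline_ploidy = ploidy)
}

#' Write a copy-number matrix as TSV (with its ploidy column)
#' @param mat a [copy_number_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_copy_number_matrix <- function(mat, path) {
  df <- data.frame(strain = mat$strains, ploidy = mat$baseline_ploidy,
                   mat$copies, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# DepthProfile

#' Construct a windowed depth profile
#'
#' Windows are 0-based half-open (BED convention) and must not overlap
#' within a chromosome; `depth` is mean fold-coverage over the window.
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `depth`.
#' @return Object of class `depth_profile` (a validated data.frame).
#' @export
depth_profile <- function(records) {
  records <- as.data.frame(records)
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(records))) {
    stopf("depth profile needs columns: %s", paste(need, collapse = ", "))
  }
  records <- records[, need]
  records$chrom <- as.character(records$chrom)
  if (any(records$depth < 0)) stopf("negative depth")
  if (any(records$end <= records$start)) stopf("empty or inverted window")
  for (ch in unique(records$chrom)) {
    w <- records[records$chrom == ch, ]
    w <- w[order(w$start), ]
    if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)])) {
      stopf("overlapping windows on chromosome '%s'", ch)
    }
  }
  ord <- order(records$chrom, records$start)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("depth_profile", "data.frame")
  records
}

#' Read a windowed BED depth file (chrom, start, end, mean depth)
#' @param path path to the BED-like TSV (header row required).
#' @return A [depth_profile()].
#' @export
load_depth_bed <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "depth")
  depth_profile(df)
}

#' Read samtools-depth output into fixed windows
#'
#' Consumes the three-column `samtools depth` dialect (chrom, 1-based
#' position, depth). Positions absent from the file are counted as depth 0
#' (`-a` semantics): omission would bias window means upward on lost
#' chromosomes. Every chromosome of `map` is tiled with `window_size`
#' windows (last window may be short).
#'
#' @param path path to the per-base depth TSV (no header).
#' @param map a [genome_map()] providing chromosome bounds.
#' @param window_size window width in bp.
#' @return A [depth_profile()].
#' @export
load_samtools_depth <- function(path, map, window_size = 1000L) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "depth"))
  lens <- chromosome_lengths(map)
  unknown <- setdiff(unique(df$chrom), names(lens))
  if (length(unknown) > 0) {
    stopf("depth file cites unknown chromosome '%s'", unknown[1])
  }
  out <- lapply(names(lens), function(ch) {
    len <- lens[[ch]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    ends <- pmin(starts + window_size, len)
    sums <- numeric(length(starts))
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 0) {
      if (any(sub$pos < 1 | sub$pos > len)) {
        stopf("position outside chromosome '%s'", ch)
      }
      idx <- (sub$pos - 1L) %/% window_size + 1L
      agg <- tapply(sub$depth, idx, sum)
      sums[as.integer(names(agg))] <- agg
    }
    data.frame(chrom = ch, start = starts, end = ends,
               depth = sums / (ends - starts))
  })
  depth_profile(do.call(rbind, out))
}

#' Write a depth profile as windowed BED
#' @param depth a [depth_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(depth, path) {
  df <- as.data.frame(depth)
  df$depth <- sprintf("%.17g", df$depth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# InteractionTable

#' Construct a gene-gene interaction table
#'
#' Applies the table invariants: self-pairs are dropped, and duplicate
#' unordered pairs are collapsed -- genetic scores to their arithmetic mean
#' (symmetric and order-independent, so downstream sums are well defined),
#' physical pairs to a single row. Drop counts are reported via [message()].
#'
#' @param rows data.frame with columns `gene_a`, `gene_b` and, for
#'   `kind = "genetic"`, a numeric signed `score`.
#' @param kind `"genetic"` (signed epistasis scores) or `"physical"`
#'   (unsigned pairs).
#' @return Object of class `interaction_table`: a data.frame with attribute
#'   `kind`.
#' @export
interaction_table <- function(rows, kind = c("genetic", "physical")) {
  kind <- match.arg(kind)
  rows <- as.data.frame(rows)
  if (!all(c("gene_a", "gene_b") %in% names(rows))) {
    stopf("interaction table needs columns gene_a, gene_b")
  }
  rows$gene_a <- as.character(rows$gene_a)
  rows$gene_b <- as.character(rows$gene_b)
  if (kind == "genetic") {
    if (!"score" %in% names(rows)) stopf("genetic table needs a score column")
    if (!is.numeric(rows$score) || anyNA(rows$score)) {
      stopf("non-numeric score in genetic interaction table")
    }
  }
  self <- rows$gene_a == rows$gene_b
  if (any(self)) {
    msgf("dropped %d self-pair(s)", sum(self))
    rows <- rows[!self, , drop = FALSE]
  }
  key <- ifelse(rows$gene_a < rows$gene_b,
                paste(rows$gene_a, rows$gene_b, sep = "\r"),
                paste(rows$gene_b, rows$gene_a, sep = "\r"))
  ndup <- sum(duplicated(key))
  if (kind == "genetic") {
    if (ndup > 0) {
      score <- tapply(rows$score, key, mean)
      keep <- !duplicated(key)
      rows <- rows[keep, , drop = FALSE]
      rows$score <- as.numeric(score[key[keep]])
      msgf("collapsed %d duplicate unordered pair(s) to mean score", ndup)
    }
    out <- rows[, c("gene_a", "gene_b", "score")]
  } else {
    if (ndup > 0) {
      rows <- rows[!duplicated(key), , drop = FALSE]
      msgf("collapsed %d duplicate unordered pair(s)", ndup)
    }
    out <- rows[, c("gene_a", "gene_b")]
  }
  rownames(out) <- NULL
  structure(out, kind = kind, class = c("interaction_table", "data.frame"))
}

#' Kind of an interaction table ("genetic" or "physical")
#' @param table an [interaction_table()].
#' @return Character scalar.
#' @export
interaction_kind <- function(table) attr(table, "kind")

#' Read a gene-gene interaction TSV
#'
#' Columns `gene_a`, `gene_b` and (for genetic tables) `score`. Shaped like
#' pair-score exports from genome-wide genetic interaction screens or
#' curated physical-interaction pair lists. Self-pairs and duplicate
#' unordered pairs are handled by [interaction_table()].
#'
#' @param path path to the TSV.
#' @param kind `"genetic"` or `"physical"`.
#' @return An [interaction_table()].
#' @export
load_interaction_table <- function(path, kind = c("genetic", "physical")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (kind == "genetic") {
    if (!"score" %in% names(df)) stopf("'%s' lacks a score column", path)
    sc <- suppressWarnings(as.numeric(df$score))
    if (anyNA(sc)) {
      stopf("non-numeric score '%s' in row %d of '%s'",
            df$score[which(is.na(sc))[1]], which(is.na(sc))[1], path)
    }
    df$score <- sc
  }
  interaction_table(df, kind)
}

#' Write an interaction table as TSV
#'
#' Scores are serialized with 17 significant digits so write -> load is the
#' identity.
#'
#' @param table an [interaction_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path) {
  df <- as.data.frame(table)
  if ("score" %in% names(df)) df$score <- sprintf("%.17g", df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ExpressionFlags and ComplexMembership

#' Construct per-gene binary stress up-regulation flags
#'
#' One row per gene x condition; `flag` is 1 if the gene is up-regulated in
#' the stress condition relative to control, 0 if not differentially
#' expressed or down-regulated.
#'
#' @param rows data.frame with columns `gene`, `condition`, `flag`.
#' @param conditions allowed condition labels.
#' @return Object of class `expression_flags` (a validated data.frame).
#' @export
expression_flags <- function(rows, conditions = c("GLY", "LAC", "ETOH", "OXD")) {
  rows <- as.data.frame(rows)
  need <- c("gene", "condition", "flag")
  if (!all(need %in% names(rows))) {
    stopf("expression flags need columns: %s", paste(need, collapse = ", "))
  }
  rows$gene <- as.character(rows$gene)
  rows$condition <- as.character(rows$condition)
  if (!all(rows$condition %in% conditions)) {
    stopf("unknown condition '%s'",
          setdiff(unique(rows$condition), conditions)[1])
  }
  if (!all(rows$flag %in% c(0L, 1L))) stopf("flags must be 0 or 1")
  rows$flag <- as.integer(rows$flag)
  if (anyDuplicated(rows[, c("gene", "condition")])) {
    stopf("more than one row for some gene x condition")
  }
  rows <- rows[order(rows$condition, rows$gene), need]
  rownames(rows) <- NULL
  structure(rows, class = c("expression_flags", "data.frame"))
}

#' Read per-gene binary expression flags (gene, condition, flag)
#' @param path path to the TSV.
#' @return An [expression_flags()].
#' @export
load_expression_flags <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  expression_flags(df)
}

#' Write expression flags as TSV
#' @param flags an [expression_flags()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_flags <- function(flags, path) {
  utils::write.table(as.data.frame(flags), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a protein-complex membership table
#'
#' A gene may belong to several complexes; the enrichment feature derived
#' from this table is the binary indicator "gene appears in the table".
#'
#' @param rows data.frame with columns `gene`, `complex`.
#' @return Object of class `complex_membership` (a validated data.frame).
#' @export
complex_membership <- function(rows) {
  rows <- as.data.frame(rows)
  if (!all(c("gene", "complex") %in% names(rows))) {
    stopf("complex membership needs columns gene, complex")
  }
  rows$gene <- as.character(rows$gene)
  rows$complex <- as.character(rows$complex)
  rows <- unique(rows[, c("gene", "complex")])
  rows <- rows[order(rows$complex, rows$gene), ]
  rownames(rows) <- NULL
  structure(rows, class = c("complex_membership", "data.frame"))
}

#' Read a complex-membership TSV (gene/ORF, complex)
#' @param path path to the TSV.
#' @return A [complex_membership()].
#' @export
load_complex_membership <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "complex")
  complex_membership(df)
}

#' Write complex membership as TSV
#' @param membership a [complex_membership()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_membership <- function(membership, path) {
  utils::write.table(as.data.frame(membership), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
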