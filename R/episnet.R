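# Signed chromosome-pair epistasis sums and the "least-epistasis" directed
# network: summed genetic-interaction scores between chromosomes, with
# positive interactions compensating negative ones, and one arrow per
# chromosome pointing to the partner whose summed interaction is nearest to
# zero -- the chromosome whose copy-number change has the least epistatic
# effect.

#' Pairwise inter-chromosomal interaction sums
#'
#' `S(i, j)` is the sum of signed genetic-interaction scores over all
#' retained pairs with one gene on chromosome i and the other on j; positive
#' and negative scores offset. Intra-chromosomal pairs are excluded. Pairs
#' whose genes cannot be resolved to a chromosome of the map are skipped
#' with a logged count. Chromosome pairs with no interactions sum to 0.
#'
#' @param table an [interaction_table()] with kind `"genetic"`.
#' @param map a [genome_map()].
#' @return Symmetric numeric matrix of class `epistasis_sums` over the map's
#'   chromosomes, diagonal `NA`.
#' @export
pairwise_interaction_sums <- function(table, map) {
  if (interaction_kind(table) != "genetic") {
    stopf("epistasis sums need a genetic interaction table")
  }
  chroms <- map$chromosomes$chrom
  chrom_of <- stats::setNames(map$genes$chrom, map$genes$gene)
  S <- matrix(0, length(chroms), length(chroms),
              dimnames = list(chroms, chroms))
  tab <- as.data.frame(table)
  ca <- chrom_of[tab$gene_a]
  cb <- chrom_of[tab$gene_b]
  unresolved <- is.na(ca) | is.na(cb)
  if (any(unresolved)) {
    msgf("skipped %d pair(s) with gene(s) not resolvable to a chromosome",
         sum(unresolved))
  }
  keep <- !unresolved & ca != cb
  if (any(keep)) {
    agg <- tapply(tab$score[keep],
                  list(factor(ca[keep], levels = chroms),
                       factor(cb[keep], levels = chroms)),
                  sum, default = 0)
    S <- agg + t(agg)
  }
  diag(S) <- NA_real_
  structure(S, class = c("epistasis_sums", "matrix"))
}

#' Least-epistasis directed network
#'
#' One out-edge per chromosome, pointing to the partner j minimizing
#' `|S(i, j)|` -- the chromosome whose summed epistatic interaction with i
#' is nearest to zero, hence the least-perturbing partner if i's copy
#' number changes. Ties at equal `|S|` are broken toward the
#' lexicographically smallest target id. Mutual edge pairs (i -> j and
#' j -> i) are flagged.
#'
#' @param S an [pairwise_interaction_sums()] matrix (symmetric, `NA`
#'   diagonal).
#' @return List of class `least_epistasis_network` with `edges` (data.frame:
#'   `source`, `target`, `S`, `abs_S`, `mutual`) and `in_degree` (named
#'   integer, every chromosome reported).
#' @export
least_epistasis_network <- function(S) {
  S <- unclass(S)
  chroms <- rownames(S)
  if (is.null(chroms) || nrow(S) < 2) stopf("need >= 2 chromosomes")
  edges <- lapply(chroms, function(i) {
    s <- S[i, ]
    s <- s[!is.na(s) & names(s) != i]
    if (length(s) == 0) return(NULL)
    a <- abs(s)
    cand <- sort(names(s)[a == min(a)])  # lexicographic tie-break
    data.frame(source = i, target = cand[1], S = unname(s[cand[1]]),
               abs_S = unname(a[cand[1]]))
  })
  edges <- do.call(rbind, edges)
  key <- paste(edges$source, edges$target)
  rev_key <- paste(edges$target, edges$source)
  edges$mutual <- key %in% rev_key
  indeg <- table(factor(edges$target, levels = chroms))
  structure(list(edges = edges,
                 in_degree = stats::setNames(as.integer(indeg), chroms)),
            class = "least_epistasis_network")
}

#' @export
print.least_epistasis_network <- function(x, ...) {
  cat(sprintf("least_epistasis_network: %d nodes, %d edges (%d mutual)\n",
              length(x$in_degree), nrow(x$edges), sum(x$edges$mutual)))
  invisible(x)
}

#' Top network hubs by in-degree
#'
#' Chromosomes most often chosen as the "most neutral" partner. Ordering is
#' stable: in-degree descending, then chromosome id.
#'
#' @param net a [least_epistasis_network()].
#' @param k number of hubs to return.
#' @return Character vector of chromosome ids, named by in-degree.
#' @export
network_hubs <- function(net, k = 2L) {
  d <- net$in_degree
  ord <- order(-d, names(d))
  top <- d[ord][seq_len(min(k, length(d)))]
  stats::setNames(names(top), top)
}

#' Write a least-epistasis network as DOT or TSV edge list
#'
#' @param net a [least_epistasis_network()].
#' @param path output file.
#' @param format `"dot"` (Graphviz digraph) or `"tsv"` (columns source,
#'   target, S, abs_S).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("dot", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges[, c("source", "target", "S", "abs_S")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    quote_id <- function(x) ifelse(grepl("^[A-Za-z_][A-Za-z0-9_]*$", x),
                                   x, sprintf("\"%s\"", x))
    lines <- c("digraph least_epistasis {",
               sprintf("  %s -> %s [label=\"%.4g\"];",
                       quote_id(net$edges$source), quote_id(net$edges$target),
                       net$edges$S),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
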