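# Per-chromosome aneuploidy frequency over a strain panel and its
# correlation with chromosome size.

#' Strains aneuploid for at least one chromosome
#'
#' @param matrix a [copy_number_matrix()].
#' @return Character vector of strain ids with at least one non-missing
#'   chromosome copy number different from the strain's baseline ploidy.
#' @export
detect_aneuploid_strains <- function(matrix) {
  dev <- sweep(matrix$copies, 1, matrix$baseline_ploidy, `!=`)
  matrix$strains[apply(dev, 1, function(x) any(x, na.rm = TRUE))]
}

#' Per-chromosome aneuploidy frequency
#'
#' Within the subset of aneuploid strains (those deviating from baseline on
#' at least one chromosome), counts for each chromosome the strains with an
#' abnormal copy number -- independently of whether it is a gain or a loss --
#' and the strains with the normal (baseline) copy number. The frequency
#' statistic is, by default, the ratio
#' `f = n_abnormal / n_normal`: an abnormal:normal odds, which can exceed 1
#' and is undefined (`NA`, flagged) when no aneuploid strain is normal for
#' the chromosome. Missing cells are excluded from both counts.
#'
#' @param matrix a [copy_number_matrix()].
#' @param denominator `"normal"` (default: strains with baseline copy
#'   number, the odds form), `"aneuploid"` (number of aneuploid strains with
#'   a call for the chromosome), or `"all"` (all strains in the panel with a
#'   call for the chromosome).
#' @return data.frame of class `aneuploidy_frequencies`: `chrom`,
#'   `n_abnormal`, `n_normal`, `f`, `undefined`; attributes
#'   `aneuploid_strains` and `denominator`.
#' @examples
#' m <- copy_number_matrix(matrix(
#'   c(3, 2, 2,  2, 2, 1,  3, 2, 2,  2, 2, 2), nrow = 4, byrow = TRUE,
#'   dimnames = list(paste0("S", 1:4), c("A", "B", "C"))),
#'   baseline_ploidy = 2)
#' aneuploidy_frequency(m)$f  # 2.0, 0.0, 0.5
#' @export
aneuploidy_frequency <- function(matrix,
                                 denominator = c("normal", "aneuploid", "all")) {
  denominator <- match.arg(denominator)
  aneu <- detect_aneuploid_strains(matrix)
  if (length(aneu) == 0) {
    stopf("no aneuploid strains in the panel; the frequency statistic is undefined")
  }
  sub <- matrix$copies[aneu, , drop = FALSE]
  base <- matrix$baseline_ploidy[aneu]
  abnormal <- sweep(sub, 1, base, `!=`)
  n_abnormal <- colSums(abnormal, na.rm = TRUE)
  n_normal <- colSums(!abnormal, na.rm = TRUE)
  denom <- switch(denominator,
                  normal = n_normal,
                  aneuploid = colSums(!is.na(sub)),
                  all = colSums(!is.na(matrix$copies)))
  f <- ifelse(denom > 0, n_abnormal / denom, NA_real_)
  out <- data.frame(chrom = matrix$chromosomes,
                    n_abnormal = as.integer(n_abnormal),
                    n_normal = as.integer(n_normal),
                    f = f, undefined = denom == 0)
  attr(out, "aneuploid_strains") <- aneu
  attr(out, "denominator") <- denominator
  class(out) <- c("aneuploidy_frequencies", "data.frame")
  out
}

#' Correlation between chromosome size and aneuploidy frequency
#'
#' Pearson correlation of chromosome length against the aneuploidy frequency
#' f, with the two-sided p-value from the t distribution on n-2 degrees of
#' freedom. Chromosomes with undefined f are excluded.
#'
#' @param freqs an [aneuploidy_frequency()] result.
#' @param map a [genome_map()] providing chromosome lengths.
#' @return List of class `correlation_result` with `r`, `p_value`, `n`.
#' @export
size_frequency_correlation <- function(freqs, map) {
  lens <- chromosome_lengths(map)
  keep <- !is.na(freqs$f) & freqs$chrom %in% names(lens)
  x <- lens[freqs$chrom[keep]]
  y <- freqs$f[keep]
  if (length(y) < 3) stopf("need >= 3 chromosomes with defined f")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined: constant size or constant frequency")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(y)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, P = %.3g (n = %d chromosomes)\n",
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Write an aneuploidy-frequency table as TSV
#' @param freqs an [aneuploidy_frequency()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_aneuploidy_table <- function(freqs, path) {
  utils::write.table(as.data.frame(freqs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
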