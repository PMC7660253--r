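# Depth profiles -> per-chromosome coverage summaries, expected-coverage
# baselines, and population-frequency (phi) estimates. In a mixed population
# where only a fraction phi of cells carries a chromosome, its mean depth is
# phi * expected-per-copy, so phi_hat = observed / expected.

#' Per-chromosome coverage summary
#'
#' Length-weighted mean and median window depth per chromosome. Chromosomes
#' of the map with no depth windows are reported with `n_windows = 0`, `NA`
#' summaries, and a warning, never dropped.
#'
#' @param depth a [depth_profile()].
#' @param map a [genome_map()]; depth chromosomes must be a subset of the
#'   map's, and windows must lie within chromosome bounds.
#' @return data.frame of class `coverage_summary`: one row per map
#'   chromosome with `chrom`, `mean_depth`, `median_depth`, `n_windows`.
#' @export
chromosome_depth_summary <- function(depth, map) {
  lens <- chromosome_lengths(map)
  unknown <- setdiff(unique(depth$chrom), names(lens))
  if (length(unknown) > 0) {
    stopf("depth profile cites chromosome '%s' absent from the genome map",
          unknown[1])
  }
  beyond <- depth$end > lens[depth$chrom]
  if (any(beyond)) {
    stopf("window [%d,%d) extends beyond chromosome '%s' (length %d)",
          depth$start[which(beyond)[1]], depth$end[which(beyond)[1]],
          depth$chrom[which(beyond)[1]], lens[[depth$chrom[which(beyond)[1]]]])
  }
  out <- data.frame(chrom = names(lens), mean_depth = NA_real_,
                    median_depth = NA_real_, n_windows = 0L)
  for (k in seq_along(lens)) {
    w <- depth[depth$chrom == names(lens)[k], ]
    if (nrow(w) == 0) next
    width <- w$end - w$start
    out$mean_depth[k] <- sum(w$depth * width) / sum(width)
    out$median_depth[k] <- stats::median(w$depth)
    out$n_windows[k] <- nrow(w)
  }
  if (any(out$n_windows == 0)) {
    warnf("no depth windows for chromosome(s): %s",
          paste(out$chrom[out$n_windows == 0], collapse = ", "))
  }
  class(out) <- c("coverage_summary", "data.frame")
  out
}

#' Expected coverage per haploid sub-genome copy
#'
#' Sequencing `read_pairs` paired-end reads of `read_length` bp yields
#' `read_pairs * 2 * read_length` bases; spread over a model genome made of
#' one haploid copy of each sub-genome, the expected mean coverage per
#' haploid copy is total bases divided by the summed sub-genome sizes. For a
#' paired-end library of 116,062,916 pairs of 100 bp reads over a ~36 Mb
#' triploid model genome this gives ~645x per haploid sub-genome copy.
#'
#' @param read_pairs number of read pairs (raw, pre-filter).
#' @param read_length read length in bp.
#' @param subgenome_sizes bp sizes of each haploid sub-genome copy in the
#'   model genome.
#' @return List of class `expected_coverage` with `expected_per_copy`,
#'   `total_bases`, `model_genome_size`.
#' @examples
#' expected_subgenome_coverage(116062916, 100, rep(12e6, 3))$expected_per_copy
#' @export
expected_subgenome_coverage <- function(read_pairs, read_length, subgenome_sizes) {
  if (length(subgenome_sizes) == 0) stopf("empty sub-genome size list")
  if (read_pairs <= 0 || read_length <= 0 || any(subgenome_sizes <= 0)) {
    stopf("read counts, read length and sizes must be positive")
  }
  total_bases <- read_pairs * 2 * read_length
  model_genome_size <- sum(subgenome_sizes)
  structure(list(expected_per_copy = total_bases / model_genome_size,
                 total_bases = total_bases,
                 model_genome_size = model_genome_size),
            class = "expected_coverage")
}

#' @export
print.expected_coverage <- function(x, ...) {
  cat(sprintf("expected coverage: %.1fx per haploid copy (%.3g bases / %.3g bp model genome)\n",
              x$expected_per_copy, x$total_bases, x$model_genome_size))
  invisible(x)
}

#' Estimate per-chromosome population frequencies from coverage
#'
#' For each chromosome, `phi_hat = mean_depth / expected_per_copy`: the
#' fraction of cells in the sequenced population carrying the chromosome
#' (times its copy number in carriers). `phi_hat` is reported unclipped,
#' with a clipped companion in `[0, max_copies]`. States: `lost` when
#' `phi_hat < lost_below`, `present` when `phi_hat > present_above`,
#' `low_frequency` between, `no_data` for chromosomes without windows.
#' When the window-level `depth` profile is supplied, a nonparametric
#' bootstrap over windows (seeded) gives a percentile confidence interval.
#'
#' @param summary a [chromosome_depth_summary()] result.
#' @param expected an [expected_subgenome_coverage()] result (or any list
#'   with `expected_per_copy > 0`).
#' @param thresholds named vector `c(lost_below=, present_above=)` on the
#'   phi scale.
#' @param depth optional [depth_profile()] for the bootstrap CI.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @param max_copies upper bound of the clipped estimate.
#' @return data.frame of class `chromosome_frequency`: `chrom`, `phi_hat`,
#'   `phi_hat_clipped`, `ci_low`, `ci_high`, `state`, plus attribute `seed`.
#' @export
estimate_chromosome_frequency <- function(summary, expected,
                                          thresholds = c(lost_below = 0.002,
                                                         present_above = 0.5),
                                          depth = NULL, n_boot = 1000L,
                                          seed = 1L, conf = 0.95,
                                          max_copies = 4) {
  epc <- expected$expected_per_copy
  if (is.null(epc) || epc <= 0) stopf("expected_per_copy must be > 0")
  lost_below <- thresholds[["lost_below"]]
  present_above <- thresholds[["present_above"]]
  phi_hat <- summary$mean_depth / epc
  state <- ifelse(summary$n_windows == 0, "no_data",
           ifelse(phi_hat < lost_below, "lost",
           ifelse(phi_hat > present_above, "present", "low_frequency")))
  out <- data.frame(chrom = summary$chrom, phi_hat = phi_hat,
                    phi_hat_clipped = pmin(pmax(phi_hat, 0), max_copies),
                    ci_low = NA_real_, ci_high = NA_real_, state = state)
  if (!is.null(depth)) {
    alpha <- (1 - conf) / 2
    with_seed(seed, {
      for (k in seq_len(nrow(out))) {
        w <- depth[depth$chrom == out$chrom[k], ]
        if (nrow(w) == 0) next
        width <- w$end - w$start
        reps <- vapply(seq_len(n_boot), function(r) {
          i <- sample.int(nrow(w), nrow(w), replace = TRUE)
          sum(w$depth[i] * width[i]) / sum(width[i])
        }, numeric(1))
        ci <- stats::quantile(reps / epc, c(alpha, 1 - alpha), names = FALSE)
        out$ci_low[k] <- ci[1]
        out$ci_high[k] <- ci[2]
      }
    })
  }
  attr(out, "seed") <- seed
  class(out) <- c("chromosome_frequency", "data.frame")
  out
}

#' Write a coverage/frequency table as TSV
#'
#' Joins a coverage summary and a frequency estimate into the standard
#' output table (chrom, mean, median, n_windows, phi_hat, ci_low, ci_high,
#' state).
#'
#' @param summary a [chromosome_depth_summary()] result.
#' @param freq an [estimate_chromosome_frequency()] result.
#' @param path output file.
#' @return The merged data.frame, invisibly.
#' @export
write_coverage_table <- function(summary, freq, path) {
  stopifnot(identical(summary$chrom, freq$chrom))
  df <- data.frame(chrom = summary$chrom, mean_depth = summary$mean_depth,
                   median_depth = summary$median_depth,
                   n_windows = summary$n_windows, phi_hat = freq$phi_hat,
                   ci_low = freq$ci_low, ci_high = freq$ci_high,
                   state = freq$state)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
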