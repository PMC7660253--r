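# Seeded generators for every pipeline input, each with planted, recoverable
# structure. All generators are pure functions of (arguments, config$seed):
# fixed seed gives identical output across runs; the caller's RNG stream is
# left untouched.

# Reference-like chromosome lengths (bp) for a 16-chromosome budding-yeast
# nuclear genome, ~12.07 Mb total; used as the default simulated karyotype.
YEAST_CHROM_LENGTHS <- c(
  chrI = 230218L, chrII = 813184L, chrIII = 316620L, chrIV = 1531933L,
  chrV = 576874L, chrVI = 270161L, chrVII = 1090940L, chrVIII = 562643L,
  chrIX = 439888L, chrX = 745751L, chrXI = 666816L, chrXII = 1078177L,
  chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults emulate
#' the study conditions of a large natural-isolate panel on a budding-yeast
#' karyotype: 16 chromosomes with reference-like lengths, ~50 genes per
#' 100 kb (~6000 genes), 1011 diploid strains, a per-chromosome aneuploidy
#' probability inversely proportional to chromosome length with mean 0.015
#' (so roughly a fifth of strains carry at least one aneuploidy), gains twice
#' as likely as losses, Poisson sequencing depth at 100x per haploid copy.
#'
#' @param seed integer master seed; every generator derives its stream from it.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_lengths bp lengths (named or not); `NULL` uses the
#'   reference-like yeast lengths when `n_chromosomes == 16`, otherwise an
#'   even spread between 230 kb and 1.53 Mb.
#' @param genes_per_100kb expected gene density (genes per 100 kb).
#' @param n_strains number of strains in the copy-number panel.
#' @param baseline_ploidies per-strain baseline ploidy (recycled).
#' @param aneuploidy_prob per-chromosome probability that a strain deviates
#'   from baseline there; scalar, per-chromosome vector, or `NULL` for the
#'   inverse-length default with mean `mean_aneuploidy_prob`.
#' @param mean_aneuploidy_prob mean of the inverse-length default.
#' @param gain_loss_odds odds of a gain versus a loss given an aneuploidy.
#' @param interaction_rate expected interaction pairs per gene.
#' @param score_mu mean interaction score: scalar, or a symmetric
#'   chromosome x chromosome matrix of planted block means.
#' @param score_sigma standard deviation of interaction scores.
#' @param expression_base_prob baseline probability a gene is up-regulated.
#' @param planted_enriched_chromosomes named list mapping condition to the
#'   chromosomes whose up-regulation probability is multiplied by
#'   `enrichment_factor` (clipped to 1).
#' @param enrichment_factor multiplier for planted chromosomes.
#' @param conditions stress condition labels.
#' @param complex_member_prob probability a gene belongs to some protein
#'   complex (complexes are assembled from the member genes in blocks of
#'   2-10).
#' @param depth_lambda expected fold coverage per haploid chromosome copy.
#' @param depth_copies copies of the focal sub-genome per cell (1 = haploid
#'   sub-genome of a hybrid).
#' @param phi per-chromosome population frequency in `[0,1]` (scalar or
#'   vector): fraction of cells in the population carrying the chromosome.
#' @param overdispersion gamma-mixing variance for depth; 0 = pure Poisson.
#' @param window_size depth window width in bp.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 16L,
                              chromosome_lengths = NULL,
                              genes_per_100kb = 50,
                              n_strains = 1011L,
                              baseline_ploidies = 2L,
                              aneuploidy_prob = NULL,
                              mean_aneuploidy_prob = 0.015,
                              gain_loss_odds = 2,
                              interaction_rate = 2,
                              score_mu = 0,
                              score_sigma = 0.1,
                              expression_base_prob = 0.1,
                              planted_enriched_chromosomes = list(),
                              enrichment_factor = 3,
                              conditions = c("GLY", "LAC", "ETOH", "OXD"),
                              complex_member_prob = 0.27,
                              depth_lambda = 100,
                              depth_copies = 1,
                              phi = 1,
                              overdispersion = 0,
                              window_size = 1000L) {
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- if (n_chromosomes == 16L) {
      YEAST_CHROM_LENGTHS
    } else {
      round(seq(230218, 1531933, length.out = n_chromosomes))
    }
  }
  if (length(chromosome_lengths) != n_chromosomes) {
    stopf("chromosome_lengths must have length n_chromosomes")
  }
  if (any(chromosome_lengths <= 0)) stopf("chromosome lengths must be > 0")
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- sprintf("chr%02d", seq_len(n_chromosomes))
  }
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_lengths = chromosome_lengths,
              genes_per_100kb = genes_per_100kb,
              n_strains = as.integer(n_strains),
              baseline_ploidies = as.integer(baseline_ploidies),
              aneuploidy_prob = aneuploidy_prob,
              mean_aneuploidy_prob = mean_aneuploidy_prob,
              gain_loss_odds = gain_loss_odds,
              interaction_rate = interaction_rate,
              score_mu = score_mu, score_sigma = score_sigma,
              expression_base_prob = expression_base_prob,
              planted_enriched_chromosomes = planted_enriched_chromosomes,
              enrichment_factor = enrichment_factor,
              conditions = conditions,
              complex_member_prob = complex_member_prob,
              depth_lambda = depth_lambda, depth_copies = depth_copies,
              phi = phi, overdispersion = overdispersion,
              window_size = as.integer(window_size))
  probs <- c(cfg$mean_aneuploidy_prob, cfg$expression_base_prob,
             cfg$complex_member_prob, cfg$aneuploidy_prob, cfg$phi)
  if (any(probs < 0 | probs > 1)) stopf("probabilities and phi must lie in [0, 1]")
  if (cfg$genes_per_100kb < 0 || cfg$interaction_rate < 0 ||
      cfg$depth_lambda < 0 || cfg$overdispersion < 0) {
    stopf("rates must be non-negative")
  }
  if (any(cfg$baseline_ploidies < 1)) stopf("baseline ploidy must be >= 1")
  structure(cfg, class = "simulation_config")
}

# Resolve a scalar / named / positional per-chromosome parameter.
per_chromosome <- function(x, chroms, what) {
  if (is.null(x)) stopf("%s is NULL", what)
  if (length(x) == 1L) return(stats::setNames(rep(x, length(chroms)), chroms))
  if (!is.null(names(x))) {
    missing <- setdiff(chroms, names(x))
    if (length(missing) > 0) stopf("%s lacks chromosome '%s'", what, missing[1])
    return(x[chroms])
  }
  if (length(x) != length(chroms)) {
    stopf("%s must be scalar or one value per chromosome", what)
  }
  stats::setNames(x, chroms)
}

# Default per-chromosome aneuploidy probability: inversely proportional to
# chromosome length, scaled so the mean over chromosomes is `mean_prob`.
default_aneuploidy_prob <- function(lengths, mean_prob) {
  p <- 1 / lengths
  p <- p * mean_prob / mean(p)
  pmin(p, 1)
}

#' Simulate a genome map
#'
#' Gene counts per chromosome are Poisson with mean
#' `length * genes_per_100kb / 1e5`; gene bodies are 300-3000 bp at uniform
#' random starts (overlaps allowed), strands uniform.
#'
#' @param config a [simulation_config()].
#' @return A [genome_map()]; deterministic for a fixed seed.
#' @export
simulate_genome_map <- function(config) {
  lens <- config$chromosome_lengths
  with_seed(derive_seed(config$seed, 1L), {
    genes <- lapply(names(lens), function(ch) {
      len <- lens[[ch]]
      n <- stats::rpois(1, len * config$genes_per_100kb / 1e5)
      if (n == 0) return(NULL)
      size <- sample(300:3000, n, replace = TRUE)
      size <- pmin(size, len)
      start <- vapply(size, function(s) sample.int(len - s + 1L, 1L), 1L)
      data.frame(gene = sprintf("%s_g%04d", sub("^chr", "", ch), seq_len(n)),
                 chrom = ch, start = start, end = start + size - 1L,
                 strand = sample(c("+", "-"), n, replace = TRUE))
    })
    genes <- do.call(rbind, genes)
    if (is.null(genes)) {
      genes <- data.frame(gene = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
    }
    genome_map(data.frame(chrom = names(lens), length = unname(lens)), genes)
  })
}

#' Simulate a strain x chromosome copy-number matrix
#'
#' Each strain-chromosome cell deviates from the strain's baseline ploidy
#' with its chromosome's aneuploidy probability; given a deviation, a gain
#' (+1 copy) has odds `gain_loss_odds : 1` over a loss (-1 copy, floored at
#' zero copies).
#'
#' @param map a [genome_map()].
#' @param config a [simulation_config()].
#' @return A [copy_number_matrix()].
#' @export
simulate_copy_number_matrix <- function(map, config) {
  chroms <- map$chromosomes$chrom
  p <- config$aneuploidy_prob
  if (is.null(p)) {
    p <- default_aneuploidy_prob(chromosome_lengths(map),
                                 config$mean_aneuploidy_prob)
  }
  p <- per_chromosome(p, chroms, "aneuploidy_prob")
  n <- config$n_strains
  base <- rep_len(config$baseline_ploidies, n)
  p_gain <- config$gain_loss_odds / (config$gain_loss_odds + 1)
  with_seed(derive_seed(config$seed, 2L), {
    hit <- matrix(stats::runif(n * length(chroms)) <
                    matrix(p, n, length(chroms), byrow = TRUE),
                  n, length(chroms))
    gain <- matrix(stats::runif(n * length(chroms)) < p_gain, n, length(chroms))
    delta <- ifelse(hit, ifelse(gain, 1L, -1L), 0L)
    copies <- pmax(matrix(base, n, length(chroms)) + delta, 0L)
    dimnames(copies) <- list(sprintf("S%04d", seq_len(n)), chroms)
    copy_number_matrix(copies, baseline_ploidy = base)
  })
}

#' Simulate a gene-gene interaction table
#'
#' The number of pairs is Poisson with mean `interaction_rate * n_genes`;
#' gene pairs are drawn uniformly over distinct genes. For genetic tables,
#' scores are Normal with mean taken from `score_mu` -- a scalar, or a
#' symmetric chromosome x chromosome matrix of planted block means -- and sd
#' `score_sigma`. Physical tables carry no scores.
#'
#' @param map a [genome_map()].
#' @param config a [simulation_config()].
#' @param kind `"genetic"` or `"physical"`.
#' @return An [interaction_table()] (self-pairs and duplicates already
#'   collapsed by the constructor).
#' @export
simulate_interaction_table <- function(map, config,
                                       kind = c("genetic", "physical")) {
  kind <- match.arg(kind)
  genes <- map$genes
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score = numeric())
  if (nrow(genes) < 2 || config$interaction_rate == 0) {
    return(suppressMessages(interaction_table(empty, kind)))
  }
  with_seed(derive_seed(config$seed, 3L), {
    n_pairs <- stats::rpois(1, config$interaction_rate * nrow(genes))
    rows <- if (n_pairs == 0) {
      empty
    } else {
      i <- sample.int(nrow(genes), n_pairs, replace = TRUE)
      j <- sample.int(nrow(genes), n_pairs, replace = TRUE)
      keep <- i != j
      i <- i[keep]; j <- j[keep]
      df <- data.frame(gene_a = genes$gene[i], gene_b = genes$gene[j])
      if (kind == "genetic") {
        mu <- config$score_mu
        df$score <- if (is.matrix(mu)) {
          stats::rnorm(length(i),
                       mean = mu[cbind(genes$chrom[i], genes$chrom[j])],
                       sd = config$score_sigma)
        } else {
          stats::rnorm(length(i), mean = mu, sd = config$score_sigma)
        }
      }
      df
    }
    suppressMessages(interaction_table(rows, kind))
  })
}

#' Simulate binary stress up-regulation flags
#'
#' Each gene is flagged 1 with probability `expression_base_prob`, multiplied
#' by `enrichment_factor` (clipped to 1) on chromosomes planted for the
#' condition in `planted_enriched_chromosomes`.
#'
#' @param map a [genome_map()].
#' @param config a [simulation_config()].
#' @return An [expression_flags()] with one row per gene x condition.
#' @export
simulate_expression_flags <- function(map, config) {
  genes <- map$genes
  with_seed(derive_seed(config$seed, 4L), {
    rows <- lapply(config$conditions, function(cond) {
      p <- rep(config$expression_base_prob, nrow(genes))
      planted <- config$planted_enriched_chromosomes[[cond]]
      if (!is.null(planted)) {
        p[genes$chrom %in% planted] <- pmin(
          config$expression_base_prob * config$enrichment_factor, 1)
      }
      data.frame(gene = genes$gene, condition = cond,
                 flag = stats::rbinom(nrow(genes), 1, p))
    })
    expression_flags(do.call(rbind, rows), conditions = config$conditions)
  })
}

#' Simulate a protein-complex membership table
#'
#' Each gene joins the complex pool with probability `complex_member_prob`;
#' member genes are then grouped into complexes of 2-10 (a trailing group
#' may be smaller).
#'
#' @param map a [genome_map()].
#' @param config a [simulation_config()].
#' @return A [complex_membership()].
#' @export
simulate_complex_membership <- function(map, config) {
  genes <- map$genes$gene
  with_seed(derive_seed(config$seed, 6L), {
    member <- genes[stats::runif(length(genes)) < config$complex_member_prob]
    rows <- if (length(member) < 2) {
      data.frame(gene = character(), complex = character())
    } else {
      member <- sample(member)
      sizes <- integer()
      while (sum(sizes) < length(member)) {
        sizes <- c(sizes, sample(2:10, 1))
      }
      cid <- rep(sprintf("CPX%04d", seq_along(sizes)), times = sizes)
      data.frame(gene = member, complex = cid[seq_along(member)])
    }
    complex_membership(rows)
  })
}

#' Simulate a windowed depth profile from a mixed population
#'
#' Emulates sequencing a population in which each chromosome of the focal
#' sub-genome is carried by a fraction `phi` of cells. The effective copy
#' number is `depth_copies * phi`, so a window of width w gets
#' `Poisson(depth_lambda * depth_copies * phi * w) / w` fold coverage; with
#' `overdispersion` d > 0 the Poisson mean is gamma-mixed (shape 1/d,
#' scale d), giving a negative-binomial-like marginal.
#'
#' @param map a [genome_map()].
#' @param config a [simulation_config()].
#' @return A [depth_profile()] tiling every chromosome with
#'   `window_size`-bp windows (last window may be short).
#' @export
simulate_depth <- function(map, config) {
  lens <- chromosome_lengths(map)
  phi <- per_chromosome(config$phi, names(lens), "phi")
  with_seed(derive_seed(config$seed, 5L), {
    out <- lapply(names(lens), function(ch) {
      len <- lens[[ch]]
      starts <- seq.int(0L, len - 1L, by = config$window_size)
      ends <- pmin(starts + config$window_size, len)
      w <- ends - starts
      mu <- config$depth_lambda * config$depth_copies * phi[[ch]] * w
      if (config$overdispersion > 0) {
        mu <- mu * stats::rgamma(length(w), shape = 1 / config$overdispersion,
                                 scale = config$overdispersion)
      }
      data.frame(chrom = ch, start = starts, end = ends,
                 depth = stats::rpois(length(w), mu) / w)
    })
    depth_profile(do.call(rbind, out))
  })
}

#' Write a full set of synthetic fixtures to a directory
#'
#' Generates every pipeline input from one config and writes them in the
#' package's TSV dialects plus a `manifest.yaml` recording the seed and
#' parameters.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
simulate_all <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- simulate_genome_map(config)
  paths <- c(
    genome = write_genome_map(map, file.path(dir, "genome_map.tsv")),
    copies = write_copy_number_matrix(simulate_copy_number_matrix(map, config),
                                      file.path(dir, "copy_number.tsv")),
    gi = write_interaction_table(simulate_interaction_table(map, config, "genetic"),
                                 file.path(dir, "genetic_interactions.tsv")),
    pi = write_interaction_table(simulate_interaction_table(map, config, "physical"),
                                 file.path(dir, "physical_interactions.tsv")),
    expr = write_expression_flags(simulate_expression_flags(map, config),
                                  file.path(dir, "expression_flags.tsv")),
    complexes = write_complex_membership(simulate_complex_membership(map, config),
                                         file.path(dir, "complexes.tsv")),
    depth = write_depth_bed(simulate_depth(map, config),
                            file.path(dir, "depth_windows.bed")))
  manifest <- config
  attributes(manifest) <- list(names = names(config))
  manifest$chromosome_lengths <- as.list(manifest$chromosome_lengths)
  manifest$score_mu <- if (is.matrix(config$score_mu)) "matrix" else config$score_mu
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  paths <- c(paths, manifest = file.path(dir, "manifest.yaml"))
  invisible(paths)
}
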