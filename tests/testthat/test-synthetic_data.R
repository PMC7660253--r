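test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(seed = 7, genes_per_100kb = 5, n_strains = 30,
                           window_size = 100000)
  map <- simulate_genome_map(cfg)
  expect_identical(simulate_genome_map(cfg), map)
  expect_identical(simulate_copy_number_matrix(map, cfg),
                   simulate_copy_number_matrix(map, cfg))
  expect_identical(simulate_interaction_table(map, cfg, "genetic"),
                   simulate_interaction_table(map, cfg, "genetic"))
  expect_identical(simulate_expression_flags(map, cfg),
                   simulate_expression_flags(map, cfg))
  expect_identical(simulate_complex_membership(map, cfg),
                   simulate_complex_membership(map, cfg))
  expect_identical(simulate_depth(map, cfg), simulate_depth(map, cfg))

  # and they leave the caller's RNG stream untouched
  set.seed(123)
  x1 <- stats::runif(1)
  set.seed(123)
  invisible(simulate_genome_map(cfg))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("gene counts follow the configured density", {
  cfg0 <- simulation_config(seed = 2, genes_per_100kb = 0)
  expect_equal(nrow(simulate_genome_map(cfg0)$genes), 0)

  # 2 chromosomes x 100 kb at 50 genes/100kb: Poisson(100) total
  cfg <- simulation_config(seed = 3, n_chromosomes = 2,
                           chromosome_lengths = c(a = 100000, b = 100000),
                           genes_per_100kb = 50)
  n <- nrow(simulate_genome_map(cfg)$genes)
  expect_gt(n, 100 - 4 * sqrt(100))
  expect_lt(n, 100 + 4 * sqrt(100))
})

test_that("copy-number simulation plants recoverable aneuploidy structure", {
  cfg0 <- simulation_config(seed = 5, aneuploidy_prob = 0, n_strains = 50,
                            genes_per_100kb = 1)
  map <- simulate_genome_map(cfg0)
  cn <- simulate_copy_number_matrix(map, cfg0)
  expect_true(all(cn$copies == cn$baseline_ploidy))

  # inverse-length probabilities: recovered f correlates negatively with size
  cfg <- simulation_config(seed = 11, n_strains = 1000, genes_per_100kb = 1,
                           aneuploidy_prob = NULL, mean_aneuploidy_prob = 0.05)
  cn <- simulate_copy_number_matrix(map, cfg)
  f <- aneuploidy_frequency(cn)
  r <- stats::cor(chromosome_lengths(map)[f$chrom], f$f)
  expect_lt(r, -0.5)

  # prob 1 for one chromosome: every strain abnormal there, denominator 0
  p <- stats::setNames(rep(0.05, 16), names(chromosome_lengths(map)))
  p["chrI"] <- 1
  cfg1 <- simulation_config(seed = 5, n_strains = 50, aneuploidy_prob = p)
  cn1 <- simulate_copy_number_matrix(map, cfg1)
  f1 <- aneuploidy_frequency(cn1)
  expect_true(f1$undefined[f1$chrom == "chrI"])
  expect_true(is.na(f1$f[f1$chrom == "chrI"]))
})

test_that("gains are twice as likely as losses by default", {
  cfg <- simulation_config(seed = 19, n_strains = 3000, aneuploidy_prob = 0.2,
                           genes_per_100kb = 1)
  map <- simulate_genome_map(cfg)
  cn <- simulate_copy_number_matrix(map, cfg)
  dev <- sweep(cn$copies, 1, cn$baseline_ploidy, `-`)
  odds <- sum(dev > 0) / sum(dev < 0)
  expect_gt(odds, 1.8)
  expect_lt(odds, 2.2)
})

test_that("interaction simulation plants recoverable chromosome-pair blocks", {
  cfg <- simulation_config(seed = 5, n_chromosomes = 3,
                           chromosome_lengths = c(chrA = 1e5, chrB = 1e5, chrC = 1e5),
                           genes_per_100kb = 100, interaction_rate = 5,
                           score_sigma = 0.1)
  map <- simulate_genome_map(cfg)
  chroms <- map$chromosomes$chrom
  mu <- matrix(0, 3, 3, dimnames = list(chroms, chroms))
  mu["chrA", "chrB"] <- mu["chrB", "chrA"] <- 0.5
  cfg$score_mu <- mu
  gi <- simulate_interaction_table(map, cfg, "genetic")
  S <- suppressMessages(pairwise_interaction_sums(gi, map))
  # planted block: S(A,B) positive with margin >= 3 SE of the pair sum
  se <- sqrt(nrow(gi)) * cfg$score_sigma  # conservative upper bound
  expect_gt(S["chrA", "chrB"], 3 * se)
  expect_lt(abs(S["chrA", "chrC"]), S["chrA", "chrB"])

  # null calibration: with mu = 0 everywhere the sums are centred on zero
  sums <- vapply(1:100, function(s) {
    cfg$score_mu <- 0
    cfg$seed <- s
    g <- simulate_interaction_table(map, cfg, "genetic")
    suppressMessages(pairwise_interaction_sums(g, map))["chrA", "chrB"]
  }, numeric(1))
  expect_lt(abs(mean(sums)), 3 * stats::sd(sums) / sqrt(length(sums)))

  cfg$interaction_rate <- 0
  expect_equal(nrow(simulate_interaction_table(map, cfg, "genetic")), 0)
})

test_that("expression flags respect base probability extremes", {
  cfg <- simulation_config(seed = 2, genes_per_100kb = 5,
                           expression_base_prob = 0)
  map <- simulate_genome_map(cfg)
  expect_true(all(simulate_expression_flags(map, cfg)$flag == 0))
  cfg$expression_base_prob <- 1
  expect_true(all(simulate_expression_flags(map, cfg)$flag == 1))
})

test_that("depth simulation matches its population-frequency model", {
  cfg <- simulation_config(seed = 4, n_chromosomes = 2,
                           chromosome_lengths = c(chrJ = 5e5, chrK = 5e5),
                           genes_per_100kb = 1, depth_lambda = 50,
                           phi = c(chrJ = 1, chrK = 0), window_size = 1000)
  map <- simulate_genome_map(cfg)
  dp <- simulate_depth(map, cfg)
  cs <- chromosome_depth_summary(dp, map)
  expect_lt(abs(cs$mean_depth[cs$chrom == "chrJ"] - 50) / 50, 0.02)
  expect_equal(cs$mean_depth[cs$chrom == "chrK"], 0)

  # phi = 0.5 at lambda = 100 over 1000 windows recovers 0.5 +/- 0.03
  cfg2 <- simulation_config(seed = 9, n_chromosomes = 1,
                            chromosome_lengths = c(chrM = 1e6),
                            genes_per_100kb = 1, depth_lambda = 100,
                            phi = 0.5, window_size = 1000)
  map2 <- simulate_genome_map(cfg2)
  dp2 <- simulate_depth(map2, cfg2)
  est <- estimate_chromosome_frequency(
    chromosome_depth_summary(dp2, map2), list(expected_per_copy = 100))
  expect_lt(abs(est$phi_hat - 0.5), 0.03)

  # overdispersion inflates window variance beyond Poisson
  cfg_od <- cfg2
  cfg_od$overdispersion <- 0.5
  dp_od <- simulate_depth(map2, cfg_od)
  expect_gt(stats::var(dp_od$depth), 2 * stats::var(dp2$depth))
})
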