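# End-to-end orchestration: simulate (optional) -> coverage -> aneuploidy ->
# enrich -> episnet, from a single YAML-style config, with a markdown report
# and a machine-readable summary. Every output records the seed; re-running
# with the same config and seed reproduces every output byte-identically.

#' Validate and normalize a pipeline run configuration
#'
#' A run config is a named list (or a path to a YAML file). Recognized keys:
#'
#' * `seed` (integer, default 1), `outdir` (required), `quiet` (default FALSE)
#' * `stages`: character subset of `c("simulate", "coverage", "aneuploidy",
#'   "enrich", "episnet")`; default all.
#' * `simulate`: list of [simulation_config()] arguments (used when the
#'   simulate stage is on; its seed defaults to the run seed).
#' * `inputs`: paths `genome`, `copies`, `gi`, `pi`, `complexes`, `expr`,
#'   `depth` (windowed BED). Ignored for files produced by the simulate
#'   stage. Referenced files must exist at validation time.
#' * `coverage`: `read_pairs`, `read_length`, `subgenome_sizes` (bp vector),
#'   optional `thresholds` (`lost_below`, `present_above`), `n_boot`.
#' * `aneuploidy`: `denominator` (`normal`/`aneuploid`/`all`).
#' * `enrich`: `reps` (default 10000), `method` (`normal`/`empirical`).
#'
#' @param config named list or path to a YAML file.
#' @return Normalized config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  cfg <- list(
    seed = as.integer(config$seed %||% 1L),
    outdir = config$outdir %||% stopf("config needs an 'outdir'"),
    quiet = isTRUE(config$quiet),
    stages = config$stages %||% c("simulate", "coverage", "aneuploidy",
                                  "enrich", "episnet"),
    simulate = config$simulate %||% list(),
    inputs = config$inputs %||% list(),
    coverage = config$coverage %||% list(),
    aneuploidy = config$aneuploidy %||% list(),
    enrich = config$enrich %||% list())
  bad <- setdiff(cfg$stages, c("simulate", "coverage", "aneuploidy",
                               "enrich", "episnet"))
  if (length(bad) > 0) stopf("unknown stage '%s'", bad[1])
  for (key in names(cfg$inputs)) {
    path <- cfg$inputs[[key]]
    if (!is.null(path) && !file.exists(path)) {
      stopf("input file for '%s' not found: %s", key, path)
    }
  }
  if ("coverage" %in% cfg$stages) {
    cov <- cfg$coverage
    if (is.null(cov$read_pairs) || is.null(cov$read_length) ||
        is.null(cov$subgenome_sizes)) {
      stopf("coverage stage needs read_pairs, read_length and subgenome_sizes")
    }
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, stage, fmt, ...) {
  if (!cfg$quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(cfg, stage, fun) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(fun(), error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
  pipeline_log(cfg, stage, "done in %.2f s", proc.time()[["elapsed"]] - t0)
  result
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order -- simulate (optional), coverage,
#' aneuploidy, enrich, episnet -- writing each stage's tables under
#' `outdir`, then a `report.md` with the headline numbers and a
#' machine-readable `summary.json`. The report records the seed and the md5
#' checksum of every input consumed. A stage failure aborts with the stage
#' name and cause; outputs of completed stages are retained.
#'
#' @param config a [run_config()], a named list, or a YAML file path.
#' @return Invisibly, a list with the per-stage results and the paths of the
#'   report and summary.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- cfg$inputs
  results <- list()
  summary <- list(seed = cfg$seed, stages = cfg$stages)

  if ("simulate" %in% cfg$stages) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    sim_dir <- file.path(cfg$outdir, "simulated")
    paths <- run_stage(cfg, "simulate",
                       function() suppressMessages(simulate_all(sim_cfg, sim_dir)))
    pipeline_log(cfg, "simulate", "wrote fixtures to %s", sim_dir)
    for (key in c("genome", "copies", "gi", "pi", "expr", "complexes", "depth")) {
      inputs[[key]] <- inputs[[key]] %||% unname(paths[[key]])
    }
    results$simulate <- paths
  }
  if (is.null(inputs$genome)) stopf("no genome map: supply inputs$genome or enable simulate")
  map <- load_genome_map(inputs$genome)

  if ("coverage" %in% cfg$stages) {
    if (is.null(inputs$depth)) stopf("coverage stage needs inputs$depth")
    cov <- cfg$coverage
    results$coverage <- run_stage(cfg, "coverage", function() {
      depth <- load_depth_bed(inputs$depth)
      summ <- chromosome_depth_summary(depth, map)
      expected <- expected_subgenome_coverage(cov$read_pairs, cov$read_length,
                                              unlist(cov$subgenome_sizes))
      thresholds <- c(lost_below = cov$thresholds$lost_below %||% 0.002,
                      present_above = cov$thresholds$present_above %||% 0.5)
      freq <- estimate_chromosome_frequency(summ, expected,
                                            thresholds = thresholds,
                                            depth = depth,
                                            n_boot = cov$n_boot %||% 1000L,
                                            seed = cfg$seed)
      tab <- write_coverage_table(summ, freq,
                                  file.path(cfg$outdir, "coverage.tsv"))
      list(table = tab, expected = expected)
    })
    summary$expected_per_copy <- results$coverage$expected$expected_per_copy
    summary$phi_hat <- stats::setNames(as.list(results$coverage$table$phi_hat),
                                       results$coverage$table$chrom)
  }

  if ("aneuploidy" %in% cfg$stages) {
    if (is.null(inputs$copies)) stopf("aneuploidy stage needs inputs$copies")
    results$aneuploidy <- run_stage(cfg, "aneuploidy", function() {
      cn <- load_copy_number_matrix(inputs$copies)
      freqs <- aneuploidy_frequency(cn, denominator = cfg$aneuploidy$denominator
                                    %||% "normal")
      write_aneuploidy_table(freqs, file.path(cfg$outdir, "aneuploidy.tsv"))
      corr <- tryCatch(size_frequency_correlation(freqs, map),
                       error = function(e) NULL)
      list(freqs = freqs, correlation = corr,
           n_aneuploid = length(attr(freqs, "aneuploid_strains")))
    })
    summary$n_aneuploid_strains <- results$aneuploidy$n_aneuploid
    if (!is.null(results$aneuploidy$correlation)) {
      summary$size_frequency_r <- results$aneuploidy$correlation$r
      summary$size_frequency_p <- results$aneuploidy$correlation$p_value
    }
  }

  if ("enrich" %in% cfg$stages) {
    results$enrich <- run_stage(cfg, "enrich", function() {
      sources <- list()
      if (!is.null(inputs$gi)) sources$gi <- load_interaction_table(inputs$gi, "genetic")
      if (!is.null(inputs$pi)) sources$pi <- load_interaction_table(inputs$pi, "physical")
      if (!is.null(inputs$complexes)) sources$complexes <- load_complex_membership(inputs$complexes)
      if (!is.null(inputs$expr)) sources$expr <- load_expression_flags(inputs$expr)
      if (length(sources) == 0) stopf("enrich stage needs at least one source table")
      em <- suppressMessages(enrichment_matrix(
        map, sources, reps = cfg$enrich$reps %||% 10000L, seed = cfg$seed,
        method = cfg$enrich$method %||% "normal",
        aneuploidy_f = results$aneuploidy$freqs))
      write_enrichment_matrix(em, file.path(cfg$outdir, "enrichment"))
      em
    })
  }

  if ("episnet" %in% cfg$stages) {
    if (is.null(inputs$gi)) stopf("episnet stage needs inputs$gi")
    results$episnet <- run_stage(cfg, "episnet", function() {
      gi <- load_interaction_table(inputs$gi, "genetic")
      S <- suppressMessages(pairwise_interaction_sums(gi, map))
      net <- least_epistasis_network(S)
      utils::write.table(data.frame(chrom = rownames(S), unclass(S),
                                    check.names = FALSE),
                         file.path(cfg$outdir, "episnet.sums.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_network(net, file.path(cfg$outdir, "episnet.edges.tsv"), "tsv")
      write_network(net, file.path(cfg$outdir, "episnet.dot"), "dot")
      list(S = S, net = net, hubs = network_hubs(net, 2))
    })
    summary$hubs <- as.list(results$episnet$hubs)
    summary$in_degree <- as.list(results$episnet$net$in_degree)
  }

  consumed <- unlist(inputs[!vapply(inputs, is.null, logical(1))])
  md5 <- tools::md5sum(consumed)
  names(md5) <- basename(consumed)  # content-addressed, path-independent
  summary$input_md5 <- as.list(md5)
  report <- pipeline_report(cfg, results, summary)
  report_path <- file.path(cfg$outdir, "report.md")
  writeLines(report, report_path)
  summary_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(results = results, summary = summary,
                 report = report_path, summary_json = summary_path))
}

pipeline_report <- function(cfg, results, summary) {
  lines <- c("# karyoshift run report", "",
             sprintf("- seed: %d", cfg$seed),
             sprintf("- stages: %s", paste(cfg$stages, collapse = ", ")), "",
             "## Input checksums (md5)", "",
             sprintf("- %s: %s", basename(names(summary$input_md5)),
                     unlist(summary$input_md5)))
  if (!is.null(results$coverage)) {
    tab <- results$coverage$table
    lines <- c(lines, "", "## Chromosome population frequencies", "",
               sprintf("Expected coverage per haploid copy: %.2fx",
                       results$coverage$expected$expected_per_copy), "",
               "chrom | mean_depth | phi_hat | state",
               "----- | ---------- | ------- | -----",
               sprintf("%s | %.3f | %.4f | %s", tab$chrom, tab$mean_depth,
                       tab$phi_hat, tab$state))
  }
  if (!is.null(results$aneuploidy)) {
    fr <- results$aneuploidy$freqs
    lines <- c(lines, "", "## Aneuploidy frequencies", "",
               sprintf("Aneuploid strains: %d", results$aneuploidy$n_aneuploid),
               "", "chrom | n_abnormal | n_normal | f",
               "----- | ---------- | -------- | --",
               sprintf("%s | %d | %d | %.4f", fr$chrom, fr$n_abnormal,
                       fr$n_normal, fr$f))
    if (!is.null(results$aneuploidy$correlation)) {
      co <- results$aneuploidy$correlation
      lines <- c(lines, "",
                 sprintf("Size-frequency Pearson r = %.3f (P = %.3g, n = %d)",
                         co$r, co$p_value, co$n))
    }
  }
  if (!is.null(results$enrich)) {
    lines <- c(lines, "", "## Enrichment", "",
               sprintf("CDF matrix: %d chromosomes x %d columns (reps = %d, method = %s); see enrichment.matrix.tsv",
                       nrow(results$enrich$cdf), ncol(results$enrich$cdf),
                       results$enrich$reps, results$enrich$method))
  }
  if (!is.null(results$episnet)) {
    hubs <- results$episnet$hubs
    lines <- c(lines, "", "## Least-epistasis network", "",
               sprintf("Hubs (by in-degree): %s",
                       paste(sprintf("%s (%s)", hubs, names(hubs)),
                             collapse = ", ")))
  }
  lines
}
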