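#' Run configuration for the end-to-end pipeline
#'
#' @param sim A [sim_config()] driving the synthetic-data stage (the
#'   pipeline currently always simulates its inputs; supply your own panels
#'   programmatically to skip it).
#' @param segment_size Target SNPs per ancestry segment (default 30).
#' @param smoothing_window Rolling-average window in segments (odd, default
#'   7).
#' @param origin_threshold Indicine call threshold on smoothed b (default
#'   0.6).
#' @param models Character subset of c("conventional", "interaction",
#'   "best_variable").
#' @param thresholds Significance thresholds for reporting.
#' @param out_dir Output directory.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       segment_size = 30,
                       smoothing_window = 7,
                       origin_threshold = 0.6,
                       models = c("conventional", "interaction", "best_variable"),
                       thresholds = c(1e-4, 1e-6, 5e-8),
                       out_dir = tempfile("origwas_run_")) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(
    smoothing_window >= 1, smoothing_window %% 2 == 1,
    origin_threshold > 0, origin_threshold < 1,
    all(thresholds > 0), all(thresholds < 1),
    segment_size >= 2
  )
  structure(list(sim = sim, segment_size = segment_size,
                 smoothing_window = smoothing_window,
                 origin_threshold = origin_threshold,
                 models = models, thresholds = thresholds,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline: simulate, QC, ancestry, GWAS, report
#'
#' Executes every stage on the synthetic population described by
#' `config$sim` and writes every intermediate table as TSV under
#' `config$out_dir`, plus a `manifest.tsv` with package version, seed and a
#' config hash. Reruns with an identical config produce byte-identical
#' tables.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory stage results (`sim`,
#'   `qc_report`, `origins`, `ancestry_report`, `results`, `fdr`,
#'   `patterns`, `top_snps`, `out_dir`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] stage failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("[simulate] seed %d", config$sim$seed)
  sim <- stage("simulate", simulate_population(config$sim))
  write_phased_vcf(sim$panel, file.path(config$out_dir, "genotypes.vcf"))
  write_phenotypes_tsv(sim$phenotypes, file.path(config$out_dir, "phenotypes.tsv"))
  comp_rows <- which(rep(sim$panel$group, each = 2) == "composite")
  if (length(comp_rows) > 0) {
    write_tracts_tsv(
      truth_tracts(sim$truth_ancestry[comp_rows, , drop = FALSE], sim$panel$map),
      file.path(config$out_dir, "true_tracts.tsv"))
  }

  say("[qc] %d SNPs in", ncol(sim$panel$haps))
  qc <- stage("qc", apply_qc(sim$panel))
  write_tsv_file(qc$report, file.path(config$out_dir, "qc_report.tsv"))

  say("[ancestry] segments of %d SNPs, window %d",
      config$segment_size, config$smoothing_window)
  segments <- stage("ancestry", define_segments(qc$panel$map, config$segment_size))
  ref_t <- subset_panel(qc$panel, "taurus")
  ref_i <- subset_panel(qc$panel, "indicus")
  freq_table <- tabulate_haplotype_frequencies(ref_t, ref_i, segments)
  origins <- segment_origins(qc$panel, freq_table, segments,
                             config$smoothing_window, config$origin_threshold)
  ao <- assign_allele_origins(qc$panel, origins, segments)
  write_tsv_file(origins, file.path(config$out_dir, "segment_origins.tsv"))
  anc_rep <- ancestry_fraction_report(
    origins, stats::setNames(qc$panel$group, qc$panel$animals))
  write_tsv_file(anc_rep$per_group,
                 file.path(config$out_dir, "ancestry_fractions.tsv"))

  pheno <- sim$phenotypes[match(qc$panel$animals, sim$phenotypes$animal_id), ]
  grm <- if (config$sim$heritability_polygenic > 0) compute_grm(qc$panel) else NULL

  results <- list()
  if ("conventional" %in% config$models) {
    say("[gwas] conventional")
    results$conventional <- stage("gwas",
      run_conventional_gwas(ao, pheno, grm = grm))
    write_tsv_file(results$conventional,
                   file.path(config$out_dir, "gwas_conventional.tsv"))
  }
  if ("interaction" %in% config$models) {
    say("[gwas] interaction")
    results$interaction <- stage("gwas", run_interaction_gwas(ao, pheno, grm = grm))
    write_tsv_file(results$interaction,
                   file.path(config$out_dir, "gwas_interaction.tsv"))
  }
  if ("best_variable" %in% config$models) {
    say("[gwas] best variable")
    results$best_variable <- stage("gwas",
      run_best_variable_gwas(ao, pheno, grm = grm))
    write_tsv_file(results$best_variable,
                   file.path(config$out_dir, "gwas_best_variable.tsv"))
  }

  say("[report] thresholds %s", paste(config$thresholds, collapse = ", "))
  fdr <- patterns <- top <- NULL
  if (!is.null(results$conventional)) {
    fdr <- purrr::map_dfr(config$thresholds, function(th)
      fdr_summary(results$conventional, th))
    write_tsv_file(fdr, file.path(config$out_dir, "fdr_summary.tsv"))
  }
  if (!is.null(results$interaction)) {
    patterns <- classify_patterns(results$interaction, config$thresholds[1])
    write_tsv_file(patterns, file.path(config$out_dir, "segregation_patterns.tsv"))
  }
  if (!is.null(results$best_variable)) {
    top <- infer_mutant_allele(
      select_top_snps(results$best_variable, config$thresholds[1]))
    write_tsv_file(top, file.path(config$out_dir, "top_snps.tsv"))
    write_tsv_file(effect_frequency_plot_table(top),
                   file.path(config$out_dir, "effect_frequency.tsv"))
  }

  manifest <- tibble::tibble(
    package_version = as.character(utils::packageVersion("origwas")),
    seed = config$sim$seed,
    config_hash = config_hash(config),
    n_snps_post_qc = ncol(qc$panel$haps),
    n_animals_post_qc = length(qc$panel$animals),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  )
  write_tsv_file(manifest, file.path(config$out_dir, "manifest.tsv"))
  say("[done] %s", config$out_dir)
  invisible(list(sim = sim, qc_report = qc$report, origins = origins,
                 ancestry_report = anc_rep, results = results, fdr = fdr,
                 patterns = patterns, top_snps = top,
                 out_dir = config$out_dir))
}

#' Hash of a run configuration
#'
#' MD5 of the deparsed config (excluding the output directory), so the hash
#' changes iff an analysis-relevant field changes.
#'
#' @param config A [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$sim <- unclass(x$sim)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Write / read a plain-text key-value run configuration
#'
#' Flat `key = value` format covering the scalar fields of [run_config()]
#' and [sim_config()]; list-valued fields (QTL) are not serialised.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` invisibly (writer); a [run_config()] (reader).
#' @export
write_run_config <- function(config, path) {
  kv <- c(
    segment_size = config$segment_size,
    smoothing_window = config$smoothing_window,
    origin_threshold = config$origin_threshold,
    models = paste(config$models, collapse = ","),
    thresholds = paste(config$thresholds, collapse = ","),
    out_dir = config$out_dir,
    sim.n_chromosomes = config$sim$n_chromosomes,
    sim.snps_per_chromosome = config$sim$snps_per_chromosome,
    sim.chromosome_length = config$sim$chromosome_length,
    sim.n_taurus = config$sim$n_taurus,
    sim.n_indicus = config$sim$n_indicus,
    sim.n_composite = config$sim$n_composite,
    sim.divergence_fst = config$sim$divergence_fst,
    sim.admix_generations = config$sim$admix_generations,
    sim.admix_proportion = config$sim$admix_proportion,
    sim.heritability_polygenic = config$sim$heritability_polygenic,
    sim.seed = config$sim$seed
  )
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]]) else d
  chr <- function(k, d) if (k %in% names(vals)) vals[[k]] else d
  run_config(
    sim = sim_config(
      n_chromosomes = num("sim.n_chromosomes", 2),
      snps_per_chromosome = num("sim.snps_per_chromosome", 600),
      chromosome_length = num("sim.chromosome_length", 0.05),
      n_taurus = num("sim.n_taurus", 250),
      n_indicus = num("sim.n_indicus", 250),
      n_composite = num("sim.n_composite", 100),
      divergence_fst = num("sim.divergence_fst", 0.3),
      admix_generations = num("sim.admix_generations", 8),
      admix_proportion = num("sim.admix_proportion", 0.75),
      heritability_polygenic = num("sim.heritability_polygenic", 0.3),
      seed = num("sim.seed", 1)
    ),
    segment_size = num("segment_size", 30),
    smoothing_window = num("smoothing_window", 7),
    origin_threshold = num("origin_threshold", 0.6),
    models = strsplit(chr("models", "conventional,interaction,best_variable"),
                      ",")[[1]],
    thresholds = as.numeric(strsplit(chr("thresholds", "1e-4,1e-6,5e-8"), ",")[[1]]),
    out_dir = chr("out_dir", tempfile("origwas_run_"))
  )
}
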