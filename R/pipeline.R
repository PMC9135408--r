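# Config-driven orchestration: generate synthetic inputs (or read real
# ones), run the enabled analysis stages in dependency order, write
# per-stage TSV/BED outputs and one machine-readable JSON report.

PIPELINE_SCHEMA <- list(
  top = c("version", "seed", "stages"),
  stages = c("generate", "cistrome", "enrich", "rime", "screens",
             "signatures"),
  generate = c("enabled", "genome", "cistrome", "library", "rime",
               "expression", "screens", "write_inputs"),
  cistrome = c("enabled", "control_bed", "treated_bed", "mode",
               "normalize_chr"),
  enrich = c("enabled", "bin_size"),
  rime = c("enabled", "table", "presence", "log_transform"),
  screens = c("enabled", "treated_arm", "control_arm"),
  signatures = c("enabled", "detect_frac", "p_threshold"))

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop_("unknown config key(s) in %s: %s (allowed: %s)", where,
          paste(unknown, collapse = ", "), paste(allowed, collapse = ", "))
  invisible(TRUE)
}

#' Read and validate a pipeline configuration
#'
#' YAML with a versioned schema; any unrecognised key is an error (silent
#' typos are the chief failure mode of config-driven pipelines).
#'
#' @param con Path to a YAML file, or an already-parsed list.
#' @return Validated config list with defaults filled in.
#' @export
read_pipeline_config <- function(con) {
  config <- if (is.character(con)) yaml::read_yaml(con) else con
  check_keys(config, PIPELINE_SCHEMA$top, "top level")
  if (!identical(as.integer(config$version %||% 1L), 1L))
    stop_("unsupported config version: %s", config$version)
  config$version <- 1L
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% list()
  check_keys(config$stages, PIPELINE_SCHEMA$stages, "stages")
  for (st in names(config$stages))
    check_keys(config$stages[[st]], PIPELINE_SCHEMA[[st]],
               sprintf("stages$%s", st))
  config
}

stage_enabled <- function(config, stage) {
  isTRUE((config$stages[[stage]] %||% list())$enabled)
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order — `generate`,
#' `cistrome`, `enrich`, `rime`, `screens`, `signatures` — writing stage
#' outputs under `outdir` and a JSON report (`report.json`) that echoes
#' the config and seed and contains every headline number. A missing
#' input for an enabled stage fails fast with the stage name; partial
#' outputs are removed.
#'
#' @param config Path to a YAML config or a config list (see
#'   [read_pipeline_config()]).
#' @param outdir Output directory (created).
#' @param seed Optional integer overriding the config seed.
#' @param verbose Emit one log line per stage step.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, outdir, seed = NULL, verbose = FALSE) {
  config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- config$seed
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(outdir, "report.json")))
  report <- list(schema_version = 1L,
                 package_version = as.character(
                   utils::packageVersion("dynabind")),
                 seed = seed, config = config)
  gen <- NULL

  if (stage_enabled(config, "generate")) {
    gc_ <- config$stages$generate
    pipeline_log(verbose, "generate", "planting synthetic inputs, seed %d",
                 seed)
    genome <- do.call(generate_genome,
                      c(gc_$genome %||% list(n_chroms = 10,
                                             length_per_chrom = 2e6),
                        list(seed = seed)))
    peaks <- generate_condition_peaks(
      genome, do.call(cistrome_params, gc_$cistrome %||% list()), seed = seed)
    lib <- do.call(generate_cistrome_library,
                   c(list(genome = genome, seed = seed),
                     gc_$library %||% list()))
    rime_exp <- generate_rime_experiment(
      do.call(rime_params, gc_$rime %||% list()), seed = seed)
    es <- generate_expression_and_screens(
      do.call(expression_params, gc_$expression %||% list()),
      do.call(screen_params, gc_$screens %||% list()), seed = seed)
    gen <- list(genome = genome, peaks = peaks, library = lib,
                rime = rime_exp, es = es)
    if (isTRUE(gc_$write_inputs)) {
      gdir <- file.path(outdir, "generated")
      dir.create(gdir, showWarnings = FALSE)
      write_bed(peaks$control, file.path(gdir, "control.bed"))
      write_bed(peaks$treated, file.path(gdir, "treated.bed"))
      write_rime_table(rime_exp$records, file.path(gdir, "rime.tsv"))
      write_matrix_tsv(es$expression, file.path(gdir, "expression.tsv"))
      write_matrix_tsv(es$screen$values, file.path(gdir, "screen_z.tsv"))
      write_matrix_tsv(es$dependency$values,
                       file.path(gdir, "dependency.tsv"))
      jsonlite::write_json(
        list(peak_truth = peaks$truth, rime_truth = rime_exp$truth,
             expression_truth = es$truth[c("index_gene", "target_rho")]),
        file.path(gdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
    report$generate <- list(
      n_control_peaks = length(peaks$control),
      n_treated_peaks = length(peaks$treated),
      planted_counts = as.list(peaks$planted_counts),
      n_rime_records = nrow(rime_exp$records))
  }

  union_set <- NULL
  if (stage_enabled(config, "cistrome")) {
    sc <- config$stages$cistrome
    if (!is.null(sc$control_bed)) {
      if (!file.exists(sc$control_bed) || !file.exists(sc$treated_bed))
        stop_("cistrome stage: BED input missing")
      control <- read_bed(sc$control_bed)
      treated <- read_bed(sc$treated_bed)
    } else if (!is.null(gen)) {
      control <- gen$peaks$control
      treated <- gen$peaks$treated
    } else {
      stop_("cistrome stage enabled but no peak inputs (enable generate or give BED paths)")
    }
    mode <- sc$mode %||% "region"
    diff <- classify_differential_peaks(control, treated, mode = mode,
                                        normalize_chr =
                                          isTRUE(sc$normalize_chr))
    pipeline_log(verbose, "cistrome", "lost %d retained %d gained %d",
                 diff$counts["lost"], diff$counts["retained"],
                 diff$counts["gained"])
    write_differential_beds(diff, file.path(outdir, "cistrome"))
    union_set <- condition_union(control, treated)
    report$cistrome <- list(counts = as.list(diff$counts),
                            n_union = length(union_set),
                            mode = mode)
    if (!is.null(gen) && !is.null(gen$peaks$class_sets)) {
      tax <- annotate_arbs_classes(union_set, gen$peaks$class_sets)
      report$cistrome$arbs_fractions <- as.list(tax$fractions)
      if (!is.null(gen$peaks$pioneer)) {
        cs <- class_overlap_summary(tax, gen$peaks$pioneer)
        report$cistrome$pioneer_overlap_by_class <-
          setNames(as.list(cs$fraction), cs$class)
      }
    }
  }

  if (stage_enabled(config, "enrich")) {
    if (is.null(gen))
      stop_("enrich stage requires the generate stage (cistrome library)")
    if (is.null(union_set))
      stop_("enrich stage requires the cistrome stage (query peak set)")
    bin_size <- config$stages$enrich$bin_size %||% 1000
    uni <- universe_spec(gen$genome, bin_size = bin_size)
    ranking <- rank_library(union_set, gen$library$library, uni)
    pipeline_log(verbose, "enrich", "top factor %s (combo %.2f)",
                 ranking$label[1], ranking$combo_score[1])
    write_ranking_tsv(ranking, file.path(outdir, "enrichment_ranking.tsv"))
    report$enrich <- list(bin_size = bin_size,
                          top_factor = ranking$label[1],
                          ranking = setNames(as.list(ranking$combo_score),
                                             ranking$label))
  }

  if (stage_enabled(config, "rime")) {
    sr <- config$stages$rime
    if (!is.null(sr$table)) {
      if (!file.exists(sr$table)) stop_("rime stage: table input missing")
      records <- read_rime_table(sr$table)
      rp <- NULL
    } else if (!is.null(gen)) {
      records <- gen$rime$records
      rp <- gen$rime$params
    } else {
      stop_("rime stage enabled but no peptide table (enable generate or give a path)")
    }
    presence <- sr$presence %||% "any"
    baits <- setdiff(unique(records$bait),
                     rp$control_bait %||% "LUCIFERASE")
    control_bait <- setdiff(unique(records$bait), baits)
    conditions <- sort(unique(records$condition))
    n_rep <- max(records$replicate)
    profiles <- list()
    for (b in baits) for (cd in intersect(conditions,
                                          records$condition[records$bait == b])) {
      cleaned <- collapse_unique_peptides(records, b, cd, n_rep)
      if (length(control_bait) == 1) {
        ctl <- collapse_unique_peptides(records, control_bait, cd, n_rep)
        cleaned <- subtract_control(cleaned, ctl)
      }
      profiles[[paste(b, cd, sep = ".")]] <-
        build_profile(cleaned, b, cd, presence = presence)
    }
    report$rime <- list(baits = baits, n_records = nrow(records))
    first <- baits[1]
    if (length(conditions) == 2 &&
        all(paste(first, conditions, sep = ".") %in% names(profiles))) {
      di <- classify_differential_interactions(
        profiles[[paste(first, conditions[1], sep = ".")]],
        profiles[[paste(first, conditions[2], sep = ".")]])
      report$rime$differential <- as.list(di$counts)
      pipeline_log(verbose, "rime", "lost %d retained %d gained %d",
                   di$counts["lost"], di$counts["retained"],
                   di$counts["gained"])
    }
    if (length(baits) >= 2) {
      cd <- conditions[length(conditions)]
      sets <- lapply(baits, function(b)
        setdiff(names(profiles[[paste(b, cd, sep = ".")]]$values),
                c(b, "V5")))
      names(sets) <- baits
      if (length(baits) >= 3) sets <- sets[1:3]
      vc <- venn_counts(sets)
      report$rime$venn <- as.list(vc$regions)
      cors <- list()
      pairs <- utils::combn(names(sets), 2, simplify = FALSE)
      for (pr in pairs) {
        key <- paste(pr, collapse = "_vs_")
        cors[[key]] <- tryCatch(
          correlate_profiles(profiles[[paste(pr[1], cd, sep = ".")]],
                             profiles[[paste(pr[2], cd, sep = ".")]]),
          error = function(e) NA_real_)
      }
      report$rime$profile_correlations <- cors
    }
    prof_tab <- do.call(rbind, lapply(profiles, function(p)
      data.frame(bait = p$bait, condition = p$condition,
                 protein = names(p$values), mean_unique_peptides =
                   unname(p$values))))
    write.table(prof_tab, file.path(outdir, "rime_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (stage_enabled(config, "screens")) {
    if (is.null(gen))
      stop_("screens stage requires generated inputs in this version")
    ss <- config$stages$screens
    arms <- colnames(gen$es$screen$values)
    treated_arm <- ss$treated_arm %||% arms[2]
    control_arm <- ss$control_arm %||% arms[1]
    dz <- differential_z_rank(gen$es$screen, treated_arm, control_arm)
    write.table(head(dz, 50), file.path(outdir, "screen_top50.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$screens <- list(
      top_gene = dz$gene[1], top_delta = dz$delta[1],
      top_z_treated = dz$z_treated[1], top_z_control = dz$z_control[1])
    dep <- gen$es$dependency
    groups <- unique(dep$groups)
    percentiles <- list()
    for (gp in groups) {
      rp_ <- rank_percentile(average_dependency(dep, gp))
      percentiles[[gp]] <- setNames(
        as.list(rp_$percentile[match(gen$es$truth$dep_genes, rp_$gene)]),
        gen$es$truth$dep_genes)
    }
    report$screens$dependency_percentiles <- percentiles
    pipeline_log(verbose, "screens", "top differential gene %s",
                 dz$gene[1])
  }

  if (stage_enabled(config, "signatures")) {
    if (is.null(gen))
      stop_("signatures stage requires generated inputs in this version")
    sg <- config$stages$signatures
    assoc <- spearman_all_genes(gen$es$expression,
                                gen$es$truth$index_gene,
                                detect_frac = sg$detect_frac %||% 0.2)
    volcano <- signature_volcano(assoc, gen$es$truth$signature_genes,
                                 p_threshold = sg$p_threshold %||% 0.05)
    write.table(assoc, file.path(outdir, "association.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$signatures <- list(
      index_gene = gen$es$truth$index_gene,
      median_signature_rho = stats::median(volcano$rho),
      n_significant = sum(volcano$significant))
    pipeline_log(verbose, "signatures", "median signature rho %.3f",
                 report$signatures$median_signature_rho)
  }

  write_report(report, file.path(outdir, "report.json"))
  ok <- TRUE
  invisible(report)
}

#' Write a pipeline report as JSON
#'
#' @param results Non-empty named list of stage results.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path) {
  if (!is.list(results) || length(results) == 0)
    stop_("empty results: nothing to report")
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}
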