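#' Default pipeline configuration
#'
#' A flat key-value list controlling [run_pipeline()]; every value can be
#' overridden by the `config` argument. The defaults describe a desk-scale
#' experiment: a 3-chromosome model genome, two F5-derived RIL populations
#' of unequal size (mimicking a large primary and a smaller secondary
#' mapping population), an assembly carrying planted inversions and
#' translocations plus detached scaffolds.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(n_chromosomes = 3L, n_markers = 120L,
       n_lines_pop1 = 150L, n_lines_pop2 = 130L,
       selfing_generations = 4L,
       error_rate = 0, missing_rate = 0.02,
       max_missing = 0.10, alpha = 0.01,
       lod_threshold = 11, window = Inf,
       n_inversions = 3L, n_translocations = 2L,
       n_detached_scaffolds = 3L,
       min_run = 2L, complex_threshold = 5L,
       slope_ratio_max = 0.25, min_segment = 2e6)
}

#' Run the full map-and-curate pipeline on synthetic data
#'
#' Executes the stages in order — simulate (two populations), QC, binning
#' and map construction per population, concordance detection against the
#' corrupted assembly with two-population support merging, scaffold
#' anchoring, and chromatin partitioning — writing every intermediate
#' artifact under `out_dir` and returning a run manifest (seed, config,
#' stage timings, output paths with digests, and a truth-recovery
#' summary).
#'
#' @param config Named list overriding [default_config()] entries.
#' @param seed Integer seed governing all sampling.
#' @param out_dir Output directory (created if absent).
#' @return The run manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = list(), seed = 1,
                         out_dir = tempfile("mapforge_run_")) {
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  outputs <- character(0)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
    stages[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  genome <- default_genome(cfg$n_chromosomes, cfg$n_markers, seed = seed)
  sim <- tick("simulate", {
    g1 <- simulate_population(genome, cfg$n_lines_pop1,
                              cfg$selfing_generations, cfg$error_rate,
                              cfg$missing_rate, seed = seed,
                              population_id = "pop1")
    g2 <- simulate_population(genome, cfg$n_lines_pop2,
                              cfg$selfing_generations, cfg$error_rate,
                              cfg$missing_rate, seed = seed + 1L,
                              population_id = "pop2")
    truth <- corrupt_assembly(model_placement(genome),
                              cfg$n_inversions, cfg$n_translocations,
                              cfg$n_detached_scaffolds, seed = seed + 2L)
    write_genotypes(g1, emit(file.path(out_dir, "pop1_genotypes.csv")))
    write_genotypes(g2, emit(file.path(out_dir, "pop2_genotypes.csv")))
    write_placement(truth$corrupted_assembly,
                    emit(file.path(out_dir, "assembly_corrupted.tsv")))
    write_scaffolds(truth$detached_scaffolds,
                    emit(file.path(out_dir, "scaffolds.tsv")))
    list(g1 = g1, g2 = g2, truth = truth)
  })

  qc <- tick("qc", {
    q1 <- qc_genotypes(sim$g1, cfg$max_missing, cfg$alpha)
    q2 <- qc_genotypes(sim$g2, cfg$max_missing, cfg$alpha)
    list(q1 = q1, q2 = q2)
  })

  bins <- tick("bin", {
    list(b1 = bin_markers(qc$q1$genotypes),
         b2 = bin_markers(qc$q2$genotypes))
  })

  placement <- sim$truth$corrupted_assembly
  maps <- tick("map", {
    m1 <- build_linkage_map(qc$q1$genotypes, cfg$lod_threshold,
                            placement = placement, window = cfg$window)
    m2 <- build_linkage_map(qc$q2$genotypes, cfg$lod_threshold,
                            placement = placement, window = cfg$window)
    write_linkage_map(m1, emit(file.path(out_dir, "pop1_map.tsv")))
    write_linkage_map(m2, emit(file.path(out_dir, "pop2_map.tsv")))
    list(m1 = m1, m2 = m2)
  })

  concord <- tick("concord", {
    d1 <- detect_corrections(maps$m1, placement, cfg$min_run,
                             cfg$complex_threshold, support = "POP1_ONLY")
    d2 <- detect_corrections(maps$m2, placement, cfg$min_run,
                             cfg$complex_threshold, support = "POP2_ONLY")
    merged <- merge_support(d1$ledger, d2$ledger)
    write.table(merged$entries,
                emit(file.path(out_dir, "corrections.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    applied <- suppressWarnings(apply_corrections(placement, merged))
    write_placement(applied$placement,
                    emit(file.path(out_dir, "assembly_corrected.tsv")))
    write_agp(applied$agp, emit(file.path(out_dir, "assembly.agp")))
    list(d1 = d1, d2 = d2, merged = merged, applied = applied)
  })

  anchors <- tick("anchor", {
    a <- anchor_scaffolds(sim$truth$detached_scaffolds,
                          list(pop1 = maps$m1, pop2 = maps$m2),
                          list(pop1 = concord$d1$assignment,
                               pop2 = concord$d2$assignment))
    if (!is.null(a$anchors)) {
      write.table(a$anchors, emit(file.path(out_dir, "anchors.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    a
  })

  chromatin <- tick("chromatin", {
    lens <- setNames(
      vapply(genome$chromosomes, `[[`, numeric(1), "length"),
      vapply(genome$chromosomes, `[[`, character(1), "name"))
    part <- partition_chromatin(maps$m1, model_placement(genome),
                                chromosome_lengths = lens,
                                slope_ratio_max = cfg$slope_ratio_max,
                                min_segment = cfg$min_segment)
    write_bed(part, emit(file.path(out_dir, "chromatin.bed")))
    part
  })

  planted <- sim$truth$planted_errors$entries
  detected <- concord$merged$entries
  recovery <- list(
    n_planted = nrow(planted),
    n_detected = nrow(detected),
    n_planted_recovered = sum(vapply(seq_len(nrow(planted)), function(i) {
      any(detected$chromosome == planted$chromosome[i] &
            detected$action == planted$action[i] &
            detected$span_start <= planted$span_end[i] &
            detected$span_end >= planted$span_start[i])
    }, logical(1))))

  manifest <- list(seed = seed, config = cfg,
                   stage_seconds = stages,
                   outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                                      basename(outputs)),
                   truth_recovery = recovery,
                   n_stages = length(stages))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
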