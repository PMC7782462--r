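#' Run the full genomic-prediction pipeline from one configuration
#'
#' Executes simulate (optional) -> MAF filter -> GRM -> stage-one BLUPs ->
#' validation schemes, writing every table plus a run manifest (package
#' version, seeds, input checksums, per-stage runtimes) to `out_dir`.
#'
#' The configuration is a named list (or a YAML file path) with keys:
#' \describe{
#'   \item{simulation}{either a [sim_config()] object, a list of
#'     `sim_config` arguments (e.g. `list(preset = "minimal")`), or absent
#'     when `genotypes`/`pedigree`/`phenotypes` paths are given.}
#'   \item{genotypes, pedigree, phenotypes}{paths to delimited input files
#'     (used when no simulation block is present).}
#'   \item{maf}{MAF threshold, default 0.05.}
#'   \item{chain}{chain preset name or list for [chain_settings()],
#'     default `"quick"`.}
#'   \item{schemes}{list of scheme specs, each a list with `kind` one of
#'     `cv5`, `across_year`, `size_adjusted`, `sibship`,
#'     `partial_conversion` plus that scheme's arguments.}
#'   \item{seed}{master seed.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return invisibly, a list with `manifest`, `data` (the `gs_dataset`) and
#'   `results` (named list of `validation_result`s).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  known <- c("simulation", "genotypes", "pedigree", "phenotypes", "maf",
             "chain", "schemes", "seed", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop_config("unknown pipeline config key(s): %s",
                               paste(bad, collapse = ", "))
  has_files <- all(c("genotypes", "pedigree", "phenotypes") %in% names(config))
  if (is.null(config$simulation) && !has_files)
    stop_config("config needs either a 'simulation' block or genotype/pedigree/phenotype paths")
  out_dir <- config$out_dir %||% stop_config("config needs 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  chain <- if (inherits(config$chain, "chain_settings")) config$chain
    else if (is.character(config$chain %||% "quick"))
      chain_settings(config$chain %||% "quick", seed = seed)
    else do.call(chain_settings, config$chain)

  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  if (!is.null(config$simulation)) {
    sim_cfg <- if (inherits(config$simulation, "sim_config")) config$simulation
      else do.call(sim_config, utils::modifyList(config$simulation,
                                                 list(seed = seed)))
    program <- simulate_program(sim_cfg)
    write_markers(program$markers, file.path(out_dir, "genotypes.tsv"))
    write_tsv_table(program$pedigree[c("line_id", "parent1", "parent2",
                                       "year", "tester")],
                    file.path(out_dir, "pedigree.tsv"))
    write_tsv_table(program$phenotypes, file.path(out_dir, "phenotypes.tsv"))
  } else {
    program <- list(markers = read_markers(config$genotypes),
                    pedigree = read_pedigree(config$pedigree),
                    phenotypes = read_phenotypes(config$phenotypes))
  }
  timings["simulate_or_load"] <- tic() - t0

  t0 <- tic()
  data <- prepare_validation_data(program, maf_threshold = config$maf %||% 0.05)
  write_grm(data$G, file.path(out_dir, "grm.tsv"))
  write_tsv_table(data$within, file.path(out_dir, "blups_within.tsv"))
  write_tsv_table(data$across, file.path(out_dir, "blups_across.tsv"))
  write_tsv_table(data$h2, file.path(out_dir, "heritability.tsv"))
  timings["grm_and_blup"] <- tic() - t0

  results <- list()
  for (i in seq_along(config$schemes)) {
    sc <- config$schemes[[i]]
    kind <- sc$kind %||% stop_config("scheme %d lacks a 'kind'", i)
    sc$kind <- NULL
    t0 <- tic()
    args <- c(list(data = data), sc, list(chain = chain))
    if (kind %in% c("cv5", "size_adjusted", "partial_conversion") &&
        is.null(args$seed)) args$seed <- seed
    res <- tryCatch(switch(kind,
      cv5 = do.call(run_cv5, args),
      across_year = do.call(run_across_year, args),
      size_adjusted = do.call(run_size_adjusted, args),
      sibship = do.call(run_sibship_partition, args),
      partial_conversion = do.call(run_partial_conversion, args),
      stop_config("unknown scheme kind '%s'", kind)
    ), error = function(e) stop_config("scheme %d (%s) failed: %s",
                                       i, kind, conditionMessage(e)))
    nm <- paste0(kind, "_", i)
    results[[nm]] <- res
    rr <- res$replicates
    if (nrow(rr)) {
      rr <- cbind(scheme = nm, rr)
      write_tsv_table(rr, file.path(out_dir, paste0("result_", nm, ".tsv")))
    }
    timings[nm] <- tic() - t0
  }

  report <- render_report(results)
  writeLines(report, file.path(out_dir, "summary_report.txt"))

  inputs <- list.files(out_dir, pattern = "\\.(tsv)$", full.names = TRUE)
  manifest <- list(
    package = "dhgs",
    version = as.character(utils::packageVersion("dhgs")),
    r_version = R.version.string,
    seed = seed,
    chain = unclass(chain),
    timings_sec = as.list(round(timings, 3)),
    checksums = as.list(tools::md5sum(inputs)),
    schemes = names(results)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, data = data, results = results))
}

#' Text report of validation accuracies
#'
#' Tabular summary grouped by scheme, model and level, with the mean
#' accuracy and, where replicated, the standard error in brackets
#' (`0.50 (0.03)` style).
#'
#' @param results a list of `validation_result` objects (or a single one).
#' @return character vector of report lines.
#' @export
render_report <- function(results) {
  if (inherits(results, "validation_result")) results <- list(results)
  if (!length(results)) stop_config("no results to report")
  fmt <- function(m, se) {
    if (is.na(m)) return("   skipped")
    if (is.na(se)) sprintf("%.2f", m) else sprintf("%.2f (%.2f)", m, se)
  }
  lines <- c("Prediction accuracy (r_MG) by validation scheme",
             strrep("-", 48))
  ord <- order(vapply(results, function(x) x$scheme$kind, ""))
  for (res in results[ord]) {
    s <- res$scheme
    desc <- paste(vapply(setdiff(names(s), "kind"), function(k)
      paste0(k, "=", s[[k]]), ""), collapse = " ")
    lines <- c(lines, sprintf("%-20s %s", s$kind, desc),
               sprintf("    r_MG = %s", fmt(res$mean, res$se)))
    if (nrow(res$replicates) && length(unique(res$replicates$group)) > 1L) {
      for (g in unique(res$replicates$group)) {
        rg <- res$replicates$r[res$replicates$group == g]
        lines <- c(lines, sprintf("      %-12s %s", g,
                                  fmt(mean(rg, na.rm = TRUE),
                                      if (length(rg) > 1L)
                                        stats::sd(rg) / sqrt(length(rg))
                                      else NA_real_)))
      }
    }
  }
  lines
}
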