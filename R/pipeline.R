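#' Pipeline configuration
#'
#' Bundles the generator configuration, the problems to assemble, and the
#' classifier roster for an end-to-end run. Validated eagerly so a
#' misspelled problem name fails before any stage executes.
#'
#' @param generator a [generator_config()].
#' @param problems character vector of problem names (see [problem_spec()]).
#' @param t_values temporal extents to assemble (subset of c(1, 6); the
#'   benchmark consumes t = 1).
#' @param classifiers list of [classifier_spec()] or names.
#' @param split_ratio train fraction.
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            problems = c("ENC2", "ENC3", "ENC4", "ENC5",
                                         "RET2", "RET3", "RET4", "RET5"),
                            t_values = 1L,
                            classifiers = default_classifier_specs(),
                            split_ratio = 0.9,
                            seed = 1L) {
  stopifnot(inherits(generator, "generator_config"))
  for (p in problems) problem_spec(p)  # validates names
  if (!all(t_values %in% c(1L, 6L))) stop("t_values must be a subset of {1, 6}")
  classifiers <- lapply(classifiers, function(s)
    if (is.character(s)) classifier_spec(s) else s)
  needs_rest <- any(vapply(problems, function(p) problem_spec(p)$includes_rest,
                           logical(1)))
  if (needs_rest && !generator$include_rest) {
    stop("problems reference REST but the generator excludes rest sessions")
  }
  structure(list(generator = generator, problems = problems,
                 t_values = as.integer(t_values), classifiers = classifiers,
                 split_ratio = split_ratio, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level keys: `generator` (arguments of
#' [generator_config()]), `problems`, `t_values`, `classifiers` (names),
#' `split_ratio`, `seed`.
#'
#' @param path .yaml/.yml or .json file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- do.call(generator_config, as.list(raw$generator %||% list()))
  pipeline_config(
    generator = gen,
    problems = raw$problems %||% c("ENC2", "ENC3", "ENC4", "ENC5",
                                   "RET2", "RET3", "RET4", "RET5"),
    t_values = as.integer(raw$t_values %||% 1L),
    classifiers = as.list(raw$classifiers %||%
                            vapply(default_classifier_specs(), `[[`, "", "name")),
    split_ratio = raw$split_ratio %||% 0.9,
    seed = raw$seed %||% 1L
  )
}

#' Run the full pipeline
#'
#' Executes generate -> segment -> assemble -> split -> benchmark for every
#' configured problem, writing per-problem benchmark TSV/JSON, a combined
#' results table shaped like the study's model-by-problem layout (one row
#' per model, one column per problem), and a manifest JSON with seeds and
#' MD5 hashes of every artifact. Identical config and seed reproduce
#' identical hashes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir = tempfile("roidecode_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  study <- stage("generate", generate_study(config$generator))
  series <- stage("segment", segment_study(study, base_seed = config$seed))
  results <- list()
  for (prob in config$problems) {
    for (t in config$t_values) {
      key <- sprintf("%s_t%d", prob, t)
      res <- stage(key, {
        ds <- assemble_problem(series, prob, t = t)
        split <- split_train_test(ds, ratio = config$split_ratio,
                                  seed = config$seed)
        if (t == 1L) {
          bench <- run_benchmark(split, config$classifiers, seed = config$seed,
                                 tune_space = search_space(n_trials = 20L))
          reports <- attr(bench, "reports")
          # wall-clock column omitted on disk so artifact hashes are reproducible
          utils::write.table(bench[, setdiff(names(bench), "fit_seconds")],
                             file.path(out_dir, paste0(key, "_bench.tsv")),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          jsonlite::write_json(
            lapply(reports, function(r) list(per_class = r$per_class,
                                             weighted_f1 = r$weighted_f1)),
            file.path(out_dir, paste0(key, "_bench.json")),
            auto_unbox = TRUE, digits = NA)
          bench
        } else NULL
      })
      if (!is.null(res)) results[[key]] <- res
    }
  }
  if (length(results) > 0) {
    models <- results[[1]]$model
    combined <- data.frame(model = models,
                           family = results[[1]]$family)
    for (key in names(results)) combined[[key]] <- results[[key]]$weighted_f1
    utils::write.table(combined, file.path(out_dir, "benchmark_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest <- list(
    seed = config$seed,
    generator = config$generator[setdiff(names(config$generator),
                                         "informative_rois")],
    problems = config$problems,
    t_values = config$t_values,
    package_version = as.character(utils::packageVersion("roidecode")),
    conventions = list(tr_indexing = "0-based", onset_units = "seconds",
                       segment_windows = "half-open"),
    artifacts = lapply(stats::setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
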