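# Orchestration: end-to-end runs (simulate -> solve -> report), YAML
# configuration and file output. One DEA model is estimated per farm type;
# farms of different types never share a frontier. Logging goes to standard
# error via message(); results are only ever written to files or returned.

#' Published benchmark aggregates
#'
#' Aggregate benchmark tables for the four European sheep meat farm types
#' (accounting year 2015) shipped with the package: the TE frequency
#' distribution, existing versus efficient-target output by size class, the
#' gross-revenue composition and per-ewe techno-economic indicators by
#' efficiency group, and category/practice adoption counts among efficient
#' farms. They calibrate the synthetic generator and serve as worked-example
#' inputs for the reporting functions.
#'
#' @param name one of `"frequency"`, `"projection"`, `"composition"`,
#'   `"indicators"`, `"practice_categories"`, `"practice_ranking"`.
#' @return the requested table as a data.frame.
#' @export
#' @examples
#' benchmark_table("projection")
benchmark_table <- function(name = c("frequency", "projection", "composition",
                                     "indicators", "practice_categories",
                                     "practice_ranking")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("benchmark_", name, ".csv"),
                      package = "sheepdea", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the full efficiency analysis
#'
#' For each farm type present in `records`: solves the output-oriented VRS
#' DEA model over that type's farms, then assembles the reporting tables
#' (TE frequency distribution, size-class projection summary, gross-revenue
#' composition and techno-economic indicators by efficiency group, and --
#' when practice selections are supplied -- the best-practice adoption
#' tables). Composition/indicator tables are skipped with a log message when
#' the optional columns are absent.
#'
#' @param records farm table (may mix farm types; each type is solved
#'   against its own frontier).
#' @param settings a [solver_settings()].
#' @param schemes optional named list of [size_class_scheme()] overrides,
#'   keyed by farm type.
#' @param selections optional named list of `practice_selection` tables,
#'   keyed by farm type; only selections of efficient farms are tabulated.
#' @param catalog a [practice_catalog()] for the selections.
#' @param outdir optional directory; when given, every table is written
#'   there as `<farm_type>_<table>.<format>`.
#' @param format `"csv"` or `"json"` for file output.
#' @return named list (one element per farm type) of lists with components
#'   `results`, `frequency`, `projection`, `composition`, `indicators`,
#'   `category_adoption`, `practice_ranking` (NULL where not computable).
#' @export
run_efficiency_analysis <- function(records, settings = solver_settings(),
                                    schemes = NULL, selections = NULL,
                                    catalog = practice_catalog(),
                                    outdir = NULL, format = c("csv", "json")) {
  format <- match.arg(format)
  validate_farm_table(records)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  types <- intersect(farm_types(), unique(records$farm_type))
  out <- list()
  for (ft in types) {
    sub <- records[records$farm_type == ft, , drop = FALSE]
    message(sprintf("[%s] solving DEA for %d farms", ft, nrow(sub)))
    res <- solve_all(dea_problem(sub), settings)
    scheme <- if (!is.null(schemes) && ft %in% names(schemes))
      schemes[[ft]] else size_class_scheme(ft)
    freq <- te_frequency_table(res, epsilon = settings$efficiency_eps)
    proj <- projection_summary(sub, res, scheme)
    comp <- tryCatch(revenue_composition(sub, res,
                                         settings$efficiency_eps),
                     error = function(e) {
                       message(sprintf("[%s] composition skipped: %s", ft,
                                       conditionMessage(e)))
                       NULL
                     })
    ind <- tryCatch(economic_indicators(sub, res, settings$efficiency_eps),
                    error = function(e) NULL)
    cat_ad <- rank_tab <- NULL
    if (!is.null(selections) && ft %in% names(selections)) {
      eff_ids <- sub$farm_id[classify_groups(res,
                                             settings$efficiency_eps)$efficient]
      sel <- selections[[ft]]
      sel_eff <- sel[sel$farm_id %in% eff_ids, , drop = FALSE]
      cat_ad <- category_adoption(sel_eff, catalog)
      rank_tab <- practice_frequency_ranking(sel_eff, catalog)
    }
    message(sprintf("[%s] n = %d, mean TE = %.3f, efficient = %d", ft,
                    nrow(res), mean(res$te), sum(res$is_efficient)))
    tabs <- list(results = res, frequency = freq, projection = proj,
                 composition = comp, indicators = ind,
                 category_adoption = cat_ad, practice_ranking = rank_tab)
    if (!is.null(outdir)) .write_report_bundle(tabs, ft, outdir, format)
    out[[ft]] <- tabs
  }
  if (!length(out)) stop("no rows with a recognised farm_type", call. = FALSE)
  invisible(out)
}

.write_report_bundle <- function(tabs, ft, outdir, format) {
  write_dea_results(tabs$results, file.path(outdir,
                                            paste0(ft, "_dea.", format)),
                    format)
  for (nm in c("frequency", "projection", "composition", "indicators",
               "category_adoption", "practice_ranking")) {
    tb <- tabs[[nm]]
    if (is.null(tb)) next
    path <- file.path(outdir, paste0(ft, "_", nm, ".", format))
    if (format == "csv") {
      utils::write.csv(as.data.frame(tb), path, row.names = FALSE)
    } else {
      jsonlite::write_json(as.data.frame(tb), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
  }
}

#' Simulate a farm population and write it to disk
#'
#' Generates a known-truth population (and, when the spec carries nonzero
#' practice rates, a practice matrix for its efficient farms) and writes the
#' farm table, the truth file (`farm_id`, `te_true`) and the practice matrix
#' as delimited text.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param seed integer seed; defaults to `spec$seed`.
#' @return invisibly, the list from [generate_population()] with an added
#'   `files` element.
#' @export
simulate_farms <- function(spec, dir, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pop <- generate_population(spec, seed = seed)
  ft <- spec$farm_type
  files <- list(farms = file.path(dir, paste0(ft, "_farms.csv")),
                truth = file.path(dir, paste0(ft, "_te_true.csv")))
  write_farm_table(pop$records, files$farms)
  utils::write.csv(data.frame(farm_id = pop$records$farm_id,
                              te_true = pop$te_true),
                   files$truth, row.names = FALSE)
  if (any(spec$practice_rates > 0)) {
    eff_ids <- pop$records$farm_id[pop$te_true >= 1 - 1e-9]
    sel <- generate_practice_matrix(spec, eff_ids, seed = pop$seed)
    files$practices <- file.path(dir, paste0(ft, "_practices.csv"))
    write_practice_matrix(sel, files$practices)
  }
  message(sprintf("[%s] wrote %d farms (seed %s) to %s", ft,
                  nrow(pop$records), format(pop$seed), dir))
  pop$files <- files
  invisible(pop)
}

#' Read a run configuration file
#'
#' YAML key-value configuration for command-line runs. Recognised keys:
#' `input` (farm table path), `farm_type`, `outdir`, `format`, `seed`,
#' `efficiency_eps`, `feasibility_tol`, `slack_normalization`, and
#' `size_schemes` (a map farm_type -> `{small_upper, large_lower}`).
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Execute a configured run
#'
#' Reads the input farm table named by the configuration, applies solver and
#' size-scheme settings, and runs [run_efficiency_analysis()].
#'
#' @param config a `run_config` list from [read_run_config()], or a path.
#' @return the report list, invisibly.
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$input)) stop("config lacks an 'input' path",
                                  call. = FALSE)
  records <- read_farm_table(config$input, farm_type = config$farm_type)
  settings <- solver_settings(
    feasibility_tol = config$feasibility_tol %||% 1e-7,
    efficiency_eps = config$efficiency_eps %||% 1e-6,
    slack_normalization = config$slack_normalization %||% "raw")
  schemes <- NULL
  if (!is.null(config$size_schemes)) {
    schemes <- lapply(names(config$size_schemes), function(ft) {
      sc <- config$size_schemes[[ft]]
      size_class_scheme(ft, sc$small_upper, sc$large_lower)
    })
    names(schemes) <- names(config$size_schemes)
  }
  run_efficiency_analysis(records, settings = settings, schemes = schemes,
                          outdir = config$outdir,
                          format = config$format %||% "csv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
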