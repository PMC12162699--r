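#' The three published models as staged rules
#'
#' Model 1: binary stenosis >= 50% (degenerate band). Model 2: stenosis >=
#' 50% gate with PAV >= 16.8%. Model 3: staged 30-70% band with PAV >=
#' 12.2%.
#'
#' @return named list of [staged_rule()] objects.
#' @export
published_models <- function() {
  list(model1 = staged_rule(50, 0, 0),          # degenerate band = cutoff 50
       model2 = staged_rule(50, Inf, 16.8),
       model3 = staged_rule(30, 70, 12.2))
}

#' Reproduce the published accuracy table from the packaged fixtures
#'
#' Computes the six-row diagnostic-accuracy table (sensitivity, specificity,
#' PPV, NPV, accuracy, AUC) for Models 1-3 from their confusion matrices.
#' Pairwise p-values are reported as `NA`: the paired tests need
#' patient-level classifications, which marginal 2x2 tables cannot provide.
#'
#' @param fixtures named list of [confusion_matrix()] objects (default the
#'   packaged tables from [load_fixture_matrices()]).
#' @param ci_level two-sided confidence level.
#' @return list with `reports` (a [metrics_from_cm()] report per model) and
#'   `table` (a data frame: rounded integer percents, 2-dp AUC, one column
#'   per model).
#' @examples
#' run_table3()$table
#' @export
run_table3 <- function(fixtures = load_fixture_matrices(), ci_level = 0.95) {
  if (!is.list(fixtures) || length(fixtures) == 0L)
    stop_field("fixtures", "must be a non-empty list of confusion matrices")
  reports <- lapply(fixtures, metrics_from_cm, ci_level = ci_level)
  fmt_pct <- function(m) {
    if (is.na(m[["estimate"]])) return(NA_character_)
    sprintf("%d (%d-%d)",
            round_half_up(100 * m[["estimate"]]),
            round_half_up(100 * m[["lower"]]),
            round_half_up(100 * m[["upper"]]))
  }
  fmt_auc <- function(m) sprintf("%.2f (%.2f-%.2f)",
                                 round_half_up(m[["estimate"]], 2),
                                 round_half_up(m[["lower"]], 2),
                                 round_half_up(m[["upper"]], 2))
  rows <- c("Sensitivity", "Specificity", "PPV", "NPV",
            "Diagnostic accuracy", "AUC")
  tab <- data.frame(metric = rows, stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    r <- reports[[nm]]
    tab[[nm]] <- c(fmt_pct(r$sensitivity), fmt_pct(r$specificity),
                   fmt_pct(r$ppv), fmt_pct(r$npv), fmt_pct(r$accuracy),
                   fmt_auc(r$auc))
  }
  list(reports = reports, table = tab, p_values = NA,
       note = "pairwise p-values unavailable from marginal tables")
}

#' Assemble a run configuration for the end-to-end pipeline
#'
#' @param source input source: exactly one of `list(type = "fixtures")`,
#'   `list(type = "csv", path = ...)` or `list(type = "generator", config =
#'   generator_config(...))`.
#' @param rules named list of rules to evaluate ([staged_rule()] objects or
#'   single numeric binary cutoffs); default [published_models()].
#' @param reference name of the reference model for pairwise comparisons.
#' @param ci_level two-sided confidence level.
#' @param run_search run the subgroup Youden search and full grid search
#'   (cohort sources only).
#' @param search_spec a [grid_spec()] for the grid search.
#' @param label label column used for evaluation (`"ischemia"` composite or
#'   `"latent_ischemia"`).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return validated `run_config` list.
#' @export
run_config <- function(source = list(type = "fixtures"),
                       rules = published_models(),
                       reference = names(rules)[1L],
                       ci_level = 0.95,
                       run_search = FALSE,
                       search_spec = grid_spec(),
                       label = "ischemia",
                       out_dir = NULL) {
  if (!is.list(source) || is.null(source$type) ||
      !source$type %in% c("fixtures", "csv", "generator"))
    stop_field("source", "type must be one of fixtures, csv, generator")
  if (source$type == "csv" && is.null(source$path))
    stop_field("source", "csv source needs a path")
  if (source$type == "generator" && is.null(source$config))
    stop_field("source", "generator source needs a generator_config")
  if (!is.list(rules) || length(rules) == 0L || is.null(names(rules)) ||
      any(!nzchar(names(rules))))
    stop_field("rules", "must be a non-empty named list")
  if (!reference %in% names(rules))
    stop_field("reference", "must name one of the rules")
  check_scalar_number(ci_level, "ci_level", lower = 0, upper = 1,
                      open_lower = TRUE, open_upper = TRUE)
  structure(list(source = source, rules = rules, reference = reference,
                 ci_level = ci_level, run_search = isTRUE(run_search),
                 search_spec = search_spec, label = label,
                 out_dir = out_dir),
            class = "run_config")
}

as_rule <- function(r) {
  if (inherits(r, "staged_rule")) r
  else if (is.numeric(r) && length(r) == 1L) staged_rule(r, 0, 0)
  else stop_field("rules", "each rule must be a staged_rule or a numeric cutoff")
}

#' Run the full analysis pipeline
#'
#' Loads or generates the input, evaluates every configured rule against
#' the reference label, runs the pairwise comparison tests against the
#' reference model, optionally runs the subgroup Youden search and the full
#' grid search, and (when `out_dir` is set) writes `report.json`,
#' `report.txt` and a `scatter.csv` export of (stenosis, PAV, label) for
#' external plotting. Fixture input delegates to [run_table3()]: no random
#' state is touched and no pairwise tests are possible.
#'
#' @param config a [run_config()].
#' @return report bundle (list); for cohort input it contains `cohort` size,
#'   per-rule `reports` and `confusions`, `comparisons`, and `search`
#'   results when requested.
#' @export
run_full <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)

  if (config$source$type == "fixtures") {
    out <- run_table3(ci_level = config$ci_level)
    if (!is.null(config$out_dir)) write_bundle(out, config$out_dir)
    return(out)
  }

  cohort <- switch(config$source$type,
                   csv = read_cohort_csv(config$source$path),
                   generator = generate_cohort(config$source$config))
  rules <- lapply(config$rules, as_rule)
  cms <- lapply(rules, function(r) evaluate_rule(cohort, r, config$label))
  reports <- lapply(cms, metrics_from_cm, ci_level = config$ci_level)

  preds <- lapply(rules, function(r)
    classify_staged(cohort$stenosis, cohort$pav, r))
  y <- as.logical(cohort[[config$label]])
  ref <- config$reference
  comparisons <- lapply(setdiff(names(rules), ref), function(nm) {
    pv <- compare_predictive_values(preds[[nm]], preds[[ref]], y)
    list(model = nm, reference = ref,
         sensitivity_p = compare_sensitivity(preds[[nm]], preds[[ref]], y)$p_value,
         specificity_p = compare_specificity(preds[[nm]], preds[[ref]], y)$p_value,
         ppv_p = pv$ppv$p_value, npv_p = pv$npv$p_value,
         auc_p = compare_auc_binary(preds[[nm]], preds[[ref]], y)$p_value)
  })

  search <- NULL
  if (config$run_search) {
    gs <- grid_search_staged(cohort, config$search_spec, config$label)
    sub <- youden_threshold_subgroup(cohort, 50, Inf, label = config$label)
    search <- list(grid = gs, subgroup_ge50 = sub)
  }

  out <- list(n = nrow(cohort),
              label = config$label,
              rules = lapply(rules, rule_to_list),
              confusions = cms,
              reports = reports,
              comparisons = comparisons,
              search = search,
              cohort = cohort)
  if (!is.null(config$out_dir)) write_bundle(out, config$out_dir)
  out
}

write_bundle <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- out
  json$cohort <- NULL
  if (!is.null(json$search)) {
    gs <- json$search$grid
    json$search$grid <- list(best_rule = rule_to_list(gs$best_rule),
                             best_j = gs$best_j,
                             best_cm = unclass(gs$best_cm),
                             n_ties = nrow(gs$ties),
                             grid_evaluated = gs$grid_evaluated)
    json$search$subgroup_ge50$cm <- unclass(json$search$subgroup_ge50$cm)
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w"); on.exit(close(con))
  if (!is.null(out$table)) {
    utils::capture.output(print(out$table), file = con)
  } else {
    for (nm in names(out$reports)) {
      writeLines(sprintf("== %s ==", nm), con)
      utils::capture.output(print(out$reports[[nm]]), file = con)
    }
  }
  if (!is.null(out$cohort))
    utils::write.csv(data.frame(stenosis = out$cohort$stenosis,
                                pav = out$cohort$pav,
                                label = as.integer(out$cohort$ischemia)),
                     file.path(dir, "scatter.csv"), row.names = FALSE)
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort CSV), `evaluate`
#' (evaluate rules on a cohort CSV), `search` (grid search on a cohort CSV),
#' `reproduce-table3` (fixture reproduction of the published accuracy
#' table). Arguments are `--key value` pairs; rules use the compact
#' `lower:upper:pav` form of [parse_rule()].
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
cad_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: stagedcad <simulate|evaluate|search|reproduce-table3> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  status <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- generator_config(
          n_patients = as.integer(opts[["n"]] %||% 2145),
          seed = as.integer(opts[["seed"]] %||% 1))
        write_cohort_csv(generate_cohort(cfg), opts[["out"]] %||% "cohort.csv")
        0L
      },
      evaluate = {
        cohort <- read_cohort_csv(opts[["cohort"]])
        rules <- if (is.null(opts[["rule"]])) published_models()
                 else stats::setNames(list(parse_rule(opts[["rule"]])), "rule")
        cfg <- run_config(source = list(type = "csv", path = opts[["cohort"]]),
                          rules = rules,
                          out_dir = opts[["out"]])
        invisible(run_full(cfg)); 0L
      },
      search = {
        cohort <- read_cohort_csv(opts[["cohort"]])
        res <- grid_search_staged(cohort)
        out <- opts[["out"]] %||% "search.json"
        jsonlite::write_json(list(best_rule = rule_to_list(res$best_rule),
                                  best_j = res$best_j,
                                  best_cm = unclass(res$best_cm),
                                  ties = res$ties,
                                  grid_evaluated = res$grid_evaluated),
                             out, auto_unbox = TRUE, digits = NA)
        0L
      },
      `reproduce-table3` = {
        res <- run_table3()
        if (!is.null(opts[["out"]]))
          utils::write.csv(res$table, opts[["out"]], row.names = FALSE)
        else
          print(res$table)
        0L
      },
      { message("unknown subcommand: ", cmd); 1L })
  }, error = function(e) {
    message("stagedcad error [", cmd, "]: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("expected --key value, got: ", a, call. = FALSE)
    if (i + 1L > length(args)) stop("missing value for ", a, call. = FALSE)
    opts[[substring(a, 3L)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}
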