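#' Pipeline configuration
#'
#' Bundles every clinically meaningful constant of an end-to-end run:
#' gating settings, cohort source, component-table source, margin recipe,
#' probability threshold, output directory and seed.  Can be read from a
#' versioned YAML file via [read_pipeline_config()].
#'
#' @param out_dir output directory for the report bundle.
#' @param component_preset preset name for [make_component_table()], or NULL
#'   when \code{component_table_path} is given.
#' @param component_table_path CSV path of a component table (overrides the
#'   preset).
#' @param cohort_source \code{"table"} (use the component table's random
#'   rows as-is), \code{"simulate"} (replace them with statistics measured
#'   from a synthetic cohort) or a directory of existing log files.
#' @param cohort_size synthetic cohort size (>= 1).
#' @param gating a \code{gating_config}.
#' @param margin_recipe \code{"vanherk"} or \code{"stroom"}.
#' @param prob_threshold_mm threshold for the sub-threshold probability
#'   estimate (mm).
#' @param cohort_params named list of extra arguments forwarded to
#'   [simulate_cohort()] (e.g. motion-model overrides) when
#'   \code{cohort_source = "simulate"}.
#' @param seed integer seed making the whole run reproducible.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            component_preset = "paper_table2",
                            component_table_path = NULL,
                            cohort_source = "table",
                            cohort_size = 30L,
                            gating = gating_config(),
                            margin_recipe = "vanherk",
                            prob_threshold_mm = 1.0,
                            cohort_params = list(),
                            seed = 1L) {
  if (cohort_size < 1L)
    stop_iconqa("cohort_size must be >= 1", "iconqa_config_error")
  if (!cohort_source %in% c("table", "simulate") && !dir.exists(cohort_source))
    stop_iconqa(paste0("cohort_source must be 'table', 'simulate' or an ",
                       "existing log directory; got '", cohort_source, "'"),
                "iconqa_config_error")
  if (!is.null(component_table_path) && !file.exists(component_table_path))
    stop_iconqa(paste0("component table not found: ", component_table_path),
                "iconqa_config_error")
  if (is.null(component_table_path) && is.null(component_preset))
    stop_iconqa("need a component preset or a component table path",
                "iconqa_config_error")
  structure(list(out_dir = out_dir,
                 component_preset = component_preset,
                 component_table_path = component_table_path,
                 cohort_source = cohort_source,
                 cohort_size = as.integer(cohort_size),
                 gating = gating,
                 margin_recipe = match.arg(margin_recipe,
                                           c("vanherk", "stroom")),
                 prob_threshold_mm = prob_threshold_mm,
                 cohort_params = cohort_params,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Schema (version 1): top-level \code{version: 1}, then any of the
#' [pipeline_config()] fields; \code{gating} is a mapping with
#' \code{threshold_mm}, \code{record_trigger_mm}, \code{window_ms}.
#'
#' @param path YAML file path.
#' @param out_dir output directory (overrides the file's value if given).
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$version) || y$version != 1)
    stop_iconqa("config file must declare 'version: 1'",
                "iconqa_config_error")
  gating <- if (is.null(y$gating)) gating_config() else
    gating_config(threshold_mm = y$gating$threshold_mm %||% 1.5,
                  record_trigger_mm = y$gating$record_trigger_mm %||% 0.2,
                  window_ms = y$gating$window_ms %||% 500)
  pipeline_config(
    out_dir = out_dir %||% y$out_dir %||% ".",
    component_preset = y$component_preset %||% "paper_table2",
    component_table_path = y$component_table_path,
    cohort_source = y$cohort_source %||% "table",
    cohort_size = y$cohort_size %||% 30L,
    gating = gating,
    margin_recipe = y$margin_recipe %||% "vanherk",
    prob_threshold_mm = y$prob_threshold_mm %||% 1.0,
    cohort_params = y$cohort_params %||% list(),
    seed = y$seed %||% 1L)
}

#' Run the end-to-end uncertainty pipeline
#'
#' Loads (or simulates) the inputs, assembles the component table, combines
#' it into an uncertainty budget, estimates the probability that the total
#' vector uncertainty stays below the configured threshold, evaluates the
#' configured setup-margin recipe per axis, and writes the report bundle
#' (\code{budget.csv}, \code{budget.json}, \code{budget.md},
#' \code{report.json}, and, when a cohort is analysed,
#' \code{sessions.csv}).  Fully reproducible: the same config and seed
#' yield byte-identical JSON output.
#'
#' The sub-threshold probability needs the SD of the total vector
#' uncertainty, which is not derivable from component summaries; it is
#' taken from the table's reference totals when present (the
#' \code{paper_table2} preset carries them) and reported as NA otherwise.
#'
#' @param config a \code{pipeline_config}.
#' @return (invisibly) list with \code{budget}, \code{prob},
#'   \code{margins}, \code{cohort} (NULL unless simulated/ingested) and
#'   \code{files}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_iconqa("config must be a pipeline_config", "iconqa_config_error")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  components <- if (!is.null(config$component_table_path))
    read_component_table(config$component_table_path)
  else
    make_component_table(config$component_preset, seed = config$seed,
                         quiet = FALSE)
  ref <- attr(components, "reference_totals")

  cohort <- NULL
  if (!identical(config$cohort_source, "table")) {
    log_dir <- if (identical(config$cohort_source, "simulate")) {
      d <- file.path(config$out_dir, "logs")
      do.call(simulate_cohort,
              c(list(dir = d, n_sessions = config$cohort_size,
                     gating = config$gating, seed = config$seed),
                config$cohort_params))
      d
    } else config$cohort_source
    files <- list.files(log_dir, pattern = "\\.(csv|log)$", full.names = TRUE)
    if (length(files) == 0L)
      stop_iconqa(paste0("no log files found in ", log_dir),
                  "iconqa_config_error")
    sessions <- lapply(files, parse_hdmm_log)
    aucs <- lapply(sessions, session_auc)
    motion_row <- cohort_summary(aucs)
    residual_row <- post_cbct_residuals(sessions)
    # measured random rows replace any table-supplied random rows
    components <- as_component_table(rbind(
      components[components$error_type == "systematic", , drop = FALSE],
      residual_row, motion_row))
    cohort <- data.frame(
      session_id = vapply(sessions, `[[`, character(1), "id"),
      mean_x_mm = vapply(aucs, `[[`, numeric(1), "mean_x_mm"),
      mean_y_mm = vapply(aucs, `[[`, numeric(1), "mean_y_mm"),
      mean_z_mm = vapply(aucs, `[[`, numeric(1), "mean_z_mm"),
      mean_radial_mm = vapply(aucs, `[[`, numeric(1), "mean_radial_mm"),
      treating_s = vapply(aucs, `[[`, numeric(1), "treating_duration_s"),
      stringsAsFactors = FALSE)
  }

  budget <- uncertainty_budget(components)
  tot <- budget$totals[budget$totals$error_type == "combined", ]
  total_sd <- if (!is.null(ref))
    ref$vec_sd[ref$error_type == "combined"] else NA_real_
  total_mean <- if (!is.null(ref))
    ref$vec_mean[ref$error_type == "combined"] else tot$vec_mean
  prob <- if (is.na(total_sd)) NA_real_ else
    prob_below(config$prob_threshold_mm, total_mean, total_sd)

  sys <- budget$totals[budget$totals$error_type == "systematic", ]
  ran <- budget$totals[budget$totals$error_type == "random", ]
  margins <- setup_margin(
    config$margin_recipe,
    Sigma_mm = c(x = sys$x_sd, y = sys$y_sd, z = sys$z_sd),
    sigma_mm = c(x = ran$x_sd, y = ran$y_sd, z = ran$z_sd))

  files <- c(budget_csv = file.path(config$out_dir, "budget.csv"),
             budget_json = file.path(config$out_dir, "budget.json"),
             budget_md = file.path(config$out_dir, "budget.md"),
             report_json = file.path(config$out_dir, "report.json"))
  writeLines(render_report(budget, "csv"), files[["budget_csv"]])
  writeLines(render_report(budget, "json"), files[["budget_json"]])
  writeLines(render_report(budget, "markdown"), files[["budget_md"]])
  report <- list(
    seed = config$seed,
    total_vector_mean_mm = tot$vec_mean,
    total_vector_sd_mm = total_sd,
    prob_threshold_mm = config$prob_threshold_mm,
    prob_below_threshold = prob,
    margin_recipe = config$margin_recipe,
    margin_mm = as.list(round(margins$margin_mm, 6)))
  jsonlite::write_json(report, files[["report_json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(cohort)) {
    f <- file.path(config$out_dir, "sessions.csv")
    utils::write.csv(cohort, f, row.names = FALSE)
    files <- c(files, sessions_csv = f)
  }
  invisible(list(budget = budget, prob = prob, margins = margins,
                 cohort = cohort, files = files))
}

#' Render an uncertainty budget
#'
#' @param budget an \code{uncertainty_budget}.
#' @param format \code{"markdown"} (display table, numbers as
#'   \code{"mean (SD)"} rounded half-up to 2 decimals), \code{"csv"} or
#'   \code{"json"} (full-precision values; these two round-trip exactly).
#' @return character vector of document lines.
#' @export
render_report <- function(budget, format = c("markdown", "csv", "json")) {
  format <- match.arg(format)
  if (!inherits(budget, "uncertainty_budget"))
    stop_iconqa("budget must be an uncertainty_budget",
                "iconqa_validation_error")
  if (nrow(budget$components) == 0L)
    stop_iconqa("budget has no components", "iconqa_validation_error")
  all_rows <- rbind(budget$components, budget$totals)
  if (format == "csv")
    return(utils::capture.output(
      utils::write.csv(all_rows, row.names = FALSE, na = "")))
  if (format == "json")
    return(jsonlite::toJSON(list(components = budget$components,
                                 totals = budget$totals),
                            dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, na = "null", pretty = TRUE))
  fmt_pair <- function(m, s) ifelse(
    is.na(m), "NA",
    sprintf("%.2f (%s)", round_half_up(m),
            ifelse(is.na(s), "-", sprintf("%.2f", round_half_up(s)))))
  md <- data.frame(
    Source = all_rows$name,
    x = fmt_pair(all_rows$x_mean, all_rows$x_sd),
    y = fmt_pair(all_rows$y_mean, all_rows$y_sd),
    z = fmt_pair(all_rows$z_mean, all_rows$z_sd),
    `Total vector mean` = fmt_pair(all_rows$vec_mean, all_rows$vec_sd),
    `Error type` = all_rows$error_type,
    check.names = FALSE, stringsAsFactors = FALSE)
  widths <- vapply(names(md), function(cn) max(nchar(c(cn, md[[cn]]))),
                   numeric(1))
  pad <- function(v, w) formatC(v, width = w, flag = "-")
  line <- function(cells) paste0("| ", paste(mapply(pad, cells, widths),
                                             collapse = " | "), " |")
  c(line(names(md)),
    line(vapply(widths, function(w) strrep("-", w), character(1))),
    apply(md, 1, line))
}
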