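#' Run the full analysis pipeline
#'
#' Ties the stages together: simulate (or load) band matrices, score
#' genotoxicity on the RAPD view, type methylation on the CRED-RA view,
#' and write the report artifacts into `out_dir`:
#'
#' * `genotox.tsv` — per-sample/per-primer polymorphism and GTS table;
#' * `methylation.tsv` — per-sample type percentages and pattern ratios;
#' * `methylation_wide.tsv` — the published wide layout, rounded half-up
#'   to 2 decimals;
#' * `summary.json` — the canonical machine-readable summary: tool
#'   version, seed, input checksums, and every percentage both unrounded
#'   and rounded (rounding happens only at this view layer).
#'
#' @param config `NULL` (simulate under the default [sim_config()]), a
#'   `sim_config`, a list of [sim_config()] arguments, or the path to a
#'   YAML file of such arguments. Alternatively supply `rapd`/`credra`
#'   paths to analyze already-scored matrices.
#' @param out_dir output directory, created if missing.
#' @param seed overrides the config seed when not `NULL`.
#' @param rapd,credra optional paths to existing band-matrix TSVs; when
#'   given, no simulation is run and these are the inputs.
#' @param genotox_mode `"pooled"` or `"per-primer"` (see [genotox_table()]).
#' @param methylation_mode `"average"` or `"pooled"` (see
#'   [methylation_table()]).
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL,
                         rapd = NULL, credra = NULL,
                         genotox_mode = c("pooled", "per-primer"),
                         methylation_mode = c("average", "pooled")) {
  genotox_mode <- match.arg(genotox_mode)
  methylation_mode <- match.arg(methylation_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_credra(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)), "credra_stage_error"))
  }
  inputs <- list()
  if (!is.null(rapd) || !is.null(credra)) {
    for (p in c(rapd, credra)) if (!file.exists(p))
      abort_credra(sprintf("input file not found: %s", p), "credra_io_error")
    rapd_m <- if (!is.null(rapd)) stage("read-rapd", read_band_matrix(rapd))
    credra_m <- if (!is.null(credra))
      stage("read-credra", read_band_matrix(credra, assay = "CREDRA"))
    if (is.null(rapd_m) && !is.null(credra_m)) rapd_m <- as_rapd(credra_m)
    inputs <- as.list(tools::md5sum(c(rapd, credra)))
    used_seed <- seed
  } else {
    cfg <- stage("config", resolve_sim_config(config))
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    used_seed <- cfg$seed
    sim <- stage("simulate", simulate_experiment(cfg, file.path(out_dir, "sim")))
    rapd_m <- sim$rapd
    credra_m <- sim$credra
    inputs <- as.list(tools::md5sum(unlist(sim$paths)))
  }
  gt <- stage("genotox", genotox_table(rapd_m, mode = genotox_mode))
  mt <- if (!is.null(credra_m))
    stage("methylation", methylation_table(credra_m, mode = methylation_mode))
  utils::write.table(gt, file.path(out_dir, "genotox.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(mt)) {
    utils::write.table(mt, file.path(out_dir, "methylation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(format_methylation_table(mt),
                       file.path(out_dir, "methylation_wide.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rounded <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !names(df) %in% c("dose_mg_per_L", "a", "n", "appeared", "disappeared",
                        "n_bands", "n_unclassifiable")
    df[num] <- lapply(df[num], round_half_up, digits = 2)
    df
  }
  summary <- list(
    tool = "credra", version = as.character(utils::packageVersion("credra")),
    seed = used_seed, input_md5 = inputs,
    genotox = list(unrounded = gt, rounded = rounded(gt)),
    methylation = if (!is.null(mt))
      list(unrounded = mt, rounded = rounded(mt)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(summary)
}

resolve_sim_config <- function(config) {
  if (is.null(config)) return(sim_config())
  if (inherits(config, "sim_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      abort_credra(sprintf("config file not found: %s", config),
                   "credra_io_error")
    config <- yaml::read_yaml(config)
    if (!is.null(config$state_probs))
      config$state_probs <- matrix(
        unlist(config$state_probs), ncol = 4, byrow = TRUE,
        dimnames = list(NULL, c("U", "HE", "IF", "FF")))
  }
  if (!is.list(config))
    abort_credra("config must be NULL, a sim_config, a list or a YAML path",
                 "credra_config_error")
  do.call(sim_config, config)
}

#' Render report figures
#'
#' Two ggplot2 charts from a [methylation_table()] data.frame (or a
#' pipeline summary containing one): a grouped-bar chart of the four type
#' percentages by dose, and a line chart of the total/full/semi pattern
#' ratios by dose. Plotting failures warn and are skipped rather than
#' aborting a report run.
#'
#' @param summary a [methylation_table()] data.frame, or the list returned
#'   by [run_pipeline()].
#' @param out_dir directory for the PNG files.
#' @return character vector of the files actually written (empty, with a
#'   warning, when there is nothing to plot).
#' @export
render_figures <- function(summary, out_dir) {
  if (is.list(summary) && !is.data.frame(summary))
    summary <- summary$methylation$unrounded
  if (is.null(summary) || !nrow(summary)) {
    warning("empty methylation summary; no figures rendered")
    return(character(0))
  }
  if (is.list(summary) && !is.data.frame(summary))
    summary <- as.data.frame(summary)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary$sample <- factor(summary$sample_id,
                           levels = summary$sample_id[order(summary$dose_mg_per_L)])
  types <- do.call(rbind, lapply(c("type_I", "type_II", "type_III", "type_IV"),
    function(col) data.frame(sample = summary$sample,
                             type = sub("type_", "Type ", col),
                             percent = summary[[col]])))
  ratios <- do.call(rbind, lapply(c("total", "full", "semi"), function(col)
    data.frame(sample = summary$sample, ratio = col,
               percent = summary[[col]])))
  written <- character(0)
  emit <- function(plot, file) {
    path <- file.path(out_dir, file)
    ok <- tryCatch({
      ggplot2::ggsave(path, plot, width = 7, height = 4.5, dpi = 150)
      TRUE
    }, error = function(e) {
      warning(sprintf("could not render %s: %s", file, conditionMessage(e)))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }
  emit(
    ggplot2::ggplot(types, ggplot2::aes(x = .data$sample, y = .data$percent,
                                        fill = .data$type)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "share of classifiable bands (%)",
                    fill = NULL, title = "Methylation types by dose") +
      ggplot2::theme_minimal(),
    "methylation_types.png")
  emit(
    ggplot2::ggplot(ratios, ggplot2::aes(x = .data$sample, y = .data$percent,
                                         colour = .data$ratio,
                                         group = .data$ratio)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = NULL, y = "pattern ratio (%)", colour = NULL,
                    title = "Methylation patterns by dose") +
      ggplot2::theme_minimal(),
    "methylation_patterns.png")
  written
}
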