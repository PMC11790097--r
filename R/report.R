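#' Render a plain-text + figure report for a training run
#'
#' Writes a deterministic set of files into `dir`: `report.md` (reward
#' summary, selection distribution, metric table), `history.tsv`,
#' `reward_trace.pdf`, `selection_hist.pdf`, and optionally one example
#' scalogram figure per class.  Returns the file list for the run
#' manifest.
#'
#' @param history iteration-history tibble of an `rlwbs_fit`.
#' @param metrics an `rlwbs_metrics` report.
#' @param family_distribution tibble from [evaluate_policy()].
#' @param dir output directory (created if missing).
#' @param scalograms optional named list of `scalogram` objects to plot.
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(history, metrics, family_distribution, dir,
                          scalograms = NULL) {
  if (nrow(history) == 0) stopf("history is empty")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  md <- file.path(dir, "report.md")
  r <- history$reward
  lines <- c(
    "# Wavelet base selection - training report", "",
    sprintf("- iterations: %d", nrow(history)),
    sprintf("- final reward: %.6f", r[length(r)]),
    sprintf("- mean reward (last 10): %.6f", mean(utils::tail(r, 10))),
    sprintf("- best reward: %.6f", max(r)), "",
    "## Greedy selection by wavelet family", "",
    sprintf("- %s: %.2f%%", family_distribution$family,
            family_distribution$share), "",
    "## Evaluation metrics", "",
    utils::capture.output(as.data.frame(tidy.rlwbs_metrics(metrics)))
  )
  writeLines(lines, md)
  files <- c(files, md)

  hist_path <- file.path(dir, "history.tsv")
  write_history(history, hist_path)
  files <- c(files, hist_path)

  trace_path <- file.path(dir, "reward_trace.pdf")
  fit_like <- structure(list(history = history), class = "rlwbs_fit")
  ggplot2::ggsave(trace_path, autoplot.rlwbs_fit(fit_like),
                  width = 6, height = 3.5)
  files <- c(files, trace_path)

  sel_path <- file.path(dir, "selection_hist.pdf")
  ggplot2::ggsave(sel_path, plot_selection_histogram(family_distribution),
                  width = 5, height = 3.5)
  files <- c(files, sel_path)

  for (nm in names(scalograms)) {
    p <- file.path(dir, sprintf("scalogram_%s.pdf", nm))
    ggplot2::ggsave(p, autoplot.scalogram(scalograms[[nm]]),
                    width = 6, height = 3.5)
    files <- c(files, p)
  }
  invisible(files)
}

#' Write a run manifest
#'
#' The manifest records everything needed to replay a run: the full
#' configuration and synthetic-data specification, the seeds, the catalog
#' hash, and the paths of all artifacts produced.
#'
#' @param dir run directory.
#' @param training a [training_config()].
#' @param synthetic a [synthetic_spec()] (or `NULL` for external data).
#' @param catalog the `wavelet_catalog` used.
#' @param files character vector of produced artifact paths.
#' @param extra named list of additional fields (e.g. dataset seed).
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, training, synthetic, catalog, files,
                           extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("rlwbs")),
    catalog_hash = catalog$hash,
    training = unclass(training),
    synthetic = if (!is.null(synthetic)) unclass(synthetic),
    files = as.list(files)
  ), extra)
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Replay a run from its manifest
#'
#' Regenerates the dataset from the manifest's synthetic specification and
#' seed, rebuilds the catalog and feature store, and reruns training with
#' the recorded configuration.  With unchanged code this reproduces the
#' reward history exactly.
#'
#' @param manifest_path path to a `manifest.yml` written by
#'   [write_manifest()].
#' @return an `rlwbs_fit`.
#' @export
replay_run <- function(manifest_path) {
  m <- yaml::read_yaml(manifest_path)
  if (is.null(m$synthetic))
    stopf("manifest has no synthetic specification; replay needs one")
  sy <- m$synthetic
  sy$classes <- lapply(sy$classes, function(cl) {
    cl$scale_range <- as.numeric(cl$scale_range)
    cl
  })
  spec_args <- sy[intersect(names(sy), names(formals(synthetic_spec)))]
  spec <- do.call(synthetic_spec, spec_args)
  tr <- m$training[intersect(names(m$training),
                             names(formals(training_config)))]
  config <- do.call(training_config, tr)
  dataset <- generate_dataset(spec,
                              n_per_class = m$n_per_class %||% 120,
                              seed = m$dataset_seed %||% 1)
  catalog <- build_catalog()
  if (!identical(catalog$hash, m$catalog_hash))
    stopf("catalog hash mismatch: manifest %s vs current %s",
          m$catalog_hash, catalog$hash)
  run_training(dataset, catalog, config)
}
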