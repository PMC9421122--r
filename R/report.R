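#' Tidiers for experiment results
#'
#' `tidy()` returns the per-arm, per-fold metric table; `glance()` the
#' per-arm mean and 95% CI summaries (long format, one row per arm and
#' metric).
#'
#' @param x a `pcg_experiment` from [run_experiment()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.pcg_experiment <- function(x, ...) x$metrics

#' @rdname tidy.pcg_experiment
#' @export
glance.pcg_experiment <- function(x, ...) x$summary

#' Plot per-arm metric summaries
#'
#' Mean and 95% CI of the selected metrics by arm, with the baseline mean
#' as a dashed reference line.
#'
#' @param object a `pcg_experiment`.
#' @param metrics metric names to show (default ROC AUC and PR AUC).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pcg_experiment <- function(object,
                                    metrics = c("roc_auc", "pr_auc"), ...) {
  d <- filter(object$summary, .data$metric %in% metrics)
  base <- filter(d, .data$arm == "0")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$mean),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "experiment arm", y = "metric (mean ± 95% CI)") +
    ggplot2::theme_minimal()
}

#' Plot ROC or PR curves per arm
#'
#' One panel per arm with each fold's curve and the no-discrimination
#' reference (the diagonal for ROC; the positive prevalence for PR).
#'
#' @param report a `pcg_experiment`.
#' @param which `"roc"` or `"pr"`.
#' @return a ggplot object.
#' @export
plot_curves <- function(report, which = c("roc", "pr")) {
  which <- match.arg(which)
  d <- filter(report$curves, .data$curve == which)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$fold)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~arm) +
    ggplot2::theme_minimal()
  if (which == "roc") {
    p + ggplot2::geom_abline(slope = 1, intercept = 0,
                             linetype = "dotted", colour = "red") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate")
  } else {
    prev <- mean(report$manifest$label == 1)
    p + ggplot2::geom_hline(yintercept = prev,
                            linetype = "dotted", colour = "red") +
      ggplot2::labs(x = "recall", y = "precision")
  }
}

#' Write the experiment report to disk
#'
#' Produces `metrics.csv` (per arm and fold), `summary.csv` (per-arm means
#' with CIs), `comparisons.csv` (fold-paired mean differences vs. the
#' baseline with 95% CIs), a machine-readable `report.json` twin, and ROC /
#' PR curve figures.
#'
#' @param report a `pcg_experiment`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(report$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(report$comparisons)) {
    write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(
      seed = report$config$seed,
      k = attr(report$fold_plan, "k"),
      fold_hash = report$fold_hash,
      arm_fold_hashes = as.list(report$arm_fold_hashes),
      model_spec_hash = report$model_spec_hash,
      n_records = nrow(report$manifest),
      class_counts = as.list(table(report$manifest$label)),
      metrics = report$metrics,
      summary = report$summary,
      comparisons = report$comparisons,
      runtime_s = report$runtime_s
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (w in c("roc", "pr")) {
    ggplot2::ggsave(file.path(dir, paste0(w, "_curves.png")),
                    plot_curves(report, w), width = 9, height = 7, dpi = 120)
  }
  invisible(dir)
}

#' Read back a written report
#'
#' @param dir directory written by [write_report()].
#' @return a list with `metrics`, `summary`, `comparisons` tibbles and the
#'   header fields of `report.json`.
#' @export
read_report <- function(dir) {
  j <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  j$metrics <- as_tibble(j$metrics)
  j$summary <- as_tibble(j$summary)
  if (!is.null(j$comparisons)) j$comparisons <- as_tibble(j$comparisons)
  j
}
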