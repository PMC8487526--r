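# Graphical and tabular reports: MAE boxplots by method (colored by the
# omic(s) used), heatmaps of matched proportion estimates and of their
# absolute errors, leaderboard and records as CSV.

save_plot_both <- function(plot, stem, width = 7, height = 4.5) {
  ggplot2::ggsave(paste0(stem, ".pdf"), plot, width = width, height = height)
  ggplot2::ggsave(paste0(stem, ".png"), plot, width = width, height = height,
                  dpi = 150)
}

heatmap_both <- function(mat, stem, main, breaks = NULL) {
  for (ext in c("pdf", "png"))
    pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                       main = main, breaks = breaks,
                       filename = paste0(stem, ".", ext),
                       width = 7, height = 3)
}

#' Render figures and tables for a benchmark report
#'
#' Writes, under `out_dir`: `figures/mae_boxplot.{pdf,png}` (matched-MAE
#' boxplots per method, colored by the omic(s) each method uses), per-method
#' `figures/a_est_<method>.{pdf,png}` (heatmap of a matched proportion
#' estimate, cell populations in rows and samples in columns) and
#' `figures/abs_error_<method>.{pdf,png}` (entrywise `|A_est - A_true|`),
#' plus `leaderboard.csv`, `records.csv` and `report.json`.
#'
#' @param report a `score_report` with at least one successful record and
#'   (for the heatmaps) kept estimates.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "score_report"))
  ok <- report$records[report$records$status == "ok", , drop = FALSE]
  if (!nrow(ok)) stop("report contains no successful record", call. = FALSE)
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  lb <- make_leaderboard(report)
  ok$method_id <- factor(ok$method_id, levels = lb$method_id)
  bp <- ggplot2::ggplot(ok, ggplot2::aes(x = .data$method_id,
                                         y = .data$matched_mae,
                                         fill = .data$modality_use)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_fill_manual(values = c(rna = "#E8C547", dnam = "#4C9BD6",
                                          both = "#63B179"),
                               name = "data used") +
    ggplot2::labs(x = NULL, y = "matched MAE on A") +
    ggplot2::theme_bw()
  save_plot_both(bp, file.path(fig_dir, "mae_boxplot"))
  paths <- c(paths, file.path(fig_dir, paste0("mae_boxplot.",
                                              c("pdf", "png"))))

  for (m in levels(ok$method_id)) {
    rec_id <- ok$record_id[ok$method_id == m][1]
    det <- report$details[[rec_id]]
    if (is.null(det$a_est_matched)) next
    est <- det$a_est_matched
    dimnames(est) <- list(det$cell_types, det$sample_ids)
    stem <- file.path(fig_dir, paste0("a_est_", m))
    heatmap_both(est, stem, paste0(m, ": matched A estimate"),
                 breaks = seq(0, 1, length.out = 101))
    err <- abs(det$a_est_matched - det$a_true)
    dimnames(err) <- dimnames(est)
    stem2 <- file.path(fig_dir, paste0("abs_error_", m))
    heatmap_both(err, stem2, paste0(m, ": |A_est - A_true|"))
    paths <- c(paths, paste0(stem, c(".pdf", ".png")),
               paste0(stem2, c(".pdf", ".png")))
  }

  lb_path <- file.path(out_dir, "leaderboard.csv")
  utils::write.csv(lb, lb_path, row.names = FALSE)
  rec_path <- file.path(out_dir, "records.csv")
  utils::write.csv(report$records, rec_path, row.names = FALSE)
  json_path <- file.path(out_dir, "report.json")
  write_score_report(report, json_path)
  invisible(c(paths, lb_path, rec_path, json_path))
}
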