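# The replicated benchmark protocol: every method x dataset x run with
# deterministically derived seeds, permutation-matched MAE scoring, per-method
# aggregates, and the leaderboard.

new_score_report <- function(records, details, aggregates, config) {
  structure(list(records = records, details = details,
                 aggregates = aggregates, config = config),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %d records (%d ok, %d failed), %d methods\n",
              nrow(x$records), sum(x$records$status == "ok"),
              sum(x$records$status == "failed"),
              length(unique(x$records$method_id))))
  invisible(x)
}

aggregate_records <- function(records) {
  ok <- records[records$status == "ok", , drop = FALSE]
  methods <- unique(records$method_id)
  do.call(rbind, lapply(methods, function(m) {
    r <- ok[ok$method_id == m, , drop = FALSE]
    data.frame(method_id = m,
               modality_use = records$modality_use[
                 match(m, records$method_id)],
               n_ok = nrow(r),
               n_failed = sum(records$method_id == m &
                                records$status == "failed"),
               mean_mae = if (nrow(r)) mean(r$matched_mae) else NA_real_,
               sd_mae = if (nrow(r) > 1) stats::sd(r$matched_mae)
                        else NA_real_,
               median_mae = if (nrow(r)) stats::median(r$matched_mae)
                            else NA_real_,
               mean_elapsed = if (nrow(r)) mean(r$elapsed_seconds)
                              else NA_real_)
  }))
}

#' Run the replicated deconvolution benchmark
#'
#' Runs every method `n_runs` times on every dataset (seeds derived
#' deterministically from `root_seed`, so the sweep is bit-reproducible apart
#' from wall-clock fields), scores each run by permutation-matched MAE
#' against the dataset's hidden truth, and aggregates per method. A failing
#' run is recorded with `status = "failed"` and never aborts the sweep.
#'
#' @param methods list of [method_spec()] objects.
#' @param datasets list of [benchmark_dataset] objects carrying truth.
#' @param n_runs runs per method x dataset (default 5).
#' @param root_seed root seed of the sweep.
#' @param k number of components requested from every method.
#' @param keep_estimates keep each run's matched proportion estimate (needed
#'   for the heatmap reports).
#' @return a `score_report`: `$records` (one row per run), `$details`
#'   (matching permutation, per-cell-type errors, optional estimates),
#'   `$aggregates` (per-method summary), `$config` (protocol snapshot).
#' @export
run_benchmark <- function(methods, datasets, n_runs = 5, root_seed = 1L,
                          k = 5, keep_estimates = TRUE) {
  stopifnot(length(methods) >= 1, length(datasets) >= 1, n_runs >= 1)
  for (ds in datasets) if (!has_truth(ds))
    stop("all benchmark datasets must carry ground truth", call. = FALSE)
  rows <- list(); details <- list()
  for (spec in methods) {
    for (di in seq_along(datasets)) {
      ds <- datasets[[di]]
      for (ri in seq_len(n_runs)) {
        run_seed <- derive_seed(root_seed, spec$method_id, di, ri)
        rec_id <- sprintf("%s.d%02d.r%d", spec$method_id, di, ri)
        res <- tryCatch(run_baseline(spec, ds, k = k, seed = run_seed),
                        error = function(e) e)
        if (inherits(res, "error")) {
          rows[[rec_id]] <- data.frame(
            record_id = rec_id, method_id = spec$method_id,
            modality_use = spec$modality_use, dataset_index = di,
            run_index = ri, run_seed = run_seed, matched_mae = NA_real_,
            elapsed_seconds = NA_real_, status = "failed",
            error_message = conditionMessage(res))
          details[[rec_id]] <- list(error = conditionMessage(res))
          next
        }
        sc <- matched_mae(res$a_est, ds$a_true)
        matched <- res$a_est$values[sc$permutation, , drop = FALSE]
        per_ct <- rowMeans(abs(matched - ds$a_true$values))
        names(per_ct) <- ds$a_true$row_labels
        rows[[rec_id]] <- data.frame(
          record_id = rec_id, method_id = spec$method_id,
          modality_use = spec$modality_use, dataset_index = di,
          run_index = ri, run_seed = run_seed, matched_mae = sc$mae,
          elapsed_seconds = res$elapsed_seconds, status = "ok",
          error_message = NA_character_)
        details[[rec_id]] <- list(
          permutation = sc$permutation, per_cell_type_abs_error = per_ct,
          a_est_matched = if (keep_estimates) matched else NULL,
          a_true = if (keep_estimates) ds$a_true$values else NULL,
          cell_types = ds$a_true$row_labels,
          sample_ids = ds$a_true$sample_ids)
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  new_score_report(records, details, aggregate_records(records),
                   config = list(root_seed = root_seed, n_runs = n_runs,
                                 k = k, n_datasets = length(datasets),
                                 methods = vapply(methods, `[[`,
                                                  character(1), "method_id")))
}

#' Build the leaderboard from a score report
#'
#' Methods are ranked by ascending mean matched MAE over their successful
#' runs; ties are broken by sd, then method id. Methods with no successful
#' run are ranked last and flagged. Elapsed time is informational only and
#' never enters the ranking.
#'
#' @param report a `score_report`.
#' @return a data.frame with columns rank, method_id, modality_use, mean_mae,
#'   sd_mae, mean_elapsed, n_ok, n_failed, status.
#' @export
make_leaderboard <- function(report) {
  stopifnot(inherits(report, "score_report"))
  ag <- report$aggregates
  if (!nrow(ag)) stop("empty report", call. = FALSE)
  ag$status <- ifelse(ag$n_ok > 0, "ok", "all_failed")
  key_mean <- ifelse(is.na(ag$mean_mae), Inf, ag$mean_mae)
  key_sd <- ifelse(is.na(ag$sd_mae), Inf, ag$sd_mae)
  ord <- order(key_mean, key_sd, ag$method_id)
  lb <- ag[ord, c("method_id", "modality_use", "mean_mae", "sd_mae",
                  "mean_elapsed", "n_ok", "n_failed", "status")]
  lb <- cbind(rank = seq_len(nrow(lb)), lb)
  rownames(lb) <- NULL
  lb
}

#' Write or read a score report as JSON
#'
#' On read, per-method aggregates are recomputed from the raw records and
#' checked against the stored ones.
#'
#' @param report a `score_report`.
#' @param path JSON file path.
#' @return `write_score_report`: the path, invisibly; `read_score_report`:
#'   the `score_report`.
#' @export
write_score_report <- function(report, path) {
  stopifnot(inherits(report, "score_report"))
  payload <- list(records = report$records, aggregates = report$aggregates,
                  config = report$config,
                  details = lapply(report$details, function(d)
                    d[setdiff(names(d), c("a_est_matched", "a_true"))]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_score_report
#' @export
read_score_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  records <- as.data.frame(p$records)
  stored <- as.data.frame(p$aggregates)
  recomputed <- aggregate_records(records)
  m <- match(stored$method_id, recomputed$method_id)
  for (col in c("mean_mae", "sd_mae", "median_mae")) {
    diff <- abs(stored[[col]] - recomputed[[col]][m])
    if (any(diff > 1e-8, na.rm = TRUE))
      stop("stored aggregates do not match recomputation from records",
           call. = FALSE)
  }
  new_score_report(records, p$details, recomputed, p$config)
}
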