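# The baseline deconvolution pipelines: compositions of feature selection,
# deconvolution and multi-omic integration, plus the external-program
# adapter that runs an arbitrary submitted method on a truth-hidden bundle.

BASELINE_IDS <- c("r_WIC", "r_WNM", "m_EDC", "m_MDC", "m_WIC",
                  "b_WIC", "b_COM", "b_MEA", "ref_OLS", "ref_RLR",
                  "external")

MODALITY_USE <- c(r_WIC = "rna", r_WNM = "rna", m_EDC = "dnam",
                  m_MDC = "dnam", m_WIC = "dnam", b_WIC = "both",
                  b_COM = "both", b_MEA = "both", ref_OLS = "rna",
                  ref_RLR = "rna", external = "both")

#' List the built-in baseline method identifiers
#'
#' @return character vector of valid `method_id`s, with their modality use as
#'   names attribute accessible via [method_spec()].
#' @export
baseline_methods <- function() BASELINE_IDS

#' Specify a deconvolution method for the benchmark
#'
#' The eight reference-free baselines combine three building blocks:
#' ICA-stability gene selection, the most-variable-probe filter, and one of
#' the deconvolution engines (weighted ICA, sparse NMF, constrained NMF,
#' regularized constrained NMF); the `b_*` methods integrate transcriptome
#' and methylome estimates by warm-starting or component-matched averaging.
#' `ref_OLS` / `ref_RLR` are reference-based regressions requiring the
#' dataset's reference profiles, and `external` wraps a user-supplied
#' program.
#'
#' @param method_id one of [baseline_methods()].
#' @param ica_sel an [ica_selection_config()] for the ICA gene-selection
#'   stage (duplicate policy is overridden per method).
#' @param nmf an [nmf_config()] for the NMF stages.
#' @param ica_decon an [ica_decon_config()] for the weighted-ICA stages.
#' @param n_var_probes size of the most-variable-probe filter (default 5000).
#' @param filter_probes_for_ica apply the probe filter before weighted ICA on
#'   methylation (`m_WIC`/`b_WIC`); default `TRUE`.
#' @param prematch_start_a for `b_COM`: row-match the RNA-derived `A` to a
#'   preliminary DNAm fit before using it as warm start, instead of passing
#'   it as-is (default `FALSE`: both factorizations are anonymous, so the
#'   matching happens implicitly through the optimization).
#' @param external_command command template for `external`, with placeholders
#'   `{rna}`, `{met}`, `{k}`, `{out}`.
#' @param external_timeout timeout in seconds for the external program.
#' @return a `method_spec` list with `modality_use` filled in.
#' @export
method_spec <- function(method_id, ica_sel = ica_selection_config(),
                        nmf = nmf_config(), ica_decon = ica_decon_config(),
                        n_var_probes = 5000, filter_probes_for_ica = TRUE,
                        prematch_start_a = FALSE, external_command = NULL,
                        external_timeout = 600) {
  if (!method_id %in% BASELINE_IDS)
    stop("unknown method_id '", method_id, "'; valid ids: ",
         paste(BASELINE_IDS, collapse = ", "), call. = FALSE)
  if (method_id == "external" && is.null(external_command))
    stop("external method needs an external_command template", call. = FALSE)
  structure(list(method_id = method_id,
                 modality_use = unname(MODALITY_USE[method_id]),
                 ica_sel = ica_sel, nmf = nmf, ica_decon = ica_decon,
                 n_var_probes = n_var_probes,
                 filter_probes_for_ica = isTRUE(filter_probes_for_ica),
                 prematch_start_a = isTRUE(prematch_start_a),
                 external_command = external_command,
                 external_timeout = external_timeout),
            class = "method_spec")
}

# --- single-omic stage helpers -------------------------------------------

stage_rna_ica_selection <- function(ds, spec, seed, keep_duplicates) {
  cfg <- spec$ica_sel
  cfg$keep_duplicates <- keep_duplicates
  cfg$seed <- seed
  sel <- ica_stability_selection(ds$d_rna, cfg)
  if (!length(sel$indices))
    stop("ICA feature selection returned no genes", call. = FALSE)
  list(sel = sel, d = apply_selection(ds$d_rna, sel))
}

stage_met_filter <- function(ds, spec) {
  sel <- select_most_variable(ds$d_met, spec$n_var_probes)
  list(sel = sel, d = apply_selection(ds$d_met, sel))
}

run_rna_wic <- function(ds, spec, k, seed) {
  st <- stage_rna_ica_selection(ds, spec, derive_seed(seed, "select"),
                                keep_duplicates = FALSE)
  cfg <- spec$ica_decon; cfg$k <- k; cfg$seed <- derive_seed(seed, "decon")
  res <- ica_weighted_proportions(st$d, cfg)
  res$diagnostics$n_selected <- length(st$sel$indices)
  res
}

run_rna_wnm <- function(ds, spec, k, seed) {
  st <- stage_rna_ica_selection(ds, spec, derive_seed(seed, "select"),
                                keep_duplicates = TRUE)
  cfg <- spec$nmf; cfg$k <- k; cfg$seed <- derive_seed(seed, "decon")
  res <- sparse_nmf(st$d, cfg)
  res$diagnostics$n_selected <- length(st$sel$indices)
  res
}

run_met_nmf <- function(ds, spec, k, seed, regularized, start_a = NULL) {
  st <- stage_met_filter(ds, spec)
  cfg <- spec$nmf; cfg$k <- k; cfg$seed <- derive_seed(seed, "decon")
  cfg$start_a <- start_a
  if (regularized) regularized_constrained_nmf(st$d, cfg)
  else constrained_nmf(st$d, cfg)
}

run_met_wic <- function(ds, spec, k, seed) {
  d <- if (spec$filter_probes_for_ica) stage_met_filter(ds, spec)$d
  else ds$d_met
  cfg <- spec$ica_decon; cfg$k <- k; cfg$seed <- derive_seed(seed, "decon")
  ica_weighted_proportions(d, cfg)
}

# --- the dispatcher -------------------------------------------------------

#' Run one baseline method on a benchmark dataset
#'
#' Executes the method's full pipeline (feature selection, deconvolution,
#' and, for the `b_*` methods, cross-omic integration), deriving one child
#' seed per stage from `seed` so every stage is independently reproducible.
#' Diagnostics record the stages, sub-seeds, and — for `b_COM` — the warm
#' start provenance.
#'
#' @param spec a [method_spec()].
#' @param ds a [benchmark_dataset] (truth optional except for `ref_*`, which
#'   need `t_rna`).
#' @param k number of components to extract (default 5).
#' @param seed run seed.
#' @return a [deconvolution_result].
#' @export
run_baseline <- function(spec, ds, k = 5, seed = 1L) {
  stopifnot(inherits(spec, "method_spec"), inherits(ds, "benchmark_dataset"))
  t0 <- proc.time()[["elapsed"]]
  res <- switch(
    spec$method_id,
    r_WIC = run_rna_wic(ds, spec, k, seed),
    r_WNM = run_rna_wnm(ds, spec, k, seed),
    m_EDC = run_met_nmf(ds, spec, k, seed, regularized = FALSE),
    m_MDC = run_met_nmf(ds, spec, k, seed, regularized = TRUE),
    m_WIC = run_met_wic(ds, spec, k, seed),
    b_WIC = {
      rna <- run_rna_wic(ds, spec, k, derive_seed(seed, "rna"))
      met <- run_met_wic(ds, spec, k, derive_seed(seed, "met"))
      p <- match_components(rna$a_est, met$a_est,
                            seed = derive_seed(seed, "match"))
      avg <- average_proportions(rna$a_est, permute_rows(met$a_est, p))
      deconvolution_result(avg, "b_WIC", seed,
                           diagnostics = list(match_permutation = p,
                                              rna = rna$diagnostics,
                                              met = met$diagnostics))
    },
    b_COM = {
      rna <- run_rna_wnm(ds, spec, k, derive_seed(seed, "rna"))
      start_a <- rna$a_est
      prematched <- FALSE
      if (spec$prematch_start_a) {
        prelim_spec <- spec
        prelim_spec$nmf$n_init <- 1
        prelim_spec$nmf$max_iter <- min(50, spec$nmf$max_iter)
        prelim <- run_met_nmf(ds, prelim_spec, k,
                              derive_seed(seed, "prematch"),
                              regularized = TRUE)
        p <- match_components(prelim$a_est, start_a,
                              seed = derive_seed(seed, "match"))
        start_a <- permute_rows(start_a, p)
        prematched <- TRUE
      }
      met <- run_met_nmf(ds, spec, k, derive_seed(seed, "met"),
                         regularized = TRUE, start_a = start_a)
      met$method_id <- "b_COM"
      met$diagnostics$start_a_provenance <-
        list(source = "r_WNM transcriptome estimate",
             rna_seed = derive_seed(seed, "rna"),
             prematched = prematched)
      met$diagnostics$rna_stage <- rna$diagnostics
      met
    },
    b_MEA = {
      rna <- run_rna_wnm(ds, spec, k, derive_seed(seed, "rna"))
      met <- run_met_nmf(ds, spec, k, derive_seed(seed, "met"),
                         regularized = TRUE)
      p <- match_components(rna$a_est, met$a_est,
                            seed = derive_seed(seed, "match"))
      avg <- average_proportions(rna$a_est, permute_rows(met$a_est, p))
      deconvolution_result(avg, "b_MEA", seed,
                           diagnostics = list(match_permutation = p,
                                              rna = rna$diagnostics,
                                              met = met$diagnostics))
    },
    ref_OLS = ,
    ref_RLR = {
      if (is.null(ds$t_rna))
        stop(spec$method_id, " needs reference profiles (t_rna) in the ",
             "dataset", call. = FALSE)
      reference_regression(ds$d_rna, ds$t_rna,
                           if (spec$method_id == "ref_OLS") "ols" else "rlr")
    },
    external = {
      workdir <- tempfile("external_run_")
      dir.create(workdir)
      bundle <- file.path(workdir, "bundle")
      save_dataset_bundle(ds, bundle, hide_truth = TRUE)
      run_external_method(spec$external_command, bundle, k,
                          workdir = workdir,
                          timeout = spec$external_timeout)
    })
  res$method_id <- spec$method_id
  res$run_seed <- seed
  res$elapsed_seconds <- proc.time()[["elapsed"]] - t0
  res
}

#' Run an external deconvolution program on a truth-hidden bundle
#'
#' Substitutes `{rna}`, `{met}`, `{k}` and `{out}` into the command template,
#' runs it in an isolated working directory with only the truth-hidden
#' bundle visible, and reads back the K x N proportion TSV the program must
#' write at `{out}` (header = the bundle's sample ids; near-stochastic
#' columns are renormalized with a warning). Nonzero exit, timeout, or
#' missing/invalid output raise a structured failure that a benchmark sweep
#' records without aborting.
#'
#' @param command_template shell command with the four placeholders.
#' @param bundle_dir a truth-hidden bundle from [save_dataset_bundle()].
#' @param k expected number of components.
#' @param workdir working directory for the program (default: fresh temp).
#' @param timeout seconds before the program is killed.
#' @return a [deconvolution_result]; stdout/stderr are kept in diagnostics.
#' @export
run_external_method <- function(command_template, bundle_dir, k,
                                workdir = tempfile("external_"),
                                timeout = 600) {
  for (ph in c("{rna}", "{met}", "{k}", "{out}"))
    if (!grepl(ph, command_template, fixed = TRUE))
      stop("command template must contain placeholder ", ph, call. = FALSE)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  out_path <- file.path(workdir, "a_est.tsv")
  cmd <- command_template
  subs <- c("{rna}" = file.path(bundle_dir, "d_rna.tsv"),
            "{met}" = file.path(bundle_dir, "d_met.tsv"),
            "{k}" = as.character(k), "{out}" = out_path)
  for (ph in names(subs)) cmd <- gsub(ph, subs[[ph]], cmd, fixed = TRUE)
  t0 <- proc.time()[["elapsed"]]
  log <- suppressWarnings(
    system2("sh", c("-c", shQuote(cmd)), stdout = TRUE, stderr = TRUE,
            timeout = timeout))
  status <- attr(log, "status") %||% 0L
  fail <- function(msg) {
    cnd <- structure(class = c("mixdecon_external_failure", "error",
                               "condition"),
                     list(message = msg, call = NULL,
                          stdout = as.character(log), exit_status = status))
    stop(cnd)
  }
  if (status != 0) fail(paste0("external program exited with status ", status))
  if (!file.exists(out_path)) fail("external program wrote no output at {out}")
  a <- tryCatch(read_proportion_matrix(out_path, labeled = FALSE),
                error = function(e) fail(paste0("invalid output: ",
                                                conditionMessage(e))))
  if (nrow(a$values) != k)
    fail(sprintf("expected %d components, got %d", k, nrow(a$values)))
  deconvolution_result(a, "external",
                       elapsed_seconds = proc.time()[["elapsed"]] - t0,
                       diagnostics = list(command = cmd,
                                          log = as.character(log),
                                          exit_status = status))
}
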