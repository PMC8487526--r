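# Synthetic benchmark generator: marker-structured cell-type reference
# profiles for a 5-population pancreatic-tumor-like mixture, hierarchical
# Dirichlet proportion sampling, linear mixing with additive Gaussian noise,
# and replicated paired-omic dataset construction.

DEFAULT_CELL_TYPES <- c("fibroblast", "immune", "normal_epithelial",
                        "cancer_basal", "cancer_classic")

#' Simulation configuration for the paired-omic benchmark
#'
#' Defines the study conditions of the benchmark: sample size, feature
#' dimensions, the hierarchical Dirichlet model for cell-type proportions and
#' the additive Gaussian technical noise.
#'
#' The composition model is hierarchical: a 4-way global draw
#' `g ~ Dirichlet(alpha0_global * mean_global)` over fibroblast, immune,
#' normal-epithelial and (total) cancer mass, then an independent 2-way split
#' `s ~ Dirichlet(alpha0_cancer * mean_cancer_split)` of the cancer mass into
#' basal-like and classic subtypes. `alpha0` is the Dirichlet precision: the
#' global compartment uses 10 (moderately concentrated around the mean
#' composition), the cancer split uses 1 (highly variable subtype balance).
#'
#' @param cell_type_labels names of the 5 populations, cancer subtypes last.
#' @param n_samples number of bulk samples per dataset (default 30).
#' @param n_genes,n_probes feature dimensions of the transcriptome and
#'   methylome (desk-scale defaults 5000 / 10000).
#' @param mean_global mean composition over (fibroblast, immune,
#'   normal_epithelial, cancer); a configurable stand-in for an expert-defined
#'   tumor composition, default `(0.35, 0.25, 0.10, 0.30)`.
#' @param mean_cancer_split mean (basal, classic) split of the cancer mass.
#' @param alpha0_global,alpha0_cancer Dirichlet precisions (defaults 10 and 1).
#' @param noise_mu,noise_sd additive Gaussian noise parameters applied to each
#'   bulk matrix (defaults 0 and 0.05).
#' @param n_datasets number of replicated datasets (default 10).
#' @param seed root seed for the whole simulation.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(cell_type_labels = DEFAULT_CELL_TYPES,
                              n_samples = 30, n_genes = 5000,
                              n_probes = 10000,
                              mean_global = c(fibroblast = 0.35, immune = 0.25,
                                              normal_epithelial = 0.10,
                                              cancer = 0.30),
                              mean_cancer_split = c(basal = 0.5,
                                                    classic = 0.5),
                              alpha0_global = 10, alpha0_cancer = 1,
                              noise_mu = 0, noise_sd = 0.05,
                              n_datasets = 10, seed = 1L) {
  stopifnot(length(cell_type_labels) == 5, !anyDuplicated(cell_type_labels),
            n_samples >= 1, n_genes >= 1, n_probes >= 1,
            length(mean_global) == 4, length(mean_cancer_split) == 2,
            alpha0_global > 0, alpha0_cancer > 0, noise_sd >= 0,
            n_datasets >= 1)
  if (any(mean_global <= 0) || abs(sum(mean_global) - 1) > 1e-8)
    stop("mean_global must be a positive 4-vector summing to 1", call. = FALSE)
  if (any(mean_cancer_split <= 0) || abs(sum(mean_cancer_split) - 1) > 1e-8)
    stop("mean_cancer_split must be a positive 2-vector summing to 1",
         call. = FALSE)
  structure(list(cell_type_labels = cell_type_labels, n_samples = n_samples,
                 n_genes = n_genes, n_probes = n_probes,
                 mean_global = unname(mean_global),
                 mean_cancer_split = unname(mean_cancer_split),
                 alpha0_global = alpha0_global, alpha0_cancer = alpha0_cancer,
                 noise_mu = noise_mu, noise_sd = noise_sd,
                 n_datasets = n_datasets, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Configuration of the synthetic reference-profile generator
#'
#' Controls the marker structure of the synthetic `T` matrices: each cell type
#' owns an exclusive block of marker features where its profile exceeds every
#' other type by at least the stated effect size, and the two cancer subtypes
#' additionally share a common pan-cancer marker block that makes them more
#' mutually similar than the other populations.
#'
#' @param n_markers_per_type exclusive markers per cell type and per modality
#'   (default 100).
#' @param rna_marker_logfc marker effect size on the log2 expression scale
#'   (default 4).
#' @param rna_background_mean,rna_background_sd background log2 expression
#'   distribution (defaults 4 and 2; negative draws clipped to 0).
#' @param meth_marker_delta marker effect size in beta units (default 0.6).
#' @param meth_background_modes list of two `c(shape1, shape2)` Beta parameter
#'   pairs for the unmethylated/methylated background modes (defaults Beta(3,
#'   12) and Beta(12, 3), i.e. modes near 0.2 and 0.8 — far enough from the
#'   boundaries that additive noise rarely clips).
#' @param seed seed for profile generation.
#' @return a `profile_config` list.
#' @export
profile_config <- function(n_markers_per_type = 100, rna_marker_logfc = 4.0,
                           rna_background_mean = 4.0, rna_background_sd = 2.0,
                           meth_marker_delta = 0.6,
                           meth_background_modes = list(c(3, 12), c(12, 3)),
                           seed = 1L) {
  stopifnot(n_markers_per_type >= 1, rna_marker_logfc > 0,
            meth_marker_delta > 0, meth_marker_delta < 1,
            length(meth_background_modes) == 2)
  structure(list(n_markers_per_type = n_markers_per_type,
                 rna_marker_logfc = rna_marker_logfc,
                 rna_background_mean = rna_background_mean,
                 rna_background_sd = rna_background_sd,
                 meth_marker_delta = meth_marker_delta,
                 meth_background_modes = meth_background_modes,
                 seed = as.integer(seed)),
            class = "profile_config")
}

# Marker block layout for K = 5 plus a shared pan-cancer block: returns a list
# of index vectors into 1..n_features.
marker_blocks <- function(n_markers, labels) {
  blocks <- lapply(seq_along(labels), function(i)
    ((i - 1) * n_markers + 1):(i * n_markers))
  names(blocks) <- labels
  blocks$pan_cancer <- (length(labels) * n_markers + 1):
    ((length(labels) + 1) * n_markers)
  blocks
}

#' Generate marker-structured synthetic reference profiles
#'
#' Builds the paired `T_RNA` / `T_MET` matrices: each of the 5 cell types owns
#' `n_markers_per_type` exclusive marker rows per modality (owner value =
#' shared background + effect size), the two cancer subtypes share one extra
#' pan-cancer marker block, and all remaining rows are background shared
#' across cell types. RNA values are non-negative log2 expression; methylation
#' values are beta-values in `[0, 1]`.
#'
#' @param pcfg a [profile_config()].
#' @param scfg a [simulation_config()].
#' @return list with elements `t_rna` and `t_met` ([reference_profiles]).
#' @export
generate_reference_profiles <- function(pcfg = profile_config(),
                                        scfg = simulation_config()) {
  nm <- pcfg$n_markers_per_type
  if (scfg$n_genes < 5 * nm || scfg$n_probes < 5 * nm)
    stop("need n_genes and n_probes >= 5 * n_markers_per_type", call. = FALSE)
  if (scfg$noise_sd > 0 &&
      (pcfg$rna_marker_logfc <= 10 * scfg$noise_sd ||
       pcfg$meth_marker_delta <= 10 * scfg$noise_sd))
    warning("marker effect sizes do not exceed 10 x noise_sd; ",
            "components may not be separable", call. = FALSE)
  labels <- scfg$cell_type_labels
  K <- length(labels)
  cancer_idx <- c(4L, 5L)
  with_seed(derive_seed(pcfg$seed, "profiles"), {
    ## transcriptome: background genes share one baseline across cell types;
    ## marker genes are near-silent in non-owner types (as real cell-type
    ## markers are), which is what makes the mixture identifiable
    bg <- pmax(stats::rnorm(scfg$n_genes, pcfg$rna_background_mean,
                            pcfg$rna_background_sd), 0)
    t_rna <- matrix(bg, scfg$n_genes, K)
    blocks <- marker_blocks(nm, labels)
    for (i in seq_len(K)) {
      base <- stats::runif(nm, 0, 0.2)
      t_rna[blocks[[i]], ] <- base
      t_rna[blocks[[i]], i] <- base + pcfg$rna_marker_logfc
    }
    base <- stats::runif(nm, 0, 0.2)
    t_rna[blocks$pan_cancer, ] <- base
    t_rna[blocks$pan_cancer, cancer_idx] <- base + pcfg$rna_marker_logfc
    ## methylome: bimodal background shared across types; marker probes
    ## unmethylated in non-owners, hypermethylated (base + delta) in the owner
    mode_pick <- stats::runif(scfg$n_probes) < 0.5
    mb <- pcfg$meth_background_modes
    bgm <- ifelse(mode_pick,
                  stats::rbeta(scfg$n_probes, mb[[1]][1], mb[[1]][2]),
                  stats::rbeta(scfg$n_probes, mb[[2]][1], mb[[2]][2]))
    t_met <- matrix(bgm, scfg$n_probes, K)
    pblocks <- marker_blocks(nm, labels)
    for (i in seq_len(K)) {
      base <- stats::runif(nm, 0.02, 0.10)
      t_met[pblocks[[i]], ] <- base
      t_met[pblocks[[i]], i] <- base + pcfg$meth_marker_delta
    }
    base <- stats::runif(nm, 0.02, 0.10)
    t_met[pblocks$pan_cancer, ] <- base
    t_met[pblocks$pan_cancer, cancer_idx] <- base + pcfg$meth_marker_delta
  })
  list(
    t_rna = reference_profiles(
      t_rna, "rna_log2",
      feature_ids = sprintf("gene_%05d", seq_len(scfg$n_genes)),
      cell_type_labels = labels),
    t_met = reference_profiles(
      t_met, "meth_beta",
      feature_ids = sprintf("cpg_%06d", seq_len(scfg$n_probes)),
      cell_type_labels = labels))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              ncol = length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Sample cell-type proportions from the hierarchical Dirichlet model
#'
#' Per sample: draw the 4-way global composition
#' `g ~ Dirichlet(alpha0_global * mean_global)`, independently draw the cancer
#' subtype split `s ~ Dirichlet(alpha0_cancer * mean_cancer_split)`, and emit
#' `(g_fibro, g_immune, g_normal, g_cancer * s_basal, g_cancer * s_classic)`.
#' Columns sum to 1 exactly (up to floating-point closure of the split).
#'
#' @param scfg a [simulation_config()].
#' @param n number of samples to draw (default `scfg$n_samples`).
#' @param seed seed; defaults to a child of `scfg$seed`.
#' @return a labeled [proportion_matrix] with K = 5 rows.
#' @export
sample_proportions <- function(scfg = simulation_config(),
                               n = scfg$n_samples,
                               seed = derive_seed(scfg$seed, "proportions")) {
  stopifnot(n >= 1)
  with_seed(seed, {
    g <- rdirichlet(n, scfg$alpha0_global * scfg$mean_global)
    s <- rdirichlet(n, scfg$alpha0_cancer * scfg$mean_cancer_split)
  })
  a <- cbind(g[, 1:3, drop = FALSE], g[, 4] * s)
  proportion_matrix(t(a), row_labels = scfg$cell_type_labels,
                    sample_ids = sprintf("S%02d", seq_len(n)), labeled = TRUE)
}

#' Mix reference profiles into a noisy bulk matrix
#'
#' Implements the linear mixture model `D = T A + eps` with
#' `eps ~ Normal(noise_mu, noise_sd)` i.i.d. per entry, then clips the result
#' to the modality's valid range (`[0, 1]` for beta-values, `[0, Inf)` for
#' log2 expression). The fraction of clipped entries is recorded in the
#' `"clipped_fraction"` attribute of the result.
#'
#' @param t a [reference_profiles] matrix.
#' @param a a [proportion_matrix] whose row labels match `t`'s cell types.
#' @param noise_mu,noise_sd Gaussian noise parameters.
#' @param seed RNG seed for the noise draw.
#' @return an [omic_matrix] with `a$sample_ids` as samples.
#' @export
mix_bulk <- function(t, a, noise_mu = 0, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(t, "reference_profiles"),
            inherits(a, "proportion_matrix"))
  if (!identical(t$cell_type_labels, a$row_labels))
    stop("cell-type labels of t and row labels of a must match in order",
         call. = FALSE)
  d <- t$values %*% a$values
  if (noise_sd > 0 || noise_mu != 0)
    d <- d + with_seed(seed, matrix(stats::rnorm(length(d), noise_mu,
                                                 noise_sd), nrow(d)))
  lo <- 0
  hi <- if (t$modality == "meth_beta") 1 else Inf
  clipped <- mean(d < lo | d > hi)
  d[d < lo] <- lo
  d[d > hi] <- hi
  out <- omic_matrix(d, t$modality, feature_ids = t$feature_ids,
                     sample_ids = a$sample_ids)
  attr(out, "clipped_fraction") <- clipped
  out
}

#' Simulate the full replicated paired-omic benchmark
#'
#' Generates one shared pair of reference profiles, then `n_datasets`
#' independent realizations of the proportion matrix; each dataset's bulk
#' methylome and transcriptome are mixed from the *same* `A` (paired omics)
#' with independent noise. Fully deterministic given `scfg$seed`.
#'
#' @param scfg a [simulation_config()].
#' @param pcfg a [profile_config()].
#' @return list of `n_datasets` [benchmark_dataset] objects sharing identical
#'   `t_rna` / `t_met`.
#' @export
simulate_benchmark <- function(scfg = simulation_config(),
                               pcfg = profile_config()) {
  pcfg$seed <- derive_seed(scfg$seed, "profiles-root")
  profs <- generate_reference_profiles(pcfg, scfg)
  lapply(seq_len(scfg$n_datasets), function(i) {
    a <- sample_proportions(scfg, scfg$n_samples,
                            seed = derive_seed(scfg$seed, "dataset", i, "a"))
    d_rna <- mix_bulk(profs$t_rna, a, scfg$noise_mu, scfg$noise_sd,
                      seed = derive_seed(scfg$seed, "dataset", i, "noise-rna"))
    d_met <- mix_bulk(profs$t_met, a, scfg$noise_mu, scfg$noise_sd,
                      seed = derive_seed(scfg$seed, "dataset", i, "noise-met"))
    benchmark_dataset(
      d_met = d_met, d_rna = d_rna, a_true = a,
      t_met = profs$t_met, t_rna = profs$t_rna,
      meta = list(seed = scfg$seed, dataset_index = i,
                  alpha0_global = scfg$alpha0_global,
                  alpha0_cancer = scfg$alpha0_cancer,
                  noise_mu = scfg$noise_mu, noise_sd = scfg$noise_sd,
                  cell_type_labels = scfg$cell_type_labels,
                  clipped_fraction_met = attr(d_met, "clipped_fraction"),
                  clipped_fraction_rna = attr(d_rna, "clipped_fraction")))
  })
}
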