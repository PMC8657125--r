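#' Configuration for the paired-cohort simulator
#'
#' Defaults describe a cohort structurally resembling a 94-patient early
#' breast cancer series: subtype mix 14% basal-like, 6% HER2-enriched,
#' 52% luminal A, 28% luminal B (no true normal-like tumors); ~80%
#' ER-positive; 38% of tumors larger than 2 cm; node classes 68% pN0,
#' 27% pN1-3, 5% pN4+. The macrodissected-like assay sees near-pure tumor
#' signal (purity uniform on \[0.85, 1\]); the bulk assay sees the same
#' tumor profile mixed with normal epithelium at Beta(4, 1.5) purity
#' (mean ~0.73), plus per-gene platform distortion (slope ~ N(1, 0.1),
#' offset ~ N(0, 0.3)) and measurement noise.
#'
#' @param n_samples Cohort size (>= 6).
#' @param subtype_proportions Named probabilities over the 5 subtypes,
#'   summing to 1.
#' @param purity_macro_range Uniform range of tumor purity in the
#'   macrodissected-like matrix.
#' @param purity_bulk_beta `c(a, b)` of the Beta distribution of bulk
#'   purity.
#' @param noise_sd Per-gene Gaussian noise, log2 units.
#' @param platform_slope_sd,platform_offset_sd SDs of the per-gene bulk
#'   platform slope (around 1) and offset (around 0).
#' @param er_pos_fraction Target ER-positive fraction. Luminal tumors are
#'   always ER-positive; when the luminal mass falls short of this target,
#'   non-luminal samples are promoted at random to make up the difference.
#' @param p_size_gt2cm Probability of tumor size > 2 cm.
#' @param node_class_probs Named probabilities over pN0/pN1_3/pN4plus.
#' @param seed Integer seed driving one global random stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 94,
                       subtype_proportions = c(Basal = 0.14, Her2 = 0.06,
                                               LumA = 0.52, LumB = 0.28,
                                               Normal = 0),
                       purity_macro_range = c(0.85, 1),
                       purity_bulk_beta = c(4, 1.5),
                       noise_sd = 0.3,
                       platform_slope_sd = 0.1,
                       platform_offset_sd = 0.3,
                       er_pos_fraction = 0.8,
                       p_size_gt2cm = 0.38,
                       node_class_probs = c(pN0 = 0.68, pN1_3 = 0.27,
                                            pN4plus = 0.05),
                       seed = 1L) {
  if (n_samples < 6) stop("n_samples must be >= 6")
  if (!setequal(names(subtype_proportions), pam50_subtypes()))
    stop("subtype_proportions must be named over the 5 subtypes")
  subtype_proportions <- subtype_proportions[pam50_subtypes()]
  if (abs(sum(subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must sum to 1")
  if (any(subtype_proportions < 0)) stop("subtype_proportions must be >= 0")
  if (length(purity_macro_range) != 2 ||
      any(purity_macro_range < 0 | purity_macro_range > 1) ||
      purity_macro_range[1] > purity_macro_range[2])
    stop("purity_macro_range must be an increasing pair in [0, 1]")
  if (length(purity_bulk_beta) != 2 || any(purity_bulk_beta <= 0))
    stop("purity_bulk_beta must be two positive Beta parameters")
  if (noise_sd < 0 || platform_slope_sd < 0 || platform_offset_sd < 0)
    stop("noise/platform SDs must be >= 0")
  if (!setequal(names(node_class_probs), node_levels()) ||
      abs(sum(node_class_probs) - 1) > 1e-9)
    stop("node_class_probs must be named over pN0/pN1_3/pN4plus and sum to 1")
  structure(list(n_samples = as.integer(n_samples),
                 subtype_proportions = subtype_proportions,
                 purity_macro_range = purity_macro_range,
                 purity_bulk_beta = purity_bulk_beta,
                 noise_sd = noise_sd,
                 platform_slope_sd = platform_slope_sd,
                 platform_offset_sd = platform_offset_sd,
                 er_pos_fraction = er_pos_fraction,
                 p_size_gt2cm = p_size_gt2cm,
                 node_class_probs = node_class_probs[node_levels()],
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a paired macro/bulk cohort with ground truth
#'
#' Per sample of true subtype k: a tumor profile `t = centroid_k + noise`
#' and a normal-epithelium profile `n = normal_centroid + noise` are drawn
#' on the 50-gene panel (log2 scale). The macrodissected-like measurement
#' is the mixture `p_macro * t + (1 - p_macro) * n`; the bulk measurement
#' mixes at the (lower) bulk purity and then passes through a per-gene
#' platform distortion `slope * x + offset` plus measurement noise. Mixing
#' is affine in log2 space — a stated simplification, since the centroids
#' exist only in log-ratio space (set `linear_mix = TRUE` to mix on the
#' 2^x scale instead for sensitivity checks).
#'
#' All draws come from one stream seeded by `config$seed`; the same call is
#' bit-reproducible.
#'
#' @param config A `sim_config`.
#' @param centroids A `centroid_set` (default: packaged synthetic set).
#' @param linear_mix Mix on the linear (2^x) scale instead of log2.
#' @return List with `macro` and `bulk` (`expr_matrix`, identical sample
#'   IDs), `truth` (per-sample `true_subtype`, `purity_macro`,
#'   `purity_bulk`, `er_status`, `size_gt_2cm`, `node_class`), and
#'   `clinical` (a table in the [load_clinical()] layout, including
#'   `er_status`/`her2_status` for subset filters).
#' @export
simulate_cohort <- function(config = sim_config(),
                            centroids = load_centroids(),
                            linear_mix = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(centroids, "centroid_set"))
  set.seed(config$seed)
  n <- config$n_samples
  G <- length(centroids$genes)
  ids <- sprintf("S%03d", seq_len(n))
  sub <- pam50_subtypes()

  true_subtype <- sample(sub, n, replace = TRUE,
                         prob = config$subtype_proportions)
  purity_macro <- stats::runif(n, config$purity_macro_range[1],
                               config$purity_macro_range[2])
  purity_bulk <- stats::rbeta(n, config$purity_bulk_beta[1],
                              config$purity_bulk_beta[2])

  # ER: luminal tumors are ER-positive; promote non-luminal at random if
  # the configured marginal exceeds the luminal mass
  er <- true_subtype %in% c("LumA", "LumB")
  deficit <- round(config$er_pos_fraction * n) - sum(er)
  if (deficit > 0 && any(!er)) {
    pool <- which(!er)
    er[sample(pool, min(deficit, length(pool)))] <- TRUE
  }
  size <- stats::runif(n) < config$p_size_gt2cm
  node <- sample(node_levels(), n, replace = TRUE,
                 prob = config$node_class_probs)

  slope <- stats::rnorm(G, 1, config$platform_slope_sd)
  offset <- stats::rnorm(G, 0, config$platform_offset_sd)

  tumor <- centroids$values[, true_subtype, drop = FALSE] +
    matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n)
  normal <- matrix(centroids$values[, "Normal"], G, n) +
    matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n)

  mix <- function(t, nrm, p) {
    pm <- matrix(p, G, n, byrow = TRUE)
    if (linear_mix) log2(pm * 2^t + (1 - pm) * 2^nrm)
    else pm * t + (1 - pm) * nrm
  }
  macro <- mix(tumor, normal, purity_macro)
  bulk <- slope * mix(tumor, normal, purity_bulk) + offset +
    matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n)

  dimnames(macro) <- dimnames(bulk) <- list(centroids$genes, ids)
  truth <- data.frame(sample_id = ids,
                      true_subtype = factor(true_subtype, levels = sub),
                      purity_macro = purity_macro,
                      purity_bulk = purity_bulk,
                      er_status = ifelse(er, "ER_pos", "ER_neg"),
                      size_gt_2cm = size,
                      node_class = factor(node, levels = node_levels()),
                      stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = ids,
                         nodes = as.character(truth$node_class),
                         size_gt_2cm = size,
                         er_status = truth$er_status,
                         her2_status = ifelse(true_subtype == "Her2",
                                              "positive", "negative"),
                         node_class = truth$node_class,
                         stringsAsFactors = FALSE)
  list(macro = expression_matrix(macro, platform = "simulated"),
       bulk = expression_matrix(bulk, platform = "simulated"),
       truth = truth, clinical = clinical)
}

#' ROR and normal-like call rate along a tumor-purity gradient
#'
#' For one subtype, generates `m` replicate profiles at each purity on a
#' descending grid (tumor centroid mixed with normal epithelium plus
#' noise), scores them through the centering/subtyping/ROR pipeline, and
#' reports the mean continuous ROR and the fraction of replicates called
#' normal-like at each purity. Replicates are centered with a reference
#' learned from a background cohort simulated under the same configuration
#' (using the simulator's true ER labels), so the curve isolates the purity
#' effect. The tumor-size indicator is held at 0.
#'
#' @param subtype One of the five subtype labels.
#' @param purity_grid Descending purities in \[0, 1\].
#' @param config A `sim_config` (its seed drives the whole curve).
#' @param centroids A `centroid_set`.
#' @param m Replicates per purity (default 100).
#' @return Data.frame with `purity`, `mean_ror`, `normal_like_call_rate`.
#' @export
contamination_curve <- function(subtype, purity_grid, config = sim_config(),
                                centroids = load_centroids(), m = 100) {
  subtype <- match.arg(subtype, pam50_subtypes())
  if (length(purity_grid) == 0) stop("purity_grid must be non-empty")
  if (any(purity_grid < 0 | purity_grid > 1))
    stop("purity values must lie in [0, 1]")
  if (is.unsorted(rev(purity_grid), strictly = FALSE))
    stop("purity_grid must be sorted in descending order")

  background <- simulate_cohort(config, centroids)
  er <- er_call_from_status(background$truth$sample_id,
                            background$truth$er_status)
  ref <- weighted_center(background$macro, er)$reference

  set.seed(config$seed + 1L)
  G <- length(centroids$genes)
  ck <- centroids$values[, subtype]
  cn <- centroids$values[, "Normal"]
  coeffs <- ror_coefficients()
  out <- lapply(purity_grid, function(p) {
    t_prof <- matrix(ck, G, m) + matrix(stats::rnorm(G * m, 0, config$noise_sd), G, m)
    n_prof <- matrix(cn, G, m) + matrix(stats::rnorm(G * m, 0, config$noise_sd), G, m)
    X <- p * t_prof + (1 - p) * n_prof
    dimnames(X) <- list(centroids$genes, sprintf("R%03d", seq_len(m)))
    centered <- apply_centering(expression_matrix(X, platform = "simulated"),
                                ref)
    res <- assign_subtypes(centroid_correlations(centered, centroids))
    prolif <- proliferation_score(centered)
    ror <- coeffs$scale * (coeffs$basal * res$corr_Basal +
                             coeffs$her2 * res$corr_Her2 +
                             coeffs$luma * res$corr_LumA +
                             coeffs$lumb * res$corr_LumB +
                             coeffs$prolif * prolif +
                             coeffs$intercept)
    data.frame(purity = p, mean_ror = mean(ror),
               normal_like_call_rate = mean(res$call == "Normal"))
  })
  do.call(rbind, out)
}
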