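#' Cell type classes used for marker-gene abundance maps
#'
#' The eight canonical cortical cell classes: astrocytes, endothelial cells,
#' microglia, excitatory and inhibitory neurons, oligodendrocytes,
#' oligodendrocyte precursor cells (OPCs) and pericytes. Fixed identifiers
#' keep joins between expression, placement and spin stages unambiguous.
#'
#' @return Character vector of length 8.
#' @export
cell_type_names <- function() {
  c("astro", "endo", "micro", "neuro_ex", "neuro_in", "oligo", "opc", "per")
}

#' Construct the ground truth for the synthetic cohort generator
#'
#' Bundles every parameter the generator uses so downstream stages can be
#' tested by parameter recovery: an analytic normative chart per region and
#' sex, per-study location offsets, the gestational-age (GA) law for the
#' number of injected extranormal regions, cell-map-weighted placement,
#' two-timepoint persistence, within-subject score stability, the
#' socio-economic status (SES) effect on the global deviation level, and the
#' deviation-to-cognition coupling.
#'
#' The extent law is `lambda(GA) = lambda0 + lambda1 * max(0, 40 - GA)`
#' (expected number of injected extranormal regions, Poisson). Placement
#' weights per cell type follow
#' `w_c(GA) = max(0, weight_c + slope_c * max(0, 40 - GA))`; the weighted sum
#' of latent cell maps, standardised and passed through a softmax with
#' temperature `tau`, gives region sampling probabilities.
#'
#' @param seed Integer RNG seed; every stochastic choice in the generator is
#'   a deterministic function of it.
#' @param region_names Region identifiers (default 34 Desikan-Killiany).
#' @param study_offsets Named numeric vector of additive location shifts (mm)
#'   per study label.
#' @param lambda0,lambda1 Nonnegative coefficients of the GA extent law.
#' @param placement_weights `data.frame` with columns `cell_type`, `weight`
#'   (mixing weight, sums to 1) and `slope` (per week of prematurity).
#' @param tau Softmax temperature for deviation placement concentration.
#' @param persistence_prob Probability an injected extranormal region is
#'   retained at timepoint 2.
#' @param stability Within-subject correlation of the latent Gaussian
#'   percentile between timepoints (longitudinal stability of the
#'   non-injected scores).
#' @param global_factor Share of each observation's latent Gaussian variance
#'   carried by a stable per-subject global factor shared across regions
#'   (induces the positively correlated regional deviations that make PC1 a
#'   global deviation axis; marginals stay standard normal).
#' @param direction_supra Probability an injected deviation is supranormal
#'   (vs infranormal).
#' @param ses_effect Numeric `c(a, b)`: global deviation shift in
#'   within-region standard deviation units,
#'   `delta = a * ses + b * ses * (40 - GA)` with SES coded low = 1,
#'   middle = 2, high = 3.
#' @param cognition_coupling Slope linking the standardised per-subject mean
#'   deviation score to the cognition score (cognition scale: mean 100,
#'   residual SD 10).
#' @param length_scale Gaussian-kernel length scale (chord distance on the
#'   unit sphere) of the latent cell maps.
#' @param geometry Parcel geometry; default a seeded Fibonacci lattice.
#' @return Object of class `ibap_truth`.
#' @export
default_ground_truth <- function(seed = 1L,
                                 region_names = dk_region_names(),
                                 study_offsets = c(SYNTH = 0),
                                 lambda0 = 0.5, lambda1 = 0.8,
                                 placement_weights = NULL,
                                 tau = 5,
                                 persistence_prob = 0.8,
                                 stability = 0.9,
                                 global_factor = 0.15,
                                 direction_supra = 0.8,
                                 ses_effect = c(a = 0.03, b = 0.05),
                                 cognition_coupling = 3,
                                 length_scale = 0.6,
                                 geometry = NULL) {
  stopifnot(lambda0 >= 0, lambda1 >= 0,
            persistence_prob >= 0, persistence_prob <= 1,
            stability >= 0, stability < 1,
            global_factor >= 0, global_factor < 1,
            direction_supra >= 0, direction_supra <= 1)
  if (is.null(placement_weights)) {
    # Late-gestation placement follows the oligodendrocyte map; with every
    # week of prematurity the mixture slides toward the OPC / astrocyte /
    # endothelial maps (the cell classes vulnerable to perinatal injury).
    placement_weights <- data.frame(
      cell_type = cell_type_names(),
      weight = c(0, 0, 0.03, 0.09, 0.05, 0.78, 0, 0.05),
      slope  = c(0.030, 0.030, 0, 0, 0, -0.070, 0.045, 0),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("cell_type", "weight", "slope") %in%
                  names(placement_weights)),
            all(placement_weights$weight >= 0))
  if (abs(sum(placement_weights$weight) - 1) > 1e-8) {
    stopf("placement weights must sum to 1")
  }
  if (is.null(geometry)) {
    geometry <- synthetic_centroids(region_names, seed = derive_seed(seed, 11))
  }
  validate_geometry(geometry)
  stopifnot(identical(geometry$region, region_names))

  nreg <- length(region_names)
  # Analytic chart: per-region adult cortical thickness levels around
  # 2.2-3.1 mm with mild log-age thinning, sigma ~0.10-0.14 mm, small skew.
  pars <- with_seed(derive_seed(seed, 13), {
    data.frame(
      region = rep(region_names, each = 2L),
      sex = rep(c("M", "F"), nreg),
      b0 = rep(2.2 + 0.9 * stats::runif(nreg), each = 2L) -
        rep(c(0, 0.03), nreg),
      b1 = rep(-0.06 * (1 + 0.3 * stats::runif(nreg)), each = 2L),
      b2 = rep(-0.01, 2L * nreg),
      g0 = rep(log(0.10 + 0.04 * stats::runif(nreg)), each = 2L),
      g1 = rep(0.05, 2L * nreg),
      nu = rep(stats::runif(nreg, -0.15, 0.25), each = 2L),
      converged = TRUE,
      stringsAsFactors = FALSE
    )
  })
  chart <- new_chart(
    coef = pars, family = "shash",
    center = log(280 + 27 * 365.25), scale = 0.4,
    df_location = 2L, df_scale = 1L,
    support = age_to_days(c(18, 45), "years"),
    offsets = study_offsets, excluded = character(0)
  )

  # Latent spatially autocorrelated cell-type abundance maps (GP on chord
  # distance), standardised per type; stored for recovery tests.
  K <- chord_kernel(geometry, length_scale) + diag(1e-8, nreg)
  L <- chol(K)
  latent <- with_seed(derive_seed(seed, 17), {
    z <- matrix(stats::rnorm(8L * nreg), nreg, 8L)
    m <- crossprod(L, z)
    # orthogonalise across cell types: linear combinations of GP draws stay
    # spatially smooth, and zero cross-correlation keeps each type's
    # alignment signal identifiable rather than confounded by chance
    # correlations between maps
    if (nreg >= 8L) {
      m <- qr.Q(qr(scale(m, center = TRUE, scale = FALSE)))
    }
    m <- scale(m)
    dimnames(m) <- list(region_names, cell_type_names())
    t(m)
  })

  truth <- list(
    seed = as.integer(seed),
    region_names = region_names,
    chart = chart,
    study_offsets = study_offsets,
    extent_params = c(lambda0 = lambda0, lambda1 = lambda1),
    placement_weights = placement_weights,
    tau = tau,
    persistence_prob = persistence_prob,
    stability = stability,
    global_factor = global_factor,
    direction_supra = direction_supra,
    ses_effect = c(a = unname(ses_effect[1]), b = unname(ses_effect[2])),
    cognition_coupling = cognition_coupling,
    length_scale = length_scale,
    geometry = geometry,
    latent_maps = latent
  )
  class(truth) <- "ibap_truth"
  truth
}

# Expected number of injected extranormal regions at gestational age `ga`.
extent_lambda <- function(truth, ga) {
  unname(truth$extent_params["lambda0"] +
           truth$extent_params["lambda1"] * pmax(0, 40 - ga))
}

# Region sampling probabilities for deviation placement at a given GA.
placement_probs <- function(truth, ga) {
  w <- pmax(0, truth$placement_weights$weight +
              truth$placement_weights$slope * max(0, 40 - ga))
  if (sum(w) <= 0) w <- rep(1, length(w))
  m <- drop(w %*% truth$latent_maps) / sum(w)
  s <- stats::sd(m)
  if (s > 0) m <- (m - mean(m)) / s
  e <- exp(truth$tau * m)
  e / sum(e)
}

#' @export
print.ibap_truth <- function(x, ...) {
  cat("ibap ground truth\n")
  cat(sprintf("  regions: %d   studies: %s\n", length(x$region_names),
              paste(names(x$study_offsets), collapse = ", ")))
  cat(sprintf("  extent law: lambda(GA) = %.3g + %.3g * max(0, 40 - GA)\n",
              x$extent_params["lambda0"], x$extent_params["lambda1"]))
  cat(sprintf("  persistence: %.2f   stability: %.2f   supra share: %.2f\n",
              x$persistence_prob, x$stability, x$direction_supra))
  cat(sprintf("  SES effect: a = %.3g, b = %.3g   cognition coupling: %.3g\n",
              x$ses_effect["a"], x$ses_effect["b"], x$cognition_coupling))
  invisible(x)
}
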