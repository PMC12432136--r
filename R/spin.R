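## Spatial permutation (spin) null models on the parcellated sphere.

#' Sample a uniform random 3D rotation
#'
#' Haar-uniform over SO(3): QR-orthonormalise a Gaussian 3x3 matrix, fix the
#' sign convention of the factorisation, and correct the determinant to +1.
#'
#' @param seed Optional integer seed (deterministic result).
#' @return 3x3 rotation matrix (`R'R = I`, `det R = 1`).
#' @export
sample_rotation <- function(seed = NULL) {
  with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
  })
}

#' Build a spin permutation schedule for a parcel geometry
#'
#' For each spin, all centroids are rotated by one shared random rotation
#' and a one-to-one assignment between rotated and original centroids is
#' solved by minimum-total-chord-distance matching, so every spun map is a
#' true permutation of the original values (spatial autocorrelation is
#' preserved, alignment broken). A nearest-centroid-with-replacement
#' variant is exposed for toolchain parity but is not a permutation.
#'
#' @param geom Parcel geometry (see [synthetic_centroids()]).
#' @param n_spins Number of spins (default 1000).
#' @param seed RNG seed for the rotations.
#' @param method `"assignment"` (default) or `"nearest"`.
#' @return Object of class `ibap_spin`: list with `schedule`
#'   (`n_spins` x n matrix; row `s`, entry `j` gives the source parcel whose
#'   value lands at parcel `j`), `regions`, `n_spins`, `seed`, `method`.
#' @export
build_spin_schedule <- function(geom, n_spins = 1000L, seed = 1L,
                                method = c("assignment", "nearest")) {
  method <- match.arg(method)
  validate_geometry(geom)
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  n <- nrow(xyz)
  rotations <- with_seed(seed, {
    lapply(seq_len(n_spins), function(s) sample_rotation(NULL))
  })
  schedule <- matrix(0L, n_spins, n)
  for (s in seq_len(n_spins)) {
    schedule[s, ] <- spin_perm_one(xyz, rotations[[s]], method)
  }
  out <- list(schedule = schedule, regions = geom$region,
              n_spins = n_spins, seed = seed, method = method)
  class(out) <- "ibap_spin"
  out
}

# One spin: rotate all centroids by `rot`, then map rotated parcels back to
# the original slots. Returns perm with perm[j] = source parcel whose value
# lands at slot j.
spin_perm_one <- function(xyz, rot, method = "assignment") {
  n <- nrow(xyz)
  rxyz <- xyz %*% t(rot)
  # cost[i, j] = squared chord distance from rotated parcel i to slot j
  cost <- outer(rowSums(rxyz^2), rowSums(xyz^2), "+") - 2 * rxyz %*% t(xyz)
  if (method == "assignment") {
    a <- lap_solve(cost)          # a[i] = slot of rotated parcel i
    perm <- integer(n)
    perm[a] <- seq_len(n)
    perm
  } else {
    apply(cost, 2L, which.min)
  }
}

#' @export
print.ibap_spin <- function(x, ...) {
  cat(sprintf("ibap spin schedule: %d spins x %d parcels (%s, seed %d)\n",
              x$n_spins, length(x$regions), x$method, x$seed))
  invisible(x)
}

check_map <- function(map, schedule, what) {
  if (!is.null(names(map)) && all(schedule$regions %in% names(map))) {
    map <- map[schedule$regions]
  }
  if (length(map) != length(schedule$regions) || anyNA(map)) {
    stopf("%s must be complete on the schedule's %d regions", what,
          length(schedule$regions))
  }
  if (stats::sd(map) == 0) stopf("%s has zero variance", what)
  as.numeric(map)
}

#' Spin-test p-value for the spatial correlation of two parcel maps
#'
#' Observed statistic is the Spearman correlation of the two maps; the null
#' distribution correlates spun versions of `map_a` with `map_b`. Two-sided
#' p with +1 smoothing: `p = (1 + #{|rho_null| >= |rho_obs|}) / (1 + n_spins)`
#' (never exactly 0). Rank-based, hence invariant to strictly monotone
#' transforms of either map.
#'
#' @param map_a,map_b Numeric region vectors (named vectors are aligned to
#'   the schedule's region order).
#' @param schedule An [`ibap_spin`][build_spin_schedule] schedule.
#' @return List with `rho_obs`, `p_spin`, and the `null` correlation sample.
#' @export
spin_pvalue <- function(map_a, map_b, schedule) {
  stopifnot(inherits(schedule, "ibap_spin"))
  a <- check_map(map_a, schedule, "map_a")
  b <- check_map(map_b, schedule, "map_b")
  ra <- rank(a); rb <- rank(b)
  rho_obs <- stats::cor(ra, rb)
  # rank(a[perm]) == rank(a)[perm], so spin the ranks directly
  null <- apply(schedule$schedule, 1L, function(perm) {
    stats::cor(ra[perm], rb)
  })
  p <- (1 + sum(abs(null) >= abs(rho_obs))) / (1 + schedule$n_spins)
  list(rho_obs = rho_obs, p_spin = p, null = null)
}

#' Subject-level spatial correlations with cell-type maps
#'
#' For each subject's continuous deviation-score profile and each cell-type
#' map, the spatial Spearman correlation across regions together with a
#' spin-test p-value. One shared schedule is used for all subjects and cell
#' types, keeping results reproducible and subject-comparable.
#'
#' @param profiles Classified profiles (scores are used, not labels).
#' @param maps Cell type x region matrix (see [aggregate_marker_sets()]).
#' @param schedule An [`ibap_spin`][build_spin_schedule] schedule over the
#'   same regions.
#' @param timepoint Timepoint (default 1).
#' @param group Optional group restriction (e.g. `"preterm"`).
#' @return List with matrices `rho` and `p_spin`
#'   (subjects x cell types) and the per-subject covariate frame `subjects`.
#' @export
subject_cellmap_correlations <- function(profiles, maps, schedule,
                                         timepoint = 1L, group = NULL) {
  stopifnot(inherits(schedule, "ibap_spin"), is.matrix(maps))
  p <- profiles[profiles$timepoint == timepoint, , drop = FALSE]
  if (!is.null(group)) p <- p[p$group %in% group, , drop = FALSE]
  regs <- schedule$regions
  if (!all(regs %in% colnames(maps))) {
    stopf("cell maps missing schedule regions")
  }
  wide <- profiles_matrix(p)
  if (!all(regs %in% colnames(wide))) {
    stopf("profiles missing schedule regions (rebuild the schedule on the included regions)")
  }
  wide <- wide[, regs, drop = FALSE]
  if (anyNA(wide)) stopf("profiles contain missing scores on schedule regions")
  M <- t(maps[, regs, drop = FALSE])            # regions x cell types
  nreg <- length(regs)
  zs <- function(m) scale(apply(m, 2L, rank)) / sqrt(nreg - 1)
  Z <- zs(t(wide))                               # regions x subjects
  W <- zs(M)                                     # regions x cell types
  rho <- crossprod(Z, W)                         # subjects x cell types
  exceed <- matrix(0L, nrow(rho), ncol(rho))
  for (s in seq_len(schedule$n_spins)) {
    null_s <- crossprod(Z[schedule$schedule[s, ], , drop = FALSE], W)
    exceed <- exceed + (abs(null_s) >= abs(rho))
  }
  p_spin <- (1 + exceed) / (1 + schedule$n_spins)
  dimnames(rho) <- dimnames(p_spin) <- list(rownames(wide), colnames(M))
  first <- !duplicated(p$subject_id)
  keep <- intersect(c("subject_id", "study", "age", "sex", "group",
                      "ga_weeks", "ses", "ses_code", "piri", "cognition"),
                    names(p))
  subjects <- p[first, keep, drop = FALSE]
  subjects <- subjects[match(rownames(wide), subjects$subject_id), ,
                       drop = FALSE]
  rownames(subjects) <- NULL
  list(rho = rho, p_spin = p_spin, subjects = subjects)
}

#' Association of cell-map alignment with gestational age
#'
#' Per cell type, the Spearman correlation of subjects' deviation-map x
#' cell-map correlation coefficients with gestational age, with two-sided p
#' and a percentile bootstrap CI.
#'
#' @param rho Subjects x cell types matrix (see
#'   [subject_cellmap_correlations()]).
#' @param ga Gestational age per subject (aligned with `rho` rows).
#' @param B Bootstrap replicates (default 10000; 0 skips the CI).
#' @param seed Bootstrap seed.
#' @return `data.frame` with columns `cell_type`, `rho_ga`, `p`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
cell_alignment_vs_ga <- function(rho, ga, B = 10000L, seed = 1L) {
  stopifnot(is.matrix(rho), length(ga) == nrow(rho))
  if (nrow(rho) < 10L) stopf("need >= 10 subjects")
  if (stats::sd(ga, na.rm = TRUE) == 0) {
    warnf("gestational age is constant; results undefined")
  }
  rows <- lapply(seq_len(ncol(rho)), function(j) {
    x <- rho[, j]
    if (stats::sd(x, na.rm = TRUE) == 0 ||
        stats::sd(ga, na.rm = TRUE) == 0) {
      return(data.frame(cell_type = colnames(rho)[j], rho_ga = NA_real_,
                        p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        n = sum(is.finite(x) & is.finite(ga))))
    }
    tst <- spearman_test(x, ga)
    ci <- boot_ci(length(x), function(i) spearman_rho(x[i], ga[i]),
                  B = B, seed = derive_seed(seed, j))
    data.frame(cell_type = colnames(rho)[j], rho_ga = tst$rho, p = tst$p,
               ci_lo = ci[1], ci_hi = ci[2], n = tst$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
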