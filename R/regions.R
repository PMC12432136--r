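#' Bilateral Desikan-Killiany region names
#'
#' The 34 cortical regions of the Desikan-Killiany parcellation, in the
#' standard FreeSurfer `aparc` order. All pipeline stages index regions by
#' these names; hemispheres are assumed averaged upstream.
#'
#' @return Character vector of length 34.
#' @export
dk_region_names <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' Synthetic parcel centroids on the unit sphere
#'
#' Places `length(regions)` centroids on one hemisphere of the unit sphere
#' using a Fibonacci lattice (near-uniform coverage, no coincident points),
#' with a small seeded jitter so different seeds give different but
#' reproducible geometries. Bilateral (hemisphere-averaged) maps are spun on
#' single-hemisphere centroids.
#'
#' @param regions Character vector of region names (default the 34
#'   Desikan-Killiany regions).
#' @param seed Integer seed for the jitter; `NULL` for none.
#' @param jitter Angular jitter scale in radians.
#' @return `data.frame` with columns `region`, `x`, `y`, `z`
#'   (unit-norm rows), class `ibap_geometry`.
#' @export
synthetic_centroids <- function(regions = dk_region_names(), seed = 1L,
                                jitter = 0.02) {
  n <- length(regions)
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  # z restricted to (0, 1): one hemisphere
  z <- i / n
  theta <- 2 * pi * i / phi
  xyz <- cbind(sqrt(1 - z^2) * cos(theta), sqrt(1 - z^2) * sin(theta), z)
  if (!is.null(seed) && jitter > 0) {
    xyz <- with_seed(seed, xyz + matrix(stats::rnorm(3 * n, 0, jitter), n, 3))
  }
  xyz <- xyz / sqrt(rowSums(xyz^2))
  geom <- data.frame(region = regions, x = xyz[, 1], y = xyz[, 2],
                     z = xyz[, 3], stringsAsFactors = FALSE)
  class(geom) <- c("ibap_geometry", "data.frame")
  geom
}

validate_geometry <- function(geom) {
  stopifnot(is.data.frame(geom),
            all(c("region", "x", "y", "z") %in% names(geom)))
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(xyz^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stopf("centroids must lie on the unit sphere (max |norm - 1| = %.2e)",
          max(abs(nrm - 1)))
  }
  if (anyDuplicated(geom$region)) stopf("duplicate region names in geometry")
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  if (min(d) < 1e-8) stopf("coincident centroids in geometry")
  invisible(geom)
}

#' Read / write parcel centroid geometry
#'
#' Plain CSV with columns `region, x, y, z`; rows must have unit norm.
#'
#' @param path File path.
#' @param geom Geometry `data.frame` as from [synthetic_centroids()].
#' @return `read_geometry` returns the validated geometry.
#' @export
read_geometry <- function(path) {
  geom <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(geom) <- c("ibap_geometry", "data.frame")
  validate_geometry(geom)
  geom
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  utils::write.csv(as.data.frame(geom), path, row.names = FALSE)
  invisible(path)
}

# Chord-distance Gaussian kernel between centroid rows; used both for the
# spatially autocorrelated latent cell maps and by tests.
chord_kernel <- function(geom, length_scale = 0.6) {
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  exp(-d2 / (2 * length_scale^2))
}
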