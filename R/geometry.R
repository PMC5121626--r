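#' Virtual-voxel vascular geometries
#'
#' A voxel is modelled as a square periodic lattice containing straight
#' cylindrical vessels seen in cross-section. Microvessel networks place many
#' small vessels at random with isotropically distributed orientations; the
#' voxel's physical side length is chosen so that the vessel cross-sections
#' occupy exactly the requested blood volume fraction (BVf). Two-large-vessel
#' geometries hold a pair of vessels at a prescribed angle to B0.
#'
#' @name geometry
NULL

new_voxel_geometry <- function(lattice_n, voxel_side, vessels, bvf_target,
                               kind, seed) {
  g <- structure(list(lattice_n = as.integer(lattice_n),
                      voxel_side = voxel_side,
                      vessels = vessels,
                      bvf_target = bvf_target,
                      bvf_achieved = NA_real_,
                      kind = kind,
                      seed = as.integer(seed)),
                 class = "mrvf_geometry")
  g$bvf_achieved <- mean(rasterize(g)$mask)
  g
}

#' @export
print.mrvf_geometry <- function(x, ...) {
  cat(sprintf("Voxel geometry (%s): %d vessels, lattice %d^2, side %.1f um\n",
              x$kind, nrow(x$vessels), x$lattice_n, x$voxel_side))
  cat(sprintf("  BVf target %.4f, achieved %.4f\n",
              x$bvf_target, x$bvf_achieved))
  invisible(x)
}

# Rejection-sample non-overlapping disk centers on the periodic square [0, L)^2.
# Overlap would silently violate the BVf constraint, so it is forbidden; after
# max_attempts failed draws for a vessel the configuration is declared
# infeasible.
place_centers <- function(radii, L, max_attempts = 10000L) {
  n <- length(radii)
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      x <- stats::runif(1, 0, L); y <- stats::runif(1, 0, L)
      if (i == 1L) { ok <- TRUE }
      else {
        dx <- min_image(x - cx[seq_len(i - 1L)], L)
        dy <- min_image(y - cy[seq_len(i - 1L)], L)
        ok <- all(dx * dx + dy * dy >= (radii[i] + radii[seq_len(i - 1L)])^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok)
      stop(sprintf(paste0("geometry infeasible: could not place vessel %d ",
                          "(radius %.3g um) without overlap in a %.3g um voxel ",
                          "after %d attempts"),
                   i, radii[i], L, max_attempts), call. = FALSE)
  }
  cbind(cx = cx, cy = cy)
}

#' Build a random microvessel network voxel
#'
#' Places `n_vessels` non-overlapping cylinders of common radius uniformly at
#' random (with periodic wrap-around) in a square voxel whose side is adapted
#' to the BVf constraint: `voxel_side = sqrt(n_vessels * pi * radius^2 / bvf)`.
#' Each vessel receives an independent isotropic orientation: `cos(theta)`
#' uniform on \[0, 1\] (theta is the angle to B0) and a uniform in-plane
#' azimuth `phi`. Cross-sections are kept circular.
#'
#' @param bvf Target blood volume fraction, in (0, 0.5).
#' @param radius Vessel radius, micrometers.
#' @param n_vessels Number of vessels (default 96).
#' @param lattice_n Lattice points per side (default 256).
#' @param seed Integer seed; the geometry is a deterministic function of
#'   (parameters, seed).
#' @return An object of class `mrvf_geometry`.
#' @export
#' @examples
#' g <- build_microvessel_geometry(0.05, 5, n_vessels = 24, lattice_n = 64,
#'                                 seed = 1)
#' g$voxel_side  # sqrt(24 * pi * 25 / 0.05)
build_microvessel_geometry <- function(bvf, radius, n_vessels = 96L,
                                       lattice_n = 256L, seed = 1L) {
  stopifnot(bvf > 0, bvf < 0.5, radius > 0, n_vessels >= 1)
  L <- sqrt(n_vessels * pi * radius^2 / bvf)
  with_seed(seed, {
    radii <- rep(radius, n_vessels)
    centers <- place_centers(radii, L)
    theta <- acos(stats::runif(n_vessels, 0, 1)) * 180 / pi
    phi <- stats::runif(n_vessels, 0, 360)
    vessels <- data.frame(cx = centers[, "cx"], cy = centers[, "cy"],
                          radius = radii, theta = theta, phi = phi)
    new_voxel_geometry(lattice_n, L, vessels, bvf, "microvessel", seed)
  })
}

#' Build a two-large-vessel voxel with a prescribed orientation
#'
#' Places exactly two non-overlapping vessels, both at angle `theta` to B0,
#' in a voxel whose side is adapted so their cross-sections occupy `bvf`.
#' In-plane azimuths are drawn from the seed.
#'
#' @param bvf Target blood volume fraction (the large-vessel dictionary uses
#'   0.30-0.50).
#' @param radius Vessel radius, micrometers.
#' @param theta Angle between the vessels and B0, degrees in \[0, 90\].
#' @param lattice_n Lattice points per side (default 256).
#' @param seed Integer seed.
#' @return An object of class `mrvf_geometry`.
#' @export
build_large_vessel_geometry <- function(bvf, radius, theta,
                                        lattice_n = 256L, seed = 1L) {
  stopifnot(bvf > 0, bvf < 1, radius > 0)
  if (theta < 0 || theta > 90)
    stop("`theta` must lie in [0, 90] degrees", call. = FALSE)
  L <- sqrt(2 * pi * radius^2 / bvf)
  with_seed(seed, {
    radii <- rep(radius, 2L)
    centers <- place_centers(radii, L)
    phi <- stats::runif(2L, 0, 360)
    vessels <- data.frame(cx = centers[, "cx"], cy = centers[, "cy"],
                          radius = radii, theta = rep(theta, 2L), phi = phi)
    new_voxel_geometry(lattice_n, L, vessels, bvf, "two_large_vessels", seed)
  })
}

#' Rasterize a voxel geometry onto its lattice
#'
#' Lattice point (i, j) sits at the center of cell (i, j); a point belongs to
#' a vessel iff its center lies inside the vessel cross-section under the
#' minimum-image (periodic) distance. Where this is ambiguous (it cannot be
#' for non-overlapping disks) the nearest vessel wins.
#'
#' @param geometry An `mrvf_geometry`.
#' @return A list with `mask` (n x n 0/1 matrix), `labels` (n x n integer
#'   matrix, 0 = tissue, k = vessel k) and `bvf_achieved = mean(mask)`.
#' @export
rasterize <- function(geometry) {
  stopifnot(inherits(geometry, "mrvf_geometry"))
  n <- geometry$lattice_n
  L <- geometry$voxel_side
  dx <- L / n
  labels <- matrix(0L, n, n)
  v <- geometry$vessels
  if (nrow(v) > 0) {
    coords <- (seq_len(n) - 0.5) * dx
    # squared distance to current best vessel, for nearest-vessel tie-break
    best <- matrix(Inf, n, n)
    for (k in seq_len(nrow(v))) {
      ddx <- min_image(coords - v$cx[k], L)
      ddy <- min_image(coords - v$cy[k], L)
      d2 <- outer(ddx^2, ddy^2, `+`)
      inside <- d2 <= v$radius[k]^2
      take <- inside & (d2 < best)
      labels[take] <- k
      best[take] <- d2[take]
    }
  }
  mask <- (labels > 0L) + 0L
  list(mask = mask, labels = labels, bvf_achieved = mean(mask))
}

#' Serialize a geometry to JSON
#'
#' @param geometry An `mrvf_geometry`.
#' @param path Optional file path; when missing the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
geometry_to_json <- function(geometry, path = NULL) {
  stopifnot(inherits(geometry, "mrvf_geometry"))
  x <- unclass(geometry)
  js <- jsonlite::toJSON(x, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a geometry back from JSON
#' @param path_or_json A file path or a JSON string from [geometry_to_json()].
#' @return An `mrvf_geometry`.
#' @export
geometry_from_json <- function(path_or_json) {
  x <- jsonlite::fromJSON(path_or_json)
  g <- structure(x, class = "mrvf_geometry")
  g$lattice_n <- as.integer(g$lattice_n)
  g$vessels <- as.data.frame(g$vessels)
  g
}
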