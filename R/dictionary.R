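#' Dictionary parameter grids
#'
#' A grid specification lists the axes of a fingerprint dictionary: BVf,
#' vessel radius, oxygen saturation (equivalently the pre-contrast
#' susceptibility difference), ADC and, for large-vessel grids, orientation.
#' The three presets mirror the published dictionaries:
#' \itemize{
#' \item A: 42 BVf values (0.25-25\%, log-spaced) x 32 radii (0.5-100 um,
#'   log-spaced) x 29 delta-chi values (0-1.4 ppm, linear), ADC fixed at
#'   800 um^2/s: 38,976 fingerprints.
#' \item B: A extended with a 27-node ADC axis (500-1800 um^2/s, step 50,
#'   containing 800): 1,052,352 fingerprints.
#' \item C: B plus two-large-vessel voxels: 5 BVf (30-50\%) x 8 radii
#'   (50-1000 um) x 6 orientations (0-90 degrees) x 29 delta-chi x 14 ADC
#'   nodes: 97,440 additional fingerprints.
#' }
#' The exact node placement within the printed ranges is a package choice
#' (log spacing for BVf/radius, linear elsewhere) and every axis can be
#' overridden.
#'
#' @name dictionary
NULL

logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Construct a dictionary grid specification
#'
#' @param bvf_values Blood volume fractions (fractions, strictly increasing).
#' @param radius_values Vessel radii, um.
#' @param sto2_values Oxygen saturations (fractions). The pre-contrast
#'   susceptibility axis is derived from these via [delta_chi_from_sto2()].
#' @param adc_values ADC axis, um^2/s.
#' @param orientation_values Orientation axis in degrees (two-large-vessel
#'   grids), or `"isotropic"` for random microvessel networks.
#' @param geometry_kind `"microvessel"` or `"two_large_vessels"`.
#' @param n_vessels Vessels per voxel for microvessel grids (default 96).
#' @param lattice_n Lattice points per side.
#' @param base_seed Base seed; each (geometry-defining) tuple gets
#'   `base_seed + tuple index`.
#' @return An object of class `mrvf_grid`.
#' @export
grid_spec <- function(bvf_values, radius_values, sto2_values,
                      adc_values = 800,
                      orientation_values = "isotropic",
                      geometry_kind = c("microvessel", "two_large_vessels"),
                      n_vessels = 96L, lattice_n = 256L, base_seed = 20160101L) {
  geometry_kind <- match.arg(geometry_kind)
  chk <- function(x, nm) {
    if (length(x) < 1 || is.unsorted(x, strictly = TRUE))
      stop(sprintf("axis `%s` must be non-empty and strictly increasing", nm),
           call. = FALSE)
  }
  chk(bvf_values, "bvf"); chk(radius_values, "radius")
  chk(sto2_values, "sto2"); chk(adc_values, "adc")
  if (!identical(orientation_values, "isotropic")) {
    chk(orientation_values, "orientation")
    if (geometry_kind != "two_large_vessels")
      stop("explicit orientations require two-large-vessel geometries",
           call. = FALSE)
  }
  structure(list(bvf_values = bvf_values, radius_values = radius_values,
                 sto2_values = sto2_values, adc_values = adc_values,
                 orientation_values = orientation_values,
                 geometry_kind = geometry_kind,
                 n_vessels = as.integer(n_vessels),
                 lattice_n = as.integer(lattice_n),
                 base_seed = as.integer(base_seed)),
            class = "mrvf_grid")
}

#' Number of parameter tuples (fingerprints) of a grid
#' @param spec An `mrvf_grid` (or a list of them).
#' @return Integer count: the product of the axis lengths, summed over grids.
#' @export
grid_size <- function(spec) {
  if (inherits(spec, "mrvf_grid")) {
    n_or <- if (identical(spec$orientation_values, "isotropic")) 1L
            else length(spec$orientation_values)
    return(prod(length(spec$bvf_values), length(spec$radius_values),
                length(spec$sto2_values), length(spec$adc_values), n_or))
  }
  sum(vapply(spec, grid_size, numeric(1)))
}

#' @export
print.mrvf_grid <- function(x, ...) {
  n_or <- if (identical(x$orientation_values, "isotropic")) "isotropic"
          else paste(length(x$orientation_values), "values")
  cat(sprintf("Dictionary grid (%s): %d BVf x %d radius x %d StO2 x %d ADC, orientation %s\n",
              x$geometry_kind, length(x$bvf_values), length(x$radius_values),
              length(x$sto2_values), length(x$adc_values), n_or))
  cat(sprintf("  %d fingerprints\n", grid_size(x)))
  invisible(x)
}

# StO2 axis shared by all presets: 29 nodes spanning StO2 = 0..1, i.e. a
# linear pre-contrast delta-chi axis from 1.4 ppm down to 0 (Hct = 0.42).
preset_sto2_axis <- function() seq(0, 1, length.out = 29)

preset_adc_axis_b <- function() seq(500, 1800, by = 50)   # 27 nodes, has 800

#' Dictionary grid presets
#'
#' @param name `"A"`, `"B"` or `"C"`. Presets A and B return a single
#'   microvessel grid; C returns a list of two grids: the microvessel grid of
#'   B and the two-large-vessel additions.
#' @param lattice_n Lattice points per side (default 256).
#' @param base_seed Base seed for per-entry geometry seeds.
#' @return An `mrvf_grid`, or for C a list
#'   `list(microvessel = <grid>, large_vessel = <grid>)`.
#' @export
#' @examples
#' grid_size(grid_preset("A"))                 # 38976
#' grid_size(grid_preset("C")$large_vessel)    # 97440
grid_preset <- function(name = c("A", "B", "C"), lattice_n = 256L,
                        base_seed = 20160101L) {
  name <- match.arg(name)
  micro <- function(adc) grid_spec(
    bvf_values = logspace(0.0025, 0.25, 42),
    radius_values = logspace(0.5, 100, 32),
    sto2_values = preset_sto2_axis(),
    adc_values = adc,
    geometry_kind = "microvessel", n_vessels = 96L,
    lattice_n = lattice_n, base_seed = base_seed)
  if (name == "A") return(micro(800))
  if (name == "B") return(micro(preset_adc_axis_b()))
  adc27 <- preset_adc_axis_b()
  list(microvessel = micro(adc27),
       large_vessel = grid_spec(
         bvf_values = seq(0.30, 0.50, length.out = 5),
         radius_values = logspace(50, 1000, 8),
         sto2_values = preset_sto2_axis(),
         adc_values = adc27[seq(1, 27, by = 2)],   # 14 nodes incl. endpoints
         orientation_values = seq(0, 90, by = 18),
         geometry_kind = "two_large_vessels",
         lattice_n = lattice_n, base_seed = base_seed + 1000000L))
}

# Full factorial parameter table of a grid, in a fixed deterministic order.
# Geometry realizations are shared across the sto2 and adc axes: one seed per
# (bvf, radius[, orientation]) combination, so the signal count equals the
# tuple count.
grid_params <- function(spec) {
  orient <- if (identical(spec$orientation_values, "isotropic")) NA_real_
            else spec$orientation_values
  tab <- expand.grid(sto2 = spec$sto2_values, adc = spec$adc_values,
                     radius = spec$radius_values, bvf = spec$bvf_values,
                     orientation = orient,
                     KEEP.OUT.ATTRS = FALSE)
  geo <- expand.grid(radius = spec$radius_values, bvf = spec$bvf_values,
                     orientation = orient, KEEP.OUT.ATTRS = FALSE)
  geo$geom_seed <- spec$base_seed + seq_len(nrow(geo))
  tab <- merge(tab, geo, by = c("radius", "bvf", "orientation"), sort = FALSE)
  tab <- tab[order(tab$bvf, tab$radius, tab$orientation, tab$adc, tab$sto2), ]
  rownames(tab) <- NULL
  tab$entry <- seq_len(nrow(tab))
  tab$geometry_kind <- spec$geometry_kind
  tab
}

build_geometry_for <- function(spec, row) {
  if (spec$geometry_kind == "microvessel")
    build_microvessel_geometry(row$bvf, row$radius, spec$n_vessels,
                               spec$lattice_n, seed = row$geom_seed)
  else
    build_large_vessel_geometry(row$bvf, row$radius, row$orientation,
                                spec$lattice_n, seed = row$geom_seed)
}

#' Build a fingerprint dictionary from a grid specification
#'
#' Simulates the pre/post contrast GESFIDE pair for every parameter tuple and
#' stores the resulting fingerprints (post/pre echo ratios with the noisy
#' tail echoes dropped) together with the parameter table and a manifest
#' sufficient to regenerate any row bit-exactly. Entries are computed
#' independently, so the result does not depend on the number of workers.
#'
#' @param spec An `mrvf_grid` or list of grids (as returned by
#'   `grid_preset("C")`); list entries are concatenated.
#' @param seq An `mrvf_sequence`.
#' @param physics An `mrvf_physics`.
#' @param n_drop Trailing echoes removed from the fingerprint (default 8).
#' @param workers Parallel workers (forked; 1 = serial).
#' @param ratio Fingerprint ratio convention, `"post-pre"` (default) or
#'   `"pre-post"`; must match the data at matching time.
#' @param progress Print a line every `progress` entries (0 = quiet).
#' @return An object of class `mrvf_dictionary`: list with `entries`
#'   (n_entries x n_kept matrix), `params` (data.frame), `echo_times`
#'   (kept echoes, ms), `signals_pre` / `signals_post` (full-echo magnitude
#'   matrices, used by the phantom generator), and `manifest`.
#' @export
build_dictionary <- function(spec, seq = sequence_params(),
                             physics = physics_constants(),
                             n_drop = 8L, workers = 1L,
                             ratio = c("post-pre", "pre-post"),
                             progress = 0L) {
  ratio <- match.arg(ratio)
  specs <- if (inherits(spec, "mrvf_grid")) list(spec) else spec
  stopifnot(all(vapply(specs, inherits, logical(1), "mrvf_dictionary") == FALSE))
  params <- do.call(rbind, lapply(specs, function(s) {
    p <- grid_params(s)
    p$lattice_n <- s$lattice_n
    p$n_vessels <- if (s$geometry_kind == "microvessel") s$n_vessels else 2L
    p
  }))
  params$entry <- seq_len(nrow(params))
  if (anyDuplicated(params[, c("bvf", "radius", "sto2", "adc", "orientation",
                               "geometry_kind")]))
    stop("duplicate parameter tuples across grids", call. = FALSE)
  spec_of <- rep(seq_along(specs),
                 vapply(specs, function(s) nrow(grid_params(s)), integer(1)))

  one_entry <- function(i) {
    row <- params[i, ]
    s <- specs[[spec_of[i]]]
    geom <- build_geometry_for(s, row)
    pair <- simulate_pair(geom, row$sto2, row$adc, seq, physics)
    fp <- make_fingerprint(pair$pre, pair$post, n_drop = n_drop, ratio = ratio)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  entry %d / %d", i, nrow(params)))
    list(fp = fp$ratio, pre = pair$pre$signal, post = pair$post$signal)
  }
  idx <- seq_len(nrow(params))
  res <- if (workers > 1L)
    parallel::mclapply(idx, one_entry, mc.cores = workers)
  else lapply(idx, one_entry)
  failed <- vapply(res, inherits, logical(1), "try-error")
  if (any(failed))
    stop(sprintf("dictionary build failed for entries: %s",
                 paste(idx[failed], collapse = ", ")), call. = FALSE)
  entries <- do.call(rbind, lapply(res, `[[`, "fp"))
  if (any(!is.finite(entries)) || any(entries <= 0))
    stop("dictionary entries must be finite and positive", call. = FALSE)
  n_kept <- seq$n_echoes - n_drop
  manifest <- list(sequence = unclass(seq), physics = unclass(physics),
                   n_drop = n_drop, ratio = ratio,
                   grids = lapply(specs, unclass),
                   package_version = as.character(utils::packageVersion("mrvf")))
  structure(list(entries = entries,
                 params = params,
                 echo_times = seq$echo_times[seq_len(n_kept)],
                 signals_pre = do.call(rbind, lapply(res, `[[`, "pre")),
                 signals_post = do.call(rbind, lapply(res, `[[`, "post")),
                 manifest = manifest),
            class = "mrvf_dictionary")
}

#' @export
print.mrvf_dictionary <- function(x, ...) {
  cat(sprintf("Fingerprint dictionary: %d entries x %d echoes (%s ratio)\n",
              nrow(x$entries), ncol(x$entries), x$manifest$ratio))
  axes <- c("bvf", "radius", "sto2", "adc", "orientation")
  for (a in axes) {
    u <- sort(unique(x$params[[a]]))
    u <- u[is.finite(u)]
    if (length(u) > 1)
      cat(sprintf("  %-11s: %d values in [%.4g, %.4g]\n", a, length(u),
                  min(u), max(u)))
  }
  invisible(x)
}

#' Rebuild one dictionary entry from its manifest
#'
#' Determinism check helper: regenerates the fingerprint of entry `i` from
#' the stored manifest alone.
#'
#' @param dict An `mrvf_dictionary`.
#' @param i Entry index.
#' @return Numeric fingerprint vector.
#' @export
rebuild_entry <- function(dict, i) {
  row <- dict$params[i, ]
  g_idx <- which(vapply(dict$manifest$grids, function(g)
    g$geometry_kind == row$geometry_kind, logical(1)))[1]
  s <- structure(dict$manifest$grids[[g_idx]], class = "mrvf_grid")
  seqp <- do.call(sequence_params, dict$manifest$sequence[
    c("delta_te", "se_time", "tr", "dt", "echo_times")])
  phys <- do.call(physics_constants, dict$manifest$physics)
  geom <- build_geometry_for(s, row)
  pair <- simulate_pair(geom, row$sto2, row$adc, seqp, phys)
  make_fingerprint(pair$pre, pair$post, n_drop = dict$manifest$n_drop,
                   ratio = dict$manifest$ratio)$ratio
}

#' Restrict a dictionary to the ADC plane nearest a measured value
#'
#' The measured ADC is rounded to the closest simulated ADC node (ties to the
#' lower node, values beyond the axis clamped to its ends) and the
#' corresponding subset of curves is returned.
#'
#' @param dict An `mrvf_dictionary`.
#' @param adc_measured Measured ADC, um^2/s.
#' @return An `mrvf_dictionary` view containing only the selected plane; its
#'   `adc_plane` field records the node.
#' @export
restrict_to_adc <- function(dict, adc_measured) {
  stopifnot(inherits(dict, "mrvf_dictionary"), nrow(dict$entries) > 0)
  axis <- sort(unique(dict$params$adc))
  d <- abs(axis - adc_measured)
  sel_adc <- axis[which.min(d + 1e-12 * seq_along(axis))]  # ties -> lower
  keep <- dict$params$adc == sel_adc
  out <- dict
  out$entries <- dict$entries[keep, , drop = FALSE]
  out$params <- dict$params[keep, , drop = FALSE]
  if (!is.null(dict$signals_pre)) {
    out$signals_pre <- dict$signals_pre[keep, , drop = FALSE]
    out$signals_post <- dict$signals_post[keep, , drop = FALSE]
  }
  out$adc_plane <- sel_adc
  out
}

#' Save / load a dictionary
#'
#' The dictionary is stored as an RDS file together with a JSON manifest
#' sidecar (`<path>.manifest.json`) recording grids, sequence, physics and
#' software version.
#'
#' @param dict An `mrvf_dictionary`.
#' @param path Output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "mrvf_dictionary"))
  saveRDS(dict, path)
  jsonlite::write_json(dict$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  dict <- readRDS(path)
  stopifnot(inherits(dict, "mrvf_dictionary"))
  dict
}
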