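#' Fingerprints and dictionary matching
#'
#' A vascular fingerprint is the per-echo ratio of the post- and pre-contrast
#' GESFIDE signals. Any multiplicative factor common to the two acquisitions
#' (T2 decay, B1 and macroscopic B0 modulation, coil sensitivity) cancels in
#' the ratio, so the fingerprint isolates the susceptibility-driven
#' dephasing. The last echoes (default 8 of 32), acquired at low SNR, are
#' removed. Matching finds the dictionary entry minimizing the reduced
#' chi-squared `sum((fp - row)^2) / (n - 1)` (unit noise weights, so the
#' ranking equals the sum of squared errors) and reports the coefficient of
#' determination r^2 of the selected row.
#'
#' @name matching
NULL

#' Compute a fingerprint from a pre/post signal pair
#'
#' @param pre,post `mrvf_signal` objects sharing echo times, or bare
#'   magnitude vectors.
#' @param n_drop Number of trailing echoes to remove (default 8).
#' @param ratio `"post-pre"` (default: post/pre) or `"pre-post"`.
#' @param echo_times Echo times when `pre`/`post` are bare vectors.
#' @return An object of class `mrvf_fingerprint`: list with `ratio`,
#'   `echo_times`, `n_dropped_tail`, `valid`. Non-positive signal on a kept
#'   echo flags the voxel invalid rather than erroring.
#' @export
make_fingerprint <- function(pre, post, n_drop = 8L,
                             ratio = c("post-pre", "pre-post"),
                             echo_times = NULL) {
  ratio <- match.arg(ratio)
  if (inherits(pre, "mrvf_signal")) {
    if (!isTRUE(all.equal(pre$times, post$times)))
      stop("pre and post arms must share echo times", call. = FALSE)
    echo_times <- pre$times
    pre <- pre$signal; post <- post$signal
  }
  stopifnot(length(pre) == length(post), n_drop >= 0,
            n_drop < length(pre))
  keep <- seq_len(length(pre) - n_drop)
  num <- if (ratio == "post-pre") post[keep] else pre[keep]
  den <- if (ratio == "post-pre") pre[keep] else post[keep]
  valid <- all(is.finite(num)) && all(is.finite(den)) && all(den > 0) &&
    all(num > 0)
  r <- if (valid) num / den else rep(NA_real_, length(keep))
  structure(list(ratio = r,
                 echo_times = if (!is.null(echo_times)) echo_times[keep],
                 n_dropped_tail = as.integer(n_drop),
                 valid = valid),
            class = "mrvf_fingerprint")
}

#' In-plane 3x3 Gaussian smoothing of a multi-echo volume
#'
#' Applied slice-by-slice and echo-by-echo before fingerprint computation to
#' increase SNR. The kernel has unit sum; edges are handled by renormalizing
#' over the in-image footprint, which preserves constants exactly.
#'
#' @param volume 4D array (x, y, slice, echo); 3D and 2D inputs are promoted.
#' @param sigma Kernel standard deviation in voxels (default 0.8).
#' @return Smoothed array of the original shape.
#' @export
smooth_inplane <- function(volume, sigma = 0.8) {
  dms <- dim(volume)
  orig_dim <- dms
  if (is.null(dms)) stop("`volume` must be an array", call. = FALSE)
  if (length(dms) == 2) dim(volume) <- dms <- c(dms, 1L, 1L)
  if (length(dms) == 3) dim(volume) <- dms <- c(dms, 1L)
  if (dms[1] < 3 || dms[2] < 3)
    stop("in-plane extent must be at least 3 x 3", call. = FALSE)
  g1 <- exp(-((-1):1)^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  out <- volume
  # zero-pad the data and the weight image, then renormalize: unit-sum
  # everywhere in the interior, rescaled footprint at the edges
  for (z in seq_len(dms[3])) for (e in seq_len(dms[4])) {
    img <- volume[, , z, e]
    acc <- matrix(0, dms[1], dms[2]); wacc <- matrix(0, dms[1], dms[2])
    for (di in -1:1) for (dj in -1:1) {
      w <- kern[di + 2, dj + 2]
      si <- max(1, 1 - di):min(dms[1], dms[1] - di)
      sj <- max(1, 1 - dj):min(dms[2], dms[2] - dj)
      acc[si, sj] <- acc[si, sj] + w * img[si + di, sj + dj]
      wacc[si, sj] <- wacc[si, sj] + w
    }
    out[, , z, e] <- acc / wacc
  }
  dim(out) <- orig_dim
  out
}

excluded_match <- function() {
  structure(list(bvf = NA_real_, radius = NA_real_, sto2 = NA_real_,
                 orientation = NA_real_, adc_plane = NA_real_,
                 r2 = -Inf, chi2 = NA_real_, entry_index = NA_integer_,
                 excluded = TRUE),
            class = "mrvf_match")
}

#' Match a single fingerprint against a dictionary
#'
#' When the dictionary has an ADC axis and a measured ADC is supplied, the
#' search is restricted to the nearest simulated ADC plane first. The entry
#' minimizing the reduced chi-squared is selected (first minimum on ties);
#' r^2 is computed against the selected row. Invalid or degenerate
#' (constant) fingerprints yield an excluded result with `r2 = -Inf`.
#'
#' @param fp An `mrvf_fingerprint` or bare ratio vector.
#' @param dict An `mrvf_dictionary`.
#' @param adc_measured Measured ADC, um^2/s, or `NULL`.
#' @return An object of class `mrvf_match` with fields `bvf`, `radius`,
#'   `sto2`, `orientation`, `adc_plane`, `r2`, `chi2`, `entry_index`,
#'   `excluded`.
#' @export
match_voxel <- function(fp, dict, adc_measured = NULL) {
  v <- if (inherits(fp, "mrvf_fingerprint")) {
    if (!fp$valid) return(excluded_match())
    fp$ratio
  } else fp
  if (any(!is.finite(v))) return(excluded_match())
  if (ncol(dict$entries) != length(v))
    stop(sprintf("fingerprint length %d does not match dictionary row length %d",
                 length(v), ncol(dict$entries)), call. = FALSE)
  sstot <- sum((v - mean(v))^2)
  if (sstot == 0) return(excluded_match())
  sub <- if (!is.null(adc_measured) && length(unique(dict$params$adc)) > 1)
    restrict_to_adc(dict, adc_measured) else dict
  E <- sub$entries
  sse <- pmax(rowSums(E * E) - 2 * drop(E %*% v) + sum(v * v), 0)
  best <- which.min(sse)
  n <- length(v)
  row <- sub$params[best, ]
  structure(list(bvf = row$bvf, radius = row$radius, sto2 = row$sto2,
                 orientation = row$orientation,
                 adc_plane = sub$adc_plane %||% row$adc,
                 r2 = 1 - sse[best] / sstot,
                 chi2 = sse[best] / (n - 1),
                 entry_index = row$entry,
                 excluded = FALSE),
            class = "mrvf_match")
}

#' @export
print.mrvf_match <- function(x, ...) {
  if (x$excluded) { cat("Match: excluded voxel\n"); return(invisible(x)) }
  cat(sprintf("Match: BVf %.3g, radius %.3g um, StO2 %.3g, r2 %.4f (entry %d)\n",
              x$bvf, x$radius, x$sto2, x$r2, x$entry_index))
  invisible(x)
}

#' Match pre/post multi-echo volumes against a dictionary
#'
#' The full fingerprinting pipeline: in-plane 3x3 Gaussian smoothing of both
#' arms, per-voxel fingerprint computation, dictionary search (restricted to
#' the nearest ADC plane where an ADC axis and map exist), and assembly of
#' parametric maps. Voxels with invalid fingerprints or `r^2 <` threshold
#' are recorded in the exclusion mask.
#'
#' @param pre4d,post4d 4D arrays (x, y, slice, echo) of echo magnitudes.
#' @param adc_map 3D ADC array (um^2/s) or `NULL`.
#' @param dict An `mrvf_dictionary`.
#' @param r2_threshold Exclusion threshold on r^2 (default 0.8).
#' @param smooth Apply the 3x3 smoothing (default TRUE; disable for
#'   already-clean synthetic data).
#' @param n_drop Trailing echoes removed per fingerprint; defaults to the
#'   dictionary's convention.
#' @return An object of class `mrvf_maps`: list of 3D arrays `bvf`, `radius`,
#'   `sto2`, `orientation`, `r2`, plus `excluded` (logical) and
#'   `r2_threshold`.
#' @export
match_volume <- function(pre4d, post4d, adc_map = NULL, dict,
                         r2_threshold = 0.8, smooth = TRUE, n_drop = NULL) {
  if (!identical(dim(pre4d), dim(post4d)))
    stop("pre and post volumes have different shapes", call. = FALSE)
  dms <- dim(pre4d)
  if (length(dms) != 4) stop("expected 4D (x, y, slice, echo) input",
                             call. = FALSE)
  if (!is.null(adc_map) && !identical(dim(adc_map), dms[1:3]))
    stop("ADC map shape does not match the echo volumes", call. = FALSE)
  n_drop <- n_drop %||% dict$manifest$n_drop
  ratio <- dict$manifest$ratio %||% "post-pre"
  if (smooth) { pre4d <- smooth_inplane(pre4d); post4d <- smooth_inplane(post4d) }
  shp <- dms[1:3]
  mk <- function() array(NA_real_, shp)
  maps <- list(bvf = mk(), radius = mk(), sto2 = mk(), orientation = mk(),
               r2 = mk())
  excluded <- array(TRUE, shp)
  has_adc_axis <- length(unique(dict$params$adc)) > 1
  # precompute per-ADC-plane views once; per-voxel restriction would be slow
  planes <- if (has_adc_axis) {
    axis <- sort(unique(dict$params$adc))
    stats::setNames(lapply(axis, function(a) restrict_to_adc(dict, a)),
                    as.character(axis))
  }
  for (k in seq_len(shp[3])) for (j in seq_len(shp[2])) for (i in seq_len(shp[1])) {
    fp <- make_fingerprint(pre4d[i, j, k, ], post4d[i, j, k, ],
                           n_drop = n_drop, ratio = ratio)
    d <- dict
    if (has_adc_axis && !is.null(adc_map)) {
      axis <- as.numeric(names(planes))
      d <- planes[[which.min(abs(axis - adc_map[i, j, k]))]]
    }
    m <- match_voxel(fp, d)
    maps$r2[i, j, k] <- m$r2
    if (!m$excluded) {
      maps$bvf[i, j, k] <- m$bvf
      maps$radius[i, j, k] <- m$radius
      maps$sto2[i, j, k] <- m$sto2
      maps$orientation[i, j, k] <- m$orientation
      excluded[i, j, k] <- !(m$r2 >= r2_threshold)
    }
  }
  structure(c(maps, list(excluded = excluded, r2_threshold = r2_threshold)),
            class = "mrvf_maps")
}

#' @export
print.mrvf_maps <- function(x, ...) {
  cat(sprintf("Parametric maps %s: %.1f%% voxels excluded (r2 < %.2f or invalid)\n",
              paste(dim(x$bvf), collapse = " x "),
              100 * mean(x$excluded), x$r2_threshold))
  invisible(x)
}
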