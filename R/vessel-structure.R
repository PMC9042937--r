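#' Construct a confocal fluorescence volume
#'
#' Container for a scanning-laser-confocal z-stack of vessel fluorescence
#' (e.g. IB4-labelled endothelium), indexed (x, y, z-plane). Voxels are
#' anisotropic: lateral pixel sizes are sub-micron while the z-step between
#' optical planes is several microns, so volumes in µm³ must use all three
#' voxel dimensions.
#'
#' @param intensity Numeric 3-d array `(nx, ny, nplanes)`.
#' @param voxel_size `(dx, dy, dz)` in µm; default `c(0.56, 0.56, 5)`, a 10x
#'   lens with a 5 µm z-step and ten planes.
#' @param roi Optional logical `(nx, ny)` in-plane mask delimiting the
#'   hippocampus; `NULL` means the full field.
#' @return A `fluor_volume` object.
#' @export
fluor_volume <- function(intensity, voxel_size = c(0.56, 0.56, 5), roi = NULL) {
  abort_if(!(is.array(intensity) && length(dim(intensity)) == 3 && is.numeric(intensity)),
           "`intensity` must be a numeric 3-d array (x, y, plane).")
  abort_if(length(voxel_size) != 3 || any(voxel_size <= 0),
           "`voxel_size` must be three positive values (dx, dy, dz) in um.")
  if (!is.null(roi)) {
    abort_if(!is.logical(roi) || !identical(dim(roi), dim(intensity)[1:2]),
             "`roi` must be a logical (nx, ny) matrix matching the planes.")
  }
  structure(list(intensity = intensity, voxel_size = as.numeric(voxel_size), roi = roi),
            class = "fluor_volume")
}

#' @export
print.fluor_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<fluor_volume> %d x %d px, %d planes, voxel %g x %g x %g um\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# iterative intermeans (IsoData) threshold of a numeric vector:
# split at t, move t to the mean of the two class means, iterate to fixpoint
isodata_threshold <- function(x, tol = 1e-7) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  t <- mean(x)
  for (i in 1:500) {
    lo <- x[x < t]; hi <- x[x >= t]
    if (length(lo) == 0 || length(hi) == 0) return(t)
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) <= tol * (rng[2] - rng[1])) return(t_new)
    t <- t_new
  }
  t
}

# Otsu threshold (maximum between-class variance) on a binned histogram
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
  w <- cumsum(h); mu <- cumsum(h * seq_len(n_bins))
  tot_w <- w[n_bins]; tot_mu <- mu[n_bins]
  between <- (tot_mu * w - mu * tot_w)^2 / (w * (tot_w - w))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  breaks[k + 1]
}

#' Binarize a fluorescence z-stack plane by plane
#'
#' Each optical plane gets its own automatic threshold computed from the
#' in-ROI pixels; voxels at or above the plane threshold are vessel
#' foreground. The default algorithm is the iterative intermeans (IsoData)
#' rule, the classic default automatic threshold of image-analysis tools;
#' Otsu's maximum between-class variance is available as an alternative. A
#' constant plane has no separable classes: it yields an empty foreground
#' and is flagged.
#'
#' @param volume A [fluor_volume()].
#' @param method `"isodata"` (default) or `"otsu"`.
#' @return A `binary_volume`: list with `mask` (logical array), `thresholds`
#'   (tibble `plane, threshold, degenerate`), `voxel_size` and `roi`.
#' @export
binarize_stack <- function(volume, method = c("isodata", "otsu")) {
  abort_if(!inherits(volume, "fluor_volume"), "`volume` must be a fluor_volume.")
  method <- match.arg(method)
  d <- dim(volume$intensity)
  roi <- volume$roi %||% matrix(TRUE, d[1], d[2])
  mask <- array(FALSE, d)
  thr <- numeric(d[3]); degen <- logical(d[3])
  for (p in seq_len(d[3])) {
    plane <- volume$intensity[, , p]
    vals <- plane[roi]
    t <- switch(method, isodata = isodata_threshold(vals), otsu = otsu_threshold(vals))
    if (is.na(t)) {                      # constant plane: nothing separable
      degen[p] <- TRUE
      thr[p] <- NA_real_
      rlang::warn(sprintf("plane %d is constant; no foreground extracted.", p))
    } else {
      thr[p] <- t
      mask[, , p] <- (plane >= t) & roi
    }
  }
  structure(list(mask = mask,
                 thresholds = tibble::tibble(plane = seq_len(d[3]),
                                             threshold = thr, degenerate = degen),
                 voxel_size = volume$voxel_size, roi = roi, method = method),
            class = "binary_volume")
}

# 3-d connectivity offsets
connectivity_offsets <- function(connectivity) {
  abort_if(!connectivity %in% c(6L, 26L), "`connectivity` must be 6 or 26.")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# connected-component labels of a logical 3-d array.
# Vectorized label propagation: every foreground voxel starts labelled with
# its own linear index; sweeps take the minimum label over the neighborhood,
# with pointer-jumping (label <- label[label]) between sweeps, until stable.
# Returns an integer array, 0 = background, components numbered 1..n in
# order of their minimum linear index.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (length(fg) == 0) return(lab)
  lab[fg] <- fg
  offs <- connectivity_offsets(as.integer(connectivity))
  src_rng <- function(n, o) if (o >= 0) seq_len(n - o) else seq(1 - o, n)
  repeat {
    before <- lab[fg]
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      sx <- src_rng(d[1], o[1]); sy <- src_rng(d[2], o[2]); sz <- src_rng(d[3], o[3])
      tx <- sx + o[1]; ty <- sy + o[2]; tz <- sz + o[3]
      nb <- array(0L, d)
      nb[tx, ty, tz] <- lab[sx, sy, sz]
      take <- nb > 0L & lab > 0L & nb < lab
      lab[take] <- nb[take]
    }
    repeat {                              # pointer jumping: compress chains
      jumped <- lab[lab[fg]]
      if (identical(jumped, lab[fg])) break
      lab[fg] <- jumped
    }
    if (identical(lab[fg], before)) break
  }
  reps <- sort(unique(lab[fg]))
  lab[fg] <- match(lab[fg], reps)
  lab
}

#' Label 3-d connected vessel components
#'
#' Partitions the foreground of a binarized z-stack into maximal connected
#' components — individual vessels — and measures each one. The default
#' 26-neighborhood connects voxels sharing a face, edge or corner, which
#' suits elongated vessels running diagonally through the anisotropic grid;
#' 6-connectivity (faces only) is available.
#'
#' @param binary A [binarize_stack()] result (or a logical 3-d array, in
#'   which case `voxel_size` must be given).
#' @param connectivity 26 (default) or 6.
#' @param voxel_size `(dx, dy, dz)` µm, taken from `binary` when available.
#' @param min_voxels Drop components smaller than this many voxels
#'   (default 1 = keep everything; no size filter is applied unless asked).
#' @return A tibble, one row per component: `id`, `voxel_count`,
#'   `volume_um3` (voxel count times voxel volume), bounding box
#'   (`x0,x1,y0,y1,z0,z1`), `touches_edge` (component reaches the array
#'   border, kept but recorded for sensitivity analyses), plus attributes
#'   `label_array` (integer array of labels) and `connectivity`.
#' @export
label_vessels <- function(binary, connectivity = 26, voxel_size = NULL,
                          min_voxels = 1) {
  if (inherits(binary, "binary_volume")) {
    mask <- binary$mask
    voxel_size <- voxel_size %||% binary$voxel_size
  } else {
    abort_if(!(is.array(binary) && is.logical(binary) && length(dim(binary)) == 3),
             "`binary` must be a binary_volume or a logical 3-d array.")
    mask <- binary
    abort_if(is.null(voxel_size), "`voxel_size` is required for a bare array.")
  }
  lab <- label_components(mask, connectivity)
  fg <- which(lab > 0L)
  if (length(fg) == 0) {
    out <- tibble::tibble(id = integer(), voxel_count = integer(),
                          volume_um3 = numeric(), x0 = integer(), x1 = integer(),
                          y0 = integer(), y1 = integer(), z0 = integer(),
                          z1 = integer(), touches_edge = logical())
  } else {
    coords <- arrayInd(fg, dim(mask))
    d <- dim(mask)
    out <- tibble::tibble(id = lab[fg], x = coords[, 1], y = coords[, 2],
                          z = coords[, 3]) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(voxel_count = dplyr::n(),
                       x0 = min(.data$x), x1 = max(.data$x),
                       y0 = min(.data$y), y1 = max(.data$y),
                       z0 = min(.data$z), z1 = max(.data$z),
                       touches_edge = any(.data$x == 1L | .data$x == d[1] |
                                          .data$y == 1L | .data$y == d[2] |
                                          .data$z == 1L | .data$z == d[3]),
                       .groups = "drop") |>
      dplyr::mutate(volume_um3 = .data$voxel_count * prod(voxel_size)) |>
      dplyr::relocate("id", "voxel_count", "volume_um3")
    if (min_voxels > 1)
      out <- dplyr::filter(out, .data$voxel_count >= min_voxels)
  }
  attr(out, "label_array") <- lab
  attr(out, "connectivity") <- as.integer(connectivity)
  attr(out, "voxel_size") <- voxel_size
  out
}

#' Hippocampus geometry for volume-fraction normalization
#'
#' The hippocampal reference volume is the in-plane hippocampal surface area
#' multiplied by the height (thickness) of the coronal section.
#'
#' @param surface_um2 In-plane ROI area in µm²; alternatively supply `roi`
#'   plus `voxel_size` and the area is `sum(roi) * dx * dy`.
#' @param section_height_um Coronal section thickness in µm (e.g. 50).
#' @param roi Optional logical in-plane mask.
#' @param voxel_size `(dx, dy, ...)` µm, needed with `roi`.
#' @return A `hippocampus_geometry` list: `surface_um2`, `section_height_um`,
#'   `volume_um3 = surface * height`.
#' @export
hippocampus_geometry <- function(surface_um2 = NULL, section_height_um,
                                 roi = NULL, voxel_size = NULL) {
  if (is.null(surface_um2)) {
    abort_if(is.null(roi) || is.null(voxel_size),
             "supply `surface_um2`, or `roi` with `voxel_size`.")
    surface_um2 <- sum(roi) * voxel_size[1] * voxel_size[2]
  }
  abort_if(surface_um2 <= 0 || section_height_um <= 0,
           "surface and section height must be positive.")
  structure(list(surface_um2 = surface_um2,
                 section_height_um = section_height_um,
                 volume_um3 = surface_um2 * section_height_um),
            class = "hippocampus_geometry")
}

#' Vessel volume fraction of each component
#'
#' VVF expresses each vessel's volume as a fraction of the hippocampal
#' volume, scaled by 1000: `vvf = 1000 * volume_um3 / hippocampal volume`.
#'
#' @param components Tibble from [label_vessels()].
#' @param geometry A [hippocampus_geometry()].
#' @return The components tibble with a `vvf` column added.
#' @export
compute_vvf <- function(components, geometry) {
  abort_if(!inherits(geometry, "hippocampus_geometry"),
           "`geometry` must be a hippocampus_geometry.")
  abort_if(geometry$volume_um3 <= 0, "hippocampal volume must be positive.")
  dplyr::mutate(components, vvf = 1000 * .data$volume_um3 / geometry$volume_um3)
}

#' Canonical VVF range boundaries
#'
#' The four vessel-caliber ranges `[0, 0.0003)`, `[0.0003, 0.003)`,
#' `[0.003, 1]` and `(1, Inf)`, aligned with capillary-venule, arteriole,
#' venule and artery-vein reserve-capacity levels. The third range closes at
#' 1 so that the last range is strictly "> 1".
#' @export
vvf_range_labels <- c("0-0.0003", "0.0003-0.003", "0.003-1", ">1")

vvf_range_of <- function(vvf, boundaries = c(3e-4, 3e-3, 1)) {
  abort_if(any(vvf < 0), "negative VVF.")
  dplyr::case_when(vvf < boundaries[1] ~ vvf_range_labels[1],
                   vvf < boundaries[2] ~ vvf_range_labels[2],
                   vvf <= boundaries[3] ~ vvf_range_labels[3],
                   TRUE ~ vvf_range_labels[4])
}

#' Partition vessels into the four VVF ranges
#'
#' Assigns every vessel to exactly one caliber range and summarises each
#' range: vessel count, mean VVF, total VVF, and the volume-per-vessel ratio
#' (total VVF over count, the supplementary per-range measure). Empty ranges
#' are reported with a count of 0 and missing means.
#'
#' @param components Tibble with a `vvf` column (see [compute_vvf()]).
#' @param boundaries The three inner boundaries, default `c(0.0003, 0.003, 1)`.
#' @return A `vvf_partition` tibble with one row per range:
#'   `range, n_vessels, mean_vvf, total_vvf, vvf_per_vessel`; attribute
#'   `boundaries`.
#' @export
partition_ranges <- function(components, boundaries = c(3e-4, 3e-3, 1)) {
  abort_if(!"vvf" %in% names(components), "components need a `vvf` column (compute_vvf).")
  comp <- dplyr::mutate(components,
                        range = factor(vvf_range_of(.data$vvf, boundaries),
                                       levels = vvf_range_labels))
  out <- comp |>
    dplyr::group_by(.data$range, .drop = FALSE) |>
    dplyr::summarise(n_vessels = dplyr::n(),
                     mean_vvf = mean(.data$vvf),
                     total_vvf = sum(.data$vvf), .groups = "drop") |>
    dplyr::mutate(mean_vvf = ifelse(.data$n_vessels == 0, NA_real_, .data$mean_vvf),
                  total_vvf = ifelse(.data$n_vessels == 0, 0, .data$total_vvf),
                  vvf_per_vessel = ifelse(.data$n_vessels == 0, NA_real_,
                                          .data$total_vvf / .data$n_vessels))
  attr(out, "boundaries") <- boundaries
  class(out) <- c("vvf_partition", class(out))
  out
}

#' Average per-range summaries of two consecutive slices
#'
#' One mean VVF value per range, per hippocampus and per mouse is obtained
#' by averaging the per-range summaries of two consecutive coronal confocal
#' slices (together about as thick as the Doppler beam in elevation).
#'
#' @param a,b `vvf_partition` tibbles with identical range boundaries.
#' @return A `vvf_partition` with pairwise-averaged summaries; attribute
#'   `provenance` records that two slices were averaged.
#' @export
average_slices <- function(a, b) {
  abort_if(!inherits(a, "vvf_partition") || !inherits(b, "vvf_partition"),
           "`a` and `b` must be vvf_partition tibbles.")
  abort_if(!isTRUE(all.equal(attr(a, "boundaries"), attr(b, "boundaries"))),
           "range boundaries differ between slices.")
  abort_if(!identical(as.character(a$range), as.character(b$range)),
           "range rows differ between slices.")
  avg <- function(x, y) (x + y) / 2
  out <- tibble::tibble(range = a$range,
                        n_vessels = avg(a$n_vessels, b$n_vessels),
                        mean_vvf = avg(a$mean_vvf, b$mean_vvf),
                        total_vvf = avg(a$total_vvf, b$total_vvf),
                        vvf_per_vessel = avg(a$vvf_per_vessel, b$vvf_per_vessel))
  attr(out, "boundaries") <- attr(a, "boundaries")
  attr(out, "provenance") <- "mean of two consecutive slices"
  class(out) <- c("vvf_partition", class(out))
  out
}
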