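#' Ground truth for a synthetic Doppler scene
#'
#' Describes a compound-frame stack as the sum of three components with a
#' known singular-value structure: (i) `tissue_rank` rank-one clutter terms
#' — spatially smooth profiles times slow temporal oscillations — carrying
#' the highest energy; (ii) blood flow confined to `vessel_mask`, each
#' vessel pixel a complex exponential at the Doppler frequency of a velocity
#' drawn from `blood_velocity_range`; (iii) circularly-symmetric complex
#' white noise. Amplitudes default so that tissue singular values dominate
#' the blood band, which in turn dominates the noise plateau.
#'
#' @param tissue_rank Number of rank-one tissue components (>= 0).
#' @param tissue_amplitude Linear amplitude scale of the strongest tissue
#'   component; successive components decay geometrically (factor 0.85).
#' @param vessel_mask Logical (nx, nz) matrix of vessel pixels, or `NULL` to
#'   let [gen_doppler_scene()] place two vertical vessels.
#' @param blood_amplitude Per-pixel modulus of the flow signal.
#' @param blood_velocity_range `(min, max)` blood speed in mm/s; Doppler
#'   frequency is `2 v f0 / c` with `f0` = 15 MHz, `c` = 1540 m/s.
#' @param noise_sigma Root-mean-square modulus of the complex noise.
#' @param seed RNG seed making the scene bit-reproducible.
#' @return A `doppler_truth` list.
#' @export
doppler_scene_truth <- function(tissue_rank = 4, tissue_amplitude = 40,
                                vessel_mask = NULL, blood_amplitude = 4,
                                blood_velocity_range = c(2, 10),
                                noise_sigma = 0.5, seed = 1) {
  abort_if(!(is.numeric(tissue_rank) && tissue_rank >= 0 && tissue_rank == trunc(tissue_rank)),
           "`tissue_rank` must be a non-negative integer.")
  abort_if(tissue_amplitude < 0 || blood_amplitude < 0 || noise_sigma < 0,
           "amplitudes must be non-negative.")
  abort_if(blood_velocity_range[1] > blood_velocity_range[2],
           "`blood_velocity_range` is inverted.")
  if (tissue_amplitude > 0 && blood_amplitude > 0 && noise_sigma > 0)
    abort_if(!(tissue_amplitude > blood_amplitude && blood_amplitude > noise_sigma),
             "require tissue_amplitude > blood_amplitude > noise_sigma.")
  structure(list(tissue_rank = as.integer(tissue_rank),
                 tissue_amplitude = tissue_amplitude, vessel_mask = vessel_mask,
                 blood_amplitude = blood_amplitude,
                 blood_velocity_range = blood_velocity_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "doppler_truth")
}

#' Generate a synthetic compound-frame Doppler scene
#'
#' Builds the complex (x, z, t) stack described by a [doppler_scene_truth()].
#' Tissue terms are outer products of unit-norm 2-d Gaussian blobs and
#' unit-modulus temporal oscillations below 5 Hz, so the tissue part has
#' numerical rank at most `tissue_rank`. Flow pixels advance in phase at the
#' Doppler frequency of their own velocity, giving spectral separation from
#' the near-DC clutter. Identical truth (including seed) gives bit-identical
#' stacks.
#'
#' @param truth A [doppler_scene_truth()].
#' @param nx,nz,nt Stack dimensions (the reference acquisition is
#'   128 x 92 x 350).
#' @param frame_rate Hz, default 500.
#' @param dx,dz Pixel pitch in mm.
#' @return A [compound_stack()] with attribute `truth` (the truth, with the
#'   realized `vessel_mask` filled in).
#' @export
gen_doppler_scene <- function(truth, nx = 128, nz = 92, nt = 350,
                              frame_rate = 500, dx = 0.1, dz = 0.1) {
  abort_if(!inherits(truth, "doppler_truth"), "`truth` must be a doppler_scene_truth.")
  abort_if(!(is_count(nx) && is_count(nz) && is_count(nt)),
           "dimensions must be positive integers.")
  mask <- truth$vessel_mask
  if (!is.null(mask))
    abort_if(!identical(dim(mask), c(as.integer(nx), as.integer(nz))),
             "vessel_mask shape must match (nx, nz).")
  with_seed(truth$seed, {
    if (is.null(mask)) {               # two vertical vessels at 1/3 and 2/3 width
      mask <- matrix(FALSE, nx, nz)
      for (cx in unique(pmax(1, round(c(nx / 3, 2 * nx / 3))))) {
        w <- max(1, round(nx / 40))
        mask[max(1, cx - w):min(nx, cx + w), ] <- TRUE
      }
    }
    data <- array(0i, c(nx, nz, nt))
    tt <- seq_len(nt) - 1

    if (truth$tissue_rank > 0 && truth$tissue_amplitude > 0) {
      # Tissue clutter must occupy exactly tissue_rank leading singular
      # components with predictable energies, so both factors of each
      # rank-one term are built orthonormal: spatial modes are randomly
      # rotated orthonormalized low-order 2-d polynomials (smooth, global
      # support, so clutter energy reaches every ROI, as tissue does);
      # temporal modes are QR-orthonormalized slow complex oscillations
      # (< 5 Hz, distinct frequencies -- sub-Hz oscillations over a short
      # acquisition are nearly collinear, so without orthogonalization the
      # clutter would collapse below its nominal rank and the tissue
      # cut-off would be unidentifiable). Singular value i of the tissue
      # part is then exactly tissue_amplitude * 0.9^(i-1) * sqrt(nt).
      r <- truth$tissue_rank
      xc <- (seq_len(nx) - (nx + 1) / 2) / nx
      zc <- (seq_len(nz) - (nz + 1) / 2) / nz
      degs <- expand.grid(p = 0:(r), q = 0:(r))
      degs <- degs[order(degs$p + degs$q, degs$p), ][seq_len(r), ]
      basis <- mapply(function(p, q) as.vector(outer(xc^p, zc^q)),
                      degs$p, degs$q)
      q_sp <- qr.Q(qr(basis)) %*% qr.Q(qr(matrix(stats::rnorm(r * r), r)))
      freqs <- sample(seq(0.3, 4.9, length.out = max(24, r)), r)
      taus <- vapply(freqs, function(f)
        exp(1i * (2 * pi * f * tt / frame_rate + stats::runif(1, 0, 2 * pi))),
        complex(nt))
      q_t <- qr.Q(qr(taus))
      amps <- truth$tissue_amplitude * 0.9^(seq_len(r) - 1) * sqrt(nt)
      flat <- matrix(data, nx * nz, nt)
      flat <- flat + q_sp %*% (amps * t(q_t))
      data <- array(flat, c(nx, nz, nt))
    }

    if (truth$blood_amplitude > 0 && any(mask)) {
      px <- which(mask)
      v <- stats::runif(length(px), truth$blood_velocity_range[1],
                        truth$blood_velocity_range[2])          # mm/s
      f_dop <- 2 * (v * 1e-3) * 15e6 / 1540                     # Hz
      phase0 <- stats::runif(length(px), 0, 2 * pi)
      flow <- truth$blood_amplitude *
        exp(1i * (outer(f_dop, tt) * 2 * pi / frame_rate + phase0))
      flat <- matrix(data, nx * nz, nt)
      flat[px, ] <- flat[px, ] + flow
      data <- array(flat, c(nx, nz, nt))
    }

    if (truth$noise_sigma > 0) {
      n <- nx * nz * nt
      data <- data + array(complex(real = stats::rnorm(n, sd = truth$noise_sigma / sqrt(2)),
                                   imaginary = stats::rnorm(n, sd = truth$noise_sigma / sqrt(2))),
                           c(nx, nz, nt))
    }
    out <- compound_stack(data, dx = dx, dz = dz, frame_rate = frame_rate)
    truth$vessel_mask <- mask
    attr(out, "truth") <- truth
    out
  })
}

#' Ground truth for a tubular vessel phantom
#'
#' A set of cylindrical tubes (straight or polyline centerlines) standing in
#' for lectin-labelled vessels in a confocal z-stack. Analytic volumes
#' (`pi r^2 L` summed over segments) give an independent check on rasterized
#' voxel volumes.
#'
#' @param tubes List of tubes; each a list with `centerline` (n x 3 matrix
#'   of µm coordinates, at least 2 points) and `radius` (µm, > 0).
#' @param voxel_size `(dx, dy, dz)` µm.
#' @param seed RNG seed (used only when noise is added at generation).
#' @return A `vessel_tree_truth` list; `tubes` gain an `analytic_volume_um3`.
#' @export
vessel_tree_truth <- function(tubes, voxel_size = c(1, 1, 1), seed = 1) {
  abort_if(!is.list(tubes), "`tubes` must be a list.")
  tubes <- lapply(tubes, function(tb) {
    cl <- tb$centerline
    abort_if(!(is.matrix(cl) && ncol(cl) == 3 && nrow(cl) >= 2),
             "each centerline must be an n x 3 matrix (n >= 2).")
    abort_if(!(is.numeric(tb$radius) && tb$radius > 0), "tube radius must be > 0.")
    seg_len <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
    tb$analytic_volume_um3 <- pi * tb$radius^2 * sum(seg_len)
    tb
  })
  structure(list(tubes = tubes, voxel_size = as.numeric(voxel_size),
                 seed = as.integer(seed)),
            class = "vessel_tree_truth")
}

#' Convenience straight tube
#' @param from,to Endpoints in µm (length-3).
#' @param radius Radius in µm.
#' @return A tube list usable in [vessel_tree_truth()].
#' @export
straight_tube <- function(from, to, radius) {
  list(centerline = rbind(as.numeric(from), as.numeric(to)), radius = radius)
}

# squared distance from points (m x 3) to segment p-q
dist2_to_segment <- function(pts, p, q) {
  d <- q - p
  l2 <- sum(d^2)
  if (l2 == 0) return(rowSums(sweep(pts, 2, p)^2))
  t <- pmin(1, pmax(0, (sweep(pts, 2, p) %*% d) / l2))
  proj <- cbind(p[1] + t * d[1], p[2] + t * d[2], p[3] + t * d[3])
  rowSums((pts - proj)^2)
}

#' Rasterize a vessel-tree phantom into a fluorescence volume
#'
#' A voxel is vessel foreground iff its center lies within a tube radius of
#' that tube's centerline — a simple, exactly auditable rule. Foreground
#' voxels get `fg_level`, background `bg_level`, plus optional Gaussian
#' intensity noise. Per-tube rasterized voxel counts and the multi-tube
#' overlap excess are recorded so phantom bookkeeping can be checked
#' exactly.
#'
#' @param truth A [vessel_tree_truth()].
#' @param shape `(nx, ny, nplanes)` voxels.
#' @param bg_level,fg_level Background/foreground intensities.
#' @param noise_sd Gaussian intensity noise (0 = none; seeded by the truth).
#' @param roi Optional in-plane logical ROI.
#' @return A [fluor_volume()] with attribute `truth` extended by
#'   `tube_voxels` (per-tube rasterized counts), `foreground_voxels` and
#'   `overlap_excess` (`sum(tube_voxels) - foreground_voxels`).
#' @export
gen_vessel_volume <- function(truth, shape, bg_level = 20, fg_level = 200,
                              noise_sd = 0, roi = NULL) {
  abort_if(!inherits(truth, "vessel_tree_truth"), "`truth` must be a vessel_tree_truth.")
  abort_if(length(shape) != 3 || any(shape < 1), "`shape` must be three positive counts.")
  shape <- as.integer(shape)
  vs <- truth$voxel_size
  bounds <- shape * vs
  # voxel centers in um
  cx <- (seq_len(shape[1]) - 0.5) * vs[1]
  cy <- (seq_len(shape[2]) - 0.5) * vs[2]
  cz <- (seq_len(shape[3]) - 0.5) * vs[3]
  count <- array(0L, shape)
  tube_voxels <- integer(length(truth$tubes))
  for (ti in seq_along(truth$tubes)) {
    tb <- truth$tubes[[ti]]
    cl <- tb$centerline
    abort_if(any(cl < -tb$radius) || any(sweep(cl, 2, bounds) > tb$radius),
             sprintf("tube %d lies outside the volume bounds.", ti))
    member <- array(FALSE, shape)
    for (s in seq_len(nrow(cl) - 1)) {
      p <- cl[s, ]; q <- cl[s + 1, ]
      lo <- pmin(p, q) - tb$radius; hi <- pmax(p, q) + tb$radius
      ix <- which(cx >= lo[1] & cx <= hi[1])
      iy <- which(cy >= lo[2] & cy <= hi[2])
      iz <- which(cz >= lo[3] & cz <= hi[3])
      if (!length(ix) || !length(iy) || !length(iz)) next
      pts <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz]))
      inside <- dist2_to_segment(pts, p, q) <= tb$radius^2
      if (any(inside)) {
        idx <- as.matrix(expand.grid(x = ix, y = iy, z = iz))[inside, , drop = FALSE]
        member[idx] <- TRUE
      }
    }
    tube_voxels[ti] <- sum(member)
    count <- count + member
  }
  fg <- count > 0L
  intensity <- array(bg_level, shape)
  intensity[fg] <- fg_level
  if (noise_sd > 0)
    intensity <- with_seed(truth$seed,
                           intensity + array(stats::rnorm(prod(shape), sd = noise_sd), shape))
  vol <- fluor_volume(intensity, voxel_size = vs, roi = roi)
  truth$tube_voxels <- tube_voxels
  truth$foreground_voxels <- sum(fg)
  truth$overlap_excess <- sum(tube_voxels) - sum(fg)
  attr(vol, "truth") <- truth
  vol
}

#' Ground truth for a synthetic two-group cohort
#'
#' Emulates a cross-sectional design of two age groups of mice, each mouse
#' contributing its left and right hippocampus as independent measurements.
#' Per-level values are Gaussian with stated group means and SDs.
#'
#' @param group_sizes Named vector of mice per group, e.g.
#'   `c(young = 6, old = 6)`; each >= 2.
#' @param hippocampi_per_mouse Default 2 (left and right).
#' @param means Named list: `means[[group]]` is a named numeric vector over
#'   levels (e.g. quartiles or VVF ranges).
#' @param sds Same shape as `means`; all > 0 (0 allowed for degenerate
#'   checks).
#' @param seed RNG seed.
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(group_sizes = c(young = 6, old = 6),
                         hippocampi_per_mouse = 2, means, sds, seed = 1) {
  abort_if(is.null(names(group_sizes)) || any(group_sizes < 2),
           "`group_sizes` must be named and each >= 2.")
  abort_if(!all(names(group_sizes) %in% names(means)) ||
             !all(names(group_sizes) %in% names(sds)),
           "`means` and `sds` must have one entry per group.")
  for (g in names(group_sizes))
    abort_if(!identical(names(means[[g]]), names(sds[[g]])) || any(sds[[g]] < 0),
             "per-group means/sds must share level names; sds >= 0.")
  structure(list(group_sizes = group_sizes,
                 hippocampi_per_mouse = as.integer(hippocampi_per_mouse),
                 means = means, sds = sds, seed = as.integer(seed)),
            class = "cohort_truth")
}

#' Generate a tidy synthetic cohort table
#'
#' One row per (mouse, hemisphere, level) with the given measure name;
#' values drawn from the group's Gaussian for that level. Seeded and
#' bit-reproducible.
#'
#' @param truth A [cohort_truth()].
#' @param measure Name of the measured quantity (e.g. `"quartile_cutoff_db"`
#'   or `"mean_vvf"`).
#' @return A tibble with columns
#'   `mouse_id, group, hemisphere, measure, level, value`.
#' @export
gen_cohort <- function(truth, measure = "value") {
  abort_if(!inherits(truth, "cohort_truth"), "`truth` must be a cohort_truth.")
  abort_if(!is.character(measure) || length(measure) != 1 || !nzchar(measure),
           "`measure` must be a single non-empty name.")
  hemis <- if (truth$hippocampi_per_mouse == 2) c("left", "right")
           else paste0("h", seq_len(truth$hippocampi_per_mouse))
  with_seed(truth$seed, {
    purrr::imap(as.list(truth$group_sizes), function(n, g) {
      levels <- names(truth$means[[g]])
      grid <- tidyr::expand_grid(mouse = seq_len(n), hemisphere = hemis,
                                 level = levels)
      grid$value <- stats::rnorm(nrow(grid),
                                 mean = truth$means[[g]][grid$level],
                                 sd = truth$sds[[g]][grid$level])
      tibble::tibble(mouse_id = sprintf("%s_%02d", g, grid$mouse), group = g,
                     hemisphere = grid$hemisphere, measure = measure,
                     level = grid$level, value = grid$value)
    }) |> purrr::list_rbind()
  })
}
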