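#' Demo run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of the simulate -> filter -> segment -> vessels ->
#' stats chain with small, fast defaults: two age groups of three mice, a
#' 48 x 36 x 80-frame Doppler scene per mouse (three repeats averaged), a
#' 96 x 96 x 10-plane confocal phantom per hemisphere (two consecutive
#' slices), and the cohort analysis at alpha 0.05. A single master seed fans
#' out to per-stage seeds through a documented derivation, so a rerun with
#' the same seed is bit-identical.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param master_seed Master RNG seed.
#' @param ... Named overrides of any default listed below.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, master_seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, master_seed = as.integer(master_seed),
    groups = c("young", "old"), n_mice = c(young = 3, old = 3),
    # Doppler scene
    nx = 48, nz = 36, nt = 80, frame_rate = 500, dx = 0.1, dz = 0.1,
    n_repeats = 3, tissue_rank = 4, tissue_amplitude = 40,
    blood_amplitude = c(young = 4, old = 2.8), noise_sigma = 0.1,
    blood_velocity_range = c(2, 10),
    band_tissue = 2:10, band_noise = seq(20, 80, by = 4),
    # ROIs (pixel rectangles x0, x1, z0, z1)
    roi_blood = c(14, 18, 10, 20), roi_noise = c(22, 26, 8, 20),
    roi_left = c(6, 20, 8, 28), roi_right = c(28, 42, 8, 28),
    # confocal phantom
    conf_shape = c(96, 96, 10), conf_voxel = c(0.5, 0.5, 5),
    hippocampus_surface_um2 = 2e5, section_height_um = 50,
    n_capillaries = list(young = 6:10, old = 3:6),
    range_boundaries = c(3e-4, 3e-3, 1),
    alpha = 0.05)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  abort_if(length(unknown) > 0,
           paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return A `run_config` (read); `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  abort_if(!file.exists(path), paste("config file not found:", path))
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(out_dir = raw$out_dir,
                             master_seed = raw$master_seed),
                        raw[setdiff(names(raw), c("out_dir", "master_seed"))]))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

rect_mask <- function(nx, nz, r, label) {
  m <- matrix(FALSE, nx, nz)
  m[r[1]:r[2], r[3]:r[4]] <- TRUE
  roi_mask(m, label = label)
}

# Tube templates per hemisphere, all coordinates in um on the 48 x 48 x 50 um
# default field (96 x 96 px at 0.5 um, 10 planes at 5 um). The four caliber
# classes live in disjoint y-strips (and the capillaries in their own
# x-strip), separated by > 1 voxel everywhere, so components never merge.
# Jitter is in whole-voxel steps along x so rasterized counts stay stable;
# lengths and tube counts vary per mouse to give the cohort its spread.
phantom_truth <- function(cfg, seed, n_cap) {
  vs <- cfg$conf_voxel
  ext <- cfg$conf_shape * vs                       # um extents
  zc_of <- function(p) (p - 0.5) * vs[3]           # plane-center z
  with_seed(seed, {
    tubes <- list()
    jx <- function(k) sample.int(k, 1) * vs[1]     # whole-voxel x offsets
    # one artery/vein-caliber vessel along x, mid-depth
    L4 <- sample(seq(36, 44, by = 2), 1)
    x0 <- 2 + jx(4)
    tubes[[length(tubes) + 1]] <- straight_tube(c(x0, 11, ext[3] / 2),
                                                c(x0 + L4, 11, ext[3] / 2), 10)
    # two venule-caliber vessels in single planes
    for (i in 1:2) {
      L3 <- sample(seq(16, 24, by = 1), 1)
      x0 <- 2 + jx(10)
      zc <- zc_of(sample(c(2, 5, 8), 1))
      tubes[[length(tubes) + 1]] <- straight_tube(c(x0, 23 + 4 * i, zc),
                                                  c(x0 + L3, 23 + 4 * i, zc), 2)
    }
    # arteriole-caliber stubs in their own y-strip, low x
    for (i in seq_len(sample(3:5, 1))) {
      L2 <- sample(c(1.5, 2, 2.5), 1)
      x0 <- 3 + jx(16)
      zc <- zc_of(sample(10, 1))
      yc <- 36 + 2.5 * (i - 1)
      tubes[[length(tubes) + 1]] <- straight_tube(c(x0, yc, zc),
                                                  c(x0 + L2, yc, zc), 0.6)
    }
    # capillary-caliber one- or two-voxel specks on a separated x-grid;
    # centers pinned to voxel centers so each speck rasterizes to exactly
    # one (or two) voxels
    for (i in seq_len(n_cap)) {
      cx <- (3 * i + 40 - 0.5) * vs[1]
      cy <- (72 + 5 * (sample(5, 1) - 1) - 0.5) * vs[2]
      zc <- zc_of(sample(10, 1))
      if (stats::runif(1) < 0.5)
        tubes[[length(tubes) + 1]] <- straight_tube(c(cx - 0.1, cy, zc),
                                                    c(cx + 0.1, cy, zc), 0.26)
      else
        tubes[[length(tubes) + 1]] <- straight_tube(c(cx, cy, zc),
                                                    c(cx + vs[1], cy, zc), 0.26)
    }
    vessel_tree_truth(tubes, voxel_size = vs, seed = seed)
  })
}

run_doppler_stage <- function(cfg) {
  rows <- list(); bands <- list()
  idx <- 0
  for (g in cfg$groups) {
    for (m in seq_len(cfg$n_mice[[g]])) {
      idx <- idx + 1
      mouse <- sprintf("%s_%02d", g, m)
      images <- vector("list", cfg$n_repeats)
      band <- NULL; snr <- NA_real_
      for (r in seq_len(cfg$n_repeats)) {
        truth <- doppler_scene_truth(
          tissue_rank = cfg$tissue_rank, tissue_amplitude = cfg$tissue_amplitude,
          blood_amplitude = cfg$blood_amplitude[[g]],
          blood_velocity_range = cfg$blood_velocity_range,
          noise_sigma = cfg$noise_sigma,
          seed = derive_seed(cfg$master_seed, idx * 100 + r))
        scene <- gen_doppler_scene(truth, nx = cfg$nx, nz = cfg$nz, nt = cfg$nt,
                                   frame_rate = cfg$frame_rate,
                                   dx = cfg$dx, dz = cfg$dz)
        cas <- to_casorati(scene)
        if (r == 1) {                    # band tuned once per mouse, reused
          opt <- optimize_band(cas,
                               rect_mask(cfg$nx, cfg$nz, cfg$roi_blood, "blood"),
                               rect_mask(cfg$nx, cfg$nz, cfg$roi_noise, "noise"),
                               n_tissue = cfg$band_tissue, n_noise = cfg$band_noise)
          band <- opt$band; snr <- opt$snr
        }
        images[[r]] <- power_doppler(apply_clutter_filter(cas, band))
      }
      final <- average_images(images)
      summ <- summarize_hippocampus(final,
                                    rect_mask(cfg$nx, cfg$nz, cfg$roi_left, "hippocampus_left"),
                                    rect_mask(cfg$nx, cfg$nz, cfg$roi_right, "hippocampus_right"),
                                    mouse_id = mouse)
      rows[[idx]] <- dplyr::mutate(summ$rows, group = g)
      bands[[idx]] <- tibble::tibble(mouse_id = mouse, group = g,
                                     n_tissue = band$n_tissue,
                                     n_noise = band$n_noise, snr = snr)
    }
  }
  list(quartiles = purrr::list_rbind(rows) |>
         dplyr::transmute(mouse_id = .data$mouse_id, group = .data$group,
                          hemisphere = .data$hemisphere,
                          measure = "quartile_cutoff_db",
                          level = .data$quartile, value = .data$cutoff_db),
       bands = purrr::list_rbind(bands))
}

run_confocal_stage <- function(cfg) {
  geom <- hippocampus_geometry(surface_um2 = cfg$hippocampus_surface_um2,
                               section_height_um = cfg$section_height_um)
  rows <- list(); comps <- list()
  idx <- 0
  for (g in cfg$groups) {
    for (m in seq_len(cfg$n_mice[[g]])) {
      mouse <- sprintf("%s_%02d", g, m)
      for (hemi in c("left", "right")) {
        idx <- idx + 1
        slices <- vector("list", 2)
        for (s in 1:2) {
          seed <- derive_seed(cfg$master_seed, 5000 + idx * 10 + s)
          n_cap <- with_seed(seed + 1, sample(cfg$n_capillaries[[g]], 1))
          truth <- phantom_truth(cfg, seed, n_cap)
          vol <- gen_vessel_volume(truth, cfg$conf_shape)
          # planes without any vessel are constant by construction; the
          # binarizer flags them, which is expected here, not a problem
          bin <- withCallingHandlers(binarize_stack(vol),
                                     warning = function(w) invokeRestart("muffleWarning"))
          comp <- label_vessels(bin, connectivity = 26) |>
            compute_vvf(geom)
          comps[[length(comps) + 1]] <-
            dplyr::mutate(comp, mouse_id = mouse, group = g, hemisphere = hemi,
                          slice = s)
          slices[[s]] <- partition_ranges(comp, boundaries = cfg$range_boundaries)
        }
        part <- average_slices(slices[[1]], slices[[2]])
        rows[[idx]] <- tibble::tibble(mouse_id = mouse, group = g,
                                      hemisphere = hemi, measure = "mean_vvf",
                                      level = as.character(part$range),
                                      value = part$mean_vvf)
      }
    }
  }
  list(vvf = purrr::list_rbind(rows),
       components = purrr::list_rbind(comps) |>
         dplyr::select("mouse_id", "group", "hemisphere", "slice", "id",
                       "voxel_count", "volume_um3", "vvf"))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes all stages in order — Doppler simulation, clutter-filter band
#' optimization, power-Doppler formation and quartile segmentation per
#' hemisphere; confocal phantom generation, thresholding, 3-d vessel
#' labeling and VVF range partition over two consecutive slices; then the
#' cohort statistics on both measures — writing tidy CSVs and a JSON run
#' manifest (parameters, per-stage seeds, file hashes) under
#' `config$out_dir`. Fails fast with a stage-scoped error message; outputs
#' are bit-identical for a fixed master seed.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  abort_if(!inherits(config, "run_config"), "`config` must be a run_config.")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  abort_if(!dir.exists(config$out_dir), "could not create `out_dir`.")
  paths <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e))))
  }
  dop <- stage("doppler", run_doppler_stage(config))
  paths$quartiles <- file.path(config$out_dir, "doppler_quartiles.csv")
  readr::write_csv(dop$quartiles, paths$quartiles)
  paths$bands <- file.path(config$out_dir, "doppler_bands.csv")
  readr::write_csv(dop$bands, paths$bands)

  conf <- stage("confocal", run_confocal_stage(config))
  paths$vvf <- file.path(config$out_dir, "vvf_ranges.csv")
  readr::write_csv(conf$vvf, paths$vvf)
  paths$components <- file.path(config$out_dir, "vessel_components.csv")
  readr::write_csv(conf$components, paths$components)

  stats_rows <- stage("stats", {
    res <- list()
    for (tab in list(dop$quartiles, conf$vvf)) {
      complete <- tab |>
        dplyr::group_by(.data$level) |>
        dplyr::filter(!any(is.na(.data$value))) |>
        dplyr::ungroup()
      res[[length(res) + 1]] <-
        dplyr::mutate(run_cohort_analysis(complete, alpha = config$alpha),
                      measure = tab$measure[1], .before = 1)
    }
    purrr::list_rbind(res)
  })
  paths$stats <- file.path(config$out_dir, "stats_results.csv")
  readr::write_csv(stats_rows, paths$stats)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hippovasc")),
    master_seed = config$master_seed,
    parameters = unclass(config),
    outputs = purrr::imap(paths, function(p, nm)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarise a completed pipeline run
#'
#' Reads the stage CSVs back from a run directory and produces report
#' tables: per-group mean quartile cut-offs, per-group per-range VVF
#' summaries, and the statistics grid; each is also written as
#' `report_*.csv`.
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @return A list of tibbles: `quartiles`, `vvf_ranges`, `stats`.
#' @export
pipeline_report <- function(out_dir) {
  need <- c("doppler_quartiles.csv", "vvf_ranges.csv", "stats_results.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  abort_if(length(missing) > 0,
           paste("incomplete run; missing:", paste(missing, collapse = ", ")))
  qu <- readr::read_csv(file.path(out_dir, "doppler_quartiles.csv"),
                        show_col_types = FALSE, progress = FALSE)
  vv <- readr::read_csv(file.path(out_dir, "vvf_ranges.csv"),
                        show_col_types = FALSE, progress = FALSE)
  st <- readr::read_csv(file.path(out_dir, "stats_results.csv"),
                        show_col_types = FALSE, progress = FALSE)
  q_tab <- qu |>
    dplyr::group_by(.data$group, .data$level) |>
    dplyr::summarise(mean_cutoff_db = mean(.data$value),
                     sd_cutoff_db = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  v_tab <- vv |>
    dplyr::group_by(.data$group, .data$level) |>
    dplyr::summarise(mean_vvf = mean(.data$value, na.rm = TRUE),
                     sd_vvf = stats::sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  readr::write_csv(q_tab, file.path(out_dir, "report_quartiles.csv"))
  readr::write_csv(v_tab, file.path(out_dir, "report_vvf_ranges.csv"))
  list(quartiles = q_tab, vvf_ranges = v_tab, stats = st)
}

#' Structural diff of two run manifests
#'
#' Compares the `parameters` of two manifests (as returned by
#' [run_pipeline()] or read from `manifest.json`) field by field.
#'
#' @param a,b Manifest lists or paths to `manifest.json` files.
#' @return A tibble `field, a, b` with one row per differing parameter.
#' @export
manifest_diff <- function(a, b) {
  load_m <- function(x) if (is.character(x)) jsonlite::read_json(x) else x
  pa <- load_m(a)$parameters; pb <- load_m(b)$parameters
  fields <- union(names(pa), names(pb))
  fmt <- function(v) if (is.null(v)) NA_character_ else
    paste(unlist(v), collapse = ",")
  out <- purrr::map(fields, function(f) {
    va <- fmt(pa[[f]]); vb <- fmt(pb[[f]])
    if (identical(va, vb)) NULL
    else tibble::tibble(field = f, a = va, b = vb)
  })
  purrr::list_rbind(purrr::compact(out))
}
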