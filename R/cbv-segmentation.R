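#' Convert in-ROI power-Doppler intensity to decibels
#'
#' The Doppler intensity inside a hippocampus ROI is expressed in dB relative
#' to the maximum intensity within that same ROI, so the brightest in-ROI
#' pixel is exactly 0 dB and every other pixel is negative. Power Doppler is
#' a squared-magnitude (power) quantity, hence `10 * log10`. Zero-intensity
#' pixels are clamped to a documented floor rather than -Inf.
#'
#' @param image A `power_doppler` image.
#' @param roi A [roi_mask()] delimiting the hippocampus.
#' @param floor_db Floor for zero-power pixels (default -120 dB).
#' @return A `db_image`: matrix of dB values (`NA` outside the ROI) with
#'   attributes `reference` (the in-ROI maximum linear power), `roi` and
#'   `floor_db`.
#' @export
to_db <- function(image, roi, floor_db = -120) {
  abort_if(!inherits(image, "power_doppler"), "`image` must be a power_doppler.")
  abort_if(!inherits(roi, "roi_mask"), "`roi` must be a roi_mask.")
  abort_if(!identical(dim(roi), dim(image)), "ROI shape must match the image.")
  ref <- max(image[roi])
  abort_if(ref <= 0, "in-ROI maximum is zero: cannot form a dB reference.")
  vals <- matrix(NA_real_, nrow(image), ncol(image))
  v <- 10 * log10(unclass(image)[roi] / ref)
  v[!is.finite(v) | v < floor_db] <- floor_db
  vals[roi] <- v
  structure(vals, class = c("db_image", "matrix"),
            reference = ref, roi = roi, floor_db = floor_db,
            dx = attr(image, "dx"), dz = attr(image, "dz"))
}

#' Quartile cut-off values of an intensity sample
#'
#' Returns the 25th, 50th and 75th percentiles and the maximum of a sample,
#' the four cut-offs (Q1..Q4) that segment an intensity distribution into
#' quartile classes. Percentiles use linear interpolation between closest
#' order statistics (the convention is recorded so cut-offs are
#' reproducible).
#'
#' @param values Non-empty numeric vector (typically in-ROI dB values).
#' @return Named numeric vector `c(Q1, Q2, Q3, Q4)`, non-decreasing, with
#'   `Q4 = max(values)`; attribute `percentile_type` records the convention
#'   (type 7, linear interpolation).
#' @export
quartile_cutoffs <- function(values) {
  values <- values[!is.na(values)]
  abort_if(length(values) == 0, "empty sample.")
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  structure(stats::setNames(q, c("Q1", "Q2", "Q3", "Q4")), percentile_type = 7L)
}

#' Segment a dB image into intensity quartile classes
#'
#' Pixels are classified by their position in the in-ROI intensity
#' distribution: class 1 holds pixels `<= Q1`; class k (k = 2, 3, 4) holds
#' pixels in the half-open interval `(Q_{k-1}, Q_k]`. Since `Q4` is the
#' in-ROI maximum, the classes partition the ROI exactly. Classes are named
#' by cut-off percentile (Q1 = lowest-intensity 25%), independent of any
#' display colour convention. A constant ROI collapses every pixel into
#' class 1 and is flagged `degenerate`.
#'
#' @param db_image A [to_db()] image.
#' @return A `quartile_seg`: list with `cutoffs_db` (named Q1..Q4 vector),
#'   `label_map` (integer matrix 1-4, `NA` outside the ROI), `counts`
#'   (pixels per class), `roi` and `degenerate`.
#' @export
segment_quartiles <- function(db_image) {
  abort_if(!inherits(db_image, "db_image"), "`db_image` must come from to_db().")
  roi <- attr(db_image, "roi")
  vals <- unclass(db_image)[roi]
  q <- quartile_cutoffs(vals)
  lab <- rep(NA_integer_, length(vals))
  lab[vals <= q[1]] <- 1L
  for (k in 2:4) lab[vals > q[k - 1] & vals <= q[k]] <- k
  label_map <- matrix(NA_integer_, nrow(db_image), ncol(db_image))
  label_map[roi] <- lab
  structure(list(cutoffs_db = q, label_map = label_map,
                 counts = tabulate(lab, nbins = 4L), roi = roi,
                 degenerate = length(unique(vals)) == 1L),
            class = "quartile_seg")
}

#' @export
print.quartile_seg <- function(x, ...) {
  cat("<quartile_seg>", sum(x$counts), "pixels",
      if (x$degenerate) "(degenerate: constant ROI)" else "", "\n")
  print(round(x$cutoffs_db, 3))
  invisible(x)
}

#' Per-hemisphere quartile summaries of a hippocampal Doppler image
#'
#' Runs the dB conversion and quartile segmentation independently on the
#' left and right hippocampus, each referenced to its own in-ROI maximum, so
#' cut-off values are invariant to any per-hemisphere gain. Hemispheres are
#' independent measurements in the downstream cohort analysis.
#'
#' @param image A `power_doppler` image.
#' @param left,right Disjoint [roi_mask()]s for the two hippocampi.
#' @param mouse_id Optional identifier copied into the tidy rows.
#' @return A list with `left` and `right` ([segment_quartiles()] results) and
#'   `rows`, a tibble with one row per (hemisphere, quartile):
#'   `mouse_id, hemisphere, quartile, cutoff_db, n_pixels`.
#' @export
summarize_hippocampus <- function(image, left, right, mouse_id = NA_character_) {
  abort_if(!inherits(left, "roi_mask") || !inherits(right, "roi_mask"),
           "`left` and `right` must be roi_masks.")
  abort_if(any(left & right), "left and right hippocampus masks overlap.")
  segs <- list(left = segment_quartiles(to_db(image, left)),
               right = segment_quartiles(to_db(image, right)))
  rows <- purrr::imap(segs, function(s, hemi) {
    tibble::tibble(mouse_id = mouse_id, hemisphere = hemi,
                   quartile = names(s$cutoffs_db),
                   cutoff_db = as.numeric(s$cutoffs_db),
                   n_pixels = s$counts)
  }) |> purrr::list_rbind()
  c(segs, list(rows = rows))
}
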