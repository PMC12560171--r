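# Quality control by correlation against a group template, imaging-to-
# clinical visit matching, and the slab conventions: the axial axis is the
# third grid axis; "top"/"bottom" slices are the highest/lowest indices.

#' Voxelwise mean template over a set of volumes
#'
#' @param volumes list of [gm_volume()] (or 3D arrays) on a common grid.
#' @return A [gm_volume()] holding the voxelwise arithmetic mean.
#' @export
group_template <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  check_same_grid(volumes)
  acc <- as_volume_array(volumes[[1L]])
  if (length(volumes) > 1L) {
    for (v in volumes[-1L]) acc <- acc + as_volume_array(v)
  }
  vx <- if (inherits(volumes[[1L]], "gm_volume")) volumes[[1L]]$voxel_size else c(1.5, 1.5, 1.5)
  gm_volume(acc / length(volumes), voxel_size = vx,
            subject_id = "template", session_id = "template")
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' QC correlations of a volume against a template
#'
#' Pearson correlation of flattened voxels for the whole volume and for the
#' top and bottom `n_slices` axial slabs. A zero-variance slab makes the
#' corresponding correlation undefined and the report fails with a reason.
#'
#' @param volume,template [gm_volume()]s on the same grid.
#' @param n_slices slab thickness (grid depth must be >= `2 * n_slices`).
#' @param thresholds length-3 numeric in `[-1, 1]`: minimum acceptable
#'   r_whole, r_top, r_bottom.
#' @return data.frame row: subject_id, session_id, r_whole, r_top, r_bottom,
#'   passed, reason.
#' @export
qc_correlations <- function(volume, template, n_slices = 20L,
                            thresholds = c(0.7, 0.7, 0.7)) {
  a <- as_volume_array(volume); b <- as_volume_array(template)
  if (!identical(dim(a), dim(b))) {
    stop("volume grid ", paste(dim(a), collapse = "x"),
         " does not match template grid ", paste(dim(b), collapse = "x"),
         call. = FALSE)
  }
  depth <- dim(a)[3]
  if (depth < 2L * n_slices) {
    stop("grid depth ", depth, " < 2 * n_slices = ", 2L * n_slices, call. = FALSE)
  }
  thresholds <- rep_len(thresholds, 3L)
  top <- (depth - n_slices + 1L):depth
  bot <- seq_len(n_slices)
  r_whole <- safe_cor(as.numeric(a), as.numeric(b))
  r_top <- safe_cor(as.numeric(a[, , top]), as.numeric(b[, , top]))
  r_bottom <- safe_cor(as.numeric(a[, , bot]), as.numeric(b[, , bot]))
  rs <- c(r_whole, r_top, r_bottom)
  reason <- ""
  if (anyNA(rs)) {
    passed <- FALSE
    reason <- "zero-variance slab: correlation undefined"
  } else {
    passed <- all(rs >= thresholds)
    if (!passed) reason <- "correlation below threshold"
  }
  data.frame(
    subject_id = if (inherits(volume, "gm_volume")) volume$subject_id else NA_character_,
    session_id = if (inherits(volume, "gm_volume")) volume$session_id else NA_character_,
    r_whole = r_whole, r_top = r_top, r_bottom = r_bottom,
    passed = passed, reason = reason, stringsAsFactors = FALSE
  )
}

#' Apply the QC correlation filter to a set of volumes
#'
#' Volumes failing any correlation threshold (or with an undefined slab
#' correlation) are discarded. When the default 20-slice slab does not fit
#' the grid (depth < 40), the slab is capped at `floor(depth / 2)` slices.
#'
#' @param volumes list of [gm_volume()].
#' @param template a [group_template()] volume (computed from `volumes` when
#'   missing).
#' @param thresholds length-3 numeric thresholds in `[-1, 1]`.
#' @param n_slices requested slab thickness.
#' @return list with `retained` (volumes), `reports` (one row per input) —
#'   every input appears in exactly one of retained/discarded.
#' @export
apply_qc <- function(volumes, template = NULL, thresholds = c(0.7, 0.7, 0.7),
                     n_slices = 20L) {
  stopifnot(length(volumes) >= 1L, all(thresholds >= -1), all(thresholds <= 1))
  if (is.null(template)) template <- group_template(volumes)
  depth <- dim(as_volume_array(template))[3]
  n_slices <- min(as.integer(n_slices), depth %/% 2L)
  reports <- do.call(rbind, lapply(volumes, qc_correlations, template = template,
                                   n_slices = n_slices, thresholds = thresholds))
  list(retained = volumes[reports$passed], reports = reports)
}

#' Match imaging sessions to clinical visits
#'
#' Each imaging date is matched to the nearest clinical visit within
#' `max_days`; a tie in absolute distance is broken toward the earlier
#' visit. Unmatched sessions get `NA`.
#'
#' @param imaging_dates numeric day indices, one per session.
#' @param clinical_dates numeric day indices of available visits.
#' @param max_days window half-width in days (default 90).
#' @return integer vector: for each session, the index into `clinical_dates`
#'   of the matched visit, or `NA`.
#' @export
match_visits <- function(imaging_dates, clinical_dates, max_days = 90) {
  stopifnot(max_days >= 0, all(is.finite(imaging_dates)),
            all(is.finite(clinical_dates)))
  vapply(imaging_dates, function(d) {
    if (length(clinical_dates) == 0L) return(NA_integer_)
    delta <- abs(clinical_dates - d)
    eligible <- which(delta <= max_days)
    if (length(eligible) == 0L) return(NA_integer_)
    best <- eligible[delta[eligible] == min(delta[eligible])]
    best[which.min(clinical_dates[best])]
  }, integer(1L))
}
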