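#' Synthetic ROI atlas
#'
#' Places `n_rois` disjoint ellipsoidal regions on a 3D grid and flags the
#' first `n_signal` of them as "signal" regions, i.e. regions whose
#' gray-matter density is coupled to the latent disease severity in the
#' generator (synthetic stand-ins for the medial-temporal structures that
#' dominate Alzheimer-related atrophy: amygdala, hippocampus, temporal gyri).
#'
#' @param grid_dims integer length-3 grid size.
#' @param n_rois number of regions (>= 1).
#' @param n_signal number of severity-coupled regions (<= n_rois).
#' @param seed integer seed; the layout is deterministic given the seed.
#' @param max_tries placement retries per region before giving up.
#' @return An object of class `roi_atlas`: `labels` (3D integer array, 0 =
#'   background), `names` (length `n_rois`), `signal_flags` (logical).
#' @export
make_atlas <- function(grid_dims = c(32L, 32L, 32L), n_rois = 6L,
                       n_signal = 3L, seed = 1L, max_tries = 200L) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 4L),
            n_rois >= 1L, n_signal >= 0L, n_signal <= n_rois)
  labels <- array(0L, dim = grid_dims)
  coords <- lapply(grid_dims, seq_len)

  with_seed(seed, {
    for (r in seq_len(n_rois)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        semi <- runif(3, min = grid_dims / 16, max = grid_dims / 7)
        centre <- runif(3, min = semi + 1, max = grid_dims - semi)
        dz2 <- outer(((coords[[1]] - centre[1]) / semi[1])^2,
                     ((coords[[2]] - centre[2]) / semi[2])^2, "+")
        mask <- outer(dz2, ((coords[[3]] - centre[3]) / semi[3])^2, "+") <= 1
        if (sum(mask) >= 1L && !any(labels[mask] != 0L)) {
          labels[mask] <- r
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place region ", r, " (", region_name(r),
             ") after ", max_tries, " tries; use a larger grid or fewer ROIs",
             call. = FALSE)
      }
    }
  })

  structure(
    list(labels = labels,
         names = vapply(seq_len(n_rois), region_name, character(1L)),
         signal_flags = seq_len(n_rois) <= n_signal),
    class = "roi_atlas"
  )
}

region_name <- function(r) sprintf("region_%02d", r)

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas %d regions (%d signal) on %s grid, %d foreground voxels>\n",
              length(x$names), sum(x$signal_flags),
              paste(dim(x$labels), collapse = "x"), sum(x$labels > 0)))
  invisible(x)
}

#' Write / read an atlas as NIfTI labels plus a JSON name map
#'
#' @param atlas a `roi_atlas`.
#' @param path_labels NIfTI output path for the integer label grid.
#' @param path_names JSON output path for region names and signal flags.
#' @return `path_labels`, invisibly.
#' @export
write_atlas <- function(atlas, path_labels, path_names) {
  write_nifti(array(as.numeric(atlas$labels), dim = dim(atlas$labels)), path_labels)
  jsonlite::write_json(
    list(names = atlas$names, signal_flags = atlas$signal_flags),
    path_names, auto_unbox = FALSE
  )
  invisible(path_labels)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path_labels, path_names) {
  vol <- read_nifti(path_labels)
  meta <- jsonlite::read_json(path_names, simplifyVector = TRUE)
  structure(
    list(labels = array(as.integer(round(vol$data)), dim = dim(vol$data)),
         names = meta$names, signal_flags = as.logical(meta$signal_flags)),
    class = "roi_atlas"
  )
}
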