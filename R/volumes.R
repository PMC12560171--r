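#' Gray-matter density volume
#'
#' Container for a 3D gray-matter probability/density grid with the spatial
#' metadata the pipeline needs (voxel size in mm, subject and session ids).
#' Values are tissue densities and must be non-negative.
#'
#' @param data 3D numeric array of non-negative gray-matter densities.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param subject_id,session_id identifier strings.
#' @return An object of class `gm_volume`.
#' @export
gm_volume <- function(data, voxel_size = c(1.5, 1.5, 1.5),
                      subject_id = NA_character_, session_id = NA_character_) {
  if (length(dim(data)) != 3L) {
    stop("gm_volume data must be a 3D array, got dims: ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("gm_volume data must be finite and non-negative", call. = FALSE)
  }
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         grid_dims = dim(data),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id)),
    class = "gm_volume"
  )
}

#' @export
print.gm_volume <- function(x, ...) {
  cat(sprintf("<gm_volume %s/%s  %s voxels @ %s mm  range [%.3g, %.3g]>\n",
              x$subject_id, x$session_id,
              paste(x$grid_dims, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

as_volume_array <- function(x) {
  if (inherits(x, "gm_volume")) x$data else x
}

check_same_grid <- function(volumes) {
  dims <- lapply(volumes, function(v) as_volume_array(v) |> dim())
  ref <- dims[[1L]]
  ok <- vapply(dims, function(d) identical(d, ref), logical(1L))
  if (!all(ok)) {
    shapes <- unique(vapply(dims, paste, character(1L), collapse = "x"))
    stop("volumes are not on a common grid; shapes seen: ",
         paste(shapes, collapse = ", "), call. = FALSE)
  }
  invisible(ref)
}
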