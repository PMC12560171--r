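# Synthetic cohort generator. The generator states a forward model with the
# statistical structure the analysis assumes: a latent disease severity per
# subject that (a) orders the diagnostic groups CN < sMCI < pMCI < AD,
# (b) drives CSF abeta down and ptau/tau up with opposite-signed linear
# slopes (which also induces the negative abeta-tau / positive ptau-tau
# pairwise correlations seen in clinical cohorts), and (c) removes
# gray-matter density proportionally inside designated "signal" ROIs.

TABLE1_CLAMPS <- list(
  abeta = c(212.3, 1700.0),
  ptau  = c(8.0, 94.9),
  tau   = c(80.0, 818.0)
)

#' Effect configuration for the synthetic cohort
#'
#' Defaults are calibrated so that (i) noise-free group means are strictly
#' ordered (abeta decreasing with severity, ptau/tau increasing), (ii) pooled
#' marker standard deviations approximate the clinical reference values the
#' clamps come from (abeta ~486, ptau ~14, tau ~126 pg/mL), and (iii) the
#' severity levels 0 / 0.5 / 1.8 / 2.5 give pairwise group gaps ranking
#' (CN,AD) > (sMCI,AD) > (CN,pMCI) > (sMCI,pMCI) > (pMCI,AD) > (CN,sMCI).
#'
#' @param severity_by_group named numeric, latent severity mean per group.
#' @param severity_sd within-group severity sd.
#' @param intercepts,slopes named numeric per marker; abeta slope must be
#'   negative, ptau/tau slopes positive (pg/mL per severity unit).
#' @param marker_noise_sd named numeric per marker, residual sd in pg/mL.
#' @param clamps named list of `[min, max]` pg/mL ranges per marker.
#' @param atrophy_slope fractional gray-matter intensity loss per severity
#'   unit inside signal ROIs.
#' @param image_noise_sd voxel noise sd on the density scale (~0-0.8).
#' @param age_base,age_slope,age_sd age model: `base + slope * severity + noise`.
#' @param date_jitter_sd sd (days) of the clinical-visit offset from the
#'   imaging visit; 40 days keeps ~97% of pairs inside a +/-90-day window.
#' @return list of class `effect_config`.
#' @export
effect_config <- function(
    severity_by_group = c(CN = 0, sMCI = 0.5, pMCI = 1.8, AD = 2.5),
    severity_sd = 0.25,
    intercepts = c(abeta = 1450, ptau = 15, tau = 170),
    slopes = c(abeta = -420, ptau = 10, tau = 95),
    marker_noise_sd = c(abeta = 150, ptau = 5.5, tau = 50),
    clamps = TABLE1_CLAMPS,
    atrophy_slope = 0.08,
    image_noise_sd = 0.02,
    age_base = 72, age_slope = 1.5, age_sd = 5,
    date_jitter_sd = 40) {
  stopifnot(setequal(names(severity_by_group), DIAGNOSTIC_GROUPS),
            setequal(names(intercepts), MARKERS),
            setequal(names(slopes), MARKERS),
            setequal(names(marker_noise_sd), MARKERS),
            severity_sd >= 0, all(marker_noise_sd >= 0),
            atrophy_slope >= 0, image_noise_sd >= 0)
  if (!(slopes[["abeta"]] < 0 && slopes[["ptau"]] > 0 && slopes[["tau"]] > 0)) {
    stop("slope signs must be abeta < 0, ptau > 0, tau > 0", call. = FALSE)
  }
  sv <- severity_by_group[DIAGNOSTIC_GROUPS]
  if (any(diff(sv) <= 0)) {
    stop("severity_by_group must be strictly increasing CN < sMCI < pMCI < AD",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "effect_config")
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Sample a synthetic cohort of subject phenotypes
#'
#' One imaging session per subject. Severity is drawn per subject from a
#' normal around its group mean and floored at zero (it is a non-negative
#' latent); CSF markers are linear in severity plus noise, clamped to their
#' configured ranges; ages and visit dates follow the configured models.
#'
#' @param n_per_group subjects per diagnostic group (>= 0).
#' @param effects an [effect_config()].
#' @param seed integer seed.
#' @return data.frame with columns subject_id, session_id, group, age,
#'   severity, abeta, ptau, tau, imaging_date, clinical_date.
#' @export
sample_cohort <- function(n_per_group, effects = effect_config(), seed = 1L) {
  stopifnot(inherits(effects, "effect_config"))
  if (length(n_per_group) != 1L || is.na(n_per_group) || n_per_group < 0) {
    stop("n_per_group must be a single non-negative count", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  empty <- data.frame(subject_id = character(), session_id = character(),
                      group = character(), age = numeric(), severity = numeric(),
                      abeta = numeric(), ptau = numeric(), tau = numeric(),
                      imaging_date = integer(), clinical_date = integer(),
                      stringsAsFactors = FALSE)
  if (n_per_group == 0L) return(empty)

  with_seed(seed, {
    group <- rep(DIAGNOSTIC_GROUPS, each = n_per_group)
    n <- length(group)
    severity <- pmax(0, rnorm(n, mean = effects$severity_by_group[group],
                              sd = effects$severity_sd))
    markers <- lapply(MARKERS, function(m) {
      raw <- effects$intercepts[[m]] + effects$slopes[[m]] * severity +
        rnorm(n, sd = effects$marker_noise_sd[[m]])
      clamp(raw, effects$clamps[[m]])
    })
    names(markers) <- MARKERS
    age <- effects$age_base + effects$age_slope * severity +
      rnorm(n, sd = effects$age_sd)
    imaging_date <- as.integer(round(runif(n, 0, 2000)))
    clinical_date <- imaging_date + as.integer(round(rnorm(n, 0, effects$date_jitter_sd)))
    data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      session_id = "ses-01",
      group = group, age = age, severity = severity,
      abeta = markers$abeta, ptau = markers$ptau, tau = markers$tau,
      imaging_date = imaging_date, clinical_date = clinical_date,
      stringsAsFactors = FALSE
    )
  })
}

# Severity-free gray-matter template: smooth background plus denser ROI blobs.
baseline_template <- function(atlas) {
  base <- 0.25 + 0.45 * (atlas$labels > 0)
  smooth_array3d(base, sd_voxels = 1.5)
}

#' Render a synthetic gray-matter volume for one subject
#'
#' The volume is the smooth baseline template with a proportional intensity
#' reduction of `atrophy_slope * severity` inside signal ROIs, plus spatially
#' smoothed Gaussian noise, clipped at zero. Non-signal ROIs are unaffected
#' by severity.
#'
#' @param record one row of a [sample_cohort()] data.frame (or a list with
#'   `subject_id`, `session_id`, `severity`).
#' @param atlas a [make_atlas()] atlas.
#' @param effects an [effect_config()].
#' @param seed integer seed for the voxel noise.
#' @param voxel_size voxel edge lengths in mm.
#' @return A [gm_volume()].
#' @export
render_volume <- function(record, atlas, effects = effect_config(), seed = 1L,
                          voxel_size = c(1.5, 1.5, 1.5)) {
  stopifnot(inherits(atlas, "roi_atlas"), inherits(effects, "effect_config"))
  severity <- as.numeric(record$severity)
  if (!is.finite(severity) || severity < 0) {
    stop("record severity must be a finite non-negative scalar", call. = FALSE)
  }
  template <- baseline_template(atlas)
  signal_mask <- array(atlas$labels > 0, dim = dim(atlas$labels)) &
    array(atlas$signal_flags[pmax(atlas$labels, 1L)], dim = dim(atlas$labels))
  vol <- template
  shrink <- max(0, 1 - effects$atrophy_slope * severity)
  vol[signal_mask] <- vol[signal_mask] * shrink
  if (effects$image_noise_sd > 0) {
    noise <- with_seed(seed, array(rnorm(length(vol), sd = effects$image_noise_sd),
                                   dim = dim(vol)))
    vol <- vol + smooth_array3d(noise, sd_voxels = 1)
  }
  vol[vol < 0] <- 0
  gm_volume(vol, voxel_size = voxel_size,
            subject_id = as.character(record$subject_id),
            session_id = as.character(record$session_id))
}

#' Generate a full synthetic dataset
#'
#' Composes [make_atlas()], [sample_cohort()] and [render_volume()], then
#' corrupts a `qc_fail_fraction` subset of volumes by zeroing their bottom 20
#' axial slices (the slab the downstream QC correlation filter inspects).
#' When `out_dir` is given, volumes are written as NIfTI (`.nii.gz`), the
#' phenotype table as CSV, and the atlas as NIfTI + JSON.
#'
#' @param n_per_group subjects per group.
#' @param effects an [effect_config()].
#' @param qc_fail_fraction proportion in `[0, 1)` of volumes to corrupt.
#' @param seed integer seed driving atlas, phenotypes, noise and corruption.
#' @param grid_dims grid size (default 32^3; the full-scale clinical grid
#'   121 x 145 x 121 is supported but far slower).
#' @param n_rois,n_signal atlas layout.
#' @param out_dir optional output directory.
#' @return list with `volumes` (list of [gm_volume()]), `records`
#'   (phenotypes, including a logical `qc_corrupted` column giving ground
#'   truth), and `atlas`.
#' @export
generate_dataset <- function(n_per_group, effects = effect_config(),
                             qc_fail_fraction = 0, seed = 1L,
                             grid_dims = c(32L, 32L, 32L),
                             n_rois = 6L, n_signal = 3L, out_dir = NULL) {
  stopifnot(qc_fail_fraction >= 0, qc_fail_fraction < 1)
  atlas <- make_atlas(grid_dims, n_rois = n_rois, n_signal = n_signal,
                      seed = derive_seed(seed, "atlas"))
  records <- sample_cohort(n_per_group, effects, seed = derive_seed(seed, "cohort"))
  n <- nrow(records)
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    volumes[[i]] <- render_volume(records[i, ], atlas, effects,
                                  seed = derive_seed(seed, paste0("vol", i)))
  }
  n_corrupt <- round(qc_fail_fraction * n)
  corrupt_idx <- if (n_corrupt > 0) {
    with_seed(derive_seed(seed, "corrupt"), sample.int(n, n_corrupt))
  } else integer(0)
  for (i in corrupt_idx) {
    d <- volumes[[i]]$data
    d[, , seq_len(min(20L, dim(d)[3]))] <- 0
    volumes[[i]]$data <- d
  }
  records$qc_corrupted <- seq_len(n) %in% corrupt_idx

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      p <- file.path(out_dir, sprintf("%s_%s.nii.gz", records$subject_id[i],
                                      records$session_id[i]))
      tryCatch(write_nifti(volumes[[i]], p),
               error = function(e) stop("failed writing ", p, ": ",
                                        conditionMessage(e), call. = FALSE))
    }
    write.csv(records, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
    write_atlas(atlas, file.path(out_dir, "atlas.nii.gz"),
                file.path(out_dir, "atlas_names.json"))
  }
  list(volumes = volumes, records = records, atlas = atlas)
}
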