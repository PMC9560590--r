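#' Default per-stratum electrode displacement model
#'
#' Mean displacement vectors and per-axis standard deviations (mm) of the
#' realised electrode position around the planned target, keyed by
#' `hemisphere.nucleus`.  Defaults encode the two features of the study
#' cohort the generator must reproduce: pallidal implantations are noisier
#' than subthalamic ones, and the right hemisphere (implanted second)
#' carries extra lateral (X) variance, applied on top of these values via
#' `right_x_variance_multiplier`.
#'
#' @return named list with entries `left.GPi`, `right.GPi`, `left.STN`,
#'   `right.STN`, each a list with `mean` and `sd` (length-3, mm).
#' @export
default_displacement_model <- function() {
  gpi <- list(mean = c(0, 0, 0), sd = c(0.6, 0.5, 0.5))
  stn <- list(mean = c(0, 0, 0), sd = c(0.3, 0.3, 0.3))
  list(`left.GPi` = gpi, `right.GPi` = gpi,
       `left.STN` = stn, `right.STN` = stn)
}

#' Default post-operative outcome effects
#'
#' Mean percentage change and standard deviation (percentage points) per
#' clinical score, calibrated to the study cohort's reported outcome table
#' (which prints mean and 2 SD).  LEDD is stratified by target nucleus:
#' subthalamic stimulation allows a large medication reduction, pallidal
#' stimulation essentially none.
#'
#' @return named list keyed by score; each entry has `mean` and `sd`, or a
#'   per-nucleus `GPi`/`STN` pair of such entries.
#' @export
default_outcome_effects <- function() {
  list(UPDRS3 = list(mean = -45.9, sd = 11.75),
       UPDRS4 = list(mean = -72.2, sd = 11.75),
       LEDD = list(GPi = list(mean = 0.9, sd = 12.55),
                   STN = list(mean = -54.3, sd = 12.45)),
       PDQ39 = list(mean = -32.1, sd = 17.3),
       weight = list(mean = 8.7, sd = 2.7))
}

#' Default pre-operative score distributions
#'
#' Baseline means and SDs per clinical score (UPDRS parts in points, LEDD
#' in mg, PDQ-39 in points, weight in kg), calibrated to the cohort's
#' baseline table.
#' @return named list keyed by score with `mean` and `sd` entries.
#' @export
default_baseline_scores <- function() {
  list(UPDRS3 = list(mean = 48.1, sd = 4.75),
       UPDRS4 = list(mean = 8.6, sd = 2.2),
       LEDD = list(mean = 1112.8, sd = 287.65),
       PDQ39 = list(mean = 76.5, sd = 11.25),
       weight = list(mean = 75, sd = 7.5))
}

#' Default nucleus geometry for the synthetic atlas
#'
#' Axis-aligned ellipsoids per side: GPi about 470 mm^3 and STN about
#' 160 mm^3, at roughly anatomical standard-space positions, inside a
#' large ellipsoidal brain mask.  Centres are for the right side; the left
#' mirrors X.
#' @return list with `GPi`, `STN` (each `centre`, `semi_axes` in mm) and
#'   `brain_semi_axes`.
#' @export
default_nucleus_geometry <- function() {
  list(GPi = list(centre = c(20, -2, -4), semi_axes = c(7.3, 5.5, 2.8)),
       STN = list(centre = c(11, -13, -7), semi_axes = c(5.3, 4.0, 1.8)),
       brain_semi_axes = c(55, 65, 55))
}

#' Cohort simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator.  Defaults
#' reproduce the study conditions: 38 subjects with a 15:23 GPi:STN mix,
#' per-stratum Gaussian displacement of the realised electrode around the
#' motor-subnucleus centroid, doubled lateral standard deviation on the
#' second (right) side, frontal air cavities, small rigid SCRF transforms,
#' and outcome percentage changes per the default effect table.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param gpi_fraction probability that a subject's target is the GPi.
#' @param displacement_model see [default_displacement_model()].
#' @param right_x_variance_multiplier multiplier (>= 1) applied to the
#'   right-hemisphere X standard deviation.
#' @param pneumocephalus_volume_range min/max air-cavity volume, mL.
#' @param scrf_translation_scale SD of SCRF translations, mm.
#' @param scrf_rotation_scale SD of SCRF rotations, degrees.
#' @param outcome_effects see [default_outcome_effects()].
#' @param baseline_scores see [default_baseline_scores()].
#' @param nucleus_geometry see [default_nucleus_geometry()].
#' @param grid_shape atlas grid dimensions (voxels).
#' @param voxel_size atlas voxel edge length, mm.
#' @param lead_model lead model name looked up in the shipped library.
#' @param stimulation list with `amplitude` (V), `pulse_width` (us),
#'   `frequency` (Hz); the pulse width/frequency defaults are the
#'   standard initial programming settings.
#' @param seed integer root seed; each subject derives an independent
#'   substream from it, so subject k is invariant to `n_subjects`.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 38,
                          gpi_fraction = 15 / 38,
                          displacement_model = default_displacement_model(),
                          right_x_variance_multiplier = 2,
                          pneumocephalus_volume_range = c(0, 25),
                          scrf_translation_scale = 1,
                          scrf_rotation_scale = 1,
                          outcome_effects = default_outcome_effects(),
                          baseline_scores = default_baseline_scores(),
                          nucleus_geometry = default_nucleus_geometry(),
                          grid_shape = c(120L, 144L, 120L),
                          voxel_size = 1,
                          lead_model = "3389",
                          stimulation = list(amplitude = 2.5,
                                             pulse_width = 60,
                                             frequency = 130),
                          seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("'n_subjects' must be >= 1")
  if (gpi_fraction < 0 || gpi_fraction > 1)
    stop("'gpi_fraction' must be in [0, 1]")
  if (right_x_variance_multiplier < 1)
    stop("'right_x_variance_multiplier' must be >= 1")
  for (nm in names(displacement_model)) {
    e <- displacement_model[[nm]]
    if (any(e$sd < 0)) stop("negative displacement SD in stratum ", nm)
  }
  if (scrf_translation_scale < 0 || scrf_rotation_scale < 0)
    stop("SCRF scales must be >= 0")
  if (length(pneumocephalus_volume_range) != 2L ||
      any(pneumocephalus_volume_range < 0) ||
      diff(pneumocephalus_volume_range) < 0)
    stop("'pneumocephalus_volume_range' must be a non-negative (min, max)")
  structure(list(n_subjects = as.integer(n_subjects),
                 gpi_fraction = gpi_fraction,
                 displacement_model = displacement_model,
                 right_x_variance_multiplier = right_x_variance_multiplier,
                 pneumocephalus_volume_range = pneumocephalus_volume_range,
                 scrf_translation_scale = scrf_translation_scale,
                 scrf_rotation_scale = scrf_rotation_scale,
                 outcome_effects = outcome_effects,
                 baseline_scores = baseline_scores,
                 nucleus_geometry = nucleus_geometry,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size,
                 lead_model = lead_model,
                 stimulation = stimulation,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-subject, per-stage seed derived from the root seed.
# Keeps subject k's draws invariant to the cohort size.
substream_seed <- function(seed, k, stage) {
  as.integer((as.double(seed %% 100003L) * 7919 + k * 613 + stage * 101) %%
               2147483647)
}

draw_target <- function(config, k) {
  set.seed(substream_seed(config$seed, k, 1L))
  if (rbinom(1L, 1L, config$gpi_fraction) == 1L) "GPi" else "STN"
}

#' Generate the synthetic bilateral nucleus atlas
#'
#' Builds a labelled volume holding, per hemisphere, the GPi and STN as
#' axis-aligned voxelised ellipsoids with a motor sub-region (the
#' posteroventral half for the GPi, the posterior half for the STN), plus
#' a brain mask that contains all nuclei.  Motor voxels carry a distinct
#' code but belong to the main-nucleus region by construction; composite
#' regions are addressed by name, e.g. `"STN_main_left"`.
#'
#' @param grid_shape length-3 voxel counts.
#' @param voxel_size voxel edge length, mm (> 0).
#' @param geometry see [default_nucleus_geometry()].
#' @return a [label_volume] with a region-name table.
#' @export
generate_atlas <- function(grid_shape = c(120L, 144L, 120L), voxel_size = 1,
                           geometry = default_nucleus_geometry()) {
  if (voxel_size <= 0) stop("'voxel_size' must be > 0")
  grid_shape <- as.integer(grid_shape)
  aff <- diag(c(rep(voxel_size, 3), 1))
  aff[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  xs <- aff[1, 4] + voxel_size * (seq_len(grid_shape[1]) - 1)
  ys <- aff[2, 4] + voxel_size * (seq_len(grid_shape[2]) - 1)
  zs <- aff[3, 4] + voxel_size * (seq_len(grid_shape[3]) - 1)

  half_extent <- voxel_size * (grid_shape - 1) / 2
  for (nuc in c("GPi", "STN")) {
    g <- geometry[[nuc]]
    if (any(abs(g$centre) + g$semi_axes > half_extent))
      stop("grid too small to fit the ", nuc,
           " ellipsoids; enlarge 'grid_shape'")
  }
  if (any(geometry$brain_semi_axes > half_extent))
    stop("grid too small to fit the brain mask; enlarge 'grid_shape'")

  data <- array(0L, dim = grid_shape)
  # brain mask (code 1 where no nucleus label lands)
  bs <- geometry$brain_semi_axes
  q <- outer(outer((xs / bs[1])^2, (ys / bs[2])^2, `+`), (zs / bs[3])^2, `+`)
  data[q <= 1] <- 1L

  ellipsoid_codes <- list()
  code <- 1L
  for (nuc in c("GPi", "STN")) {
    g <- geometry[[nuc]]
    for (hemi in c("left", "right")) {
      ctr <- g$centre
      if (hemi == "left") ctr[1] <- -ctr[1]
      a <- g$semi_axes
      q <- outer(outer(((xs - ctr[1]) / a[1])^2, ((ys - ctr[2]) / a[2])^2,
                       `+`), ((zs - ctr[3]) / a[3])^2, `+`)
      inside <- q <= 1
      # motor sub-region: posterior half (STN), posteroventral half (GPi)
      yy <- array(rep(ys - ctr[2], each = grid_shape[1]), dim = grid_shape)
      if (nuc == "GPi") {
        zz <- array(rep(zs - ctr[3], each = grid_shape[1] * grid_shape[2]),
                    dim = grid_shape)
        motor_side <- (yy + zz) < 0
      } else {
        motor_side <- yy < 0
      }
      shell_code <- code + 1L
      motor_code <- code + 2L
      data[inside & !motor_side] <- shell_code
      data[inside & motor_side] <- motor_code
      ellipsoid_codes[[target_label(nuc, "main", hemi)]] <-
        c(shell_code, motor_code)
      ellipsoid_codes[[target_label(nuc, "motor", hemi)]] <- motor_code
      code <- code + 2L

      vol_target <- 4 / 3 * pi * prod(a)
      vol_vox <- sum(inside) * voxel_size^3
      if (abs(vol_vox - vol_target) > 0.2 * vol_target)
        stop("voxelised ", nuc, " ", hemi, " volume (", round(vol_vox),
             " mm^3) deviates more than 20% from the configured ",
             round(vol_target), " mm^3; refine 'voxel_size'")
    }
  }
  labels <- c(list(brain = 1:code), ellipsoid_codes)
  label_volume(data, aff, labels = labels)
}

# Standard frontal trajectory: from the tip towards an anterior-superior,
# slightly lateral entry point.
trajectory_direction <- function(hemisphere) {
  d <- c(if (hemisphere == "left") -0.15 else 0.15, 0.35, 0.92)
  d / sqrt(sum(d^2))
}

#' Generate per-subject electrode pairs
#'
#' For each subject, places one electrode per hemisphere.  The planned
#' target is the centre of gravity of the motor sub-region of the target
#' nucleus; the realised position displaces the first (most distal)
#' contact centre from the planned point by a Gaussian draw from the
#' stratum's displacement distribution, with the right-hemisphere X
#' standard deviation inflated by `right_x_variance_multiplier`.
#'
#' @param atlas atlas from [generate_atlas()].
#' @param config a [cohort_config].
#' @param seed root seed (defaults to `config$seed`).
#' @param targets optional character vector of per-subject target nuclei
#'   (`"GPi"`/`"STN"`); drawn from the configured mix when `NULL`.
#' @return list of per-subject lists with `target`, `left`, `right`
#'   ([electrode_model]s) and `truth` (the injected displacement per
#'   hemisphere, mm).
#' @export
generate_electrodes <- function(atlas, config, seed = config$seed,
                                targets = NULL) {
  lib <- load_lead_library()
  spec <- lib[[config$lead_model]]
  if (is.null(spec)) stop("unknown lead model '", config$lead_model, "'")
  centroids <- new.env(parent = emptyenv()) # planned targets, per stratum
  out <- vector("list", config$n_subjects)
  for (k in seq_len(config$n_subjects)) {
    target <- if (is.null(targets)) {
      cfg_k <- config; cfg_k$seed <- seed
      draw_target(cfg_k, k)
    } else targets[k]
    set.seed(substream_seed(seed, k, 2L))
    electrodes <- list()
    truth <- list()
    for (hemi in c("left", "right")) {
      stratum <- paste(hemi, target, sep = ".")
      entry <- config$displacement_model[[stratum]]
      if (is.null(entry))
        stop("no displacement model for stratum '", stratum, "'")
      sd_use <- entry$sd
      if (hemi == "right")
        sd_use[1] <- sd_use[1] * config$right_x_variance_multiplier
      disp <- rnorm(3, entry$mean, sd_use)
      lab <- target_label(target, "motor", hemi)
      if (is.null(centroids[[lab]]))
        centroids[[lab]] <- label_centroid(atlas, lab)
      planned <- centroids[[lab]]
      dir <- trajectory_direction(hemi)
      # place so that contact 0 sits at planned + displacement
      tip <- planned + disp - spec$tip_to_first_contact_centre * dir
      electrodes[[hemi]] <- electrode_model(tip, dir, spec, hemi)
      truth[[hemi]] <- disp
    }
    out[[k]] <- list(target = target, left = electrodes$left,
                     right = electrodes$right, truth = truth)
  }
  out
}

# Rigid-body affine from XYZ translation (mm) and rotations (degrees,
# applied as Rz Ry Rx about the origin).
make_rigid_affine <- function(translation = c(0, 0, 0),
                              rotation_deg = c(0, 0, 0)) {
  a <- rotation_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  m <- diag(4)
  m[1:3, 1:3] <- rz %*% ry %*% rx
  m[1:3, 4] <- translation
  affine_transform(m)
}

# Carve a spherical air cavity (intersected with the mask) out of a brain
# mask; returns the modified volume and the carved voxel count.
carve_air_cavity <- function(brain, centre, radius) {
  m <- label_mask(brain, "brain")
  d <- dim(m)
  vs <- voxel_size(brain)
  cv <- world_to_voxel(brain, centre)[1, ]
  rr <- ceiling(radius / vs) + 1
  lo <- pmax(1, floor(cv - rr)); hi <- pmin(d, ceiling(cv + rr))
  carved <- 0L
  if (radius > 0 && all(lo <= hi)) {
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    wx <- (voxel_to_world(brain, cbind(ii, 1, 1))[, 1] - centre[1])^2
    wy <- (voxel_to_world(brain, cbind(1, jj, 1))[, 2] - centre[2])^2
    wz <- (voxel_to_world(brain, cbind(1, 1, kk))[, 3] - centre[3])^2
    q <- outer(outer(wx, wy, `+`), wz, `+`)
    sub <- m[ii, jj, kk, drop = FALSE]
    rem <- sub & (q <= radius^2)
    carved <- sum(rem)
    data <- brain$data
    subdat <- data[ii, jj, kk, drop = FALSE]
    subdat[rem] <- 0L
    data[ii, jj, kk] <- subdat
    brain <- label_volume(data, brain$affine, labels = brain$labels)
  }
  list(brain = brain, carved_voxels = carved)
}

#' Generate the post-operative state of one subject
#'
#' Carves a frontal (anterior-third) spherical air cavity of the
#' configured volume out of the brain mask, draws small rigid SCRF
#' transforms per hemisphere, and records the ground truth (actual carved
#' cavity volume and affine parameters) for downstream recovery tests.
#'
#' @param brain_mask a [label_volume] whose `"brain"` region is non-empty.
#' @param config a [cohort_config].
#' @param seed root seed.
#' @param k subject index (drives the per-subject substream).
#' @return list with `brain` (air-modified mask), `scrf` (left/right
#'   [affine_transform]s) and `truth` (cavity centre/radius/volume in mL
#'   and the SCRF translation/rotation parameters).
#' @export
generate_postop_state <- function(brain_mask, config, seed = config$seed,
                                  k = 1L) {
  m <- label_mask(brain_mask, "brain")
  if (!any(m)) stop("brain mask is empty")
  mask_ml <- sum(m) * voxel_volume_mm3(brain_mask) / 1000
  set.seed(substream_seed(seed, k, 3L))
  vol_ml <- runif(1, config$pneumocephalus_volume_range[1],
                  config$pneumocephalus_volume_range[2])
  if (vol_ml > mask_ml)
    stop("requested cavity volume (", round(vol_ml, 1),
         " mL) exceeds brain mask volume (", round(mask_ml, 1), " mL)")
  radius <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
  # cavity centre in the most-anterior third of the mask, near the midline
  wy <- voxel_to_world(brain_mask, which(m, arr.ind = TRUE))[, 2]
  y_top <- max(wy); y_lo <- min(wy) + 2 / 3 * (y_top - min(wy))
  centre <- c(runif(1, -8, 8),
              min(y_lo + 0.55 * (y_top - y_lo), y_top - radius - 2),
              runif(1, -8, 8))
  carved <- carve_air_cavity(brain_mask, centre, radius)
  scrf <- list(); scrf_params <- list()
  for (hemi in c("left", "right")) {
    tr <- rnorm(3, 0, config$scrf_translation_scale)
    ro <- rnorm(3, 0, config$scrf_rotation_scale)
    if (config$scrf_translation_scale == 0) tr <- c(0, 0, 0)
    if (config$scrf_rotation_scale == 0) ro <- c(0, 0, 0)
    scrf[[hemi]] <- make_rigid_affine(tr, ro)
    scrf_params[[hemi]] <- list(translation = tr, rotation_deg = ro)
  }
  list(brain = carved$brain, scrf = scrf,
       truth = list(cavity_centre = centre, cavity_radius = radius,
                    requested_ml = vol_ml,
                    pneumocephalus_ml = carved$carved_voxels *
                      voxel_volume_mm3(brain_mask) / 1000,
                    scrf = scrf_params))
}

draw_effect <- function(effects, score, target) {
  e <- effects[[score]]
  if (is.null(e)) stop("no outcome effect configured for score ", score)
  if (!is.null(e$mean)) e else {
    if (is.null(e[[target]]))
      stop("no outcome effect configured for score ", score,
           " and target ", target)
    e[[target]]
  }
}

#' Generate pre/post clinical scores
#'
#' Pre-operative scores are Gaussian around the configured baselines;
#' post-operative scores are `pre * (1 + pct/100)` with the percentage
#' change drawn per score from the configured effect distribution (LEDD
#' effects differ by target nucleus).  All scores are floored at 0.
#'
#' @param config a [cohort_config].
#' @param seed root seed.
#' @param targets per-subject target nuclei; drawn from the configured
#'   mix when `NULL`.
#' @return list of per-subject data.frames with columns `score`, `pre`,
#'   `post`, `pct_change`.
#' @export
generate_outcomes <- function(config, seed = config$seed, targets = NULL) {
  scores <- names(config$baseline_scores)
  out <- vector("list", config$n_subjects)
  for (k in seq_len(config$n_subjects)) {
    target <- if (is.null(targets)) {
      cfg_k <- config; cfg_k$seed <- seed
      draw_target(cfg_k, k)
    } else targets[k]
    set.seed(substream_seed(seed, k, 4L))
    rows <- lapply(scores, function(s) {
      b <- config$baseline_scores[[s]]
      e <- draw_effect(config$outcome_effects, s, target)
      pre <- max(0, rnorm(1, b$mean, b$sd))
      pct <- rnorm(1, e$mean, e$sd)
      if (e$sd == 0) pct <- e$mean # exact under zero dispersion
      data.frame(score = s, pre = pre,
                 post = max(0, pre * (1 + pct / 100)), pct_change = pct)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Assembles atlas, electrodes, post-operative state and outcomes into a
#' list of subject records under a single root seed.  Identical
#' configuration and seed give a bit-identical cohort, and subject k's
#' draws do not depend on `n_subjects`.
#'
#' @param config a [cohort_config].
#' @return list with `atlas`, `template_brain` (pre-operative brain mask as
#'   its own volume), `subjects` (per-subject records) and `config`.
#'   Each subject record holds `id`, `target`, `electrodes` (left/right),
#'   `scrf` (left/right), `air_cavity` (centre, radius, truth volume),
#'   `pneumocephalus_truth` (mL), `scores` (data.frame), `stimulation`
#'   and `truth` (injected displacements and SCRF parameters).
#' @export
generate_cohort <- function(config = cohort_config()) {
  atlas <- generate_atlas(config$grid_shape, config$voxel_size,
                          config$nucleus_geometry)
  template_brain <- label_volume(
    array(as.integer(label_mask(atlas, "brain")), dim = dim(atlas$data)),
    atlas$affine, labels = list(brain = 1L))
  targets <- vapply(seq_len(config$n_subjects), function(k)
    draw_target(config, k), character(1))
  electrodes <- generate_electrodes(atlas, config, targets = targets)
  outcomes <- generate_outcomes(config, targets = targets)
  subjects <- vector("list", config$n_subjects)
  for (k in seq_len(config$n_subjects)) {
    post <- generate_postop_state(template_brain, config, k = k)
    subjects[[k]] <- list(
      id = sprintf("sub-%03d", k),
      target = targets[k],
      electrodes = list(left = electrodes[[k]]$left,
                        right = electrodes[[k]]$right),
      scrf = post$scrf,
      air_cavity = list(centre = post$truth$cavity_centre,
                        radius = post$truth$cavity_radius),
      pneumocephalus_truth = post$truth$pneumocephalus_ml,
      scores = outcomes[[k]],
      stimulation = config$stimulation,
      truth = list(displacement = electrodes[[k]]$truth,
                   scrf = post$truth$scrf,
                   requested_cavity_ml = post$truth$requested_ml))
  }
  list(atlas = atlas, template_brain = template_brain,
       subjects = subjects, config = config)
}

#' Post-operative brain mask of one subject
#'
#' Re-carves the subject's recorded air cavity from the template brain
#' mask (masks are not stored per subject to keep cohorts light).
#'
#' @param cohort result of [generate_cohort()].
#' @param k subject index.
#' @return a [label_volume].
#' @export
subject_brain_mask <- function(cohort, k) {
  s <- cohort$subjects[[k]]
  carve_air_cavity(cohort$template_brain, s$air_cavity$centre,
                   s$air_cavity$radius)$brain
}

#' Write per-subject electrode/SCRF/truth records as JSON
#'
#' @param subject one subject record from [generate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_subject_json <- function(subject, path) {
  enc <- subject
  enc$electrodes <- lapply(subject$electrodes, function(e)
    list(tip = e$tip, direction = e$direction,
         lead_model = e$spec$model_name, hemisphere = e$hemisphere,
         implantation_order = e$implantation_order))
  enc$scrf <- lapply(subject$scrf, function(a)
    apply(unclass(as.matrix(a)), 1, as.numeric, simplify = FALSE))
  enc$scores <- NULL
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the cohort score table as CSV
#'
#' Long format: one row per subject x score, columns
#' `id, target, score, pre, post`.
#'
#' @param subjects list of subject records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_scores <- function(subjects, path) {
  rows <- lapply(subjects, function(s)
    data.frame(id = s$id, target = s$target, score = s$scores$score,
               pre = s$scores$pre, post = s$scores$post))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
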