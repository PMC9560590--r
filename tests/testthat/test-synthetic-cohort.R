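test_that("atlas labels are disjoint with motor nested in main", {
  atlas <- generate_atlas(c(80L, 92L, 80L), 1, small_geometry())
  for (nuc in c("GPi", "STN")) for (hemi in c("left", "right")) {
    main <- label_mask(atlas, target_label(nuc, "main", hemi))
    motor <- label_mask(atlas, target_label(nuc, "motor", hemi))
    expect_true(all(main[motor]))          # motor subset of main
    expect_true(sum(motor) < sum(main))    # strict
    expect_true(all(label_mask(atlas, "brain")[main])) # inside brain
  }
  # grids are deterministic
  atlas2 <- generate_atlas(c(80L, 92L, 80L), 1, small_geometry())
  expect_identical(atlas$data, atlas2$data)
  # volumes close to the configured ellipsoid volumes
  g <- small_geometry()
  for (nuc in c("GPi", "STN")) {
    want <- 4 / 3 * pi * prod(g[[nuc]]$semi_axes)
    got <- label_volume_mm3(atlas, target_label(nuc, "main", "right"))
    expect_lt(abs(got - want) / want, 0.2)
  }
  expect_error(generate_atlas(c(20L, 20L, 20L), 1, small_geometry()),
               "too small")
})

test_that("zero-noise electrodes land exactly on the planned target", {
  dm <- default_displacement_model()
  for (nm in names(dm)) { dm[[nm]]$mean <- c(0, 0, 0); dm[[nm]]$sd <- c(0, 0, 0) }
  cfg <- small_config(n_subjects = 2, displacement_model = dm, seed = 5)
  atlas <- generate_atlas(cfg$grid_shape, cfg$voxel_size, cfg$nucleus_geometry)
  els <- generate_electrodes(atlas, cfg, targets = c("GPi", "STN"))
  for (k in 1:2) for (hemi in c("left", "right")) {
    el <- els[[k]][[hemi]]
    lab <- target_label(els[[k]]$target, "motor", hemi)
    expect_equal(boundary_distance(el, atlas, lab), 0)
    co <- centroid_offset(el, atlas, lab)
    expect_equal(co$norm, 0, tolerance = 1e-9)
  }
})

test_that("a fixed injected offset is recovered exactly", {
  dm <- default_displacement_model()
  for (nm in names(dm)) { dm[[nm]]$mean <- c(1, 0, 0); dm[[nm]]$sd <- c(0, 0, 0) }
  cfg <- small_config(n_subjects = 1, displacement_model = dm, seed = 5)
  atlas <- generate_atlas(cfg$grid_shape, cfg$voxel_size, cfg$nucleus_geometry)
  el <- generate_electrodes(atlas, cfg, targets = "STN")[[1]]$left
  co <- centroid_offset(el, atlas, target_label("STN", "motor", "left"))
  expect_equal(co$offset, c(1, 0, 0), tolerance = 1e-9)
})

test_that("the right-hemisphere X variance multiplier scales as configured", {
  cfg <- small_config(n_subjects = 500, gpi_fraction = 0,
                      right_x_variance_multiplier = 2, seed = 99)
  atlas <- generate_atlas(cfg$grid_shape, cfg$voxel_size, cfg$nucleus_geometry)
  els <- generate_electrodes(atlas, cfg,
                             targets = rep("STN", cfg$n_subjects))
  dx <- sapply(els, function(e) c(e$truth$left[1], e$truth$right[1]))
  ratio <- var(dx[2, ]) / var(dx[1, ])
  expect_gt(ratio, 3)   # true ratio 4, n = 500 per side
  expect_lt(ratio, 5.3)
})

test_that("a missing displacement stratum is a configuration error", {
  cfg <- small_config(n_subjects = 1)
  cfg$displacement_model[["left.STN"]] <- NULL
  atlas <- generate_atlas(cfg$grid_shape, cfg$voxel_size, cfg$nucleus_geometry)
  expect_error(generate_electrodes(atlas, cfg, targets = "STN"),
               "left.STN")
})

test_that("air cavities carve the configured volume and are recoverable", {
  cfg <- small_config(n_subjects = 1,
                      pneumocephalus_volume_range = c(5, 5),
                      scrf_translation_scale = 0, scrf_rotation_scale = 0)
  atlas <- generate_atlas(cfg$grid_shape, cfg$voxel_size, cfg$nucleus_geometry)
  brain <- label_volume(
    array(as.integer(label_mask(atlas, "brain")), dim = dim(atlas$data)),
    atlas$affine, labels = list(brain = 1L))
  post <- generate_postop_state(brain, cfg, k = 1L)
  # ~5000 voxels removed at 1 mm^3 (voxelisation of the 5 mL sphere)
  removed <- sum(brain$data) - sum(post$brain$data)
  expect_lt(abs(removed - 5000), 0.02 * 5000)
  # the recorded truth is the exact carved volume
  expect_equal(pneumocephalus_volume(brain, post$brain),
               post$truth$pneumocephalus_ml)
  # zero SCRF scales give the identity transform
  expect_equal(unclass(as.matrix(post$scrf$left)), diag(4))
  # zero cavity leaves the mask untouched
  cfg0 <- small_config(n_subjects = 1,
                       pneumocephalus_volume_range = c(0, 0))
  post0 <- generate_postop_state(brain, cfg0, k = 1L)
  expect_identical(post0$brain$data, brain$data)
  # impossible volumes are refused
  cfgbig <- small_config(n_subjects = 1)
  cfgbig$pneumocephalus_volume_range <- c(1e5, 1e5)
  expect_error(generate_postop_state(brain, cfgbig, k = 1L), "exceeds")
})

test_that("cavity centres sit in the most-anterior third of the mask", {
  cfg <- small_config(n_subjects = 6, seed = 3)
  coh <- generate_cohort(cfg)
  m <- label_mask(coh$template_brain, "brain")
  wy <- voxel_to_world(coh$template_brain, which(m, arr.ind = TRUE))[, 2]
  y_third <- min(wy) + 2 / 3 * (max(wy) - min(wy))
  for (s in coh$subjects)
    expect_gt(s$air_cavity$centre[2], y_third)
})

test_that("outcome generation follows the configured percentage effects", {
  # zero dispersion: UPDRS3 change is exactly the configured -45.9%
  eff <- default_outcome_effects()
  for (nm in names(eff)) {
    if (!is.null(eff[[nm]]$sd)) eff[[nm]]$sd <- 0
    else { eff[[nm]]$GPi$sd <- 0; eff[[nm]]$STN$sd <- 0 }
  }
  cfg <- small_config(n_subjects = 3, outcome_effects = eff, seed = 8)
  outs <- generate_outcomes(cfg, targets = c("GPi", "STN", "GPi"))
  for (o in outs) {
    u <- o[o$score == "UPDRS3", ]
    expect_equal(100 * (u$post - u$pre) / u$pre, -45.9, tolerance = 1e-9)
  }
  # null effects: post equals pre
  for (nm in names(eff)) {
    if (!is.null(eff[[nm]]$mean)) eff[[nm]]$mean <- 0
    else { eff[[nm]]$GPi$mean <- 0; eff[[nm]]$STN$mean <- 0 }
  }
  cfg0 <- small_config(n_subjects = 2, outcome_effects = eff, seed = 8)
  for (o in generate_outcomes(cfg0, targets = c("GPi", "STN")))
    expect_equal(o$post, o$pre)
})

test_that("STN subjects reduce medication far more than GPi subjects", {
  cfg <- small_config(n_subjects = 200, seed = 17)
  targets <- rep(c("GPi", "STN"), 100)
  outs <- generate_outcomes(cfg, targets = targets)
  ledd_pct <- vapply(outs, function(o) {
    l <- o[o$score == "LEDD", ]; 100 * (l$post - l$pre) / l$pre
  }, numeric(1))
  expect_lt(mean(ledd_pct[targets == "STN"]),
            mean(ledd_pct[targets == "GPi"]))
  expect_lt(mean(ledd_pct[targets == "STN"]), -40)
  expect_gt(mean(ledd_pct[targets == "GPi"]), -10)
})

test_that("cohorts are deterministic and subject-stable under resizing", {
  cfg <- small_config(n_subjects = 4, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # subject 3 is unchanged when the cohort grows
  cfg6 <- small_config(n_subjects = 6, seed = 21)
  c6 <- generate_cohort(cfg6)
  expect_equal(a$subjects[[3]]$electrodes$left$tip,
               c6$subjects[[3]]$electrodes$left$tip)
  expect_equal(a$subjects[[3]]$scores, c6$subjects[[3]]$scores)
  expect_equal(a$subjects[[3]]$pneumocephalus_truth,
               c6$subjects[[3]]$pneumocephalus_truth)
})

test_that("cohort artefacts round-trip through their file formats", {
  cfg <- small_config(n_subjects = 2, seed = 33)
  coh <- generate_cohort(cfg)
  # label volumes are lossless through the NIfTI writer/reader
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(coh$atlas, p)
  back <- read_nifti(p, labels = coh$atlas$labels)
  expect_identical(back$data, coh$atlas$data)
  expect_lt(max(abs(back$affine - coh$atlas$affine)), 1e-6)
  # scores CSV has the documented header
  sc <- withr::local_tempfile(fileext = ".csv")
  write_cohort_scores(coh$subjects, sc)
  tab <- read.csv(sc)
  expect_identical(names(tab), c("id", "target", "score", "pre", "post"))
  expect_equal(nrow(tab), 10) # 2 subjects x 5 scores
  # subject JSON is parseable and carries the electrode record
  js <- withr::local_tempfile(fileext = ".json")
  write_subject_json(coh$subjects[[1]], js)
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$electrodes$left$tip,
               coh$subjects[[1]]$electrodes$left$tip)
  expect_equal(rec$id, "sub-001")
})
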