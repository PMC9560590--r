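test_that("boundary distance clamps to zero inside and is analytic outside", {
  vol <- sphere_volume(4, voxel = 1)
  sp <- lead_spec("mono", 1, 1, 1.5, 0)
  at_centre <- electrode_model(c(0, 0, 0), c(0, 0, 1), sp, "left")
  expect_equal(boundary_distance(at_centre, vol, "sphere"), 0)
  # nearest labelled voxel centre on the z axis is (0,0,4): 2 mm away
  outside <- electrode_model(c(0, 0, 6), c(0, 0, 1), sp, "left")
  expect_equal(boundary_distance(outside, vol, "sphere"), 2, tolerance = 1e-6)
  expect_error(boundary_distance(outside, vol, 99L), "99")
})

test_that("signed boundary distance reports penetration depth", {
  vol <- sphere_volume(5, voxel = 1)
  sp <- lead_spec("mono", 1, 1, 1.5, 0)
  at_centre <- electrode_model(c(0, 0, 0), c(0, 0, 1), sp, "left")
  d <- boundary_distance(at_centre, vol, "sphere", signed = TRUE)
  expect_lt(d, -3) # deepest contact is ~5 mm from the surface
  outside <- electrode_model(c(0, 0, 8), c(0, 0, 1), sp, "left")
  expect_equal(boundary_distance(outside, vol, "sphere", signed = TRUE),
               boundary_distance(outside, vol, "sphere"))
})

test_that("boundary distance agrees with the brute-force surface oracle", {
  set.seed(42)
  sp <- default_lead()
  n_cases <- 110
  for (i in seq_len(n_cases)) {
    voxel <- runif(1, 0.8, 1.4)
    semi <- runif(3, 2.5, 6)
    half <- ceiling(max(semi) / voxel) + 3
    n <- 2L * half + 1L
    aff <- diag(c(voxel, voxel, voxel, 1)); aff[1:3, 4] <- -voxel * half
    if (i %% 3 == 0) { # exercise rotated grids too
      r <- random_rotation()
      aff[1:3, 1:3] <- r * voxel
      aff[1:3, 4] <- -as.numeric(r %*% rep(voxel * half, 3))
    }
    ax <- seq(-voxel * half, voxel * half, by = voxel)
    q <- outer(outer((ax / semi[1])^2, (ax / semi[2])^2, `+`),
               (ax / semi[3])^2, `+`)
    vol <- label_volume(array(as.integer(q <= 1), dim = c(n, n, n)), aff,
                        labels = list(blob = 1L))
    tip <- rnorm(3, 0, max(semi))
    el <- electrode_model(tip, rnorm(3), sp, "left")
    got <- boundary_distance(el, vol, "blob")
    want <- brute_boundary_distance(el, vol, "blob")
    expect_lt(abs(got - want), sqrt(3) * voxel)
  }
})

test_that("boundary distance is invariant under joint rigid motion", {
  set.seed(43)
  vol <- sphere_volume(4, voxel = 1)
  sp <- default_lead()
  el <- electrode_model(c(1, 5, 3), c(0.2, 0.1, 1), sp, "left")
  d0 <- boundary_distance(el, vol, "sphere")
  for (i in 1:10) {
    m <- unclass(as.matrix(random_rigid()))
    vol_t <- label_volume(vol$data, m %*% vol$affine, labels = vol$labels)
    el_t <- electrode_model(as.numeric(m %*% c(el$tip, 1))[1:3],
                            as.numeric(m[1:3, 1:3] %*% el$direction),
                            sp, "left")
    expect_equal(boundary_distance(el_t, vol_t, "sphere"), d0,
                 tolerance = 1e-6)
  }
})

test_that("boundary distance never exceeds the centroid offset outside", {
  set.seed(44)
  vol <- sphere_volume(4, voxel = 1)
  sp <- default_lead()
  for (i in 1:30) {
    el <- electrode_model(rnorm(3, 0, 8), rnorm(3), sp, "left")
    bd <- boundary_distance(el, vol, "sphere")
    if (bd > 0)
      expect_lte(bd, centroid_offset(el, vol, "sphere")$norm)
  }
})

test_that("centroid offset picks the nearest contact and reports the norm", {
  vol <- sphere_volume(4, voxel = 1)
  sp <- lead_spec("mono", 1, 1, 1.5, 0)
  cg <- label_centroid(vol, "sphere")
  on_target <- electrode_model(cg, c(0, 0, 1), sp, "left")
  co <- centroid_offset(on_target, vol, "sphere")
  expect_equal(co$offset, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(co$norm, 0, tolerance = 1e-9)

  shifted <- electrode_model(cg + c(1, 2, 2), c(0, 0, 1), sp, "left")
  co2 <- centroid_offset(shifted, vol, "sphere")
  expect_equal(co2$norm, 3) # 1-2-2 right triangle
  expect_equal(co2$offset, c(1, 2, 2))
  expect_equal(co2$contact, 0L)
})

test_that("apply_scrf is exact for translations and composes", {
  set.seed(45)
  sp <- default_lead()
  el <- electrode_model(c(1, 2, 3), c(0.1, 0.2, 1), sp, "right")
  expect_equal(apply_scrf(el, diag(4))$tip, el$tip)

  tr <- make_rigid_affine(translation = c(2, -1, 0.5))
  vol <- sphere_volume(4)
  co0 <- centroid_offset(el, vol, "sphere")
  co1 <- centroid_offset(apply_scrf(el, tr), vol, "sphere")
  expect_equal(co1$offset - co0$offset, c(2, -1, 0.5), tolerance = 1e-9)

  for (i in 1:10) {
    a <- random_rigid(); b <- random_rigid()
    ab <- affine_transform(unclass(as.matrix(a)) %*% unclass(as.matrix(b)))
    e1 <- apply_scrf(el, ab)
    e2 <- apply_scrf(apply_scrf(el, b), a)
    expect_equal(e1$tip, e2$tip, tolerance = 1e-9)
    expect_equal(e1$direction, e2$direction, tolerance = 1e-9)
  }
  sing <- diag(4); sing[1, 1] <- 0
  expect_error(apply_scrf(el, sing), "singular")
})

test_that("Tukey outlier flagging matches a literal recomputation", {
  expect_error(flag_outliers(c(1, 2, 3)), "at least 4")
  expect_false(any(flag_outliers(rep(2, 10))))
  expect_identical(flag_outliers(c(rep(0, 7), 10)),
                   c(rep(FALSE, 7), TRUE))
  set.seed(46)
  for (i in 1:25) {
    x <- rexp(sample(5:60, 1))
    q1 <- quantile(x, 0.25, names = FALSE)
    q3 <- quantile(x, 0.75, names = FALSE)
    expect_identical(flag_outliers(x), x > q3 + 1.5 * (q3 - q1))
  }
})

test_that("stratified summary reproduces hand-computed group statistics", {
  res <- data.frame(
    id = rep(c("a", "b", "c", "d"), each = 2),
    nucleus = rep(c("GPi", "STN"), each = 4),
    hemisphere = rep(c("left", "right"), 4),
    boundary_distance = c(0, 1, 2, 5, 0, 0, 0.5, 3),
    outlier = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  tab <- summarise_accuracy(res, "nucleus")
  gpi <- tab[tab$nucleus == "GPi", ]
  expect_equal(gpi$n, 4)
  expect_equal(gpi$mean, 2)
  expect_equal(gpi$sd, sd(c(0, 1, 2, 5)))
  expect_equal(gpi$upper_2sd, 2 + 2 * sd(c(0, 1, 2, 5)))
  expect_equal(gpi$lower_2sd, 2 - 2 * sd(c(0, 1, 2, 5)))
  expect_equal(gpi$n_outliers, 1)
  expect_equal(gpi$n_within, 3)
  stn <- tab[tab$nucleus == "STN", ]
  expect_equal(stn$mean, 0.875)
  expect_equal(stn$n_within, 3)
  expect_error(summarise_accuracy(res, "nonexistent"), "unknown grouping")

  zero <- res; zero$boundary_distance <- 0; zero$outlier <- FALSE
  tz <- summarise_accuracy(zero, c("nucleus", "hemisphere"))
  expect_true(all(tz$mean == 0))
  expect_true(all(tz$n_within == tz$n))
})

test_that("target plot table carries both SCRF variants and all axes", {
  res <- data.frame(
    id = rep("s1", 4), nucleus = "STN", hemisphere = "left",
    reference = rep(c("main", "motor"), 2),
    scrf_applied = rep(c(TRUE, FALSE), each = 2),
    dx = 1:4, dy = 5:8, dz = 9:12,
    boundary_distance = 0, offset_norm = 0, outlier = FALSE)
  tab <- target_plot_table(res)
  expect_setequal(tab$variant, c("SCRF", "nSCRF"))
  expect_true(all(c("x", "y", "z") %in% names(tab)))
  only <- target_plot_table(res, reference = "main",
                            with_and_without_scrf = FALSE)
  expect_equal(nrow(only), 1)
  expect_equal(only$variant, "SCRF")
})
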