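# Shared small solved problem: spherical contact inside a grounded
# spherical shell, homogeneous grey matter.  The exact solution is
# V(r) = V0 * (1/r - 1/R) / (1/r0 - 1/R), the point-source (monopole)
# law corrected for the grounded boundary.
shell_problem <- function(spacing = 1, nh = 16L, R = 14, r0 = 1.5,
                          amplitude = 1) {
  n <- 2L * nh + 1L
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- rep(-spacing * nh, 3)
  ax <- seq(-spacing * nh, spacing * nh, by = spacing)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  data <- array(1L, dim = c(n, n, n))
  data[r2 > R^2] <- 0L
  data[r2 <= r0^2] <- 3L
  dom <- label_volume(data, aff,
                      labels = list(grey = 1L, tissue = 1L, metal = 3L))
  list(domain = dom, active = r2 <= r0^2, r = sqrt(r2), R = R, r0 = r0,
       amplitude = amplitude, tissue = data == 1L, spacing = spacing)
}

test_that("potential solve obeys the maximum principle and homogeneity", {
  pb <- shell_problem()
  sol <- solve_potential(pb$domain, pb$active, amplitude = 1)
  expect_gte(min(sol$voltage), 0)
  expect_lte(max(sol$voltage), 1)
  # scaling all conductivities leaves the Laplace solution unchanged
  c10 <- conductivity_model(3.3, 1.4, 1e9, 1e-5)
  sol10 <- solve_potential(pb$domain, pb$active, c10, amplitude = 1)
  expect_equal(sol10$voltage, sol$voltage, tolerance = 1e-5)
})

test_that("potential matches the analytic grounded point-source solution", {
  pb <- shell_problem(spacing = 0.5, nh = 40L, R = 18, r0 = 1)
  sol <- solve_potential(pb$domain, pb$active, amplitude = 1)
  analytic <- function(r) (1 / r - 1 / pb$R) / (1 / pb$r0 - 1 / pb$R)
  for (rt in c(2, 3, 5, 8, 12)) {
    sel <- abs(pb$r - rt) < 0.25
    expect_lt(abs(mean(sol$voltage[sel]) / analytic(rt) - 1), 0.05)
  }
})

test_that("field magnitude handles ramps, constants and the monopole", {
  ramp <- array(rep(seq(0, 3, length.out = 16), each = 100),
                dim = c(10, 10, 16))
  f <- field_magnitude(ramp, 1)
  expect_equal(max(abs(f - 0.2)), 0, tolerance = 1e-9)
  expect_equal(field_magnitude(array(2, dim = c(5, 5, 5)), 1),
               array(0, dim = c(5, 5, 5)))

  pb <- shell_problem(spacing = 0.5, nh = 40L, R = 18, r0 = 1)
  sol <- solve_potential(pb$domain, pb$active, amplitude = 1)
  f <- field_magnitude(sol$voltage, pb$spacing)
  scale <- 1 / (1 / pb$r0 - 1 / pb$R) # analytic |E| = scale / r^2
  for (rt in c(3, 5, 7)) {
    sel <- abs(pb$r - rt) < 0.25 & pb$tissue
    expect_lt(abs(mean(f[sel]) / (scale / rt^2) - 1), 0.10)
  }
})

test_that("VAT binarisation is thresholded, tissue-restricted, monotone", {
  pb <- shell_problem(spacing = 0.5, nh = 40L, R = 18, r0 = 1,
                      amplitude = 3)
  sol <- solve_potential(pb$domain, pb$active, amplitude = 3)
  f <- field_magnitude(sol$voltage, pb$spacing)
  vat <- binarise_vat(f, 0.2, pb$tissue)
  # radius from the monopole field (boundary-insensitive)
  scale <- 3 / (1 / pb$r0 - 1 / pb$R)
  r_pred <- sqrt(scale / 0.2)
  r_got <- max(pb$r[vat])
  expect_lt(abs(r_got - r_pred), pb$spacing) # within one voxel
  # threshold monotonicity and tissue exclusion
  vat3 <- binarise_vat(f, 0.3, pb$tissue)
  expect_true(all(pb$tissue[vat]))
  expect_true(all(vat[vat3]))
  expect_false(any(binarise_vat(array(0.1, dim = c(4, 4, 4)), 0.2)))
  # amplitude monotonicity
  sol1 <- solve_potential(pb$domain, pb$active, amplitude = 1.5)
  vat1 <- binarise_vat(field_magnitude(sol1$voltage, pb$spacing), 0.2,
                       pb$tissue)
  expect_lte(sum(vat1), sum(vat))
})

test_that("solver refuses degenerate problems", {
  pb <- shell_problem()
  expect_error(solve_potential(pb$domain, array(FALSE, dim(pb$domain$data))),
               "empty")
  touching <- array(FALSE, dim(pb$domain$data))
  touching[1, 1, 1] <- TRUE
  expect_error(solve_potential(pb$domain, touching), "boundary")
  expect_error(solve_potential(pb$domain, pb$active, amplitude = 1,
                               max_iter = 3L), "converge")
  expect_error(build_vat_domain(electrode_model(c(0, 0, 0), c(0, 0, 1),
                                                default_lead(), "left"),
                                extent_mm = 15), "10 mm")
  expect_error(conductivity_model(grey = 0.1, white = 0.2), "require")
})

test_that("overlap equals the exhaustive voxelwise intersection", {
  set.seed(81)
  d <- c(20, 20, 20)
  regions <- label_volume(array(sample(0:2, prod(d), TRUE), dim = d),
                          diag(c(0.5, 0.5, 0.5, 1)),
                          labels = list(main = c(1L, 2L), motor = 2L))
  vat <- array(runif(prod(d)) < 0.3, dim = d)
  ov <- vat_overlap(vat, regions, c("main", "motor"))
  vv <- 0.125
  expect_equal(ov$overlap_mm3[1], sum(vat & regions$data >= 1) * vv)
  expect_equal(ov$overlap_mm3[2], sum(vat & regions$data == 2) * vv)
  expect_equal(ov$fraction, ov$overlap_mm3 / ov$label_mm3)
  # disjoint and superset limits
  none <- array(FALSE, dim = d)
  expect_equal(vat_overlap(none, regions, "main")$overlap_mm3, 0)
  all_on <- array(TRUE, dim = d)
  expect_equal(vat_overlap(all_on, regions, "motor")$fraction, 1)
  # grid mismatch refused
  small <- label_volume(array(0L, dim = c(5, 5, 5)), diag(4))
  expect_error(vat_overlap(vat, small, "main"), "mismatch|unknown")
})

test_that("full VAT pipeline yields a plausible activation around the lead", {
  atlas <- generate_atlas(c(80L, 92L, 80L), 1, small_geometry())
  cg <- label_centroid(atlas, "STN_motor_right")
  dirv <- c(0.15, 0.35, 0.92); dirv <- dirv / sqrt(sum(dirv^2))
  el <- electrode_model(cg - 2.25 * dirv, dirv, default_lead(), "right")
  res <- compute_vat(el, contact = 0, amplitude = 2.5, atlas = atlas,
                     overlap_labels = c("STN_main_right", "STN_motor_right"),
                     extent_mm = 24, spacing = 1)
  expect_gt(res$vat_volume_mm3, 20)
  expect_lt(res$vat_volume_mm3, 500)
  expect_true(all(res$overlap$fraction >= 0 & res$overlap$fraction <= 1))
  expect_gt(res$overlap$overlap_mm3[2], 0) # activates the motor region
  expect_lte(max(res$overlap$overlap_mm3), res$vat_volume_mm3)
})

test_that("halving the grid spacing barely moves the activation radius", {
  coarse <- shell_problem(spacing = 1, nh = 16L, R = 14, r0 = 1.5,
                          amplitude = 3)
  fine <- shell_problem(spacing = 0.5, nh = 32L, R = 14, r0 = 1.5,
                        amplitude = 3)
  radius_of <- function(pb) {
    sol <- solve_potential(pb$domain, pb$active, amplitude = 3)
    vat <- binarise_vat(field_magnitude(sol$voltage, pb$spacing), 0.2,
                        pb$tissue)
    max(pb$r[vat])
  }
  r1 <- radius_of(coarse); r2 <- radius_of(fine)
  expect_lt(abs(r1 - r2) / r2, 0.05)
})
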