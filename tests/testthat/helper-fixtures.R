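# Shared fixtures: everything is generated in code at test time.

# Compact nucleus geometry + grid so cohort-level tests stay fast; the
# anatomy is a scaled-down version of the default generator conditions.
small_geometry <- function() {
  list(GPi = list(centre = c(20, -2, -4), semi_axes = c(7.3, 5.5, 2.8)),
       STN = list(centre = c(11, -13, -7), semi_axes = c(5.3, 4.0, 1.8)),
       brain_semi_axes = c(34, 40, 34))
}

small_config <- function(...) {
  cohort_config(nucleus_geometry = small_geometry(),
                grid_shape = c(80L, 92L, 80L), voxel_size = 1, ...)
}

# Voxelised sphere of given radius (mm) centred at the world origin.
sphere_volume <- function(radius, voxel = 1, pad = 4) {
  half <- ceiling(radius / voxel) + pad
  n <- 2L * half + 1L
  aff <- diag(c(voxel, voxel, voxel, 1))
  aff[1:3, 4] <- -voxel * half
  ax <- seq(-voxel * half, voxel * half, by = voxel)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  label_volume(array(as.integer(r2 <= radius^2), dim = c(n, n, n)), aff,
               labels = list(sphere = 1L))
}

# Random 3-D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid <- function(trans_scale = 5) {
  m <- diag(4)
  m[1:3, 1:3] <- random_rotation()
  m[1:3, 4] <- rnorm(3, 0, trans_scale)
  affine_transform(m)
}

# Brute-force boundary distance: min over contacts of distance to surface
# voxel centres (surface = labelled voxel with an unlabelled 6-neighbour),
# 0 if a contact centre lies inside a labelled voxel.
brute_boundary_distance <- function(electrode, region, label) {
  contacts <- contact_centers(electrode)
  mask <- label_mask(region, label)
  d <- dim(mask)
  vox <- round(world_to_voxel(region, contacts))
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    if (all(v >= 1) && all(v <= d) && mask[v[1], v[2], v[3]]) return(0)
  }
  idx <- which(mask, arr.ind = TRUE)
  surface <- apply(idx, 1, function(v) {
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + s
      if (any(w < 1) || any(w > d) || !mask[w[1], w[2], w[3]]) return(TRUE)
    }
    FALSE
  })
  sv <- voxel_to_world(region, idx[surface, , drop = FALSE])
  min(apply(contacts, 1, function(p)
    sqrt(min(rowSums(sweep(sv, 2, p)^2)))))
}

default_lead <- function() load_lead_library()[["3389"]]
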