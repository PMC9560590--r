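#' Four-compartment conductivity model
#'
#' Conductivities (S/m) for the grey matter, white matter, conducting
#' contact and insulating shaft compartments of the stimulation field
#' model.  The defaults are conventional isotropic values: 0.33 (grey),
#' 0.14 (white), a near-perfect conductor for the metal contact and a
#' near-perfect insulator for the lead body.
#'
#' @param grey,white,contact_metal,insulation conductivities in S/m; all
#'   must be positive and ordered `contact_metal >> grey > white >>
#'   insulation`.
#' @return object of class `conductivity_model`.
#' @export
conductivity_model <- function(grey = 0.33, white = 0.14,
                               contact_metal = 1e8, insulation = 1e-6) {
  v <- c(grey = grey, white = white, contact_metal = contact_metal,
         insulation = insulation)
  if (any(v <= 0)) stop("all conductivities must be > 0")
  if (!(contact_metal > grey && grey > white && white > insulation))
    stop("require contact_metal > grey > white > insulation")
  structure(as.list(v), class = "conductivity_model")
}

# Compartment codes used on VAT solver grids.
VAT_GROUND <- 0L; VAT_GREY <- 1L; VAT_WHITE <- 2L
VAT_METAL <- 3L; VAT_INSULATION <- 4L

#' Build the solver domain around an active contact
#'
#' Constructs a cubic regular grid centred on the active contact, fills it
#' with white matter, overlays grey matter wherever an atlas nucleus label
#' falls, and voxelises the lead as an insulating cylinder with metal
#' contact bands.
#'
#' @param electrode an [electrode_model].
#' @param contact 0-based index of the active contact.
#' @param atlas optional atlas [label_volume]; voxels whose nearest atlas
#'   voxel carries a nucleus code (> 1) become grey matter.
#' @param extent_mm cube edge length, mm (the boundary must be at least
#'   10 mm from the contact, so `extent_mm >= 20`).
#' @param spacing grid spacing, mm.
#' @param lead_radius lead body radius, mm.
#' @return list with `domain` (a [label_volume] of compartment codes),
#'   `active` (logical array of active-contact voxels) and `centre`
#'   (world position of the active contact).
#' @export
build_vat_domain <- function(electrode, contact = 0L, atlas = NULL,
                             extent_mm = 40, spacing = 0.5,
                             lead_radius = 0.635) {
  if (extent_mm / 2 < 10)
    stop("domain boundary must be at least 10 mm from the contact")
  sp <- electrode$spec
  if (contact < 0 || contact >= sp$n_contacts)
    stop("contact index out of range")
  centres <- contact_centers(electrode)
  centre <- centres[contact + 1L, ]

  half <- round(extent_mm / 2 / spacing)
  n <- 2L * half + 1L
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- centre - spacing * half
  ax <- aff[1, 4] + spacing * (seq_len(n) - 1)
  ay <- aff[2, 4] + spacing * (seq_len(n) - 1)
  az <- aff[3, 4] + spacing * (seq_len(n) - 1)

  data <- array(VAT_WHITE, dim = c(n, n, n))
  if (!is.null(atlas)) {
    pts <- cbind(rep(ax, times = n * n),
                 rep(rep(ay, each = n), times = n),
                 rep(az, each = n * n))
    vox <- round(world_to_voxel(atlas, pts))
    d <- dim(atlas$data)
    ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
      vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
    codes <- integer(nrow(vox))
    codes[ok] <- atlas$data[cbind(vox[ok, 1], vox[ok, 2], vox[ok, 3])]
    data[array(codes > 1L, dim = dim(data))] <- VAT_GREY
  }

  # lead geometry in cylindrical coordinates about the lead axis
  relx <- ax - electrode$tip[1]
  rely <- ay - electrode$tip[2]
  relz <- az - electrode$tip[3]
  dir <- electrode$direction
  tpar <- outer(outer(relx * dir[1], rely * dir[2], `+`), relz * dir[3], `+`)
  r2 <- outer(outer(relx^2, rely^2, `+`), relz^2, `+`) - tpar^2
  shaft <- (r2 <= lead_radius^2) & (tpar >= 0)
  data[shaft] <- VAT_INSULATION
  for (k in seq_len(sp$n_contacts) - 1L) {
    tk <- sp$tip_to_first_contact_centre + k * sp$contact_pitch
    band <- shaft & (abs(tpar - tk) <= sp$contact_length / 2)
    data[band] <- VAT_METAL
  }
  t_active <- sp$tip_to_first_contact_centre + contact * sp$contact_pitch
  active <- shaft & (abs(tpar - t_active) <= sp$contact_length / 2)
  if (!any(active))
    stop("active contact voxelises to an empty set; refine 'spacing'")
  domain <- label_volume(data, aff,
                         labels = list(grey = VAT_GREY, white = VAT_WHITE,
                                       metal = VAT_METAL,
                                       insulation = VAT_INSULATION,
                                       tissue = c(VAT_GREY, VAT_WHITE)))
  list(domain = domain, active = active, centre = centre)
}

#' Solve the stimulation potential
#'
#' Solves the conduction problem `div(sigma grad V) = 0` on the regular
#' domain grid by finite differences with successive over-relaxation:
#' Dirichlet `V = amplitude` on the active contact voxels and `V = 0` on
#' the domain boundary (the grid faces and any compartment-0 voxels).
#'
#' @param domain compartment [label_volume] from [build_vat_domain] (codes
#'   0 = grounded exterior, 1 grey, 2 white, 3 metal, 4 insulation).
#' @param active logical array of active-contact voxels at `amplitude`.
#' @param conductivity a [conductivity_model].
#' @param amplitude stimulation amplitude, V.
#' @param tol convergence tolerance: maximum voxel-equation imbalance
#'   (normalised by the diagonal) below `tol * amplitude`.
#' @param max_iter iteration cap.
#' @param omega SOR relaxation factor; default near-optimal for the grid.
#' @return list with `voltage` (3-D array, V), `affine`, `spacing`,
#'   `iterations`, `residual`.
#' @export
solve_potential <- function(domain, active, conductivity = conductivity_model(),
                            amplitude = 3, tol = 1e-6, max_iter = 50000L,
                            omega = NULL) {
  dims <- dim(domain$data)
  if (!any(active)) stop("active contact voxel set is empty")
  idx <- which(active, arr.ind = TRUE)
  if (any(idx == 1L) || any(sweep(idx, 2, dims) == 0L))
    stop("active contact touches the domain boundary")
  sig_lut <- c(conductivity$grey, conductivity$grey, conductivity$white,
               conductivity$contact_metal, conductivity$insulation)
  # codes 0..4 index the lut (code 0, grounded exterior, value unused)
  sigma <- array(sig_lut[domain$data + 1L], dim = dims)
  fixed <- array(0L, dim = dims)
  fixed[1, , ] <- 1L; fixed[dims[1], , ] <- 1L
  fixed[, 1, ] <- 1L; fixed[, dims[2], ] <- 1L
  fixed[, , 1] <- 1L; fixed[, , dims[3]] <- 1L
  fixed[domain$data == VAT_GROUND] <- 1L
  vinit <- array(0, dim = dims)
  vinit[active] <- amplitude
  fixed[active] <- 1L
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(dims)))
  sol <- .sor_solve(as.numeric(sigma), as.integer(fixed),
                    as.numeric(vinit), as.integer(dims),
                    voxel_size(domain), amplitude, tol,
                    as.integer(max_iter), omega)
  if (!sol$converged)
    stop("potential solve did not converge within ", max_iter,
         " iterations (residual ", format(sol$residual), " V)")
  list(voltage = sol$V, affine = domain$affine,
       spacing = voxel_size(domain), iterations = sol$iterations,
       residual = sol$residual)
}

#' Electric-field magnitude of a potential grid
#'
#' Gradient by central differences in the interior and one-sided
#' differences at the edges; the magnitude is the Euclidean norm of the
#' three components, in V/mm.
#'
#' @param voltage 3-D array of potentials (V).
#' @param voxel_size grid spacing, mm (scalar or length 3).
#' @return 3-D array of field magnitudes (V/mm).
#' @export
field_magnitude <- function(voltage, voxel_size = 1) {
  h <- rep(voxel_size, length.out = 3)
  d <- dim(voltage)
  grad_axis <- function(v, axis) {
    n <- d[axis]
    idx <- function(i) {
      args <- list(quote(v), TRUE, TRUE, TRUE)
      args[[axis + 1]] <- i
      do.call(`[`, c(args, drop = FALSE))
    }
    g <- (idx(c(2:n, n)) - idx(c(1, 1:(n - 1))))
    den <- rep(2, n); den[1] <- 1; den[n] <- 1
    shape <- c(1, 1, 1); shape[axis] <- n
    g / array(rep(den, each = prod(d[seq_len(axis - 1)])), dim = d) /
      h[axis]
  }
  gx <- grad_axis(voltage, 1)
  gy <- grad_axis(voltage, 2)
  gz <- grad_axis(voltage, 3)
  sqrt(gx^2 + gy^2 + gz^2)
}

#' Binarise the field into a VAT mask
#'
#' Voxels whose field magnitude reaches the activation threshold,
#' restricted to tissue (electrode compartments excluded).
#'
#' @param field 3-D field-magnitude array (V/mm).
#' @param threshold activation threshold (V/mm), default 0.2.
#' @param tissue logical array of tissue voxels (same grid).
#' @return logical VAT mask.
#' @export
binarise_vat <- function(field, threshold = 0.2, tissue = NULL) {
  if (threshold <= 0) stop("'threshold' must be > 0")
  mask <- field >= threshold
  if (!is.null(tissue)) mask <- mask & tissue
  mask
}

#' Nearest-neighbour resample of a labelled volume onto another grid
#'
#' @param vol source [label_volume].
#' @param affine,dims target grid affine and dimensions.
#' @return a [label_volume] on the target grid with `vol`'s label table.
#' @export
resample_labels <- function(vol, affine, dims) {
  target <- label_volume(array(0L, dim = dims), affine)
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  pts <- voxel_to_world(target, ijk)
  vox <- round(world_to_voxel(vol, pts))
  d <- dim(vol$data)
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
    vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
  codes <- integer(nrow(vox))
  codes[ok] <- vol$data[vox[ok, , drop = FALSE]]
  label_volume(array(codes, dim = dims), affine, labels = vol$labels)
}

#' Overlap of a VAT mask with labelled regions
#'
#' Shared voxel count times voxel volume, and the fraction of each label
#' covered.
#'
#' @param vat VAT mask as a [label_volume] (non-zero = activated) or
#'   logical array on the same grid as `regions`.
#' @param regions labelled [label_volume] on the same grid.
#' @param labels vector of region names or codes to report.
#' @return data.frame with columns label, overlap_mm3, label_mm3,
#'   fraction.
#' @export
vat_overlap <- function(vat, regions, labels) {
  if (is_label_volume(vat)) {
    assert_same_grid(vat, regions)
    vmask <- vat$data != 0
  } else {
    if (!identical(dim(vat), dim(regions$data)))
      stop("grid mismatch between VAT mask and regions")
    vmask <- vat
  }
  vv <- voxel_volume_mm3(regions)
  rows <- lapply(labels, function(lab) {
    m <- label_mask(regions, lab)
    ov <- sum(vmask & m) * vv
    lm <- sum(m) * vv
    data.frame(label = as.character(lab), overlap_mm3 = ov,
               label_mm3 = lm,
               fraction = if (lm > 0) ov / lm else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full VAT computation for one electrode
#'
#' Builds the domain, solves the potential, binarises the field at the
#' activation threshold and (optionally) computes nucleus overlap.
#'
#' @inheritParams build_vat_domain
#' @inheritParams solve_potential
#' @param threshold activation threshold, V/mm.
#' @param overlap_labels label names evaluated against `atlas` (resampled
#'   onto the solver grid); skipped when `NULL` or `atlas` is `NULL`.
#' @return object of class `vat_result`: list with `voltage`, `field`,
#'   `mask` (a [label_volume]), `vat_volume_mm3`, `overlap`, `threshold`,
#'   `solver` diagnostics.
#' @export
compute_vat <- function(electrode, contact = 0L, amplitude = 3,
                        conductivity = conductivity_model(), atlas = NULL,
                        overlap_labels = NULL, threshold = 0.2,
                        extent_mm = 40, spacing = 0.5,
                        lead_radius = 0.635, tol = 1e-6,
                        max_iter = 50000L) {
  dom <- build_vat_domain(electrode, contact, atlas, extent_mm, spacing,
                          lead_radius)
  sol <- solve_potential(dom$domain, dom$active, conductivity, amplitude,
                         tol, max_iter)
  field <- field_magnitude(sol$voltage, voxel_size(dom$domain))
  tissue <- label_mask(dom$domain, "tissue")
  mask <- binarise_vat(field, threshold, tissue)
  vv <- voxel_volume_mm3(dom$domain)
  overlap <- NULL
  if (!is.null(atlas) && !is.null(overlap_labels)) {
    regions <- resample_labels(atlas, dom$domain$affine,
                               dim(dom$domain$data))
    overlap <- vat_overlap(mask, regions, overlap_labels)
  }
  structure(list(voltage = sol$voltage, field = field,
                 mask = label_volume(mask, dom$domain$affine),
                 vat_volume_mm3 = sum(mask) * vv, overlap = overlap,
                 threshold = threshold,
                 solver = list(iterations = sol$iterations,
                               residual = sol$residual,
                               spacing = spacing, extent_mm = extent_mm)),
            class = "vat_result")
}
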