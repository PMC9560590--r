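#' Affine transform acting on world coordinates
#'
#' Wraps a 4x4 homogeneous matrix (mm translation units) such as the
#' subcortical-refine (SCRF) registration used to compensate intraoperative
#' brain shift.  The last row must be `(0,0,0,1)` and the matrix must be
#' invertible.
#'
#' @param m 4x4 numeric matrix.
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("last row of affine must be (0, 0, 0, 1)")
  if (abs(det(m)) < 1e-12) stop("affine matrix is singular")
  structure(m, class = c("affine_transform", "matrix"))
}

#' Read / write a 4x4 affine as whitespace-separated text
#'
#' @param path file path.
#' @return [affine_transform] for `read_affine`; `path` invisibly for
#'   `write_affine`.
#' @export
read_affine <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  dimnames(m) <- NULL
  affine_transform(m)
}

#' @rdname read_affine
#' @param m an [affine_transform] or 4x4 matrix.
#' @export
write_affine <- function(m, path) {
  write.table(format(unclass(as.matrix(m)), digits = 17, scientific = FALSE),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a rigid/affine refinement to an electrode
#'
#' Maps the tip through the transform and renormalises the direction from
#' the mapped lead axis; contact centres of the returned electrode are
#' regenerated from the transformed tip and direction.
#'
#' @param electrode an [electrode_model].
#' @param scrf an [affine_transform] (or 4x4 matrix).
#' @return a transformed [electrode_model].
#' @export
apply_scrf <- function(electrode, scrf) {
  m <- unclass(as.matrix(scrf))
  if (!all(dim(m) == c(4L, 4L))) stop("SCRF must be a 4x4 matrix")
  if (abs(det(m)) < 1e-12) stop("SCRF matrix is singular")
  tip <- as.numeric(m %*% c(electrode$tip, 1))[1:3]
  dir <- as.numeric(m[1:3, 1:3] %*% electrode$direction)
  electrode_model(tip, dir, electrode$spec, electrode$hemisphere)
}

# Distance field (mm) to the nearest labelled voxel centre, computed on a
# crop that covers the label and the query points, then sampled with
# trilinear interpolation.  The grid axes must be orthogonal (rigid motion
# plus per-axis scaling); the EDT is separable only in that case.
distance_to_label <- function(region, label, points) {
  mask <- label_mask(region, label)
  if (!any(mask))
    stop("region '", paste(label, collapse = ","), "' has no voxels")
  lin <- region$affine[1:3, 1:3]
  gram <- crossprod(lin)
  if (max(abs(gram[upper.tri(gram)])) > 1e-6 * max(diag(gram)))
    stop("volume axes are not orthogonal; distance transform unsupported")
  vs <- voxel_size(region)

  pts_vox <- world_to_voxel(region, points)
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmin(apply(idx, 2, min), floor(apply(pts_vox, 2, min))) - 2L
  hi <- pmax(apply(idx, 2, max), ceiling(apply(pts_vox, 2, max))) + 2L
  cdim <- as.integer(hi - lo + 1L)

  crop <- array(FALSE, dim = cdim)
  src_lo <- pmax(lo, 1L)
  src_hi <- pmin(hi, dim(mask))
  crop[(src_lo[1] - lo[1] + 1L):(src_hi[1] - lo[1] + 1L),
       (src_lo[2] - lo[2] + 1L):(src_hi[2] - lo[2] + 1L),
       (src_lo[3] - lo[3] + 1L):(src_hi[3] - lo[3] + 1L)] <-
    mask[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]

  dmap <- .edt3d(as.logical(crop), cdim, vs)
  pts_crop <- sweep(pts_vox, 2, as.numeric(lo) - 1)
  trilinear_sample(dmap, pts_crop)
}

# Trilinear interpolation of a 3-D field at fractional 1-based indices.
trilinear_sample <- function(field, pts) {
  d <- dim(field)
  out <- numeric(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    p <- pmin(pmax(pts[r, ], 1), d - 1e-9)
    i0 <- pmin(floor(p), d - 1)
    fr <- p - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fr[1] else 1 - fr[1]) *
           (if (dy) fr[2] else 1 - fr[2]) *
           (if (dz) fr[3] else 1 - fr[3])
      if (w > 0)
        acc <- acc + w * field[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    out[r] <- acc
  }
  out
}

#' Boundary-distance accuracy of an electrode
#'
#' The accuracy metric: the shortest Euclidean distance between any
#' electrode contact centre and the surface of the target region.  A
#' contact whose centre falls inside a labelled voxel gives distance 0
#' (electrodes on target are exactly on target; signed penetration depth is
#' available via `signed = TRUE` as a diagnostic, where negative values are
#' the depth of the deepest-inside contact below the region surface).
#'
#' @param electrode an [electrode_model].
#' @param region a [label_volume].
#' @param label region name or integer code(s).
#' @param signed if `TRUE`, return minus the depth inside the region when a
#'   contact is inside, instead of clamping to 0.
#' @return distance in mm (>= 0 unless `signed`).
#' @export
boundary_distance <- function(electrode, region, label, signed = FALSE) {
  contacts <- contact_centers(electrode)
  mask <- label_mask(region, label)
  if (!any(mask))
    stop("region '", paste(label, collapse = ","), "' has no voxels")
  vox <- round(world_to_voxel(region, contacts))
  d <- dim(mask)
  inside <- logical(nrow(vox))
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    inside[r] <- all(v >= 1) && all(v <= d) && mask[v[1], v[2], v[3]]
  }
  if (any(inside) && !signed) return(0)
  if (!any(inside))
    return(min(distance_to_label(region, label, contacts)))
  # signed: depth of the deepest contact = distance to the complement
  comp <- label_volume(!mask, region$affine)
  -max(distance_to_label(comp, 1L, contacts[inside, , drop = FALSE]))
}

#' Centroid offset of an electrode from its target
#'
#' The displacement of the electrode from the centre of gravity of the
#' target region, used for target plots and per-axis variance analysis.
#' The reference contact is the contact nearest the centroid, paralleling
#' the "any contact" convention of the boundary-distance metric.
#'
#' @inheritParams boundary_distance
#' @return list with `offset` (dx, dy, dz in mm), `norm` (Euclidean, mm),
#'   `contact` (0-based index of the reference contact) and `centroid`.
#' @export
centroid_offset <- function(electrode, region, label) {
  cg <- label_centroid(region, label)
  contacts <- contact_centers(electrode)
  d2 <- rowSums(sweep(contacts, 2, cg)^2)
  i <- which.min(d2)
  off <- contacts[i, ] - cg
  list(offset = unname(off), norm = sqrt(sum(off^2)),
       contact = i - 1L, centroid = unname(cg))
}

#' Flag high outliers by the one-sided Tukey rule
#'
#' Values above `Q3 + 1.5 * IQR` are flagged.  Only the high side is used
#' because the inputs are non-negative distances.
#'
#' @param distances numeric vector (>= 4 values).
#' @return logical vector of flags.
#' @export
flag_outliers <- function(distances) {
  if (length(distances) < 4L)
    stop("need at least 4 values to flag outliers, got ", length(distances))
  q <- quantile(distances, c(0.25, 0.75), names = FALSE)
  distances > q[2] + 1.5 * (q[2] - q[1])
}

#' Stratified accuracy summary
#'
#' One row per stratum with n, mean, SD, the mean +/- 2 SD band, the
#' outlier count, and the count of electrodes within a clinical threshold
#' of the target (default 2 mm) by the boundary-distance metric.
#'
#' @param results accuracy table (one row per electrode x reference x
#'   SCRF state) with at least `boundary_distance` and `outlier` columns.
#' @param strata character vector of grouping column names.
#' @param threshold "within target" distance threshold in mm.
#' @return data.frame, one row per stratum.
#' @export
summarise_accuracy <- function(results, strata, threshold = 2) {
  if (nrow(results) == 0L) stop("'results' is empty")
  missing_keys <- setdiff(strata, names(results))
  if (length(missing_keys))
    stop("unknown grouping key(s): ", paste(missing_keys, collapse = ", "))
  key <- interaction(results[strata], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(results)), key), function(ii) {
    d <- results$boundary_distance[ii]
    s <- if (length(d) > 1) sd(d) else NA_real_
    cbind(results[ii[1], strata, drop = FALSE],
          data.frame(n = length(d), mean = mean(d), sd = s,
                     lower_2sd = mean(d) - 2 * s,
                     upper_2sd = mean(d) + 2 * s,
                     n_outliers = sum(results$outlier[ii]),
                     n_within = sum(d <= threshold),
                     threshold_mm = threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Target-plot table of centroid offsets
#'
#' Per-electrode X/Y/Z offsets from the target centre of gravity, grouped
#' by nucleus, hemisphere and reference region, with the SCRF-applied and
#' SCRF-removed ("nSCRF") variants side by side when requested.  Z is kept
#' in the table even though target plots conventionally show X/Y.
#'
#' @param results accuracy table with `dx`, `dy`, `dz`, `scrf_applied`
#'   columns (see [accuracy_table]).
#' @param reference `"main"`, `"motor"` or `"both"`.
#' @param with_and_without_scrf if `TRUE` (default) both SCRF variants are
#'   emitted; otherwise only rows with SCRF applied.
#' @return data.frame with columns id, nucleus, hemisphere, reference,
#'   variant (`"SCRF"`/`"nSCRF"`), x, y, z.
#' @export
target_plot_table <- function(results, reference = "both",
                              with_and_without_scrf = TRUE) {
  keep <- if (identical(reference, "both")) rep(TRUE, nrow(results))
          else results$reference == reference
  if (!with_and_without_scrf) keep <- keep & results$scrf_applied
  r <- results[keep, , drop = FALSE]
  out <- data.frame(id = r$id, nucleus = r$nucleus,
                    hemisphere = r$hemisphere, reference = r$reference,
                    variant = ifelse(r$scrf_applied, "SCRF", "nSCRF"),
                    x = r$dx, y = r$dy, z = r$dz)
  rownames(out) <- NULL
  out[order(out$nucleus, out$reference, out$hemisphere,
            out$variant, out$id), , drop = FALSE]
}

#' Atlas label name for a nucleus/reference/hemisphere combination
#'
#' @param nucleus `"GPi"` or `"STN"`.
#' @param reference `"main"` or `"motor"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return label name string as used by [generate_atlas].
#' @export
target_label <- function(nucleus, reference, hemisphere) {
  paste(nucleus, reference, hemisphere, sep = "_")
}

#' Per-electrode accuracy table for a cohort
#'
#' Runs the boundary-distance and centroid-offset metrics for every
#' electrode of every subject, against main-nucleus and motor-subnucleus
#' references, with and without the SCRF brain-shift refinement, and flags
#' outliers (Tukey, per reference x SCRF group).
#'
#' @param subjects list of subject records (see [generate_cohort]).
#' @param atlas atlas [label_volume] with the naming of [target_label].
#' @param references character subset of `c("main", "motor")`.
#' @param scrf_states logical vector; `TRUE` rows apply each subject's
#'   per-hemisphere SCRF transform to the electrode before measuring.
#' @return tidy data.frame, one row per electrode x reference x SCRF
#'   state, with columns id, hemisphere, implantation_order, nucleus,
#'   reference, scrf_applied, boundary_distance, dx, dy, dz, offset_norm,
#'   outlier.
#' @export
accuracy_table <- function(subjects, atlas,
                           references = c("main", "motor"),
                           scrf_states = c(TRUE, FALSE)) {
  rows <- list()
  for (subj in subjects) {
    for (hemi in c("left", "right")) {
      el0 <- subj$electrodes[[hemi]]
      for (scrf_on in scrf_states) {
        el <- if (scrf_on) apply_scrf(el0, subj$scrf[[hemi]]) else el0
        for (ref in references) {
          lab <- target_label(subj$target, ref, hemi)
          bd <- boundary_distance(el, atlas, lab)
          co <- centroid_offset(el, atlas, lab)
          rows[[length(rows) + 1L]] <- data.frame(
            id = subj$id, hemisphere = hemi,
            implantation_order = el0$implantation_order,
            nucleus = subj$target, reference = ref,
            scrf_applied = scrf_on,
            boundary_distance = bd,
            dx = co$offset[1], dy = co$offset[2], dz = co$offset[3],
            offset_norm = co$norm)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$outlier <- FALSE
  for (ref in unique(out$reference)) for (s in unique(out$scrf_applied)) {
    ii <- which(out$reference == ref & out$scrf_applied == s)
    if (length(ii) >= 4L)
      out$outlier[ii] <- flag_outliers(out$boundary_distance[ii])
  }
  rownames(out) <- NULL
  out
}
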