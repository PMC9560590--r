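#' Pneumocephalus volume from expected vs actual brain masks
#'
#' Intracranial air is quantified as the volume by which the actual
#' (post-operative) extracted brain mask falls short of the expected
#' (template) brain volume: `(template voxels - actual voxels) * voxel
#' volume`, in mL.  A negative difference (actual larger than expected,
#' possible with real segmentations) is clamped to 0 with a warning.
#'
#' @param template_brain expected brain mask ([label_volume]).
#' @param actual_brain actual extracted brain mask on the same grid.
#' @return air volume in mL.
#' @export
pneumocephalus_volume <- function(template_brain, actual_brain) {
  assert_same_grid(template_brain, actual_brain)
  n_t <- sum(template_brain$data != 0)
  n_a <- sum(actual_brain$data != 0)
  ml <- (n_t - n_a) * voxel_volume_mm3(template_brain) / 1000
  if (ml < 0) {
    warning("actual brain volume exceeds template by ", round(-ml, 2),
            " mL; clamping pneumocephalus to 0")
    ml <- 0
  }
  ml
}

#' Brain-shift magnitude of an SCRF transform
#'
#' The summed elementwise absolute deviation of the transform from the
#' identity over the 12 active elements (the 3x3 linear block plus the
#' translation column).  Zero exactly at the identity and strictly
#' increasing along any translation ray.  Note the sum mixes unitless
#' rotational terms with millimetre translations, exactly as a raw
#' matrix sum would; it is a brain-shift proxy, not a distance.
#'
#' @param scrf an [affine_transform] or 4x4 matrix.
#' @return scalar magnitude >= 0.
#' @export
shift_magnitude <- function(scrf) {
  m <- unclass(as.matrix(scrf))
  if (!all(dim(m) == c(4L, 4L))) stop("SCRF must be a 4x4 matrix")
  sum(abs(m[1:3, 1:4] - diag(4)[1:3, 1:4]))
}

#' Build per-subject shift records
#'
#' One row per subject: mean boundary-distance accuracy across
#' hemispheres, brain-shift magnitude (mean of the two hemisphere SCRF
#' magnitudes), and pneumocephalus volume.
#'
#' @param accuracy accuracy table (see [accuracy_table]); rows with
#'   `reference == "main"` and SCRF applied are used.
#' @param subjects list of subject records.
#' @param pneumocephalus named numeric vector of air volumes (mL) keyed
#'   by subject id.
#' @return data.frame with columns id, accuracy, shift, pneumocephalus.
#' @export
shift_records <- function(accuracy, subjects, pneumocephalus) {
  acc <- accuracy[accuracy$reference == "main" & accuracy$scrf_applied, ]
  rows <- lapply(subjects, function(s) {
    a <- acc$boundary_distance[acc$id == s$id]
    data.frame(id = s$id,
               accuracy = if (length(a)) mean(a) else NA_real_,
               shift = mean(c(shift_magnitude(s$scrf$left),
                              shift_magnitude(s$scrf$right))),
               pneumocephalus = unname(pneumocephalus[s$id]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy / brain-shift / pneumocephalus correlations
#'
#' The three pairwise Pearson correlations among per-subject mean
#' accuracy, brain-shift magnitude and pneumocephalus volume, corrected
#' for multiple comparisons across the three tests.
#'
#' @param records data.frame from [shift_records] (columns `accuracy`,
#'   `shift`, `pneumocephalus`); incomplete rows are dropped pairwise
#'   with a message.
#' @param family family size for the correction (default 3, the three
#'   tests of this analysis).
#' @return data.frame of [pearson] results, one row per pair.
#' @export
shift_accuracy_correlations <- function(records, family = 3) {
  pairs <- list(c("accuracy", "shift"),
                c("accuracy", "pneumocephalus"),
                c("shift", "pneumocephalus"))
  rows <- lapply(pairs, function(p) {
    x <- records[[p[1]]]; y <- records[[p[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(!ok) > 0)
      message("dropping ", sum(!ok), " incomplete record(s) for ",
              p[1], " vs ", p[2])
    if (sum(ok) < 4)
      stop("need at least 4 complete records for ", p[1], " vs ", p[2])
    res <- pearson(x[ok], y[ok])
    data.frame(pair = paste(p, collapse = "_vs_"), r = res$estimate,
               r_squared = res$estimate^2, df = res$df, p = res$p,
               n = res$n)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- bonferroni(out$p, family)
  out$family <- family
  rownames(out) <- NULL
  out
}
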