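#' Restore a tomogram by tiled prediction
#'
#' Splits the tomogram into overlapping cubic patches, predicts each with
#' the trained network, and recombines by central-crop stitching: each tile
#' contributes only its central region (margin = `overlap/2` discarded,
#' except at the volume faces), so every output voxel is produced by
#' exactly one tile and stitching is bit-reproducible. Volumes smaller
#' than the patch on any axis are zero-padded, predicted, and cropped
#' back. Optional cosine-weighted blending is available behind
#' `blend = TRUE` for users who prefer averaged seams.
#'
#' @param model a `trained_restorer`.
#' @param tomogram a [density_volume()] (any box shape).
#' @param patch cubic tile edge (divisible by `pool_factor^depth`); default
#'   the model's training patch.
#' @param overlap_vox overlap between neighboring tiles (even, < patch).
#' @param normalize z-score the tomogram first (the training convention);
#'   set `FALSE` only if it is already normalized.
#' @param blend use cosine-window averaging instead of central-crop
#'   stitching.
#' @return the restored [density_volume()] (same shape as the input).
#' @export
restore_volume <- function(model, tomogram, patch = model$config$patch_vox,
                           overlap_vox = max(4L, patch %/% 4L),
                           normalize = TRUE, blend = FALSE) {
  stopifnot(inherits(model, "trained_restorer"),
            inherits(tomogram, "density_volume"))
  if (overlap_vox %% 2L != 0L) stop("`overlap_vox` must be even", call. = FALSE)
  if (overlap_vox >= patch) stop("`overlap_vox` must be < patch", call. = FALSE)
  vol <- if (normalize) normalize_volume(tomogram) else tomogram
  d <- dim(vol$values)
  pad <- pmax(0L, patch - d)
  work <- vol$values
  if (any(pad > 0L)) {
    padded <- array(0, pmax(d, patch))
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- work
    work <- padded
  }
  wd <- dim(work)
  stride <- patch - overlap_vox
  starts <- function(n) {
    if (n <= patch) return(1L)
    s <- seq(1L, n - patch, by = stride)
    if (s[length(s)] + patch - 1L < n) s <- c(s, n - patch + 1L)
    s
  }
  sx <- starts(wd[1]); sy <- starts(wd[2]); sz <- starts(wd[3])
  out <- array(0, wd)
  wsum <- if (blend) array(0, wd) else NULL
  margin <- overlap_vox %/% 2L
  win1 <- if (blend) {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(patch) - 0.5) / patch)
    w / max(w)
  } else NULL
  for (x0 in sx) for (y0 in sy) for (z0 in sz) {
    tile <- work[x0:(x0 + patch - 1L), y0:(y0 + patch - 1L),
                 z0:(z0 + patch - 1L)]
    pred <- predict_patch(model, tile)
    if (blend) {
      w3 <- outer(outer(win1, win1), win1)
      out[x0:(x0 + patch - 1L), y0:(y0 + patch - 1L), z0:(z0 + patch - 1L)] <-
        out[x0:(x0 + patch - 1L), y0:(y0 + patch - 1L), z0:(z0 + patch - 1L)] +
        pred * w3
      wsum[x0:(x0 + patch - 1L), y0:(y0 + patch - 1L), z0:(z0 + patch - 1L)] <-
        wsum[x0:(x0 + patch - 1L), y0:(y0 + patch - 1L), z0:(z0 + patch - 1L)] + w3
    } else {
      # keep the central region; extend to the volume face on border tiles
      keep_rng <- function(s0, n) {
        lo <- if (s0 == 1L) 1L else margin + 1L
        hi <- if (s0 + patch - 1L == n) patch else patch - margin
        c(lo, hi)
      }
      rx <- keep_rng(x0, wd[1]); ry <- keep_rng(y0, wd[2]); rz <- keep_rng(z0, wd[3])
      out[(x0 + rx[1] - 1L):(x0 + rx[2] - 1L),
          (y0 + ry[1] - 1L):(y0 + ry[2] - 1L),
          (z0 + rz[1] - 1L):(z0 + rz[2] - 1L)] <-
        pred[rx[1]:rx[2], ry[1]:ry[2], rz[1]:rz[2]]
    }
  }
  if (blend) out <- out / pmax(wsum, 1e-12)
  out <- out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  density_volume(array(out, d), tomogram$voxel_A, tomogram$origin)
}
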