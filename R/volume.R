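#' Cubic density volume
#'
#' The universal volume currency of the package: a 3D grid of densities with
#' a physical voxel size. Axis convention: array dimension 1 is x, 2 is y,
#' 3 is z; the electron beam runs along z and the tilt axis is y. The
#' rotation center (`origin`) is the voxel at 0-based index `floor(box/2)`
#' on each axis, stored 1-based for R indexing.
#'
#' @param values numeric 3D array (need not be cubic; cubic-only operations
#'   check for themselves).
#' @param voxel_A voxel edge length in Angstrom (> 0).
#' @param origin optional 1-based rotation-center voxel (length-3); defaults
#'   to `floor(dim/2) + 1`.
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(values, voxel_A, origin = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_A) || length(voxel_A) != 1L || voxel_A <= 0)
    stop("`voxel_A` must be a positive scalar", call. = FALSE)
  if (!all(is.finite(values)))
    stop("volume values must all be finite", call. = FALSE)
  structure(
    list(values = values, voxel_A = as.numeric(voxel_A),
         origin = if (is.null(origin)) dim(values) %/% 2L + 1L
                  else as.integer(origin)),
    class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %d x %d x %d voxels @ %.3f A/vox\n",
              d[1], d[2], d[3], x$voxel_A))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g, sd %.4g\n",
              min(x$values), max(x$values), mean(x$values),
              stats::sd(as.vector(x$values))))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$values)

is_cubic <- function(vol) {
  d <- dim(vol$values)
  d[1] == d[2] && d[2] == d[3]
}

assert_cubic <- function(vol, what = "this operation") {
  if (!is_cubic(vol))
    stop(sprintf("%s requires a cubic volume (got %s)", what,
                 paste(dim(vol$values), collapse = "x")), call. = FALSE)
  invisible(vol)
}

#' Z-score normalize a volume
#'
#' Scales a volume to zero mean and unit standard deviation, the convention
#' applied to every training pair and to tomograms before restoration. A
#' constant (zero-variance) volume maps to all zeros and is flagged via the
#' `"degenerate"` attribute, with a warning.
#'
#' @param vol a [density_volume()].
#' @return a normalized `density_volume`; attribute `degenerate` is `TRUE`
#'   when the input had zero variance.
#' @export
normalize_volume <- function(vol) {
  stopifnot(inherits(vol, "density_volume"))
  v <- as.vector(vol$values)
  s <- stats::sd(v)
  if (s == 0) {
    warning("constant volume: normalized to all zeros", call. = FALSE)
    out <- density_volume(array(0, dim(vol$values)), vol$voxel_A, vol$origin)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- density_volume((vol$values - mean(v)) / s, vol$voxel_A, vol$origin)
  attr(out, "degenerate") <- FALSE
  out
}

#' Pearson correlation between two volumes
#'
#' The package's restoration-fidelity metric: the standard Pearson
#' correlation over (optionally masked) voxels.
#'
#' @param a,b `density_volume` objects of equal dimensions.
#' @param mask optional logical array selecting the voxels to correlate
#'   (at least 2 must be selected).
#' @return a scalar in \[-1, 1\].
#' @export
pearson_cc <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "density_volume"), inherits(b, "density_volume"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("volumes have different dimensions", call. = FALSE)
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (!is.null(mask)) {
    m <- as.vector(mask)
    if (sum(m) < 2) stop("mask selects fewer than 2 voxels", call. = FALSE)
    va <- va[m]; vb <- vb[m]
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero variance volume: correlation undefined",
         call. = FALSE)
  stats::cor(va, vb)
}

#' Extract cubic subvolumes around listed centers
#'
#' Crops `box`^3 subvolumes centered (box/2 convention, matching the volume
#' origin) on each given voxel. Out-of-bounds voxels are zero-filled under
#' `pad_policy = "zero"`, or rejected with an error naming the offending
#' center under `"reject"`.
#'
#' @param tomogram a [density_volume()].
#' @param centers integer matrix (n x 3) or list of length-3 vectors of
#'   1-based voxel centers.
#' @param box even subvolume edge in voxels.
#' @param pad_policy `"zero"` or `"reject"`.
#' @return list of `density_volume` crops.
#' @export
extract_subvolumes <- function(tomogram, centers, box,
                               pad_policy = c("zero", "reject")) {
  stopifnot(inherits(tomogram, "density_volume"))
  pad_policy <- match.arg(pad_policy)
  if (box %% 2L != 0L) stop("`box` must be even", call. = FALSE)
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.integer(centers), ncol = 3)
  d <- dim(tomogram$values)
  half <- box %/% 2L
  lapply(seq_len(nrow(centers)), function(i) {
    ctr <- centers[i, ]
    lo <- ctr - half          # first voxel, 1-based
    hi <- lo + box - 1L
    if (pad_policy == "reject" && (any(lo < 1L) || any(hi > d)))
      stop(sprintf("center (%s) out of bounds for box %d",
                   paste(ctr, collapse = ", "), box), call. = FALSE)
    out <- array(0, c(box, box, box))
    slo <- pmax(lo, 1L); shi <- pmin(hi, d)
    if (all(slo <= shi)) {
      out[(slo[1] - lo[1] + 1L):(shi[1] - lo[1] + 1L),
          (slo[2] - lo[2] + 1L):(shi[2] - lo[2] + 1L),
          (slo[3] - lo[3] + 1L):(shi[3] - lo[3] + 1L)] <-
        tomogram$values[slo[1]:shi[1], slo[2]:shi[2], slo[3]:shi[3]]
    }
    density_volume(out, tomogram$voxel_A)
  })
}

# Run expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
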