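#' Elastic-network normal modes (anisotropic network model)
#'
#' Builds the ANM Hessian — pairwise harmonic springs of unit stiffness
#' between all atom pairs closer than `cutoff_A` — and returns its lowest
#' `n_modes` eigenpairs. Mode indexing is 1-based with eigenvalues in
#' ascending order, so for a non-collinear model modes 1-6 are the
#' zero-frequency rigid-body motions and deformations start at mode 7.
#'
#' @param model a [pseudo_atom_model()].
#' @param cutoff_A spring distance cutoff in Angstrom (8 suits atomistic
#'   models, 16 coarse pseudo-atom ones).
#' @param n_modes number of modes to return (<= 3N).
#' @return a `normal_mode_set`: `eigenvalues` (ascending), `eigenvectors`
#'   (3N x M, orthonormal columns, atom-major xyz interleaved), `cutoff_A`,
#'   `n_zero` (count of numerically zero modes).
#' @export
compute_enm_modes <- function(model, cutoff_A = 8, n_modes = 20) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  n <- nrow(model$atom_coords)
  if (n_modes > 3 * n) stop("`n_modes` exceeds 3N", call. = FALSE)
  dmat <- as.matrix(stats::dist(model$atom_coords))
  adj <- dmat <= cutoff_A & dmat > 0
  ncomp <- n_components(adj)
  if (ncomp > 1)
    stop(sprintf(
      "spring graph is disconnected at cutoff %.1f A (%d components); %s",
      cutoff_A, ncomp,
      "increase the cutoff or the spurious zero modes would go unnoticed"),
      call. = FALSE)
  H <- enm_hessian(model$atom_coords, adj, dmat)
  eig <- eigen(H, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))         # ascending
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  vals[abs(vals) < .Machine$double.eps^0.75 * max(abs(vals))] <-
    pmax(vals[abs(vals) < .Machine$double.eps^0.75 * max(abs(vals))], 0)
  keep <- seq_len(n_modes)
  structure(list(eigenvalues = vals[keep],
                 eigenvectors = vecs[, keep, drop = FALSE],
                 cutoff_A = cutoff_A,
                 n_zero = sum(vals < 1e-8 * max(vals)),
                 n_atoms = n),
            class = "normal_mode_set")
}

# union-find connected components of an adjacency matrix
n_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(max(0, n - 1))) for (j in which(adj[i, ] & seq_len(n) > i)) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# ANM Hessian: 3N x 3N, unit spring constant
enm_hessian <- function(coords, adj, dmat) {
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    d <- coords[j, ] - coords[i, ]
    blk <- tcrossprod(d) / sum(d^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("<normal_mode_set> %d modes of a %d-atom model (cutoff %.1f A)\n",
              length(x$eigenvalues), x$n_atoms, x$cutoff_A))
  cat(sprintf("  %d zero modes; first non-rigid eigenvalues: %s\n", x$n_zero,
              paste(signif(x$eigenvalues[x$n_zero + seq_len(
                min(3, length(x$eigenvalues) - x$n_zero))], 3),
                collapse = ", ")))
  invisible(x)
}

#' Displace a model along normal modes
#'
#' Adds `sum_k amplitude_k * eigenvector_k` (reshaped to N x 3) to the atom
#' coordinates. Amplitudes are in the elastic-network's native units (the
#' eigenvectors are unit-norm over 3N coordinates); use [mode_rmsd()] to
#' express an amplitude as a coordinate RMSD. Rigid-body modes (1-6) are
#' refused: they would translate or rotate, not deform.
#'
#' @param model a [pseudo_atom_model()].
#' @param modes a `normal_mode_set` from [compute_enm_modes()].
#' @param amplitudes named list/vector: `mode_index` (>= 7) and `amplitude`,
#'   given as a data frame with columns `mode` and `amplitude`, or a numeric
#'   vector named by mode index.
#' @return the displaced [pseudo_atom_model()] (weights unchanged).
#' @export
displace_along_modes <- function(model, modes, amplitudes) {
  stopifnot(inherits(model, "pseudo_atom_model"),
            inherits(modes, "normal_mode_set"))
  amp <- as_mode_amplitudes(amplitudes)
  if (any(amp$mode <= 6))
    stop("modes 1-6 are rigid-body modes; displacement requires mode >= 7",
         call. = FALSE)
  if (any(amp$mode > ncol(modes$eigenvectors)))
    stop("mode index exceeds the computed mode set", call. = FALSE)
  if (!all(is.finite(amp$amplitude)))
    stop("amplitudes must be finite", call. = FALSE)
  disp <- numeric(3 * nrow(model$atom_coords))
  for (r in seq_len(nrow(amp)))
    disp <- disp + amp$amplitude[r] * modes$eigenvectors[, amp$mode[r]]
  new_coords <- model$atom_coords + matrix(disp, ncol = 3, byrow = TRUE)
  pseudo_atom_model(new_coords, model$atom_weights, model$labels)
}

as_mode_amplitudes <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("mode", "amplitude") %in% names(x)))
    data.frame(mode = as.integer(x$mode), amplitude = as.numeric(x$amplitude))
  } else if (is.numeric(x) && !is.null(names(x))) {
    data.frame(mode = as.integer(names(x)), amplitude = as.numeric(x))
  } else stop("amplitudes must be a data frame (mode, amplitude) or a named vector",
              call. = FALSE)
}

#' Coordinate RMSD produced by a unit amplitude of a mode
#' @param modes a `normal_mode_set`.
#' @param mode_index 1-based mode index.
#' @param amplitude amplitude in mode units (default 1).
#' @return RMSD in coordinate units (Angstrom) over atoms.
#' @export
mode_rmsd <- function(modes, mode_index, amplitude = 1) {
  v <- matrix(modes$eigenvectors[, mode_index], ncol = 3, byrow = TRUE)
  amplitude * sqrt(mean(rowSums(v^2)))
}

#' Sample a continuum of conformations along selected modes
#'
#' Draws `n` conformations, each displacing the model by independent
#' uniform amplitudes in `amplitude_range` on every listed mode — the
#' standard recipe for emulating a continuous conformational transition
#' (e.g. modes 7 and 13 with amplitudes in \[-250, 250\] for a nucleosome
#' with flexible linkers).
#'
#' @param model a [pseudo_atom_model()].
#' @param modes a `normal_mode_set`.
#' @param n number of conformations (>= 1).
#' @param mode_indices non-empty list of deformation modes (>= 7).
#' @param amplitude_range length-2 `c(lo, hi)`, lo <= hi.
#' @param seed integer seed; the draw is reproducible.
#' @return list of `n` [pseudo_atom_model()]s, each carrying its drawn
#'   amplitudes as attribute `"amplitudes"`.
#' @export
sample_conformations <- function(model, modes, n, mode_indices = c(7, 13),
                                 amplitude_range = c(-250, 250), seed = 1) {
  if (length(mode_indices) == 0) stop("`mode_indices` is empty", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  lo <- amplitude_range[1]; hi <- amplitude_range[2]
  if (lo > hi) stop("`amplitude_range` must satisfy lo <= hi", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- stats::runif(length(mode_indices), lo, hi)
      m <- displace_along_modes(model, modes,
                                data.frame(mode = mode_indices, amplitude = a))
      attr(m, "amplitudes") <- stats::setNames(a, mode_indices)
      m
    })
  })
}
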