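#' Pseudo-atomic point model
#'
#' A point-mass model: N atoms with coordinates in Angstrom and non-negative
#' weights (mass/occupancy in arbitrary units). This is the input to the
#' elastic-network normal-mode machinery and to density rendering.
#'
#' @param atom_coords N x 3 numeric matrix of positions in Angstrom.
#' @param atom_weights length-N non-negative weights (default all 1).
#' @param labels optional per-atom character labels.
#' @return a `pseudo_atom_model`.
#' @export
pseudo_atom_model <- function(atom_coords, atom_weights = NULL, labels = NULL) {
  atom_coords <- as.matrix(atom_coords)
  if (ncol(atom_coords) != 3 || nrow(atom_coords) < 1)
    stop("`atom_coords` must be an N x 3 matrix with N >= 1", call. = FALSE)
  if (!all(is.finite(atom_coords)))
    stop("coordinates must be finite", call. = FALSE)
  if (is.null(atom_weights)) atom_weights <- rep(1, nrow(atom_coords))
  if (length(atom_weights) != nrow(atom_coords) || any(atom_weights < 0))
    stop("`atom_weights` must be N non-negative scalars", call. = FALSE)
  structure(list(atom_coords = unname(atom_coords),
                 atom_weights = as.numeric(atom_weights),
                 labels = labels),
            class = "pseudo_atom_model")
}

#' @export
print.pseudo_atom_model <- function(x, ...) {
  cat(sprintf("<pseudo_atom_model> %d atoms, extent %.1f A\n",
              nrow(x$atom_coords),
              max(dist(x$atom_coords[seq_len(min(500, nrow(x$atom_coords))), ,
                                     drop = FALSE]))))
  invisible(x)
}

#' Generate a deterministic toy pseudo-atomic model
#'
#' Built-in stand-in particles so the whole pipeline runs without any
#' external structure. `disc_with_arms` emulates a nucleosome-like particle:
#' a rigid core disc (histone-core/wrapped-DNA scale, ~100 A across) with
#' two flexible linker arms leaving the disc on opposite sides — the arms
#' dominate the softest normal modes, as linker DNA does. `helix` is an
#' elongated helical chain; `blob_cluster` a set of globular blobs.
#'
#' @param kind `"disc_with_arms"`, `"helix"` or `"blob_cluster"`.
#' @param n_atoms number of pseudo-atoms (>= 10).
#' @param seed integer seed; output is a pure function of (kind, n_atoms, seed).
#' @param disc_radius_A core disc radius (disc_with_arms), Angstrom.
#' @param arm_length_A length of each linker arm, Angstrom.
#' @return a [pseudo_atom_model()] with region labels (`"core"`/`"arm"` for
#'   disc_with_arms).
#' @export
generate_toy_model <- function(kind = c("disc_with_arms", "helix", "blob_cluster"),
                               n_atoms, seed,
                               disc_radius_A = 40, arm_length_A = 60) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop(sprintf("unknown model kind '%s'",
                                                    kind[1]), call. = FALSE))
  if (n_atoms < 10) stop("`n_atoms` must be >= 10", call. = FALSE)
  with_seed(seed, {
    if (kind == "disc_with_arms") {
      n_arm_each <- max(3L, round(n_atoms * 0.15))
      n_core <- n_atoms - 2L * n_arm_each
      # sunflower-spiral layout in two z-layers: quasi-uniform and always
      # connected at coarse-grain cutoffs, unlike purely random placement
      i <- seq_len(n_core)
      r <- disc_radius_A * sqrt((i - 0.5) / n_core)
      th <- i * pi * (3 - sqrt(5))
      core <- cbind(r * cos(th), r * sin(th),
                    ifelse(i %% 2 == 0, 5, -5)) +
        matrix(stats::rnorm(n_core * 3, sd = 1.0), ncol = 3)
      arm <- function(sign) {
        s <- seq(0, 1, length.out = n_arm_each)
        start <- c(sign * disc_radius_A, 0, 0)
        dir <- c(sign * 0.8, sign * 0.55, 0.25)
        dir <- dir / sqrt(sum(dir^2))
        sweep(outer(s * arm_length_A, dir), 2, start, `+`) +
          matrix(stats::rnorm(n_arm_each * 3, sd = 1.0), ncol = 3)
      }
      coords <- rbind(core, arm(+1), arm(-1))
      labels <- c(rep("core", n_core), rep("arm", 2L * n_arm_each))
      pseudo_atom_model(coords, labels = labels)
    } else if (kind == "helix") {
      t <- seq(0, 6 * pi, length.out = n_atoms)
      coords <- cbind(10 * cos(t), 10 * sin(t), 16 * t / (2 * pi)) +
        matrix(stats::rnorm(n_atoms * 3, sd = 0.4), ncol = 3)
      pseudo_atom_model(coords, labels = rep("helix", n_atoms))
    } else {
      n_blob <- 4L
      centers <- matrix(stats::runif(n_blob * 3, -35, 35), ncol = 3)
      idx <- sort(rep_len(seq_len(n_blob), n_atoms))
      coords <- centers[idx, ] + matrix(stats::rnorm(n_atoms * 3, sd = 8),
                                        ncol = 3)
      pseudo_atom_model(coords, labels = paste0("blob", idx))
    }
  })
}

#' Center a model on its weighted centroid
#' @param model a [pseudo_atom_model()].
#' @return the recentered model.
#' @export
center_model <- function(model) {
  w <- model$atom_weights
  ctr <- colSums(model$atom_coords * w) / sum(w)
  pseudo_atom_model(sweep(model$atom_coords, 2, ctr), w, model$labels)
}

#' Read a pseudo-atomic model from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d; occupancy is used as the atom
#' weight (1.0 where absent).
#'
#' @param path PDB file path.
#' @return a [pseudo_atom_model()].
#' @export
read_pdb_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  occ <- pdb$atom$o
  occ[is.na(occ)] <- 1.0
  pseudo_atom_model(cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z),
                    atom_weights = occ,
                    labels = pdb$atom$elety)
}

#' Render a pseudo-atomic model as a density volume
#'
#' Each atom becomes an isotropic 3D Gaussian of width set by the target
#' resolution (`sigma = resolution_A / (pi * sqrt(2))`, the common
#' pdb-to-map convention), discretely normalized so its voxel sum equals
#' the atom weight; blobs falling partly outside the box are clipped (with
#' a warning). The model is rendered about the volume origin voxel.
#'
#' @param model a [pseudo_atom_model()] (should be centered; see
#'   [center_model()]).
#' @param voxel_A voxel size in Angstrom.
#' @param box cubic box edge in voxels (>= 8).
#' @param resolution_A nominal resolution controlling the Gaussian width.
#' @param warn_clip warn when density is clipped at the box edge (the pair
#'   factory disables this: extreme-amplitude linker arms legitimately
#'   extend past a subvolume box).
#' @return a [density_volume()] whose voxel sum is the total clipped-adjusted
#'   weight.
#' @export
model_to_density <- function(model, voxel_A, box, resolution_A,
                             warn_clip = TRUE) {
  stopifnot(inherits(model, "pseudo_atom_model"))
  if (voxel_A <= 0) stop("`voxel_A` must be positive", call. = FALSE)
  if (resolution_A <= 0) stop("`resolution_A` must be positive", call. = FALSE)
  if (box < 8) stop("`box` must be >= 8", call. = FALSE)
  sigma_vox <- resolution_A / (pi * sqrt(2)) / voxel_A
  half <- as.integer(ceiling(4 * sigma_vox) + 1L)
  ctr <- box %/% 2L                        # 0-based origin voxel
  vox <- model$atom_coords / voxel_A       # atom positions, voxel units
  vals <- array(0, c(box, box, box))
  g1 <- function(off) exp(-off^2 / (2 * sigma_vox^2))
  clipped <- FALSE
  for (a in seq_len(nrow(vox))) {
    p <- vox[a, ] + ctr                    # 0-based position in grid
    i0 <- round(p)
    gx <- (i0[1] - half):(i0[1] + half)
    gy <- (i0[2] - half):(i0[2] + half)
    gz <- (i0[3] - half):(i0[3] + half)
    blob <- outer(outer(g1(gx - p[1]), g1(gy - p[2])), g1(gz - p[3]))
    blob <- blob / sum(blob) * model$atom_weights[a]
    okx <- gx >= 0 & gx < box; oky <- gy >= 0 & gy < box; okz <- gz >= 0 & gz < box
    if (!(all(okx) && all(oky) && all(okz))) clipped <- TRUE
    if (any(okx) && any(oky) && any(okz)) {
      vals[gx[okx] + 1L, gy[oky] + 1L, gz[okz] + 1L] <-
        vals[gx[okx] + 1L, gy[oky] + 1L, gz[okz] + 1L] +
        blob[okx, oky, okz]                # same shape: R drops both sides
    }
  }
  if (clipped && warn_clip)
    warning("model extends beyond the box: density clipped", call. = FALSE)
  density_volume(vals, voxel_A)
}
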