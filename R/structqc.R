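#' Read a multi-MODEL PDB file as a structure ensemble
#'
#' Thin wrapper over bio3d. Each model becomes a data.frame of atoms
#' (residue, resname, atom, x, y, z).
#'
#' @param path PDB file with one or more MODEL records.
#' @return list of class `structure_ensemble`: models (list of data.frames).
#' @export
read_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  n_models <- dim(pdb$xyz)[1]
  models <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    data.frame(residue = at$resno, resname = at$resid, atom = at$elety,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  structure(list(models = models), class = "structure_ensemble")
}

backbone_atoms <- c("N", "CA", "C", "O")

# coordinate matrix for one model restricted to residues/atoms, ordered
# identically across models
.model_coords <- function(model, residues = NULL, atoms = "backbone") {
  sel <- rep(TRUE, nrow(model))
  if (!is.null(residues)) sel <- sel & model$residue %in% residues
  if (identical(atoms, "backbone")) sel <- sel & model$atom %in% backbone_atoms
  else if (identical(atoms, "heavy")) sel <- sel & !grepl("^H", model$atom)
  else sel <- sel & model$atom %in% atoms
  m <- model[sel, , drop = FALSE]
  m <- m[order(m$residue, match(m$atom, c(backbone_atoms, sort(unique(m$atom))))), ]
  list(coords = as.matrix(m[, c("x", "y", "z")]),
       key = paste(m$residue, m$atom))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `mov` onto `ref` via SVD of the
#' covariance matrix; reflections are rejected by the determinant
#' correction so the rotation is always proper.
#'
#' @param ref,mov n x 3 coordinate matrices (same n >= 3, not collinear).
#' @return list(rotation 3x3, translation length-3, rmsd, transformed).
#' @export
kabsch <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  stopifnot(ncol(ref) == 3, ncol(mov) == 3, nrow(ref) == nrow(mov),
            nrow(ref) >= 3)
  cr <- colMeans(ref); cm <- colMeans(mov)
  a <- sweep(ref, 2, cr); b <- sweep(mov, 2, cm)
  sv_b <- svd(b)$d  # collinear sets have rank 1 (planar sets are fine)
  if (sv_b[2] < 1e-9 * max(sv_b[1], 1))
    stop("degenerate (collinear) coordinate set")
  h <- t(b) %*% a
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  moved <- sweep(mov %*% t(rot), 2, trans, "+")
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((moved - ref)^2))),
       transformed = moved)
}

#' Ensemble RMSD to the mean structure
#'
#' Iteratively superposes every model on the current mean coordinates,
#' recomputes the mean, and repeats until the average RMSD changes by less
#' than `tol` (1e-6 A). Reports the average over models of the RMSD to the
#' converged mean.
#'
#' @param ens `structure_ensemble` (>= 2 models with identical atom
#'   rosters over the selection).
#' @param residues Residue index vector (NULL for all).
#' @param atoms "backbone" (N, CA, C, O), "heavy" (non-hydrogen), or an
#'   explicit atom-name vector.
#' @param tol Convergence tolerance on the mean RMSD (A).
#' @return list(rmsd_mean, per_model, mean_coords, n_atoms).
#' @export
ensemble_rmsd <- function(ens, residues = NULL, atoms = "backbone",
                          tol = 1e-6) {
  stopifnot(inherits(ens, "structure_ensemble"), length(ens$models) >= 2L)
  sels <- lapply(ens$models, .model_coords, residues = residues, atoms = atoms)
  key <- sels[[1]]$key
  if (!all(vapply(sels, function(s) identical(s$key, key), logical(1))))
    stop("models do not share the same atom roster over the selection")
  coords <- lapply(sels, `[[`, "coords")
  mean_c <- coords[[1]]
  prev <- Inf
  for (iter in 1:200) {
    fitted <- lapply(coords, function(x) kabsch(mean_c, x)$transformed)
    mean_c <- Reduce(`+`, fitted) / length(fitted)
    rmsds <- vapply(fitted, function(x)
      sqrt(mean(rowSums((x - mean_c)^2))), numeric(1))
    cur <- mean(rmsds)
    if (abs(prev - cur) < tol) break
    prev <- cur
  }
  list(rmsd_mean = cur, per_model = rmsds, mean_coords = mean_c,
       n_atoms = nrow(mean_c))
}

# signed dihedral (degrees, in (-180, 180]) of four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Backbone phi/psi dihedrals for one residue of one model
#'
#' phi needs the preceding C', psi the following N; chain termini yield NA.
#' An optional coarse region label separates broadly helix/sheet-like
#' ("favored_like") from other combinations; it is a simplified descriptive
#' label, not a validation-grade Ramachandran classification.
#'
#' @param model One model data.frame from a `structure_ensemble`.
#' @param residue Residue index.
#' @return list(phi, psi, region).
#' @export
dihedrals <- function(model, residue) {
  get_atom <- function(res, name) {
    r <- model[model$residue == res & model$atom == name, c("x", "y", "z")]
    if (nrow(r) != 1L) return(NULL)
    as.numeric(r)
  }
  n <- get_atom(residue, "N"); ca <- get_atom(residue, "CA")
  c_ <- get_atom(residue, "C")
  c_prev <- get_atom(residue - 1L, "C"); n_next <- get_atom(residue + 1L, "N")
  phi <- if (!is.null(c_prev) && !is.null(n) && !is.null(ca) && !is.null(c_))
    .dihedral(c_prev, n, ca, c_) else NA_real_
  psi <- if (!is.null(n) && !is.null(ca) && !is.null(c_) && !is.null(n_next))
    .dihedral(n, ca, c_, n_next) else NA_real_
  region <- if (is.na(phi) || is.na(psi)) NA_character_
    else if (phi < 0 && ((psi > -80 && psi < 40) || psi > 80 || psi <= -160))
      "favored_like" else "other"
  list(phi = phi, psi = psi, region = region)
}
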