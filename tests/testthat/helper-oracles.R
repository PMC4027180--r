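# independent superposition oracle: optimize RMSD over Euler angles with
# multiple random restarts (no SVD)
oracle_superpose_rmsd <- function(ref, mov, n_starts = 12) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  a <- sweep(ref, 2, cr); b <- sweep(mov, 2, cm)
  rot_from_angles <- function(th) {
    cx <- cos(th[1]); sx <- sin(th[1]); cy <- cos(th[2]); sy <- sin(th[2])
    cz <- cos(th[3]); sz <- sin(th[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(th) sqrt(mean(rowSums((b %*% t(rot_from_angles(th)) - a)^2)))
  best <- Inf
  for (i in seq_len(n_starts)) {
    th0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

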