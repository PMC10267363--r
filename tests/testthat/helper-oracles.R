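# Independent oracles and small fixtures shared across the test files.

# Brute-force maximal-constrained-entropy solution: directly maximizes the
# cross-entropy -sum p log(p/pt) over the probability simplex subject to
# sum(p * xi) = s, by augmented-Lagrangian BFGS on a softmax
# parameterization.  Deliberately shares no code with the package's
# exponential-tilt solution.
brute_force_mec <- function(p_tilde, xi, s_target) {
  n <- length(xi)
  A <- rbind(rep(1, n), xi)                  # the two equality constraints
  b <- c(1, s_target)
  # least-squares feasible point, nudged strictly inside the simplex by
  # blending with the two-vertex mixture that also meets the constraints
  p_ls <- rep(1 / n, n) -
    drop(t(A) %*% solve(A %*% t(A), A %*% rep(1 / n, n) - b))
  ia <- which.min(xi); ib <- which.max(xi)
  theta <- (s_target - xi[ia]) / (xi[ib] - xi[ia])
  p_vx <- numeric(n); p_vx[ia] <- 1 - theta; p_vx[ib] <- theta
  gam <- 0
  while (any((1 - gam) * p_ls + gam * p_vx <= 1e-5) && gam < 1)
    gam <- gam + 0.05
  p0 <- (1 - gam) * p_ls + gam * p_vx
  p0 <- pmax(p0, 1e-6); p0 <- p0 + (1 - sum(p0)) / n   # tiny renorm
  # null space of A: p = p0 + N y stays feasible for any y
  N <- qr.Q(qr(t(A)), complete = TRUE)[, -(1:2), drop = FALSE]
  negS <- function(y) {
    p <- p0 + drop(N %*% y)
    if (any(p <= 0)) return(1e8 + sum(pmax(-p, 0)) * 1e8)
    sum(p * log(p / p_tilde))
  }
  negS_grad <- function(y) {
    p <- p0 + drop(N %*% y)
    if (any(p <= 0)) p <- pmax(p, 1e-12)
    drop(crossprod(N, log(p / p_tilde) + 1))
  }
  fit <- optim(rep(0, n - 2), negS, negS_grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
  # polish with a second start to guard against line-search stalls
  fit2 <- optim(fit$par, negS, negS_grad, method = "BFGS",
                control = list(maxit = 5000, reltol = 1e-16))
  p0 + drop(N %*% fit2$par)
}

# 3D rotation matrix about a unit axis by angle (radians)
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  matrix(c(
    a[1]*a[1]*C + c_,      a[1]*a[2]*C - a[3]*s_, a[1]*a[3]*C + a[2]*s_,
    a[2]*a[1]*C + a[3]*s_, a[2]*a[2]*C + c_,      a[2]*a[3]*C - a[1]*s_,
    a[3]*a[1]*C - a[2]*s_, a[3]*a[2]*C + a[1]*s_, a[3]*a[3]*C + c_),
    3, 3, byrow = TRUE)
}

# apply a rigid-body transform to a structure3d
transform_structure <- function(frame, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% t(R)
  frame$atoms$x <- xyz[, 1] + shift[1]
  frame$atoms$y <- xyz[, 2] + shift[2]
  frame$atoms$z <- xyz[, 3] + shift[3]
  frame
}

# tiny deterministic metastatistics fixture
tiny_ms <- function() {
  metastatistics(data.frame(
    xi = c(0, 1, 2), energy = c(5, 1, 3), multiplicity = c(0.5, 0.3, 0.2)))
}

# fixed-width PDB ATOM record
pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          chain = "A") {
  sprintf("ATOM  %5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, resname, chain, resno, x, y, z)
}
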