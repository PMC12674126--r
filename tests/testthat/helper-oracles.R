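# Independent oracles and fixture builders shared across tests.

# Torsion by plane projection: project the two branch vectors onto the plane
# normal to the central bond and take the signed angle between them. This is
# algebraically independent of the atan2(normal, normal) formulation used by
# torsion_angle().
oracle_torsion <- function(p1, p2, p3, p4) {
  e <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u <- (p1 - p2) - sum((p1 - p2) * e) * e
  v <- (p4 - p3) - sum((p4 - p3) * e) * e
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  ang <- atan2(sum(cr * e), sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Direct minimisation of the superposition RMSD over rotations: coarse Euler
# grid, then Nelder-Mead refinement of the best cell. Never touches the SVD
# path under test.
rmsd_at_euler <- function(ang, P, Q) {
  R <- rotation_matrix(ang[1], c(0, 0, 1)) %*%
    rotation_matrix(ang[2], c(0, 1, 0)) %*%
    rotation_matrix(ang[3], c(1, 0, 0))
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

brute_force_rmsd <- function(P, Q, step = 10) {
  a1 <- seq(-180, 180 - step, by = step)
  a2 <- seq(-90, 90, by = step)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (x in a1) for (y in a2) for (z in a1) {
    r <- rmsd_at_euler(c(x, y, z), P, Q)
    if (r < best) { best <- r; best_ang <- c(x, y, z) }
  }
  opt <- stats::optim(best_ang, rmsd_at_euler, P = P, Q = Q,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, opt$value)
}

# Uniform-ish random rotation from a normalised quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Alpha-helix-like CA trace: non-degenerate geometry for superposition tests.
helical_chain <- function(resno, chain_id = "A") {
  t <- seq_along(resno)
  new_chain_model(data.frame(
    elety = "CA", resid = "ALA", resno = resno, elesy = "C",
    x = 2.3 * cos(t * 100 * pi / 180),
    y = 2.3 * sin(t * 100 * pi / 180),
    z = 1.5 * t), chain_id = chain_id)
}

# Simple straight-chain fixture: one CA per residue along x.
straight_chain <- function(resno, chain_id = "A", spacing = 3.8) {
  n <- length(resno)
  new_chain_model(data.frame(
    elety = "CA", resid = "ALA", resno = resno, elesy = "C",
    x = spacing * seq_len(n), y = 0, z = 0), chain_id = chain_id)
}

# Hand-written minimal PDB fixtures.
write_minimal_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ", type = "ATOM", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(trimws(name), 1, 1)
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf("%-4s", paste0(" ", name))
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, alt, resid, chain, resno, x, y, z, occ, 0,
          sprintf("%2s", elesy))
}

# Trimer fixture used by tilt/interface/reporting tests: longitudinal pair
# (A over C) plus a lateral subunit B.
trimer_placements <- function() {
  list(A = rigid_transform(translation = c(0, 0, 55)),
       B = rigid_transform(translation = c(28, 0, 27)),
       C = rigid_transform())
}

compose_transforms <- function(second, first) {
  list(rotation = second$rotation %*% first$rotation,
       translation = as.numeric(second$rotation %*% first$translation) +
         second$translation)
}
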