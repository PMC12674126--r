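# Synthetic actin-like conformer generator: pseudo-atom chains with the
# canonical subdomain layout, an exactly controllable flattening dihedral,
# controllable W-loop gate geometry, hinge-interpolated twist series,
# two-state gate trajectories, and trimer assembly. These are geometric
# fixtures, not physical models: they exist so the full analysis chain is
# testable without downloading deposited coordinates.

# Run code with a private, restored RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Fixed geometric frame for the generator (Angstrom). Subdomain centers of
# mass sit on a four-point scaffold with actin-like ~17-25 A separations;
# SD4's out-of-plane angle realizes the requested dihedral exactly.
.GEN <- list(
  c_sd1 = c(0, 0, 0),
  c_sd3 = c(24, 0, 0),
  sd2_off = c(-8, 17, 0),      # SD2 COM relative to SD1 COM
  sd4_lever = 17,               # SD4 COM distance from the hinge axis
  sd4_along = 8,                # SD4 COM advance along the hinge axis
  o168_off = c(-6, 4, 1),      # Gly168 O relative to SD3 COM
  gate_dir = c(0, 0.6, 0.8)    # direction from G168 O to Y143 OH
)

gen_pools <- function() {
  sch <- subdomain_scheme()
  list(sd1 = sch$sd1, sd2 = sch$sd2,
       sd3 = setdiff(sch$sd3, c(168L, 169L)),  # gate residues placed explicitly
       sd4 = sch$sd4)
}

# Evenly spaced residue picks from a pool; SD4 always includes Asp244 (the
# standard displacement probe).
pick_resnos <- function(pool, n, force = integer()) {
  n <- min(n, length(pool))
  idx <- unique(round(seq(1, length(pool), length.out = n)))
  sel <- pool[idx]
  for (f in force) {
    if (!f %in% sel && f %in% pool) sel[which.min(abs(sel - f))] <- f
  }
  sort(unique(sel))
}

#' Generate a synthetic actin-like conformer
#'
#' Builds a single-chain pseudo-atom structure whose subdomain centers of
#' mass realize a prescribed flattening dihedral `phi` exactly (before
#' noise): one Calpha pseudo-atom per residue, clustered around four COM
#' sites on an actin-scale scaffold, with residue numbers drawn from the
#' canonical subdomain ranges so the real partitioning/lookup code paths
#' run unchanged. Gate residues Tyr143 (CA, OH), Gly168 (CA, O) and Tyr169
#' (CA) are placed at a configurable gate distance.
#'
#' @param phi target flattening dihedral in degrees, in (-180, 180].
#' @param n_per_domain residues per subdomain, capped at the range size; the
#'   default `Inf` uses every residue of each canonical range, giving full
#'   subdomain coverage.
#' @param atoms_per_residue heavy pseudo-atoms per cluster residue (default
#'   3: CA, CB, CG). Real actin residues average ~8 heavy atoms; a few per
#'   residue keeps the center-of-mass averaging of coordinate noise
#'   realistic while staying fast.
#' @param noise_sigma isotropic Gaussian coordinate noise in Angstrom
#'   (default 0; applied after the exact construction).
#' @param seed RNG seed; the same spec and seed give bit-identical
#'   coordinates.
#' @param gate_distance Tyr143 OH to Gly168 O distance in Angstrom
#'   (default 3.6, a closed gate).
#' @param ca_distance Tyr143 CA to Tyr169 CA distance (default 11).
#' @param cluster_radius scale of the atom clusters around each COM site
#'   (default 5 Angstrom).
#' @param chain_id chain identifier (default `"A"`).
#' @return an `actin_structure` with one frame; attribute `phi_target`
#'   records the requested dihedral.
#' @export
#' @examples
#' s <- make_conformer(phi = -15)
#' flattening_dihedral(select_chain(s, "A"))  # -15 (exact)
make_conformer <- function(phi = -15, n_per_domain = Inf, noise_sigma = 0,
                           seed = 1, gate_distance = 3.6, ca_distance = 11,
                           cluster_radius = 5, atoms_per_residue = 3,
                           chain_id = "A") {
  if (!is.finite(phi) || phi <= -180 || phi > 180) {
    stop("phi must lie in (-180, 180]", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (n_per_domain < 1) stop("need at least 1 atom per subdomain", call. = FALSE)
  atoms_per_residue <- max(1L, min(3L, as.integer(atoms_per_residue)))
  g <- .GEN
  phi_r <- phi * pi / 180
  sites <- rbind(
    sd1 = g$c_sd1,
    sd2 = g$c_sd1 + g$sd2_off,
    sd3 = g$c_sd3,
    sd4 = g$c_sd3 + c(g$sd4_along, g$sd4_lever * cos(phi_r),
                      g$sd4_lever * sin(phi_r))
  )
  pools <- gen_pools()

  # gate atoms (fixed geometry, independent of phi)
  o168 <- g$c_sd3 + g$o168_off
  ca168 <- o168 + c(1.2, 0.5, -0.3)
  ca169 <- ca168 + c(2.0, 2.5, 0.8)
  oh143 <- o168 + gate_distance * unitv(g$gate_dir)
  ca143 <- ca169 + ca_distance * unitv(c(-0.3, 0.8, 0.52))
  gate <- data.frame(
    elety = c("CA", "OH", "CA", "O", "CA"),
    resid = c("TYR", "TYR", "GLY", "GLY", "TYR"),
    resno = c(143L, 143L, 168L, 168L, 169L),
    elesy = c("C", "O", "C", "O", "C"),
    x = c(ca143[1L], oh143[1L], ca168[1L], o168[1L], ca169[1L]),
    y = c(ca143[2L], oh143[2L], ca168[2L], o168[2L], ca169[2L]),
    z = c(ca143[3L], oh143[3L], ca168[3L], o168[3L], ca169[3L]),
    stringsAsFactors = FALSE
  )

  with_seed(seed, {
    parts <- lapply(names(pools), function(sd) {
      res <- pick_resnos(pools[[sd]], n_per_domain,
                         force = if (sd == "sd4") 244L else integer())
      names_per_res <- c("CA", "CB", "CG")[seq_len(atoms_per_residue)]
      res <- rep(res, each = atoms_per_residue)
      elety <- rep(names_per_res, length.out = length(res))
      n <- length(res)
      off <- matrix(stats::rnorm(n * 3, sd = cluster_radius / 2), n, 3L)
      off <- sweep(off, 2L, colMeans(off))  # exact zero-mean cluster
      if (sd == "sd3") {
        # gate atoms 168/169 live inside SD3's residue range; shift the
        # cluster so the mass-weighted SD3 COM stays exactly on its site
        fix <- gate[gate$resno %in% c(168L, 169L), ]
        m_fix <- element_mass(fix$elesy)
        S <- colSums(as.matrix(fix[, c("x", "y", "z")]) * m_fix) -
          sum(m_fix) * sites["sd3", ]
        off <- sweep(off, 2L, S / (n * 12.011), "-")
      }
      xyz <- sweep(off, 2L, sites[sd, ], "+")
      data.frame(elety = elety, resid = "ALA", resno = res, elesy = "C",
                 x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                 stringsAsFactors = FALSE)
    })
    atoms <- rbind(do.call(rbind, parts), gate)
    atoms <- atoms[order(atoms$resno, atoms$elety), ]
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (noise_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                          nrow(xyz), 3L)
    }
    atoms$x <- NULL; atoms$y <- NULL; atoms$z <- NULL
    atoms$chain <- chain_id
    atoms$eleno <- seq_len(nrow(atoms))
    s <- new_structure(atoms, list(xyz),
                       id = sprintf("synthetic-conformer-phi%+.1f", phi))
    attr(s, "phi_target") <- phi
    s
  })
}

#' Twist-interpolated conformer series (G-to-F hinge sweep)
#'
#' Generates conformers whose flattening dihedral is linearly interpolated
#' between two endpoints, realized by rotating the SD1+SD2 block of a single
#' base conformer about the SD1-COM to SD3-COM hinge axis. Because rotation
#' about the central torsion axis adds directly to the dihedral, the
#' constructed sweep is exact (up to the base conformer's noise), and SD3/SD4
#' coordinates are identical across the series.
#'
#' @param phi_start,phi_end endpoint dihedrals in degrees.
#' @param n_steps number of conformers (>= 2), endpoints included.
#' @param ... further arguments to [make_conformer()] (the base conformer is
#'   built at `phi_start`).
#' @return list of `actin_structure`s; each carries its `phi_target`
#'   attribute.
#' @export
#' @examples
#' series <- twist_series(-23.6, -6.2, n_steps = 5)
#' sapply(series, attr, "phi_target")
twist_series <- function(phi_start, phi_end, n_steps, ...) {
  if (n_steps < 2L) stop("n_steps must be >= 2", call. = FALSE)
  base <- make_conformer(phi = phi_start, ...)
  phis <- seq(phi_start, phi_end, length.out = n_steps)
  sch <- subdomain_scheme()
  moving <- base$atoms$resno %in% c(sch$sd1, sch$sd2)
  hinge_axis <- .GEN$c_sd3 - .GEN$c_sd1
  lapply(seq_along(phis), function(i) {
    alpha <- phi_start - phis[i]  # block rotation subtracts from the torsion
    xyz <- base$frames[[1L]]
    if (abs(alpha) > 0) {
      R <- rotation_matrix(alpha, hinge_axis)
      xyz[moving, ] <- sweep(
        sweep(xyz[moving, , drop = FALSE], 2L, .GEN$c_sd1) %*% t(R),
        2L, .GEN$c_sd1, "+")
    }
    s <- new_structure(base$atoms, list(xyz),
                       id = sprintf("twist-series-%02d-phi%+.1f", i, phis[i]))
    attr(s, "phi_target") <- phis[i]
    s
  })
}

#' Two-state W-loop gate trajectory
#'
#' Generates a multi-frame structure of the five gate atoms in which Tyr143
#' OH sits at the closed or open distance from Gly168 O according to a
#' two-state process: independent draws at probability `p_open`, or a
#' stationary two-state Markov chain (closed-to-open rate
#' `(1 - stay_prob) * p_open`, open-to-closed rate
#' `(1 - stay_prob) * (1 - p_open)`, so the stationary open probability is
#' exactly `p_open` and switching is autocorrelated as in real trajectory
#' data).
#'
#' @param p_open stationary open probability in \[0, 1\].
#' @param n_frames number of frames.
#' @param d_closed,d_open gate distances of the two states in Angstrom
#'   (defaults 3.5 and 10; `d_open > d_closed` required).
#' @param switching `"iid"` (default) or `"markov"`.
#' @param stay_prob Markov persistence parameter in \[0, 1) (default 0.95).
#' @param seed RNG seed.
#' @param chain_id chain identifier.
#' @return a multi-frame `actin_structure`; attribute `states` holds the
#'   true logical open/closed sequence for oracle testing.
#' @export
make_gate_trajectory <- function(p_open = 0.4, n_frames = 1000,
                                 d_closed = 3.5, d_open = 10,
                                 switching = c("iid", "markov"),
                                 stay_prob = 0.95, seed = 1, chain_id = "A") {
  switching <- match.arg(switching)
  if (p_open < 0 || p_open > 1) stop("p_open must be in [0, 1]", call. = FALSE)
  if (d_open <= d_closed) stop("d_open must exceed d_closed", call. = FALSE)
  if (n_frames < 1L) stop("need at least one frame", call. = FALSE)
  base <- make_conformer(phi = -15, n_per_domain = 1, seed = seed,
                         gate_distance = d_closed, chain_id = chain_id)
  at <- base$atoms
  keep <- at$resno %in% c(143L, 168L, 169L)
  at <- at[keep, , drop = FALSE]
  xyz0 <- base$frames[[1L]][keep, , drop = FALSE]
  i_oh <- which(at$resno == 143L & trimws(at$elety) == "OH")
  i_o <- which(at$resno == 168L & trimws(at$elety) == "O")
  o168 <- xyz0[i_o, ]
  u <- unitv(.GEN$gate_dir)
  states <- with_seed(seed, {
    if (switching == "iid") {
      stats::runif(n_frames) < p_open
    } else {
      a <- (1 - stay_prob) * p_open        # closed -> open
      b <- (1 - stay_prob) * (1 - p_open)  # open -> closed
      st <- logical(n_frames)
      st[1L] <- stats::runif(1) < p_open
      if (n_frames > 1L) for (f in 2L:n_frames) {
        st[f] <- if (st[f - 1L]) stats::runif(1) >= b else stats::runif(1) < a
      }
      st
    }
  })
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- xyz0
    d <- if (states[f]) d_open else d_closed
    xyz[i_oh, ] <- o168 + d * u
    xyz
  })
  at$eleno <- seq_len(nrow(at))
  s <- new_structure(at, frames, id = sprintf("gate-trajectory-p%.2f", p_open))
  attr(s, "states") <- states
  attr(s, "p_open") <- p_open
  s
}

#' Assemble a trimer (or general oligomer) from rigid placements
#'
#' Places copies of a single-chain subunit under a list of rigid transforms,
#' producing a multi-chain structure with sequential chain ids — the
#' synthetic counterpart of an actin nucleus (two longitudinal subunits plus
#' one lateral).
#'
#' @param subunit a single-chain `actin_structure` (frame 1 used).
#' @param placements list of [rigid_transform()] objects (>= 2).
#' @param chain_ids chain identifiers (default `"A"`, `"B"`, `"C"`, ...).
#' @return a multi-chain `actin_structure`. Placements bringing any
#'   inter-chain atom pair closer than 1 Angstrom trigger a clash warning
#'   (not an error).
#' @export
make_trimer <- function(subunit, placements,
                        chain_ids = LETTERS[seq_along(placements)]) {
  stopifnot(inherits(subunit, "actin_structure"))
  if (length(placements) < 2L) stop("need at least 2 placements", call. = FALSE)
  stopifnot(length(chain_ids) == length(placements))
  at0 <- subunit$atoms
  xyz0 <- subunit$frames[[1L]]
  parts <- vector("list", length(placements))
  coords_list <- vector("list", length(placements))
  for (i in seq_along(placements)) {
    tr <- placements[[i]]
    xyz <- apply_transform(xyz0, tr)
    at <- at0
    at$chain <- chain_ids[[i]]
    parts[[i]] <- at
    coords_list[[i]] <- xyz
  }
  atoms <- do.call(rbind, parts)
  atoms$eleno <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, coords_list)
  for (i in seq_along(placements)) {
    for (j in seq_along(placements)) {
      if (j <= i) next
      a <- coords_list[[i]]; b <- coords_list[[j]]
      d2min <- min(vapply(seq_len(nrow(a)), function(k) {
        min(rowSums(sweep(b, 2L, a[k, ])^2))
      }, numeric(1L)))
      if (d2min < 1) {
        warning("clashing placements: chains ", chain_ids[[i]], " and ",
                chain_ids[[j]], " have atoms ",
                sprintf("%.2f", sqrt(d2min)), " A apart", call. = FALSE)
      }
    }
  }
  new_structure(atoms, list(xyz), id = "synthetic-oligomer")
}
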