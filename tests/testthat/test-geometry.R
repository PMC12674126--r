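# Geometry primitives: centers of mass, torsions, Kabsch superposition,
# residue matching.

test_that("center of mass handles geometric and mass weighting", {
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(center_of_mass(x, weighting = "geometric"), c(1, 0, 0))
  # carbon at origin, oxygen at (1,0,0): COM at m_O / (m_C + m_O)
  expect_equal(
    center_of_mass(x / 2, masses = c(12.011, 15.999)),
    c(15.999 / 28.010, 0, 0),
    tolerance = 1e-12)
  expect_error(center_of_mass(x[0, , drop = FALSE], weighting = "geometric"),
               "empty")
})

test_that("torsion reproduces the planar references and the sign convention", {
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0, 1)), 0)
  expect_equal(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1)), 180)
  v <- torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1))
  expect_equal(abs(v), 90)
  expect_equal(v, oracle_torsion(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1)))
  expect_error(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(torsion_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 1, 1)),
               "zero-length")
})

test_that("torsion matches the independent projection oracle on random quadruples", {
  set.seed(42)
  for (i in 1:1000) {
    p <- matrix(rnorm(12, sd = 4), 4)
    a <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    b <- oracle_torsion(p[1, ], p[2, ], p[3, ], p[4, ])
    d <- abs(a - b)
    expect_lt(min(d, 360 - d), 1e-9)
  }
})

test_that("torsion is reversal-invariant and rigid-motion invariant", {
  # reading the quadruple from either end must give the same dihedral (the
  # angle between the two planes does not depend on the traversal direction)
  set.seed(7)
  for (i in 1:200) {
    p <- matrix(rnorm(12, sd = 4), 4)
    a <- torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    rev <- torsion_angle(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(rev, a, tolerance = 1e-9)
    R <- random_rotation(); t <- rnorm(3, sd = 10)
    q <- sweep(p %*% t(R), 2, t, "+")
    expect_equal(torsion_angle(q[1, ], q[2, ], q[3, ], q[4, ]), a,
                 tolerance = 1e-8)
  }
})

test_that("kabsch recovers exact rigid motions and suppresses reflections", {
  set.seed(5)
  P <- matrix(rnorm(15, sd = 3), 5)
  # identity case
  fit <- kabsch_fit(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
  # constructed rotation + translation
  R <- rotation_matrix(90, c(0, 0, 1)); t <- c(1, 2, 3)
  Q <- sweep(P %*% t(R), 2, t, "+")
  fit <- kabsch_fit(P, Q)
  expect_equal(fit$rotation, R, tolerance = 1e-10)
  expect_equal(fit$translation, t, tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-10)
  # mirror image of a chiral set: proper rotation enforced, rmsd > 0,
  # and the residual equals the brute-force rotational minimum
  Pm <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Qm <- Pm; Qm[, 1] <- -Qm[, 1]
  fitm <- kabsch_fit(Pm, Qm)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0)
  expect_equal(fitm$rmsd, brute_force_rmsd(Pm, Qm), tolerance = 1e-3)
})

test_that("kabsch rmsd is the global minimum and never exceeds the unfitted rmsd", {
  set.seed(9)
  for (i in 1:3) {
    n <- sample(4:6, 1)
    P <- matrix(rnorm(3 * n, sd = 3), n)
    Q <- matrix(rnorm(3 * n, sd = 3), n)
    fit <- kabsch_fit(P, Q)
    expect_lte(fit$rmsd, sqrt(mean(rowSums((P - Q)^2))) + 1e-12)
    expect_equal(fit$rmsd, brute_force_rmsd(P, Q), tolerance = 1e-3)
  }
})

test_that("degenerate kabsch inputs are refused", {
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "3 point pairs")
  L <- cbind(1:5, 0, 0)  # collinear: rotation about the line is undetermined
  expect_error(kabsch_fit(L, L), "degenerate")
})

test_that("residue matching pairs by author number and errors without overlap", {
  a <- straight_chain(1:100)
  b <- straight_chain(1:100, chain_id = "B")
  m <- match_residues(a, b)
  expect_equal(m$n_matched, 100L)

  gap <- straight_chain(setdiff(1:100, 41:50))
  m <- match_residues(gap, b)
  expect_equal(m$n_matched, 90L)
  expect_false(any(m$resno %in% 41:50))

  far <- straight_chain(201:250)
  expect_error(match_residues(a, far), "fewer than 3 common")
})

test_that("iterative trimming drops gross outlier pairs", {
  a <- helical_chain(1:50)
  b <- a
  b$y[b$resno == 25] <- 40  # one displaced residue
  m <- match_residues(a, b, trim = "iterative")
  expect_false(25 %in% m$resno)
  expect_equal(m$n_matched, 49L)
})

test_that("chain superposition is rigid-motion invariant and symmetric", {
  set.seed(3)
  ch <- select_chain(make_conformer(phi = -20, noise_sigma = 0.5, seed = 8), "A")
  # self fit after an arbitrary rigid motion: rmsd 0
  tr <- rigid_transform(37, axis = c(1, 2, 3), translation = c(5, -4, 2))
  moved <- apply_transform(ch, tr)
  fit <- superpose_chains(moved, ch)
  expect_lt(fit$rmsd, 1e-8)
  # a vs b symmetric in rmsd when trim = none
  ch2 <- select_chain(make_conformer(phi = -8, noise_sigma = 0.5, seed = 9), "A")
  f12 <- superpose_chains(ch, ch2)
  f21 <- superpose_chains(ch2, ch)
  expect_equal(f12$rmsd, f21$rmsd, tolerance = 1e-6)
  expect_equal(f12$n_matched, f21$n_matched)
})

test_that("fit and report selections can differ", {
  sch <- subdomain_scheme()
  ends <- twist_series(-23.6, -6.2, n_steps = 2)  # shared SD3/SD4 block
  a <- select_chain(ends[[1]], "A")
  b <- select_chain(ends[[2]], "A")
  fit_sel <- c(sch$sd3, sch$sd4)
  f <- superpose_chains(a, b, fit_selection = fit_sel, report_selection = sch$sd2)
  expect_gt(f$rmsd, 1)   # SD2 moved by the twist
  expect_equal(f$n_matched, length(intersect(sch$sd2, a$resno)))
  g <- superpose_chains(a, b, fit_selection = fit_sel, report_selection = fit_sel)
  expect_lt(g$rmsd, 1e-8)  # SD3/SD4 identical across the hinge sweep
})
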