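# Subdomain partitioning, flattening dihedral, offsets, gate metrics,
# classification, tilt.

test_that("subdomain partitioning tracks modeled residues and coverage", {
  full <- straight_chain(1:375)
  p <- assign_subdomains(full)
  expect_true(all(p$coverage == 1))
  expect_equal(lengths(p$residues),
               lengths(subdomain_scheme()), ignore_attr = TRUE)

  # a disordered D-loop (residues 40-50) lies outside every subdomain range:
  # coverage stays 1.0 and no warning fires
  dloop_gap <- straight_chain(setdiff(1:375, 40:50))
  expect_no_warning(p2 <- assign_subdomains(dloop_gap))
  expect_true(all(p2$coverage == 1))

  # a genuine gap inside SD2 (53-68 lost) drops coverage below 0.8
  sd2_gap <- straight_chain(setdiff(1:375, 53:68))
  expect_warning(p3 <- assign_subdomains(sd2_gap), "SD2")
  expect_equal(p3$coverage[["sd2"]], 6 / 22)

  # truncation before SD4 leaves it empty: partition error
  trunc <- straight_chain(1:180)
  expect_error(assign_subdomains(trunc), "SD4")
})

test_that("the generator round-trips the flattening dihedral exactly", {
  ch <- select_chain(make_conformer(phi = -15, seed = 2), "A")
  expect_equal(flattening_dihedral(ch), -15, tolerance = 1e-9)
  # weighting variants stay close for symmetric clusters
  expect_equal(flattening_dihedral(ch, weighting = "calpha"), -15,
               tolerance = 0.5)
})

test_that("collinear subdomain centers give an undefined-torsion error", {
  # four single-atom subdomains on a straight line
  at <- data.frame(elety = "CA", resid = "ALA",
                   resno = c(10L, 35L, 150L, 200L), elesy = "C",
                   x = c(0, 10, 20, 30), y = 0, z = 0)
  ch <- new_chain_model(at)
  expect_error(suppressWarnings(flattening_dihedral(ch)), "collinear")
})

test_that("dihedral and offsets are invariant under rigid motions", {
  set.seed(31)
  ch <- select_chain(make_conformer(phi = -17.3, noise_sigma = 0.2, seed = 4), "A")
  phi0 <- flattening_dihedral(ch)
  ref <- select_chain(make_conformer(phi = -23.6, seed = 5), "A")
  off0 <- delta_offsets(ch, ref)
  for (i in 1:5) {
    tr <- rigid_transform(runif(1, -180, 180), axis = rnorm(3),
                          translation = rnorm(3, sd = 20))
    moved <- apply_transform(ch, tr)
    expect_equal(flattening_dihedral(moved), phi0, tolerance = 1e-8)
    off <- delta_offsets(moved, ref)
    expect_equal(off$delta_sd2, off0$delta_sd2, tolerance = 1e-7)
    expect_equal(off$delta_sd1$distance, off0$delta_sd1$distance,
                 tolerance = 1e-7)
    expect_equal(off$delta_sd1$angle_deg, off0$delta_sd1$angle_deg,
                 tolerance = 1e-6)
  }
})

test_that("offsets against an identical reference are zero", {
  ch <- select_chain(make_conformer(phi = -10, seed = 6), "A")
  off <- delta_offsets(ch, ch)
  expect_equal(off$delta_sd2, 0, tolerance = 1e-9)
  expect_equal(off$delta_sd1$distance, 0, tolerance = 1e-9)
  expect_equal(off$delta_sd1$angle_deg, 0, tolerance = 1e-9)
})

test_that("twist increases the SD2 offset from the G endpoint", {
  series <- twist_series(-23.6, -6.2, n_steps = 5)
  g_ref <- select_chain(series[[1]], "A")
  d <- vapply(series, function(s) {
    delta_offsets(select_chain(s, "A"), g_ref)$delta_sd2
  }, numeric(1))
  expect_equal(d[1], 0, tolerance = 1e-9)
  expect_true(all(diff(d) > 0))
})

test_that("W-loop gate distances and state calls follow the thresholds", {
  closed <- select_chain(make_conformer(gate_distance = 3.6), "A")
  g <- wloop_gate(closed)
  expect_equal(g$d_y143oh_g168o, 3.6, tolerance = 1e-9)
  expect_equal(g$gate_state, "closed")

  open <- select_chain(make_conformer(gate_distance = 12.6), "A")
  expect_equal(wloop_gate(open)$gate_state, "open")

  mid <- select_chain(make_conformer(gate_distance = 6.5), "A")
  expect_equal(wloop_gate(mid)$gate_state, "intermediate")

  # boundary behaviour: closed at exactly 5, open at exactly 8
  expect_equal(wloop_gate(select_chain(make_conformer(gate_distance = 5), "A"))$gate_state,
               "closed")
  expect_equal(wloop_gate(select_chain(make_conformer(gate_distance = 8), "A"))$gate_state,
               "open")

  # the CA-CA width is controlled independently of the gate bond
  wide <- select_chain(make_conformer(gate_distance = 3.6, ca_distance = 12.6), "A")
  expect_equal(wloop_gate(wide)$d_y143ca_y169ca, 12.6, tolerance = 1e-9)
})

test_that("missing gate atoms fail loudly, naming the atom", {
  ch <- select_chain(make_conformer(), "A")
  no_oh <- ch[!(ch$resno == 143 & trimws(ch$elety) == "OH"), ]
  no_oh <- new_chain_model(no_oh)
  expect_error(wloop_gate(no_oh), "OH of residue 143")
})

test_that("classification is a step function with the documented thresholds", {
  expect_equal(classify_conformer(-8.1), "F_like")
  expect_equal(classify_conformer(-22.7), "G_like")
  expect_equal(classify_conformer(-13.0), "intermediate")
  expect_equal(classify_conformer(-12.0), "F_like")       # boundary inclusive
  expect_equal(classify_conformer(-14.0), "G_like")
  expect_equal(classify_conformer(c(-6, -13, -20)),
               c("F_like", "intermediate", "G_like"))
  # custom thresholds shift the step
  expect_equal(classify_conformer(-13, f_threshold = -13.5, g_threshold = -15),
               "F_like")
  expect_error(classify_conformer(NaN), "non-finite")
})

test_that("a twist sweep flips classification exactly once, G to F", {
  series <- twist_series(-23.6, -6.2, n_steps = 19)
  phi <- vapply(series, function(s) flattening_dihedral(select_chain(s, "A")),
                numeric(1))
  expect_true(all(diff(phi) > 0))            # strictly monotone
  cls <- classify_conformer(phi)
  runs <- rle(cls)$values
  expect_equal(runs, c("G_like", "intermediate", "F_like"))
})

test_that("helix engagement uses a strict 4-Angstrom cutoff", {
  mk <- function(d) {
    a <- new_chain_model(data.frame(elety = "N", resid = "LYS", resno = 113L,
                                    elesy = "N", x = 0, y = 0, z = 0),
                         chain_id = "A")
    b <- new_chain_model(data.frame(elety = "O", resid = "GLU", resno = 195L,
                                    elesy = "O", x = d, y = 0, z = 0),
                         chain_id = "B")
    helix_engagement(a, b)
  }
  expect_true(mk(3.0)$engaged)
  expect_false(mk(4.0)$engaged)   # boundary: strictly below 4
  expect_false(mk(15)$engaged)
  expect_equal(mk(3.0)$d_k113n_e195o, 3)
})

test_that("tilt/displacement is zero for an identical nucleus and recovers a constructed rotation", {
  s <- make_conformer(phi = -8, seed = 12)
  pl <- trimer_placements()
  fil <- make_trimer(s, pl, chain_ids = names(pl))
  z <- tilt_displacement(fil, fil, anchor_chains = c("C", "C"),
                         probe_chains = c("A", "A"))
  expect_lt(z$tilt_deg, 1e-4)
  expect_lt(z$displacement, 1e-9)

  for (angle in c(7, 10)) {
    hinge <- rigid_transform(angle, axis = c(0, 1, 0), center = c(12, 8, 55))
    pl_t <- pl
    pl_t$A <- compose_transforms(hinge, pl$A)
    nuc <- make_trimer(s, pl_t, chain_ids = names(pl))
    r <- tilt_displacement(nuc, fil, anchor_chains = c("C", "C"),
                           probe_chains = c("A", "A"))
    expect_equal(r$tilt_deg, angle, tolerance = 0.2)
    expect_gt(r$displacement, 0)
    # the probe displacement equals the hinge's direct action on Asp244
    p0 <- get_asp244 <- coords(select_chain(fil, "A"))[
      which(select_chain(fil, "A")$resno == 244 &
              trimws(select_chain(fil, "A")$elety) == "CA"), ]
    expect_equal(r$displacement,
                 sqrt(sum((apply_transform(matrix(p0, 1), hinge) - p0)^2)),
                 tolerance = 1e-6)
  }
})
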