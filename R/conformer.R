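# Core conformational analysis of a single actin subunit: subdomain
# partitioning, the SD1-SD4 flattening dihedral, center-of-mass offsets
# against G/F references, W-loop gate metrics, G/F classification, nucleus
# tilt, and lateral-helix engagement.

#' Canonical actin subdomain residue scheme
#'
#' The default author-numbered residue ranges defining the four actin
#' subdomains for center-of-mass work: SD1 = 7-31, 74-136, 347-364;
#' SD2 = 34-39, 53-68; SD3 = 149-179, 274-331; SD4 = 185-256. These ranges
#' deliberately exclude the mobile D-loop (40-50) and termini so they are
#' modeled in essentially every deposited actin structure.
#'
#' @param sd1,sd2,sd3,sd4 integer vectors of author residue numbers; defaults
#'   are the canonical ranges above. Ranges must be pairwise disjoint.
#' @return object of class `subdomain_scheme` (named list of integer vectors).
#' @export
#' @examples
#' sch <- subdomain_scheme()
#' lengths(sch)
subdomain_scheme <- function(sd1 = c(7:31, 74:136, 347:364),
                             sd2 = c(34:39, 53:68),
                             sd3 = c(149:179, 274:331),
                             sd4 = 185:256) {
  sch <- list(sd1 = as.integer(sd1), sd2 = as.integer(sd2),
              sd3 = as.integer(sd3), sd4 = as.integer(sd4))
  all_res <- unlist(sch, use.names = FALSE)
  if (anyDuplicated(all_res)) {
    stop("subdomain ranges must be pairwise disjoint", call. = FALSE)
  }
  structure(sch, class = "subdomain_scheme")
}

#' @export
print.subdomain_scheme <- function(x, ...) {
  cat("subdomain_scheme:",
      paste(sprintf("%s (%d res)", toupper(names(x)), lengths(x)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Realize a subdomain scheme on a concrete chain
#'
#' Intersects each subdomain range with the residues actually modeled in the
#' chain. An empty subdomain is an error; coverage below 80% of a range
#' triggers a warning (a partially disordered subdomain biases its center of
#' mass).
#'
#' @param chain a `chain_model`.
#' @param scheme a [subdomain_scheme()].
#' @return object of class `subdomain_partition`: list with `residues`
#'   (realized residue sets per subdomain) and `coverage` (fractions).
#' @export
assign_subdomains <- function(chain, scheme = subdomain_scheme()) {
  modeled <- unique(chain$resno)
  realized <- lapply(scheme, intersect, modeled)
  empty <- names(realized)[lengths(realized) == 0L]
  if (length(empty)) {
    stop("subdomain(s) ", paste(toupper(empty), collapse = ", "),
         " have no modeled residues in chain '", attr(chain, "chain_id"),
         "'", call. = FALSE)
  }
  coverage <- lengths(realized) / lengths(scheme)
  low <- names(coverage)[coverage < 0.8]
  if (length(low)) {
    warning("low subdomain coverage (", paste(sprintf(
      "%s %.0f%%", toupper(low), 100 * coverage[low]), collapse = ", "),
      ") in chain '", attr(chain, "chain_id"), "'", call. = FALSE)
  }
  structure(list(residues = realized, coverage = coverage,
                 chain_id = attr(chain, "chain_id")),
            class = "subdomain_partition")
}

#' @export
print.subdomain_partition <- function(x, ...) {
  cat("subdomain_partition for chain '", x$chain_id, "': ",
      paste(sprintf("%s %d res (%.0f%%)", toupper(names(x$residues)),
                    lengths(x$residues), 100 * x$coverage),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Center of mass of one subdomain (non-hydrogen atoms of the realized
# residues; mass-weighted by default, "calpha" restricts to CA atoms).
subdomain_com <- function(chain, partition, sd,
                          weighting = c("mass", "geometric", "calpha")) {
  weighting <- match.arg(weighting)
  res <- partition$residues[[sd]]
  rows <- chain$resno %in% res & chain$elesy != "H"
  if (weighting == "calpha") {
    rows <- rows & trimws(chain$elety) == "CA"
    weighting <- "geometric"
  }
  sub <- chain[rows, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no atoms in subdomain ", toupper(sd), call. = FALSE)
  center_of_mass(as.matrix(as.data.frame(sub)[, c("x", "y", "z")]),
                 masses = sub$mass, weighting = weighting)
}

#' Subdomain centers of mass
#'
#' @param chain a `chain_model`.
#' @param scheme a [subdomain_scheme()].
#' @param weighting `"mass"` (all non-hydrogen atoms, mass-weighted;
#'   default), `"geometric"` (unweighted all-atom), or `"calpha"`.
#' @return 4 x 3 matrix with rows sd1..sd4.
#' @export
subdomain_coms <- function(chain, scheme = subdomain_scheme(),
                           weighting = c("mass", "geometric", "calpha")) {
  weighting <- match.arg(weighting)
  part <- assign_subdomains(chain, scheme)
  out <- t(vapply(names(scheme), function(sd) {
    subdomain_com(chain, part, sd, weighting)
  }, numeric(3L)))
  rownames(out) <- names(scheme)
  out
}

#' Flattening dihedral phi SD1-SD4
#'
#' The torsion angle through the subdomain centers of mass, taken in the
#' order SD2-SD1-SD3-SD4 so that the relative rotation of the SD1/SD2 lobe
#' against the SD3/SD4 lobe reads out as a single signed angle: about -23
#' degrees for twisted G-actin, about -6 degrees for flattened F-actin.
#'
#' @inheritParams subdomain_coms
#' @param order character vector of the four subdomain names giving the
#'   torsion ordering; the default is the established flattening convention.
#' @return angle in degrees, in (-180, 180].
#' @export
#' @examples
#' ch <- select_chain(make_conformer(phi = -15), "A")
#' flattening_dihedral(ch)
flattening_dihedral <- function(chain, scheme = subdomain_scheme(),
                                weighting = c("mass", "geometric", "calpha"),
                                order = c("sd2", "sd1", "sd3", "sd4")) {
  stopifnot(length(order) == 4L, all(order %in% names(scheme)))
  coms <- subdomain_coms(chain, scheme, match.arg(weighting))
  torsion_angle(coms[order[1L], ], coms[order[2L], ],
                coms[order[3L], ], coms[order[4L], ])
}

#' Classify a subunit as G-like, F-like or intermediate
#'
#' Step-function classification of the flattening dihedral. Defaults
#' (F-like at phi >= -12, G-like at phi <= -14) sit in the gap between the
#' observed F-like range (about -6.2 to -10.9 degrees) and G-like range
#' (about -14.8 to -23.6 degrees) of crystallographic and cryo-EM actin
#' conformers.
#'
#' @param phi flattening dihedral(s) in degrees (vectorized).
#' @param f_threshold F-like boundary (degrees, default -12).
#' @param g_threshold G-like boundary (degrees, default -14; must be below
#'   `f_threshold`).
#' @return character vector in `{"G_like", "F_like", "intermediate"}`.
#' @export
classify_conformer <- function(phi, f_threshold = -12, g_threshold = -14) {
  stopifnot(g_threshold < f_threshold)
  if (any(!is.finite(phi))) stop("non-finite dihedral", call. = FALSE)
  ifelse(phi >= f_threshold, "F_like",
         ifelse(phi <= g_threshold, "G_like", "intermediate"))
}

#' SD1/SD2 center-of-mass offsets against a reference conformer
#'
#' Superposes the query chain onto a reference (G- or F-actin) via the
#' Calpha atoms of SD3 and SD4 — the rigid lobe — and measures how far the
#' SD1 and SD2 centers of mass have moved: Delta SD2 as a displacement
#' (Angstrom), Delta SD1 both as a displacement and as the angle subtended
#' at the SD3 center of mass between the two SD1 positions (degrees).
#'
#' @param query,reference `chain_model` objects.
#' @param scheme a [subdomain_scheme()].
#' @param weighting center-of-mass weighting, see [subdomain_coms()].
#' @return list with `delta_sd1` (list `angle_deg`, `distance`), `delta_sd2`
#'   (Angstrom) and `superposition` (the SD3/SD4 fit).
#' @details Centers of mass are computed over residues modeled in *both*
#'   chains within each subdomain, so unmodeled loops in one structure
#'   cannot masquerade as conformational change.
#' @export
delta_offsets <- function(query, reference, scheme = subdomain_scheme(),
                          weighting = c("mass", "geometric", "calpha")) {
  weighting <- match.arg(weighting)
  pq <- assign_subdomains(query, scheme)
  pr <- assign_subdomains(reference, scheme)
  common <- mapply(intersect, pq$residues, pr$residues, SIMPLIFY = FALSE)
  if (length(common$sd3) + length(common$sd4) < 3L) {
    stop("fewer than 3 common SD3/SD4 residues for the reference fit",
         call. = FALSE)
  }
  fit <- superpose_chains(query, reference,
                          fit_selection = c(common$sd3, common$sd4))
  qf <- apply_transform(query, fit)
  shared <- structure(list(residues = common,
                           coverage = lengths(common) / lengths(scheme),
                           chain_id = pq$chain_id),
                      class = "subdomain_partition")
  com_q <- function(sd) subdomain_com(qf, shared, sd, weighting)
  com_r <- function(sd) subdomain_com(reference, shared, sd, weighting)
  d_sd2 <- vnorm(com_q("sd2") - com_r("sd2"))
  c1q <- com_q("sd1"); c1r <- com_r("sd1"); c3 <- com_r("sd3")
  d_sd1 <- vnorm(c1q - c1r)
  ang <- if (d_sd1 < 1e-9) 0 else {
    u <- unitv(c1q - c3); v <- unitv(c1r - c3)
    acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  }
  list(delta_sd1 = list(angle_deg = ang, distance = d_sd1),
       delta_sd2 = d_sd2, superposition = fit)
}

#' W-loop gate metrics
#'
#' Measures the two distances that report on the W-loop and its gate: the
#' Tyr143 Calpha to Tyr169 Calpha distance (W-loop position) and the Tyr143
#' side-chain hydroxyl (OH) to Gly168 carbonyl oxygen (O) distance (the
#' gate's hydrogen bond). The gate is called closed at or below
#' `closed_max` (default 5 Angstrom, accommodating observed closed states up
#' to ~4.1), open at or above `open_min` (default 8, the lower edge of the
#' observed open range of 8-12), and intermediate between.
#'
#' @param chain a `chain_model` containing residues 143 (CA, OH), 168 (O)
#'   and 169 (CA); a missing atom raises an error naming it.
#' @param closed_max,open_min gate-state thresholds in Angstrom.
#' @return list with `d_y143ca_y169ca`, `d_y143oh_g168o` (Angstrom) and
#'   `gate_state` in `{"closed", "open", "intermediate"}`.
#' @export
wloop_gate <- function(chain, closed_max = 5, open_min = 8) {
  stopifnot(closed_max < open_min)
  ca143 <- get_atom(chain, 143L, "CA", context = "W-loop gate")
  oh143 <- get_atom(chain, 143L, "OH", context = "W-loop gate")
  o168 <- get_atom(chain, 168L, "O", context = "W-loop gate")
  ca169 <- get_atom(chain, 169L, "CA", context = "W-loop gate")
  d_gate <- vnorm(oh143 - o168)
  d_ca <- vnorm(ca143 - ca169)
  state <- if (d_gate <= closed_max) "closed" else if (d_gate >= open_min) "open" else "intermediate"
  list(d_y143ca_y169ca = d_ca, d_y143oh_g168o = d_gate, gate_state = state)
}

#' Lateral helix engagement
#'
#' Tests whether the mobile SD1 helix of one subunit engages the static SD4
#' helix of a lateral neighbour: the main-chain nitrogen of Lys113 (chain
#' `a`) within hydrogen-bonding distance (< 4 Angstrom, strict) of the
#' carbonyl oxygen of Glu195 (chain `b`).
#'
#' @param a chain providing Lys113 N.
#' @param b chain providing Glu195 O.
#' @param cutoff engagement cutoff in Angstrom (default 4, strict `<`).
#' @return list with `d_k113n_e195o` (Angstrom) and `engaged` (logical).
#' @export
helix_engagement <- function(a, b, cutoff = 4) {
  n113 <- get_atom(a, 113L, "N", context = "helix engagement")
  o195 <- get_atom(b, 195L, "O", context = "helix engagement")
  d <- vnorm(n113 - o195)
  list(d_k113n_e195o = d, engaged = d < cutoff)
}

#' Tilt and probe displacement of a nucleus subunit against a filament
#'
#' Superposes a nucleus structure onto a filament reference through an
#' anchor subunit (all common Calpha), then measures how a second (probe)
#' subunit deviates from its filament position: the displacement of a named
#' probe atom (default Asp244 Calpha, in SD4) and the residual rigid-body
#' rotation (tilt) of the whole probe chain.
#'
#' @param nucleus,filament `actin_structure` objects (frame 1 is used).
#' @param anchor_chains length-2 character vector: the anchor chain id in
#'   the nucleus and its counterpart in the filament.
#' @param probe_chains length-2 character vector: probe chain ids in nucleus
#'   and filament.
#' @param probe_resno author residue number of the probe atom (default 244).
#' @param probe_atom probe atom name (default `"CA"`).
#' @return object of class `tilt_result`: list with `tilt_deg`,
#'   `displacement` (Angstrom), `anchor_fit` and `probe_fit`
#'   (`superposition` objects).
#' @export
tilt_displacement <- function(nucleus, filament, anchor_chains, probe_chains,
                              probe_resno = 244L, probe_atom = "CA") {
  stopifnot(length(anchor_chains) == 2L, length(probe_chains) == 2L)
  anc_n <- select_chain(nucleus, anchor_chains[[1L]])
  anc_f <- select_chain(filament, anchor_chains[[2L]])
  prb_n <- select_chain(nucleus, probe_chains[[1L]])
  prb_f <- select_chain(filament, probe_chains[[2L]])
  anchor_fit <- superpose_chains(anc_n, anc_f)
  prb_nf <- apply_transform(prb_n, anchor_fit)
  p_n <- get_atom(prb_nf, probe_resno, probe_atom, context = "tilt probe")
  p_f <- get_atom(prb_f, probe_resno, probe_atom, context = "tilt probe")
  m <- match_residues(prb_nf, prb_f)
  probe_fit <- kabsch_fit(m$P, m$Q)
  structure(list(tilt_deg = rotation_angle(probe_fit$rotation),
                 displacement = vnorm(p_n - p_f),
                 anchor_fit = anchor_fit, probe_fit = probe_fit),
            class = "tilt_result")
}

#' @export
print.tilt_result <- function(x, ...) {
  cat(sprintf("tilt_result: tilt %.2f deg, probe displacement %.2f A (anchor rmsd %.3f A over %d CA)\n",
              x$tilt_deg, x$displacement, x$anchor_fit$rmsd,
              x$anchor_fit$n_matched))
  invisible(x)
}

#' All conformational metrics for one subunit
#'
#' Convenience wrapper assembling the flattening dihedral, its G/F
#' classification, the W-loop gate metrics, and (when references are given)
#' the SD1/SD2 offsets against G- and F-actin.
#'
#' @param chain a `chain_model`.
#' @param ref_g,ref_f optional reference `chain_model`s (twisted G-actin and
#'   flattened F-actin).
#' @param config analysis parameters, see [default_config()].
#' @return object of class `conformer_metrics` (named list; `NA` entries for
#'   metrics whose reference was not supplied).
#' @export
#' @examples
#' ch <- select_chain(make_conformer(phi = -8.1), "A")
#' conformer_metrics(ch)
conformer_metrics <- function(chain, ref_g = NULL, ref_f = NULL,
                              config = default_config()) {
  phi <- flattening_dihedral(chain, weighting = config$com_weighting)
  gate <- wloop_gate(chain, closed_max = config$gate_closed_max,
                     open_min = config$gate_open_min)
  out <- list(
    chain_id = attr(chain, "chain_id"),
    phi_sd1_sd4 = phi,
    conformer_class = classify_conformer(phi, config$f_threshold,
                                         config$g_threshold),
    d_y143ca_y169ca = gate$d_y143ca_y169ca,
    d_y143oh_g168o = gate$d_y143oh_g168o,
    gate_state = gate$gate_state,
    delta_sd2_g = NA_real_, delta_sd1_g_deg = NA_real_,
    delta_sd1_g = NA_real_,
    delta_sd2_f = NA_real_, delta_sd1_f_deg = NA_real_,
    delta_sd1_f = NA_real_
  )
  if (!is.null(ref_g)) {
    d <- delta_offsets(chain, ref_g, weighting = config$com_weighting)
    out$delta_sd2_g <- d$delta_sd2
    out$delta_sd1_g_deg <- d$delta_sd1$angle_deg
    out$delta_sd1_g <- d$delta_sd1$distance
  }
  if (!is.null(ref_f)) {
    d <- delta_offsets(chain, ref_f, weighting = config$com_weighting)
    out$delta_sd2_f <- d$delta_sd2
    out$delta_sd1_f_deg <- d$delta_sd1$angle_deg
    out$delta_sd1_f <- d$delta_sd1$distance
  }
  structure(out, class = "conformer_metrics")
}

#' @export
print.conformer_metrics <- function(x, ...) {
  cat("conformer_metrics, chain '", x$chain_id, "':\n", sep = "")
  cat(sprintf("  phi SD1-SD4      %8.2f deg  (%s)\n", x$phi_sd1_sd4,
              x$conformer_class))
  cat(sprintf("  Y143 CA-Y169 CA  %8.2f A\n", x$d_y143ca_y169ca))
  cat(sprintf("  Y143 OH-G168 O   %8.2f A    (gate %s)\n", x$d_y143oh_g168o,
              x$gate_state))
  if (!is.na(x$delta_sd2_g)) {
    cat(sprintf("  dSD2 vs G-actin  %8.2f A;  dSD1 %.2f A / %.2f deg\n",
                x$delta_sd2_g, x$delta_sd1_g, x$delta_sd1_g_deg))
  }
  if (!is.na(x$delta_sd2_f)) {
    cat(sprintf("  dSD2 vs F-actin  %8.2f A;  dSD1 %.2f A / %.2f deg\n",
                x$delta_sd2_f, x$delta_sd1_f, x$delta_sd1_f_deg))
  }
  invisible(x)
}
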