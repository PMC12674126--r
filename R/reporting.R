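# Assembled reports: per-subunit metrics tables with the pairwise RMSD
# matrix, trajectory summaries, and fixture simulation with a manifest.

#' Default analysis configuration
#'
#' All tunable thresholds and parameters in one place. Defaults:
#' gate closed at <= 5 Angstrom and open at >= 8 (bracketing observed closed
#' states up to ~4.1 and the 8-12 open range); G/F classification thresholds
#' -14/-12 degrees (inside the gap between observed G-like and F-like
#' dihedral ranges); mass-weighted all-atom centers of mass; 1.4 Angstrom
#' probe and 960 lattice points for surface areas; trajectory open threshold
#' 8 Angstrom.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters.
#' @export
#' @examples
#' default_config(gate_open_min = 9)$gate_open_min
default_config <- function(...) {
  cfg <- list(
    gate_closed_max = 5,
    gate_open_min = 8,
    f_threshold = -12,
    g_threshold = -14,
    com_weighting = "mass",
    probe_radius = 1.4,
    sasa_points = 960,
    traj_open_threshold = 8,
    trim = "none"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Conformational metrics table over a set of subunits
#'
#' Runs the full per-subunit analysis (flattening dihedral, classification,
#' gate metrics, SD1/SD2 offsets against optional references), the pairwise
#' all-common-Calpha RMSD matrix with matched counts, and optional interface
#' buried areas, over a named set of chains. Roles are explicit — chains are
#' supplied under the names you want in the table, never guessed from the
#' file.
#'
#' @param chains named list of `chain_model` objects; names are the subunit
#'   roles (e.g. `A1`, `A2`, `A3`).
#' @param ref_g,ref_f optional reference `chain_model`s (twisted G-actin,
#'   flattened F-actin) for the offset columns.
#' @param interface_pairs optional list of length-2 character vectors of
#'   role names whose interface buried area should be computed.
#' @param config analysis parameters, see [default_config()].
#' @param out_dir if given, writes `metrics.tsv`, `rmsd.tsv` and
#'   `report.json` there (deterministic content for fixed inputs).
#' @return object of class `metrics_table`: list with `metrics` (data
#'   frame, one row per role), `rmsd` and `n_matched` (matrices),
#'   `interfaces` (data frame or NULL) and `config`.
#' @export
analyze_structures <- function(chains, ref_g = NULL, ref_f = NULL,
                               interface_pairs = NULL,
                               config = default_config(), out_dir = NULL) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  roles <- names(chains)
  if (is.null(roles) || any(!nzchar(roles))) {
    stop("chains must be a *named* list of chain models (names are roles)",
         call. = FALSE)
  }
  rows <- lapply(roles, function(r) {
    m <- conformer_metrics(chains[[r]], ref_g = ref_g, ref_f = ref_f,
                           config = config)
    data.frame(role = r, phi_sd1_sd4 = m$phi_sd1_sd4,
               conformer_class = m$conformer_class,
               d_y143ca_y169ca = m$d_y143ca_y169ca,
               d_y143oh_g168o = m$d_y143oh_g168o,
               gate_state = m$gate_state,
               delta_sd2_g = m$delta_sd2_g, delta_sd1_g = m$delta_sd1_g,
               delta_sd1_g_deg = m$delta_sd1_g_deg,
               delta_sd2_f = m$delta_sd2_f, delta_sd1_f = m$delta_sd1_f,
               delta_sd1_f_deg = m$delta_sd1_f_deg,
               stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  n <- length(roles)
  rmsd <- matrix(0, n, n, dimnames = list(roles, roles))
  nmat <- matrix(NA_integer_, n, n, dimnames = list(roles, roles))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) next
      if (i == j) {
        nmat[i, j] <- match_residues(chains[[i]], chains[[i]])$n_matched
        next
      }
      fit <- superpose_chains(chains[[i]], chains[[j]], trim = config$trim)
      rmsd[i, j] <- rmsd[j, i] <- fit$rmsd
      nmat[i, j] <- nmat[j, i] <- fit$n_matched
    }
  }
  interfaces <- NULL
  if (!is.null(interface_pairs)) {
    interfaces <- do.call(rbind, lapply(interface_pairs, function(p) {
      stopifnot(length(p) == 2L, all(p %in% roles))
      ba <- buried_area(chains[[p[1L]]], chains[[p[2L]]],
                        probe_radius = config$probe_radius,
                        n_points = config$sasa_points)
      data.frame(chain_a = p[1L], chain_b = p[2L],
                 buried_area = ba$buried_area, stringsAsFactors = FALSE)
    }))
  }
  out <- structure(list(metrics = metrics, rmsd = rmsd, n_matched = nmat,
                        interfaces = interfaces, config = config),
                   class = "metrics_table")
  if (!is.null(out_dir)) write_metrics_table(out, out_dir)
  out
}

write_metrics_table <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(format(x$metrics, digits = 6, trim = TRUE),
                     file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rm <- data.frame(role = rownames(x$rmsd), round(x$rmsd, 4),
                   check.names = FALSE)
  utils::write.table(rm, file.path(out_dir, "rmsd.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(x$interfaces)) {
    utils::write.table(format(x$interfaces, digits = 6, trim = TRUE),
                       file.path(out_dir, "interfaces.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(metrics = x$metrics, rmsd = as.data.frame(x$rmsd),
         n_matched = as.data.frame(x$n_matched),
         interfaces = x$interfaces, config = x$config),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(out_dir)
}

#' @export
print.metrics_table <- function(x, ...) {
  cat("metrics_table:", nrow(x$metrics), "subunit(s)\n")
  print(format(x$metrics[, c("role", "phi_sd1_sd4", "conformer_class",
                             "d_y143oh_g168o", "gate_state")],
               digits = 4), row.names = FALSE)
  cat("pairwise RMSD (A):\n")
  print(round(x$rmsd, 2))
  if (!is.null(x$interfaces)) {
    cat("interfaces:\n")
    print(format(x$interfaces, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Trajectory gate report
#'
#' Extracts the gate time series for one chain of a multi-model structure
#' (or a trajectory file path) and summarizes the open fraction.
#'
#' @param traj an `actin_structure` or a path to a multi-model PDB/mmCIF.
#' @param chain_id chain to analyze.
#' @param threshold open threshold in Angstrom (default from
#'   [default_config()]).
#' @param out_dir if given, writes `gate_series.tsv` and
#'   `gate_summary.json` there.
#' @return list with `series` ([gate_timeseries()]) and `summary`
#'   ([open_fraction()]).
#' @export
trajectory_report <- function(traj, chain_id,
                              threshold = default_config()$traj_open_threshold,
                              out_dir = NULL) {
  if (is.character(traj)) traj <- read_structure(traj)
  series <- gate_timeseries(traj, chain_id)
  summary <- open_fraction(series, threshold = threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(format(as.data.frame(series), digits = 6, trim = TRUE),
                       file.path(out_dir, "gate_series.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(summary),
                         file.path(out_dir, "gate_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(series = series, summary = summary)
}

#' Simulate fixture files from a specification
#'
#' Writes synthetic PDB fixtures described by a specification list (or a
#' JSON file holding one) and a manifest recording the seeds, targets and
#' the analyzer-measured dihedral of every conformer, so fixtures are fully
#' reproducible and self-checking.
#'
#' @param spec a list (or path to a JSON file) with any of the elements:
#'   `conformers` (list of argument lists for [make_conformer()]),
#'   `trajectory` (argument list for [make_gate_trajectory()]),
#'   `twist` (argument list for [twist_series()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
simulate_fixtures <- function(spec, out_dir) {
  if (is.character(spec)) spec <- jsonlite::read_json(spec, simplifyVector = TRUE)
  stopifnot(is.list(spec))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(files = list())
  add <- function(entry) manifest$files[[length(manifest$files) + 1L]] <<- entry
  if (!is.null(spec$conformers)) {
    for (i in seq_along(spec$conformers)) {
      args <- as.list(spec$conformers[[i]])
      s <- do.call(make_conformer, args)
      f <- file.path(out_dir, sprintf("conformer_%02d.pdb", i))
      write_pdb(s, f)
      add(list(file = basename(f), kind = "conformer", args = args,
               phi_target = attr(s, "phi_target"),
               phi_measured = flattening_dihedral(select_chain(s, args$chain_id %||% "A"))))
    }
  }
  if (!is.null(spec$trajectory)) {
    args <- as.list(spec$trajectory)
    s <- do.call(make_gate_trajectory, args)
    f <- file.path(out_dir, "gate_trajectory.pdb")
    write_pdb(s, f)
    add(list(file = basename(f), kind = "trajectory", args = args,
             n_frames = n_frames(s),
             true_open_fraction = mean(attr(s, "states"))))
  }
  if (!is.null(spec$twist)) {
    args <- as.list(spec$twist)
    series <- do.call(twist_series, args)
    for (i in seq_along(series)) {
      f <- file.path(out_dir, sprintf("twist_%02d.pdb", i))
      write_pdb(series[[i]], f)
      add(list(file = basename(f), kind = "twist",
               phi_target = attr(series[[i]], "phi_target")))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
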