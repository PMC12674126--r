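# Per-frame metric extraction from multi-model structures and the counting
# statistics summarizing them.

#' W-loop gate distance time series
#'
#' Extracts the two W-loop distances ([wloop_gate()]) for one chain from
#' every frame of a multi-model structure. A frame with a missing gate atom
#' aborts with an error naming the frame, rather than being skipped — silent
#' frame-dropping would bias open-fraction statistics.
#'
#' @param traj an `actin_structure` (typically multi-frame).
#' @param chain_id chain to analyze.
#' @return object of class `gate_timeseries`: data frame with columns
#'   `frame`, `d_gate` (Tyr143 OH - Gly168 O, Angstrom) and `d_ca`
#'   (Tyr143 CA - Tyr169 CA, Angstrom); attribute `chain_id`.
#' @export
gate_timeseries <- function(traj, chain_id) {
  nf <- n_frames(traj)
  d_gate <- numeric(nf); d_ca <- numeric(nf)
  for (f in seq_len(nf)) {
    g <- tryCatch(wloop_gate(select_chain(traj, chain_id, frame = f)),
                  error = function(e) {
                    stop("frame ", f, ": ", conditionMessage(e), call. = FALSE)
                  })
    d_gate[f] <- g$d_y143oh_g168o
    d_ca[f] <- g$d_y143ca_y169ca
  }
  structure(data.frame(frame = seq_len(nf), d_gate = d_gate, d_ca = d_ca),
            class = c("gate_timeseries", "data.frame"), chain_id = chain_id)
}

#' Gate open fraction
#'
#' Counting statistic over a gate time series: the fraction of frames whose
#' gate distance is at or above the open threshold.
#'
#' @param series a [gate_timeseries()] (or any data frame with a `d_gate`
#'   column).
#' @param threshold open threshold in Angstrom (default 8, the lower edge of
#'   the observed open-gate range).
#' @return object of class `gate_summary`: list with `open_fraction`,
#'   `n_frames`, `threshold`.
#' @export
open_fraction <- function(series, threshold = 8) {
  d <- series$d_gate
  if (is.null(d) || length(d) == 0L) {
    stop("empty gate series", call. = FALSE)
  }
  structure(list(open_fraction = mean(d >= threshold),
                 n_frames = length(d), threshold = threshold),
            class = "gate_summary")
}

#' @export
print.gate_summary <- function(x, ...) {
  cat(sprintf("gate_summary: open fraction %.3f over %d frames (threshold %.1f A)\n",
              x$open_fraction, x$n_frames, x$threshold))
  invisible(x)
}

#' @export
print.gate_timeseries <- function(x, ...) {
  cat(sprintf("gate_timeseries, chain '%s': %d frames, d_gate %.2f-%.2f A\n",
              attr(x, "chain_id"), nrow(x), min(x$d_gate), max(x$d_gate)))
  invisible(x)
}

#' Plot a gate time series
#'
#' Trace of the gate distance (red) and the W-loop Calpha-Calpha width
#' (blue) against frame index, with the open threshold as a dashed line.
#'
#' @param x a [gate_timeseries()].
#' @param threshold open threshold drawn as a guide (default 8 Angstrom).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.gate_timeseries <- function(x, threshold = 8, ...) {
  graphics::plot(x$frame, x$d_gate, type = "l", col = "red3",
                 xlab = "frame", ylab = "distance (Å)",
                 ylim = range(c(x$d_gate, x$d_ca, threshold)), ...)
  graphics::lines(x$frame, x$d_ca, col = "blue3")
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  graphics::legend("topright", legend = c("Y143 OH - G168 O (gate)",
                                          "Y143 CA - Y169 CA"),
                   col = c("red3", "blue3"), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Probe displacement time series after per-frame anchor superposition
#'
#' For every frame: Kabsch-fit the anchor chain onto its counterpart in a
#' reference structure, apply that fit to the probe atom, and record its
#' distance to the probe atom's reference position. This is the standard way
#' of tracking how far a nucleus subunit sits from its filament position
#' along a trajectory.
#'
#' @param traj an `actin_structure` (multi-frame).
#' @param anchor_chain anchor chain id in the trajectory.
#' @param reference reference `actin_structure` (frame 1 used).
#' @param probe_chain probe chain id in the trajectory.
#' @param ref_anchor_chain,ref_probe_chain counterpart chain ids in the
#'   reference (default: same as in the trajectory).
#' @param probe_resno,probe_atom the probe atom (default Asp244 Calpha).
#' @return object of class `displacement_series`: data frame with columns
#'   `frame`, `displacement` (Angstrom).
#' @export
displacement_timeseries <- function(traj, anchor_chain, reference,
                                    probe_chain,
                                    ref_anchor_chain = anchor_chain,
                                    ref_probe_chain = probe_chain,
                                    probe_resno = 244L, probe_atom = "CA") {
  ref_anc <- select_chain(reference, ref_anchor_chain)
  ref_prb <- select_chain(reference, ref_probe_chain)
  p_ref <- get_atom(ref_prb, probe_resno, probe_atom,
                    context = "displacement probe (reference)")
  nf <- n_frames(traj)
  disp <- numeric(nf)
  for (f in seq_len(nf)) {
    res <- tryCatch({
      anc <- select_chain(traj, anchor_chain, frame = f)
      prb <- select_chain(traj, probe_chain, frame = f)
      fit <- superpose_chains(anc, ref_anc)
      p <- get_atom(apply_transform(prb, fit), probe_resno, probe_atom,
                    context = "displacement probe")
      vnorm(p - p_ref)
    }, error = function(e) {
      stop("frame ", f, ": ", conditionMessage(e), call. = FALSE)
    })
    disp[f] <- res
  }
  structure(data.frame(frame = seq_len(nf), displacement = disp),
            class = c("displacement_series", "data.frame"))
}
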