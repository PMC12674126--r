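# Coordinate-file I/O and the chain/residue/atom data model used by every
# analysis stage. Parsing is delegated to bio3d; the writer is local because
# trajectory output needs one MODEL block per frame.

#' Read a coordinate file into a structure model
#'
#' Parses a PDB or mmCIF file into an `actin_structure`: a flat atom table
#' (author numbering, altlocs retained, ATOM/HETATM flagged) plus a list of
#' coordinate frames. Multi-MODEL PDB files become multi-frame structures, so
#' the same object carries both single crystal structures and trajectories.
#'
#' @param path path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension, falling back
#'   to content sniffing).
#' @param id identifier stored on the structure; defaults to the file name.
#' @return an object of class `actin_structure` with elements
#'   \describe{
#'     \item{id}{identifier.}
#'     \item{atoms}{data frame with columns `type` (ATOM/HETATM), `eleno`,
#'       `elety` (atom name), `alt`, `resid` (3-letter residue name),
#'       `chain`, `resno` (author number), `insert`, `o` (occupancy),
#'       `elesy` (element).}
#'     \item{frames}{list of N x 3 coordinate matrices, one per model.}
#'   }
#' @details Hetero records (ions, nucleotide, waters) are kept in the atom
#'   table but flagged, and are excluded by [select_chain()] so they never
#'   enter protein metrics. If the number of parsed atoms disagrees with the
#'   number of ATOM/HETATM records in the file a warning reports the
#'   difference, so records are never dropped silently.
#' @seealso [select_chain()], [write_pdb()], [resolve_altlocs()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb" else {
      head <- readLines(path, n = 20L, warn = FALSE)
      if (any(startsWith(head, "data_")) || any(grepl("^_atom_site", head))) "mmcif" else "pdb"
    }
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      # bio3d tags read.cif as beta and warns about SSE records we never use
      withCallingHandlers(
        bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
        warning = function(w) {
          if (grepl("beta version|helix/sheet", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    },
    error = function(e) stop("parse error reading ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  atoms <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  })
  keep <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
            "insert", "o", "elesy")
  for (k in setdiff(keep, names(atoms))) atoms[[k]] <- NA
  atoms <- atoms[, keep]
  atoms$o[is.na(atoms$o)] <- 1
  blank <- is.na(atoms$elesy) | !nzchar(trimws(atoms$elesy))
  if (any(blank)) atoms$elesy[blank] <- guess_element(atoms$elety[blank])
  atoms$elesy <- toupper(trimws(atoms$elesy))
  s <- structure(
    list(id = id %||% basename(path), atoms = atoms, frames = frames),
    class = "actin_structure"
  )
  if (format == "pdb") {
    n_rec <- length(grep("^(ATOM  |HETATM)", readLines(path, warn = FALSE)))
    n_parsed <- nrow(atoms) * length(frames)
    if (n_rec != n_parsed) {
      warning(n_rec - n_parsed, " coordinate record(s) in '", basename(path),
              "' not represented after parsing (", n_rec, " in file, ",
              n_parsed, " parsed)", call. = FALSE)
    }
    attr(s, "n_file_records") <- n_rec
  }
  s
}

#' Construct a structure model from parts
#'
#' Low-level constructor used by the synthetic-conformer generator and by
#' tests; checks the atom-table invariants.
#'
#' @param atoms atom data frame (see [read_structure()] for columns; missing
#'   optional columns are filled with defaults).
#' @param frames list of N x 3 coordinate matrices, all with
#'   `N == nrow(atoms)`.
#' @param id identifier.
#' @return an `actin_structure`.
#' @export
new_structure <- function(atoms, frames, id = "synthetic") {
  atoms <- fill_atom_defaults(atoms)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    stopifnot(ncol(f) == 3L)
    if (nrow(f) != nrow(atoms)) {
      stop("frame has ", nrow(f), " rows but atom table has ", nrow(atoms),
           call. = FALSE)
    }
    if (!all(is.finite(f))) stop("non-finite coordinates", call. = FALSE)
    dimnames(f) <- NULL
    f
  })
  structure(list(id = id, atoms = atoms, frames = frames),
            class = "actin_structure")
}

fill_atom_defaults <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  stopifnot(all(c("elety", "resno") %in% names(atoms)))
  atoms$type <- atoms$type %||% rep("ATOM", n)
  atoms$eleno <- atoms$eleno %||% seq_len(n)
  atoms$alt <- atoms$alt %||% rep(NA_character_, n)
  atoms$resid <- atoms$resid %||% rep("ALA", n)
  atoms$chain <- atoms$chain %||% rep("A", n)
  atoms$insert <- atoms$insert %||% rep(NA_character_, n)
  atoms$o <- atoms$o %||% rep(1, n)
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  if (any(atoms$o < 0 | atoms$o > 1)) {
    stop("occupancy outside [0, 1]", call. = FALSE)
  }
  cols <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
            "insert", "o", "elesy")
  atoms[, cols]
}

#' @export
print.actin_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("actin_structure '", x$id, "': ", length(x$frames), " frame(s), ",
      length(ch), " chain(s) [", paste(ch, collapse = ", "), "], ",
      nrow(x$atoms), " atoms (", sum(x$atoms$type == "HETATM"),
      " hetero)\n", sep = "")
  invisible(x)
}

#' Number of frames in a structure
#' @param structure an `actin_structure`.
#' @return integer frame count.
#' @export
n_frames <- function(structure) length(structure$frames)

#' Extract one protein chain from a structure frame
#'
#' Returns a `chain_model`: the polymer (ATOM) records of one chain in one
#' frame, with waters and hetero groups excluded, ordered by author residue
#' number and insertion code. This is the unit all conformational metrics
#' operate on.
#'
#' @param structure an `actin_structure`.
#' @param chain_id chain identifier.
#' @param frame 1-based frame index (default 1).
#' @return a `chain_model` (data frame with atom columns plus `x`, `y`, `z`,
#'   `mass`; attributes `chain_id` and `frame`).
#' @export
select_chain <- function(structure, chain_id, frame = 1L) {
  stopifnot(inherits(structure, "actin_structure"))
  if (frame < 1L || frame > length(structure$frames)) {
    stop("frame ", frame, " out of range (structure has ",
         length(structure$frames), " frame(s))", call. = FALSE)
  }
  at <- structure$atoms
  avail <- unique(at$chain[at$type == "ATOM"])
  if (!chain_id %in% avail) {
    stop("chain '", chain_id, "' not found; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  sel <- which(at$chain == chain_id & at$type == "ATOM" &
                 !(at$resid %in% c("HOH", "WAT", "DOD")))
  atoms <- at[sel, , drop = FALSE]
  xyz <- structure$frames[[frame]][sel, , drop = FALSE]
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  new_chain_model(atoms, chain_id = chain_id, frame = as.integer(frame))
}

#' Construct a chain model
#'
#' Low-level constructor used by [select_chain()], the generator, and tests.
#' Atoms are ordered by (author residue number, insertion code) and per-atom
#' masses are attached.
#'
#' @param atoms data frame with at least `elety`, `resno`, `x`, `y`, `z`;
#'   optional `alt`, `insert`, `resid`, `o`, `elesy` are defaulted.
#' @param chain_id chain identifier stored as an attribute.
#' @param frame frame index stored as an attribute.
#' @return object of class `chain_model`.
#' @export
new_chain_model <- function(atoms, chain_id = "A", frame = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("elety", "resno", "x", "y", "z") %in% names(atoms)))
  xyz <- atoms[, c("x", "y", "z")]
  atoms$x <- NULL; atoms$y <- NULL; atoms$z <- NULL
  atoms <- fill_atom_defaults(atoms)
  atoms$x <- xyz$x; atoms$y <- xyz$y; atoms$z <- xyz$z
  if (!all(is.finite(as.matrix(xyz)))) {
    stop("non-finite coordinates in chain model", call. = FALSE)
  }
  atoms$mass <- element_mass(atoms$elesy)
  key_ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
  atoms <- atoms[order(atoms$resno, key_ins), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(atoms, class = c("chain_model", "data.frame"),
            chain_id = chain_id, frame = frame)
}

#' @export
print.chain_model <- function(x, ...) {
  cat("chain_model '", attr(x, "chain_id"), "' (frame ", attr(x, "frame"),
      "): ", length(unique(x$resno)), " residues, ", nrow(x), " atoms, ",
      "residues ", min(x$resno), "-", max(x$resno), "\n", sep = "")
  invisible(x)
}

#' Coordinates of a chain model
#' @param chain a `chain_model`.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(chain) {
  unname(as.matrix(as.data.frame(chain)[, c("x", "y", "z")]))
}

# Coordinates of one named atom; errors name the atom, which the gate
# metrics rely on for diagnosable failures.
get_atom <- function(chain, resno, elety, context = NULL) {
  i <- which(chain$resno == resno & trimws(chain$elety) == elety)
  if (length(i) == 0L) {
    stop(if (!is.null(context)) paste0(context, ": ") else "",
         "missing atom ", elety, " of residue ", resno,
         " in chain '", attr(chain, "chain_id"), "'", call. = FALSE)
  }
  if (length(i) > 1L) i <- i[1L]  # altlocs: caller resolves; first by order
  c(chain$x[i], chain$y[i], chain$z[i])
}

#' Collapse alternate locations to a single conformation
#'
#' Keeps exactly one atom per (residue, atom name). `highest_occupancy`
#' takes the highest-occupancy altloc, ties broken by altloc letter order;
#' `prefer_A` takes altloc A (or the alphabetically first present).
#' Chains without altlocs are returned unchanged.
#'
#' @param chain a `chain_model`.
#' @param policy `"highest_occupancy"` (default) or `"prefer_A"`.
#' @return a `chain_model` with no duplicated atoms.
#' @export
resolve_altlocs <- function(chain, policy = c("highest_occupancy", "prefer_A")) {
  policy <- match.arg(policy)
  alt <- ifelse(is.na(chain$alt), "", trimws(chain$alt))
  if (!any(nzchar(alt))) return(chain)
  key <- paste(chain$resno, ifelse(is.na(chain$insert), "", chain$insert),
               trimws(chain$elety), sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(chain)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    a <- alt[idx]
    if (policy == "prefer_A") {
      idx[order(a)][1L]
    } else {
      occ <- chain$o[idx]
      idx[order(-occ, a)][1L]
    }
  }), use.names = FALSE)
  out <- chain[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(chain), chain_id = attr(chain, "chain_id"),
            frame = attr(chain, "frame"))
}

#' Write a structure to a PDB file
#'
#' Writes fixed-width PDB v3.3 records; multi-frame structures get one
#' MODEL/ENDMDL block per frame. Coordinates round-trip through
#' [read_structure()] to the format's 3-decimal precision.
#'
#' @param structure an `actin_structure`.
#' @param path output file path.
#' @return invisibly, the path.
#' @details Residue numbers above 9999 and atom serials above 99999 do not
#'   fit the fixed-width columns and are refused with an error rather than
#'   written corrupted.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "actin_structure"))
  at <- structure$atoms
  if (any(at$resno > 9999L | at$resno < -999L)) {
    stop("residue number outside the PDB fixed-width range (-999..9999); ",
         "refusing to write", call. = FALSE)
  }
  eleno <- at$eleno
  if (any(eleno > 99999L)) eleno <- seq_len(nrow(at))
  name4 <- vapply(trimws(at$elety), function(nm) {
    if (nchar(nm) >= 4L) substr(nm, 1L, 4L) else sprintf("%-4s", paste0(" ", nm))
  }, character(1L))
  alt <- ifelse(is.na(at$alt), " ", substr(at$alt, 1L, 1L))
  ins <- ifelse(is.na(at$insert), " ", substr(at$insert, 1L, 1L))
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), " ",
                  substr(at$chain, 1L, 1L))
  con <- file(path, open = "wt")
  on.exit(close(con))
  multi <- length(structure$frames) > 1L
  for (f in seq_along(structure$frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    xyz <- structure$frames[[f]]
    lines <- sprintf(
      "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$type, eleno, name4, alt, substr(at$resid, 1L, 3L), chain,
      at$resno, ins, xyz[, 1L], xyz[, 2L], xyz[, 3L], at$o, 0,
      sprintf("%2s", at$elesy))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
#' @rdname write_pdb
#' @param x object to write (alias kept for symmetry with `read_structure`).
write_structure <- function(x, path) write_pdb(x, path)
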