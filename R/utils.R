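# Element tables and small vector helpers shared across modules.

# Standard atomic masses (u) for elements commonly found in protein models.
.ATOMIC_MASS <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  NA. = 22.990, MG = 24.305, P = 30.974, S = 32.06, CL = 35.45, K = 39.098,
  CA = 40.078, MN = 54.938, FE = 55.845, ZN = 65.38, SE = 78.971, BR = 79.904,
  I = 126.904
)

# van der Waals radii (Angstrom) used for SASA; others fall back to 1.80.
.VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.VDW_DEFAULT <- 1.80

#' Atomic mass lookup
#'
#' Returns standard atomic masses for element symbols. Unknown symbols fall
#' back to the mass of carbon (12.011 u) with a warning, so that pseudo-atom
#' fixtures and exotic elements never abort an analysis.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in atomic mass units.
#' @export
#' @examples
#' element_mass(c("C", "O", "N"))
element_mass <- function(element) {
  key <- toupper(trimws(as.character(element)))
  key[key == "NA"] <- "NA."   # sodium; avoid clash with missing values
  m <- .ATOMIC_MASS[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    bad <- unique(key[unknown])
    bad <- bad[!is.na(bad) & nzchar(bad)]
    if (length(bad)) {
      warning("unknown element(s) ", paste(bad, collapse = ", "),
              "; using carbon mass 12.011", call. = FALSE)
    }
    m[unknown] <- 12.011
  }
  unname(m)
}

#' @rdname element_mass
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(as.character(element)))
  r <- .VDW_RADIUS[key]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Guess the element symbol from a PDB atom name ("CA" -> C for protein
# ATOM records; two-letter symbols only arise in hetero records, which the
# protein metrics exclude).
guess_element <- function(elety) {
  nm <- gsub("[^A-Za-z].*$", "", trimws(elety))
  substr(toupper(nm), 1L, 1L)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: proper rotation by `angle_deg` degrees about the
#' direction `axis` (right-hand rule).
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis 3-vector giving the rotation axis direction.
#' @return 3x3 proper orthonormal matrix.
#' @export
rotation_matrix <- function(angle_deg, axis = c(0, 0, 1)) {
  u <- unitv(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Angle of a rotation matrix
#'
#' The magnitude of the rotation encoded by a proper rotation matrix,
#' recovered from its trace.
#'
#' @param R 3x3 rotation matrix.
#' @return angle in degrees, in \[0, 180\].
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Rigid-body transform
#'
#' Builds a rigid transform (proper rotation plus translation) from a
#' rotation about an axis through a given center, followed by a translation.
#' Applied as `x' = R x + t`.
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis rotation axis direction (3-vector).
#' @param center point the rotation axis passes through (3-vector, Angstrom).
#' @param translation translation applied after the rotation (3-vector).
#' @return an object of class `rigid_transform` with elements `rotation`
#'   (3x3) and `translation` (length 3).
#' @export
#' @examples
#' tr <- rigid_transform(90, axis = c(0, 0, 1))
#' apply_transform(matrix(c(1, 0, 0), 1), tr)
rigid_transform <- function(angle_deg = 0, axis = c(0, 0, 1),
                            center = c(0, 0, 0), translation = c(0, 0, 0)) {
  R <- rotation_matrix(angle_deg, axis)
  center <- as.numeric(center)
  t <- as.numeric(center - R %*% center) + as.numeric(translation)
  structure(list(rotation = R, translation = t), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or a chain
#'
#' @param x an N x 3 coordinate matrix or a [chain_model][new_chain_model].
#' @param transform a `rigid_transform`, or a list with elements `rotation`
#'   and `translation`.
#' @return object of the same kind as `x` with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  R <- transform$rotation
  t <- as.numeric(transform$translation)
  if (inherits(x, "chain_model")) {
    xyz <- coords(x) %*% t(R)
    xyz <- sweep(xyz, 2L, t, "+")
    x$x <- xyz[, 1L]; x$y <- xyz[, 2L]; x$z <- xyz[, 3L]
    return(x)
  }
  xyz <- as.matrix(x) %*% t(R)
  sweep(xyz, 2L, t, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
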