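# Explicit hydration shell on a face-centered cubic water lattice:
# build the lattice over the structure's bounding box, keep points within
# a distance window of the C-alpha trace, and scatter them with the
# whole-molecule water form factor.

#' Build a face-centered cubic water lattice
#'
#' Corner plus face-center points of every unit cell of edge `l_cell`
#' over a box, deduplicated where cells share corners/faces. In the bulk
#' each cell contributes 8*(1/8) + 6*(1/2) = 4 effective waters, so the
#' point density tends to 4 / l_cell^3.
#'
#' @param box Either a `saxs_structure` (its bounding box plus `margin` is
#'   used) or a 2 x 3 matrix `rbind(min, max)` of box corners, Angstrom.
#' @param l_cell Unit-cell edge length, Angstrom.
#' @param margin Padding added around a structure's bounding box,
#'   Angstrom (default 6.5, the outer shell cutoff).
#' @return A tibble of class `saxs_fcc` with columns `x`, `y`, `z` and
#'   attributes `l_cell`, `k` (cells per axis) and `origin`.
#' @export
build_fcc_lattice <- function(box, l_cell, margin = 6.5) {
  stopifnot(l_cell > 0)
  if (inherits(box, "saxs_structure") || is.data.frame(box)) {
    xyz <- coords(box)
    lo <- apply(xyz, 2, min) - margin
    hi <- apply(xyz, 2, max) + margin
  } else {
    lo <- box[1, ]; hi <- box[2, ]
  }
  if (any(hi <= lo)) stop("degenerate bounding box", call. = FALSE)
  k <- max(ceiling((hi - lo) / l_cell))
  ix <- 0:k
  # corners of all cells
  corners <- as.matrix(expand.grid(ix, ix, ix))
  # face centers: offsets (1/2,1/2,0) etc. within each of the k^3 cells,
  # including boundary faces
  cell <- as.matrix(expand.grid(0:(k - 1), 0:(k - 1), 0:(k - 1)))
  fc <- rbind(
    cbind(cell[, 1] + 0.5, cell[, 2] + 0.5, cell[, 3]),
    cbind(cell[, 1] + 0.5, cell[, 2] + 0.5, cell[, 3] + 1),
    cbind(cell[, 1] + 0.5, cell[, 2], cell[, 3] + 0.5),
    cbind(cell[, 1] + 0.5, cell[, 2] + 1, cell[, 3] + 0.5),
    cbind(cell[, 1], cell[, 2] + 0.5, cell[, 3] + 0.5),
    cbind(cell[, 1] + 1, cell[, 2] + 0.5, cell[, 3] + 0.5)
  )
  pts <- rbind(unname(corners), unname(fc)) * l_cell
  # deduplicate shared corner/face points on a 1e-6 A snap grid
  key <- paste(round(pts[, 1] / 1e-6), round(pts[, 2] / 1e-6),
               round(pts[, 3] / 1e-6))
  pts <- pts[!duplicated(key), , drop = FALSE]
  out <- tibble::tibble(x = pts[, 1] + lo[1], y = pts[, 2] + lo[2],
                        z = pts[, 3] + lo[3])
  class(out) <- c("saxs_fcc", class(tibble::tibble()))
  attr(out, "l_cell") <- l_cell
  attr(out, "k") <- k
  attr(out, "origin") <- lo
  out
}

#' Retain lattice waters in the hydration shell
#'
#' Keeps lattice points whose minimum distance to any C-alpha atom falls
#' in `shell_range` (default 3.5-6.5 Angstrom) and returns them as water
#' scatterers carrying the whole-molecule water form factor.
#'
#' @param lattice A `saxs_fcc` lattice.
#' @param structure A `saxs_structure` with at least one C-alpha atom.
#' @param shell_range Length-2 distance window, Angstrom.
#' @return A `saxs_structure` of shell waters (`is_water`, `is_shell`).
#' @export
filter_shell_waters <- function(lattice, structure,
                                shell_range = c(3.5, 6.5)) {
  ca <- structure[structure$is_calpha, , drop = FALSE]
  if (nrow(ca) == 0) {
    stop("structure has no C-alpha atoms; the shell filter needs a ",
         "C-alpha trace", call. = FALSE)
  }
  lp <- cbind(lattice$x, lattice$y, lattice$z)
  cxyz <- coords(ca)
  # min distance of each lattice point to the C-alpha set
  dmin <- rep(Inf, nrow(lp))
  for (i in seq_len(nrow(cxyz))) {
    d <- sqrt((lp[, 1] - cxyz[i, 1])^2 + (lp[, 2] - cxyz[i, 2])^2 +
                (lp[, 3] - cxyz[i, 3])^2)
    dmin <- pmin(dmin, d)
  }
  keep <- dmin >= shell_range[1] & dmin <= shell_range[2]
  pts <- lp[keep, , drop = FALSE]
  w <- saxs_structure(
    element = rep("O", nrow(pts)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    atom_name = "O", res_name = "HOH",
    res_id = seq_len(nrow(pts)), chain = "W",
    is_water = TRUE, is_shell = TRUE,
    identifier = "fcc-shell-waters"
  )
  w
}

#' Hydration-shell electron-density contrast
#'
#' Each FCC cell carries 4 effective waters x 10 electrons = 40 electrons,
#' so the excess density of the shell over bulk is delta-rho =
#' 40 / l_cell^3. The shell contrast is therefore set by the cell edge.
#'
#' @param l_cell Unit-cell edge length, Angstrom.
#' @return Contrast in e/A^3.
#' @export
#' @examples
#' shell_contrast(10)  # 0.04
shell_contrast <- function(l_cell) {
  stopifnot(l_cell > 0)
  40 / l_cell^3
}

#' Default FCC cell edge
#'
#' Chosen so the shell contrast is about 0.03 e/A^3, a commonly assumed
#' hydration-shell excess density: l_cell = (40 / 0.03)^(1/3) ~ 11 A.
#'
#' @param contrast Desired shell contrast, e/A^3.
#' @return Cell edge in Angstrom.
#' @export
default_l_cell <- function(contrast = 0.03) {
  stopifnot(contrast > 0)
  (40 / contrast)^(1 / 3)
}

#' Exact Debye intensity over protein plus explicit waters
#'
#' Concatenates the structure with a set of shell waters and runs the
#' exact double sum over all N + W scatterers; waters contribute the
#' water form factor. Coincident positions are allowed (the sinc limit
#' applies).
#'
#' @param structure A `saxs_structure` (may be empty for waters-only).
#' @param waters A `saxs_structure` of waters (e.g. from
#'   [filter_shell_waters()]), or NULL.
#' @param q Momentum-transfer grid, 1/Angstrom.
#' @param solvent A [solvent_model()].
#' @return A `saxs_profile`.
#' @export
debye_with_waters <- function(structure, waters, q = default_q_grid(),
                              solvent = solvent_model()) {
  if (is.null(waters) || nrow(waters) == 0) {
    return(debye_exact(structure, q = q, solvent = solvent))
  }
  all_atoms <- if (is.null(structure) || nrow(structure) == 0) {
    waters
  } else {
    out <- dplyr::bind_rows(as.data.frame(structure), as.data.frame(waters))
    class(out) <- c("saxs_structure", class(tibble::tibble()))
    attr(out, "identifier") <- paste0(attr(structure, "identifier"),
                                      "+waters")
    out
  }
  p <- debye_exact(all_atoms, q = q, solvent = solvent)
  attr(p, "engine") <- "debye-explicit-waters"
  p
}
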