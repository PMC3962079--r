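# Structures as tidy atom tables: one row per scatterer, coordinates in
# Angstrom, plus the per-atom quantities the scattering engines need
# (displaced volume, implicit hydrogens, SASA fraction).

#' Build a structure from atom vectors
#'
#' Low-level constructor; most users get structures from [read_pdb()] or
#' [make_toy()]. Displaced volumes are filled from the van der Waals radii
#' unless supplied.
#'
#' @param element Element symbols.
#' @param x,y,z Coordinates, Angstrom.
#' @param atom_name PDB atom names (default = element).
#' @param res_name Residue names (default "UNK").
#' @param res_id Residue numbers.
#' @param chain Chain identifiers.
#' @param n_implicit_h Implicit hydrogen counts.
#' @param vdw_radius Van der Waals radii, Angstrom (default from
#'   [default_vdw_radii()]).
#' @param sasa_fraction Fractional solvent accessibility in \[0,1\]
#'   (NA until [compute_sasa()] runs).
#' @param is_calpha Logical, alpha-carbon flag.
#' @param is_water Logical, water flag.
#' @param is_shell Logical, hydration-shell water flag (these scatter with
#'   the whole-molecule water factor and carry no excluded-volume term).
#' @param identifier Free-text structure identifier.
#' @return A tibble of class `saxs_structure`.
#' @export
saxs_structure <- function(element, x, y, z,
                           atom_name = element, res_name = "UNK",
                           res_id = 1L, chain = "A",
                           n_implicit_h = 0L, vdw_radius = NULL,
                           sasa_fraction = NA_real_,
                           is_calpha = NULL, is_water = FALSE,
                           is_shell = FALSE, identifier = "structure") {
  n <- length(element)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (is.null(vdw_radius)) {
    vdw_radius <- unname(.vdw_radii[.element_key(element)])
  }
  if (is.null(is_calpha)) {
    is_calpha <- toupper(trimws(atom_name)) == "CA" &
      toupper(element) == "C"
  }
  out <- tibble::tibble(
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    atom_name = rep_len(as.character(atom_name), n),
    res_name = rep_len(as.character(res_name), n),
    res_id = rep_len(as.integer(res_id), n),
    chain = rep_len(as.character(chain), n),
    n_implicit_h = rep_len(as.integer(n_implicit_h), n),
    vdw_radius = rep_len(as.numeric(vdw_radius), n),
    displaced_volume = NA_real_,
    sasa_fraction = rep_len(as.numeric(sasa_fraction), n),
    sasa_area = NA_real_,
    is_calpha = rep_len(as.logical(is_calpha), n),
    is_water = rep_len(as.logical(is_water), n),
    is_shell = rep_len(as.logical(is_shell), n)
  )
  out$displaced_volume <- ifelse(is.na(out$vdw_radius), NA_real_,
                                 4 / 3 * pi * out$vdw_radius^3)
  class(out) <- c("saxs_structure", class(tibble::tibble()))
  attr(out, "identifier") <- identifier
  out
}

#' Coordinates of a structure as a matrix
#'
#' @param structure A `saxs_structure`.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

#' Read a PDB file into an atom table
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d), resolving elements
#' from columns 77-78 with an atom-name fallback. Only the first MODEL of
#' multi-model files is used; for alternate locations the highest-occupancy
#' conformer is kept (first encountered on ties). In the default implicit
#' hydrogen mode, explicit hydrogens are dropped and standard per-atom-name
#' hydrogen counts are folded into the parent heavy atoms.
#'
#' @param path Path to a PDB file.
#' @param hydrogens `"implicit"` (default) or `"explicit"`.
#' @param keep_waters Keep HETATM waters (flagged `is_water`)?
#' @param radii Named vector of van der Waals radii overriding
#'   [default_vdw_radii()].
#' @return A `saxs_structure`.
#' @export
read_pdb <- function(path, hydrogens = c("implicit", "explicit"),
                     keep_waters = TRUE, radii = NULL) {
  hydrogens <- match.arg(hydrogens)
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no parsable ATOM/HETATM records in ", path, call. = FALSE)
  }
  # resolve element: columns 77-78 when present, else leading letters of
  # the atom name (digits and primes stripped)
  elesy <- trimws(as.character(at$elesy))
  guess <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", trimws(at$elety)))
  # 4-character names like 1HG1/HD21 are hydrogens; 2-letter guesses that
  # are not known elements fall back to their first letter
  guess <- toupper(substr(guess, 1, 2))
  bad <- !(.element_key(guess) %in% names(.cromer_mann)) & nchar(guess) == 2
  guess[bad] <- substr(guess[bad], 1, 1)
  element <- ifelse(elesy == "" | is.na(elesy), guess, elesy)
  element <- toupper(element)
  # normalise case like "Zn" -> "ZN" handled above; single letters stay
  at$element <- element

  # altloc: keep the highest-occupancy record per (chain, resno, insert,
  # resid, atom name); ties go to the first encountered
  at$alt[is.na(at$alt)] <- ""
  if (any(at$alt != "" & at$alt != " ")) {
    at$o[is.na(at$o)] <- 1
    grp <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
    ord <- order(grp, -at$o, seq_len(nrow(at)))
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                               at$elety, sep = "|")), ]
    at <- at[order(as.integer(rownames(at))), ]
  }

  is_h <- at$element == "H" | at$element == "D"
  if (hydrogens == "implicit" && any(is_h)) at <- at[!is_h, ]
  is_water <- toupper(at$resid) %in% c("HOH", "WAT", "DOD")
  if (!keep_waters) {
    at <- at[!is_water, ]
    is_water <- rep(FALSE, nrow(at))
  }
  if (nrow(at) == 0) stop("no atoms left after filtering in ", path,
                          call. = FALSE)
  unknown <- !(.element_key(at$element) %in% names(.cromer_mann))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("unknown element '", at$element[i], "' in record ", rownames(at)[i],
         " (atom name '", trimws(at$elety[i]), "', residue ",
         at$resid[i], at$resno[i], ") and no fallback available",
         call. = FALSE)
  }
  n_h <- if (hydrogens == "implicit") {
    implicit_h_count(at$resid, at$elety)
  } else 0L
  rad_tab <- .vdw_radii
  if (!is.null(radii)) rad_tab[.element_key(names(radii))] <- radii
  out <- saxs_structure(
    element = at$element, x = at$x, y = at$y, z = at$z,
    atom_name = trimws(at$elety), res_name = trimws(at$resid),
    res_id = at$resno, chain = ifelse(is.na(at$chain), "A", at$chain),
    n_implicit_h = n_h,
    vdw_radius = unname(rad_tab[.element_key(at$element)]),
    is_water = is_water,
    identifier = basename(path)
  )
  out
}

#' Write a structure to PDB format
#'
#' Fixed-column ATOM/HETATM records with the element in columns 77-78;
#' hydration-shell waters are written as HETATM HOH oxygens.
#'
#' @param structure A `saxs_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  n <- nrow(structure)
  if (n == 0) stop("empty structure", call. = FALSE)
  het <- structure$is_water | structure$is_shell
  rec <- ifelse(het, "HETATM", "ATOM  ")
  elem <- structure$element
  elem[structure$is_shell] <- "O"
  name <- structure$atom_name
  name[structure$is_shell] <- "O"
  resn <- structure$res_name
  resn[structure$is_shell] <- "HOH"
  # PDB atom-name column: single-letter elements start in column 14
  name_fmt <- ifelse(nchar(elem) == 1 & nchar(name) <= 3,
                     sprintf(" %-3s", name), sprintf("%-4s", name))
  lines <- sprintf(
    "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(n), name_fmt, substr(resn, 1, 3),
    substr(structure$chain, 1, 1), structure$res_id %% 10000L,
    structure$x, structure$y, structure$z, 1.00, 0.00,
    formatC(elem, width = 2, flag = " ")
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Assign displaced solvent volumes from van der Waals radii
#'
#' Each atom displaces a solvent sphere of its van der Waals radius:
#' V = (4/3) pi r^3.
#'
#' @param structure A `saxs_structure`.
#' @param radii Named element -> radius (Angstrom) map; defaults to the
#'   embedded Bondi-style table.
#' @return The structure with `vdw_radius` and `displaced_volume` set.
#' @export
assign_volumes <- function(structure, radii = default_vdw_radii()) {
  keys <- .element_key(structure$element)
  rad_tab <- radii
  names(rad_tab) <- .element_key(names(radii))
  missing <- setdiff(unique(keys[!structure$is_shell]), names(rad_tab))
  if (length(missing) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(sub("_$", "", missing), collapse = ", "), call. = FALSE)
  }
  r <- unname(rad_tab[keys])
  structure$vdw_radius <- ifelse(structure$is_shell, structure$vdw_radius, r)
  structure$displaced_volume <- ifelse(structure$is_shell,
                                       structure$displaced_volume,
                                       4 / 3 * pi * r^3)
  structure
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over each atom: test points on the expanded sphere
#' of radius r_vdw + probe are marked buried when they fall inside any
#' neighbour's expanded sphere. The exposed fraction is stored in
#' `sasa_fraction` (the S weight of the hydration-shell form-factor term)
#' and the absolute exposed area in `sasa_area` (A^2).
#'
#' @param structure A `saxs_structure` with radii assigned.
#' @param probe_radius Probe radius, Angstrom (water = 1.4).
#' @param n_sphere_points Test points per atom (>= 16; default 960).
#' @return The structure with `sasa_fraction` and `sasa_area` filled.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4,
                         n_sphere_points = 960) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 16)
  if (any(is.na(structure$vdw_radius))) {
    stop("van der Waals radii missing; run assign_volumes() first",
         call. = FALSE)
  }
  xyz <- coords(structure)
  n <- nrow(xyz)
  rad <- structure$vdw_radius + probe_radius
  pts <- .sphere_points(n_sphere_points)
  frac <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) { frac[i] <- 1; next }
    test <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- (test[, 1] - xyz[j, 1])^2 + (test[, 2] - xyz[j, 2])^2 +
        (test[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 > rad[j]^2
      if (!any(exposed)) break
    }
    frac[i] <- sum(exposed) / n_sphere_points
  }
  structure$sasa_fraction <- frac
  structure$sasa_area <- frac * 4 * pi * rad^2
  structure
}

#' Largest interatomic distance
#'
#' d_max sets both the support of the pair-distance distribution p(r) and
#' the Nyquist bound for the spherical-harmonic order.
#'
#' @param structure A `saxs_structure` with at least 2 atoms.
#' @return Maximum pairwise distance, Angstrom.
#' @export
d_max <- function(structure) {
  if (nrow(structure) < 2) {
    stop("d_max needs at least 2 atoms", call. = FALSE)
  }
  max(pair_distances_cpp(coords(structure)))
}

#' Rigidly transform a structure
#'
#' @param structure A `saxs_structure`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 shift, Angstrom.
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- coords(structure) %*% t(rotation)
  structure$x <- xyz[, 1] + translation[1]
  structure$y <- xyz[, 2] + translation[2]
  structure$z <- xyz[, 3] + translation[3]
  structure
}

#' @export
print.saxs_structure <- function(x, ...) {
  cat(sprintf("<saxs_structure> '%s': %d atoms", attr(x, "identifier"),
              nrow(x)))
  if (any(x$is_shell)) cat(sprintf(" (%d shell waters)", sum(x$is_shell)))
  cat("\n")
  NextMethod()
}
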