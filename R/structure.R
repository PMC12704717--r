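# Bondi-style van der Waals radii (Angstrom); hydrogens are usually absent
# from cryo-EM models and are dropped by default on reading.
vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.10)

vdw_radius_for <- function(element, default = 1.7) {
  el <- toupper(trimws(element))
  r <- unname(vdw_table[el])
  unknown <- is.na(r) & !is.na(el) & nzchar(el)
  if (any(unknown)) {
    warning(sprintf("unknown element(s) %s: using default vdW radius %.2f A",
                    paste(unique(el[unknown]), collapse = ", "), default),
            call. = FALSE)
  }
  r[is.na(r)] <- default
  r
}

#' Build a structure from atom data
#'
#' The atom container used by all volume and superposition operations: one
#' row per atom with element, van der Waals radius and Cartesian coordinates
#' in Angstrom.
#'
#' @param x,y,z Coordinates in Angstrom (finite).
#' @param element Element symbols; used to assign vdW radii when `vdw` is
#'   not given.
#' @param vdw vdW radii in Angstrom (> 0); defaults to a Bondi-style table
#'   lookup by element (unknown elements get 1.7 A with a warning).
#' @param chain,resno,resid,elety Chain id, residue number, residue name and
#'   atom name (optional annotations).
#' @param het Logical heteroatom flags.
#' @return A data.frame of class `"opsin_structure"`.
#' @export
#' @examples
#' s <- opsin_structure(x = c(0, 3), y = 0, z = 0, element = c("C", "O"))
#' s$vdw
opsin_structure <- function(x, y, z, element = "C", vdw = NULL,
                            chain = "A", resno = seq_along(x), resid = "UNK",
                            elety = element, het = FALSE) {
  n <- length(x)
  if (n == 0L) stop("structure must contain at least one atom", call. = FALSE)
  co <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (nrow(co) != n || any(!is.finite(co))) {
    stop("coordinates must be finite and of equal length", call. = FALSE)
  }
  if (is.null(vdw)) vdw <- vdw_radius_for(rep_len(element, n))
  vdw <- rep_len(vdw, n)
  if (any(vdw <= 0)) stop("vdW radii must be > 0", call. = FALSE)
  out <- data.frame(
    element = rep_len(as.character(element), n),
    vdw = vdw,
    x = co[, 1L], y = co[, 2L], z = co[, 3L],
    chain = rep_len(as.character(chain), n),
    resno = rep_len(as.integer(resno), n),
    resid = rep_len(as.character(resid), n),
    elety = rep_len(as.character(elety), n),
    het = rep_len(as.logical(het), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("opsin_structure", "data.frame")
  out
}

struct_xyz <- function(s) as.matrix(s[, c("x", "y", "z")])

#' Read a protein structure from PDB or mmCIF
#'
#' Parses the file with bio3d and assigns element-based van der Waals radii
#' from the bundled Bondi-style table (unknown elements get 1.7 A with a
#' warning). Hydrogens are dropped by default, matching hydrogen-free cryo-EM
#' models. Residue numbering is taken verbatim from the file.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param chain Optional chain id(s) to keep.
#' @param resno Optional residue numbers to keep.
#' @param drop_hydrogens Drop H atoms (default TRUE).
#' @return An [opsin_structure()] data.frame.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           chain = NULL, resno = NULL,
                           drop_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("could not parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no atoms in ", path, call. = FALSE)
  # prefer the file's element column; infer from atom names only where blank
  element <- at$elesy %||% rep("", nrow(at))
  element[is.na(element)] <- ""
  blank <- !nzchar(trimws(element))
  if (any(blank)) {
    element[blank] <- suppressWarnings(bio3d::atom2ele(at$elety[blank]))
  }
  keep <- rep(TRUE, nrow(at))
  if (drop_hydrogens) keep <- keep & toupper(element) != "H"
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!any(keep)) stop("selection matches no atoms", call. = FALSE)
  at <- at[keep, , drop = FALSE]
  opsin_structure(at$x, at$y, at$z, element = element[keep],
                  chain = at$chain, resno = at$resno, resid = at$resid,
                  elety = at$elety, het = at$type == "HETATM")
}

#' Write a structure as a minimal PDB file
#'
#' @param struct An [opsin_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "opsin_structure"))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(struct_xyz(struct))),
                   type = ifelse(struct$het, "HETATM", "ATOM"),
                   resno = struct$resno,
                   resid = struct$resid,
                   chain = struct$chain,
                   elety = struct$elety,
                   elesy = struct$element)
  invisible(path)
}

#' Generate a toy shell structure with a known internal cavity
#'
#' Places atoms quasi-uniformly (Fibonacci lattice) on one or more spherical
#' shells. A sufficiently dense single shell encloses a spherical cavity of
#' probe-accessible radius `shell_radius - atom_radius - probe_in` whose
#' volume is known analytically and checkable by brute-force flood fill;
#' concentric shells create nested cavities. Optional ligand atoms are placed
#' inside the innermost shell.
#'
#' @param shell_radius Shell radius (or radii, for concentric shells), A.
#' @param atom_radius vdW radius assigned to every shell atom, A
#'   (0 < atom_radius < min(shell_radius)).
#' @param n_atoms Atom count per shell (recycled), > 0. Atoms must be dense
#'   enough that nearest-neighbour gaps stay below twice the probe radius of
#'   the intended cavity run.
#' @param ligand Optional [opsin_structure()] (or data.frame with x, y, z,
#'   vdw) of ligand atoms to embed, flagged with `resid = "LIG"`.
#' @return An [opsin_structure()] with `het = TRUE`.
#' @export
#' @examples
#' shell <- generate_toy_structure(10, 1.7, 1000)
#' nrow(shell)
generate_toy_structure <- function(shell_radius, atom_radius, n_atoms,
                                   ligand = NULL) {
  if (length(shell_radius) == 0L || any(shell_radius <= 0)) {
    stop("'shell_radius' must be positive", call. = FALSE)
  }
  if (atom_radius <= 0 || atom_radius >= min(shell_radius)) {
    stop("need 0 < atom_radius < shell_radius", call. = FALSE)
  }
  n_atoms <- rep_len(as.integer(n_atoms), length(shell_radius))
  if (any(n_atoms <= 0)) stop("'n_atoms' must be positive", call. = FALSE)
  golden <- pi * (3 - sqrt(5))
  coords <- do.call(rbind, lapply(seq_along(shell_radius), function(s) {
    n <- n_atoms[s]
    i <- seq_len(n) - 0.5
    zu <- 1 - 2 * i / n
    r2 <- sqrt(pmax(1 - zu^2, 0))
    th <- golden * (i - 0.5)
    shell_radius[s] * cbind(r2 * cos(th), r2 * sin(th), zu)
  }))
  out <- opsin_structure(coords[, 1L], coords[, 2L], coords[, 3L],
                         element = "C", vdw = atom_radius,
                         resid = "SHL", het = TRUE)
  if (!is.null(ligand)) {
    lig <- opsin_structure(ligand$x, ligand$y, ligand$z,
                           element = ligand$element %||% "C",
                           vdw = ligand$vdw,
                           resid = "LIG", het = TRUE)
    lig$resno <- max(out$resno) + seq_len(nrow(lig))
    out <- rbind(out, lig)
    class(out) <- c("opsin_structure", "data.frame")
  }
  out
}
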