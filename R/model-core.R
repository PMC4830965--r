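#' @include AllClasses.R
NULL

## Amino-acid codes cover the standard 20 plus common protonation-state
## dialects; lipid/water codes cover the force-field dialects the pipeline
## meets (CHARMM/GROMACS style). Anything unknown is a ligand.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "ILE", "LEU", "LYS",
          "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
.lipid3 <- c("POP", "POPC", "POPE", "POPS", "DPPC", "DOPC", "DMPC", "PC")
.water3 <- c("HOH", "SOL", "TIP3", "TIP", "WAT", "SPC", "T3P")

#' Infer molecule classes from residue names
#'
#' Maps residue names to one of `protein`, `lipid`, `water`, `ligand` using a
#' built-in lookup (standard amino-acid codes; common phosphatidylcholine
#' lipid codes; `HOH`/`SOL`/`TIP3`-style water codes; everything else is a
#' ligand). The lookup is extensible: `overrides` is a named character vector
#' `c(RESNAME = "class", ...)` that wins over the built-in table, so
#' force-field residue-name dialects can be accommodated from a config file.
#'
#' @param resname character vector of residue names
#' @param overrides optional named character vector of class overrides
#' @return character vector of molecule classes
#' @examples
#' moleculeClass(c("ALA", "POPC", "TIP3", "CLR"))
#' moleculeClass("CLR", overrides = c(CLR = "lipid"))
#' @export
moleculeClass <- function(resname, overrides = NULL) {
  cls <- rep("ligand", length(resname))
  cls[resname %in% .aa3] <- "protein"
  cls[resname %in% .lipid3] <- "lipid"
  cls[resname %in% .water3] <- "water"
  if (length(overrides)) {
    bad <- setdiff(unique(overrides), c("protein", "lipid", "water", "ligand"))
    if (length(bad)) {
      stop("unknown molecule class in overrides: ", paste(bad, collapse = ", "))
    }
    hit <- resname %in% names(overrides)
    cls[hit] <- unname(overrides[resname[hit]])
  }
  cls
}

#' Construct a StructureModel
#'
#' Low-level constructor; most users get models from [loadStructure()] or
#' [buildSystem()]. Coordinates are in nm, the box is orthorhombic.
#'
#' @param atoms atom table (see [StructureModel-class])
#' @param coords numeric N x 3 matrix, nm
#' @param box numeric length-3 box lengths, nm
#' @param helixTable optional `data.frame(helix, start, end)` of TM residue
#'   ranges
#' @param bwAnchors optional named integer vector (helix index -> x.50
#'   residue id)
#' @return a validated [StructureModel-class]
#' @export
StructureModel <- function(atoms, coords, box,
                           helixTable = data.frame(helix = integer(),
                                                   start = integer(),
                                                   end = integer()),
                           bwAnchors = integer()) {
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  if (length(bwAnchors)) bwAnchors <- vapply(bwAnchors, as.integer, 1L)
  new("StructureModel", atoms = atoms, coords = coords,
      box = as.numeric(box),
      helixTable = as.data.frame(helixTable), bwAnchors = bwAnchors)
}

#' Construct a Trajectory
#'
#' @param model the shared [StructureModel-class]
#' @param coords numeric N x 3 x F array, nm
#' @param times frame times, ns; defaults to 0, 1, ... (frame index)
#' @param boxes 3 x F matrix of per-frame box lengths; defaults to the
#'   model box in every frame
#' @return a validated [Trajectory-class]
#' @export
Trajectory <- function(model, coords, times = NULL, boxes = NULL) {
  d <- dim(coords)
  if (is.null(times)) times <- seq_len(d[3]) - 1
  if (is.null(boxes)) boxes <- matrix(model@box, nrow = 3, ncol = d[3])
  new("Trajectory", model = model, coords = coords,
      times = as.numeric(times), boxes = boxes)
}

#' Select atom indices from a StructureModel
#'
#' Deterministic, order-preserving atom selection. All criteria are optional
#' and combined with AND; a criterion given as a vector matches any of its
#' values. An empty result is legal, not an error.
#'
#' @param model a [StructureModel-class]
#' @param class molecule class(es) to keep (`protein`, `lipid`, `water`,
#'   `ligand`)
#' @param resid residue id(s) to keep (vector of ids; ranges via `a:b`)
#' @param resname residue name(s) to keep
#' @param name atom name(s) to keep (e.g. `"P"`, `c("N","CA","C","O")`)
#' @param chain chain id(s) to keep
#' @return integer vector of atom indices in model order (possibly empty)
#' @examples
#' cfg <- generatorConfig(seed = 1, n_frames = 1, lipids_per_leaflet = 8,
#'                        waters = list(count = 0))
#' m <- buildSystem(cfg)
#' length(selectAtoms(m, class = "lipid", name = "P"))
#' @export
selectAtoms <- function(model, class = NULL, resid = NULL, resname = NULL,
                        name = NULL, chain = NULL) {
  a <- model@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(class)) keep <- keep & a$class %in% class
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  which(keep)
}

#' Minimum-image displacement under orthorhombic periodic boundaries
#'
#' Returns b - a with each component wrapped into \[-L/2, L/2), so the norm of
#' the result is the minimum-image distance between the two points.
#' Vectorised: `a` and `b` may be M x 3 matrices (or one matrix and one
#' 3-vector).
#'
#' @param a,b 3-vectors or M x 3 matrices of positions, nm
#' @param box numeric length-3 orthorhombic box lengths, nm
#' @return displacement(s), same shape as the broadcast of the inputs
#' @examples
#' minImageDisplacement(c(0, 0, 0), c(9.9, 0, 0), box = c(10, 10, 10))
#' @export
minImageDisplacement <- function(a, b, box) {
  stopifnot(length(box) == 3, all(box > 0))
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  d <- b - a
  for (k in 1:3) {
    L <- box[k]
    d[, k] <- d[, k] - L * floor(d[, k] / L + 0.5)
  }
  if (n == 1) drop(d) else d
}

#' Minimum-image distances between one point and many
#'
#' @param p a 3-vector, nm
#' @param pts M x 3 matrix, nm
#' @param box box lengths, nm
#' @return numeric vector of M minimum-image distances
#' @export
minImageDistance <- function(p, pts, box) {
  d <- minImageDisplacement(matrix(p, ncol = 3), pts, box)
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  sqrt(rowSums(d^2))
}

## row index of the (chain, resid) residue key for each atom
.residueKey <- function(atoms) paste(atoms$chain, atoms$resid, sep = "|")
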