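#' Load protein heavy atoms from a PDB file
#'
#' Reads \code{ATOM} records via \pkg{bio3d}, keeps heavy atoms of the 20
#' standard amino-acid residues, and drops hydrogens/deuteriums, waters,
#' and all \code{HETATM} content (ligands, ions, cofactors). Alternate
#' locations keep conformer \code{'A'} (or blank) only. Non-standard
#' residues are skipped with a warning: they have no dictionary entry and
#' therefore produce no features.
#'
#' @param path path to a PDB file.
#' @return data.frame with columns \code{residue}, \code{atom_name},
#'   \code{element}, \code{x}, \code{y}, \code{z} (Angstrom).
#' @seealso [typeProteinAtom()], [enumeratePairs()]
#' @export
loadProtein <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  std <- standardResidues()
  nonstd <- setdiff(unique(at$resid), std)
  if (length(nonstd))
    warning("skipping non-standard protein residues: ",
            paste(nonstd, collapse = ", "))
  at <- at[at$resid %in% std, , drop = FALSE]
  elem <- elementOf(at$elesy, at$elety)
  at <- at[!elem %in% c("H", "D"), , drop = FALSE]
  elem <- elem[!elem %in% c("H", "D")]
  if (nrow(at) == 0L)
    stop("empty structure: no standard-residue heavy atoms in '", path, "'")
  coords <- cbind(at$x, at$y, at$z)
  if (any(!is.finite(coords))) stop("non-finite coordinates in '", path, "'")
  data.frame(residue = at$resid, atom_name = at$elety, element = elem,
             x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
}

standardResidues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# Element symbol from PDB element column, falling back to the atom name
# (leading digits stripped, e.g. "1HG1" -> H, "NE2" -> N).
elementOf <- function(elesy, elety) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fb <- toupper(sub("^[0-9]*", "", trimws(elety)))
  two <- substr(fb, 1L, 2L)
  fb <- ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN"),
               two, substr(fb, 1L, 1L))
  ifelse(nzchar(e), e, fb)
}

#' Load and perceive ligand heavy atoms from an SDF/MOL file
#'
#' Reads the first molecule of an SDF (MOL V2000) file via \pkg{ChemmineR}
#' and annotates every heavy atom with the attributes the ECIF
#' representation needs: explicit valence (bond-order sum including
#' hydrogens, implicit hydrogens filled against standard element valences
#' adjusted by formal charge), number of heavy neighbors, number of
#' attached hydrogens (explicit plus implicit), aromaticity and ring
#' membership (perceived from the ring system via [ChemmineR::rings()];
#' bonds written with MOL aromatic bond order 4 are honored directly).
#'
#' The protonation/tautomer state is taken exactly as written in the file;
#' no pKa adjustment is performed.
#'
#' @param path path to an SDF or MOL file with a 3D conformer and a bond
#'   block.
#' @param molecule index of the molecule within the SDF (default 1).
#' @return data.frame with one row per heavy atom: \code{element},
#'   \code{explicit_valence}, \code{n_heavy_neighbors},
#'   \code{n_attached_hydrogens}, \code{is_aromatic}, \code{in_ring},
#'   \code{x}, \code{y}, \code{z}.
#' @seealso [typeLigandAtom()], [enumeratePairs()]
#' @export
loadLigand <- function(path, molecule = 1L) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  set <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                  error = function(e) stop("cannot parse SDF file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) < molecule)
    stop("SDF file '", path, "' has no molecule ", molecule)
  sdf <- set[[molecule]]
  if (!ChemmineR::validSDF(set[molecule]))
    stop("sanitization failure for molecule ",
         ChemmineR::header(sdf)[["Molecule_Name"]], " in '", path, "'")
  hdr <- ChemmineR::header(sdf)
  if (length(hdr) >= 2L && grepl("2D", hdr[[2L]], fixed = TRUE))
    stop("no 3D coordinates: '", path, "' declares a 2D connection table")
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(ab) == 0L)
    stop("SDF '", path, "' lacks an atom or bond block")
  coords <- ab[, 1:3, drop = FALSE]
  if (all(abs(coords) < 1e-8))
    stop("no 3D coordinates: all atom coordinates are zero in '", path, "'")
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  charges <- readSdfCharges(path, molecule, n)

  ord <- as.numeric(bb[, 3L])
  ord[!ord %in% c(1, 2, 3, 4)] <- 1
  a1 <- as.integer(bb[, 1L]); a2 <- as.integer(bb[, 2L])
  w <- ifelse(ord == 4, 1.5, ord)

  isH <- elem %in% c("H", "D")
  bondSum <- numeric(n); heavyNb <- integer(n); explH <- integer(n)
  aromBond <- logical(n)
  for (k in seq_along(a1)) {
    i <- a1[k]; j <- a2[k]
    bondSum[i] <- bondSum[i] + w[k]; bondSum[j] <- bondSum[j] + w[k]
    if (ord[k] == 4) { aromBond[i] <- TRUE; aromBond[j] <- TRUE }
    if (isH[j]) explH[i] <- explH[i] + 1L else heavyNb[i] <- heavyNb[i] + 1L
    if (isH[i]) explH[j] <- explH[j] + 1L else heavyNb[j] <- heavyNb[j] + 1L
  }

  ringInfo <- perceiveRings(sdf, n)
  inRing <- ringInfo$inRing
  arom <- ringInfo$aromatic | (aromBond & inRing)

  nominal <- floor(bondSum + 1e-6)
  implH <- pmax(0L, defaultValence(elem, charges) - as.integer(nominal))
  valence <- as.integer(nominal) + implH

  keep <- !isH
  out <- data.frame(
    element = elem, explicit_valence = as.integer(valence),
    n_heavy_neighbors = heavyNb,
    n_attached_hydrogens = as.integer(explH + implH),
    is_aromatic = arom, in_ring = inRing,
    x = as.numeric(coords[, 1L]), y = as.numeric(coords[, 2L]),
    z = as.numeric(coords[, 3L]), stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("empty structure: no heavy atoms in '", path, "'")
  if (any(out$n_heavy_neighbors > out$explicit_valence))
    stop("perception inconsistency: heavy-neighbor count exceeds valence")
  out
}

# Ring membership and ring-level aromaticity via ChemmineR's ring perception.
perceiveRings <- function(sdf, n) {
  inRing <- logical(n); aromatic <- logical(n)
  rr <- tryCatch(ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE),
                 error = function(e) NULL)
  if (!is.null(rr) && length(rr$RINGS)) {
    for (k in seq_along(rr$RINGS)) {
      idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
      inRing[idx] <- TRUE
      if (isTRUE(rr$AROMATIC[[k]])) aromatic[idx] <- TRUE
    }
  }
  list(inRing = inRing, aromatic = aromatic)
}

# Standard organic valences, adjusted by formal charge. Hypervalent S/P are
# handled upstream: when the explicit bond-order sum already exceeds the
# default, no implicit hydrogens are added.
defaultValence <- function(elem, charge = 0L) {
  v <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
         Cl = 1, Br = 1, I = 1, Se = 2)[elem]
  v[is.na(v)] <- 0
  adj <- ifelse(elem %in% c("N", "O", "S", "P", "Se"), charge,
                ifelse(elem == "C", -abs(charge), 0L))
  pmax(0, v + adj)
}

# ChemmineR drops "M  CHG" lines; recover formal charges from the raw text.
readSdfCharges <- function(path, molecule, n) {
  txt <- readLines(path, warn = FALSE)
  recEnd <- c(0L, grep("^\\$\\$\\$\\$", txt))
  from <- recEnd[molecule] + 1L
  to <- if (length(recEnd) > molecule) recEnd[molecule + 1L] else length(txt)
  block <- txt[from:to]
  charges <- integer(n)
  for (line in grep("^M  CHG", block, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substring(line, 7L)), "\\s+")[[1]])
    cnt <- flds[1L]
    for (k in seq_len(cnt)) {
      idx <- flds[2L * k]; val <- flds[2L * k + 1L]
      if (!is.na(idx) && idx >= 1L && idx <= n) charges[idx] <- val
    }
  }
  charges
}
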