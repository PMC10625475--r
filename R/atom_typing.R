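#' ECIF-style atom types
#'
#' An ECIF atom type is the semicolon-joined qualitative description of a
#' heavy atom. The six-element variant renders
#' \code{symbol;valence;heavyNeighbors;hydrogens;aromatic;ring}; the
#' five-element variant omits the aromaticity flag (whose information
#' largely duplicates ring membership) and renders
#' \code{symbol;valence;heavyNeighbors;hydrogens;ring}. For example an
#' amide-like nitrogen with valence 3, two heavy neighbors and one hydrogen
#' renders as \code{"N;3;2;1;0;0"} (six-element) or \code{"N;3;2;1;0"}
#' (five-element).
#'
#' @param symbol element symbol, e.g. \code{"N"}.
#' @param valence explicit valence (bond-order sum including hydrogens).
#' @param heavyNeighbors number of attached heavy atoms.
#' @param hydrogens number of attached hydrogens (explicit plus implicit).
#' @param aromatic logical; omit (\code{NULL}) for the five-element variant.
#' @param ring logical; ring membership.
#' @return \code{renderAtomType}: a character vector of rendered types.
#' @examples
#' renderAtomType("N", 3, 2, 1, aromatic = FALSE, ring = FALSE)
#' renderAtomType("N", 3, 2, 1, ring = FALSE)
#' parseAtomType("N;3;2;1;0;0")
#' @export
renderAtomType <- function(symbol, valence, heavyNeighbors, hydrogens,
                           aromatic = NULL, ring) {
  if (is.null(aromatic))
    paste(symbol, valence, heavyNeighbors, hydrogens,
          as.integer(ring), sep = ";")
  else
    paste(symbol, valence, heavyNeighbors, hydrogens,
          as.integer(aromatic), as.integer(ring), sep = ";")
}

#' @rdname renderAtomType
#' @param x rendered atom-type string(s).
#' @return \code{parseAtomType}: a data.frame with columns \code{symbol},
#'   \code{valence}, \code{heavyNeighbors}, \code{hydrogens},
#'   \code{aromatic} (NA for five-element types), \code{ring},
#'   \code{variant}.
#' @export
parseAtomType <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  n <- lengths(parts)
  if (!all(n %in% c(5L, 6L)))
    stop("malformed atom type(s): ",
         paste(x[!n %in% c(5L, 6L)], collapse = ", "))
  data.frame(
    symbol = vapply(parts, `[`, "", 1L),
    valence = as.integer(vapply(parts, `[`, "", 2L)),
    heavyNeighbors = as.integer(vapply(parts, `[`, "", 3L)),
    hydrogens = as.integer(vapply(parts, `[`, "", 4L)),
    aromatic = ifelse(n == 6L,
                      vapply(parts, `[`, "", 5L) == "1", NA),
    ring = vapply(parts, function(p) p[length(p)], "") == "1",
    variant = ifelse(n == 6L, "six_element", "five_element"),
    stringsAsFactors = FALSE)
}

#' @rdname renderAtomType
#' @return \code{dropAromaticity}: the five-element rendering of a
#'   six-element type (five-element input is returned unchanged).
#' @export
dropAromaticity <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 6L) paste(p[-5L], collapse = ";")
    else paste(p, collapse = ";")
  }, "")
}

typeVariantOf <- function(x) {
  n <- lengths(strsplit(x, ";", fixed = TRUE))
  ifelse(n == 6L, "six_element", ifelse(n == 5L, "five_element", NA))
}

normalizeVariant <- function(variant) {
  variant <- as.character(variant)
  v <- match.arg(variant[1L],
                 c("five_element", "six_element", "five", "six", "5", "6"))
  switch(v,
         five = , "5" = "five_element",
         six = , "6" = "six_element",
         v)
}

#' Protein atom-type dictionary
#'
#' Returns the packaged dictionary mapping each heavy atom of the 20
#' standard amino acids (one fixed protonation/tautomer state: protonated
#' LYS/ARG, deprotonated ASP/GLU, neutral histidine carrying its hydrogen
#' on NE2) to its ECIF type under both variants.
#'
#' @return data.frame with columns \code{residue}, \code{atom_name},
#'   \code{five_element_type}, \code{six_element_type}.
#' @examples
#' head(proteinTypeTable())
#' @export
proteinTypeTable <- function() {
  if (is.null(.msecifCache$proteinTypes)) {
    tab <- utils::read.delim(pkgAsset("protein_types.tsv"),
                             stringsAsFactors = FALSE)
    need <- c("residue", "atom_name", "five_element_type",
              "six_element_type")
    if (!all(need %in% names(tab)))
      stop("protein_types.tsv asset is corrupt: missing columns")
    .msecifCache$proteinTypes <- tab
  }
  .msecifCache$proteinTypes
}

#' Type a protein atom by dictionary lookup
#'
#' Protein atoms are typed uniformly by a (residue, atom name) dictionary;
#' atoms without an entry (non-standard residues, metals, terminal OXT)
#' yield \code{NA}, which downstream code treats as "produces no features"
#' rather than as an error.
#'
#' @param residue 3-letter residue code(s), e.g. \code{"HIS"}.
#' @param atomName PDB atom name(s), e.g. \code{"NE2"}.
#' @param variant \code{"five_element"} (default) or \code{"six_element"}.
#' @return character vector of rendered types, \code{NA} where no entry
#'   exists.
#' @examples
#' typeProteinAtom("HIS", "NE2")                  # "N;3;2;1;1"
#' typeProteinAtom("HIS", "NE2", "six_element")   # "N;3;2;1;1;1"
#' typeProteinAtom("XYZ", "FE1")                  # NA
#' @export
typeProteinAtom <- function(residue, atomName, variant = "five_element") {
  variant <- normalizeVariant(variant)
  tab <- proteinTypeTable()
  col <- if (variant == "five_element") "five_element_type"
         else "six_element_type"
  idx <- match(paste(toupper(residue), toupper(atomName)),
               paste(tab$residue, tab$atom_name))
  tab[[col]][idx]
}

#' Type a perceived ligand atom
#'
#' Copies the perceived attributes of a ligand heavy atom into the rendered
#' type string. The six-element variant inserts the aromaticity flag before
#' ring membership; the five-element variant omits it.
#'
#' @param atom a one-or-more-row data.frame with columns \code{element},
#'   \code{explicit_valence}, \code{n_heavy_neighbors},
#'   \code{n_attached_hydrogens}, \code{is_aromatic}, \code{in_ring}
#'   (as returned by [loadLigand()]).
#' @param variant \code{"five_element"} (default) or \code{"six_element"}.
#' @return character vector of rendered types, one per row.
#' @examples
#' atom <- data.frame(element = "N", explicit_valence = 3,
#'                    n_heavy_neighbors = 2, n_attached_hydrogens = 1,
#'                    is_aromatic = FALSE, in_ring = FALSE)
#' typeLigandAtom(atom, "six_element")   # "N;3;2;1;0;0"
#' typeLigandAtom(atom)                  # "N;3;2;1;0"
#' @export
typeLigandAtom <- function(atom, variant = "five_element") {
  variant <- normalizeVariant(variant)
  if (variant == "six_element")
    renderAtomType(atom$element, atom$explicit_valence,
                   atom$n_heavy_neighbors, atom$n_attached_hydrogens,
                   aromatic = atom$is_aromatic, ring = atom$in_ring)
  else
    renderAtomType(atom$element, atom$explicit_valence,
                   atom$n_heavy_neighbors, atom$n_attached_hydrogens,
                   ring = atom$in_ring)
}

#' Compose a pair name from a protein-side and a ligand-side type
#'
#' @param ptype rendered protein atom type(s).
#' @param ltype rendered ligand atom type(s), same variant.
#' @return \code{"<protein>-<ligand>"} with a single ASCII hyphen.
#' @examples
#' pairName("N;3;2;1;0;0", "O;2;1;1;0;0")
#' @export
pairName <- function(ptype, ltype) {
  vp <- typeVariantOf(ptype)
  vl <- typeVariantOf(ltype)
  if (anyNA(vp) || anyNA(vl))
    stop("malformed atom type in pairName()")
  if (any(vp != vl))
    stop("variant mismatch: protein type(s) are ", paste(unique(vp), collapse = "/"),
         " but ligand type(s) are ", paste(unique(vl), collapse = "/"))
  paste0(ptype, "-", ltype)
}

#' Build the pair vocabulary
#'
#' The vocabulary is the full cross product of the packaged protein-side
#' and ligand-side type lists, in deterministic order: protein types and
#' ligand types are each sorted bytewise, and pair names enumerate ligand
#' types within each protein type. Both variants span 1540 pair names
#' (22 protein x 70 ligand types); the five-element lists are the
#' aromaticity-free collapse of the six-element lists, which is one-to-one
#' on the packaged types.
#'
#' @param variant \code{"five_element"} (default) or \code{"six_element"}.
#' @param proteinTypes,ligandTypes optional explicit type lists (already
#'   rendered under \code{variant}); defaults to the packaged assets.
#' @return a [PairVocabulary-class].
#' @examples
#' v <- buildVocabulary()
#' length(pairNames(v))   # 1540
#' @export
buildVocabulary <- function(variant = "five_element",
                            proteinTypes = NULL, ligandTypes = NULL) {
  variant <- normalizeVariant(variant)
  if (is.null(proteinTypes)) {
    col <- if (variant == "five_element") "five_element_type"
           else "six_element_type"
    proteinTypes <- unique(proteinTypeTable()[[col]])
  }
  if (is.null(ligandTypes)) {
    lig6 <- readLines(pkgAsset("ligand_types.txt"))
    lig6 <- lig6[nzchar(lig6)]
    ligandTypes <- if (variant == "five_element") dropAromaticity(lig6)
                   else lig6
    if (anyDuplicated(ligandTypes))
      stop("ligand type list collapses to duplicates under variant ",
           variant)
  }
  proteinTypes <- sortC(unique(proteinTypes))
  ligandTypes <- sortC(unique(ligandTypes))
  pn <- as.vector(t(outer(proteinTypes, ligandTypes, paste, sep = "-")))
  new("PairVocabulary", variant = variant, proteinTypes = proteinTypes,
      ligandTypes = ligandTypes, pairNames = pn)
}
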