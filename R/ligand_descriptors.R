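#' The whole-ligand descriptor catalog
#'
#' Names of every descriptor [computeDescriptors()] reports, in canonical
#' order. Physicochemical properties (molecular weight, logP, topological
#' polar surface area, molar refractivity, hydrogen-bond donor/acceptor
#' counts) come from Open Babel via \pkg{ChemmineOB}; composition and
#' topology counts (atoms by element, bonds by order, rings, aromatic
#' rings) are derived from the connection table via \pkg{ChemmineR}.
#'
#' @return character vector of descriptor names.
#' @export
descriptorCatalog <- function() {
  c("MW", "LogP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
    "HeavyAtomCount", "nC", "nN", "nO", "nS", "nP", "nHal",
    "nBonds", "nSingleBonds", "nDoubleBonds", "nTripleBonds",
    "nAromaticBonds", "RingCount", "AromaticRingCount",
    "MaxRingSize", "FracRingAtoms")
}

#' Compute whole-ligand physicochemical descriptors
#'
#' One value per catalog descriptor (see [descriptorCatalog()]).
#' Descriptors that cannot be computed for a molecule are reported as
#' \code{NA} rather than dropped, so a downstream filter can act on them.
#'
#' @param ligand an SDF file path or a \code{ChemmineR::SDFset}.
#' @param molecule molecule index when several are present (default 1).
#' @return named numeric vector, names = \code{descriptorCatalog()}.
#' @examples
#' \donttest{
#' toy <- makeToyComplex(data.frame(protein_type = "N;3;2;1;0",
#'                                  ligand_type = "O;2;1;1;0",
#'                                  distance = 3))
#' computeDescriptors(toy$sdf)[c("MW", "HBD")]
#' }
#' @export
computeDescriptors <- function(ligand, molecule = 1L) {
  set <- if (is.character(ligand)) {
    tryCatch(suppressWarnings(ChemmineR::read.SDFset(ligand)),
             error = function(e) stop("perception failure for ligand '",
                                      ligand, "': ", conditionMessage(e),
                                      call. = FALSE))
  } else ligand
  if (!is(set, "SDFset")) stop("ligand must be an SDF path or an SDFset")
  if (length(set) < molecule) stop("no molecule ", molecule, " in ligand input")
  sdf <- set[[molecule]]
  out <- stats::setNames(rep(NA_real_, length(descriptorCatalog())),
                         descriptorCatalog())

  ob <- tryCatch(suppressWarnings(ChemmineR::propOB(set[molecule])),
                 error = function(e) NULL)
  if (!is.null(ob) && nrow(ob) >= 1L) {
    num <- function(col) if (col %in% names(ob)) as.numeric(ob[[col]][1L])
                         else NA_real_
    out["MW"] <- num("MW"); out["LogP"] <- num("logP")
    out["TPSA"] <- num("TPSA"); out["MR"] <- num("MR")
    out["HBA1"] <- num("HBA1"); out["HBA2"] <- num("HBA2")
    out["HBD"] <- num("HBD"); out["nF"] <- num("nF")
  }

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  heavy <- !elem %in% c("H", "D")
  out["HeavyAtomCount"] <- sum(heavy)
  out["nC"] <- sum(elem == "C"); out["nN"] <- sum(elem == "N")
  out["nO"] <- sum(elem == "O"); out["nS"] <- sum(elem == "S")
  out["nP"] <- sum(elem == "P")
  out["nHal"] <- sum(elem %in% c("F", "Cl", "Br", "I"))
  if (!is.null(bb) && nrow(bb)) {
    ord <- as.numeric(bb[, 3L])
    isH <- elem %in% c("H", "D")
    heavyBond <- !(isH[as.integer(bb[, 1L])] | isH[as.integer(bb[, 2L])])
    out["nBonds"] <- sum(heavyBond)
    out["nSingleBonds"] <- sum(ord == 1 & heavyBond)
    out["nDoubleBonds"] <- sum(ord == 2 & heavyBond)
    out["nTripleBonds"] <- sum(ord == 3 & heavyBond)
    out["nAromaticBonds"] <- sum(ord == 4 & heavyBond)
  }
  rr <- tryCatch(ChemmineR::rings(sdf, upper = 14, type = "all",
                                  arom = TRUE),
                 error = function(e) NULL)
  if (!is.null(rr)) {
    out["RingCount"] <- length(rr$RINGS)
    out["AromaticRingCount"] <- sum(unlist(rr$AROMATIC))
    sizes <- lengths(rr$RINGS)
    out["MaxRingSize"] <- if (length(sizes)) max(sizes) else 0
    ringAtoms <- unique(unlist(rr$RINGS))
    out["FracRingAtoms"] <- if (sum(heavy)) length(ringAtoms) / sum(heavy)
                            else 0
  }
  out
}

#' Filter a descriptor table the way the training protocol does
#'
#' Drops every descriptor with (a) zero variance across the table, (b) at
#' least one null (\code{NA}/\code{NaN}) value, or (c) any absolute value
#' exceeding \code{extremeBound}. The surviving names, in their original
#' order, define the retained descriptor list; that list is a function of
#' the training table only and is re-applied verbatim to new ligands
#' (never recomputed at prediction time), which guards against train/test
#' leakage.
#'
#' @param table matrix or data.frame, rows = ligands, columns =
#'   descriptors (named).
#' @param extremeBound absolute-value cutoff for "extreme" descriptor
#'   values (default 1e8, removing numeric-overflow artifacts without
#'   touching legitimate descriptors).
#' @return character vector of retained descriptor names.
#' @examples
#' tab <- cbind(MW = c(46, 78), Const = c(1, 1), Bad = c(NA, 2))
#' filterDescriptors(tab)   # "MW"
#' @export
filterDescriptors <- function(table, extremeBound = 1e8) {
  m <- as.matrix(table)
  if (is.null(colnames(m)) || nrow(m) == 0L)
    stop("descriptor table must be non-empty with named columns")
  storage.mode(m) <- "double"
  hasNull <- apply(m, 2L, function(v) any(!is.finite(v)))
  zeroVar <- apply(m, 2L, function(v) isTRUE(stats::var(v) == 0))
  extreme <- apply(m, 2L, function(v) any(abs(v) > extremeBound,
                                          na.rm = TRUE))
  keep <- !(hasNull | zeroVar | extreme)
  if (!any(keep)) stop("all descriptors were dropped by the filter")
  colnames(m)[keep]
}

#' Drop interaction features never observed in a training table
#'
#' The full vocabulary-cross-shell matrix carries many all-zero columns
#' (pair/shell combinations never seen in the training complexes).
#' Trained models conventionally keep only the observed columns; this
#' helper returns that observed-only view while leaving the full matrix
#' available.
#'
#' @param features feature matrix/data.frame, rows = complexes, named
#'   columns.
#' @return the input restricted to columns with at least one non-zero
#'   entry, column order preserved.
#' @export
dropZeroFeatures <- function(features) {
  m <- as.matrix(features)
  if (is.null(colnames(m))) stop("feature matrix must have column names")
  features[, colSums(m != 0) > 0, drop = FALSE]
}

#' Concatenate interaction features with retained ligand descriptors
#'
#' Interaction features come first, then the retained descriptors in the
#' retained-list order; feature names are preserved.
#'
#' @param interaction named numeric interaction feature vector.
#' @param descriptors named numeric descriptor vector for the same ligand.
#' @param retained character vector of retained descriptor names
#'   (a subset of \code{names(descriptors)}).
#' @return named numeric vector of length
#'   \code{length(interaction) + length(retained)}.
#' @export
assembleFeatures <- function(interaction, descriptors, retained) {
  if (is.null(names(interaction)) ||
      (length(descriptors) && is.null(names(descriptors))))
    stop("interaction and descriptor vectors must be named")
  missing <- setdiff(retained, names(descriptors))
  if (length(missing))
    stop("retained descriptor(s) missing from the descriptor vector: ",
         paste(missing, collapse = ", "))
  c(interaction, descriptors[retained])
}
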