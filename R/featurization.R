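#' Enumerate typed protein-ligand atom pairs within a distance threshold
#'
#' Every combination of a typed protein heavy atom and a typed ligand heavy
#' atom whose Euclidean distance is at most \code{threshold} (boundary
#' inclusive) yields one typed pair. Protein atoms without a dictionary
#' entry are skipped silently (they produce no features); ligand atoms
#' whose type is outside the packaged ligand vocabulary are skipped with a
#' warning.
#'
#' @param proteinAtoms data.frame from [loadProtein()].
#' @param ligandAtoms data.frame from [loadLigand()].
#' @param threshold distance threshold in Angstrom (> 0).
#' @param variant type variant, \code{"five_element"} (default) or
#'   \code{"six_element"}.
#' @param vocab optional [PairVocabulary-class]; defaults to
#'   \code{buildVocabulary(variant)}.
#' @return data.frame with columns \code{protein_type}, \code{ligand_type},
#'   \code{distance} (one row per contact).
#' @examples
#' \donttest{
#' toy <- makeToyComplex(data.frame(protein_type = "N;3;2;1;0",
#'                                  ligand_type = "O;2;1;1;0",
#'                                  distance = c(2, 3, 4)))
#' enumeratePairs(loadProtein(toy$pdb), loadLigand(toy$sdf), threshold = 6)
#' }
#' @export
enumeratePairs <- function(proteinAtoms, ligandAtoms, threshold = 6,
                           variant = "five_element", vocab = NULL) {
  stopifnot(threshold > 0)
  variant <- normalizeVariant(variant)
  if (is.null(vocab)) vocab <- buildVocabulary(variant)
  if (typeVariant(vocab) != variant)
    stop("vocabulary variant does not match requested variant")

  ptype <- typeProteinAtom(proteinAtoms$residue, proteinAtoms$atom_name,
                           variant)
  pKeep <- !is.na(ptype)
  ltype <- typeLigandAtom(ligandAtoms, variant)
  lKeep <- ltype %in% ligandTypes(vocab)
  if (any(!lKeep))
    warning("skipping ", sum(!lKeep),
            " ligand atom(s) with types outside the packaged vocabulary: ",
            paste(unique(ltype[!lKeep]), collapse = ", "))
  empty <- data.frame(protein_type = character(0),
                      ligand_type = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(pKeep) || !any(lKeep)) return(empty)

  P <- as.matrix(proteinAtoms[pKeep, c("x", "y", "z")])
  L <- as.matrix(ligandAtoms[lKeep, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d <= threshold, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  out <- data.frame(protein_type = ptype[pKeep][hit[, 1L]],
                    ligand_type = ltype[lKeep][hit[, 2L]],
                    distance = d[hit], stringsAsFactors = FALSE)
  out[order(hit[, 1L], hit[, 2L]), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Construct a shell scheme
#'
#' Shell upper bounds run \code{minShell, minShell + step, ...} and are
#' capped so the final bound equals \code{threshold} exactly; the terminal
#' shell may be narrower than \code{step}. The innermost shell is
#' (0, minShell]: the minimum shell is fixed at 2.5 Angstrom by default
#' because shorter protein-ligand contacts are essentially absent in
#' curated complexes.
#'
#' @param threshold outer distance threshold, Angstrom.
#' @param step constant shell width, Angstrom.
#' @param minShell upper bound of the innermost shell (default 2.5).
#' @return a [ShellScheme-class].
#' @examples
#' shellBounds(shellScheme(6, 2))    # 2.5 4.5 6.0
#' shellBounds(shellScheme(10, 2))   # 2.5 4.5 6.5 8.5 10.0
#' @export
shellScheme <- function(threshold, step, minShell = 2.5) {
  if (minShell >= threshold)
    stop("minShell must be smaller than threshold")
  if (step <= 0) stop("step must be > 0")
  b <- seq(minShell, threshold, by = step)
  if (b[length(b)] < threshold - 1e-9) b <- c(b, threshold)
  b[length(b)] <- threshold
  new("ShellScheme", minShell = minShell, step = step,
      threshold = threshold, bounds = b)
}

pairNamesOf <- function(pairs) paste0(pairs$protein_type, "-",
                                      pairs$ligand_type)

matchPairs <- function(pairs, vocab) {
  idx <- match(pairNamesOf(pairs), pairNames(vocab))
  if (anyNA(idx)) {
    bad <- unique(pairNamesOf(pairs)[is.na(idx)])
    warning("dropping ", sum(is.na(idx)),
            " pair(s) outside the vocabulary: ",
            paste(utils::head(bad, 5L), collapse = ", "))
  }
  idx
}

#' Multi-shelled pair-count features
#'
#' Subdivides the single-threshold pair counts into concentric distance
#' shells. Each feature is named \code{"<protein>-<ligand>-<bound>"} where
#' \code{<bound>} is the shell's upper limit; its value is the number of
#' pairs of that type whose distance falls in (previous bound, bound].
#' For three pairs of one type at 2, 3 and 4 Angstrom under bounds
#' 2.5/4.5/6.0 the three features take the values 1, 2 and 0.
#'
#' @param pairs data.frame from [enumeratePairs()], enumerated at
#'   \code{threshold = shellThreshold(scheme)}.
#' @param scheme a [ShellScheme-class].
#' @param vocab a [PairVocabulary-class] matching the pairs' variant.
#' @return named numeric vector of length
#'   \code{length(pairNames(vocab)) * length(shellBounds(scheme))}, ordered
#'   by vocabulary pair name, then shell bound ascending.
#' @export
multiShellFeatures <- function(pairs, scheme, vocab = buildVocabulary()) {
  stopifnot(is(scheme, "ShellScheme"), is(vocab, "PairVocabulary"))
  bounds <- shellBounds(scheme)
  nb <- length(bounds)
  pn <- pairNames(vocab)
  out <- numeric(length(pn) * nb)
  names(out) <- paste0(rep(pn, each = nb), "-",
                       rep(formatBound(bounds), length(pn)))
  if (nrow(pairs)) {
    if (any(pairs$distance > shellThreshold(scheme) + 1e-9))
      stop("pair distance exceeds the scheme threshold; enumerate pairs ",
           "at threshold = shellThreshold(scheme)")
    idx <- matchPairs(pairs, vocab)
    shell <- findInterval(pairs$distance, c(0, bounds) + 1e-9,
                          left.open = FALSE)
    keep <- !is.na(idx) & shell >= 1L & shell <= nb
    pos <- (idx[keep] - 1L) * nb + shell[keep]
    tab <- tabulate(pos, nbins = length(out))
    out[] <- tab
  }
  out
}

#' Inverse-distance-weighted pair features
#'
#' For each pair type, sums \code{1/d} (\code{squared = FALSE}) or
#' \code{1/d^2} (\code{squared = TRUE}) over all contacts of that type
#' within the enumeration threshold, reflecting the intuition that closer
#' contacts matter more. Three pairs of one type at 2, 3 and 4 Angstrom
#' with squared weights give 1/4 + 1/9 + 1/16 = 0.4236.
#'
#' @param pairs data.frame from [enumeratePairs()].
#' @param squared use inverse-square weights (default TRUE, the
#'   best-performing setting at a 10 Angstrom threshold).
#' @param vocab a [PairVocabulary-class].
#' @return named numeric vector of length \code{length(pairNames(vocab))}.
#' @export
weightedFeatures <- function(pairs, squared = TRUE,
                             vocab = buildVocabulary()) {
  stopifnot(is(vocab, "PairVocabulary"))
  pn <- pairNames(vocab)
  out <- numeric(length(pn))
  names(out) <- pn
  if (nrow(pairs)) {
    if (any(pairs$distance <= 0))
      stop("zero or negative pair distance: physically impossible contact")
    idx <- matchPairs(pairs, vocab)
    w <- if (squared) 1 / pairs$distance^2 else 1 / pairs$distance
    keep <- !is.na(idx)
    s <- rowsum(w[keep], group = idx[keep])
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

#' Single-threshold pair-count features (original ECIF)
#'
#' The number of contacts of each pair type within the enumeration
#' threshold; equals [multiShellFeatures()] with a single shell bound at
#' the threshold.
#'
#' @inheritParams weightedFeatures
#' @return named numeric vector of length \code{length(pairNames(vocab))}.
#' @export
ecifCounts <- function(pairs, vocab = buildVocabulary()) {
  stopifnot(is(vocab, "PairVocabulary"))
  pn <- pairNames(vocab)
  out <- numeric(length(pn))
  names(out) <- pn
  if (nrow(pairs)) {
    idx <- matchPairs(pairs, vocab)
    tab <- tabulate(idx[!is.na(idx)], nbins = length(pn))
    out[] <- tab
  }
  out
}

#' Featurize one protein-ligand complex from structure files
#'
#' Convenience wrapper: load both structures, enumerate typed pairs, and
#' compute the requested feature set. Defaults follow the tuned settings:
#' multi-shelled features at threshold 10 Angstrom with step 2.0; weighted
#' features at threshold 10 Angstrom with squared weights; original counts
#' at threshold 6 Angstrom.
#'
#' @param proteinPath PDB file.
#' @param ligandPath SDF file.
#' @param method \code{"multishell"}, \code{"weighted"} or \code{"ecif"}.
#' @param threshold distance threshold; default depends on \code{method}.
#' @param step shell width for \code{"multishell"} (default 2.0).
#' @param squared inverse-square weights for \code{"weighted"}
#'   (default TRUE).
#' @param variant type variant (default five-element).
#' @param vocab optional [PairVocabulary-class].
#' @return named numeric feature vector.
#' @export
featurizeComplex <- function(proteinPath, ligandPath,
                             method = c("multishell", "weighted", "ecif"),
                             threshold = NULL, step = 2.0, squared = TRUE,
                             variant = "five_element", vocab = NULL) {
  method <- match.arg(method)
  variant <- normalizeVariant(variant)
  if (is.null(threshold))
    threshold <- switch(method, multishell = 10, weighted = 10, ecif = 6)
  if (is.null(vocab)) vocab <- buildVocabulary(variant)
  pairs <- enumeratePairs(loadProtein(proteinPath), loadLigand(ligandPath),
                          threshold = threshold, variant = variant,
                          vocab = vocab)
  switch(method,
         multishell = multiShellFeatures(pairs,
                                         shellScheme(threshold, step),
                                         vocab),
         weighted = weightedFeatures(pairs, squared = squared, vocab = vocab),
         ecif = ecifCounts(pairs, vocab))
}
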