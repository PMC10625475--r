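# Fragment library: minimal explicit-hydrogen molecules whose perceived
# atom attributes are known by construction. Each fragment lists the
# five-element type of every heavy atom (hydrogens carry no type) and which
# atom realizes which requested type.
fragmentLibrary <- function() {
  if (!is.null(.msecifCache$fragments)) return(.msecifCache$fragments)
  frag <- function(atoms, bonds, types5) {
    a <- do.call(rbind, lapply(atoms, function(x)
      data.frame(element = x[[1]], x = x[[2]], y = x[[3]], z = x[[4]],
                 stringsAsFactors = FALSE)))
    b <- do.call(rbind, lapply(bonds, function(x)
      data.frame(a1 = x[1], a2 = x[2], order = x[3])))
    list(atoms = a, bonds = b, types5 = types5)
  }
  lib <- list(
    methanol = frag(
      list(list("C", 0, 0, 0), list("O", 1.43, 0, 0),
           list("H", -0.36, 1.028, 0), list("H", -0.36, -0.514, 0.89),
           list("H", -0.36, -0.514, -0.89), list("H", 1.75, 0.89, 0)),
      list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1), c(2, 6, 1)),
      c("C;4;1;3;0", "O;2;1;1;0")),
    ethane = frag(
      list(list("C", 0, 0, 0), list("C", 1.54, 0, 0),
           list("H", -0.39, 0.6, 0.82), list("H", -0.39, 0.41, -0.93),
           list("H", -0.39, -1.01, 0.11), list("H", 1.93, -0.6, -0.82),
           list("H", 1.93, -0.41, 0.93), list("H", 1.93, 1.01, -0.11)),
      list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1), c(2, 6, 1),
           c(2, 7, 1), c(2, 8, 1)),
      c("C;4;1;3;0", "C;4;1;3;0")),
    dimethylamine = frag(
      list(list("N", 0, 0, 0), list("C", 1.47, 0, 0),
           list("C", -0.73, 1.27, 0), list("H", -0.33, -0.85, 0.35),
           list("H", 1.84, 0.99, 0.26), list("H", 1.86, -0.73, 0.72),
           list("H", 1.83, -0.28, -0.99), list("H", -1.81, 1.12, 0.11),
           list("H", -0.38, 1.92, 0.81), list("H", -0.53, 1.77, -0.95)),
      list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(2, 5, 1), c(2, 6, 1),
           c(2, 7, 1), c(3, 8, 1), c(3, 9, 1), c(3, 10, 1)),
      c("N;3;2;1;0", "C;4;1;3;0", "C;4;1;3;0")),
    formaldehyde = frag(
      list(list("C", 0, 0, 0), list("O", 1.21, 0, 0),
           list("H", -0.55, 0.94, 0), list("H", -0.55, -0.94, 0)),
      list(c(1, 2, 2), c(1, 3, 1), c(1, 4, 1)),
      c("C;4;1;2;0", "O;2;1;0;0")),
    benzene = frag(
      list(list("C", 1.39, 0, 0), list("C", 0.695, 1.2037, 0),
           list("C", -0.695, 1.2037, 0), list("C", -1.39, 0, 0),
           list("C", -0.695, -1.2037, 0), list("C", 0.695, -1.2037, 0),
           list("H", 2.47, 0, 0), list("H", 1.235, 2.139, 0),
           list("H", -1.235, 2.139, 0), list("H", -2.47, 0, 0),
           list("H", -1.235, -2.139, 0), list("H", 1.235, -2.139, 0)),
      list(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1), c(5, 6, 2),
           c(6, 1, 1), c(1, 7, 1), c(2, 8, 1), c(3, 9, 1), c(4, 10, 1),
           c(5, 11, 1), c(6, 12, 1)),
      rep("C;4;2;1;1", 6)),
    trimethylamine = frag(
      list(list("N", 0, 0, 0), list("C", 1.45, 0, 0),
           list("C", -0.725, 1.256, 0), list("C", -0.725, -1.256, 0),
           list("H", 1.82, 0.51, 0.89), list("H", 1.82, 0.51, -0.89),
           list("H", 1.83, -1.02, 0), list("H", -1.8, 1.13, 0.1),
           list("H", -0.36, 1.87, 0.82), list("H", -0.47, 1.79, -0.92),
           list("H", -1.8, -1.13, 0.1), list("H", -0.36, -1.87, 0.82),
           list("H", -0.47, -1.79, -0.92)),
      list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(2, 5, 1), c(2, 6, 1),
           c(2, 7, 1), c(3, 8, 1), c(3, 9, 1), c(3, 10, 1), c(4, 11, 1),
           c(4, 12, 1), c(4, 13, 1)),
      c("N;3;3;0;0", "C;4;1;3;0", "C;4;1;3;0", "C;4;1;3;0")),
    methanethiol = frag(
      list(list("C", 0, 0, 0), list("S", 1.82, 0, 0),
           list("H", -0.36, 1.028, 0), list("H", -0.36, -0.514, 0.89),
           list("H", -0.36, -0.514, -0.89), list("H", 2.12, 1.27, 0)),
      list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1), c(2, 6, 1)),
      c("C;4;1;3;0", "S;2;1;1;0")),
    cyclohexane = frag(
      list(list("C", 1.262, 0.728, 0.25), list("C", 1.262, -0.728, -0.25),
           list("C", 0, -1.456, 0.25), list("C", -1.262, -0.728, -0.25),
           list("C", -1.262, 0.728, 0.25), list("C", 0, 1.456, -0.25),
           list("H", 2.14, 1.23, -0.15), list("H", 1.28, 0.74, 1.34),
           list("H", 2.14, -1.23, 0.15), list("H", 1.28, -0.74, -1.34),
           list("H", 0, -2.47, -0.15), list("H", 0, -1.48, 1.34),
           list("H", -2.14, -1.23, 0.15), list("H", -1.28, -0.74, -1.34),
           list("H", -2.14, 1.23, -0.15), list("H", -1.28, 0.74, 1.34),
           list("H", 0, 2.47, 0.15), list("H", 0, 1.48, -1.34)),
      list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1), c(5, 6, 1),
           c(6, 1, 1), c(1, 7, 1), c(1, 8, 1), c(2, 9, 1), c(2, 10, 1),
           c(3, 11, 1), c(3, 12, 1), c(4, 13, 1), c(4, 14, 1),
           c(5, 15, 1), c(5, 16, 1), c(6, 17, 1), c(6, 18, 1)),
      rep("C;4;2;2;1", 6))
  )
  .msecifCache$fragments <- lib
  lib
}

#' Ligand atom types realizable by the packaged fragment library
#'
#' @return character vector of five-element ligand types that
#'   [makeToyComplex()] can realize.
#' @export
realizableLigandTypes <- function() {
  sortC(unique(unlist(lapply(fragmentLibrary(), `[[`, "types5"))))
}

#' Protein atom types realizable by the packaged dictionary
#'
#' @return character vector of five-element protein types that
#'   [makeToyComplex()] can realize (all 22 dictionary types).
#' @export
realizableProteinTypes <- function() {
  sortC(unique(proteinTypeTable()$five_element_type))
}

fragmentForType <- function(type5) {
  lib <- fragmentLibrary()
  for (nm in names(lib)) {
    hit <- match(type5, lib[[nm]]$types5)
    if (!is.na(hit)) return(list(name = nm, frag = lib[[nm]], target = hit))
  }
  stop("unrealizable ligand type '", type5,
       "': no fragment in the packaged library produces it")
}

proteinAtomForType <- function(type5) {
  tab <- proteinTypeTable()
  hit <- which(tab$five_element_type == type5)
  if (!length(hit))
    stop("unrealizable protein type '", type5,
         "': no (residue, atom) dictionary entry produces it")
  tab[hit[1L], c("residue", "atom_name")]
}

# Rotation matrix mapping unit vector u onto unit vector v (Rodrigues).
rotationTo <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u; w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / sum(w^2))
}

writeFixturePdb <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom_name) < 4L, paste0(" ", atoms$atom_name),
           atoms$atom_name),
    atoms$residue, seq_len(nrow(atoms)),
    atoms$x, atoms$y, atoms$z, atoms$element)
  writeLines(c(lines, "END"), path)
}

writeFixtureSdf <- function(atoms, bonds, path, title = "msecif_fixture") {
  n <- nrow(atoms); b <- if (is.null(bonds)) 0L else nrow(bonds)
  header <- c(title, "  msecif          3D", "synthetic fixture")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, b)
  atomLines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       atoms$x, atoms$y, atoms$z, atoms$element)
  bondLines <- if (b) sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2,
                              bonds$order) else character(0)
  writeLines(c(header, counts, atomLines, bondLines, "M  END", "$$$$"),
             path)
}

#' Write a synthetic toy protein-ligand complex
#'
#' Realizes a list of requested typed pairs as a minimal PDB/SDF file
#' pair. Each request places one isolated protein atom (a residue/atom
#' name whose dictionary entry renders the requested protein type) and one
#' ligand fragment oriented so its realizing atom sits at exactly the
#' requested distance, on a station far enough from all other stations
#' that no cross-station contacts fall inside the widest supported
#' threshold. Requests sharing \code{station} are placed against the same
#' protein atom, which realizes multi-contact worked examples.
#'
#' Because any realizable ligand atom carries covalently bonded heavy
#' neighbors, those neighbors also form (predictable) typed pairs with the
#' station's protein atom; the returned \code{expected} table lists the
#' complete typed-pair set implied by the written geometry, so callers can
#' assert exact agreement with [enumeratePairs()].
#'
#' @param specs data.frame with columns \code{protein_type},
#'   \code{ligand_type} (five-element renderings), \code{distance}
#'   (Angstrom, > 0) and optionally \code{station} (integer grouping;
#'   default: rows requesting the same protein type share a station when
#'   \code{shareStations = TRUE}).
#' @param dir output directory (default: a fresh tempdir subdirectory).
#' @param threshold widest threshold the expectation table covers
#'   (default 10).
#' @param shareStations place pairs with identical protein type on a
#'   common protein atom (default TRUE, matching the worked-example
#'   geometry of several contacts to one typed environment).
#' @return list with \code{pdb}, \code{sdf} (file paths), \code{specs}
#'   (the request, with realized residue/atom names), and \code{expected}
#'   (data.frame \code{protein_type}, \code{ligand_type}, \code{distance},
#'   \code{requested} flag) covering every typed pair within
#'   \code{threshold}.
#' @examples
#' \donttest{
#' toy <- makeToyComplex(data.frame(protein_type = "N;3;2;1;0",
#'                                  ligand_type = "O;2;1;1;0",
#'                                  distance = c(2, 3, 4)))
#' subset(toy$expected, requested)
#' }
#' @export
makeToyComplex <- function(specs, dir = NULL, threshold = 10,
                           shareStations = TRUE) {
  if (is.null(dir)) dir <- tempfile("toycomplex")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdbPath <- file.path(dir, "protein.pdb")
  sdfPath <- file.path(dir, "ligand.sdf")

  if (nrow(specs) == 0L) {
    writeFixturePdb(data.frame(residue = "ALA", atom_name = "N",
                               element = "N", x = 0, y = 0, z = 0),
                    pdbPath)
    writeFixtureSdf(data.frame(element = c("C", "C"),
                               x = c(5000, 5001.54), y = 0, z = 0),
                    data.frame(a1 = 1L, a2 = 2L, order = 1L), sdfPath)
    return(list(pdb = pdbPath, sdf = sdfPath, specs = specs,
                expected = data.frame(protein_type = character(0),
                                      ligand_type = character(0),
                                      distance = numeric(0),
                                      requested = logical(0))))
  }
  stopifnot(all(c("protein_type", "ligand_type", "distance") %in%
                names(specs)))
  if (any(specs$distance <= 0)) stop("pair distances must be > 0")

  if (is.null(specs$station)) {
    specs$station <- if (shareStations)
      match(specs$protein_type, unique(specs$protein_type))
    else seq_len(nrow(specs))
  }
  stations <- sort(unique(specs$station))
  spacing <- 40 + 2 * threshold  # stations cannot interact

  protAtoms <- NULL; ligAtoms <- NULL; ligBonds <- NULL
  ligTypes5 <- character(0)
  stationOfLig <- integer(0)
  targetRow <- integer(nrow(specs))

  for (si in seq_along(stations)) {
    st <- stations[si]
    rows <- which(specs$station == st)
    ptype <- unique(specs$protein_type[rows])
    if (length(ptype) != 1L)
      stop("station ", st, " mixes different protein types")
    pa <- proteinAtomForType(ptype)
    origin <- c(0, (si - 1) * spacing, 0)
    protAtoms <- rbind(protAtoms, data.frame(
      residue = pa$residue, atom_name = pa$atom_name,
      element = parseAtomType(ptype)$symbol,
      x = origin[1], y = origin[2], z = origin[3],
      stringsAsFactors = FALSE))
    # spread this station's fragments over directions in the xz plane
    for (k in seq_along(rows)) {
      i <- rows[k]
      fr <- fragmentForType(specs$ligand_type[i])
      ang <- (k - 1) * (2 * pi / max(1L, length(rows))) / 3
      dirv <- c(cos(ang), 0, sin(ang))
      tpos <- origin + specs$distance[i] * dirv
      f <- fr$frag
      heavyIdx <- which(!f$atoms$element %in% c("H", "D"))
      tgt <- as.numeric(f$atoms[fr$target, c("x", "y", "z")])
      rel <- t(t(as.matrix(f$atoms[, c("x", "y", "z")])) - tgt)
      others <- rel[setdiff(heavyIdx, fr$target), , drop = FALSE]
      away <- if (nrow(others)) -colMeans(others) else c(1, 0, 0)
      if (sqrt(sum(away^2)) < 1e-9) away <- c(1, 0, 0)
      R <- rotationTo(-away, dirv)  # fragment body points outward
      placed <- t(R %*% t(rel)) + rep(tpos, each = nrow(rel))
      offset <- nrow(ligAtoms %||% data.frame())
      ligAtoms <- rbind(ligAtoms, data.frame(
        element = f$atoms$element, x = placed[, 1], y = placed[, 2],
        z = placed[, 3], stringsAsFactors = FALSE))
      fb <- f$bonds
      fb$a1 <- fb$a1 + offset; fb$a2 <- fb$a2 + offset
      ligBonds <- rbind(ligBonds, fb)
      t5 <- rep(NA_character_, nrow(f$atoms))
      t5[heavyIdx] <- f$types5
      ligTypes5 <- c(ligTypes5, t5)
      stationOfLig <- c(stationOfLig, rep(si, nrow(f$atoms)))
      targetRow[i] <- offset + fr$target
    }
  }

  # written precision: PDB 1e-3, SDF 1e-4
  protAtoms$x <- round(protAtoms$x, 3); protAtoms$y <- round(protAtoms$y, 3)
  protAtoms$z <- round(protAtoms$z, 3)
  ligAtoms$x <- round(ligAtoms$x, 4); ligAtoms$y <- round(ligAtoms$y, 4)
  ligAtoms$z <- round(ligAtoms$z, 4)

  writeFixturePdb(protAtoms, pdbPath)
  writeFixtureSdf(ligAtoms, ligBonds, sdfPath)

  # expectation table from the written (rounded) geometry
  P <- as.matrix(protAtoms[, c("x", "y", "z")])
  L <- as.matrix(ligAtoms[, c("x", "y", "z")])
  typed <- which(!is.na(ligTypes5))
  exp <- NULL
  for (pi_ in seq_len(nrow(P))) {
    d <- sqrt(colSums((t(L[typed, , drop = FALSE]) - P[pi_, ])^2))
    keep <- d <= threshold
    if (any(keep)) {
      ptype <- typeProteinAtom(protAtoms$residue[pi_],
                               protAtoms$atom_name[pi_], "five_element")
      exp <- rbind(exp, data.frame(
        protein_type = ptype, ligand_type = ligTypes5[typed[keep]],
        distance = d[keep],
        ligand_row = typed[keep], protein_row = pi_,
        stringsAsFactors = FALSE))
    }
  }
  exp$requested <- FALSE
  for (i in seq_len(nrow(specs))) {
    hit <- which(exp$ligand_row == targetRow[i] &
                 exp$protein_row ==
                   match(specs$station[i], stations) &
                 !exp$requested)
    if (length(hit)) exp$requested[hit[1L]] <- TRUE
  }
  exp <- exp[order(exp$protein_row, exp$ligand_row),
             c("protein_type", "ligand_type", "distance", "requested")]
  rownames(exp) <- NULL
  specs$residue <- protAtoms$residue[match(specs$station, stations)]
  specs$atom_name <- protAtoms$atom_name[match(specs$station, stations)]
  list(pdb = pdbPath, sdf = sdfPath, specs = specs, expected = exp)
}

#' Generate a synthetic affinity regression dataset
#'
#' Features mimic assembled interaction-plus-descriptor matrices: a block
#' of sparse non-negative integer "contact count" columns (mostly zero,
#' Poisson with small rates) and a block of dense continuous
#' "descriptor" columns. pK is a linear combination of the designated
#' informative features plus a mild two-way interaction and Gaussian
#' noise; everything is fully seeded.
#'
#' @param n number of complexes.
#' @param nInformative number of informative features (default 3).
#' @param noiseSd Gaussian noise SD in pK units (default 0.5).
#' @param seed random seed.
#' @param nSparse,nDense column counts for the two blocks (default 80/20).
#' @return list with \code{features} (data.frame), \code{pk} (numeric),
#'   \code{informative} (feature names carrying signal).
#' @examples
#' ds <- makeRegressionDataset(100, seed = 1)
#' ds$informative
#' @export
makeRegressionDataset <- function(n, nInformative = 3L, noiseSd = 0.5,
                                  seed = 1L, nSparse = 80L, nDense = 20L) {
  if (n < 10L) stop("n must be >= 10")
  if (nInformative < 1L || nInformative > nSparse + nDense)
    stop("nInformative must be in [1, nSparse + nDense]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  rates <- stats::rexp(nSparse, rate = 3)  # mostly << 1: sparse counts
  sparse <- vapply(rates, function(l) stats::rpois(n, l), numeric(n))
  colnames(sparse) <- sprintf("count_%03d", seq_len(nSparse))
  dense <- matrix(stats::rnorm(n * nDense), n, nDense,
                  dimnames = list(NULL, sprintf("desc_%03d",
                                                seq_len(nDense))))
  # informative columns alternate between the blocks and are guaranteed
  # non-degenerate (sparse informative columns get a healthy rate)
  nInfSparse <- min(nSparse, ceiling(nInformative / 2))
  infSparse <- seq_len(nInfSparse)
  for (j in infSparse) sparse[, j] <- stats::rpois(n, 2)
  infDense <- seq_len(nInformative - nInfSparse)
  informative <- c(colnames(sparse)[infSparse],
                   colnames(dense)[infDense])

  feats <- cbind(as.data.frame(sparse), as.data.frame(dense))
  z <- scale(as.matrix(feats[, informative, drop = FALSE]))
  coefs <- seq(2, 1, length.out = nInformative)
  signal <- as.vector(z %*% coefs)
  if (nInformative >= 2L) signal <- signal + 0.5 * z[, 1L] * z[, 2L]
  pk <- 6 + signal + stats::rnorm(n, 0, noiseSd)
  list(features = feats, pk = pk, informative = informative)
}
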