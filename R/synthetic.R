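## synthetic_data: ground-truth fixture generators. Every generator is a
## pure, deterministic function of its arguments (plus an explicit seed where
## noise is requested), and records its generating parameters in the model id
## or the series truth slot so tests never re-derive truth from the data.

## Smooth bounded space curve indexed by residue: distinct, non-collinear
## points spanning ~40 A, reused as the fold scaffold of all synthetic chains.
.scaffoldCurve <- function(i) {
  cbind(x = 20 * sin(0.31 * i), y = 20 * sin(0.47 * i + 1.3),
        z = 20 * sin(0.61 * i + 2.1))
}

.caAtoms <- function(chain, resno, resid, xyz, elety = "CA", elesym = "C",
                     het = FALSE) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesym = elesym, x = xyz[, 1L], y = xyz[, 2L],
             z = xyz[, 3L], o = 1, altloc = "", het = het,
             stringsAsFactors = FALSE)
}

.aa123 <- function(aa) {
  codes <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  unname(codes[strsplit(aa, "")[[1L]]])
}

#' Build a StructureModel from a raw atom table
#'
#' Constructor for programmatic models: fills in defaults (occupancy 1, no
#' altloc/insert) and assigns van der Waals radii from the bundled element
#' table where the `vdw` column is absent.
#'
#' @param id entry identifier.
#' @param atoms data.frame with at least `chain`, `resno`, `resid`, `elety`,
#'   `elesym`, `x`, `y`, `z`; optionally `insert`, `o`, `altloc`, `het`,
#'   `vdw`.
#' @return a [StructureModel-class].
#' @export
structureFromAtoms <- function(id, atoms) {
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  .newStructureModel(id, atoms, "synthetic")
}

#' Merge models into one
#'
#' Concatenates the atom tables of several models (chain ids must not
#' collide across models).
#'
#' @param models list of [StructureModel-class] objects.
#' @param id identifier of the merged model.
#' @return a [StructureModel-class].
#' @export
mergeModels <- function(models, id = "merged") {
  chains <- unlist(lapply(models, chainIds))
  if (anyDuplicated(chains))
    stop("argument error: chain ids collide across models")
  .newStructureModel(id, do.call(rbind, lapply(models, atomTable)),
                     models[[1L]]@sourceFormat)
}

#' Rigidly move (part of) a model
#'
#' @param model a [StructureModel-class].
#' @param shift length-3 translation, Angstrom.
#' @param rotation optional 3x3 rotation applied about the origin first.
#' @param chains chains to move (default all).
#' @return the moved [StructureModel-class].
#' @export
translateModel <- function(model, shift = c(0, 0, 0), rotation = NULL,
                           chains = NULL) {
  at <- model@atoms
  sel <- if (is.null(chains)) rep(TRUE, nrow(at)) else at$chain %in% chains
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  if (!is.null(rotation)) xyz <- xyz %*% t(rotation)
  at[sel, c("x", "y", "z")] <- sweep(xyz, 2L, shift, "+")
  .newStructureModel(model@id, at, model@sourceFormat)
}

#' Ideal alpha-helix model
#'
#' Calpha-only poly-alanine helix with constant rise and twist: consecutive
#' Calpha spacings and the helix radius are exactly constant, which makes it
#' the natural fixture for shift metrics and superposition checks.
#'
#' @param nRes number of residues (>= 4).
#' @param rise rise per residue along the axis, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom (2.3 approximates a real
#'   alpha-helix Calpha trace).
#' @param chain chain id.
#' @return a [StructureModel-class].
#' @export
makeIdealHelix <- function(nRes, rise = 1.5, twist = 100, radius = 2.3,
                           chain = "A") {
  if (nRes < 4L) stop("argument error: need at least 4 residues")
  i <- seq_len(nRes)
  th <- (i - 1L) * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), (i - 1L) * rise)
  .newStructureModel("synthetic_helix",
                     .caAtoms(chain, i, "ALA", xyz), "synthetic")
}

## Binder sequence: a repeated 10-mer unrelated to tubulin, length inside the
## binder length window used by the classifier.
.binderSequence <- function(nRes = 100L) {
  paste(rep(strsplit("ADKEWLRNGS", "")[[1L]], length.out = nRes),
        collapse = "")
}

#' Synthetic bent heterodimer with known inter-subunit rotation
#'
#' Builds a two-chain model carrying the bundled alpha (chain A) and beta
#' (chain B) reference sequences on a common fold scaffold. The beta chain is
#' a copy of the alpha scaffold (evaluated at the corresponding alpha
#' position for every beta residue) rotated by `angleDeg` about `axis` and
#' shifted by `offset`, so the ground-truth inter-subunit bend angle equals
#' `angleDeg` exactly and the full annotation path (classification,
#' alignment, correspondence) is exercised rather than mocked.
#'
#' @param angleDeg applied rotation, degrees, in [0, 180].
#' @param axis rotation axis (default z).
#' @param offset chain-B translation, Angstrom (default 40 along x: inside
#'   the 50 A heterodimer-pairing radius).
#' @param withBinder also add a 100-residue binder chain C hugging chain A
#'   (every binder Calpha 4 Angstrom off an alpha Calpha).
#' @param chains chain ids for alpha, beta (and binder).
#' @return a [StructureModel-class].
#' @export
makeBentDimer <- function(angleDeg, axis = c(0, 0, 1),
                          offset = c(40, 0, 0), withBinder = FALSE,
                          chains = c("A", "B", "C")) {
  if (angleDeg < 0 || angleDeg > 180)
    stop("argument error: angle must be in [0, 180] degrees")
  refs <- tubulinReferences()
  corr <- alphaBetaCorrespondence()
  seqA <- as.character(refs$alpha)
  seqB <- as.character(refs$beta)
  nA <- nchar(seqA)
  nB <- nchar(seqB)
  xyzA <- .scaffoldCurve(seq_len(nA))
  R <- .rotationAboutAxis(axis, angleDeg)
  ## beta residue j sits where the corresponding alpha scaffold point lands
  ## after the rotation; unmatched beta positions follow the curve directly.
  srcIdx <- corr$alpha_pos[match(seq_len(nB), corr$beta_pos)]
  srcIdx[is.na(srcIdx)] <- which(is.na(srcIdx)) + nA  # off-curve extension
  xyzB <- sweep(.scaffoldCurve(srcIdx) %*% t(R), 2L, offset, "+")
  atoms <- rbind(
    .caAtoms(chains[1L], seq_len(nA), .aa123(seqA), xyzA),
    .caAtoms(chains[2L], seq_len(nB), .aa123(seqB), xyzB))
  if (withBinder) {
    seqC <- .binderSequence()
    nC <- nchar(seqC)
    xyzC <- .scaffoldCurve(seq_len(nC)) + 4 / sqrt(3)
    atoms <- rbind(atoms, .caAtoms(chains[3L], seq_len(nC),
                                   .aa123(seqC), xyzC))
  }
  .newStructureModel(sprintf("synthetic_bent_dimer_%g", angleDeg), atoms,
                     "synthetic")
}

#' Sphere system with explicit radii
#'
#' Dummy atoms at given centers with given van der Waals radii; the SASA of
#' one or two spheres is analytically known, which makes these the oracle
#' fixtures for the surface-area quadrature.
#'
#' @param centers n x 3 matrix of centers, Angstrom.
#' @param radii length-n vector of van der Waals radii, Angstrom.
#' @param chain chain id.
#' @return a [StructureModel-class] (element `"X"`, one atom per residue).
#' @export
makeSphereSystem <- function(centers, radii, chain = "A") {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  if (nrow(centers) != length(radii))
    stop("argument error: one radius per center required")
  at <- .caAtoms(chain, seq_len(nrow(centers)), "SPH", centers,
                 elety = "X", elesym = "X")
  at$vdw <- as.numeric(radii)
  .newStructureModel("synthetic_spheres", at, "synthetic")
}

#' Toy protofilament lattice
#'
#' Straight (0 degree) heterodimers stacked head-to-tail along z at a fixed
#' repeat, emulating one protofilament for the graft-clash logic. Chains are
#' labelled A, B (first dimer), C, D (second), and so on; only the relative
#' geometry matters.
#'
#' @param nDimers number of stacked dimers (>= 2).
#' @param spacing longitudinal repeat per dimer, Angstrom (default 81, the
#'   approximate tubulin dimer repeat).
#' @return a [StructureModel-class].
#' @export
makeToyLattice <- function(nDimers = 2L, spacing = 81) {
  if (nDimers < 2L) stop("argument error: need at least 2 dimers")
  if (2L * nDimers > 26L) stop("argument error: too many dimers for PDB chains")
  models <- lapply(seq_len(nDimers) - 1L, function(k) {
    d <- makeBentDimer(0, offset = c(0, 0, 40),
                       chains = LETTERS[c(2L * k + 1L, 2L * k + 2L)])
    at <- d@atoms
    at$z <- at$z + k * spacing
    at
  })
  .newStructureModel("synthetic_lattice", do.call(rbind, models),
                     "synthetic")
}

#' Synthetic ITC data set
#'
#' Thin wrapper over [simulateItc()] with the standard titration geometry,
#' guaranteeing seed reproducibility; the generating parameters ride along in
#' the series' truth slot.
#'
#' @inheritParams simulateItc
#' @export
makeItcDataset <- function(params, geometry = itcGeometry(), noiseSd = 0,
                           seed = 1L) {
  simulateItc(params, geometry, noiseSd = noiseSd, seed = seed)
}

#' Write a standard fixture set to disk
#'
#' Emits the synthetic structures as PDB files and the synthetic isotherm as
#' CSV, each with a JSON sidecar recording the generating parameters (ground
#' truth). Used by the command-line `make-fixtures` subcommand.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the noisy isotherm.
#' @return invisibly, the manifest of files written.
#' @export
writeFixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  emit <- function(model, name, truth) {
    pdb <- file.path(dir, paste0(name, ".pdb"))
    writeStructure(model, pdb)
    jsonlite::write_json(truth, file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
    c(pdb, file.path(dir, paste0(name, ".json")))
  }
  for (ang in c(1.1, 11.9, 18.2))
    out <- c(out, emit(makeBentDimer(ang, withBinder = TRUE),
                       sprintf("bent_dimer_%04.1f", ang),
                       list(kind = "bent_dimer", angle_deg = ang)))
  out <- c(out, emit(makeToyLattice(3L), "toy_lattice",
                     list(kind = "lattice", n_dimers = 3, spacing = 81)))
  params <- list(n = 1, kd = 95e-9, dh = -16)
  ser <- makeItcDataset(params, noiseSd = 0.05, seed = seed)
  csv <- file.path(dir, "itc_synthetic.csv")
  utils::write.csv(titrationToFrame(ser), csv, row.names = FALSE)
  jsonlite::write_json(c(params, list(noiseSd = 0.05, seed = seed)),
                       file.path(dir, "itc_synthetic.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- c(out, csv, file.path(dir, "itc_synthetic.json"))
  invisible(out)
}

#' Tabular form of a titration series
#'
#' @param series a [TitrationSeries-class].
#' @return data.frame with columns `injection`, `volume_uL`, `heat_ucal`.
#' @export
titrationToFrame <- function(series) {
  g <- series@geometry
  data.frame(injection = seq_along(series@heats),
             volume_uL = g$injectionVolumes * 1e6,
             heat_ucal = series@heats)
}

#' Read a titration series from CSV
#'
#' Expects the [titrationToFrame()] layout (`volume_uL`, `heat_ucal`), plus
#' the cell geometry, which is not part of the CSV.
#'
#' @param path CSV path.
#' @param cellVolume,syringeConcentration,cellConcentration see
#'   [itcGeometry()].
#' @return a [TitrationSeries-class].
#' @export
readTitrationCsv <- function(path, cellVolume = 0.24e-3,
                             syringeConcentration = 160e-6,
                             cellConcentration = 15e-6) {
  tab <- utils::read.csv(path)
  if (!all(c("volume_uL", "heat_ucal") %in% names(tab)))
    stop("usage error: CSV must have columns volume_uL and heat_ucal")
  methods::new("TitrationSeries", heats = as.numeric(tab$heat_ucal),
               geometry = itcGeometry(cellVolume,
                                      as.numeric(tab$volume_uL) * 1e-6,
                                      syringeConcentration,
                                      cellConcentration),
               truth = list())
}
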