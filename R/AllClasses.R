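#' @import methods
NULL

#' StructureModel: hierarchical macromolecular coordinates
#'
#' An S4 container for one coordinate model. Atoms are held in a single
#' data.frame (`atoms`) in file order, one row per atom, with columns:
#' \describe{
#'   \item{chain}{chain identifier (single character for PDB output)}
#'   \item{resno, insert}{author residue number and insertion code (`""` if none)}
#'   \item{resid}{3-letter residue name}
#'   \item{elety}{atom name, unique within a residue after altloc resolution}
#'   \item{elesym}{chemical element symbol}
#'   \item{x, y, z}{coordinates, Angstrom}
#'   \item{o}{occupancy in [0, 1]}
#'   \item{altloc}{alternate-location code retained from the input (`""` if none)}
#'   \item{het}{TRUE for HETATM records (waters, nucleotides, ions)}
#'   \item{vdw}{van der Waals radius, Angstrom, from the bundled element table}
#' }
#'
#' @slot id entry identifier.
#' @slot atoms atom table as described above.
#' @slot sourceFormat one of `"pdb"`, `"mmcif"`, `"synthetic"`.
#' @export
setClass("StructureModel",
  representation(id = "character", atoms = "data.frame",
                 sourceFormat = "character"))

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "elesym",
                "x", "y", "z", "o", "altloc", "het", "vdw")

setValidity("StructureModel", function(object) {
  at <- object@atoms
  if (!all(.ATOM_COLS %in% names(at)))
    return(paste("atoms table must contain columns:",
                 paste(setdiff(.ATOM_COLS, names(at)), collapse = ", ")))
  if (nrow(at) == 0L) return("model must contain at least one atom")
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
    return("all coordinates must be finite")
  if (anyNA(at$chain) || any(at$chain == ""))
    return("every atom needs a chain id")
  TRUE
})

#' SuperpositionResult: rigid-body least-squares fit
#'
#' @slot rotation proper orthonormal 3x3 matrix.
#' @slot translation length-3 numeric, Angstrom. The fit maps a coordinate row
#'   vector p to `p %*% t(rotation) + translation`.
#' @slot rmsd root-mean-square deviation after fitting, Angstrom.
#' @slot nPoints number of point pairs used.
#' @slot rotationAngleDeg rotation magnitude `acos((tr(R) - 1) / 2)` in degrees,
#'   in [0, 180].
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nPoints = "integer",
                 rotationAngleDeg = "numeric"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!identical(dim(R), c(3L, 3L))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (R'R = I within 1e-8)")
  if (det(R) < 0) return("rotation must be proper (det + 1)")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (object@rmsd < 0) return("rmsd must be non-negative")
  TRUE
})

#' SasaResult: Shrake-Rupley solvent-accessible surface area
#'
#' @slot perAtomArea per-atom accessible area, Angstrom^2, in atom-table order.
#' @slot total total accessible area (sum of per-atom areas), Angstrom^2.
#' @slot probeRadius solvent probe radius, Angstrom.
#' @slot nSpherePoints number of quadrature points per atom sphere.
#' @export
setClass("SasaResult",
  representation(perAtomArea = "numeric", total = "numeric",
                 probeRadius = "numeric", nSpherePoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@perAtomArea < 0)) return("per-atom areas must be >= 0")
  if (abs(object@total - sum(object@perAtomArea)) > 1e-6)
    return("total must equal the sum of per-atom areas")
  TRUE
})

#' InterfaceReport: buried area, contacts and clashes between two chain sets
#'
#' @slot partnerA,partnerB chain ids of the two sides.
#' @slot bsaTotal buried surface area `SASA(A) + SASA(B) - SASA(AB)`,
#'   Angstrom^2 (`NA` when not computed).
#' @slot contacts data.frame of residue-residue contacts (one row per pair
#'   whose minimum heavy-atom distance is below the cutoff).
#' @slot clashCount number of heavy-atom pairs below the clash cutoff
#'   (`NA` when not computed).
#' @slot parameters list echoing probe radius, quadrature size and cutoffs.
#' @export
setClass("InterfaceReport",
  representation(partnerA = "character", partnerB = "character",
                 bsaTotal = "numeric", contacts = "data.frame",
                 clashCount = "integer", parameters = "list"))

#' TitrationSeries: per-injection ITC heats plus cell geometry
#'
#' @slot heats per-injection integrated heats, microcalories.
#' @slot geometry list with `cellVolume` (L), `injectionVolumes` (L, one per
#'   injection), `syringeConcentration` (molar) and `cellConcentration` (molar).
#' @slot truth list of generating parameters for synthetic series (empty for
#'   experimental data) so tests never re-derive ground truth from the data.
#' @export
setClass("TitrationSeries",
  representation(heats = "numeric", geometry = "list", truth = "list"))

setValidity("TitrationSeries", function(object) {
  g <- object@geometry
  need <- c("cellVolume", "injectionVolumes", "syringeConcentration",
            "cellConcentration")
  if (!all(need %in% names(g)))
    return(paste("geometry needs:", paste(need, collapse = ", ")))
  if (length(object@heats) != length(g$injectionVolumes))
    return("one heat per injection required")
  if (g$cellVolume <= 0 || any(g$injectionVolumes <= 0))
    return("volumes must be positive")
  TRUE
})

#' ItcFitResult: one-site (Wiseman) fit of a titration series
#'
#' @slot n fitted stoichiometry (sites per macromolecule).
#' @slot kd fitted dissociation constant, molar.
#' @slot dh fitted binding enthalpy, kcal/mol.
#' @slot temperature K.
#' @slot dg free energy `RT ln(Kd)`, kcal/mol.
#' @slot tds entropic term `dh - dg`, kcal/mol.
#' @slot se named standard errors for n, kd, dh (from the Jacobian).
#' @slot residualNorm residual sum of squares at the optimum, microcal^2.
#' @slot cValue Wiseman c = n * [cell] / Kd; values outside [1, 1000] are
#'   flagged in `notes` as ill-conditioned.
#' @slot notes character vector of fit diagnostics/warnings.
#' @export
setClass("ItcFitResult",
  representation(n = "numeric", kd = "numeric", dh = "numeric",
                 temperature = "numeric", dg = "numeric", tds = "numeric",
                 se = "numeric", residualNorm = "numeric", cValue = "numeric",
                 notes = "character"))

## ------------------------------------------------------------------
## Generics and accessors
## ------------------------------------------------------------------

#' Accessors for StructureModel
#'
#' `atomTable()` returns the atom data.frame (see
#' [StructureModel-class] for columns); `structureId()` the entry
#' identifier; `chainIds()` the unique chain identifiers in file order.
#'
#' @param x a [StructureModel-class].
#' @name StructureModel-accessors
#' @aliases atomTable structureId chainIds
NULL

#' @rdname StructureModel-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname StructureModel-accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
setMethod("structureId", "StructureModel", function(x) x@id)

#' @rdname StructureModel-accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
setMethod("chainIds", "StructureModel", function(x) unique(x@atoms$chain))

#' Accessors for TitrationSeries
#'
#' `injectionHeats()` returns the per-injection heats (microcal);
#' `itcGeometryOf()` the cell/injection geometry list; `seriesTruth()` the
#' generating parameters of a synthetic series (empty list for data read
#' from file).
#'
#' @param x a [TitrationSeries-class].
#' @name TitrationSeries-accessors
#' @aliases injectionHeats itcGeometryOf seriesTruth
NULL

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("injectionHeats", function(x) standardGeneric("injectionHeats"))
setMethod("injectionHeats", "TitrationSeries", function(x) x@heats)

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("itcGeometryOf", function(x) standardGeneric("itcGeometryOf"))
setMethod("itcGeometryOf", "TitrationSeries", function(x) x@geometry)

#' @rdname TitrationSeries-accessors
#' @export
setGeneric("seriesTruth", function(x) standardGeneric("seriesTruth"))
setMethod("seriesTruth", "TitrationSeries", function(x) x@truth)

setMethod("show", "StructureModel", function(object) {
  at <- object@atoms
  cat("StructureModel", shQuote(object@id),
      sprintf("[%s]\n", object@sourceFormat))
  ch <- unique(at$chain)
  cat(sprintf("  %d atoms, %d chains (%s)\n", nrow(at), length(ch),
              paste(ch, collapse = ", ")))
  nres <- nrow(unique(at[!at$het, c("chain", "resno", "insert")]))
  cat(sprintf("  %d polymer residues, %d hetero atoms\n", nres, sum(at$het)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf(
    "SuperpositionResult: rmsd %.4f A over %d points, rotation %.3f deg\n",
    object@rmsd, object@nPoints, object@rotationAngleDeg))
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf(
    "SasaResult: total %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
    object@total, length(object@perAtomArea), object@probeRadius,
    object@nSpherePoints))
})

setMethod("show", "InterfaceReport", function(object) {
  cat("InterfaceReport:", paste(object@partnerA, collapse = "+"), "vs",
      paste(object@partnerB, collapse = "+"), "\n")
  if (!is.na(object@bsaTotal))
    cat(sprintf("  buried surface area: %.1f A^2\n", object@bsaTotal))
  if (nrow(object@contacts))
    cat(sprintf("  %d residue-residue contacts\n", nrow(object@contacts)))
  if (!is.na(object@clashCount))
    cat(sprintf("  %d clashing atom pairs\n", object@clashCount))
})

setMethod("show", "TitrationSeries", function(object) {
  g <- object@geometry
  cat(sprintf(
    "TitrationSeries: %d injections, cell %.3g mL at %.3g uM, syringe %.3g uM\n",
    length(object@heats), g$cellVolume * 1e3, g$cellConcentration * 1e6,
    g$syringeConcentration * 1e6))
})

setMethod("show", "ItcFitResult", function(object) {
  cat("One-site ITC fit:\n")
  cat(sprintf("  n   = %.3f +/- %.3f\n", object@n, object@se["n"]))
  cat(sprintf("  Kd  = %.3g +/- %.3g M (c = %.1f)\n", object@kd,
              object@se["kd"], object@cValue))
  cat(sprintf("  dH  = %.2f +/- %.2f kcal/mol\n", object@dh, object@se["dh"]))
  cat(sprintf("  dG  = %.2f kcal/mol, TdS = %.2f kcal/mol at %.2f K\n",
              object@dg, object@tds, object@temperature))
  for (w in object@notes) cat("  note:", w, "\n")
})
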