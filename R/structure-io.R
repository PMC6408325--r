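## structure_model: coordinate I/O and atom selection.
## Parsing of the two standard dialects is delegated to bio3d (read.pdb /
## read.cif); this layer enforces the package's model policies: first model
## only, highest-occupancy altloc conformer, waters kept but flagged hetero,
## van der Waals radii assigned from the bundled element table.

.pkgEnv <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "bendkit")
  if (path == "") stop("bundled data file not found: ", file)
  path
}

#' Bundled van der Waals radius table
#'
#' Fixed element radii (Angstrom) used for SASA and clash detection, so that
#' surface areas are reproducible. C 1.70, N 1.55, O 1.52, S 1.80; the full
#' table is in `extdata/vdw_radii.tsv`. Element `"X"` is the generic dummy
#' used by synthetic systems with explicit radii.
#'
#' @return named numeric vector of radii keyed by upper-case element symbol.
#' @export
vdwRadii <- function() {
  if (is.null(.pkgEnv$vdw)) {
    tab <- utils::read.delim(.extdata("vdw_radii.tsv"), comment.char = "#")
    .pkgEnv$vdw <- stats::setNames(tab$radius, toupper(tab$element))
  }
  .pkgEnv$vdw
}

## Element symbol from a PDB atom name when the element column is absent:
## strip digits/primes, drop a leading digit, take the standard 1-2 letters.
.elementFromName <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA", "K")
  ifelse(nm %in% two, nm, substr(nm, 1L, 1L))
}

.standardAa <- function() {
  c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU","LYS",
    "MET","PHE","PRO","SER","THR","TRP","TYR","VAL","MSE")
}

## Build a validated StructureModel from a raw atom data.frame.
.newStructureModel <- function(id, atoms, sourceFormat) {
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  if (is.null(atoms$vdw))
    atoms$vdw <- unname(vdwRadii()[toupper(atoms$elesym)])
  rownames(atoms) <- NULL
  methods::new("StructureModel", id = id, atoms = atoms,
               sourceFormat = sourceFormat)
}

## Altloc policy: within (chain, resno, insert, elety) keep the conformer of
## highest occupancy; ties broken by altloc letter order.
.resolveAltlocs <- function(at) {
  if (!any(nzchar(at$altloc))) return(at)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$altloc)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), ]
  at[order(as.integer(rownames(at))), ]
}

#' Read a macromolecular coordinate file
#'
#' Reads PDB or mmCIF coordinates into a [StructureModel-class]. Only the
#' first deposited model of multi-model files is kept; alternate locations are
#' resolved to the highest-occupancy conformer (ties by altloc letter);
#' waters and other non-polymer components are retained but flagged hetero.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (inferred from the extension:
#'   `.cif`/`.mmcif` is mmCIF, anything else PDB).
#' @return a [StructureModel-class].
#' @examples
#' helix <- makeIdealHelix(10)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(helix, f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  if (format == "pdb") .checkPdbRecords(path)
  raw <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                         verbose = FALSE)
    else bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- raw$atom
  elesym <- at$elesy
  if (is.null(elesym)) elesym <- rep(NA_character_, nrow(at))
  miss <- is.na(elesym) | !nzchar(trimws(elesym))
  elesym[miss] <- .elementFromName(at$elety[miss])
  atoms <- data.frame(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    insert = as.character(at$insert), resid = as.character(at$resid),
    elety = as.character(at$elety), elesym = toupper(trimws(elesym)),
    x = at$x, y = at$y, z = at$z, o = as.numeric(at$o),
    altloc = as.character(at$alt),
    het = at$type == "HETATM", stringsAsFactors = FALSE)
  atoms <- .resolveAltlocs(atoms)
  m <- .newStructureModel(toupper(sub("\\.[^.]+$", "", basename(path))),
                          atoms, format)
  if (!any(!m@atoms$het & m@atoms$resid %in% .standardAa()))
    stop("empty model: no protein chains in '", path, "'")
  m
}

## Reject obviously truncated PDB input rather than building a partial model.
.checkPdbRecords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop("parse error in '", path, "': no coordinate records")
  bad <- rec[nchar(lines[rec]) < 54L]
  if (length(bad))
    stop("parse error in '", path, "': truncated coordinate record at line ",
         bad[1L])
  invisible(TRUE)
}

#' Write a StructureModel as a PDB file
#'
#' Emits fixed-width ATOM/HETATM records (coordinates to 3 decimals) with TER
#' separators, so that re-reading the file reproduces the model atom-wise.
#'
#' @param model a [StructureModel-class].
#' @param path output path.
#' @param format only `"pdb"` is supported.
#' @export
writeStructure <- function(model, path, format = "pdb") {
  stopifnot(is(model, "StructureModel"))
  if (!identical(format, "pdb")) stop("unsupported output format: ", format)
  at <- model@atoms
  if (any(nchar(at$chain) > 1L))
    stop("format error: PDB chain ids are a single character (got '",
         at$chain[which(nchar(at$chain) > 1L)[1L]], "')")
  if (any(abs(at[, c("x", "y", "z")]) >= 1e4))
    stop("format error: coordinates exceed PDB fixed-width fields")
  name <- ifelse(nchar(at$elety) < 4L, paste0(" ", at$elety), at$elety)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)) %% 100000L, name,
    substr(at$altloc, 1L, 1L), at$resid, at$chain, at$resno %% 10000L,
    substr(at$insert, 1L, 1L), at$x, at$y, at$z, at$o, 0, at$elesym)
  ter <- cumsum(rle(at$chain)$lengths)
  out <- character(0)
  prev <- 0L
  for (k in seq_along(ter)) {
    out <- c(out, lines[(prev + 1L):ter[k]], "TER")
    prev <- ter[k]
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Select atoms from a StructureModel
#'
#' Deterministic atom selection: the result is ordered by chain (in the order
#' requested), residue number, insertion code and atom name, independent of
#' file order. An empty selection is allowed and returns a zero-row table.
#'
#' @param model a [StructureModel-class].
#' @param chains chain ids (default all). Referencing a chain absent from the
#'   model is an error.
#' @param residues residue numbers to keep (default all).
#' @param atomNames atom names to keep, e.g. `"CA"` (default all).
#' @param heavyOnly drop hydrogens/deuteriums.
#' @param includeHet keep HETATM records (waters, ligands); default drops them.
#' @return atom data.frame (same columns as [atomTable()]).
#' @export
selectAtoms <- function(model, chains = NULL, residues = NULL,
                        atomNames = NULL, heavyOnly = FALSE,
                        includeHet = FALSE) {
  stopifnot(is(model, "StructureModel"))
  at <- model@atoms
  if (!is.null(chains)) {
    missing <- setdiff(chains, at$chain)
    if (length(missing))
      stop("selection error: no such chain(s): ",
           paste(missing, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
    at$chain <- factor(at$chain, levels = chains)
  }
  if (!includeHet) at <- at[!at$het, , drop = FALSE]
  if (!is.null(residues)) at <- at[at$resno %in% residues, , drop = FALSE]
  if (!is.null(atomNames)) at <- at[at$elety %in% atomNames, , drop = FALSE]
  if (heavyOnly) at <- at[!(at$elesym %in% c("H", "D")), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$elety), , drop = FALSE]
  at$chain <- as.character(at$chain)
  rownames(at) <- NULL
  at
}

#' Coordinate matrix of an atom table
#' @param atoms an atom data.frame (from [selectAtoms()] or [atomTable()]).
#' @return n x 3 numeric matrix.
#' @export
coordMatrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

## Subset a model by chains, preserving validity.
.subsetModel <- function(model, chains) {
  at <- model@atoms[model@atoms$chain %in% chains, , drop = FALSE]
  .newStructureModel(model@id, at, model@sourceFormat)
}
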