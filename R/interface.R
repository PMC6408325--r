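## interface_analysis: Shrake-Rupley solvent-accessible surface area on a
## deterministic golden-spiral quadrature, buried surface area, residue
## contact mapping and the lattice-graft steric-clash test.

#' Deterministic golden-spiral unit-sphere point set
#'
#' Near-uniform quadrature nodes on the unit sphere (spiral with the golden
#' angle), fully deterministic so surface areas are bit-reproducible.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
goldenSpiralPoints <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

## Atom table for surface work: heavy atoms, polymer only unless includeHet.
.sasaAtoms <- function(x, includeHet = FALSE) {
  at <- if (is(x, "StructureModel")) x@atoms else x
  at <- at[!(at$elesym %in% c("H", "D")), , drop = FALSE]
  if (!includeHet) at <- at[!at$het, , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms to analyze")
  bad <- unique(at$elesym[is.na(at$vdw)])
  if (length(bad))
    stop("configuration error: no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "))
  at
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a spherical probe over the heavy atoms: each atom's accessible area
#' is the fraction of test points on its expanded sphere (radius
#' `vdw + probeRadius`) not buried inside any neighboring expanded sphere,
#' times the expanded sphere area. Test points come from the deterministic
#' golden-spiral set, so results are exactly reproducible. Waters and other
#' hetero components are excluded by default.
#'
#' @param x a [StructureModel-class] or atom data.frame (with a `vdw` column).
#' @param probeRadius probe radius, Angstrom (water: 1.4).
#' @param nSpherePoints quadrature points per atom (default 960; quadrature
#'   error on a free sphere is well below 0.5 percent).
#' @param includeHet include hetero (ligand/water) atoms.
#' @return a [SasaResult-class].
#' @examples
#' s <- makeSphereSystem(matrix(0, 1, 3), 1.9)
#' shrakeRupleySasa(s)@total       # ~ 4*pi*(1.9+1.4)^2
#' @export
shrakeRupleySasa <- function(x, probeRadius = 1.4, nSpherePoints = 960L,
                             includeHet = FALSE) {
  at <- .sasaAtoms(x, includeHet)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rext <- at$vdw + probeRadius
  n <- nrow(xyz)
  sphere <- goldenSpiralPoints(nSpherePoints)
  area <- numeric(n)
  ## coarse neighbor prefilter on a grid of the largest interaction radius
  cell <- 2 * max(rext)
  key <- floor(sweep(xyz, 2L, apply(xyz, 2L, min)) / cell)
  keyStr <- paste(key[, 1L], key[, 2L], key[, 3L])
  cellIndex <- split(seq_len(n), keyStr)
  neighborCells <- function(i) {
    k <- key[i, ]
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    unlist(cellIndex[paste(k[1L] + offs[, 1L], k[2L] + offs[, 2L],
                           k[3L] + offs[, 3L])], use.names = FALSE)
  }
  for (i in seq_len(n)) {
    cand <- neighborCells(i)
    cand <- cand[cand != i]
    if (length(cand)) {
      dvec <- sweep(xyz[cand, , drop = FALSE], 2L, xyz[i, ])
      d2 <- rowSums(dvec^2)
      keep <- d2 < (rext[i] + rext[cand])^2
      cand <- cand[keep]
    }
    if (!length(cand)) {
      area[i] <- 4 * pi * rext[i]^2
      next
    }
    pts <- sweep(sphere * rext[i], 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, nSpherePoints)
    ord <- cand[order(rowSums(sweep(xyz[cand, , drop = FALSE],
                                    2L, xyz[i, ])^2))]
    for (j in ord) {
      if (!any(exposed)) break
      idx <- which(exposed)
      dj2 <- rowSums(sweep(pts[idx, , drop = FALSE], 2L,
                           as.numeric(xyz[j, ]))^2)
      exposed[idx[dj2 < rext[j]^2]] <- FALSE
    }
    area[i] <- 4 * pi * rext[i]^2 * sum(exposed) / nSpherePoints
  }
  methods::new("SasaResult", perAtomArea = area, total = sum(area),
               probeRadius = probeRadius, nSpherePoints = as.integer(nSpherePoints))
}

#' Buried surface area between two chain sets
#'
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)`, computed
#' with identical parameters throughout. Values that come out slightly
#' negative from quadrature noise (above -1 Angstrom^2) are reported as 0.
#'
#' @param model a [StructureModel-class].
#' @param partnerA,partnerB disjoint, non-empty chain-id sets.
#' @inheritParams shrakeRupleySasa
#' @return an [InterfaceReport-class] with `bsaTotal` filled in.
#' @export
buriedSurfaceArea <- function(model, partnerA, partnerB, probeRadius = 1.4,
                              nSpherePoints = 960L, includeHet = FALSE) {
  if (length(intersect(partnerA, partnerB)))
    stop("argument error: partner chain sets overlap")
  if (!length(partnerA) || !length(partnerB))
    stop("argument error: both partners must be non-empty")
  missing <- setdiff(c(partnerA, partnerB), chainIds(model))
  if (length(missing))
    stop("argument error: no such chain(s): ", paste(missing, collapse = ", "))
  sasaOf <- function(chains)
    shrakeRupleySasa(.subsetModel(model, chains), probeRadius,
                     nSpherePoints, includeHet)@total
  bsa <- sasaOf(partnerA) + sasaOf(partnerB) - sasaOf(c(partnerA, partnerB))
  if (bsa < 0 && bsa > -1) bsa <- 0
  methods::new("InterfaceReport", partnerA = partnerA, partnerB = partnerB,
               bsaTotal = bsa, contacts = data.frame(),
               clashCount = NA_integer_,
               parameters = list(probeRadius = probeRadius,
                                 nSpherePoints = nSpherePoints,
                                 includeHet = includeHet))
}

## All residue pairs across two atom sets with min heavy-atom distance below
## cutoff. Returns one row per residue pair.
.residueContacts <- function(atA, atB, cutoff) {
  xyzA <- as.matrix(atA[, c("x", "y", "z")])
  xyzB <- as.matrix(atB[, c("x", "y", "z")])
  resA <- paste(atA$chain, atA$resno, atA$insert, sep = "\r")
  resB <- paste(atB$chain, atB$resno, atB$insert, sep = "\r")
  hits <- list()
  step <- max(1L, floor(4e6 / max(1L, nrow(xyzB))))
  for (i0 in seq(1L, nrow(xyzA), by = step)) {
    idx <- i0:min(nrow(xyzA), i0 + step - 1L)
    d2 <- outer(rowSums(xyzA[idx, , drop = FALSE]^2), rowSums(xyzB^2), "+") -
      2 * xyzA[idx, , drop = FALSE] %*% t(xyzB)
    w <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(w))
      hits[[length(hits) + 1L]] <-
        data.frame(ia = idx[w[, 1L]], ib = w[, 2L],
                   dist = sqrt(pmax(0, d2[w])))
  }
  if (!length(hits))
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resid_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resid_b = character(0),
                      min_dist = numeric(0)))
  hits <- do.call(rbind, hits)
  key <- paste(resA[hits$ia], resB[hits$ib], sep = "\n")
  best <- tapply(hits$dist, key, min)
  first <- hits[!duplicated(key), ]
  first <- first[match(names(best), paste(resA[first$ia], resB[first$ib],
                                          sep = "\n")), ]
  out <- data.frame(
    chain_a = atA$chain[first$ia], resno_a = atA$resno[first$ia],
    resid_a = atA$resid[first$ia], chain_b = atB$chain[first$ib],
    resno_b = atB$resno[first$ib], resid_b = atB$resid[first$ib],
    min_dist = as.numeric(best))
  out <- out[order(out$chain_a, out$resno_a, out$chain_b, out$resno_b), ]
  rownames(out) <- NULL
  out
}

#' Residue-residue contacts between two chain sets
#'
#' Lists every residue pair whose minimum heavy-atom distance is below
#' `cutoff` (default 5 Angstrom, the conventional contact threshold for
#' interface mapping). When a residue map and registry are supplied for
#' partner B (the tubulin side), each contact is annotated with the canonical
#' position and the registry element containing it, so binder footprints can
#' be attributed to named tubulin elements (T7 loop, H8, H10-S9 loop, S9 and
#' so on).
#'
#' @param model a [StructureModel-class].
#' @param partnerA,partnerB disjoint chain-id sets (A: binder side, B:
#'   tubulin side by convention).
#' @param cutoff contact distance, Angstrom.
#' @param mapB optional residue map for the partner-B chain.
#' @param registry registry data.frame used for element attribution.
#' @return data.frame of contacts; columns `canonical_b` and `sse_b` are
#'   present when `mapB` is given.
#' @export
contactResidues <- function(model, partnerA, partnerB, cutoff = 5,
                            mapB = NULL, registry = loadSseRegistry()) {
  if (length(intersect(partnerA, partnerB)))
    stop("argument error: partner chain sets overlap")
  atA <- selectAtoms(model, chains = partnerA, heavyOnly = TRUE)
  atB <- selectAtoms(model, chains = partnerB, heavyOnly = TRUE)
  out <- .residueContacts(atA, atB, cutoff)
  if (!is.null(mapB) && nrow(out)) {
    idx <- match(paste(out$resno_b, ""), paste(mapB$resno, mapB$insert))
    out$canonical_b <- mapB$canonical[idx]
    sse <- registry[registry$category != "domain", ]
    out$sse_b <- vapply(out$canonical_b, function(p) {
      if (is.na(p)) return(NA_character_)
      hit <- sse$name[sse$start <= p & sse$end >= p]
      if (length(hit)) hit[1L] else NA_character_
    }, character(1))
  }
  out
}

#' Steric-clash test of a complex grafted onto a lattice
#'
#' Superposes the alpha-tubulin of a complex onto a chosen alpha subunit of a
#' lattice model (protofilament / microtubule fragment) using the
#' N-terminal-domain helix/strand Calpha, applies the transform to the
#' binder's heavy atoms, and counts binder/lattice heavy-atom pairs closer
#' than `clashCutoff`. A positive count means the binder cannot be
#' accommodated at that lattice site - the geometric argument for why an
#' alpha-tubulin longitudinal-surface binder blocks head-to-tail tubulin
#' association.
#'
#' @param complexModel complex structure (tubulin + binder).
#' @param latticeModel lattice structure with at least 2 longitudinally
#'   adjacent heterodimers.
#' @param targetAlphaChain lattice alpha-tubulin chain to graft onto.
#' @param binderChain binder chain of the complex (default: first binder of
#'   the first heterodimer pair).
#' @param clashCutoff heavy-atom clash distance, Angstrom (default 2.2, well
#'   below any plausible nonbonded separation).
#' @param registry registry data.frame.
#' @return an [InterfaceReport-class] with `clashCount` and per-pair details
#'   in `contacts`.
#' @export
latticeGraftClash <- function(complexModel, latticeModel, targetAlphaChain,
                              binderChain = NULL, clashCutoff = 2.2,
                              registry = loadSseRegistry()) {
  annC <- annotateModel(complexModel, registry)
  annL <- annotateModel(latticeModel, registry)
  rolesL <- annL$roles
  if (!targetAlphaChain %in%
      rolesL$chain_id[rolesL$role == "alpha_tubulin"])
    stop("argument error: chain ", targetAlphaChain,
         " is not an alpha-tubulin chain of the lattice model")
  if (is.null(binderChain)) {
    binders <- unlist(lapply(annC$pairs, `[[`, "binders"))
    if (!length(binders)) stop("argument error: complex model has no binder")
    binderChain <- binders[1L]
  }
  if (!binderChain %in% chainIds(complexModel))
    stop("argument error: no chain ", binderChain, " in the complex model")
  hit <- which(vapply(annC$pairs, function(p)
    binderChain %in% p$binders, logical(1)))
  alphaC <- if (length(hit)) annC$pairs[[hit[1L]]]$alpha else
    annC$pairs[[1L]]$alpha
  xyzC <- getElementCalphas(complexModel, annC$maps[[alphaC]],
                            "alpha_tubulin", domain = "n_terminal",
                            registry = registry)
  xyzL <- getElementCalphas(latticeModel, annL$maps[[targetAlphaChain]],
                            "alpha_tubulin", domain = "n_terminal",
                            registry = registry)
  common <- intersect(rownames(xyzC), rownames(xyzL))
  if (length(common) < 3L)
    stop("geometry error: too few common alpha positions for the graft")
  fit <- kabschFit(xyzC[common, , drop = FALSE],
                   xyzL[common, , drop = FALSE])
  atB <- selectAtoms(complexModel, chains = binderChain, heavyOnly = TRUE)
  atB[, c("x", "y", "z")] <- applyTransform(atB, fit)
  atL <- selectAtoms(latticeModel, chains = chainIds(latticeModel),
                     heavyOnly = TRUE)
  pairs <- .atomClashes(atB, atL, clashCutoff)
  methods::new("InterfaceReport", partnerA = binderChain,
               partnerB = setdiff(chainIds(latticeModel), character(0)),
               bsaTotal = NA_real_, contacts = pairs,
               clashCount = nrow(pairs),
               parameters = list(clashCutoff = clashCutoff,
                                 targetAlphaChain = targetAlphaChain,
                                 graftRmsd = fit@rmsd))
}

## Atom pairs below cutoff (one row per atom pair, not per residue).
.atomClashes <- function(atA, atB, cutoff) {
  xyzA <- as.matrix(atA[, c("x", "y", "z")])
  xyzB <- as.matrix(atB[, c("x", "y", "z")])
  rows <- list()
  step <- max(1L, floor(4e6 / max(1L, nrow(xyzB))))
  for (i0 in seq(1L, nrow(xyzA), by = step)) {
    idx <- i0:min(nrow(xyzA), i0 + step - 1L)
    d2 <- outer(rowSums(xyzA[idx, , drop = FALSE]^2), rowSums(xyzB^2), "+") -
      2 * xyzA[idx, , drop = FALSE] %*% t(xyzB)
    w <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(w)) {
      ia <- idx[w[, 1L]]
      ib <- w[, 2L]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = atA$chain[ia], resno_a = atA$resno[ia],
        atom_a = atA$elety[ia], chain_b = atB$chain[ib],
        resno_b = atB$resno[ib], atom_b = atB$elety[ib],
        dist = sqrt(pmax(0, d2[w])))
    }
  }
  if (!length(rows))
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      atom_a = character(0), chain_b = character(0),
                      resno_b = integer(0), atom_b = character(0),
                      dist = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
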