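## conformation_metrics: heterodimer pairing, inter-subunit bend angle,
## bend-angle survey, H7 helix shift and the pairwise complex RMSD matrix.

#' Annotate a model: roles, residue maps and heterodimer pairing in one pass
#'
#' Convenience wrapper running [classifyChains()], [buildResidueMap()] for
#' every tubulin chain and [pairHeterodimers()].
#'
#' @param model a [StructureModel-class].
#' @param registry registry data.frame (default bundled).
#' @return list with elements `roles` (data.frame), `maps` (named list of
#'   residue maps keyed by chain id) and `pairs` (list of heterodimer pairs).
#' @export
annotateModel <- function(model, registry = loadSseRegistry()) {
  roles <- classifyChains(model)
  tub <- roles[roles$role %in% c("alpha_tubulin", "beta_tubulin"), ]
  maps <- lapply(seq_len(nrow(tub)), function(i)
    buildResidueMap(model, tub$chain_id[i], tub$role[i]))
  names(maps) <- tub$chain_id
  list(roles = roles, maps = maps,
       pairs = pairHeterodimers(model, roles))
}

#' Pair alpha and beta chains into heterodimers and attach binders
#'
#' Each alpha chain is paired with the nearest unpaired beta chain by Calpha
#' centroid distance, provided it lies within 50 Angstrom; binder chains are
#' attached to the pair whose tubulin heavy atoms they approach within 5
#' Angstrom. Pairing is deterministic (alpha chains processed in file order).
#' Unpairable tubulin chains are excluded and listed in the `"warnings"`
#' attribute.
#'
#' @param model a [StructureModel-class].
#' @param roles role table from [classifyChains()].
#' @param maxCentroidDist pairing radius, Angstrom.
#' @return list of pairs, each `list(alpha =, beta =, binders =)`.
#' @export
pairHeterodimers <- function(model, roles, maxCentroidDist = 50) {
  centroid <- function(ch)
    colMeans(coordMatrix(selectAtoms(model, chains = ch, atomNames = "CA")))
  alphas <- roles$chain_id[roles$role == "alpha_tubulin"]
  betas <- roles$chain_id[roles$role == "beta_tubulin"]
  warnings <- character(0)
  pairs <- list()
  freeBetas <- betas
  betaCent <- if (length(betas)) t(vapply(betas, centroid, numeric(3))) else
    matrix(0, 0, 3)
  for (a in alphas) {
    if (!length(freeBetas)) {
      warnings <- c(warnings, paste("alpha chain", a, "left unpaired"))
      next
    }
    ca <- centroid(a)
    d <- sqrt(rowSums(sweep(betaCent[match(freeBetas, betas), , drop = FALSE],
                            2L, ca)^2))
    if (min(d) > maxCentroidDist) {
      warnings <- c(warnings, paste("alpha chain", a, "has no beta within",
                                    maxCentroidDist, "A"))
      next
    }
    b <- freeBetas[which.min(d)]
    freeBetas <- setdiff(freeBetas, b)
    pairs[[length(pairs) + 1L]] <- list(alpha = a, beta = b,
                                        binders = character(0))
  }
  if (length(freeBetas))
    warnings <- c(warnings, paste("beta chain(s) left unpaired:",
                                  paste(freeBetas, collapse = ", ")))
  for (bc in roles$chain_id[roles$role == "binder"]) {
    bx <- coordMatrix(selectAtoms(model, chains = bc, heavyOnly = TRUE))
    dmin <- vapply(pairs, function(p) {
      tx <- coordMatrix(selectAtoms(model, chains = c(p$alpha, p$beta),
                                    heavyOnly = TRUE))
      .minInterDistance(bx, tx)
    }, numeric(1))
    if (length(dmin) && min(dmin) < 5)
      pairs[[which.min(dmin)]]$binders <-
        c(pairs[[which.min(dmin)]]$binders, bc)
    else warnings <- c(warnings, paste("binder chain", bc,
                                       "contacts no heterodimer"))
  }
  attr(pairs, "warnings") <- warnings
  pairs
}

## Coordinates of the bend-angle reference set for one pair: Calpha of the
## N-terminal-domain helix/strand positions having an alpha<->beta
## correspondence and being modeled in both chains.
.bendAngleSets <- function(model, pair, maps, registry, corr) {
  posA <- registryPositions(registry, domain = "n_terminal")
  corrSub <- corr[corr$alpha_pos %in% posA, , drop = FALSE]
  mapA <- maps[[pair$alpha]]
  mapB <- maps[[pair$beta]]
  if (is.null(mapA) || is.null(mapB))
    stop("geometry error: both chains of the pair must carry residue maps")
  corrSub <- corrSub[corrSub$alpha_pos %in% mapA$canonical &
                       corrSub$beta_pos %in% mapB$canonical, , drop = FALSE]
  xyzA <- getElementCalphas(model, mapA, "alpha_tubulin",
                            domain = "n_terminal", registry = registry)
  xyzA <- xyzA[match(corrSub$alpha_pos, as.integer(rownames(xyzA))), ,
               drop = FALSE]
  atB <- selectAtoms(model, chains = pair$beta, atomNames = "CA")
  idxB <- match(paste(mapB$resno, mapB$insert)[
    match(corrSub$beta_pos, mapB$canonical)],
    paste(atB$resno, atB$insert))
  keep <- !is.na(idxB) & !is.na(xyzA[, 1L])
  list(alpha = xyzA[keep, , drop = FALSE],
       beta = coordMatrix(atB[idxB[keep], , drop = FALSE]),
       n = sum(keep))
}

#' Inter-subunit bend (curvature) angle of one heterodimer
#'
#' The rotation relating the alpha and beta subunit frames, obtained by
#' superposing the Calpha of the alpha N-terminal-domain helix/strand
#' elements onto the structurally equivalent beta positions (fixed
#' alpha/beta correspondence table) and taking the rotation angle of the
#' fit. Straight, microtubule-like tubulin scores close to 0 degrees; curved
#' soluble tubulin 10 degrees or more. At least 50 correspondence positions
#' must be modeled in both chains for a reportable value. The result is
#' invariant under any global rigid motion of the model.
#'
#' @param model a [StructureModel-class].
#' @param pair heterodimer pair from [pairHeterodimers()].
#' @param maps named list of residue maps (see [annotateModel()]).
#' @param registry registry data.frame.
#' @param corr alpha/beta correspondence table.
#' @param minPositions minimum usable positions.
#' @return list with `pair`, `angle_deg`, `n_positions_used`, `fit_rmsd`.
#' @export
interSubunitBendAngle <- function(model, pair, maps,
                                  registry = loadSseRegistry(),
                                  corr = alphaBetaCorrespondence(),
                                  minPositions = 50L) {
  sets <- .bendAngleSets(model, pair, maps, registry, corr)
  if (sets$n < minPositions)
    stop("geometry error: only ", sets$n, " alpha/beta correspondence ",
         "positions resolved (need ", minPositions, ")")
  fit <- kabschFit(sets$alpha, sets$beta)
  list(pair = pair, angle_deg = fit@rotationAngleDeg,
       n_positions_used = sets$n, fit_rmsd = fit@rmsd)
}

#' Bend-angle survey over a set of structures
#'
#' Runs annotation, pairing and [interSubunitBendAngle()] for every entry,
#' reporting one row per heterodimer plus a per-entry mean. Rows of the
#' per-entry table are sorted by mean angle ascending. Entries that fail
#' annotation are reported in the `skipped` element, not silently dropped.
#'
#' @param entries named list of [StructureModel-class] objects, or a
#'   character vector of file paths.
#' @param registry registry data.frame.
#' @return list with `perDimer` (data.frame: entry_id, alpha_chain,
#'   beta_chain, angle_deg, n_positions, fit_rmsd), `perEntry` (data.frame:
#'   entry_id, mean_angle_deg, n_dimers) and `skipped` (data.frame:
#'   entry_id, reason).
#' @export
bendAngleSurvey <- function(entries, registry = loadSseRegistry()) {
  if (is.character(entries)) {
    paths <- entries
    entries <- lapply(paths, function(p)
      tryCatch(readStructure(p), error = function(e) e))
    names(entries) <- toupper(sub("\\.[^.]+$", "", basename(paths)))
  }
  if (is.null(names(entries)))
    names(entries) <- paste0("entry", seq_along(entries))
  corr <- alphaBetaCorrespondence()
  perDimer <- list()
  skipped <- list()
  for (id in names(entries)) {
    model <- entries[[id]]
    rows <- tryCatch({
      if (inherits(model, "error")) stop(conditionMessage(model))
      ann <- annotateModel(model, registry)
      if (!length(ann$pairs)) stop("no heterodimer pairs found")
      do.call(rbind, lapply(ann$pairs, function(p) {
        r <- interSubunitBendAngle(model, p, ann$maps, registry, corr)
        data.frame(entry_id = id, alpha_chain = p$alpha, beta_chain = p$beta,
                   angle_deg = r$angle_deg, n_positions = r$n_positions_used,
                   fit_rmsd = r$fit_rmsd)
      }))
    }, error = function(e)
      structure(conditionMessage(e), class = "skipReason"))
    if (inherits(rows, "skipReason"))
      skipped[[length(skipped) + 1L]] <-
        data.frame(entry_id = id, reason = unclass(rows))
    else perDimer[[length(perDimer) + 1L]] <- rows
  }
  perDimer <- if (length(perDimer)) do.call(rbind, perDimer) else
    data.frame(entry_id = character(0), alpha_chain = character(0),
               beta_chain = character(0), angle_deg = numeric(0),
               n_positions = integer(0), fit_rmsd = numeric(0))
  perEntry <- if (nrow(perDimer)) {
    agg <- stats::aggregate(angle_deg ~ entry_id, perDimer, mean)
    cnt <- stats::aggregate(angle_deg ~ entry_id, perDimer, length)
    out <- data.frame(entry_id = agg$entry_id,
                      mean_angle_deg = agg$angle_deg,
                      n_dimers = cnt$angle_deg)
    out[order(out$mean_angle_deg), ]
  } else data.frame(entry_id = character(0), mean_angle_deg = numeric(0),
                    n_dimers = integer(0))
  rownames(perEntry) <- NULL
  list(perDimer = perDimer, perEntry = perEntry,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(entry_id = character(0), reason = character(0)))
}

#' Shift of a named element between two structures after domain alignment
#'
#' Superposes the query alpha subunit onto the reference alpha subunit using
#' the Calpha of the N-terminal-domain helix/strand elements (common modeled
#' canonical positions), then reports the displacement between the two
#' element Calpha centroids. This is the metric behind the observation that
#' the H7 central helix translates by about 1 Angstrom between differently
#' curved alpha-subunit conformations.
#'
#' @param refModel,refPair,refMaps reference structure, pair and maps.
#' @param queryModel,queryPair,queryMaps query structure, pair and maps.
#' @param element registry element name (default `"H7"`).
#' @param registry registry data.frame.
#' @return list with `element`, `shift_A` (centroid displacement, Angstrom),
#'   `alignment_rmsd`, `n_align`, `n_element`.
#' @export
helixShift <- function(refModel, refPair, refMaps, queryModel, queryPair,
                       queryMaps, element = "H7",
                       registry = loadSseRegistry()) {
  refMap <- refMaps[[refPair$alpha]]
  qMap <- queryMaps[[queryPair$alpha]]
  alignRef <- getElementCalphas(refModel, refMap, "alpha_tubulin",
                                domain = "n_terminal", registry = registry)
  alignQ <- getElementCalphas(queryModel, qMap, "alpha_tubulin",
                              domain = "n_terminal", registry = registry)
  common <- intersect(rownames(alignRef), rownames(alignQ))
  if (length(common) < 3L)
    stop("geometry error: too few common N-terminal-domain positions")
  fit <- kabschFit(alignQ[common, , drop = FALSE],
                   alignRef[common, , drop = FALSE])
  elRef <- getElementCalphas(refModel, refMap, "alpha_tubulin",
                             names = element, registry = registry)
  elQ <- getElementCalphas(queryModel, qMap, "alpha_tubulin",
                           names = element, registry = registry)
  commonEl <- intersect(rownames(elRef), rownames(elQ))
  if (!length(commonEl))
    stop("geometry error: element ", element,
         " not resolved in both structures")
  cRef <- colMeans(elRef[commonEl, , drop = FALSE])
  cQ <- colMeans(applyTransform(elQ[commonEl, , drop = FALSE], fit))
  list(element = element, shift_A = sqrt(sum((cRef - cQ)^2)),
       alignment_rmsd = fit@rmsd, n_align = length(common),
       n_element = length(commonEl))
}

#' Pairwise RMSD matrix over the complexes of one model
#'
#' For models with several copies of the complex (e.g. three per asymmetric
#' unit), computes the Kabsch-fit RMSD between every pair of copies over the
#' common resolved Calpha set: tubulin positions modeled in all copies (in
#' canonical numbering, per role) plus binder positions sharing author
#' numbering across copies.
#'
#' @param model a [StructureModel-class].
#' @param pairs heterodimer pairs (each ideally with one binder).
#' @param maps named list of residue maps.
#' @return symmetric matrix of RMSDs (Angstrom), zero diagonal, with
#'   attribute `"nPoints"` giving the size of the common Calpha set.
#' @export
pairwiseComplexRmsd <- function(model, pairs, maps) {
  if (length(pairs) < 2L)
    stop("not applicable: need at least 2 complexes, got ", length(pairs))
  caOf <- function(chain) selectAtoms(model, chains = chain, atomNames = "CA")
  roleCommon <- function(slot) {
    Reduce(intersect, lapply(pairs, function(p) maps[[p[[slot]]]]$canonical))
  }
  commonA <- roleCommon("alpha")
  commonB <- roleCommon("beta")
  nBind <- min(vapply(pairs, function(p) length(p$binders), integer(1)))
  commonBind <- if (nBind >= 1L)
    Reduce(intersect, lapply(pairs, function(p) caOf(p$binders[1L])$resno))
  else integer(0)
  stack <- lapply(pairs, function(p) {
    coordsFor <- function(chain, canon) {
      map <- maps[[chain]]
      at <- caOf(chain)
      idx <- match(paste(map$resno, map$insert)[match(canon, map$canonical)],
                   paste(at$resno, at$insert))
      coordMatrix(at[idx, , drop = FALSE])
    }
    xyz <- rbind(coordsFor(p$alpha, commonA), coordsFor(p$beta, commonB))
    if (length(commonBind)) {
      at <- caOf(p$binders[1L])
      xyz <- rbind(xyz, coordMatrix(at[match(commonBind, at$resno), ,
                                       drop = FALSE]))
    }
    xyz
  })
  n <- length(stack)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <- kabschFit(stack[[i]], stack[[j]])@rmsd
  }
  attr(out, "nPoints") <- nrow(stack[[1L]])
  out
}
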