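## tubulin_annotation: chain role calls, canonical residue numbering and the
## secondary-structure-element registry. Global sequence alignment is done
## with Biostrings::pairwiseAlignment; everything downstream works in the
## canonical numbering of the bundled alpha-tubulin reference.

#' Bundled tubulin reference sequences
#'
#' Consensus mammalian brain alpha- (451 aa) and beta-tubulin (444 aa)
#' reference sequences defining the canonical residue numbering used by the
#' registry, shipped as FASTA under `extdata/` so users can substitute their
#' own references.
#'
#' @param alphaPath,betaPath optional paths to replacement FASTA files.
#' @return named list of two `AAString` objects, `alpha` and `beta`.
#' @export
tubulinReferences <- function(alphaPath = NULL, betaPath = NULL) {
  if (is.null(alphaPath) && is.null(betaPath) && !is.null(.pkgEnv$refs))
    return(.pkgEnv$refs)
  a <- Biostrings::readAAStringSet(
    if (is.null(alphaPath)) .extdata("tubulin_alpha_ref.fasta") else alphaPath)
  b <- Biostrings::readAAStringSet(
    if (is.null(betaPath)) .extdata("tubulin_beta_ref.fasta") else betaPath)
  refs <- list(alpha = a[[1L]], beta = b[[1L]])
  if (is.null(alphaPath) && is.null(betaPath)) .pkgEnv$refs <- refs
  refs
}

#' Load the secondary-structure-element registry
#'
#' The registry names tubulin elements (H7, T7 loop, H8, S8, S9, H10, the
#' H1-S2 and H10-S9 loops, ...) and the tripartite domain partition
#' (N-terminal 1-205, intermediate 206-381, C-terminal 382-440) as inclusive
#' canonical residue intervals in alpha-tubulin numbering. Helix and strand
#' intervals must not overlap, element names are unique, and the three
#' domains are ordered and disjoint. The default file can be replaced by any
#' TSV of the same layout.
#'
#' @param path optional path to a replacement registry TSV.
#' @return data.frame with columns `name`, `category`
#'   (`helix|strand|loop|domain`), `start`, `end`.
#' @export
loadSseRegistry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pkgEnv$registry)) return(.pkgEnv$registry)
    path <- .extdata("sse_registry.tsv")
    cache <- TRUE
  } else cache <- FALSE
  reg <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "category", "start", "end") %in% names(reg)))
  if (any(reg$end < reg$start)) stop("registry: interval end before start")
  if (anyDuplicated(reg$name)) stop("registry: duplicated element names")
  sse <- reg[reg$category %in% c("helix", "strand"), ]
  pos <- unlist(mapply(seq.int, sse$start, sse$end, SIMPLIFY = FALSE))
  if (anyDuplicated(pos)) stop("registry: overlapping helix/strand intervals")
  dom <- reg[reg$category == "domain", ]
  if (nrow(dom) != 3L || is.unsorted(dom$start) ||
      any(dom$start[-1L] <= dom$end[-3L]))
    stop("registry: domain partition must be three ordered disjoint intervals")
  if (cache) .pkgEnv$registry <- reg
  reg
}

#' @describeIn loadSseRegistry canonical positions covered by named elements,
#'   or by all helix/strand elements inside a named domain.
#' @param registry a registry data.frame.
#' @param names element names to resolve.
#' @param domain domain name (`"n_terminal"`, `"intermediate"`,
#'   `"c_terminal"`); helices and strands inside it are used, loops excluded.
#' @export
registryPositions <- function(registry, names = NULL, domain = NULL) {
  if (is.null(names) == is.null(domain))
    stop("give exactly one of 'names' or 'domain'")
  if (!is.null(names)) {
    rows <- registry[registry$name %in% names, ]
    if (nrow(rows) < length(names))
      stop("unknown registry element(s): ",
           paste(setdiff(names, registry$name), collapse = ", "))
  } else {
    dom <- registry[registry$category == "domain" & registry$name == domain, ]
    if (nrow(dom) != 1L) stop("unknown domain: ", domain)
    rows <- registry[registry$category %in% c("helix", "strand") &
                       registry$start >= dom$start & registry$end <= dom$end, ]
  }
  sort(unique(unlist(mapply(seq.int, rows$start, rows$end,
                            SIMPLIFY = FALSE))))
}

#' Alpha/beta canonical position correspondence
#'
#' Fixed position table pairing canonical alpha positions with canonical beta
#' positions, derived from the global alignment of the bundled references and
#' shipped as TSV. Only positions aligned in both subunits appear.
#'
#' @param path optional replacement TSV with columns `alpha_pos`, `beta_pos`.
#' @return data.frame with columns `alpha_pos`, `beta_pos`.
#' @export
alphaBetaCorrespondence <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkgEnv$corr))
      .pkgEnv$corr <- utils::read.delim(
        .extdata("alpha_beta_correspondence.tsv"), comment.char = "#")
    return(.pkgEnv$corr)
  }
  utils::read.delim(path, comment.char = "#")
}

## One-letter sequence of a chain's polymer residues, plus their author ids,
## ordered by residue number then insertion code.
.chainResidues <- function(model, chain) {
  at <- model@atoms
  at <- at[at$chain == chain & !at$het & at$resid %in% .standardAa(), ,
           drop = FALSE]
  if (!nrow(at)) return(NULL)
  res <- unique(at[, c("resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), ]
  res$aa <- bio3d::aa321(res$resid)
  res$aa[res$resid == "MSE"] <- "M"
  res[res$aa != "X", , drop = FALSE]
}

## Alignment-free k-mer similarity: fraction of the chain's k-mers present in
## the reference. 1.0 for a chain identical to the reference.
.kmerScore <- function(seq, ref, k = 4L) {
  if (nchar(seq) < k) return(0)
  kmers <- function(s) {
    n <- nchar(s)
    unique(substring(s, seq_len(n - k + 1L), k:n))
  }
  qs <- kmers(seq)
  mean(qs %in% kmers(ref))
}

#' Classify chains as alpha-tubulin, beta-tubulin, binder or other
#'
#' Protein chains are scored against the bundled alpha and beta references by
#' alignment-free k-mer similarity; a chain is called tubulin when its best
#' score reaches `threshold` (0.6 by default: tubulin paralogs score far
#' above it, unrelated binders far below). Non-tubulin chains of 80-300
#' residues lying within 5 Angstrom (heavy atoms) of a tubulin chain are
#' called `binder`; everything else is `other`. The result is independent of
#' chain order.
#'
#' @param model a [StructureModel-class].
#' @param threshold minimum k-mer identity for a tubulin call.
#' @return data.frame with columns `chain_id`, `role`, `identity_score`.
#' @export
classifyChains <- function(model, threshold = 0.6) {
  refs <- tubulinReferences()
  refA <- as.character(refs$alpha)
  refB <- as.character(refs$beta)
  chains <- chainIds(model)
  rows <- lapply(chains, function(ch) {
    res <- .chainResidues(model, ch)
    if (is.null(res) || nrow(res) == 0L) return(NULL)
    seq <- paste(res$aa, collapse = "")
    sa <- .kmerScore(seq, refA)
    sb <- .kmerScore(seq, refB)
    role <- if (max(sa, sb) >= threshold) {
      if (sa >= sb) "alpha_tubulin" else "beta_tubulin"
    } else "unassigned"
    data.frame(chain_id = ch, role = role,
               identity_score = max(sa, sb), n_res = nrow(res))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("annotation error: no protein chains")
  if (!any(tab$role %in% c("alpha_tubulin", "beta_tubulin")))
    stop("annotation error: no tubulin chain found; scores: ",
         paste(sprintf("%s=%.2f", tab$chain_id, tab$identity_score),
               collapse = ", "))
  tubChains <- tab$chain_id[tab$role %in% c("alpha_tubulin", "beta_tubulin")]
  tubXyz <- coordMatrix(selectAtoms(model, chains = tubChains,
                                    heavyOnly = TRUE))
  for (i in which(tab$role == "unassigned")) {
    near <- FALSE
    if (tab$n_res[i] >= 80L && tab$n_res[i] <= 300L) {
      xyz <- coordMatrix(selectAtoms(model, chains = tab$chain_id[i],
                                     heavyOnly = TRUE))
      near <- .minInterDistance(xyz, tubXyz, cutoff = 5) < 5
    }
    tab$role[i] <- if (near) "binder" else "other"
  }
  tab$n_res <- NULL
  rownames(tab) <- NULL
  tab
}

## Minimum distance between two coordinate sets, chunked to bound memory.
.minInterDistance <- function(a, b, cutoff = 0) {
  best <- Inf
  step <- max(1L, floor(2e6 / max(1L, nrow(b))))
  for (i0 in seq(1L, nrow(a), by = step)) {
    idx <- i0:min(nrow(a), i0 + step - 1L)
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[idx, , drop = FALSE] %*% t(b)
    best <- min(best, sqrt(max(0, min(d2))))
    if (best < cutoff) return(best)
  }
  best
}

#' Map author residue numbering onto canonical tubulin numbering
#'
#' Globally aligns the chain sequence to the bundled reference of its role
#' (BLOSUM62, gap open 10, extend 0.5); aligned positions define the
#' one-to-one, monotone author-to-canonical map. Disordered (unmodeled)
#' canonical positions are simply absent from the map.
#'
#' @param model a [StructureModel-class].
#' @param chainId chain to map.
#' @param role `"alpha_tubulin"` or `"beta_tubulin"`.
#' @param minIdentity alignment percent-identity threshold below which the
#'   chain is rejected (default 60).
#' @return data.frame with columns `chain_id`, `resno`, `insert`, `canonical`.
#' @export
buildResidueMap <- function(model, chainId, role, minIdentity = 60) {
  stopifnot(role %in% c("alpha_tubulin", "beta_tubulin"))
  refs <- tubulinReferences()
  ref <- if (role == "alpha_tubulin") refs$alpha else refs$beta
  res <- .chainResidues(model, chainId)
  if (is.null(res) || nrow(res) < 10L)
    stop("annotation error: chain ", chainId, " has too few residues")
  seq <- Biostrings::AAString(paste(res$aa, collapse = ""))
  pa <- Biostrings::pairwiseAlignment(
    seq, ref, type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  if (Biostrings::pid(pa, type = "PID2") < minIdentity)
    stop("annotation error: chain ", chainId, " aligns to the ", role,
         " reference at ", round(Biostrings::pid(pa, type = "PID2"), 1),
         "% identity (< ", minIdentity, "%)")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qi <- cumsum(pat != "-")
  ri <- cumsum(sub != "-")
  keep <- pat != "-" & sub != "-"
  data.frame(chain_id = chainId, resno = res$resno[qi[keep]],
             insert = res$insert[qi[keep]], canonical = ri[keep])
}

## Translate alpha-canonical registry positions into the numbering of the
## requested subunit; beta positions go through the correspondence table.
.subunitPositions <- function(positions, role, corr = alphaBetaCorrespondence()) {
  if (role == "alpha_tubulin") return(positions)
  corr$beta_pos[match(positions, corr$alpha_pos)][
    positions %in% corr$alpha_pos]
}

#' Calpha coordinates of registry elements for a mapped tubulin chain
#'
#' Returns the Calpha coordinates of the residues falling inside the
#' requested registry element(s) (or inside all helix/strand elements of a
#' domain), ordered by canonical position. Registry intervals are stated in
#' alpha numbering; for a beta chain they are translated through the
#' alpha/beta correspondence table. Positions unmodeled in the chain are
#' skipped and reported in the `"skipped"` attribute.
#'
#' @param model a [StructureModel-class].
#' @param map residue map from [buildResidueMap()].
#' @param role `"alpha_tubulin"` or `"beta_tubulin"`.
#' @param names,domain element selector, passed to [registryPositions()].
#' @param registry registry data.frame (default bundled).
#' @return n x 3 coordinate matrix with canonical positions as rownames.
#' @export
getElementCalphas <- function(model, map, role, names = NULL, domain = NULL,
                              registry = loadSseRegistry()) {
  want <- registryPositions(registry, names = names, domain = domain)
  want <- .subunitPositions(want, role)
  hit <- map[map$canonical %in% want, , drop = FALSE]
  hit <- hit[order(hit$canonical), ]
  at <- selectAtoms(model, chains = unique(map$chain_id), atomNames = "CA")
  key <- paste(at$resno, at$insert)
  idx <- match(paste(hit$resno, hit$insert), key)
  hit <- hit[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (length(idx) < 3L)
    stop("geometry error: only ", length(idx),
         " of ", length(want), " requested positions resolvable in chain ",
         unique(map$chain_id))
  xyz <- coordMatrix(at[idx, , drop = FALSE])
  rownames(xyz) <- hit$canonical
  attr(xyz, "skipped") <- setdiff(want, hit$canonical)
  xyz
}
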