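## C-alpha contact maps and ensemble contact probabilities, typed
## side-chain contact detection and censuses, and a geometric
## hydrogen-bond counter.

#' ContactProbabilityMatrix: per-pair contact probabilities
#'
#' @slot pairs data.frame with columns \code{chain_i}, \code{res_i},
#'   \code{chain_j}, \code{res_j}, \code{i}, \code{j} (global indices),
#'   \code{class}, \code{probability}, \code{n_eff} (denominator used).
#' @slot cutoff C-alpha cutoff (A).
#' @slot weighting "per-model" or "per-frame".
#' @slot n_frames,n_models ensemble sizes the aggregation saw.
#' @exportClass ContactProbabilityMatrix
setClass("ContactProbabilityMatrix",
         representation(pairs = "data.frame", cutoff = "numeric",
                        weighting = "character", n_frames = "integer",
                        n_models = "integer"))

setValidity("ContactProbabilityMatrix", function(object) {
  p <- object@pairs
  if (nrow(p) && (any(p$probability < 0) || any(p$probability > 1)))
    return("probabilities must lie in [0, 1]")
  if (nrow(p) && any(p$i >= p$j)) return("pairs must be canonical (i < j)")
  TRUE
})

setMethod("show", "ContactProbabilityMatrix", function(object) {
  cat(sprintf(paste0("ContactProbabilityMatrix: %d pairs (< %.1f A), %s ",
                     "weighting over %d frames / %d models\n"),
              nrow(object@pairs), object@cutoff, object@weighting,
              object@n_frames, object@n_models))
})

#' Global residue index of a dimer or ensemble
#'
#' Residues of the first chain come first, then the second chain, each in
#' residue-number order; for ensembles the union over frames is indexed so
#' full and truncated models address the same matrix rows.
#'
#' @param x \linkS4class{DimerStructure} or \linkS4class{StructureEnsemble}.
#' @return data.frame: \code{chain}, \code{resnum}, \code{global}.
#' @export
globalIndexMap <- function(x) {
  fr <- if (is(x, "StructureEnsemble")) x@frames else list(x)
  labs <- vapply(fr[[1L]]@chains, chainLabel, character(1L))
  per_chain <- lapply(labs, function(lab) {
    nums <- sort(unique(unlist(lapply(fr, function(f) {
      ch <- dimerChains(f)[[lab]]
      if (is.null(ch)) integer() else unique(ch@atoms$resnum)
    }))))
    data.frame(chain = lab, resnum = nums, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chain)
  out$global <- seq_len(nrow(out))
  out
}

pairKey <- function(chain_i, res_i, chain_j, res_j)
  paste(chain_i, res_i, chain_j, res_j, sep = "|")

#' C-alpha contact map of one frame
#'
#' All and only residue pairs whose C-alpha distance is strictly below the
#' cutoff, classified by chain pairing (e.g. K1-K1, K10-K10, K1-K10).
#' Intra-chain pairs closer than \code{exclusion} in sequence are dropped
#' (near-diagonal pairs are trivially in contact).
#'
#' @param frame a \linkS4class{DimerStructure}.
#' @param cutoff C-alpha distance cutoff in Angstrom (strict \code{<}).
#' @param exclusion intra-chain sequence exclusion: pairs with
#'   |res_i - res_j| <= exclusion are skipped.
#' @param index optional global index map (from \code{\link{globalIndexMap}}
#'   of the enclosing ensemble) so truncated frames address shared indices.
#' @return a \linkS4class{ContactMap}.
#' @export
caContactMap <- function(frame, cutoff = 12, exclusion = 2L, index = NULL) {
  if (is.null(index)) index <- globalIndexMap(frame)
  tabs <- lapply(frame@chains, function(ch) {
    ca <- caCoords(ch)
    data.frame(chain = ch@label, resnum = as.integer(rownames(ca)),
               x = ca[, 1L], y = ca[, 2L], z = ca[, 3L],
               stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, tabs)
  m <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(m)
  d2 <- outer(rowSums(m^2), rowSums(m^2), "+") - 2 * m %*% t(m)
  hit <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit)) {
    ci <- at$chain[hit[, 1L]]; cj <- at$chain[hit[, 2L]]
    ri <- at$resnum[hit[, 1L]]; rj <- at$resnum[hit[, 2L]]
    keep <- !(ci == cj & abs(ri - rj) <= exclusion)
    ci <- ci[keep]; cj <- cj[keep]; ri <- ri[keep]; rj <- rj[keep]
    gi <- index$global[match(paste(ci, ri), paste(index$chain, index$resnum))]
    gj <- index$global[match(paste(cj, rj), paste(index$chain, index$resnum))]
    swap <- gi > gj
    tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
    tmpc <- ci[swap]; ci[swap] <- cj[swap]; cj[swap] <- tmpc
    tmpr <- ri[swap]; ri[swap] <- rj[swap]; rj[swap] <- tmpr
    pairs <- data.frame(i = gi, j = gj, chain_i = ci, res_i = ri,
                        chain_j = cj, res_j = rj,
                        class = paste(ci, cj, sep = "-"),
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(i = integer(), j = integer(), chain_i = character(),
                        res_i = integer(), chain_j = character(),
                        res_j = integer(), class = character(),
                        stringsAsFactors = FALSE)
  }
  new("ContactMap", pairs = pairs, cutoff = cutoff,
      exclusion = as.integer(exclusion), frame_id = frame@frame_id)
}

#' Aggregate contact maps into per-pair probabilities
#'
#' The probability of a pair is the weighted fraction of frames in which it
#' is in contact. Pairs involving residues absent from truncated models are
#' averaged only over the models (or frames) that contain both residues, so
#' mixed full/truncated ensembles are normalized for their differing
#' residue counts. With "per-model" weighting (default) each model
#' contributes its within-model frame frequency with equal weight; with
#' "per-frame" every frame counts equally.
#'
#' @param maps list of \linkS4class{ContactMap}, one per ensemble frame, in
#'   frame order.
#' @param ensemble the \linkS4class{StructureEnsemble} the maps came from.
#' @param weighting "per-model" or "per-frame".
#' @return a \linkS4class{ContactProbabilityMatrix}.
#' @export
aggregateContactProbability <- function(maps, ensemble,
                                        weighting = c("per-model",
                                                      "per-frame")) {
  weighting <- match.arg(weighting)
  if (length(maps) != length(ensemble@frames))
    stop("need one contact map per ensemble frame")
  cutoffs <- unique(vapply(maps, function(m) m@cutoff, numeric(1L)))
  if (length(cutoffs) != 1L)
    stop("contact maps have inconsistent cutoffs")
  index <- globalIndexMap(ensemble)
  ## residue presence per frame, as keys chain|resnum
  res_keys <- lapply(ensemble@frames, function(f)
    unlist(lapply(f@chains, function(ch)
      paste(ch@label, unique(ch@atoms$resnum), sep = "|"))))
  all_pairs <- unique(do.call(rbind, lapply(maps, function(m)
    m@pairs[, c("i", "j", "chain_i", "res_i", "chain_j", "res_j", "class")])))
  if (!nrow(all_pairs)) {
    return(new("ContactProbabilityMatrix",
               pairs = cbind(all_pairs,
                             data.frame(probability = numeric(),
                                        n_eff = numeric())),
               cutoff = cutoffs, weighting = weighting,
               n_frames = length(maps),
               n_models = length(unique(ensemble@model_id))))
  }
  pk <- pairKey(all_pairs$chain_i, all_pairs$res_i,
                all_pairs$chain_j, all_pairs$res_j)
  present_mat <- vapply(seq_along(maps), function(k) {
    keys_i <- paste(all_pairs$chain_i, all_pairs$res_i, sep = "|")
    keys_j <- paste(all_pairs$chain_j, all_pairs$res_j, sep = "|")
    keys_i %in% res_keys[[k]] & keys_j %in% res_keys[[k]]
  }, logical(nrow(all_pairs)))
  contact_mat <- vapply(seq_along(maps), function(k) {
    mk <- maps[[k]]@pairs
    pk %in% pairKey(mk$chain_i, mk$res_i, mk$chain_j, mk$res_j)
  }, logical(nrow(all_pairs)))
  present_mat <- matrix(present_mat, nrow = nrow(all_pairs))
  contact_mat <- matrix(contact_mat, nrow = nrow(all_pairs))
  if (weighting == "per-frame") {
    n_eff <- rowSums(present_mat)
    prob <- ifelse(n_eff > 0, rowSums(contact_mat & present_mat) / n_eff, 0)
  } else {
    mids <- unique(ensemble@model_id)
    per_model <- vapply(mids, function(id) {
      cols <- which(ensemble@model_id == id)
      pres <- rowSums(present_mat[, cols, drop = FALSE]) == length(cols)
      freq <- rowMeans(contact_mat[, cols, drop = FALSE])
      ifelse(pres, freq, NA_real_)
    }, numeric(nrow(all_pairs)))
    per_model <- matrix(per_model, nrow = nrow(all_pairs))
    n_eff <- rowSums(!is.na(per_model))
    prob <- ifelse(n_eff > 0, rowMeans(per_model, na.rm = TRUE), 0)
  }
  out <- all_pairs
  out$probability <- prob
  out$n_eff <- n_eff
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  new("ContactProbabilityMatrix", pairs = out, cutoff = cutoffs,
      weighting = weighting, n_frames = length(maps),
      n_models = length(unique(ensemble@model_id)))
}

#' Dense symmetric probability matrix
#'
#' @param cpm a \linkS4class{ContactProbabilityMatrix}.
#' @param index the global index map the pairs refer to (defaults to the
#'   extent of the stored indices).
#' @return symmetric numeric matrix of probabilities.
#' @export
contactMatrix <- function(cpm, index = NULL) {
  n <- if (is.null(index)) max(c(0L, cpm@pairs$j)) else nrow(index)
  m <- matrix(0, n, n)
  p <- cpm@pairs
  if (nrow(p)) {
    m[cbind(p$i, p$j)] <- p$probability
    m[cbind(p$j, p$i)] <- p$probability
  }
  m
}

## ---- typed side-chain contacts -----------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

RES_ACIDIC <- c("ASP", "GLU")
RES_BASIC <- c("LYS", "ARG", "HIS")
RES_AROMATIC <- c("PHE", "TYR", "TRP", "HIS")
RES_HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                     "PRO", "TYR")
RES_POLAR <- c("SER", "THR", "ASN", "GLN", "TYR", "HIS", "TRP", "LYS",
               "ARG", "ASP", "GLU", "CYS")

## Side-chain reference atoms per residue type and interaction class.
sidechainRefAtoms <- function(resname, class) {
  ring <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
               TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
                       "CZ3", "CH2"),
               HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))
  polar <- list(SER = "OG", THR = "OG1", ASN = c("OD1", "ND2"),
                GLN = c("OE1", "NE2"), TYR = "OH", HIS = c("ND1", "NE2"),
                TRP = "NE1", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), CYS = "SG")
  switch(class,
         "acid-base" = polar[[resname]],  # the charged-group N/O atoms
         "hydrogen-bond" = polar[[resname]],
         "aromatic" = ring[[resname]],
         "hydrophobic" = NULL)  # resolved from the atom table (carbons)
}

#' Default side-chain contact-type table
#'
#' Interaction classes, reference-atom semantics and distance cutoffs used
#' by \code{\link{detectSidechainContacts}}: acid-base 4.0 A between
#' side-chain charged N/O atoms; hydrogen-bond 3.5 A between polar
#' side-chain heavy atoms (for Ser/Thr/Gln/Asn both candidate sites are
#' checked); aromatic 7.0 A between ring centroids; hydrophobic 5.4 A
#' between the closest side-chain carbons. Precedence (one type per residue
#' pair): acid-base > hydrogen-bond > aromatic > hydrophobic. The table is
#' shipped as an editable TSV; these defaults are declared substitutes for
#' an unavailable published pairing matrix, not reconstructions of it.
#'
#' @param path optional TSV with columns class/cutoff/precedence.
#' @return data.frame with columns \code{class}, \code{cutoff},
#'   \code{precedence}, ordered by precedence.
#' @export
defaultContactTypeTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "contact_types.tsv",
                        package = "IFDimerTools", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "cutoff", "precedence") %in% names(tab)),
            all(tab$cutoff > 0))
  tab[order(tab$precedence), , drop = FALSE]
}

## Which interaction class applies to a residue-type pair (precedence rule).
pairInteractionClass <- function(resA, resB, table) {
  for (cl in table$class) {
    ok <- switch(cl,
      "acid-base" = (resA %in% RES_ACIDIC && resB %in% RES_BASIC) ||
                    (resB %in% RES_ACIDIC && resA %in% RES_BASIC),
      "hydrogen-bond" = resA %in% RES_POLAR && resB %in% RES_POLAR,
      "aromatic" = resA %in% RES_AROMATIC && resB %in% RES_AROMATIC,
      "hydrophobic" = resA %in% RES_HYDROPHOBIC && resB %in% RES_HYDROPHOBIC,
      FALSE)
    if (ok) return(cl)
  }
  NA_character_
}

## Reference coordinates of one residue for one class; NULL if atoms absent.
refCoords <- function(atoms, resname, class) {
  side <- atoms[!atoms$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  if (class == "hydrophobic") {
    cc <- side[startsWith(side$atom, "C"), , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    return(as.matrix(cc[, c("x", "y", "z")]))
  }
  want <- sidechainRefAtoms(resname, class)
  if (is.null(want)) return(NULL)
  sel <- side[side$atom %in% want, , drop = FALSE]
  if (!nrow(sel)) return(NULL)
  m <- as.matrix(sel[, c("x", "y", "z")])
  if (class == "aromatic") matrix(colMeans(m), 1L, 3L) else m
}

#' Detect typed side-chain contacts in one frame
#'
#' Each residue pair is assigned at most one interaction class, chosen by
#' residue-type precedence (acid-base > hydrogen-bond > aromatic >
#' hydrophobic); a contact is recorded when the minimum distance between
#' the class's reference atoms is strictly below the class cutoff (ring
#' centroids for the aromatic class; for polar pairs the minimum over both
#' candidate hydrogen-bonding sites is used). Residues lacking the required
#' side-chain atoms are skipped with one aggregated warning.
#'
#' @param frame a \linkS4class{DimerStructure} with side-chain atoms.
#' @param table contact-type table (see
#'   \code{\link{defaultContactTypeTable}}).
#' @param exclusion intra-chain sequence exclusion, as for C-alpha maps.
#' @param prefilter C-alpha pre-screen distance (A): residue pairs whose
#'   C-alpha atoms are farther apart than this are not examined.
#' @return data.frame: chain_i, res_i, chain_j, res_j, class, chain_class,
#'   distance.
#' @export
detectSidechainContacts <- function(frame, table = defaultContactTypeTable(),
                                    exclusion = 2L, prefilter = 20) {
  tabs <- lapply(frame@chains, function(ch) {
    a <- ch@atoms
    a$chain <- ch@label
    a
  })
  at <- do.call(rbind, tabs)
  res <- unique(at[, c("chain", "resnum", "resname")])
  ca <- at[at$atom == "CA", , drop = FALSE]
  res$cax <- ca$x[match(paste(res$chain, res$resnum),
                        paste(ca$chain, ca$resnum))]
  res$cay <- ca$y[match(paste(res$chain, res$resnum),
                        paste(ca$chain, ca$resnum))]
  res$caz <- ca$z[match(paste(res$chain, res$resnum),
                        paste(ca$chain, ca$resnum))]
  n <- nrow(res)
  skipped <- character()
  out <- list()
  cut_by_class <- stats::setNames(table$cutoff, table$class)
  for (a_i in seq_len(n - 1L)) for (b_i in (a_i + 1L):n) {
    if (res$chain[a_i] == res$chain[b_i] &&
        abs(res$resnum[a_i] - res$resnum[b_i]) <= exclusion) next
    dca <- sqrt((res$cax[a_i] - res$cax[b_i])^2 +
                  (res$cay[a_i] - res$cay[b_i])^2 +
                  (res$caz[a_i] - res$caz[b_i])^2)
    if (is.na(dca) || dca > prefilter) next
    cl <- pairInteractionClass(res$resname[a_i], res$resname[b_i], table)
    if (is.na(cl)) next
    atomsA <- at[at$chain == res$chain[a_i] & at$resnum == res$resnum[a_i], ]
    atomsB <- at[at$chain == res$chain[b_i] & at$resnum == res$resnum[b_i], ]
    mA <- refCoords(atomsA, res$resname[a_i], cl)
    mB <- refCoords(atomsB, res$resname[b_i], cl)
    if (is.null(mA) || is.null(mB)) {
      skipped <- c(skipped, sprintf("%s:%d/%s:%d", res$chain[a_i],
                                    res$resnum[a_i], res$chain[b_i],
                                    res$resnum[b_i]))
      next
    }
    d2 <- outer(rowSums(mA^2), rowSums(mB^2), "+") - 2 * mA %*% t(mB)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin < cut_by_class[[cl]]) {
      out[[length(out) + 1L]] <- data.frame(
        chain_i = res$chain[a_i], res_i = res$resnum[a_i],
        chain_j = res$chain[b_i], res_j = res$resnum[b_i], class = cl,
        chain_class = paste(res$chain[a_i], res$chain[b_i], sep = "-"),
        distance = dmin, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning(sprintf("%d residue pair(s) skipped for missing reference atoms (e.g. %s)",
                    length(skipped), skipped[1L]))
  if (length(out)) do.call(rbind, out) else
    data.frame(chain_i = character(), res_i = integer(),
               chain_j = character(), res_j = integer(), class = character(),
               chain_class = character(), distance = numeric(),
               stringsAsFactors = FALSE)
}

#' Summarize typed side-chain contacts over an ensemble
#'
#' Per-pair occurrence probabilities (frame frequency) and mean contact
#' counts by chain pairing and interaction class; the total per chain class
#' equals the sum of the per-pair probabilities. When a heptad register is
#' supplied, the inter-chain subtotal restricted to a/d core positions is
#' reported separately.
#'
#' @param ensemble a \linkS4class{StructureEnsemble}.
#' @param table contact-type table.
#' @param register optional named list (by chain label) of heptad registers
#'   (named letter vectors from \code{\link{heptadRegister}}).
#' @param ... passed to \code{\link{detectSidechainContacts}}.
#' @return list: \code{mean_counts} (chain_class x class table),
#'   \code{pair_probs} data.frame, \code{total} (sum of probabilities),
#'   \code{ad_interchain} (a/d-restricted inter-chain subtotal or NA).
#' @export
summarizeContacts <- function(ensemble, table = defaultContactTypeTable(),
                              register = NULL, ...) {
  per_frame <- lapply(ensemble@frames, detectSidechainContacts,
                      table = table, ...)
  nf <- length(per_frame)
  all_df <- do.call(rbind, per_frame)
  if (!nrow(all_df))
    return(list(mean_counts = table(character(), character()),
                pair_probs = all_df, total = 0, ad_interchain = NA_real_))
  key <- pairKey(all_df$chain_i, all_df$res_i, all_df$chain_j, all_df$res_j)
  agg <- all_df[!duplicated(key), , drop = FALSE]
  agg$probability <- as.numeric(table(key)[pairKey(agg$chain_i, agg$res_i,
                                                   agg$chain_j,
                                                   agg$res_j)]) / nf
  agg$distance <- NULL
  mean_counts <- tapply(agg$probability,
                        list(agg$chain_class, agg$class), sum, default = 0)
  ad <- NA_real_
  if (!is.null(register)) {
    lets_i <- mapply(function(ch, r) {
      reg <- register[[ch]]
      if (is.null(reg)) NA_character_ else unname(reg[as.character(r)])
    }, agg$chain_i, agg$res_i)
    lets_j <- mapply(function(ch, r) {
      reg <- register[[ch]]
      if (is.null(reg)) NA_character_ else unname(reg[as.character(r)])
    }, agg$chain_j, agg$res_j)
    inter <- agg$chain_i != agg$chain_j
    core <- !is.na(lets_i) & !is.na(lets_j) &
      lets_i %in% c("a", "d") & lets_j %in% c("a", "d")
    ad <- sum(agg$probability[inter & core])
  }
  list(mean_counts = mean_counts, pair_probs = agg,
       total = sum(agg$probability), ad_interchain = ad)
}

## ---- hydrogen bonds -----------------------------------------------------

#' Geometric hydrogen-bond count
#'
#' Counts donor-acceptor heavy-atom pairs (N or hydroxyl/thiol O donors; N/O
#' acceptors) within the distance criterion, split into backbone-backbone,
#' backbone-sidechain and sidechain-sidechain classes. When explicit
#' hydrogens are present the donor-H-acceptor angle criterion is applied;
#' with heavy atoms only, a Baker-Hubbard-style angle at the acceptor
#' (donor...acceptor-antecedent, e.g. N...O=C, at least
#' \code{acceptor_angle_min}) stands in for it, which suppresses the
#' near-diagonal false positives a pure distance criterion admits in
#' helices. Same-residue pairs are excluded, as are backbone-backbone
#' pairs of sequence-adjacent residues (covalent neighbours).
#'
#' @param frame a \linkS4class{DimerStructure}.
#' @param dist_cutoff donor-acceptor heavy-atom distance (A), inclusive.
#' @param angle_min minimum donor-H-acceptor angle (degrees) when hydrogens
#'   exist.
#' @param acceptor_angle_min minimum donor-acceptor-antecedent angle
#'   (degrees), applied when the acceptor's bonded heavy atom is present;
#'   set to 0 for a distance-only count.
#' @return list: \code{counts} named vector (backbone-backbone,
#'   backbone-sidechain, sidechain-sidechain) and \code{pairs} data.frame
#'   with donor/acceptor chain, residue, atom, distance and separation.
#' @export
countHbonds <- function(frame, dist_cutoff = 3.5, angle_min = 120,
                        acceptor_angle_min = 120) {
  at <- do.call(rbind, lapply(frame@chains, function(ch) {
    a <- ch@atoms
    a$chain <- ch@label
    a
  }))
  heavyN <- at[startsWith(at$atom, "N"), , drop = FALSE]
  hydroxyl <- at[at$atom %in% c("OG", "OG1", "OH", "SG"), , drop = FALSE]
  donors <- rbind(heavyN, hydroxyl)
  acceptors <- at[startsWith(at$atom, "O"), , drop = FALSE]
  if (!nrow(donors) || !nrow(acceptors))
    return(list(counts = c("backbone-backbone" = 0L,
                           "backbone-sidechain" = 0L,
                           "sidechain-sidechain" = 0L),
                pairs = data.frame()))
  dm <- as.matrix(donors[, c("x", "y", "z")])
  am <- as.matrix(acceptors[, c("x", "y", "z")])
  d2 <- outer(rowSums(dm^2), rowSums(am^2), "+") - 2 * dm %*% t(am)
  hit <- which(d2 <= dist_cutoff^2, arr.ind = TRUE)
  res <- data.frame()
  if (nrow(hit)) {
    di <- hit[, 1L]; ai <- hit[, 2L]
    same_res <- donors$chain[di] == acceptors$chain[ai] &
      donors$resnum[di] == acceptors$resnum[ai]
    don_bb <- donors$atom[di] %in% BACKBONE_ATOMS
    acc_bb <- acceptors$atom[ai] %in% BACKBONE_ATOMS
    sep <- ifelse(donors$chain[di] == acceptors$chain[ai],
                  abs(donors$resnum[di] - acceptors$resnum[ai]), NA)
    adjacent_bb <- don_bb & acc_bb & !is.na(sep) & sep <= 1L
    keep <- !same_res & !adjacent_bb
    di <- di[keep]; ai <- ai[keep]
    don_bb <- don_bb[keep]; acc_bb <- acc_bb[keep]; sep <- sep[keep]
    if (acceptor_angle_min > 0 && length(di)) {
      antecedent <- c(O = "C", OXT = "C", OG = "CB", OG1 = "CB", OH = "CZ",
                      OD1 = "CG", OD2 = "CG", OE1 = "CD", OE2 = "CD")
      ok_acc <- vapply(seq_along(di), function(k) {
        ante <- antecedent[acceptors$atom[ai[k]]]
        if (is.na(ante)) return(TRUE)
        row <- at[at$chain == acceptors$chain[ai[k]] &
                    at$resnum == acceptors$resnum[ai[k]] &
                    at$atom == ante, , drop = FALSE]
        if (!nrow(row)) return(TRUE)   # antecedent absent: distance-only
        apos <- as.numeric(acceptors[ai[k], c("x", "y", "z")])
        v1 <- as.numeric(donors[di[k], c("x", "y", "z")]) - apos
        v2 <- as.numeric(row[1L, c("x", "y", "z")]) - apos
        ang <- deg(acos(max(-1, min(1, sum(v1 * v2) /
                                      (vnorm(v1) * vnorm(v2))))))
        ang >= acceptor_angle_min
      }, logical(1L))
      di <- di[ok_acc]; ai <- ai[ok_acc]
      don_bb <- don_bb[ok_acc]; acc_bb <- acc_bb[ok_acc]; sep <- sep[ok_acc]
    }
    type <- ifelse(don_bb & acc_bb, "backbone-backbone",
                   ifelse(!don_bb & !acc_bb, "sidechain-sidechain",
                          "backbone-sidechain"))
    ## angle criterion when the donor carries explicit hydrogens
    hs <- at[startsWith(at$atom, "H"), , drop = FALSE]
    ok_angle <- rep(TRUE, length(di))
    if (nrow(hs)) {
      for (k in seq_along(di)) {
        hres <- hs[hs$chain == donors$chain[di[k]] &
                     hs$resnum == donors$resnum[di[k]], , drop = FALSE]
        if (!nrow(hres)) next
        dpos <- as.numeric(donors[di[k], c("x", "y", "z")])
        apos <- as.numeric(acceptors[ai[k], c("x", "y", "z")])
        hd <- sqrt(rowSums(sweep(as.matrix(hres[, c("x", "y", "z")]),
                                 2L, dpos)^2))
        hres <- hres[hd < 1.3, , drop = FALSE]  # hydrogens bonded to donor
        if (!nrow(hres)) next
        angs <- apply(as.matrix(hres[, c("x", "y", "z")]), 1L, function(h) {
          v1 <- dpos - h; v2 <- apos - h
          deg(acos(max(-1, min(1, sum(v1 * v2) /
                                 (vnorm(v1) * vnorm(v2))))))
        })
        ok_angle[k] <- any(angs >= angle_min)
      }
    }
    di <- di[ok_angle]; ai <- ai[ok_angle]; type <- type[ok_angle]
    sep <- sep[ok_angle]
    ## one bond per unordered atom pair (hydroxyl-hydroxyl pairs qualify in
    ## both donor/acceptor directions)
    if (length(di)) {
      ka <- paste(donors$chain[di], donors$resnum[di], donors$atom[di])
      kb <- paste(acceptors$chain[ai], acceptors$resnum[ai],
                  acceptors$atom[ai])
      key <- paste(pmin(ka, kb), pmax(ka, kb))
      keep2 <- !duplicated(key)
      di <- di[keep2]; ai <- ai[keep2]; type <- type[keep2]
      sep <- sep[keep2]
    }
    if (length(di))
      res <- data.frame(
        donor_chain = donors$chain[di], donor_res = donors$resnum[di],
        donor_atom = donors$atom[di],
        acceptor_chain = acceptors$chain[ai],
        acceptor_res = acceptors$resnum[ai],
        acceptor_atom = acceptors$atom[ai],
        distance = sqrt(pmax(0, d2[cbind(di, ai)])), separation = sep,
        type = type, stringsAsFactors = FALSE)
  }
  counts <- c("backbone-backbone" = sum(res$type == "backbone-backbone"),
              "backbone-sidechain" = sum(res$type == "backbone-sidechain"),
              "sidechain-sidechain" = sum(res$type == "sidechain-sidechain"))
  list(counts = counts, pairs = res)
}
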