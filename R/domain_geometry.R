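## Head/tail domain shape and placement: radius of gyration, end-to-end
## distance, principal extents, globule axial displacement d and radial
## orientation theta_r, and the Category I/II/III position classification.

coordsOf <- function(x, backbone = FALSE) {
  if (is(x, "ChainStructure")) {
    a <- x@atoms
    if (backbone) {
      bb <- a[a$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
      if (!nrow(bb)) bb <- a[a$atom == "CA", , drop = FALSE]
      a <- bb
    } else a <- a[a$atom == "CA", , drop = FALSE]
    as.matrix(a[, c("x", "y", "z")])
  } else as.matrix(x)
}

#' Radius of gyration
#'
#' Root-mean-square distance of a point set from its center of mass. For a
#' \linkS4class{ChainStructure} the backbone atoms (N, CA, C, O) are used
#' when present, else the C-alpha trace.
#'
#' @param x numeric matrix (n x 3) or \linkS4class{ChainStructure}.
#' @param residue_range optional residue subset for chains.
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(x, residue_range = NULL) {
  if (is(x, "ChainStructure") && !is.null(residue_range)) {
    a <- x@atoms
    a <- a[a$resnum >= residue_range[1L] & a$resnum <= residue_range[2L], ,
           drop = FALSE]
    x <- ChainStructure(x@label, a)
  }
  m <- coordsOf(x, backbone = TRUE)
  if (!nrow(m)) stop("radius of gyration of an empty point set")
  centered <- sweep(m, 2L, colMeans(m))
  sqrt(mean(rowSums(centered^2)))
}

#' End-to-end distance of a head or tail domain
#'
#' Distance between the C-alpha of the chain's terminal residue (first
#' residue for the head, last for the tail) and the rod anchor point (center
#' of the N-term of 1A, or C-term of 2B).
#'
#' @param chain a \linkS4class{ChainStructure}.
#' @param domain "head" or "tail".
#' @param rod_anchor 3-vector anchor position.
#' @return distance in Angstrom.
#' @export
endToEnd <- function(chain, domain = c("head", "tail"), rod_anchor) {
  domain <- match.arg(domain)
  if (missing(rod_anchor) || length(rod_anchor) != 3L)
    stop("rod_anchor must be a 3-vector")
  ca <- caCoords(chain)
  term <- if (domain == "head") ca[1L, ] else ca[nrow(ca), ]
  vnorm(term - rod_anchor)
}

#' Principal extents of a point set
#'
#' Spread (max minus min) of the centered coordinates projected on each
#' principal axis of the point cloud, in descending order. Invariant under
#' rigid-body motion.
#'
#' @param x numeric matrix (n x 3) or \linkS4class{ChainStructure}.
#' @return numeric length-3 vector, descending, in Angstrom.
#' @export
principalExtents <- function(x) {
  m <- coordsOf(x, backbone = TRUE)
  if (!nrow(m)) stop("principal extents of an empty point set")
  centered <- sweep(m, 2L, colMeans(m))
  ev <- eigen(crossprod(centered) / nrow(centered), symmetric = TRUE)$vectors
  proj <- centered %*% ev
  sort(apply(proj, 2L, function(p) diff(range(p))), decreasing = TRUE)
}

## Anchor frame of the rod at the head (1A N-term) or tail (2B C-term):
## outward unit axis M, K1-pointing in-plane reference O, and the anchor
## point on the central axis.
rodAnchorFrame <- function(dimer, annotation, end = c("head", "tail")) {
  end <- match.arg(end)
  sub <- if (end == "head") "1A" else "2B"
  ch1 <- dimer@chains[[1L]]
  ch2 <- dimer@chains[[2L]]
  r1 <- subdomainRange(annotation, ch1@label, sub)
  r2 <- subdomainRange(annotation, ch2@label, sub)
  a1 <- computeHelixAxis(ch1, r1)
  a2 <- computeHelixAxis(ch2, r2)
  p2 <- axisPoints(a2)
  if (nrow(p2) != nrow(axisPoints(a1)))
    stop(sprintf("%s subdomain differs in length between chains", sub))
  rownames(p2) <- rownames(axisPoints(a1))  # in-register renumbering
  P <- computeCentralAxis(axisPoints(a1), p2)
  u <- computeMajorAxis(P, r1, sub)
  if (end == "head") {
    m_vec <- -u$vector           # outward = away from the rod, past 1A N-term
    anchor <- u$start_anchor     # axis point at the 2nd residue of 1A
    ref1 <- r1[1L]; ref2 <- r2[1L]   # N-terminal residues of 1A
  } else {
    m_vec <- u$vector            # outward past the 2B C-term
    anchor <- u$end_anchor       # axis point at the 3rd-to-last residue of 2B
    ref1 <- r1[2L] - 2L; ref2 <- r2[2L] - 2L
  }
  c1 <- caCoords(ch1, ref1)[1L, ]
  c2 <- caCoords(ch2, ref2)[1L, ]
  k1 <- if (ch1@label == "K10" && ch2@label == "K1") c2 else c1
  center <- (c1 + c2) / 2
  ov <- k1 - center
  ov <- ov - sum(ov * m_vec) * m_vec
  list(m_vec = m_vec, o_vec = unitv(ov), anchor = anchor,
       axis = u, central = P)
}

#' Globule axial displacement and radial orientation
#'
#' Position of a globular head/tail subdomain relative to the rod: with V
#' the vector from the anchor (central-axis point at the 2nd residue of 1A,
#' or 3rd-to-last of 2B) to the globule's C-alpha center of mass, the axial
#' displacement is d = V . M (M the outward unit anchor axis; positive d =
#' beyond the rod terminus) and theta_r is the angle, in the plane
#' perpendicular to M, between the projection P of V and the K1-pointing
#' reference O (0 = K1 side, 180 = K10 side). theta_r is reported signed
#' (right-hand rule about M); its absolute value is the unsigned angle
#' acos(P . O).
#'
#' @param dimer annotated \linkS4class{DimerStructure} containing rod and
#'   globule residues.
#' @param annotation \linkS4class{SubdomainAnnotation} for the dimer.
#' @param chain chain label whose globule is measured.
#' @param subdomain globular subdomain name (e.g. "V1", "V2"); alternatively
#'   pass explicit \code{globule_coords}.
#' @param end rod terminus anchoring the measurement: "head" (1A) or "tail"
#'   (2B).
#' @param globule_coords optional n x 3 matrix overriding the subdomain
#'   C-alpha lookup (e.g. a single terminal residue).
#' @return a \linkS4class{GlobulePosition}.
#' @export
globulePosition <- function(dimer, annotation, chain, subdomain = "V1",
                            end = c("head", "tail"), globule_coords = NULL) {
  end <- match.arg(end)
  fr <- rodAnchorFrame(dimer, annotation, end)
  if (is.null(globule_coords)) {
    rng <- subdomainRange(annotation, chain, subdomain)
    ca <- caCoords(getChain(dimer, chain))
    keep <- as.integer(rownames(ca)) >= rng[1L] &
      as.integer(rownames(ca)) <= rng[2L]
    if (!any(keep))
      stop(sprintf("chain %s has no residues in %s", chain, subdomain))
    globule_coords <- ca[keep, , drop = FALSE]
  }
  com <- colMeans(globule_coords)
  V <- com - fr$anchor
  d <- sum(V * fr$m_vec)
  Pv <- V - d * fr$m_vec
  if (vnorm(Pv) < 1e-6) {
    theta <- NA_real_
    p_unit <- c(0, 0, 0)
  } else {
    p_unit <- unitv(Pv)
    theta <- signedAngleAbout(fr$o_vec, p_unit, fr$m_vec)
  }
  new("GlobulePosition", chain_label = chain, subdomain_name = subdomain,
      d = d, theta_r = theta, v_vec = V, m_vec = fr$m_vec,
      o_vec = fr$o_vec, p_vec = p_unit)
}

#' Category I/II/III globule position classification
#'
#' Positive axial displacement beyond the band is Category I (globule
#' projected out along the long axis past the rod terminus), |d| within the
#' band is Category II (at right angles to the rod end), and d below the
#' negative band is Category III (folded back down onto the rod).
#'
#' @param pos a \linkS4class{GlobulePosition} or numeric d value.
#' @param band half-width of the Category II band in Angstrom.
#' @return factor level "I", "II" or "III".
#' @export
classifyCategory <- function(pos, band = 10) {
  d <- if (is(pos, "GlobulePosition")) pos@d else as.numeric(pos)
  if (is.na(d)) stop("axial displacement is undefined")
  if (d > band) "I" else if (d < -band) "III" else "II"
}

#' Tabulate globule positions
#'
#' @param positions list of \linkS4class{GlobulePosition} objects.
#' @param band Category II half-width passed to
#'   \code{\link{classifyCategory}}.
#' @return data.frame: chain, subdomain, d, theta_r, category.
#' @export
positionTable <- function(positions, band = 10) {
  do.call(rbind, lapply(positions, function(p) data.frame(
    chain = p@chain_label, subdomain = p@subdomain_name, d = p@d,
    theta_r = p@theta_r,
    category = if (is.na(p@d)) NA_character_ else classifyCategory(p, band),
    stringsAsFactors = FALSE)))
}

#' 2-D occurrence histogram of globule positions
#'
#' Counts of (d, theta_r) observations on a regular grid, the occurrence
#' map summarizing where a globular subdomain sits relative to the rod.
#' Counts over concatenated position lists add.
#'
#' @param positions list of \linkS4class{GlobulePosition} or a data.frame
#'   with columns \code{d} and \code{theta_r}.
#' @param d_bin bin width for d (A).
#' @param theta_bin bin width for theta_r (degrees; bins tile (-180, 180]).
#' @return data.frame: d_mid, theta_mid, count; counts sum to the number of
#'   observations with defined theta_r.
#' @export
positionHistogram <- function(positions, d_bin = 5, theta_bin = 15) {
  df <- if (is.data.frame(positions)) positions else positionTable(positions)
  df <- df[!is.na(df$theta_r), , drop = FALSE]
  if (!nrow(df)) stop("no positions with defined theta_r")
  d_idx <- floor(df$d / d_bin)
  t_idx <- ceiling(df$theta_r / theta_bin) - 1L  # bins tile (-180, 180]
  key <- paste(d_idx, t_idx)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(d_mid = (as.numeric(parts[, 1L]) + 0.5) * d_bin,
                    theta_mid = (as.numeric(parts[, 2L]) + 0.5) * theta_bin,
                    count = as.integer(tab))
  out[order(out$d_mid, out$theta_mid), , drop = FALSE]
}

#' Shape metrics of a domain
#'
#' @param x coordinates or \linkS4class{ChainStructure}.
#' @return list with \code{rg} (A) and \code{extents} (3 descending A
#'   values).
#' @export
shapeMetrics <- function(x) {
  list(rg = radiusOfGyration(x), extents = principalExtents(x))
}
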