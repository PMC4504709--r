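## Per-residue coiled-coil geometry: alpha-helix axis paths, the central
## axis of the two-stranded coil, local superhelical radius, rotation angle
## per residue, local pitch and handedness, plus subdomain major axes and
## hinge angles.

#' Estimate the alpha-helix axis path of a chain
#'
#' For each residue i with neighbours i-1, i, i+1, i+2 present, the local
#' helix axis point is estimated from the second differences of consecutive
#' C-alpha positions (the bisector construction): the second difference
#' A(i) = p(i-1) - 2 p(i) + p(i+1) points from the C-alpha toward the axis,
#' the per-residue twist follows from the angle between consecutive second
#' differences, and the local helix radius from |A|. On an ideal helix the
#' recovered points lie on the true axis to numerical precision.
#'
#' @param chain a \linkS4class{ChainStructure} (C-alpha required throughout).
#' @param residue_range optional \code{c(start, end)} residue numbers; the
#'   range must contain at least 4 residues.
#' @return an \linkS4class{AxisPath} with one point per interior residue
#'   (the first residue and the last two of the range have none).
#' @export
computeHelixAxis <- function(chain, residue_range = NULL) {
  ca <- caCoords(chain)
  if (!is.null(residue_range)) {
    keep <- as.integer(rownames(ca)) >= residue_range[1L] &
      as.integer(rownames(ca)) <= residue_range[2L]
    ca <- ca[keep, , drop = FALSE]
  }
  n <- nrow(ca)
  if (n < 4L) stop("axis estimation needs at least 4 residues")
  A <- ca[seq_len(n - 2L), , drop = FALSE] -
    2 * ca[1L + seq_len(n - 2L), , drop = FALSE] +
    ca[2L + seq_len(n - 2L), , drop = FALSE]  # A[k] is at residue k+1
  pts <- matrix(NA_real_, n - 3L, 3L)
  for (k in seq_len(n - 3L)) {
    a1 <- A[k, ]; a2 <- A[k + 1L, ]
    n1 <- vnorm(a1); n2 <- vnorm(a2)
    if (n1 < 1e-9 || n2 < 1e-9) { pts[k, ] <- ca[k + 1L, ]; next }
    cosd <- sum(a1 * a2) / (n1 * n2)
    if (1 - cosd < 1e-9) { pts[k, ] <- ca[k + 1L, ]; next }
    r <- n1 / (2 * (1 - cosd))
    pts[k, ] <- ca[k + 1L, ] + r * a1 / n1
  }
  rownames(pts) <- rownames(ca)[1L + seq_len(n - 3L)]
  new("AxisPath", points = pts, chain_label = chain@label)
}

axisMatrix <- function(x) {
  if (is(x, "AxisPath")) axisPoints(x) else x
}

#' Central axis of a two-stranded coil
#'
#' Pointwise midpoint P(i) of the two chains' helix-axis paths over their
#' common residue range.
#'
#' @param a,b \linkS4class{AxisPath} objects (or point matrices with
#'   residue-number rownames).
#' @return numeric matrix of P(i), residue numbers as rownames.
#' @export
computeCentralAxis <- function(a, b) {
  pa <- axisMatrix(a); pb <- axisMatrix(b)
  common <- intersect(rownames(pa), rownames(pb))
  if (!length(common)) stop("axis paths have no overlapping residues")
  common <- as.character(sort(as.integer(common)))
  (pa[common, , drop = FALSE] + pb[common, , drop = FALSE]) / 2
}

#' Local coiled-coil radius
#'
#' R(i): mean distance of the two chain axes from the central axis,
#' R(i) = (|p_A(i) - P(i)| + |p_B(i) - P(i)|) / 2.
#'
#' @param a,b the chain \linkS4class{AxisPath}s.
#' @param P central-axis matrix from \code{\link{computeCentralAxis}}.
#' @return named numeric vector of radii (A) over the common residues.
#' @export
computeLocalRadius <- function(a, b, P) {
  pa <- axisMatrix(a); pb <- axisMatrix(b)
  idx <- rownames(P)
  da <- sqrt(rowSums((pa[idx, , drop = FALSE] - P)^2))
  db <- sqrt(rowSums((pb[idx, , drop = FALSE] - P)^2))
  stats::setNames((da + db) / 2, idx)
}

## One dihedral estimate: rotation of chain-to-center vector from residue j
## to j+1, measured about the local central-axis direction.
psiStep <- function(pc, P, j) {
  idx <- rownames(P)
  v1 <- pc[idx[j], ] - P[j, ]
  v2 <- pc[idx[j + 1L], ] - P[j + 1L, ]
  signedAngleAbout(v1, v2, P[j + 1L, ] - P[j, ])
}

#' Local rotation angle Psi per residue
#'
#' The signed per-residue rotation of the chains about the central axis:
#' for residue i, the dihedral between the chain-to-center vectors at i-1
#' and i, and between i and i+1, is measured for each chain (four estimates)
#' and averaged. Negative Psi corresponds to a left-handed supercoil (the
#' sign convention is frozen against the generator); the angle flips sign
#' exactly under coordinate reflection.
#'
#' @param a,b the chain \linkS4class{AxisPath}s.
#' @param P central-axis matrix.
#' @param i optional single residue number; default computes all residues
#'   with both neighbours available.
#' @return named numeric vector of Psi in degrees (NA where a chain center
#'   coincides with the central axis).
#' @export
computeRotationAngle <- function(a, b, P, i = NULL) {
  pa <- axisMatrix(a); pb <- axisMatrix(b)
  idx <- as.integer(rownames(P))
  targets <- if (is.null(i)) idx[idx %in% (idx + 1L) & idx %in% (idx - 1L)]
             else as.integer(i)
  targets <- targets[(targets - 1L) %in% idx & (targets + 1L) %in% idx]
  if (!length(targets)) stop("no residue with both neighbours on the path")
  out <- vapply(targets, function(res) {
    j <- match(res, idx)
    ests <- c(psiStep(pa, P, j - 1L), psiStep(pa, P, j),
              psiStep(pb, P, j - 1L), psiStep(pb, P, j))
    if (any(is.na(ests))) NA_real_ else mean(ests)
  }, numeric(1L))
  stats::setNames(out, targets)
}

#' Local pitch lambda per residue
#'
#' The axial distance for one full turn of the supercoil: the local rise per
#' residue along the central path times the number of residues per full
#' turn, lambda(i) = (|P(i+1)-P(i)| + |P(i)-P(i-1)|)/2 * 360/|Psi(i)|.
#' Where |Psi| falls below \code{psi_min} the strands are effectively
#' parallel and the pitch is reported as NA (indeterminate) rather than a
#' divergent number.
#'
#' @param P central-axis matrix.
#' @param psi named Psi vector from \code{\link{computeRotationAngle}}.
#' @param psi_min parallel-strand threshold in degrees/residue.
#' @return named numeric vector of pitches (A) with NA where indeterminate.
#' @export
computeLocalPitch <- function(P, psi, psi_min = 0.5) {
  idx <- as.integer(rownames(P))
  out <- rep(NA_real_, length(psi))
  names(out) <- names(psi)
  for (k in seq_along(psi)) {
    res <- as.integer(names(psi)[k])
    j <- match(res, idx)
    if (is.na(j) || j <= 1L || j >= length(idx)) next
    if (is.na(psi[k]) || abs(psi[k]) < psi_min) next
    rise <- (vnorm(P[j + 1L, ] - P[j, ]) + vnorm(P[j, ] - P[j - 1L, ])) / 2
    out[k] <- rise * 360 / abs(psi[k])
  }
  out
}

#' Full coiled-coil profile of a dimer
#'
#' Convenience wrapper running axis estimation for both chains, the central
#' axis, local radius, rotation angle, pitch and handedness over one residue
#' range (typically one coiled-coil subdomain).
#'
#' @param dimer a two-chain \linkS4class{DimerStructure}.
#' @param residue_range optional \code{c(start, end)} (applies to both
#'   chains' numbering; chains are assumed in-register on a shared
#'   numbering, use per-chain ranges via \code{range_b} otherwise).
#' @param range_b optional separate range for the second chain.
#' @param psi_min parallel-strand threshold (degrees/residue).
#' @return a \linkS4class{CoiledCoilProfile} over the interior residues
#'   (numbered by the first chain).
#' @export
coiledCoilProfile <- function(dimer, residue_range = NULL, range_b = NULL,
                              psi_min = 0.5) {
  if (length(dimer@chains) != 2L)
    stop("profile requires a two-chain structure")
  pa <- computeHelixAxis(dimer@chains[[1L]], residue_range)
  pb <- computeHelixAxis(dimer@chains[[2L]],
                         if (is.null(range_b)) residue_range else range_b)
  pbm <- axisPoints(pb)
  if (!is.null(range_b)) {
    ## re-key the second chain onto the first chain's numbering (in-register)
    if (nrow(pbm) != nrow(axisPoints(pa)))
      stop("per-chain ranges must cover equally many residues")
    rownames(pbm) <- rownames(axisPoints(pa))
  }
  P <- computeCentralAxis(axisPoints(pa), pbm)
  R <- computeLocalRadius(axisPoints(pa), pbm, P)
  psi <- computeRotationAngle(axisPoints(pa), pbm, P)
  lam <- computeLocalPitch(P, psi, psi_min = psi_min)
  keep <- names(psi)
  ind <- is.na(psi) | abs(psi) < psi_min
  hand <- ifelse(ind, "indeterminate", ifelse(psi < 0, "left", "right"))
  lam[ind] <- NA_real_
  new("CoiledCoilProfile",
      residue = as.integer(keep),
      central_axis = P[keep, , drop = FALSE],
      radius = unname(R[keep]), rotation = unname(psi),
      pitch = unname(lam), handedness = unname(hand), psi_min = psi_min)
}

#' Major axis of a coiled-coil subdomain
#'
#' The normalized displacement vector between the central-axis positions at
#' the 2nd residue and the 3rd-to-last residue of the subdomain (N- to
#' C-oriented).
#'
#' @param P central-axis matrix (or \linkS4class{CoiledCoilProfile}).
#' @param residue_range \code{c(start, end)} residue numbers of the
#'   subdomain; at least 5 covered residues are required.
#' @param subdomain_name label carried along for reporting.
#' @return list of class \code{"MajorAxis"}: \code{vector} (unit),
#'   \code{start_anchor}, \code{end_anchor}, \code{subdomain_name}.
#' @export
computeMajorAxis <- function(P, residue_range, subdomain_name = "") {
  if (is(P, "CoiledCoilProfile")) {
    m <- P@central_axis
  } else m <- P
  idx <- as.integer(rownames(m))
  sub <- which(idx >= residue_range[1L] & idx <= residue_range[2L])
  if (length(sub) < 5L)
    stop(sprintf("subdomain %s: need >= 5 residues on the central axis, have %d",
                 subdomain_name, length(sub)))
  p1 <- m[sub[2L], ]
  p2 <- m[sub[length(sub) - 2L], ]
  structure(list(vector = unitv(p2 - p1), start_anchor = p1, end_anchor = p2,
                 subdomain_name = subdomain_name), class = "MajorAxis")
}

asAxisVector <- function(u) {
  if (inherits(u, "MajorAxis")) u$vector else unitv(u)
}

#' Hinge angle between two subdomain major axes
#'
#' With both axes N-to-C oriented, the interior convention returns
#' acos(u . v) in [0, 180] degrees; the alternative "reflex" convention
#' returns 360 degrees minus that. The interior convention is the default:
#' it is the one whose magnitudes match reported inter-subdomain hinge
#' angles (e.g. ~107 degrees between 1A and 1B).
#'
#' @param u,v \code{MajorAxis} objects or unit 3-vectors.
#' @param convention "interior" or "reflex".
#' @return angle in degrees.
#' @export
computeHingeAngle <- function(u, v, convention = c("interior", "reflex")) {
  convention <- match.arg(convention)
  uu <- asAxisVector(u); vv <- asAxisVector(v)
  ang <- deg(acos(max(-1, min(1, sum(uu * vv)))))
  if (convention == "reflex") 360 - ang else ang
}
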