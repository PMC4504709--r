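## Ground-truth structure generators. Every generator is a pure function of
## its parameters (and seed); these provide the oracles against which the
## geometry and contact machinery is validated.

#' Crick coiled-coil parameters
#'
#' Parameter bundle for the two-stranded coiled-coil generator. Defaults for
#' the minor helix are the canonical alpha-helix values (2.26 A radius,
#' 1.51 A rise per residue, 3.6 residues per turn), which reproduce the
#' 3.8 A C-alpha spacing.
#'
#' @param r0 superhelical radius (A), > 0.
#' @param pitch superhelical pitch (A), > 0.
#' @param handedness "left" or "right".
#' @param r1 minor-helix radius (A).
#' @param rise rise per residue along the superhelical axis (A).
#' @param residues_per_turn minor-helix periodicity (residues/turn).
#' @param n_residues residues per chain, >= 8.
#' @param phase_offsets superhelical phase (degrees) of each chain; the
#'   second chain sits 180 degrees across the axis by default.
#' @return a validated list of class \code{"CrickParams"}.
#' @export
crickParams <- function(r0, pitch, handedness = c("left", "right"),
                        r1 = 2.26, rise = 1.51, residues_per_turn = 3.6,
                        n_residues = 100L, phase_offsets = c(0, 180)) {
  handedness <- match.arg(handedness)
  stopifnot(r0 > 0, pitch > 0, n_residues >= 8L, r1 > 0, rise > 0,
            length(phase_offsets) == 2L)
  structure(list(r0 = r0, pitch = pitch, handedness = handedness, r1 = r1,
                 rise = rise, residues_per_turn = residues_per_turn,
                 n_residues = as.integer(n_residues),
                 phase_offsets = phase_offsets),
            class = "CrickParams")
}

## One chain of the coil: minor helix of radius r1 wound about a superhelix
## of radius r0 / pitch P. n runs 0..(n_residues-1).
crickChain <- function(p, phase_deg, label) {
  n <- seq_len(p$n_residues) - 1L
  w0 <- 2 * pi * p$rise / p$pitch          # superhelix turn per residue
  if (p$handedness == "left") w0 <- -w0
  w1 <- 2 * pi / p$residues_per_turn - w0  # minor-helix turn in local frame
  th <- w0 * n + rad(phase_deg)
  axis <- cbind(p$r0 * cos(th), p$r0 * sin(th), p$rise * n)
  coords <- matrix(0, length(n), 3L)
  for (k in seq_along(n)) {
    tangent <- unitv(c(-p$r0 * w0 * sin(th[k]), p$r0 * w0 * cos(th[k]),
                       p$rise))
    radial <- c(cos(th[k]), sin(th[k]), 0)
    u <- unitv(radial - sum(radial * tangent) * tangent)
    v <- cross3(tangent, u)
    ph <- w1 * n[k]
    coords[k, ] <- axis[k, ] + p$r1 * (cos(ph) * u + sin(ph) * v)
  }
  chainFromCA(label, coords)
}

#' Generate an ideal two-stranded Crick coiled-coil
#'
#' Deterministic construction of a two-chain coiled-coil with prescribed
#' superhelical radius, pitch and handedness; the ground truth against which
#' the profile pipeline (axis, radius, rotation, pitch) is checked.
#'
#' @param params a \code{\link{crickParams}} bundle.
#' @param labels chain labels (default K1/K10).
#' @return a \linkS4class{DimerStructure} with C-alpha atoms.
#' @export
generateCrickCoil <- function(params, labels = c("K1", "K10")) {
  stopifnot(inherits(params, "CrickParams"))
  DimerStructure(crickChain(params, params$phase_offsets[1L], labels[1L]),
                 crickChain(params, params$phase_offsets[2L], labels[2L]),
                 source = "synthetic-crick")
}

#' Generate an ideal isolated alpha-helix
#'
#' C-alpha trace of an ideal alpha-helix (2.26 A radius, 1.51 A rise,
#' 100 degrees twist per residue) about an arbitrary axis. With
#' \code{full_backbone = TRUE}, N/CA/C/O backbone atoms are built from ideal
#' helical dihedrals (phi = -57, psi = -47, omega = 180) instead.
#'
#' @param n_residues number of residues, >= 4.
#' @param axis unit direction of the helix axis.
#' @param origin 3-vector, axis point of the first residue.
#' @param radius,rise,twist helix parameters (A, A, degrees/residue).
#' @param full_backbone build full backbone via the dihedral constructor.
#' @param label chain label.
#' @return a \linkS4class{ChainStructure}.
#' @export
generateAlphaHelix <- function(n_residues, axis = c(0, 0, 1),
                               origin = c(0, 0, 0), radius = 2.26,
                               rise = 1.51, twist = 100,
                               full_backbone = FALSE, label = "A") {
  stopifnot(n_residues >= 4L)
  if (vnorm(axis) < 1e-12) stop("axis must be a nonzero vector")
  if (full_backbone) {
    n <- as.integer(n_residues)
    ch <- chainFromDihedrals(rep("ALA", n), phi = rep(-57, n),
                             psi = rep(-47, n), omega = rep(180, n),
                             label = label)
    return(ch)
  }
  axis <- unitv(axis)
  n <- seq_len(n_residues) - 1L
  local <- cbind(radius * cos(rad(twist) * n), radius * sin(rad(twist) * n),
                 rise * n)
  z <- c(0, 0, 1)
  if (sum(z * axis) > 1 - 1e-12) {
    rot <- diag(3L)
  } else if (sum(z * axis) < -1 + 1e-12) {
    rot <- rotationMatrix(c(1, 0, 0), pi)
  } else {
    rot <- rotationMatrix(cross3(z, axis), acos(sum(z * axis)))
  }
  coords <- local %*% t(rot)
  coords <- sweep(coords, 2L, -as.numeric(origin))
  chainFromCA(label, coords)
}

#' Generate a compact random-walk globule
#'
#' Self-avoiding random walk (3.8 A steps, 4.0 A exclusion between
#' non-adjacent residues, rejection sampling) rescaled about its center of
#' mass so the realized radius of gyration equals \code{target_rg} exactly.
#' A coarse stand-in for the disordered head/tail globules.
#'
#' @param n_residues chain length, >= 2.
#' @param target_rg target radius of gyration (A). Targets below the dense
#'   packing limit (~1.8 n^(1/3) A) are an error.
#' @param seed integer seed; same seed, same coordinates.
#' @param label chain label.
#' @param step,exclusion walk step length and excluded-volume distance (A).
#' @return a \linkS4class{ChainStructure} (C-alpha only).
#' @export
generateGlobularChain <- function(n_residues, target_rg, seed, label = "G",
                                  step = 3.8, exclusion = 4.0) {
  stopifnot(n_residues >= 2L, target_rg > 0)
  rg_min <- 1.8 * n_residues^(1 / 3)
  if (target_rg < rg_min)
    stop(sprintf("target Rg %.2f A below the packing limit (~%.2f A) for %d residues",
                 target_rg, rg_min, n_residues))
  coords <- withSeed(seed, {
    repeat {
      pts <- matrix(0, n_residues, 3L)
      ok <- TRUE
      for (k in seq_len(n_residues - 1L)) {
        placed <- FALSE
        for (try in seq_len(60L)) {
          dir <- stats::rnorm(3L)
          cand <- pts[k, ] + step * unitv(dir)
          if (k >= 2L) {
            prev <- pts[seq_len(k - 1L), , drop = FALSE]
            d2 <- rowSums(sweep(prev, 2L, cand)^2)
            if (min(d2) < exclusion^2) next
          }
          pts[k + 1L, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    pts
  })
  com <- colMeans(coords)
  centered <- sweep(coords, 2L, com)
  rg <- sqrt(mean(rowSums(centered^2)))
  chainFromCA(label, centered * (target_rg / rg))
}

#' Gaussian-jittered frame ensemble
#'
#' Produces \code{n_frames} independent copies of a structure with iid
#' Gaussian displacement (sd \code{sigma} per coordinate) on every atom;
#' the fixture for contact-frequency estimation.
#'
#' @param structure a \linkS4class{DimerStructure}.
#' @param n_frames number of frames, >= 1.
#' @param sigma per-coordinate noise sd (A), >= 0.
#' @param seed integer seed.
#' @param model_id,model_scope ensemble metadata for all frames.
#' @return a \linkS4class{StructureEnsemble}.
#' @export
perturbEnsemble <- function(structure, n_frames, sigma, seed,
                            model_id = 1L, model_scope = "full") {
  stopifnot(n_frames >= 1L, sigma >= 0)
  frames <- withSeed(seed, lapply(seq_len(n_frames), function(k) {
    chains <- lapply(structure@chains, function(ch) {
      a <- ch@atoms
      n <- nrow(a)
      a$x <- a$x + stats::rnorm(n, 0, sigma)
      a$y <- a$y + stats::rnorm(n, 0, sigma)
      a$z <- a$z + stats::rnorm(n, 0, sigma)
      ChainStructure(ch@label, a)
    })
    new("DimerStructure", chains = chains, frame_id = k,
        source = "synthetic-jitter")
  }))
  StructureEnsemble(frames, model_id = rep(as.integer(model_id), n_frames),
                    model_scope = rep(model_scope, n_frames))
}

#' Assemble a synthetic dimer with placed head/tail globules
#'
#' Attaches per-chain globular subdomains to a rod dimer so that each
#' globule's C-alpha center of mass reproduces a requested axial
#' displacement d and radial orientation theta_r relative to the rod anchor
#' (see \code{\link{globulePosition}} for the measurement this inverts).
#' Globule residues are renumbered to sit immediately N-terminal (head) or
#' C-terminal (tail) of the rod residues of their chain.
#'
#' @param rod a \linkS4class{DimerStructure} whose chains span the rod.
#' @param globules named list (by chain label) of \linkS4class{ChainStructure}
#'   globules.
#' @param annotation \linkS4class{SubdomainAnnotation} covering the anchor
#'   subdomain (1A for head, 2B for tail) on the rod numbering.
#' @param d requested axial displacement (A), positive = beyond the rod end.
#' @param theta_r requested radial orientation (degrees, signed; 0 = K1 side).
#' @param rho radial offset of the globule center from the axis (A).
#' @param end "head" or "tail": which rod terminus anchors the globules.
#' @param overlap_warn C-alpha clash distance (A) below which a steric
#'   warning is emitted.
#' @return a \linkS4class{DimerStructure} with the globules attached.
#' @export
assembleSyntheticDimer <- function(rod, globules, annotation, d, theta_r,
                                   rho = 12, end = c("head", "tail"),
                                   overlap_warn = 2.5) {
  end <- match.arg(end)
  fr <- rodAnchorFrame(rod, annotation, end = end)
  target <- fr$anchor + d * fr$m_vec +
    rho * (cos(rad(theta_r)) * fr$o_vec +
             sin(rad(theta_r)) * cross3(fr$m_vec, fr$o_vec))
  chains <- lapply(rod@chains, function(ch) {
    g <- globules[[ch@label]]
    if (is.null(g)) return(ch)
    ca <- caCoords(g)
    com <- colMeans(ca)
    ga <- g@atoms
    shift <- target - com
    ga$x <- ga$x + shift[1L]; ga$y <- ga$y + shift[2L]; ga$z <- ga$z + shift[3L]
    rodnums <- sort(unique(ch@atoms$resnum))
    nglob <- length(unique(ga$resnum))
    if (end == "head") {
      if (min(rodnums) - nglob < 1L)
        stop("rod numbering leaves no room for the head globule residues")
      ga$resnum <- match(ga$resnum, sort(unique(ga$resnum))) +
        (min(rodnums) - nglob - 1L)
      merged <- rbind(ga[, ATOM_COLS], ch@atoms[, ATOM_COLS])
    } else {
      ga$resnum <- match(ga$resnum, sort(unique(ga$resnum))) + max(rodnums)
      merged <- rbind(ch@atoms[, ATOM_COLS], ga[, ATOM_COLS])
    }
    merged$serial <- seq_len(nrow(merged))
    gxyz <- as.matrix(ga[ga$atom == "CA", c("x", "y", "z")])
    rxyz <- caCoords(ch)
    dmin <- sqrt(min(outer(rowSums(gxyz^2), rowSums(rxyz^2), "+") -
                       2 * gxyz %*% t(rxyz)))
    if (is.finite(dmin) && dmin < overlap_warn)
      warning(sprintf("chain %s: globule clashes with rod (min CA-CA %.2f A)",
                      ch@label, dmin))
    ChainStructure(ch@label, merged)
  })
  new("DimerStructure", chains = chains, frame_id = rod@frame_id,
      source = "synthetic-assembled")
}
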