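## Initial-configuration machinery for the disordered head/tail domains:
## backbone construction from dihedral specifications, nine-residue hairpin
## turn placement, enumeration of the 25 orientation x n-shift starting
## models, and the truncation restraint specification.

## Canonical backbone geometry (bond lengths in A, angles in degrees).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8)

#' Build a peptide backbone from dihedral angles
#'
#' Constructs N/CA/C/O backbone coordinates for a chain from per-residue
#' phi/psi/omega dihedrals using canonical bond lengths and angles (the
#' internal-to-Cartesian chain extension). phi of the first residue and
#' psi/omega of the last are not defined by the construction and are
#' ignored. Re-measuring the dihedrals from the built coordinates
#' reproduces the specification exactly (to numerical round-off).
#'
#' @param sequence character vector of 3-letter residue names (or a single
#'   one-letter string).
#' @param phi,psi,omega numeric vectors of dihedrals in degrees, one per
#'   residue, in (-180, 180].
#' @param label chain label.
#' @param clash_warn C-alpha distance (A) below which a steric
#'   self-intersection warning is emitted for non-adjacent residues.
#' @return a \linkS4class{ChainStructure} with full backbone atoms.
#' @export
chainFromDihedrals <- function(sequence, phi, psi, omega, label = "A",
                               clash_warn = 3.0) {
  if (length(sequence) == 1L && !sequence %in% AA3) {
    sequence <- aa1to3(strsplit(sequence, "")[[1L]])
  }
  n <- length(sequence)
  stopifnot(length(phi) == n, length(psi) == n, length(omega) == n)
  g <- BB_GEOM
  N <- matrix(NA_real_, n, 3L); CA <- N; C <- N; O <- N
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$n_ca, 0, 0)
  ## first C placed in the xy-plane at the ideal N-CA-C angle
  ang <- rad(g$ang_n_ca_c)
  C[1L, ] <- CA[1L, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (r in seq_len(n - 1L)) {
    N[r + 1L, ] <- placeAtom(N[r, ], CA[r, ], C[r, ], g$c_n, g$ang_ca_c_n,
                             psi[r])
    CA[r + 1L, ] <- placeAtom(CA[r, ], C[r, ], N[r + 1L, ], g$n_ca,
                              g$ang_c_n_ca, omega[r])
    C[r + 1L, ] <- placeAtom(C[r, ], N[r + 1L, ], CA[r + 1L, ], g$ca_c,
                             g$ang_n_ca_c, phi[r + 1L])
  }
  for (r in seq_len(n)) {
    ## carbonyl O opposite the next N (trans to psi); last residue uses the
    ## same construction relative to its own psi
    ref_psi <- if (r < n) psi[r] else 0
    O[r, ] <- placeAtom(N[r, ], CA[r, ], C[r, ], g$c_o, g$ang_ca_c_o,
                        ref_psi + 180)
  }
  atoms <- do.call(rbind, lapply(seq_len(n), function(r) data.frame(
    serial = 0L, atom = c("N", "CA", "C", "O"), resname = sequence[r],
    resnum = r,
    x = c(N[r, 1L], CA[r, 1L], C[r, 1L], O[r, 1L]),
    y = c(N[r, 2L], CA[r, 2L], C[r, 2L], O[r, 2L]),
    z = c(N[r, 3L], CA[r, 3L], C[r, 3L], O[r, 3L]),
    element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)))
  atoms$serial <- seq_len(nrow(atoms))
  ch <- ChainStructure(label, atoms)
  ca <- caCoords(ch)
  if (n > 2L) {
    d2 <- outer(rowSums(ca^2), rowSums(ca^2), "+") - 2 * ca %*% t(ca)
    nonadj <- abs(row(d2) - col(d2)) > 1L & upper.tri(d2)
    clashes <- which(nonadj & d2 < clash_warn^2, arr.ind = TRUE)
    if (nrow(clashes))
      warning(sprintf("built chain self-intersects: %d C-alpha pair(s) < %.1f A (first: %d-%d)",
                      nrow(clashes), clash_warn, clashes[1L, 1L],
                      clashes[1L, 2L]))
  }
  ch
}

#' Measure backbone dihedrals from coordinates
#'
#' @param chain a \linkS4class{ChainStructure} with N/CA/C backbone atoms.
#' @return data.frame: resnum, phi, psi, omega (degrees; NA where
#'   undefined at the termini).
#' @export
measureDihedrals <- function(chain) {
  a <- chain@atoms
  get <- function(atom, r) {
    row <- a[a$atom == atom & a$resnum == r, , drop = FALSE]
    if (!nrow(row)) stop(sprintf("missing %s atom in residue %d", atom, r))
    as.numeric(row[1L, c("x", "y", "z")])
  }
  resnums <- sort(unique(a$resnum))
  n <- length(resnums)
  out <- data.frame(resnum = resnums, phi = NA_real_, psi = NA_real_,
                    omega = NA_real_)
  for (k in seq_len(n)) {
    r <- resnums[k]
    if (k > 1L)
      out$phi[k] <- torsionAngle(get("C", resnums[k - 1L]), get("N", r),
                                 get("CA", r), get("C", r))
    if (k < n) {
      out$psi[k] <- torsionAngle(get("N", r), get("CA", r), get("C", r),
                                 get("N", resnums[k + 1L]))
      out$omega[k] <- torsionAngle(get("CA", r), get("C", r),
                                   get("N", resnums[k + 1L]),
                                   get("CA", resnums[k + 1L]))
    }
  }
  out
}

## Base hairpin-turn windows (9 residues) and head/tail domain bounds for
## the K1/K10 construct, on the default annotation numbering.
HAIRPIN_BASE <- list(
  head = list(K1 = c(103L, 111L), K10 = c(86L, 94L)),
  tail = list(K1 = c(534L, 542L), K10 = c(498L, 506L)))

#' Hairpin turn dihedrals
#'
#' The nine-residue hairpin turn is specified with phi = -162.5, psi =
#' +162.5 and omega = 180 degrees at every turn residue.
#'
#' @param n number of turn residues.
#' @return data.frame with columns phi, psi, omega.
#' @export
hairpinDihedrals <- function(n = 9L) {
  data.frame(phi = rep(-162.5, n), psi = rep(162.5, n), omega = rep(180, n))
}

#' Construct one head/tail hairpin configuration
#'
#' Places the nine-residue hairpin turn window for both chains of one
#' domain. The base windows (head: K1:103-111, K10:86-94; tail:
#' K1:534-542, K10:498-506) are shifted by \code{n_shift} residues toward
#' the rod domain - increasing residue numbers for the head (whose rod lies
#' C-terminal) and decreasing for the tail.
#'
#' @param domain "head" or "tail".
#' @param orientation folding direction, one of A (both chains toward the
#'   K1 face), B (toward the K10 face), C (each onto the opposite chain's
#'   face), D (each onto its own face), E (extended, not folded).
#' @param n_shift one of -5, 0, 3, 5, 10.
#' @param annotation \linkS4class{SubdomainAnnotation} used to check the
#'   shifted windows stay inside the head/tail domains.
#' @return list of class \code{"ModelConfig"}: orientation, n_shift,
#'   domain, turn windows per chain.
#' @export
makeHairpinConfig <- function(domain = c("head", "tail"),
                              orientation = c("A", "B", "C", "D", "E"),
                              n_shift = 0L, annotation = defaultAnnotation()) {
  domain <- match.arg(domain)
  orientation <- match.arg(orientation)
  if (!n_shift %in% c(-5L, 0L, 3L, 5L, 10L))
    stop("n_shift must be one of -5, 0, 3, 5, 10")
  dirn <- if (domain == "head") 1L else -1L   # toward the rod
  windows <- lapply(HAIRPIN_BASE[[domain]], function(w) w + dirn * n_shift)
  bounds <- list(
    K1 = if (domain == "head")
      c(1L, subdomainRange(annotation, "K1", "1A")[1L] - 1L)
    else c(subdomainRange(annotation, "K1", "2B")[2L] + 1L,
           annotationEntries(annotation, "K1")$end[
             annotationEntries(annotation, "K1")$subdomain == "E2"]),
    K10 = if (domain == "head")
      c(1L, subdomainRange(annotation, "K10", "1A")[1L] - 1L)
    else c(subdomainRange(annotation, "K10", "2B")[2L] + 1L,
           annotationEntries(annotation, "K10")$end[
             annotationEntries(annotation, "K10")$subdomain == "E2"]))
  for (ch in names(windows)) {
    w <- windows[[ch]]
    if (w[2L] - w[1L] != 8L) stop("turn window must span nine residues")
    if (w[1L] < bounds[[ch]][1L] || w[2L] > bounds[[ch]][2L])
      stop(sprintf("shifted turn window %d-%d leaves the %s domain of %s",
                   w[1L], w[2L], domain, ch))
  }
  structure(list(orientation = orientation, n_shift = as.integer(n_shift),
                 domain = domain, turn_windows = windows,
                 dihedrals = hairpinDihedrals(9L)),
            class = "ModelConfig")
}

#' Enumerate the 25 starting-model configurations
#'
#' The full orientation (A-E) by n-shift (-5, 0, 3, 5, 10) grid: 25
#' distinct configurations, of which ten are full-dimer models (head and
#' tail folded in the same direction) and fifteen are truncated models
#' (head-1A-L1-1B construct). The scope allocation across the grid is read
#' from an editable table reconstructing the published split.
#'
#' @param allocation optional path to a TSV with columns
#'   orientation/n_shift/scope overriding the shipped allocation.
#' @return data.frame manifest: model_id, orientation, n_shift, scope.
#' @export
enumerateModels <- function(allocation = NULL) {
  if (is.null(allocation))
    allocation <- system.file("extdata", "model_allocation.tsv",
                              package = "IFDimerTools", mustWork = TRUE)
  tab <- utils::read.delim(allocation, stringsAsFactors = FALSE)
  stopifnot(all(c("orientation", "n_shift", "scope") %in% names(tab)))
  tab <- tab[order(tab$orientation, tab$n_shift), , drop = FALSE]
  if (nrow(tab) != 25L || anyDuplicated(tab[, c("orientation", "n_shift")]))
    stop("allocation table must cover the 25 orientation x n-shift combinations")
  if (sum(tab$scope == "full") != 10L || sum(tab$scope == "truncated") != 15L)
    stop("allocation must assign 10 full and 15 truncated models")
  data.frame(model_id = seq_len(25L), tab, row.names = NULL)
}

#' Truncation restraint specification
#'
#' The truncated construct cleaves the dimer at the C-terminal end of the
#' 1B coiled-coil subdomain (residues K1:328 and K10:296, each chain
#' terminated with a COOH group); a harmonic restraint between the
#' C-alpha atoms of those residues keeps the 1B coil from unravelling.
#' The force constant is recorded as printed, 1000 kcal (A mol)^-1 - a
#' dimensionally unusual unit for a harmonic restraint (kcal mol^-1 A^-2
#' would be expected) - and flagged as such in the emitted block.
#'
#' @return list of class \code{"RestraintSpec"}: cleavage residues, atoms,
#'   force constant and equilibrium distance (14.37 A).
#' @export
truncationSpec <- function() {
  structure(list(
    cleavage = c(K1 = 328L, K10 = 296L),
    atom_a = list(chain = "K1", resnum = 328L, atom = "CA"),
    atom_b = list(chain = "K10", resnum = 296L, atom = "CA"),
    force_constant = 1000,
    force_constant_unit = "kcal (A mol)^-1 (as printed; unit flagged)",
    equilibrium_distance = 14.37), class = "RestraintSpec")
}

#' Write a restraint spec as a plain-text key-value block
#'
#' @param spec a \code{\link{truncationSpec}} result.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRestraintSpec <- function(spec, path) {
  lines <- c(
    sprintf("atom_a\t%s:%d:%s", spec$atom_a$chain, spec$atom_a$resnum,
            spec$atom_a$atom),
    sprintf("atom_b\t%s:%d:%s", spec$atom_b$chain, spec$atom_b$resnum,
            spec$atom_b$atom),
    sprintf("force_constant\t%g", spec$force_constant),
    sprintf("force_constant_unit\t%s", spec$force_constant_unit),
    sprintf("equilibrium_distance\t%.2f", spec$equilibrium_distance))
  writeLines(lines, path)
  invisible(path)
}

## 3-letter <-> 1-letter residue code helpers.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

aa1to3 <- function(x) {
  idx <- match(toupper(x), AA1)
  if (anyNA(idx)) stop("unknown one-letter residue code")
  AA3[idx]
}
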