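#' @import methods
NULL

ATOM_COLS <- c("serial", "atom", "resname", "resnum", "x", "y", "z", "element")

## Canonical subdomain vocabulary of the IF dimer: tri-partitioned head
## (E1-V1-H1), rod (coiled-coils 1A/1B/2A/2B with linkers L1/L12/L2) and
## tri-partitioned tail (H2-V2-E2).
SUBDOMAIN_NAMES <- c("E1", "V1", "H1", "1A", "L1", "1B", "L12", "2A", "L2",
                     "2B", "H2", "V2", "E2")

emptyAtoms <- function() {
  data.frame(serial = integer(), atom = character(), resname = character(),
             resnum = integer(), x = numeric(), y = numeric(), z = numeric(),
             element = character(), stringsAsFactors = FALSE)
}

#' ChainStructure: one annotated peptide chain
#'
#' Holds the atoms of a single chain as a per-atom table. Every residue must
#' carry a C-alpha atom; backbone (N, C, O) and side-chain atoms are optional.
#' Residue numbering is per-chain, 1-based and strictly increasing.
#'
#' @slot label chain label, e.g. \code{"K1"} or \code{"K10"}.
#' @slot atoms data.frame with columns \code{serial}, \code{atom},
#'   \code{resname}, \code{resnum}, \code{x}, \code{y}, \code{z},
#'   \code{element}.
#' @exportClass ChainStructure
setClass("ChainStructure",
         representation(label = "character", atoms = "data.frame"),
         prototype(label = "A", atoms = emptyAtoms()))

setValidity("ChainStructure", function(object) {
  a <- object@atoms
  if (!all(ATOM_COLS %in% names(a)))
    return(paste("atoms table must have columns:",
                 paste(ATOM_COLS, collapse = ", ")))
  if (nrow(a) == 0L) return(TRUE)
  if (!all(is.finite(c(a$x, a$y, a$z))))
    return("atom coordinates must be finite")
  if (any(a$resnum < 1L)) return("residue numbers must be >= 1")
  resnums <- unique(a$resnum)
  if (is.unsorted(resnums, strictly = TRUE))
    return("residue numbers must be strictly increasing")
  ca <- a$resnum[a$atom == "CA"]
  missing <- setdiff(resnums, ca)
  if (length(missing))
    return(sprintf("chain %s: residue %s lacks a CA atom",
                   object@label, missing[1L]))
  TRUE
})

#' DimerStructure: a two-chain structure frame
#'
#' @slot chains list of one or two \linkS4class{ChainStructure} objects with
#'   distinct labels (type II first by convention, e.g. K1 then K10); dimer
#'   analyses require two, but single-chain structures can be carried.
#' @slot frame_id integer frame identifier.
#' @slot source free-text provenance tag.
#' @exportClass DimerStructure
setClass("DimerStructure",
         representation(chains = "list", frame_id = "integer",
                        source = "character"),
         prototype(chains = list(), frame_id = 1L, source = ""))

setValidity("DimerStructure", function(object) {
  if (length(object@chains) < 1L || length(object@chains) > 2L)
    return("a DimerStructure holds one or two chains")
  if (!all(vapply(object@chains, is, logical(1L), "ChainStructure")))
    return("chains must be ChainStructure objects")
  labs <- vapply(object@chains, function(ch) ch@label, character(1L))
  if (anyDuplicated(labs)) return("chain labels must be distinct")
  TRUE
})

#' StructureEnsemble: an ordered collection of dimer frames
#'
#' Frames may come from different models (\code{model_id}) and from full or
#' truncated constructs (\code{model_scope}); contact-probability
#' normalization uses this metadata.
#'
#' @slot frames list of \linkS4class{DimerStructure}.
#' @slot model_id integer vector, one entry per frame.
#' @slot model_scope character vector, \code{"full"} or \code{"truncated"}.
#' @exportClass StructureEnsemble
setClass("StructureEnsemble",
         representation(frames = "list", model_id = "integer",
                        model_scope = "character"),
         prototype(frames = list(), model_id = integer(),
                   model_scope = character()))

setValidity("StructureEnsemble", function(object) {
  n <- length(object@frames)
  if (length(object@model_id) != n || length(object@model_scope) != n)
    return("model_id and model_scope must have one entry per frame")
  if (n && !all(object@model_scope %in% c("full", "truncated")))
    return("model_scope entries must be 'full' or 'truncated'")
  if (n && !all(vapply(object@frames, is, logical(1L), "DimerStructure")))
    return("frames must be DimerStructure objects")
  for (id in unique(object@model_id)) {
    fr <- object@frames[object@model_id == id]
    len <- vapply(fr, function(f) paste(vapply(f@chains, nResidues,
                                               integer(1L)), collapse = "/"),
                  character(1L))
    if (length(unique(len)) > 1L)
      return(sprintf("frames of model %s differ in chain lengths", id))
  }
  TRUE
})

#' SubdomainAnnotation: subdomain intervals per chain
#'
#' @slot entries data.frame with columns \code{chain}, \code{subdomain},
#'   \code{start}, \code{end} (1-based, inclusive). Per chain, intervals must
#'   be ordered and non-overlapping.
#' @exportClass SubdomainAnnotation
setClass("SubdomainAnnotation", representation(entries = "data.frame"))

setValidity("SubdomainAnnotation", function(object) {
  e <- object@entries
  need <- c("chain", "subdomain", "start", "end")
  if (!all(need %in% names(e)))
    return("entries must have columns chain/subdomain/start/end")
  bad <- setdiff(e$subdomain, SUBDOMAIN_NAMES)
  if (length(bad))
    return(sprintf("unknown subdomain name: %s", bad[1L]))
  if (any(e$end < e$start)) return("interval end before start")
  for (ch in unique(e$chain)) {
    iv <- e[e$chain == ch, , drop = FALSE]
    iv <- iv[order(iv$start), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)]))
      return(sprintf("overlapping intervals on chain %s", ch))
  }
  TRUE
})

#' AxisPath: per-residue alpha-helix axis points
#'
#' @slot points numeric matrix (n x 3) of axis points, rownames are residue
#'   numbers; the defined index range is contiguous.
#' @slot chain_label chain the path belongs to.
#' @exportClass AxisPath
setClass("AxisPath",
         representation(points = "matrix", chain_label = "character"))

setValidity("AxisPath", function(object) {
  p <- object@points
  if (ncol(p) != 3L) return("points must be an n x 3 matrix")
  if (!all(is.finite(p))) return("axis points must be finite")
  idx <- as.integer(rownames(p))
  if (any(is.na(idx))) return("rownames must be residue numbers")
  if (nrow(p) > 1L && !all(diff(idx) == 1L))
    return("defined residue range must be contiguous")
  TRUE
})

#' CoiledCoilProfile: per-residue coiled-coil geometry
#'
#' Central axis P(i), local superhelical radius R(i), signed rotation angle
#' Psi(i) per residue, local pitch lambda(i) and handedness. Pitch is NA and
#' handedness "indeterminate" where |Psi| falls below the parallel-strand
#' threshold.
#'
#' @slot residue integer residue numbers (contiguous interior range).
#' @slot central_axis numeric matrix (n x 3), central path P(i).
#' @slot radius numeric, local radius R(i) in Angstrom.
#' @slot rotation numeric, signed Psi(i) in degrees (negative = left-handed).
#' @slot pitch numeric, local pitch lambda(i) in Angstrom (NA where
#'   indeterminate).
#' @slot handedness character, "left", "right" or "indeterminate".
#' @slot psi_min numeric threshold (degrees/residue) below which strands are
#'   treated as parallel.
#' @exportClass CoiledCoilProfile
setClass("CoiledCoilProfile",
         representation(residue = "integer", central_axis = "matrix",
                        radius = "numeric", rotation = "numeric",
                        pitch = "numeric", handedness = "character",
                        psi_min = "numeric"))

setValidity("CoiledCoilProfile", function(object) {
  n <- length(object@residue)
  if (nrow(object@central_axis) != n || length(object@radius) != n ||
      length(object@rotation) != n || length(object@pitch) != n ||
      length(object@handedness) != n)
    return("profile slots must share one entry per residue")
  if (any(object@radius < 0, na.rm = TRUE)) return("radius must be >= 0")
  ind <- object@handedness == "indeterminate"
  if (!identical(unname(is.na(object@pitch)), unname(ind)))
    return("pitch must be NA exactly where handedness is indeterminate")
  TRUE
})

#' GlobulePosition: placement of a head/tail globule relative to the rod
#'
#' @slot chain_label chain whose globule was measured.
#' @slot subdomain_name globular subdomain (e.g. "V1", "V2").
#' @slot d signed axial displacement (Angstrom); positive = beyond the rod
#'   terminus, along the outward anchor axis M.
#' @slot theta_r signed radial orientation in degrees, (-180, 180]; 0 points
#'   toward the K1 chain. NA when the globule center lies on the axis.
#' @slot v_vec globule-center-to-anchor displacement V (Angstrom).
#' @slot m_vec unit outward anchor axis M.
#' @slot o_vec unit K1-pointing reference O (perpendicular to M).
#' @slot p_vec unit in-plane projection P of V (zero vector if degenerate).
#' @exportClass GlobulePosition
setClass("GlobulePosition",
         representation(chain_label = "character", subdomain_name = "character",
                        d = "numeric", theta_r = "numeric", v_vec = "numeric",
                        m_vec = "numeric", o_vec = "numeric",
                        p_vec = "numeric"))

setValidity("GlobulePosition", function(object) {
  for (nm in c("m_vec", "o_vec")) {
    v <- slot(object, nm)
    if (length(v) != 3L || abs(vnorm(v) - 1) > 1e-6)
      return(sprintf("%s must be a unit 3-vector", nm))
  }
  if (!is.na(object@theta_r) &&
      (object@theta_r <= -180 || object@theta_r > 180))
    return("theta_r must lie in (-180, 180]")
  TRUE
})

#' ContactMap: residue pairs in contact in one frame
#'
#' @slot pairs data.frame with columns \code{i}, \code{j} (global residue
#'   indices, i < j), \code{class} (K1-K1, K10-K10 or K1-K10).
#' @slot cutoff C-alpha distance cutoff in Angstrom (strict \code{<}).
#' @slot exclusion intra-chain sequence-separation exclusion |i-j| <= k.
#' @slot frame_id frame the map was computed from.
#' @exportClass ContactMap
setClass("ContactMap",
         representation(pairs = "data.frame", cutoff = "numeric",
                        exclusion = "integer", frame_id = "integer"))

setValidity("ContactMap", function(object) {
  p <- object@pairs
  if (!all(c("i", "j", "class") %in% names(p)))
    return("pairs must have columns i/j/class")
  if (nrow(p) && any(p$i >= p$j)) return("pairs must be canonical (i < j)")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

## ---- constructors -------------------------------------------------------

#' Create a ChainStructure
#'
#' @param label chain label.
#' @param atoms per-atom data.frame (see \linkS4class{ChainStructure}).
#' @return a validated \linkS4class{ChainStructure}.
#' @export
ChainStructure <- function(label, atoms) {
  atoms$serial <- as.integer(atoms$serial)
  atoms$resnum <- as.integer(atoms$resnum)
  rownames(atoms) <- NULL
  new("ChainStructure", label = as.character(label), atoms = atoms)
}

#' Build a C-alpha-only chain from a coordinate matrix
#'
#' @param label chain label.
#' @param coords numeric n x 3 matrix of C-alpha positions.
#' @param resname residue name(s), recycled.
#' @param resnum residue numbers (default 1..n).
#' @return a \linkS4class{ChainStructure}.
#' @export
chainFromCA <- function(label, coords, resname = "ALA",
                        resnum = seq_len(nrow(coords))) {
  n <- nrow(coords)
  ChainStructure(label, data.frame(
    serial = seq_len(n), atom = "CA",
    resname = rep_len(resname, n), resnum = as.integer(resnum),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    element = "C", stringsAsFactors = FALSE))
}

#' Create a DimerStructure
#'
#' @param chain1,chain2 the two \linkS4class{ChainStructure} objects.
#' @param frame_id integer frame id.
#' @param source provenance string.
#' @return a validated \linkS4class{DimerStructure}.
#' @export
DimerStructure <- function(chain1, chain2 = NULL, frame_id = 1L, source = "") {
  chains <- if (is.null(chain2)) list(chain1) else list(chain1, chain2)
  new("DimerStructure", chains = chains,
      frame_id = as.integer(frame_id), source = source)
}

#' Create a StructureEnsemble
#'
#' @param frames list of \linkS4class{DimerStructure}.
#' @param model_id integer per frame (default: all 1).
#' @param model_scope "full" or "truncated" per frame (default "full").
#' @return a validated \linkS4class{StructureEnsemble}.
#' @export
StructureEnsemble <- function(frames, model_id = rep(1L, length(frames)),
                              model_scope = rep("full", length(frames))) {
  new("StructureEnsemble", frames = frames,
      model_id = as.integer(model_id), model_scope = model_scope)
}
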