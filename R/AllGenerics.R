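#' Number of residues in a chain or dimer
#'
#' @param x a \linkS4class{ChainStructure} or \linkS4class{DimerStructure}.
#' @return integer count (per chain for dimers, summed).
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname nResidues
#' @export
setMethod("nResidues", "ChainStructure",
          function(x) length(unique(x@atoms$resnum)))

#' @rdname nResidues
#' @export
setMethod("nResidues", "DimerStructure",
          function(x) sum(vapply(x@chains, nResidues, integer(1L))))

#' Chain label accessor
#' @param x a \linkS4class{ChainStructure}.
#' @return character label.
#' @export
setGeneric("chainLabel", function(x) standardGeneric("chainLabel"))

#' @rdname chainLabel
#' @export
setMethod("chainLabel", "ChainStructure", function(x) x@label)

#' C-alpha coordinates
#'
#' @param x a \linkS4class{ChainStructure}.
#' @param resnum optional residue numbers to subset (default all).
#' @return numeric matrix (n x 3) with residue numbers as rownames.
#' @export
setGeneric("caCoords", function(x, resnum = NULL) standardGeneric("caCoords"))

#' @rdname caCoords
#' @export
setMethod("caCoords", "ChainStructure", function(x, resnum = NULL) {
  a <- x@atoms[x@atoms$atom == "CA", , drop = FALSE]
  if (!is.null(resnum)) a <- a[a$resnum %in% resnum, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resnum
  m
})

#' Chains of a dimer
#' @param x a \linkS4class{DimerStructure}.
#' @return named list of the two \linkS4class{ChainStructure} objects.
#' @export
setGeneric("dimerChains", function(x) standardGeneric("dimerChains"))

#' @rdname dimerChains
#' @export
setMethod("dimerChains", "DimerStructure", function(x) {
  stats::setNames(x@chains,
                  vapply(x@chains, chainLabel, character(1L)))
})

#' Get one chain of a dimer by label
#' @param x a \linkS4class{DimerStructure}.
#' @param label chain label.
#' @return the matching \linkS4class{ChainStructure}.
#' @export
getChain <- function(x, label) {
  ch <- dimerChains(x)
  if (!label %in% names(ch))
    stop(sprintf("no chain labelled '%s' (have: %s)", label,
                 paste(names(ch), collapse = ", ")))
  ch[[label]]
}

#' Shift the residue numbering of a chain
#'
#' @param chain a \linkS4class{ChainStructure}.
#' @param by integer offset added to every residue number.
#' @return the renumbered \linkS4class{ChainStructure}.
#' @export
shiftResidueNumbers <- function(chain, by) {
  a <- chain@atoms
  a$resnum <- a$resnum + as.integer(by)
  ChainStructure(chain@label, a)
}

#' Frames of an ensemble
#' @param x a \linkS4class{StructureEnsemble}.
#' @return list of \linkS4class{DimerStructure} frames.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "StructureEnsemble", function(x) x@frames)

#' Number of frames
#' @param x a \linkS4class{StructureEnsemble}.
#' @return integer.
#' @export
setMethod("length", "StructureEnsemble", function(x) length(x@frames))

#' Annotation entries accessor
#' @param x a \linkS4class{SubdomainAnnotation}.
#' @param chain optional chain label filter.
#' @return data.frame of intervals.
#' @export
setGeneric("annotationEntries",
           function(x, chain = NULL) standardGeneric("annotationEntries"))

#' @rdname annotationEntries
#' @export
setMethod("annotationEntries", "SubdomainAnnotation", function(x, chain = NULL) {
  e <- x@entries
  if (!is.null(chain)) e <- e[e$chain %in% chain, , drop = FALSE]
  e
})

#' Look up one subdomain interval
#' @param x a \linkS4class{SubdomainAnnotation}.
#' @param chain chain label.
#' @param subdomain subdomain name.
#' @return integer vector \code{c(start, end)}.
#' @export
subdomainRange <- function(x, chain, subdomain) {
  e <- x@entries
  hit <- e$chain == chain & e$subdomain == subdomain
  if (!any(hit))
    stop(sprintf("annotation has no %s interval for chain %s",
                 subdomain, chain))
  c(start = as.integer(e$start[hit][1L]), end = as.integer(e$end[hit][1L]))
}

#' Axis points accessor
#' @param x an \linkS4class{AxisPath}.
#' @return numeric matrix with residue-number rownames.
#' @export
setGeneric("axisPoints", function(x) standardGeneric("axisPoints"))

#' @rdname axisPoints
#' @export
setMethod("axisPoints", "AxisPath", function(x) x@points)

#' Profile as a per-residue table
#'
#' @param x a \linkS4class{CoiledCoilProfile}.
#' @param annotation optional \linkS4class{SubdomainAnnotation} used to label
#'   rows by subdomain (matched on the first chain's numbering).
#' @param chain chain label used for the annotation lookup.
#' @return data.frame: residue, R, psi, lambda, handedness (+ subdomain).
#' @export
profileTable <- function(x, annotation = NULL, chain = NULL) {
  df <- data.frame(residue = x@residue, R = x@radius, psi = x@rotation,
                   lambda = x@pitch, handedness = x@handedness,
                   stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    e <- annotationEntries(annotation, chain)
    df$subdomain <- NA_character_
    for (k in seq_len(nrow(e))) {
      inr <- df$residue >= e$start[k] & df$residue <= e$end[k]
      df$subdomain[inr] <- e$subdomain[k]
    }
  }
  df
}

## ---- show methods -------------------------------------------------------

setMethod("show", "ChainStructure", function(object) {
  cat(sprintf("ChainStructure '%s': %d residues, %d atoms\n",
              object@label, nResidues(object), nrow(object@atoms)))
})

setMethod("show", "DimerStructure", function(object) {
  labs <- vapply(object@chains, chainLabel, character(1L))
  ns <- vapply(object@chains, nResidues, integer(1L))
  cat(sprintf("DimerStructure frame %d (%s): %s\n", object@frame_id,
              object@source,
              paste(sprintf("%s(%d res)", labs, ns), collapse = " + ")))
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d frames, %d models (%d full, %d truncated)\n",
              length(object@frames), length(unique(object@model_id)),
              sum(tapply(object@model_scope, object@model_id,
                         function(s) s[1L]) == "full"),
              sum(tapply(object@model_scope, object@model_id,
                         function(s) s[1L]) == "truncated")))
})

setMethod("show", "SubdomainAnnotation", function(object) {
  cat(sprintf("SubdomainAnnotation: %d intervals on chains %s\n",
              nrow(object@entries),
              paste(unique(object@entries$chain), collapse = ", ")))
})

setMethod("show", "CoiledCoilProfile", function(object) {
  ok <- !is.na(object@pitch)
  cat(sprintf(paste0("CoiledCoilProfile: residues %d-%d | mean R %.2f A | ",
                     "mean |pitch| %.1f A | handedness: %s\n"),
              min(object@residue), max(object@residue),
              mean(object@radius),
              if (any(ok)) mean(abs(object@pitch[ok])) else NA,
              paste(names(sort(table(object@handedness),
                               decreasing = TRUE))[1L])))
})

setMethod("show", "GlobulePosition", function(object) {
  cat(sprintf("GlobulePosition %s/%s: d = %+.2f A, theta_r = %s\n",
              object@chain_label, object@subdomain_name, object@d,
              if (is.na(object@theta_r)) "indeterminate"
              else sprintf("%+.1f deg", object@theta_r)))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap frame %d: %d pairs (< %.1f A, exclusion %d)\n",
              object@frame_id, nrow(object@pairs), object@cutoff,
              object@exclusion))
})
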