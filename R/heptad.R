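## Heptad register handling and the ideal knobs-into-holes contact count.

HEPTAD_LETTERS <- c("a", "b", "c", "d", "e", "f", "g")

#' Assign a heptad register to a residue range
#'
#' Letters a-g cycle along the sequence from a starting phase. A stutter (a
#' three-residue insertion in the heptad periodicity, as conserved in the
#' 2B subdomain of IF rods) advances the phase by three at the annotated
#' residue, i.e. the cycle skips three letters after it.
#'
#' @param resnums integer residue numbers (ordered).
#' @param start letter of the first residue.
#' @param stutters residue numbers after which the register jumps by +3.
#' @return named character vector of letters, names are residue numbers.
#' @export
heptadRegister <- function(resnums, start = "a", stutters = integer()) {
  stopifnot(start %in% HEPTAD_LETTERS)
  phase <- match(start, HEPTAD_LETTERS) - 1L
  out <- character(length(resnums))
  for (k in seq_along(resnums)) {
    out[k] <- HEPTAD_LETTERS[(phase %% 7L) + 1L]
    phase <- phase + 1L
    if (resnums[k] %in% stutters) phase <- phase + 3L
  }
  stats::setNames(out, resnums)
}

#' Ideal a/d inter-chain contact count
#'
#' The theoretical number of knobs-into-holes core contacts an ideal
#' two-stranded coiled coil would form between the a- and d-heptad
#' positions of two in-register chains. The frozen pairing rule: aligned
#' residues pair a-a' and d-d' (the two core layers), and within each
#' heptad the a knob additionally packs against the partner chain's d
#' position of the same heptad (a-d' and d-a'), giving four pairings per
#' complete aligned heptad. The count is enumerated directly from the
#' register letters, so stutter discontinuities are handled by
#' construction.
#'
#' @param register_a,register_b named letter vectors (from
#'   \code{\link{heptadRegister}}) for the two chains; positions are
#'   aligned ordinally (in-register chains).
#' @return integer contact count.
#' @export
idealAdContacts <- function(register_a, register_b) {
  n <- min(length(register_a), length(register_b))
  if (n == 0L) return(0L)
  a <- unname(register_a[seq_len(n)])
  b <- unname(register_b[seq_len(n)])
  if (anyNA(a) || anyNA(b) || any(a == "") || any(b == ""))
    stop("heptad register is unassigned within the requested range")
  count <- 0L
  for (k in seq_len(n)) {
    if (a[k] == "a" && b[k] == "a") count <- count + 1L
    if (a[k] == "d" && b[k] == "d") count <- count + 1L
    ## same-heptad cross pairings: d sits three positions after a
    if (a[k] == "a" && k + 3L <= n && b[k + 3L] == "d") count <- count + 1L
    if (a[k] == "d" && k - 3L >= 1L && b[k - 3L] == "a") count <- count + 1L
  }
  count
}
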