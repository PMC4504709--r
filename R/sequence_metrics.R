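## Sequence-level summaries used when only primary structure is in hand:
## residue censuses and net side-chain formal charge.

#' Count residues of given one-letter types
#'
#' @param seqs character vector of one-letter sequences (e.g. from
#'   \code{\link{readFastaChains}}).
#' @param residues one-letter codes to count (default cysteine).
#' @return total count across all sequences.
#' @export
countResidueType <- function(seqs, residues = "C") {
  sum(vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1L]]
    sum(chars %in% toupper(residues))
  }, numeric(1L)))
}

#' Net side-chain formal charge at neutral pH
#'
#' Lys and Arg contribute +1, Asp and Glu -1; His is treated as neutral
#' (unprotonated at pH 7), as are all other residues. Termini are not
#' included (side chains only).
#'
#' @param seq one-letter sequence string.
#' @param range optional \code{c(start, end)} residue positions (1-based,
#'   inclusive), e.g. a head-domain interval.
#' @return integer net charge in units of e.
#' @export
netSidechainCharge <- function(seq, range = NULL) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  if (!is.null(range)) {
    if (range[2L] > length(chars))
      stop(sprintf("range end %d beyond sequence length %d", range[2L],
                   length(chars)))
    chars <- chars[range[1L]:range[2L]]
  }
  sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
}
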