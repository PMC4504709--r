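## Structure and sequence I/O. PDB parsing goes through bio3d; a
## whitespace-delimited fallback dialect (serial name resname chain resnum
## x y z) covers coordinate depositions that are not strict PDB.

## Scan raw lines for the first malformed ATOM/HETATM record; returns the
## line number or NA. Used to turn bio3d parse failures into actionable
## messages.
firstBadAtomLine <- function(lines) {
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  for (ln in which(is_atom)) {
    l <- lines[ln]
    if (nchar(l) < 54) return(ln)
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                         substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (any(is.na(xyz))) return(ln)
  }
  NA_integer_
}

## Parse the fallback whitespace dialect into the same per-atom table that
## the strict path produces. MODEL/ENDMDL split frames; TER/END ignored.
parseLoosePDB <- function(lines) {
  frames <- list()
  cur <- list()
  model_open <- FALSE
  push_frame <- function() {
    if (length(cur)) frames[[length(frames) + 1L]] <<- do.call(rbind, cur)
    cur <<- list()
  }
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (!nchar(l) || startsWith(l, "#") || startsWith(l, "REMARK")) next
    if (grepl("^MODEL", l)) { push_frame(); model_open <- TRUE; next }
    if (grepl("^(ENDMDL|TER|END)", l)) { push_frame(); next }
    tok <- strsplit(l, "\\s+")[[1L]]
    if (identical(tok[1L], "ATOM") || identical(tok[1L], "HETATM"))
      tok <- tok[-1L]
    if (length(tok) < 8L)
      stop(sprintf("unparseable coordinate line %d: '%s'", ln, lines[ln]))
    xyz <- suppressWarnings(as.numeric(tok[6:8]))
    serial <- suppressWarnings(as.integer(tok[1L]))
    resnum <- suppressWarnings(as.integer(tok[5L]))
    if (any(is.na(xyz)) || is.na(serial) || is.na(resnum))
      stop(sprintf("unparseable coordinate line %d: '%s'", ln, lines[ln]))
    cur[[length(cur) + 1L]] <- data.frame(
      serial = serial, atom = tok[2L], resname = tok[3L], chain = tok[4L],
      resnum = resnum, x = xyz[1L], y = xyz[2L], z = xyz[3L],
      element = substr(tok[2L], 1L, 1L), stringsAsFactors = FALSE)
  }
  push_frame()
  if (!length(frames)) stop("no coordinate records found")
  frames
}

atomsToFrame <- function(at, frame_id, source) {
  chains <- unique(at$chain)
  if (length(chains) > 2L)
    stop(sprintf("expected at most two chains, found %d (%s)",
                 length(chains), paste(chains, collapse = ", ")))
  built <- lapply(chains, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    ChainStructure(ch, a[, ATOM_COLS])
  })
  new("DimerStructure", chains = built, frame_id = as.integer(frame_id),
      source = source)
}

#' Read a (multi-model) PDB file into a StructureEnsemble
#'
#' Strict PDB records are parsed with \code{bio3d::read.pdb}; if the file is
#' not a parseable PDB, a whitespace-delimited dialect
#' (\code{serial name resname chain resnum x y z}) is tried. One frame is
#' produced per MODEL record (a single frame if there are none); chains are
#' split by chain identifier. Alternate locations other than blank/'A' are
#' dropped. Every residue must carry a C-alpha atom.
#'
#' @param path path to the structure file.
#' @param model_id,model_scope ensemble metadata applied to all frames.
#' @return a \linkS4class{StructureEnsemble}.
#' @export
readPDB <- function(path, model_id = 1L, model_scope = "full") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  strict <- any(grepl("^(ATOM|HETATM)", lines))
  frames_at <- NULL
  if (strict) {
    bad <- firstBadAtomLine(lines)
    if (!is.na(bad))
      stop(sprintf("unparseable ATOM record at line %d of %s", bad, path))
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    keep <- at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A"))
    nmodel <- nrow(pdb$xyz)
    frames_at <- lapply(seq_len(nmodel), function(k) {
      xyz <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
      lab <- at$segid
      lab <- ifelse(is.na(lab) | lab == "", at$chain, lab)
      lab <- ifelse(is.na(lab) | lab == "", "A", lab)
      data.frame(serial = at$eleno, atom = at$elety, resname = at$resid,
                 chain = lab, resnum = at$resno,
                 x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                 element = ifelse(is.na(at$elesy) | at$elesy == "",
                                  substr(at$elety, 1L, 1L), at$elesy),
                 stringsAsFactors = FALSE)[keep, , drop = FALSE]
    })
  } else {
    frames_at <- parseLoosePDB(lines)
  }
  frames <- lapply(seq_along(frames_at), function(k)
    atomsToFrame(frames_at[[k]], k, basename(path)))
  StructureEnsemble(frames,
                    model_id = rep(as.integer(model_id), length(frames)),
                    model_scope = rep(model_scope, length(frames)))
}

formatAtomName <- function(name) {
  if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

writeFrameLines <- function(frame, chain_ids) {
  out <- character()
  serial <- 0L
  for (k in seq_along(frame@chains)) {
    ch <- frame@chains[[k]]
    a <- ch@atoms
    for (r in seq_len(nrow(a))) {
      serial <- serial + 1L
      if (serial > 99999L) stop("atom serial exceeds PDB field width")
      if (a$resnum[r] > 9999L) stop("residue number exceeds PDB field width")
      xyz <- c(a$x[r], a$y[r], a$z[r])
      if (any(xyz > 9999.999 | xyz < -999.999))
        stop(sprintf("coordinate %.1f exceeds PDB fixed-width field",
                     xyz[which(xyz > 9999.999 | xyz < -999.999)][1L]))
      out <- c(out, sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s%2s",
        serial, formatAtomName(a$atom[r]), substr(a$resname[r], 1L, 3L),
        chain_ids[k], a$resnum[r], xyz[1L], xyz[2L], xyz[3L], 1, 0,
        substr(ch@label, 1L, 4L), substr(a$element[r], 1L, 2L)))
    }
    out <- c(out, "TER")
  }
  out
}

#' Write a StructureEnsemble as a standard PDB file
#'
#' Multi-frame ensembles are written as MODEL/ENDMDL blocks. Chain labels are
#' preserved in the segment-id field (columns 73-76) and one-letter chain ids
#' are assigned in order (A, B). Coordinates that do not fit the fixed-width
#' \code{\%8.3f} fields raise an error.
#'
#' @param ensemble a \linkS4class{StructureEnsemble} or single
#'   \linkS4class{DimerStructure}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePDB <- function(ensemble, path) {
  if (is(ensemble, "DimerStructure"))
    ensemble <- StructureEnsemble(list(ensemble))
  if (!length(ensemble@frames)) stop("ensemble is empty")
  chain_ids <- LETTERS[seq_along(ensemble@frames[[1L]]@chains)]
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(ensemble@frames) > 1L
  for (k in seq_along(ensemble@frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", k), con)
    writeLines(writeFrameLines(ensemble@frames[[k]], chain_ids), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Load a subdomain annotation table
#'
#' Reads a tab-separated table with header columns
#' \code{chain}/\code{subdomain}/\code{start}/\code{end} (1-based inclusive
#' residue bounds) and validates it: subdomain names must belong to the IF
#' vocabulary (E1, V1, H1, 1A, L1, 1B, L12, 2A, L2, 2B, H2, V2, E2) and
#' intervals on one chain must be ordered and non-overlapping.
#'
#' @param path path to the TSV file.
#' @return a \linkS4class{SubdomainAnnotation}.
#' @export
loadAnnotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain", "subdomain", "start", "end")
  if (!all(need %in% names(e)))
    stop("annotation table must have header columns chain/subdomain/start/end")
  e$start <- as.integer(e$start)
  e$end <- as.integer(e$end)
  e <- e[order(e$chain, e$start), , drop = FALSE]
  rownames(e) <- NULL
  new("SubdomainAnnotation", entries = e)
}

#' Default K1/K10 subdomain annotation
#'
#' The boundaries shipped with the package are a best reconstruction of the
#' published K1/K10 subdomain partition (rod boundaries anchored on the 1B
#' C-terminal truncation residues K1:328/K10:296, V1 = K1:61-153 and
#' K10:31-137, V2 = K1:498-607 and K10:461-558, H2 = K1:487-497 and
#' K10:453-460); users should edit the TSV for other constructs.
#'
#' @return a \linkS4class{SubdomainAnnotation}.
#' @export
defaultAnnotation <- function() {
  loadAnnotation(system.file("extdata", "k1_k10_subdomains.tsv",
                             package = "IFDimerTools", mustWork = TRUE))
}

#' Read chain sequences from FASTA
#'
#' @param path FASTA file; record ids become chain labels. Sequences are
#'   uppercased; characters outside the one-letter amino-acid alphabet are an
#'   error.
#' @return named character vector of one-letter sequences.
#' @export
readFastaChains <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop(sprintf("empty FASTA file: %s", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  ok <- "^[ACDEFGHIKLMNPQRSTVWYXBZJUO*-]*$"
  bad <- !grepl(ok, seqs)
  if (any(bad))
    stop(sprintf("record '%s' contains non-amino-acid characters",
                 names(seqs)[bad][1L]))
  if (any(!nchar(seqs))) stop("FASTA contains an empty sequence")
  seqs
}
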