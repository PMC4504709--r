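# Shared fixture builders. Everything is generated in code; no binary data.

# Canonical left-handed test coil at the IF-like geometry.
makeTestCoil <- function(r0 = 5, pitch = 170, handedness = "left",
                         n = 100L) {
  generateCrickCoil(crickParams(r0, pitch, handedness, n_residues = n))
}

# Rod + annotation + per-chain globules, with the rod renumbered so head
# residues fit below it.
makeAnnotatedRod <- function(n_rod = 120L, offset = 40L) {
  coil <- makeTestCoil(n = n_rod)
  rod <- DimerStructure(shiftResidueNumbers(coil@chains[[1L]], offset),
                        shiftResidueNumbers(coil@chains[[2L]], offset),
                        source = "rod")
  ann <- new("SubdomainAnnotation", entries = data.frame(
    chain = rep(c("K1", "K10"), each = 5L),
    subdomain = rep(c("E1", "V1", "1A", "L1", "1B"), 2L),
    start = rep(c(1L, 11L, offset + 1L, offset + 36L, offset + 47L), 2L),
    end = rep(c(10L, offset, offset + 35L, offset + 46L, offset + n_rod), 2L),
    stringsAsFactors = FALSE))
  list(rod = rod, annotation = ann)
}

# Apply one rigid-body transform (rotation matrix + translation) to a chain.
transformChain <- function(chain, rot, shift = c(0, 0, 0)) {
  a <- chain@atoms
  m <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  a$x <- m[, 1L] + shift[1L]
  a$y <- m[, 2L] + shift[2L]
  a$z <- m[, 3L] + shift[3L]
  ChainStructure(chain@label, a)
}

transformDimer <- function(dimer, rot, shift = c(0, 0, 0)) {
  new("DimerStructure",
      chains = lapply(dimer@chains, transformChain, rot = rot,
                      shift = shift),
      frame_id = dimer@frame_id, source = dimer@source)
}

# proper rotation (det +1) from a seeded QR decomposition
randomRotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Minimal residue with arbitrary named side-chain atoms, for typed-contact
# fixtures.
mkResidueAtoms <- function(resname, resnum, ca, side = list()) {
  df <- data.frame(serial = 1L, atom = "CA", resname = resname,
                   resnum = resnum, x = ca[1L], y = ca[2L], z = ca[3L],
                   element = "C", stringsAsFactors = FALSE)
  for (nm in names(side))
    df <- rbind(df, data.frame(serial = 1L, atom = nm, resname = resname,
                               resnum = resnum, x = side[[nm]][1L],
                               y = side[[nm]][2L], z = side[[nm]][3L],
                               element = substr(nm, 1L, 1L),
                               stringsAsFactors = FALSE))
  df
}

mkChain <- function(label, ...) {
  a <- rbind(...)
  a$serial <- seq_len(nrow(a))
  ChainStructure(label, a)
}

# Brute-force all-pairs contact oracle (independent of the production path).
bruteForceContacts <- function(frame, cutoff = 12, exclusion = 2L) {
  tabs <- lapply(frame@chains, function(ch) {
    ca <- caCoords(ch)
    data.frame(chain = ch@label, resnum = as.integer(rownames(ca)),
               x = ca[, 1L], y = ca[, 2L], z = ca[, 3L])
  })
  at <- do.call(rbind, tabs)
  hits <- list()
  for (a in seq_len(nrow(at) - 1L)) for (b in (a + 1L):nrow(at)) {
    if (at$chain[a] == at$chain[b] &&
        abs(at$resnum[a] - at$resnum[b]) <= exclusion) next
    d <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                (at$z[a] - at$z[b])^2)
    if (d < cutoff)
      hits[[length(hits) + 1L]] <- data.frame(
        chain_i = at$chain[a], res_i = at$resnum[a],
        chain_j = at$chain[b], res_j = at$resnum[b])
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(chain_i = character(), res_i = integer(),
               chain_j = character(), res_j = integer())
}
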