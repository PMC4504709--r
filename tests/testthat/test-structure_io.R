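test_that("strict PDB parsing: frames, chains, residues and robustness", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   1.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       7.500   2.000   0.500  1.00  0.00           C   ",
    "",
    "TER", "END", "")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  ens <- readPDB(f)
  expect_length(ens@frames, 1L)
  expect_length(ens@frames[[1L]]@chains, 1L)
  expect_identical(nResidues(ens@frames[[1L]]@chains[[1L]]), 3L)
  expect_equal(unname(caCoords(ens@frames[[1L]]@chains[[1L]])[2L, ]),
               c(4, 1, 0))
})

test_that("MODEL records split into frames", {
  line <- function(ser, res, x)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            ser, res, x, 0, 0)
  pdb <- c("MODEL        1", line(1L, 1L, 0), line(2L, 2L, 3.8), "ENDMDL",
           "MODEL        2", line(1L, 1L, 0.5), line(2L, 2L, 4.3), "ENDMDL",
           "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  ens <- readPDB(f)
  expect_length(ens@frames, 2L)
  expect_equal(caCoords(ens@frames[[2L]]@chains[[1L]])[1L, 1L], 0.5,
               ignore_attr = TRUE)
})

test_that("missing C-alpha and malformed records give targeted errors", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   GLY A   2       3.800   0.000   0.000  1.00  0.00           N",
    "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  expect_error(readPDB(f), "residue 2")

  bad <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       xxxxx   0.000   0.000  1.00  0.00           C")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(readPDB(f2), "line 2")
})

test_that("whitespace-delimited coordinate dialect is accepted", {
  txt <- c("# synthetic deposition dialect",
           "1 CA ALA K1 1 0.0 0.0 0.0",
           "2 CA GLY K1 2 3.8 0.0 0.0",
           "3 CA ALA K10 1 0.0 10.0 0.0",
           "4 CA GLY K10 2 3.8 10.0 0.0", "")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, f)
  ens <- readPDB(f)
  expect_length(ens@frames[[1L]]@chains, 2L)
  expect_identical(vapply(ens@frames[[1L]]@chains, chainLabel,
                          character(1L)), c("K1", "K10"))
})

test_that("PDB round trip preserves coordinates to field precision", {
  for (seed in 1:3) {
    coil <- generateCrickCoil(crickParams(4 + seed, 150, "left",
                                          n_residues = 20L))
    ens <- perturbEnsemble(coil, 2L, 0.5, seed)
    f <- withr::local_tempfile(fileext = ".pdb")
    writePDB(ens, f)
    back <- readPDB(f)
    expect_length(back@frames, 2L)
    for (k in 1:2) for (c in 1:2) {
      expect_lt(max(abs(caCoords(back@frames[[k]]@chains[[c]]) -
                          caCoords(ens@frames[[k]]@chains[[c]]))), 0.001)
    }
  }
  txt <- readLines(f)
  expect_identical(sum(grepl("^MODEL", txt)), 2L)
  expect_identical(sum(grepl("^ENDMDL", txt)), 2L)
})

test_that("coordinates exceeding PDB fixed-width fields are refused", {
  ch <- chainFromCA("A", matrix(c(0, 0, 0, 99999, 0, 0), 2L, byrow = TRUE))
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(writePDB(DimerStructure(ch), f), "fixed-width")
})

test_that("annotation loading validates names, order and overlap", {
  ok <- c("chain\tsubdomain\tstart\tend", "K1\t1B\t227\t327",
          "K1\t1A\t181\t215")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(ok, f)
  ann <- loadAnnotation(f)
  e <- annotationEntries(ann)
  expect_identical(e$subdomain, c("1A", "1B"))   # reordered by start
  expect_identical(subdomainRange(ann, "K1", "1A"),
                   c(start = 181L, end = 215L))

  overlap <- c("chain\tsubdomain\tstart\tend", "K1\t1A\t181\t215",
               "K1\t1B\t210\t327")
  writeLines(overlap, f)
  expect_error(loadAnnotation(f), "overlap")

  unknown <- c("chain\tsubdomain\tstart\tend", "K1\tZ9\t1\t10")
  writeLines(unknown, f)
  expect_error(loadAnnotation(f), "Z9")
})

test_that("shipped default annotation is valid and covers both chains", {
  ann <- defaultAnnotation()
  e <- annotationEntries(ann)
  expect_setequal(unique(e$chain), c("K1", "K10"))
  expect_identical(nrow(e), 26L)
  # the truncation construct ends at the 1B C-terminus
  expect_identical(unname(subdomainRange(ann, "K1", "1B")[2L]), 328L)
  expect_identical(unname(subdomainRange(ann, "K10", "1B")[2L]), 296L)
})

test_that("FASTA reading normalizes case and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">K1 type II", "mskv", ">K10 type I", "GGGF"), f)
  seqs <- readFastaChains(f)
  expect_length(seqs, 2L)
  expect_identical(unname(seqs["K1"]), "MSKV")

  writeLines(c(">bad", "AC1DE"), f)
  expect_error(readFastaChains(f), "non-amino-acid")

  writeLines(character(), f)
  expect_error(readFastaChains(f), "empty")
})
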