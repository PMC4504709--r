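## End-to-end orchestration: validated run configuration, the four analysis
## stages (geometry, domains, contacts, build) and machine-readable run
## reports. The same functions back the thin command-line wrapper shipped
## in inst/scripts/ifdimer.R.

#' Build and validate a run configuration
#'
#' Fails fast with actionable messages; no stage starts on an invalid
#' configuration.
#'
#' @param ensemble input \linkS4class{StructureEnsemble}, or path(s) to PDB
#'   file(s) to read; may be NULL for the build stage, which consumes no
#'   structures.
#' @param out_dir output directory (created if absent).
#' @param annotation \linkS4class{SubdomainAnnotation} or path to an
#'   annotation TSV; defaults to the shipped K1/K10 table.
#' @param contact_table contact-type table or TSV path.
#' @param ca_cutoff C-alpha contact cutoff (A).
#' @param psi_min parallel-strand threshold (degrees/residue).
#' @param category_band Category II half-width (A).
#' @param hinge_convention "interior" or "reflex".
#' @param weighting contact probability weighting, "per-model" or
#'   "per-frame".
#' @param seed integer seed for any stochastic stage.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(ensemble, out_dir, annotation = NULL,
                      contact_table = NULL, ca_cutoff = 12, psi_min = 0.5,
                      category_band = 10,
                      hinge_convention = c("interior", "reflex"),
                      weighting = c("per-model", "per-frame"), seed = 1L) {
  hinge_convention <- match.arg(hinge_convention)
  weighting <- match.arg(weighting)
  if (is.character(ensemble)) {
    missing <- ensemble[!file.exists(ensemble)]
    if (length(missing))
      stop(sprintf("ensemble input not found: %s", missing[1L]))
    ens <- NULL
    for (p in ensemble) {
      e <- readPDB(p)
      ens <- if (is.null(ens)) e else
        StructureEnsemble(c(ens@frames, e@frames),
                          c(ens@model_id, e@model_id + max(ens@model_id)),
                          c(ens@model_scope, e@model_scope))
    }
    ensemble <- ens
  }
  if (!is.null(ensemble)) {   # the build stage needs no structures
    if (!is(ensemble, "StructureEnsemble"))
      stop("ensemble must be a StructureEnsemble or PDB path(s)")
    if (!length(ensemble@frames)) stop("ensemble is empty")
  }
  if (is.null(annotation)) annotation <- defaultAnnotation()
  if (is.character(annotation)) annotation <- loadAnnotation(annotation)
  if (is.null(contact_table)) contact_table <- defaultContactTypeTable()
  if (is.character(contact_table))
    contact_table <- defaultContactTypeTable(contact_table)
  for (v in c(ca_cutoff = ca_cutoff, psi_min = psi_min,
              category_band = category_band))
    if (!is.finite(v) || v <= 0) stop("all thresholds must be positive")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  structure(list(ensemble = ensemble, annotation = annotation,
                 contact_table = contact_table, out_dir = out_dir,
                 ca_cutoff = ca_cutoff, psi_min = psi_min,
                 category_band = category_band,
                 hinge_convention = hinge_convention, weighting = weighting,
                 seed = as.integer(seed)), class = "RunConfig")
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

makeReport <- function(config, files, rows, warnings = character()) {
  rep <- structure(list(files = files, rows = rows, warnings = warnings),
                   class = "RunReport")
  jsonlite::write_json(list(files = files, rows = rows, warnings = warnings),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rep
}

chain1Label <- function(config) {
  chainLabel(config$ensemble@frames[[1L]]@chains[[1L]])
}

coilSubdomainsOf <- function(annotation, chain) {
  e <- annotationEntries(annotation, chain)
  e$subdomain[e$subdomain %in% c("1A", "1B", "2A", "2B")]
}

#' Run the coiled-coil geometry stage
#'
#' Computes per-residue coiled-coil profiles for every annotated rod
#' subdomain of every frame, per-subdomain means and per-frame hinge
#' angles between successive coiled-coil subdomains.
#'
#' @param config a \code{\link{runConfig}}.
#' @return a \code{RunReport} (files written: profile.tsv,
#'   subdomain_means.tsv, hinges.tsv, report.json).
#' @export
runGeometry <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$ensemble)) stop("this stage requires an ensemble input")
  ens <- config$ensemble
  lab1 <- chain1Label(config)
  frame1 <- ens@frames[[1L]]
  lab2 <- chainLabel(frame1@chains[[2L]])
  coils <- coilSubdomainsOf(config$annotation, lab1)
  if (!length(coils))
    stop("annotation covers no rod coiled-coil subdomain (1A/1B/2A/2B)")
  prof_rows <- list(); hinge_rows <- list()
  for (k in seq_along(ens@frames)) {
    fr <- ens@frames[[k]]
    axes <- list()
    for (sd in coils) {
      r1 <- subdomainRange(config$annotation, lab1, sd)
      r2 <- subdomainRange(config$annotation, lab2, sd)
      have1 <- range(as.integer(rownames(caCoords(fr@chains[[1L]]))))
      if (r1[1L] < have1[1L] || r1[2L] > have1[2L]) next
      p <- coiledCoilProfile(fr, r1, range_b = r2, psi_min = config$psi_min)
      tb <- profileTable(p)
      tb$frame <- k; tb$subdomain <- sd
      prof_rows[[length(prof_rows) + 1L]] <- tb
      axes[[sd]] <- computeMajorAxis(p, r1, sd)
    }
    if (length(axes) > 1L) {
      nm <- names(axes)
      for (q in seq_len(length(axes) - 1L)) {
        hinge_rows[[length(hinge_rows) + 1L]] <- data.frame(
          frame = k, pair = paste(nm[q], nm[q + 1L], sep = "-"),
          angle = computeHingeAngle(axes[[q]], axes[[q + 1L]],
                                    config$hinge_convention))
      }
    }
  }
  if (!length(prof_rows)) stop("no frame covered any rod subdomain")
  prof <- do.call(rbind, prof_rows)
  means <- do.call(rbind, lapply(split(prof, prof$subdomain), function(d)
    data.frame(subdomain = d$subdomain[1L], mean_R = mean(d$R, na.rm = TRUE),
               mean_pitch = mean(abs(d$lambda), na.rm = TRUE),
               frac_left = mean(d$handedness == "left"))))
  hinges <- if (length(hinge_rows)) do.call(rbind, hinge_rows) else
    data.frame(frame = integer(), pair = character(), angle = numeric())
  files <- c(profile = writeTSV(prof, file.path(config$out_dir, "profile.tsv")),
             means = writeTSV(means, file.path(config$out_dir,
                                               "subdomain_means.tsv")),
             hinges = writeTSV(hinges, file.path(config$out_dir,
                                                 "hinges.tsv")))
  makeReport(config, as.list(files),
             list(profile = nrow(prof), means = nrow(means),
                  hinges = nrow(hinges)))
}

#' Run the head/tail domain stage
#'
#' Globule positions (d, theta_r, category) for the annotated V1/V2
#' subdomains of each chain and frame, the occurrence histogram, and shape
#' metrics (Rg, end-to-end, principal extents in Angstrom and nm) of the
#' head and tail domains.
#'
#' @param config a \code{\link{runConfig}}.
#' @return a \code{RunReport} (files: positions.tsv, histogram.tsv,
#'   shape.tsv, report.json).
#' @export
runDomains <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$ensemble)) stop("this stage requires an ensemble input")
  ens <- config$ensemble
  ann <- config$annotation
  labs <- vapply(ens@frames[[1L]]@chains, chainLabel, character(1L))
  has_sub <- function(ch, sd)
    sd %in% annotationEntries(ann, ch)$subdomain
  if (!any(vapply(labs, has_sub, logical(1L), "V1")) &&
      !any(vapply(labs, has_sub, logical(1L), "V2")))
    stop("annotation covers no head/tail globular subdomain (V1/V2)")
  warnings <- character()
  pos_rows <- list(); shape_rows <- list()
  for (k in seq_along(ens@frames)) {
    fr <- ens@frames[[k]]
    for (lab in labs) {
      ch <- dimerChains(fr)[[lab]]
      if (is.null(ch)) next
      have <- range(ch@atoms$resnum)
      for (spec in list(list(sub = "V1", end = "head"),
                        list(sub = "V2", end = "tail"))) {
        if (!has_sub(lab, spec$sub)) next
        rng <- subdomainRange(ann, lab, spec$sub)
        if (rng[1L] < have[1L] || rng[2L] > have[2L]) {
          warnings <- c(warnings,
                        sprintf("frame %d: chain %s lacks %s residues (%s scope)",
                                k, lab, spec$sub, ens@model_scope[k]))
          next
        }
        gp <- globulePosition(fr, ann, lab, spec$sub, spec$end)
        pos_rows[[length(pos_rows) + 1L]] <- cbind(
          data.frame(frame = k), positionTable(list(gp),
                                               band = config$category_band))
      }
      ## shape metrics of the full head / tail stretches when present
      for (dom in list(list(name = "head", subs = c("E1", "V1", "H1"),
                            end = "head"),
                       list(name = "tail", subs = c("H2", "V2", "E2"),
                            end = "tail"))) {
        subs <- dom$subs[vapply(dom$subs, has_sub, logical(1L), ch = lab)]
        if (!length(subs)) next
        rngs <- vapply(subs, function(sd) subdomainRange(ann, lab, sd),
                       integer(2L))
        rng <- c(min(rngs), max(rngs))
        if (rng[1L] < have[1L] || rng[2L] > have[2L]) next
        a <- ch@atoms
        a <- a[a$resnum >= rng[1L] & a$resnum <= rng[2L], , drop = FALSE]
        sub_ch <- ChainStructure(lab, a)
        ext <- principalExtents(sub_ch)
        anchor <- rodAnchorFrame(fr, ann, dom$end)$anchor
        shape_rows[[length(shape_rows) + 1L]] <- data.frame(
          frame = k, chain = lab, domain = dom$name,
          rg = radiusOfGyration(sub_ch),
          end_to_end = endToEnd(sub_ch, dom$end, anchor),
          ext1 = ext[1L], ext2 = ext[2L], ext3 = ext[3L],
          ext1_nm = ext[1L] / 10, ext2_nm = ext[2L] / 10,
          ext3_nm = ext[3L] / 10)
      }
    }
  }
  if (!length(pos_rows)) stop("no globule position could be measured")
  pos <- do.call(rbind, pos_rows)
  hist <- positionHistogram(pos)
  shape <- if (length(shape_rows)) do.call(rbind, shape_rows) else
    data.frame()
  files <- c(positions = writeTSV(pos, file.path(config$out_dir,
                                                 "positions.tsv")),
             histogram = writeTSV(hist, file.path(config$out_dir,
                                                  "histogram.tsv")),
             shape = writeTSV(shape, file.path(config$out_dir, "shape.tsv")))
  makeReport(config, as.list(files),
             list(positions = nrow(pos), histogram = nrow(hist),
                  shape = nrow(shape)), warnings)
}

#' Run the contact stage
#'
#' C-alpha contact maps per frame, ensemble contact probabilities (written
#' as sparse triplets and per-chain-class files), the typed side-chain
#' census when side-chain atoms are present, and hydrogen-bond counts.
#'
#' @param config a \code{\link{runConfig}}.
#' @return a \code{RunReport} (files: contact_probability.tsv, per-class
#'   TSVs, census.tsv, hbonds.tsv, report.json).
#' @export
runContacts <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$ensemble)) stop("this stage requires an ensemble input")
  ens <- config$ensemble
  index <- globalIndexMap(ens)
  maps <- lapply(ens@frames, caContactMap, cutoff = config$ca_cutoff,
                 index = index)
  cpm <- aggregateContactProbability(maps, ens, config$weighting)
  files <- list()
  rows <- list()
  files$probability <- writeTSV(cpm@pairs,
                                file.path(config$out_dir,
                                          "contact_probability.tsv"))
  rows$probability <- nrow(cpm@pairs)
  dense <- contactMatrix(cpm, index)
  files$matrix <- file.path(config$out_dir, "contact_matrix.tsv")
  utils::write.table(dense, files$matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (cls in unique(cpm@pairs$class)) {
    safe <- gsub("[^A-Za-z0-9]", "_", cls)
    files[[paste0("class_", safe)]] <- writeTSV(
      cpm@pairs[cpm@pairs$class == cls, , drop = FALSE],
      file.path(config$out_dir, sprintf("contact_%s.tsv", safe)))
  }
  warnings <- character()
  has_side <- any(vapply(ens@frames[[1L]]@chains, function(ch)
    any(!ch@atoms$atom %in% BACKBONE_ATOMS), logical(1L)))
  if (has_side) {
    cen <- summarizeContacts(ens, config$contact_table)
    census <- cen$pair_probs
    files$census <- writeTSV(census, file.path(config$out_dir, "census.tsv"))
    rows$census <- nrow(census)
  } else {
    warnings <- c(warnings,
                  "no side-chain atoms present; typed census skipped")
  }
  hb <- do.call(rbind, lapply(seq_along(ens@frames), function(k) {
    counts <- countHbonds(ens@frames[[k]])$counts
    data.frame(frame = k, t(counts), check.names = FALSE)
  }))
  files$hbonds <- writeTSV(hb, file.path(config$out_dir, "hbonds.tsv"))
  rows$hbonds <- nrow(hb)
  makeReport(config, files, rows, warnings)
}

#' Run the model-building stage
#'
#' Writes the 25-configuration manifest, nine-residue hairpin-turn backbone
#' fragments for the head and tail base windows, and the truncation
#' restraint block.
#'
#' @param config a \code{\link{runConfig}} (only annotation and out_dir are
#'   used).
#' @return a \code{RunReport} (files: manifest.tsv, hairpin_head.pdb,
#'   hairpin_tail.pdb, restraint.txt, report.json).
#' @export
runBuild <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  manifest <- enumerateModels()
  files <- list(manifest = writeTSV(manifest,
                                    file.path(config$out_dir,
                                              "manifest.tsv")))
  dih <- hairpinDihedrals(9L)
  for (dom in c("head", "tail")) {
    turn <- chainFromDihedrals(rep("GLY", 9L), dih$phi, dih$psi, dih$omega,
                               label = paste0("T", substr(dom, 1L, 1L)))
    p <- file.path(config$out_dir, sprintf("hairpin_%s.pdb", dom))
    writePDB(DimerStructure(turn), p)
    files[[paste0("hairpin_", dom)]] <- p
  }
  files$restraint <- writeRestraintSpec(truncationSpec(),
                                        file.path(config$out_dir,
                                                  "restraint.txt"))
  makeReport(config, files, list(manifest = nrow(manifest)))
}

#' Materialize the standard synthetic fixture set
#'
#' Writes the reference synthetic structures (ideal Crick coil, isolated
#' alpha-helix, random globule, small jittered ensemble) as PDB files -
#' the same fixtures the test-suite builds in code.
#'
#' @param out_dir output directory.
#' @param seed integer seed for the stochastic fixtures.
#' @return invisibly, named vector of the written paths.
#' @export
writeFixtures <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    crick = file.path(out_dir, "crick_r05_p170_left.pdb"),
    helix = file.path(out_dir, "alpha_helix_50.pdb"),
    globule = file.path(out_dir, "globule_100_rg25.pdb"),
    jitter = file.path(out_dir, "jitter_ensemble.pdb"))
  coil <- generateCrickCoil(crickParams(r0 = 5, pitch = 170, "left",
                                        n_residues = 100L))
  writePDB(coil, paths["crick"])
  writePDB(DimerStructure(generateAlphaHelix(50L)), paths["helix"])
  writePDB(DimerStructure(generateGlobularChain(100L, 25, seed)),
           paths["globule"])
  writePDB(perturbEnsemble(coil, 5L, 0.3, seed + 1L), paths["jitter"])
  invisible(paths)
}
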