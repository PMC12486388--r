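# Synthetic desk-scale fixtures emulating every external input: toy chain
# structures written as valid PDB, evolutionary profile files in the real
# PSI-BLAST ASCII PSSM and HHsuite .hhm dialects, DSSP-like TSV records,
# and planted spatially coherent interface labels.  Everything is
# deterministic under a seed, and every generated file is consumed by the
# same production readers used for real data.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
             GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
             MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
             TYR = "Y", VAL = "V")

#' Synthetic dataset configuration
#'
#' Desk-scale study conditions for the synthetic fixtures: 40 proteins of
#' 20-35 residues, planted interface patches of 10 Angstrom radius, and a
#' feature signal strength of 0.8.
#'
#' @param n_proteins Number of proteins to generate.
#' @param residues_per_protein Length-2 range of residues per protein.
#' @param signal_strength Label-dependent feature offset scale in `[0, 1]`.
#' @param interface_patch_radius Patch radius in Angstroms (> 0).
#' @param seed Integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 40, residues_per_protein = c(20, 35),
                         signal_strength = 0.8, interface_patch_radius = 10,
                         seed = 1L) {
  stopifnot(interface_patch_radius > 0,
            signal_strength >= 0, signal_strength <= 1,
            length(residues_per_protein) == 2)
  structure(list(n_proteins = as.integer(n_proteins),
                 residues_per_protein = as.integer(residues_per_protein),
                 signal_strength = signal_strength,
                 interface_patch_radius = interface_patch_radius,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Self-avoiding random walk of C-alpha positions: consecutive spacing
# 3.8 +/- 0.1 Angstrom, non-consecutive separation >= 4 Angstrom.
.synth_ca_walk <- function(n, max_restarts = 25L) {
  for (attempt in seq_len(max_restarts)) {
    ca <- matrix(0, n, 3)
    ok <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        step <- stats::runif(1, 3.7, 3.9)
        cand <- ca[i - 1, ] + dir * step
        if (i > 2) {
          d2 <- rowSums(sweep(ca[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < 16) next  # 4 Angstrom exclusion
        }
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(ca)
  }
  stop("self-avoiding walk placement failed; try fewer residues")
}

.fmt_atom_name <- function(name) {
  # PDB columns 13-16: element-aligned for short names
  if (nchar(name) < 4) sprintf("%-4s", paste0(" ", name)) else substr(name, 1, 4)
}

.pdb_atom_line <- function(serial, name, res_name, chain, resno, xyz, b, element) {
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, .fmt_atom_name(name), "", res_name, chain, resno, "",
          xyz[1], xyz[2], xyz[3], 1.00, b, element)
}

#' Generate a synthetic protein chain
#'
#' Builds a toy single-chain structure: a self-avoiding random walk of
#' C-alpha positions with realistic consecutive spacing (3.8 +/- 0.1
#' Angstrom, non-consecutive separation >= 4 Angstrom), backbone N/C/O
#' atoms and 1-4 dummy side-chain atoms per residue placed near the
#' C-alpha (glycine gets none, exercising the pseudo-position fallback).
#' Optionally serialises the chain as a valid PDB file that
#' [parse_structure()] round-trips.
#'
#' @param n_residues Number of residues (>= 3).
#' @param seed Integer seed.
#' @param pdb_path Optional output PDB path.
#' @param chain_id Chain identifier (default `"A"`).
#' @return A `protein_structure` (coordinates rounded to the 0.001 Angstrom
#'   PDB precision), with the PDB text lines as attribute `"pdb_lines"`.
#' @export
synth_structure <- function(n_residues, seed = 1L, pdb_path = NULL, chain_id = "A") {
  stopifnot(n_residues >= 3)
  set.seed(seed)
  ca <- .synth_ca_walk(n_residues)
  res_names <- sample(.aa3, n_residues, replace = TRUE)

  atoms <- list()
  lines <- character(0)
  serial <- 0L
  backbone_off <- list(N = c(-1.2, 0.5, 0.3), CA = c(0, 0, 0),
                       C = c(1.2, 0.5, -0.3), O = c(1.9, 1.4, -0.3))
  for (i in seq_len(n_residues)) {
    sc_names <- names(.sidechain_nh[[res_names[i]]])
    sc_names <- utils::head(sc_names, 4L)
    b <- round(stats::runif(1, 5, 60), 2)
    for (nm in names(backbone_off)) {
      serial <- serial + 1L
      xyz <- round(ca[i, ] + backbone_off[[nm]], 3)
      el <- substr(nm, 1, 1)
      atoms[[length(atoms) + 1L]] <- list(res = i, name = nm, el = el, xyz = xyz, b = b)
      lines <- c(lines, .pdb_atom_line(serial, nm, res_names[i], chain_id, i, xyz, b, el))
    }
    for (nm in sc_names) {
      serial <- serial + 1L
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      xyz <- round(ca[i, ] + dir * stats::runif(1, 1.4, 2.6), 3)
      el <- substr(nm, 1, 1)
      atoms[[length(atoms) + 1L]] <- list(res = i, name = nm, el = el, xyz = xyz, b = b)
      lines <- c(lines, .pdb_atom_line(serial, nm, res_names[i], chain_id, i, xyz, b, el))
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(pdb_path)) writeLines(lines, pdb_path)

  backbone <- c("N", "CA", "C", "O", "OXT")
  at <- tibble::tibble(
    res_index = vapply(atoms, function(a) a$res, numeric(1)),
    atom = vapply(atoms, function(a) a$name, character(1)),
    element = vapply(atoms, function(a) a$el, character(1)),
    x = vapply(atoms, function(a) a$xyz[1], numeric(1)),
    y = vapply(atoms, function(a) a$xyz[2], numeric(1)),
    z = vapply(atoms, function(a) a$xyz[3], numeric(1)),
    b_factor = vapply(atoms, function(a) a$b, numeric(1)),
    is_sidechain = !vapply(atoms, function(a) a$name, character(1)) %in% backbone
  )
  st <- structure(
    list(id = if (is.null(pdb_path)) paste0("synth_", chain_id) else
           paste0(sub("\\.pdb$", "", basename(pdb_path)), "_", chain_id),
         chain_id = chain_id,
         residues = tibble::tibble(seq_index = seq_len(n_residues),
                                   resno = seq_len(n_residues),
                                   res_name = res_names),
         atoms = at),
    class = "protein_structure")
  attr(st, "pdb_lines") <- lines
  st
}

#' Write synthetic profile and secondary-structure files
#'
#' Emits a PSI-BLAST-dialect ASCII PSSM, an HHsuite-dialect `.hhm` and a
#' DSSP-like TSV for a structure, with values drawn from plausible ranges
#' (PSSM log-odds integers, hhm scores 0-9999 with occasional `*`, torsions
#' in (-180, 180], ASA within the residue maximum).  When `positive` labels
#' are given, the first 8 PSSM columns of positive residues are shifted by
#' `round(6 * signal_strength)` log-odds units — the planted, file-level
#' feature signal.
#'
#' @param structure A `protein_structure`.
#' @param seed Integer seed.
#' @param pssm_path,hhm_path,dssp_path Output paths.
#' @param positive Optional logical/0-1 vector of interface labels.
#' @param signal_strength Signal scale in `[0, 1]` (default 0).
#' @return Invisibly, a list of the three paths.
#' @export
synth_profiles <- function(structure, seed = 1L, pssm_path, hhm_path, dssp_path,
                           positive = NULL, signal_strength = 0) {
  set.seed(seed + 7L)
  n <- nrow(structure$residues)
  aa <- unname(.aa3to1[structure$residues$res_name])
  if (is.null(positive)) positive <- rep(FALSE, n)
  positive <- as.logical(positive)
  shift <- round(6 * signal_strength)

  # --- PSSM ---
  pssm <- matrix(sample(-8:8, n * 20, replace = TRUE), n, 20)
  pssm[positive, 1:8] <- pssm[positive, 1:8, drop = FALSE] + shift
  pct <- matrix(sample(0:100, n * 20, replace = TRUE), n, 20)
  hdr <- paste0("           ",
                paste(rep(sprintf("%3s", .aa1), 2), collapse = " "))
  rows <- vapply(seq_len(n), function(i) {
    paste0(sprintf("%5d %s  ", i, aa[i]),
           paste(sprintf("%3d", pssm[i, ]), collapse = " "), "  ",
           paste(sprintf("%3d", pct[i, ]), collapse = " "),
           sprintf("  %4.2f %8.2f", stats::runif(1, 0, 2), stats::runif(1, 0, 1)))
  }, character(1))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               hdr, rows, "", "                      K         Lambda"),
             pssm_path)

  # --- HHM ---
  hhm_aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  emit <- matrix(sample(0:9999, n * 20, replace = TRUE), n, 20)
  star <- matrix(stats::runif(n * 20) < 0.05, n, 20)
  em_lines <- character(0)
  for (i in seq_len(n)) {
    sc <- ifelse(star[i, ], "*", as.character(emit[i, ]))
    em_lines <- c(em_lines,
                  paste0(aa[i], " ", i, "\t", paste(sc, collapse = "\t"), "\t", i),
                  paste0("\t", paste(sample(0:3000, 10), collapse = "\t")))
  }
  writeLines(c("HHsearch 1.5",
               paste0("NAME  ", structure$id),
               paste0("LENG  ", n, " match states"),
               "FILT  none",
               paste0("NULL   ", paste(sample(2000:5000, 20), collapse = "\t")),
               paste0("HMM    ", paste(hhm_aa, collapse = "\t")),
               paste0("       ", paste(c("M->M", "M->I", "M->D", "I->M", "I->I",
                                         "D->M", "D->D", "Neff", "Neff_I", "Neff_D"),
                                       collapse = "\t")),
               em_lines, "//"),
             hhm_path)

  # --- DSSP-like TSV ---
  ss <- sample(c(.ss_states, "-"), n, replace = TRUE,
               prob = c(rep(0.115, 8), 0.08))
  phi <- round(stats::runif(n, -179.999, 180), 1)
  psi <- round(stats::runif(n, -179.999, 180), 1)
  phi[1] <- NA; psi[n] <- NA  # undefined at the termini
  asa <- round(stats::runif(n, 0, max_asa(structure$residues$res_name)), 1)
  utils::write.table(
    data.frame(res_index = seq_len(n), ss = ss, phi = phi, psi = psi, asa = asa),
    dssp_path, sep = "\t", row.names = FALSE, quote = FALSE)

  invisible(list(pssm = pssm_path, hhm = hhm_path, dssp = dssp_path))
}

# Geometry of the planted patch: pick a surface residue (among the most
# distant from the centroid) and label all residues within the radius.
.plant_patch <- function(coords, radius, seed) {
  set.seed(seed + 13L)
  r <- sqrt(rowSums(coords^2))
  top <- order(r, decreasing = TRUE)[seq_len(min(5L, length(r)))]
  centre <- top[sample.int(length(top), 1L)]
  d <- sqrt(rowSums(sweep(coords, 2, coords[centre, ])^2))
  list(centre = centre, labels = as.integer(d <= radius))
}

#' Plant spatially coherent interface labels on a graph
#'
#' Chooses a random surface residue as patch centre and labels every
#' residue within the patch radius as interface.  A label-dependent offset
#' (`signal_strength * 0.4`) is added to a fixed subset of 8 node-feature
#' columns (the first 8 PSSM columns) together with zero-mean Gaussian
#' noise, so both the geometry and the features carry the planted signal.
#'
#' @param graph A `protein_graph`.
#' @param config A `synth_config`.
#' @return The graph with `labels` set and boosted `node_features`.
#' @export
plant_labels <- function(graph, config = synth_config()) {
  patch <- .plant_patch(graph$coords, config$interface_patch_radius, config$seed)
  nf <- graph$node_features
  n <- nrow(nf)
  noise <- matrix(stats::rnorm(n * 8, sd = 0.03), n, 8)
  nf[, 1:8] <- nf[, 1:8] + config$signal_strength * 0.4 * patch$labels + noise
  graph$node_features <- nf
  graph$labels <- patch$labels
  graph
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `n_proteins` full samples (PDB, PSSM, hhm, DSSP TSV, 0/1 label
#' file) plus a manifest TSV consumable by [load_dataset()].  The interface
#' patch is planted geometrically from the pseudo-position graph and the
#' feature signal is baked into the written PSSM files, so production
#' readers see it.  Byte-deterministic for a fixed configuration seed.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest: `protein_id`, `pdb_path`, `pssm_path`,
#'   `hhm_path`, `dssp_path`, `label_path`, `n_residues`, `pos_frac`
#'   (paths relative to `dir`); also written to `dir/manifest.tsv`.
#' @export
make_dataset <- function(config = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  set.seed(config$seed)
  lens <- sample(seq(config$residues_per_protein[1], config$residues_per_protein[2]),
                 config$n_proteins, replace = TRUE)
  for (p in seq_len(config$n_proteins)) {
    pseed <- config$seed + 1000L * p
    id <- sprintf("synth%03d", p)
    paths <- file.path(dir, paste0(id, c(".pdb", ".pssm", ".hhm", ".dssp.tsv", ".labels.txt")))
    st <- synth_structure(lens[p], seed = pseed, pdb_path = paths[1])
    coords <- center_coordinates(pseudo_positions(st))
    patch <- .plant_patch(coords, config$interface_patch_radius, pseed)
    synth_profiles(st, seed = pseed, pssm_path = paths[2], hhm_path = paths[3],
                   dssp_path = paths[4], positive = patch$labels,
                   signal_strength = config$signal_strength)
    writeLines(as.character(patch$labels), paths[5])
    rows[[p]] <- tibble::tibble(
      protein_id = id,
      pdb_path = basename(paths[1]), pssm_path = basename(paths[2]),
      hhm_path = basename(paths[3]), dssp_path = basename(paths[4]),
      label_path = basename(paths[5]),
      n_residues = lens[p],
      pos_frac = round(mean(patch$labels), 4)
    )
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
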