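# Per-residue node feature blocks: PSSM (20), HMM (20), DSSP (14), AF (7),
# PPE (1); assembled column-wise into the 62-wide node feature matrix.

.ss_states <- c("H", "G", "I", "E", "B", "T", "S", "C")
.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the 20 log-odds columns of the standard PSI-BLAST ASCII PSSM
#' dialect (header lines, one row per sequence position with position index,
#' residue letter, 20 log-odds integers, then weighted-percentage and
#' statistics columns, and a free-form footer).
#'
#' @param path Path to the `.pssm` file.
#' @return Numeric `N_v` x 20 matrix of raw log-odds scores, with the
#'   sequence letters as attribute `"aa"`.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list(); aa <- character(0)
  in_table <- FALSE
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "") {
      if (in_table) break else next
    }
    # table rows start with an integer position then a residue letter
    if (grepl("^[0-9]+$", tok[1]) && length(tok) >= 2 && grepl("^[A-Za-z]$", tok[2])) {
      if (length(tok) < 22) {
        stop("malformed PSSM row at line ", ln, " of ", path,
             ": expected >= 22 fields, got ", length(tok))
      }
      vals <- suppressWarnings(as.numeric(tok[3:22]))
      if (any(is.na(vals))) stop("malformed PSSM row at line ", ln, " of ", path)
      rows[[length(rows) + 1L]] <- vals
      aa <- c(aa, toupper(tok[2]))
      in_table <- TRUE
    } else if (in_table) {
      break
    }
  }
  if (length(rows) == 0L) stop("no PSSM rows found in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- .aa1
  attr(m, "aa") <- aa
  m
}

#' Read an HHsuite .hhm profile
#'
#' Parses the match-state emission scores of an HHsuite `.hhm` file and
#' converts them to probabilities via `2^(-score/1000)`; the `*` marker
#' (minus infinity score) maps to 0.
#'
#' @param path Path to the `.hhm` file.
#' @return Numeric `N_v` x 20 matrix of emission probabilities.
#' @export
read_hhm <- function(path) {
  if (!file.exists(path)) stop("hhm file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hmm_at <- grep("^HMM\\s", lines)
  if (length(hmm_at) == 0L) stop("missing HMM header block in ", path)
  rows <- list(); aa <- character(0)
  for (ln in seq.int(hmm_at[1] + 1L, length(lines))) {
    line <- lines[ln]
    if (startsWith(line, "//")) break
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    # match-state emission lines: residue letter, position, 20 scores
    if (length(tok) >= 22 && grepl("^[A-Z]$", tok[1]) && grepl("^[0-9]+$", tok[2])) {
      sc <- tok[3:22]
      vals <- ifelse(sc == "*", 0, 2^(-suppressWarnings(as.numeric(sc)) / 1000))
      if (any(is.na(vals))) stop("malformed hhm emission row at line ", ln, " of ", path)
      rows[[length(rows) + 1L]] <- vals
      aa <- c(aa, tok[1])
    }
  }
  if (length(rows) == 0L) stop("no match states found in ", path)
  m <- do.call(rbind, rows)
  colnames(m) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  attr(m, "aa") <- aa
  m
}

#' Column min/max normalisation statistics
#'
#' @param matrices A matrix, or list of matrices with equal column counts
#'   (e.g. the training-set profiles), stacked row-wise.
#' @param provenance `"training-set"` or `"per-protein"`.
#' @return Object of class `norm_stats` with per-column `min` and `max`.
#' @export
compute_norm_stats <- function(matrices, provenance = "training-set") {
  if (is.matrix(matrices)) matrices <- list(matrices)
  m <- do.call(rbind, matrices)
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max),
                 provenance = provenance),
            class = "norm_stats")
}

#' Min-max normalise a matrix to [0, 1]
#'
#' Applies `(x - min) / (max - min)` per column using the supplied
#' statistics, clamping out-of-range values to `[0, 1]`.  Constant columns
#' (`max == min`) map to 0.
#'
#' @param m Numeric matrix.
#' @param stats A `norm_stats` object; defaults to per-protein statistics
#'   computed from `m` itself.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_normalize <- function(m, stats = NULL) {
  m <- as.matrix(m)
  if (is.null(stats)) stats <- compute_norm_stats(m, provenance = "per-protein")
  if (length(stats$min) != ncol(m)) stop("normalisation stats do not match matrix columns")
  rng <- stats$max - stats$min
  out <- sweep(m, 2L, stats$min)
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  pmin(pmax(out, 0), 1)  # matrix first so dims survive
}

#' Read DSSP-style secondary-structure records (TSV)
#'
#' Reads the tab-separated record format `res_index`, `ss`, `phi`, `psi`,
#' `asa` (one row per residue; `NA` torsions allowed at chain termini).
#'
#' @param path Path to the TSV file.
#' @return Tibble with those five columns.
#' @export
read_dssp_tsv <- function(path) {
  if (!file.exists(path)) stop("DSSP record file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("res_index", "ss", "phi", "psi", "asa")
  if (!all(need %in% names(df))) {
    stop("DSSP TSV must have columns ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(df[need])
}

#' 14-dimensional DSSP feature block
#'
#' Columns 1-9: one-hot secondary-structure state over H, G, I, E, B, T, S,
#' C plus a ninth unknown/missing class.  Columns 10-13: sine and cosine of
#' the backbone torsions phi and psi (degrees; undefined torsions map to
#' `(0, 0)`).  Column 14: relative solvent accessibility, ASA divided by the
#' residue type's maximum, clamped to `[0, 1]`.
#'
#' @param dssp Tibble/data.frame from [read_dssp_tsv()].
#' @param res_names Three-letter residue codes, one per row of `dssp`.
#' @return Numeric `N_v` x 14 matrix.
#' @export
dssp_features <- function(dssp, res_names) {
  n <- nrow(dssp)
  stopifnot(length(res_names) == n)
  ss <- toupper(ifelse(is.na(dssp$ss) | dssp$ss == "" | dssp$ss == "-", "?", dssp$ss))
  onehot <- matrix(0, n, 9L)
  idx <- match(ss, .ss_states)
  idx[is.na(idx)] <- 9L
  onehot[cbind(seq_len(n), idx)] <- 1
  trig <- function(deg) {
    rad <- deg * pi / 180
    cbind(ifelse(is.na(deg), 0, sin(rad)), ifelse(is.na(deg), 0, cos(rad)))
  }
  rsa <- pmin(1, pmax(0, dssp$asa / max_asa(res_names)))
  rsa[is.na(rsa)] <- 0
  out <- cbind(onehot, trig(dssp$phi), trig(dssp$psi), rsa)
  colnames(out) <- c(paste0("ss_", c(.ss_states, "X")),
                     "sin_phi", "cos_phi", "sin_psi", "cos_psi", "rsa")
  out
}

#' 7-dimensional atomic feature block
#'
#' Per residue, the mean over its heavy atoms of: atomic mass, B-factor,
#' side-chain flag, partial charge, bonded-hydrogen count, ring-membership
#' flag and van der Waals radius.  The latter five come from the shipped
#' per-residue-per-atom lookup table; atom names absent from it fall back to
#' element defaults (reported once per call).
#'
#' @param structure A `protein_structure`.
#' @return Numeric `N_v` x 7 matrix with columns `mass`, `b_factor`,
#'   `sidechain`, `charge`, `n_h`, `ring`, `vdw`.
#' @export
atomic_features <- function(structure) {
  a <- structure$atoms
  res <- structure$residues
  n <- nrow(res)
  out <- matrix(0, n, 7L)
  colnames(out) <- c("mass", "b_factor", "sidechain", "charge", "n_h", "ring", "vdw")
  unknown <- character(0)
  for (i in seq_len(n)) {
    sel <- which(a$res_index == i)
    attrs <- vapply(sel, function(k) {
      at <- atom_attributes(res$res_name[i], a$atom[k], a$element[k])
      if (!isTRUE(attr(at, "known"))) {
        unknown <<- c(unknown, paste0(res$res_name[i], ":", a$atom[k]))
      }
      at
    }, numeric(5))
    out[i, ] <- c(mean(attrs["mass", ]), mean(a$b_factor[sel]),
                  mean(a$is_sidechain[sel]), mean(attrs["charge", ]),
                  mean(attrs["n_h", ]), mean(attrs["ring", ]),
                  mean(attrs["vdw", ]))
  }
  if (length(unknown) > 0L) {
    message("atomic_features: element defaults used for ",
            paste(unique(unknown), collapse = ", "))
  }
  out
}

#' Pseudo-position embedding (PPE)
#'
#' Distance of each residue's centroid-centered pseudo-position from the
#' protein centroid, min-max rescaled to `[0, 1]` within the protein
#' (constant columns map to 0, so a single-residue chain gets 0).
#'
#' @param coords Centered `N_v` x 3 pseudo-positions.
#' @return Numeric `N_v` x 1 matrix.
#' @export
ppe_feature <- function(coords) {
  coords <- as.matrix(coords)
  r <- sqrt(rowSums(coords^2))
  minmax_normalize(matrix(r, ncol = 1L))
}

#' Assemble the 62-wide node feature matrix
#'
#' Concatenates the five feature blocks column-wise in the fixed order PSSM
#' (20), HMM (20), DSSP (14), AF (7), PPE (1).
#'
#' @param blocks Named list with elements `PSSM`, `HMM`, `DSSP`, `AF`,
#'   `PPE`, all with the same row count.
#' @return Numeric `N_v` x 62 matrix.
#' @export
assemble_node_features <- function(blocks) {
  order <- c("PSSM", "HMM", "DSSP", "AF", "PPE")
  widths <- c(PSSM = 20L, HMM = 20L, DSSP = 14L, AF = 7L, PPE = 1L)
  if (!all(order %in% names(blocks))) {
    stop("blocks must be named ", paste(order, collapse = ", "))
  }
  n <- nrow(blocks[[order[1]]])
  for (nm in order) {
    b <- as.matrix(blocks[[nm]])
    if (ncol(b) != widths[nm]) {
      stop("block ", nm, " has width ", ncol(b), ", expected ", widths[nm])
    }
    if (nrow(b) != n) {
      stop("block ", nm, " has ", nrow(b), " rows; expected ", n)
    }
  }
  out <- do.call(cbind, lapply(order, function(nm) unname(as.matrix(blocks[[nm]]))))
  colnames(out) <- unlist(lapply(order, function(nm) paste0(nm, "_", seq_len(widths[nm]))))
  out
}

#' Featurise one protein chain from its input files
#'
#' Full featurisation pipeline: parse the structure, read the profile and
#' secondary-structure files, normalise the evolutionary profiles, compute
#' the structural blocks and assemble the 62-wide node feature matrix.
#' Profile files with fewer rows than the chain has residues have the
#' missing rows imputed with the column mean (reported); extra rows are an
#' error.
#'
#' @param pdb_path,chain_id Structure input (see [parse_structure()]).
#' @param pssm_path,hhm_path,dssp_path Feature input files.
#' @param pssm_stats,hmm_stats Optional `norm_stats` (training-set
#'   statistics); default per-protein normalisation.
#' @return List with `structure` (a `protein_structure`) and `features`
#'   (`N_v` x 62 matrix).
#' @export
featurize_protein <- function(pdb_path, chain_id, pssm_path, hhm_path, dssp_path,
                              pssm_stats = NULL, hmm_stats = NULL) {
  structure <- parse_structure(pdb_path, chain_id)
  n <- nrow(structure$residues)
  align <- function(m, what) {
    if (nrow(m) > n) stop(what, " has ", nrow(m), " rows but chain has ", n, " residues")
    if (nrow(m) < n) {
      message("featurize_protein: imputing ", n - nrow(m), " missing ", what,
              " row(s) with column means")
      mu <- colMeans(m)
      m <- rbind(m, matrix(mu, n - nrow(m), ncol(m), byrow = TRUE))
    }
    m
  }
  pssm <- minmax_normalize(align(read_pssm(pssm_path), "PSSM"), pssm_stats)
  hmm <- minmax_normalize(align(read_hhm(hhm_path), "HMM"), hmm_stats)
  dssp <- read_dssp_tsv(dssp_path)
  if (nrow(dssp) != n) stop("DSSP records (", nrow(dssp), ") != residue count (", n, ")")
  coords <- center_coordinates(pseudo_positions(structure))
  blocks <- list(
    PSSM = pssm,
    HMM = hmm,
    DSSP = dssp_features(dssp, structure$residues$res_name),
    AF = atomic_features(structure),
    PPE = ppe_feature(coords)
  )
  list(structure = structure, features = assemble_node_features(blocks))
}
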