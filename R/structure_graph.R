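#' Parse a single protein chain from a PDB file
#'
#' Reads one chain out of a PDB file and returns an ordered residue/atom
#' representation suitable for graph construction.  Hydrogens are removed,
#' alternate locations are resolved to the highest-occupancy copy, only the
#' first model of multi-model files is used, and `HETATM` records are
#' ignored.  Residues left without any resolvable atom are skipped with a
#' warning.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain_id Single chain identifier (e.g. `"A"`).
#' @return An object of class `protein_structure`: a list with `id`,
#'   `residues` (tibble: `seq_index`, `resno`, `res_name`) and `atoms`
#'   (tibble: `res_index`, `atom`, `element`, `x`, `y`, `z`, `b_factor`,
#'   `is_sidechain`).
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' synth_structure(5, seed = 1, pdb_path = pdb)
#' parse_structure(pdb, "A")
parse_structure <- function(pdb_path, chain_id) {
  if (!file.exists(pdb_path)) stop("PDB file not found: ", pdb_path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(pdb_path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", pdb_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!chain_id %in% at$chain) {
    stop("chain not found: '", chain_id, "' in ", pdb_path, call. = FALSE)
  }
  at <- at[at$chain == chain_id, , drop = FALSE]

  # drop hydrogens (element H/D, or H-leading atom names when element absent)
  elem <- trimws(ifelse(is.na(at$elesy) | at$elesy == "", "", at$elesy))
  name_h <- grepl("^[0-9]*H", trimws(at$elety))
  is_h <- elem %in% c("H", "D") | (elem == "" & name_h)
  at <- at[!is_h, , drop = FALSE]

  # resolve altloc: keep the highest-occupancy copy of each (residue, atom name)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  if (any(alt != "")) {
    key <- paste(at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(occ[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  elem <- trimws(ifelse(is.na(at$elesy) | at$elesy == "", "", at$elesy))  # post-dedup

  rkey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert), sep = "|")
  rorder <- unique(rkey)
  if (length(rorder) == 0L) stop("no residues with resolvable atoms in chain ", chain_id)
  res_index <- match(rkey, rorder)

  first_of <- match(rorder, rkey)
  residues <- tibble::tibble(
    seq_index = seq_along(rorder),
    resno = at$resno[first_of],
    res_name = trimws(at$resid[first_of])
  )

  backbone <- c("N", "CA", "C", "O", "OXT")
  atoms <- tibble::tibble(
    res_index = res_index,
    atom = trimws(at$elety),
    element = ifelse(elem == "", substr(trimws(at$elety), 1, 1), elem),
    x = at$x, y = at$y, z = at$z,
    b_factor = ifelse(is.na(at$b), 0, at$b),
    is_sidechain = !(trimws(at$elety) %in% backbone)
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in ", pdb_path)
  }

  structure(
    list(id = paste0(sub("\\.pdb$", "", basename(pdb_path)), "_", chain_id),
         chain_id = chain_id, residues = residues, atoms = atoms),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$id, ": ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " heavy atoms\n", sep = "")
  invisible(x)
}

#' Side-chain-centroid pseudo-positions
#'
#' Each residue is represented by a single pseudo-position: the unweighted
#' mean of its side-chain atom coordinates.  Glycine (or any residue whose
#' side-chain atoms are unresolved) falls back to its C-alpha atom; if even
#' that is missing, the mean over all atoms of the residue is used.
#'
#' @param structure A `protein_structure`.
#' @return Numeric matrix, `N_v` x 3, in Angstroms.
#' @export
pseudo_positions <- function(structure) {
  a <- structure$atoms
  n <- nrow(structure$residues)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    sel <- a$res_index == i
    if (!any(sel)) stop("residue ", i, " has no atoms")
    sc <- sel & a$is_sidechain
    if (any(sc)) {
      out[i, ] <- c(mean(a$x[sc]), mean(a$y[sc]), mean(a$z[sc]))
    } else {
      ca <- sel & a$atom == "CA"
      use <- if (any(ca)) ca else sel
      out[i, ] <- c(mean(a$x[use]), mean(a$y[use]), mean(a$z[use]))
    }
  }
  out
}

#' Center coordinates at the protein centroid
#'
#' @param coords Numeric `N_v` x 3 matrix.
#' @return Matrix of the same shape whose column means are zero.
#' @export
center_coordinates <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 1L, ncol(coords) == 3L)
  sweep(coords, 2L, colMeans(coords))
}

#' Build the residue contact graph at a distance cutoff
#'
#' Creates an edge `(i, j)` whenever the Euclidean distance between the two
#' pseudo-positions is at most `cutoff`.  The edge set is symmetric and
#' includes self-edges `(i, i)`, so every node has at least one incident
#' edge and attention normalisation downstream is always well defined.
#'
#' @param coords Numeric `N_v` x 3 matrix of pseudo-positions.
#' @param cutoff Distance cutoff in Angstroms (default 14).
#' @return Integer matrix, `N_e` x 2, columns `i`, `j` (1-based), ordered by
#'   `i` then `j`.
#' @export
build_adjacency <- function(coords, cutoff = 14) {
  stopifnot(cutoff > 0)
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff
  idx <- which(adj, arr.ind = TRUE)
  edges <- cbind(i = idx[, 1], j = idx[, 2])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  edges
}

#' Two-dimensional spatial edge features
#'
#' For an edge `(i, j)` over centroid-centered coordinates, column 1 is the
#' Euclidean distance between the two nodes divided by the cutoff (so valid
#' edges lie in `[0, 1]`) and column 2 is the cosine of the angle between
#' the centered position vectors (the angle subtended at the protein
#' centroid).  A self-edge gets `(0, 1)`; a node lying exactly at the
#' centroid has its cosine defined as 0.
#'
#' @param coords Centered `N_v` x 3 coordinates.
#' @param edges Integer `N_e` x 2 edge list.
#' @param cutoff Distance cutoff used for normalisation (default 14).
#' @return Numeric `N_e` x 2 matrix (columns `dist`, `cos`).
#' @export
edge_features <- function(coords, edges, cutoff = 14) {
  coords <- as.matrix(coords)
  i <- edges[, 1]; j <- edges[, 2]
  di <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  dist <- sqrt(rowSums(di * di)) / cutoff
  ni <- sqrt(rowSums(coords^2))[i]
  nj <- sqrt(rowSums(coords^2))[j]
  dot <- rowSums(coords[i, , drop = FALSE] * coords[j, , drop = FALSE])
  cosv <- ifelse(ni * nj > 0, dot / (ni * nj), 0)
  cosv <- pmin(1, pmax(-1, cosv))
  self <- i == j
  dist[self] <- 0
  cosv[self] <- 1
  cbind(dist = dist, cos = cosv)
}

#' Assemble a protein graph
#'
#' Combines node features, centered pseudo-positions, the cutoff adjacency
#' and spatial edge features into a single `protein_graph` object, the input
#' to the prediction model.
#'
#' @param structure A `protein_structure`.
#' @param node_features `N_v` x 62 node feature matrix (see
#'   [assemble_node_features()]).
#' @param cutoff Distance cutoff in Angstroms (default 14).
#' @param labels Optional binary (0/1) per-residue interface labels.
#' @return An object of class `protein_graph`.
#' @export
build_protein_graph <- function(structure, node_features, cutoff = 14, labels = NULL) {
  node_features <- as.matrix(node_features)
  n <- nrow(structure$residues)
  if (nrow(node_features) != n) {
    stop("node feature rows (", nrow(node_features), ") != residue count (", n, ")")
  }
  if (any(!is.finite(node_features))) stop("non-finite node features")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("label length != residue count")
  }
  coords <- center_coordinates(pseudo_positions(structure))
  edges <- build_adjacency(coords, cutoff)
  efeat <- edge_features(coords, edges, cutoff)
  structure(
    list(id = structure$id,
         node_features = node_features,
         coords = coords,
         edges = edges,
         edge_features = efeat,
         labels = labels,
         residue_numbers = structure$residues$resno,
         cutoff = cutoff),
    class = "protein_graph"
  )
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("<protein_graph> ", x$id, ": ", nrow(x$node_features), " nodes (",
      ncol(x$node_features), " features), ", nrow(x$edges), " edges",
      if (!is.null(x$labels)) paste0(", ", sum(x$labels), " interface residues"),
      "\n", sep = "")
  invisible(x)
}

#' Serialise a protein graph to JSON
#'
#' Writes nodes, edges, features, coordinates and labels as plain JSON for
#' inspection or downstream tooling.
#'
#' @param graph A `protein_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  obj <- list(
    id = graph$id,
    n_nodes = nrow(graph$node_features),
    n_edges = nrow(graph$edges),
    cutoff = graph$cutoff,
    residue_numbers = graph$residue_numbers,
    node_features = unname(apply(graph$node_features, 1L, as.numeric, simplify = FALSE)),
    coords = unname(apply(graph$coords, 1L, as.numeric, simplify = FALSE)),
    edges = unname(apply(graph$edges, 1L, as.integer, simplify = FALSE)),
    edge_features = unname(apply(graph$edge_features, 1L, as.numeric, simplify = FALSE)),
    labels = graph$labels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
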