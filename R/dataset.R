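# Dataset loading: manifest TSV -> featurised, labelled protein graphs.

#' Load a dataset from a manifest
#'
#' Reads the manifest TSV (`protein_id`, `pdb_path`, `pssm_path`,
#' `hhm_path`, `dssp_path`, `label_path`; paths relative to the manifest
#' directory) and builds one labelled `protein_graph` per protein.
#' Profile normalisation uses dataset-level column min/max statistics
#' computed over all listed proteins (clamped at application), or
#' per-protein statistics when `norm = "per-protein"`.
#'
#' @param manifest_path Path to the manifest TSV (or a directory containing
#'   `manifest.tsv`).
#' @param chain_id Chain to extract from each PDB (default `"A"`).
#' @param cutoff Contact cutoff in Angstroms (default 14).
#' @param norm `"dataset"` or `"per-protein"`.
#' @param norm_stats Optional precomputed list with `pssm` and `hmm`
#'   `norm_stats` objects (e.g. training-set statistics applied at
#'   inference).
#' @return Named list of `protein_graph` objects with the normalisation
#'   statistics as attribute `"norm_stats"`.
#' @export
load_dataset <- function(manifest_path, chain_id = "A", cutoff = 14,
                         norm = c("dataset", "per-protein"), norm_stats = NULL) {
  norm <- match.arg(norm)
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.tsv")
  }
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  base <- dirname(manifest_path)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("protein_id", "pdb_path", "pssm_path", "hhm_path", "dssp_path", "label_path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))

  if (is.null(norm_stats) && norm == "dataset") {
    pssms <- lapply(resolve(man$pssm_path), read_pssm)
    hmms <- lapply(resolve(man$hhm_path), read_hhm)
    norm_stats <- list(pssm = compute_norm_stats(pssms),
                       hmm = compute_norm_stats(hmms))
  }

  graphs <- lapply(seq_len(nrow(man)), function(i) {
    fz <- featurize_protein(resolve(man$pdb_path[i]), chain_id,
                            resolve(man$pssm_path[i]), resolve(man$hhm_path[i]),
                            resolve(man$dssp_path[i]),
                            pssm_stats = norm_stats$pssm,
                            hmm_stats = norm_stats$hmm)
    labels <- as.integer(readLines(resolve(man$label_path[i]), warn = FALSE))
    g <- build_protein_graph(fz$structure, fz$features, cutoff = cutoff,
                             labels = labels)
    g$id <- man$protein_id[i]
    g
  })
  names(graphs) <- man$protein_id
  attr(graphs, "norm_stats") <- norm_stats
  graphs
}
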