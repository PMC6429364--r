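# Bundled reference tables for the cytoplasmic and axonemal MTBD systems:
# reported per-segment and per-residue contact totals, bound/free E-hook
# cluster RMSD matrices, and MM/GB binding-energy components. They serve as
# worked-example inputs for the aggregation, ranking, minima-flagging and
# binding-arithmetic operations.

#' Load a bundled reference table
#'
#' @param name one of `"segment_contacts"` (per-segment contact totals and
#'   reported percentages for both MTBDs in the bound state),
#'   `"residue_contacts"` (per-residue contact totals of the cytoplasmic
#'   MTBD with the B tail across offsets), `"crossstate_rmsd"` (bound/free
#'   E-hook cluster-representative RMSD matrices in long form, blocks
#'   `cyto_0`, `cyto_25`, `axo_0`, `axo_25`) or `"binding_components"`
#'   (MM/GB component energies and reported binding deltas).
#' @return A tibble.
#' @export
reference_table <- function(name = c("segment_contacts", "residue_contacts",
                                     "crossstate_rmsd",
                                     "binding_components")) {
  name <- match.arg(name)
  fname <- switch(name,
                  segment_contacts = "mtbd_segment_contacts.tsv",
                  residue_contacts = "mtbd_residue_contacts.tsv",
                  crossstate_rmsd = "ehook_crossstate_rmsd.tsv",
                  binding_components = "mmgb_binding_components.tsv")
  path <- system.file("extdata", fname, package = "mtassoc", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Cross-state RMSD matrix from the long-form reference table
#'
#' @param block one of `"cyto_0"`, `"cyto_25"`, `"axo_0"`, `"axo_25"`.
#' @return 5 x 5 numeric matrix (rows: free clusters, cols: bound clusters).
#' @export
reference_crossstate_block <- function(block) {
  tab <- reference_table("crossstate_rmsd")
  tab <- tab[tab$block == block, ]
  if (nrow(tab) == 0) abort(paste0("unknown block: ", block))
  M <- matrix(0, 5, 5)
  M[cbind(tab$free_cluster, tab$bound_cluster)] <- tab$rmsd
  rownames(M) <- paste0("free", 1:5)
  colnames(M) <- paste0("bound", 1:5)
  M
}
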