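# Pose placement: put a ligand into the protein frame by common-substructure
# transfer from a co-crystallised reference ligand, and merge protein +
# posed moiety into one tagged half-input structure.
# Pose provenance order: co-crystal > user-supplied pose > MCS transfer.

#' Transfer a ligand pose from a reference ligand
#'
#' Places `mobile_ligand` into the protein frame of `reference_ligand` by
#' rigid superposition over their maximum common substructure (heavy atoms).
#' Atoms outside the common scaffold are carried along by the same rigid
#' transform; hydrogens follow rigidly.
#'
#' @param mobile_ligand a `mol_structure` with any starting coordinates.
#' @param reference_ligand a `mol_structure` whose coordinates are already in
#'   the protein frame.
#' @param tag optional origin tag to stamp on the posed copy (`"WARHEAD"` or
#'   `"LE3"`).
#' @return the posed `mol_structure`; attributes `mapping` (the
#'   [mcs_mapping()] used) and `transform` (the [kabsch_fit()] result).
#' @export
transfer_pose <- function(mobile_ligand, reference_ligand, tag = NULL) {
  mp <- mcs_mapping(mobile_ligand, reference_ligand)
  if (nrow(mp) < 3) {
    stop("no usable common scaffold: maximum common substructure has ",
         nrow(mp), " atoms (need >= 3)")
  }
  tf <- kabsch_fit(coords(mobile_ligand)[mp$mobile, , drop = FALSE],
                   coords(reference_ligand)[mp$reference, , drop = FALSE])
  out <- apply_transform(mobile_ligand, tf)
  if (!is.null(tag)) out <- set_origin_tag(out, tag)
  attr(out, "mapping") <- mp
  attr(out, "transform") <- tf
  out
}

#' Merge a protein and a posed moiety into one half-input structure
#'
#' @param protein a `mol_structure` (receptor).
#' @param moiety a posed ligand (`mol_structure`) in the protein frame.
#' @param protein_tag `"POI"` or `"E3L"`.
#' @param moiety_tag `"WARHEAD"` or `"LE3"`.
#' @return a single tagged `mol_structure` (protein atoms first).
#' @details Errors if any moiety/protein heavy-atom pair is closer than the
#'   steric clash threshold (see [detect_clashes()]); the offending pairs are
#'   listed so the pose can be fixed upstream.
#' @export
make_half_input <- function(protein, moiety,
                            protein_tag = c("POI", "E3L"),
                            moiety_tag = c("WARHEAD", "LE3")) {
  protein_tag <- match.arg(protein_tag); moiety_tag <- match.arg(moiety_tag)
  protein <- set_origin_tag(protein, protein_tag)
  moiety <- set_origin_tag(moiety, moiety_tag)
  merged <- combine_structures(protein, moiety,
                               title = paste0(protein_tag, "-", moiety_tag))
  np <- n_atoms(protein)
  cl <- detect_clashes(merged)
  inter <- cl[(cl$atom_i <= np) != (cl$atom_j <= np), ]
  if (nrow(inter)) {
    stop("moiety pose clashes with the protein; offending pairs (protein ",
         "atom, moiety atom, distance A): ",
         paste(sprintf("(%d, %d, %.2f)",
                       pmin(inter$atom_i, inter$atom_j),
                       pmax(inter$atom_i, inter$atom_j) - np,
                       inter$distance), collapse = " "))
  }
  merged
}
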