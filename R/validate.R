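# Model-vs-reference validation: joint-protein backbone RMSD, degrader
# heavy-atom RMSD in the protein frame, and the crystal-like classification.

.backbone_names <- c("N", "CA", "C", "O")

# matched backbone coordinate pairs between two structures, by
# chain id + residue number + atom name
.backbone_match <- function(model, reference) {
  pick <- function(m) {
    a <- m$atoms
    k <- which(trimws(a$name) %in% .backbone_names & a$element != "H" &
                 !is.na(a$residue_number))
    tibble::tibble(idx = k, chain = a$chain_id[k],
                   resno = a$residue_number[k], name = trimws(a$name[k]))
  }
  am <- pick(model); ar <- pick(reference)
  j <- dplyr::inner_join(am, ar, by = c("chain", "resno", "name"),
                         suffix = c("_model", "_ref"))
  skipped <- nrow(am) + nrow(ar) - 2 * nrow(j)
  list(model_idx = j$idx_model, ref_idx = j$idx_ref, n_skipped = skipped)
}

#' Backbone RMSD between a model and a reference complex
#'
#' Backbone atoms (N, CA, C, O) of both proteins are matched by chain id,
#' residue number and atom name; one rigid superposition is computed jointly
#' over all matched atoms (both proteins together), and the RMSD after that
#' fit is returned. Unmatched residues are skipped and counted.
#'
#' @param model a `ternary_complex` or `mol_structure`.
#' @param reference a `mol_structure` (e.g. a crystal structure read with
#'   [read_pdb()]).
#' @return RMSD in Angstrom, with attributes `n_matched`, `n_skipped` and
#'   `transform` (the joint-fit [kabsch_fit()] mapping model onto
#'   reference).
#' @export
backbone_rmsd <- function(model, reference) {
  mm <- as_mol_structure(model); mr <- as_mol_structure(reference)
  bm <- .backbone_match(mm, mr)
  if (length(bm$model_idx) < 3) {
    stop("fewer than 3 matched backbone atoms between model and reference")
  }
  if (bm$n_skipped > 0) {
    message(bm$n_skipped, " unmatched backbone atom(s) skipped")
  }
  tf <- kabsch_fit(coords(mm)[bm$model_idx, , drop = FALSE],
                   coords(mr)[bm$ref_idx, , drop = FALSE])
  out <- tf$fit_rmsd
  attr(out, "n_matched") <- length(bm$model_idx)
  attr(out, "n_skipped") <- bm$n_skipped
  attr(out, "transform") <- tf
  out
}

#' Degrader heavy-atom RMSD in the protein frame
#'
#' The model's PROTAC heavy atoms are compared to a reference ligand after
#' applying the joint-protein superposition from [backbone_rmsd()] -- the
#' ligand is never re-fitted, so the value reflects placement error.
#' The atom correspondence is found by graph isomorphism on heavy atoms, and
#' the minimum RMSD over all automorphisms (e.g. flips of symmetric terminal
#' groups) is returned.
#'
#' @param model a `ternary_complex`.
#' @param reference_ligand a `mol_structure` of the reference degrader pose,
#'   graph-isomorphic to the model's PROTAC on heavy atoms.
#' @param transform a `rigid_transform` fixing the frame (typically
#'   `attr(backbone_rmsd(model, reference), "transform")`); identity when
#'   `NULL`.
#' @return RMSD in Angstrom; attribute `n_mappings` counts the
#'   automorphisms tried.
#' @export
protac_rmsd <- function(model, reference_ligand, transform = NULL) {
  stopifnot(inherits(model, "ternary_complex"))
  pro <- subset_structure(model$structure, protac_atoms(model))
  maps <- mol_isomorphisms(pro, reference_ligand, heavy_only = TRUE)
  if (!length(maps)) {
    stop("model PROTAC and reference ligand are not graph-isomorphic on ",
         "heavy atoms")
  }
  xm <- coords(pro)
  if (!is.null(transform)) xm <- apply_transform(xm, transform)
  xr <- coords(reference_ligand)
  hv <- which(is_heavy(pro))
  vals <- vapply(maps, function(mp) {
    rmsd(xm[hv, , drop = FALSE], xr[mp[hv], , drop = FALSE])
  }, numeric(1))
  out <- min(vals)
  attr(out, "n_mappings") <- length(maps)
  out
}

#' Crystal-like classification of a modeled complex
#'
#' A modeled ternary complex is called crystal-like when its protein RMSD
#' against the experimental structure is strictly below 10 Angstrom
#' (Drummond criterion).
#'
#' @param rmsd_value protein RMSD in Angstrom (non-negative).
#' @return logical.
#' @examples
#' classify_crystal_like(3.5)   # TRUE
#' classify_crystal_like(10.0)  # FALSE
#' @export
classify_crystal_like <- function(rmsd_value) {
  if (any(rmsd_value < 0)) stop("RMSD must be non-negative")
  rmsd_value < 10.0
}

#' Validate a model against a reference complex
#'
#' Convenience wrapper: joint-protein backbone RMSD, degrader RMSD in the
#' same frame, and the crystal-like call, as a one-row tibble.
#'
#' @param model a `ternary_complex`.
#' @param reference a reference complex (`mol_structure`).
#' @param reference_ligand reference degrader pose (`mol_structure`).
#' @return one-row tibble: `backbone_rmsd`, `protac_rmsd`, `crystal_like`,
#'   `n_matched_backbone`.
#' @export
validate_tc <- function(model, reference, reference_ligand) {
  br <- backbone_rmsd(model, reference)
  pr <- protac_rmsd(model, reference_ligand,
                    transform = attr(br, "transform"))
  tibble::tibble(backbone_rmsd = as.numeric(br),
                 protac_rmsd = as.numeric(pr),
                 crystal_like = classify_crystal_like(as.numeric(br)),
                 n_matched_backbone = attr(br, "n_matched"))
}
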