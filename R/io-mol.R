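# Small-molecule input: SDF (V2000) and SMILES, through ChemmineR/ChemmineOB.

.chemminer_ok <- function() {
  requireNamespace("ChemmineR", quietly = TRUE)
}

.sdf_to_mol <- function(sdf, title = "") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  chg_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  fc <- unname(code_map[as.character(chg_code)])
  fc[is.na(fc)] <- 0L
  bonds <- if (is.null(bb) || nrow(bb) == 0) NULL else
    tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  mol_structure(
    tibble::tibble(element = el, x = ab[, 1], y = ab[, 2],
                   z = if (ncol(ab) >= 3) ab[, 3] else 0,
                   formal_charge = fc),
    bonds, title = title)
}

#' Read molecules from an SDF (V2000) file
#'
#' @param path path to an SDF file.
#' @return a list of `mol_structure` objects (one per record).
#' @export
read_sdf <- function(path) {
  if (!.chemminer_ok()) stop("read_sdf requires the ChemmineR package")
  if (!file.exists(path)) stop("file not found: ", path)
  set <- ChemmineR::read.SDFset(path)
  lapply(seq_along(set), function(k) {
    sdf <- set[[k]]
    ttl <- tryCatch(ChemmineR::header(sdf)[["Molecule_Name"]],
                    error = function(e) "")
    .sdf_to_mol(sdf, title = ifelse(is.null(ttl) || is.na(ttl), "", ttl))
  })
}

#' Build a molecular graph from a SMILES string
#'
#' Converts through ChemmineOB. Coordinates are the generator's 2D layout
#' (use [build_linker_3d()] or pose placement to obtain 3D geometry);
#' hydrogens are implicit.
#'
#' @param smiles a single SMILES string.
#' @return a `mol_structure`.
#' @examples
#' \donttest{
#' pentane <- mol_from_smiles("CCCCC")
#' }
#' @export
mol_from_smiles <- function(smiles) {
  if (!.chemminer_ok()) stop("mol_from_smiles requires the ChemmineR package")
  stopifnot(is.character(smiles), length(smiles) == 1)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  .sdf_to_mol(sdf[[1]], title = smiles)
}
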