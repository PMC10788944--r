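# PROTAC fragment bookkeeping: cut the degrader at two user-specified
# acyclic single bonds into warhead / linker / E3-ligand fragments.

#' Decompose a PROTAC into warhead, linker and E3-ligand fragments
#'
#' Cuts the degrader's molecular graph at two user-specified single, acyclic
#' bonds. The component on the far side of `cut_bond_w` becomes the warhead,
#' the component on the far side of `cut_bond_e` becomes the E3 ligand
#' (L^E3), and the middle component is the linker. The severed atom pairs
#' are recorded as junctions; open valences are deliberately not capped, so
#' the attachment atoms keep their bonding role for reassembly.
#'
#' @param protac a `mol_structure`, or a SMILES string.
#' @param cut_bond_w length-2 integer vector `(warhead-side atom, linker-side
#'   atom)` of the warhead-linker bond (1-based atom indices).
#' @param cut_bond_e length-2 integer vector `(le3-side atom, linker-side
#'   atom)` of the L^E3-linker bond.
#' @return a `protac_decomposition`: list with `warhead`, `linker`, `le3`
#'   (`mol_structure` fragments), `junction_w` and `junction_e` (named
#'   integer vectors with the fragment-local attachment indices
#'   `c(moiety = ..., linker = ...)`), and `atom_map` (per-fragment original
#'   atom indices).
#' @examples
#' \donttest{
#' pent <- mol_from_smiles("CCCCC")
#' d <- decompose_protac(pent, c(1, 2), c(5, 4))
#' n_atoms(d$linker)  # 3
#' }
#' @export
decompose_protac <- function(protac, cut_bond_w, cut_bond_e) {
  if (is.character(protac)) protac <- mol_from_smiles(protac)
  stopifnot(inherits(protac, "mol_structure"),
            length(cut_bond_w) == 2, length(cut_bond_e) == 2)
  cut_bond_w <- as.integer(cut_bond_w); cut_bond_e <- as.integer(cut_bond_e)

  find_bond <- function(p) {
    k <- which((protac$bonds$i == min(p) & protac$bonds$j == max(p)))
    if (!length(k)) stop("no bond between atoms ", p[1], " and ", p[2])
    k
  }
  kw <- find_bond(cut_bond_w); ke <- find_bond(cut_bond_e)
  if (kw == ke) stop("the two cut bonds must be distinct")
  if (any(protac$bonds$order[c(kw, ke)] != 1L)) {
    stop("cut bonds must be single bonds")
  }
  rings <- ring_bonds(protac)
  if (kw %in% rings || ke %in% rings) stop("cut bond must be acyclic")

  cut <- mol_structure(protac$atoms, protac$bonds[-c(kw, ke), ],
                       title = protac$title)
  comps <- graph_components(cut)
  if (length(comps) != 3) {
    stop("removing the two cut bonds yields ", length(comps),
         " components, expected exactly 3")
  }
  in_comp <- function(atom) which(vapply(comps, function(cc) atom %in% cc, logical(1)))
  cw <- in_comp(cut_bond_w[1])   # warhead side
  ce <- in_comp(cut_bond_e[1])   # le3 side
  cl_w <- in_comp(cut_bond_w[2]); cl_e <- in_comp(cut_bond_e[2])
  if (cl_w != cl_e) stop("cut bonds do not share a middle (linker) component")
  if (cw == ce || cw == cl_w || ce == cl_w) {
    stop("cut-bond orientation inconsistent: warhead, linker and L^E3 sides ",
         "must be three distinct components")
  }
  frag <- function(comp_id, ttl) {
    idx <- sort(comps[[comp_id]])
    f <- subset_structure(cut, idx)
    f$title <- ttl
    attr(f, "orig_idx") <- idx
    f
  }
  warhead <- frag(cw, "warhead"); linker <- frag(cl_w, "linker"); le3 <- frag(ce, "le3")
  loc <- function(f, atom) match(atom, attr(f, "orig_idx"))
  out <- list(
    warhead = set_origin_tag(warhead, "WARHEAD"),
    linker = set_origin_tag(linker, "LINKER"),
    le3 = set_origin_tag(le3, "LE3"),
    junction_w = c(moiety = loc(warhead, cut_bond_w[1]),
                   linker = loc(linker, cut_bond_w[2])),
    junction_e = c(moiety = loc(le3, cut_bond_e[1]),
                   linker = loc(linker, cut_bond_e[2])),
    atom_map = list(warhead = attr(warhead, "orig_idx"),
                    linker = attr(linker, "orig_idx"),
                    le3 = attr(le3, "orig_idx"))
  )
  class(out) <- "protac_decomposition"
  out
}

#' @export
print.protac_decomposition <- function(x, ...) {
  cat("<protac_decomposition> warhead:", n_atoms(x$warhead),
      "atoms | linker:", n_atoms(x$linker),
      "atoms | L^E3:", n_atoms(x$le3), "atoms\n")
  invisible(x)
}

#' Reassemble a decomposition into one molecule
#'
#' Joins the three fragments across the two recorded junction bonds. Used to
#' verify that decomposition is lossless on the molecular graph.
#'
#' @param d a `protac_decomposition`.
#' @return a `mol_structure` with atoms ordered warhead, linker, le3.
#' @export
reassemble_protac <- function(d) {
  stopifnot(inherits(d, "protac_decomposition"))
  m <- combine_structures(combine_structures(d$warhead, d$linker), d$le3,
                          title = "reassembled protac")
  nw <- n_atoms(d$warhead); nl <- n_atoms(d$linker)
  m <- add_bond(m, d$junction_w[["moiety"]], nw + d$junction_w[["linker"]])
  m <- add_bond(m, nw + nl + d$junction_e[["moiety"]], nw + d$junction_e[["linker"]])
  m
}
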