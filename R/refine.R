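# Staged refinement of a merged ternary complex: clash-driven local
# minimization rounds -> PROTAC-only minimization -> unrestrained
# minimization, with an automated residual-clash quality check.

.clash_factor <- 0.7   # clash when d < factor * (vdW_i + vdW_j), heavy atoms

#' Detect steric clashes
#'
#' A clash is a non-bonded heavy-atom pair (1-2 and 1-3 neighbours excluded)
#' closer than `factor` times the sum of the two van der Waals radii.
#'
#' @param m a `mol_structure` (or half/ternary complex object).
#' @param factor clash threshold factor (default 0.7).
#' @return a tibble sorted by distance: `atom_i`, `atom_j`, `distance`,
#'   `threshold` (Angstrom), `inter_group` (`TRUE` when the two atoms carry
#'   different origin tags).
#' @examples
#' m <- mol_structure(data.frame(element = c("C", "C"), x = c(0, 5), y = 0, z = 0))
#' nrow(detect_clashes(m))  # 0
#' @export
detect_clashes <- function(m, factor = .clash_factor) {
  m <- as_mol_structure(m)
  empty <- tibble::tibble(atom_i = integer(), atom_j = integer(),
                          distance = numeric(), threshold = numeric(),
                          inter_group = logical())
  hv <- which(is_heavy(m))
  if (length(hv) < 2) return(empty)
  xyz <- coords(m)[hv, , drop = FALSE]
  rv <- element_param(m$atoms$element[hv], "rvdw")
  pr <- close_pairs(xyz, factor * 2 * max(rv))
  if (!nrow(pr)) return(empty)
  gi <- hv[pr[, 1]]; gj <- hv[pr[, 2]]
  excl <- .excluded_pairs(m)
  keep <- !(paste(gi, gj, sep = ":") %in% excl)
  gi <- gi[keep]; gj <- gj[keep]; pr <- pr[keep, , drop = FALSE]
  if (!nrow(pr)) return(empty)
  d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                       xyz[pr[, 2], , drop = FALSE])^2))
  thr <- factor * (rv[pr[, 1]] + rv[pr[, 2]])
  cl <- d < thr
  if (!any(cl)) return(empty)
  tags <- m$atoms$origin_tag
  out <- tibble::tibble(atom_i = gi[cl], atom_j = gj[cl], distance = d[cl],
                        threshold = thr[cl],
                        inter_group = !is.na(tags[gi[cl]]) &
                          !is.na(tags[gj[cl]]) &
                          tags[gi[cl]] != tags[gj[cl]])
  dplyr::arrange(out, .data$distance)
}

#' Local minimization rounds around detected clashes
#'
#' Atoms within `radius` of either member of any clash pair are free, all
#' other atoms are fixed; up to `max_rounds` minimization rounds run, each
#' followed by a fresh clash scan over the mobile set, stopping early once
#' the neighbourhood is clash-free. Atoms outside every clash neighbourhood
#' are bitwise unchanged.
#'
#' @param tc a `ternary_complex`.
#' @param clashes a clash table from [detect_clashes()] (non-empty).
#' @param radius neighbourhood radius in Angstrom (default 6).
#' @param config a [min_config()].
#' @param max_rounds maximum number of rounds (default 5).
#' @return the updated `ternary_complex`; attribute `stage_log` is a tibble
#'   of per-round start/end energies.
#' @export
refine_stage_local <- function(tc, clashes = detect_clashes(tc), radius = 6,
                               config = min_config(), max_rounds = 5) {
  stopifnot(inherits(tc, "ternary_complex"))
  if (!nrow(clashes)) {
    attr(tc, "stage_log") <- tibble::tibble(round = integer(),
                                            e_start = numeric(),
                                            e_end = numeric())
    return(tc)
  }
  log <- list()
  for (round in seq_len(max_rounds)) {
    if (!nrow(clashes)) break
    xyz <- coords(tc$structure)
    seeds <- unique(c(clashes$atom_i, clashes$atom_j))
    d2seed <- apply(xyz[seeds, , drop = FALSE], 1, function(p)
      sqrt(rowSums(sweep(xyz, 2, p)^2)))
    mobile <- which(apply(d2seed <= radius, 1, any))
    res <- minimize_structure(tc$structure, mobile = mobile, config = config)
    tc$structure <- res$structure
    log[[round]] <- tibble::tibble(round = round, e_start = res$e_start,
                                   e_end = res$e_end)
    cl_all <- detect_clashes(tc)
    clashes <- cl_all[cl_all$atom_i %in% mobile | cl_all$atom_j %in% mobile, ]
  }
  if (nrow(clashes)) {
    warning("local minimization left ", nrow(clashes),
            " clash(es) after ", max_rounds, " rounds; proceeding")
    attr(tc, "local_unresolved") <- nrow(clashes)
  }
  attr(tc, "stage_log") <- dplyr::bind_rows(log)
  tc
}

#' PROTAC-only minimization
#'
#' All PROTAC atoms (warhead, linker, L^E3) are free; every protein atom is
#' fixed and comes out bitwise unchanged.
#'
#' @param tc a `ternary_complex`.
#' @param config a [min_config()].
#' @return the updated `ternary_complex`; attributes `e_start`, `e_end`.
#' @export
refine_stage_protac <- function(tc, config = min_config()) {
  stopifnot(inherits(tc, "ternary_complex"))
  res <- minimize_structure(tc$structure, mobile = protac_atoms(tc),
                            config = config)
  tc$structure <- res$structure
  attr(tc, "e_start") <- res$e_start
  attr(tc, "e_end") <- res$e_end
  tc
}

#' Final unrestrained minimization and quality control
#'
#' All atoms are free. Reciprocal movement of the two proteins is permitted
#' and reported as `protein_displacement` (largest backbone-atom motion over
#' the stage). The residual-clash check runs independently of the minimizer
#' and sets `qc_pass`.
#'
#' @param tc a `ternary_complex`.
#' @param config a [min_config()].
#' @param stage_log optional tibble of earlier stage energies to prepend to
#'   the report.
#' @param pose_reference optional `ternary_complex` whose warhead/L^E3
#'   coordinates serve as the pre-refinement poses for the pose-retention
#'   metric.
#' @return list with `tc` (refined, `refined = TRUE`) and `report`, a
#'   `refinement_report`: `stage_energies` tibble, `clashes_before`,
#'   `clashes_after`, `qc_pass`, `protein_displacement`, `pose_rmsd_warhead`,
#'   `pose_rmsd_le3`.
#' @export
refine_stage_free <- function(tc, config = min_config(), stage_log = NULL,
                              pose_reference = NULL) {
  stopifnot(inherits(tc, "ternary_complex"))
  clashes_before <- nrow(detect_clashes(tc))
  xyz0 <- coords(tc$structure)
  res <- minimize_structure(tc$structure,
                            mobile = seq_len(n_atoms(tc$structure)),
                            config = config)
  tc$structure <- res$structure
  tc$refined <- TRUE
  prot <- sort(c(tc$poi_atoms, tc$e3l_atoms))
  disp <- if (length(prot))
    max(sqrt(rowSums((coords(tc$structure)[prot, , drop = FALSE] -
                        xyz0[prot, , drop = FALSE])^2))) else 0
  clashes_after_tbl <- detect_clashes(tc)
  pose_ref <- if (is.null(pose_reference)) NULL else pose_reference
  pose_rmsd <- function(idx_new, idx_old) {
    if (is.null(pose_ref) || !length(idx_new)) return(NA_real_)
    rmsd(coords(tc$structure)[idx_new, , drop = FALSE],
         coords(pose_ref$structure)[idx_old, , drop = FALSE])
  }
  stage_energies <- dplyr::bind_rows(
    stage_log,
    tibble::tibble(stage = "free", e_start = res$e_start, e_end = res$e_end))
  report <- structure(list(
    stage_energies = stage_energies,
    clashes_before = clashes_before,
    clashes_after = nrow(clashes_after_tbl),
    qc_pass = nrow(clashes_after_tbl) == 0,
    protein_displacement = disp,
    pose_rmsd_warhead = pose_rmsd(tc$warhead_atoms,
                                  if (is.null(pose_ref)) NULL else pose_ref$warhead_atoms),
    pose_rmsd_le3 = pose_rmsd(tc$le3_atoms,
                              if (is.null(pose_ref)) NULL else pose_ref$le3_atoms)
  ), class = "refinement_report")
  list(tc = tc, report = report)
}

#' @export
print.refinement_report <- function(x, ...) {
  cat("<refinement_report> qc_pass =", x$qc_pass,
      "| clashes", x$clashes_before, "->", x$clashes_after,
      sprintf("| protein displacement %.3f A\n", x$protein_displacement))
  print(x$stage_energies)
  invisible(x)
}

#' Run the full staged refinement
#'
#' Fixed stage order: clash-driven local rounds (skipped when the model is
#' already clash-free), PROTAC-only minimization, then unrestrained
#' minimization with quality control. Individual stages can be skipped for
#' ablation.
#'
#' @param tc a merged `ternary_complex`.
#' @param config a [min_config()].
#' @param skip_stages character subset of
#'   `c("local", "protac", "free")`.
#' @return list with `tc` and `report` (see [refine_stage_free()]).
#' @export
refine_tc <- function(tc, config = min_config(), skip_stages = character()) {
  stopifnot(inherits(tc, "ternary_complex"))
  pose_ref <- tc
  logs <- NULL
  if (!"local" %in% skip_stages) {
    cl <- detect_clashes(tc)
    if (nrow(cl)) {
      tc <- refine_stage_local(tc, cl, config = config)
      sl <- attr(tc, "stage_log")
      if (!is.null(sl) && nrow(sl)) {
        logs <- tibble::tibble(stage = paste0("local_", sl$round),
                               e_start = sl$e_start, e_end = sl$e_end)
      }
    }
  }
  if (!"protac" %in% skip_stages) {
    tc <- refine_stage_protac(tc, config = config)
    logs <- dplyr::bind_rows(logs,
                             tibble::tibble(stage = "protac",
                                            e_start = attr(tc, "e_start"),
                                            e_end = attr(tc, "e_end")))
  }
  if ("free" %in% skip_stages) {
    return(list(tc = tc,
                report = structure(list(stage_energies = logs,
                                        clashes_before = NA_integer_,
                                        clashes_after = nrow(detect_clashes(tc)),
                                        qc_pass = nrow(detect_clashes(tc)) == 0,
                                        protein_displacement = NA_real_,
                                        pose_rmsd_warhead = NA_real_,
                                        pose_rmsd_le3 = NA_real_),
                                   class = "refinement_report")))
  }
  refine_stage_free(tc, config = config, stage_log = logs,
                    pose_reference = pose_ref)
}
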