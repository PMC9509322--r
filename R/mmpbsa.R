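# MMPBSA post-processing: the PB/SASA solver is an external tool; this
# module consumes its component tables, aggregates total binding energies,
# determines the binding pocket from coordinates, and classifies hotspot /
# anti-hotspot residues across two ligand systems.

#' Total MMPBSA binding energy from its components
#'
#' `E_total = E_vdw + E_elec + E_polar + E_nonpolar`; the net nonbonded
#' interaction energy `E_int_net = E_vdw + E_elec` is reported alongside.
#' Component standard deviations, if given, are carried through unmodified
#' (no propagation: reproducing a total's SD requires per-frame data).
#'
#' @param e_vdw,e_elec,e_polar,e_nonpolar component energies, kJ/mol.
#' @param sd optional named numeric vector of component SDs.
#' @return List of class `energy_components` with the four components,
#'   `e_int_net`, `e_total`, and `sd`.
#' @examples
#' total_binding_energy(-142.27, -36.26, 108.47, -17.36)$e_total  # -87.42
#' @export
total_binding_energy <- function(e_vdw, e_elec, e_polar, e_nonpolar,
                                 sd = NULL) {
  comp <- c(e_vdw = e_vdw, e_elec = e_elec, e_polar = e_polar,
            e_nonpolar = e_nonpolar)
  if (length(comp) != 4L || any(!is.finite(comp)))
    stop("validation error: all four components must be single finite values")
  structure(
    c(as.list(comp),
      list(e_int_net = e_vdw + e_elec,
           e_total = e_vdw + e_elec + e_polar + e_nonpolar,
           sd = sd)),
    class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf("MMPBSA energies (kJ/mol): vdW %.2f, elec %.2f, polar %.2f, nonpolar %.2f\n",
              x$e_vdw, x$e_elec, x$e_polar, x$e_nonpolar))
  cat(sprintf("  net nonbonded %.2f; total binding energy %.2f\n",
              x$e_int_net, x$e_total))
  invisible(x)
}

#' Read a per-residue MMPBSA decomposition table
#'
#' Delimited text with columns `residue` (e.g. PHE168), `e_mm`, `e_polar`,
#' `e_nonpolar` and optionally `e_bind_res` (validated against the component
#' sum within `tol`, and computed when absent). Extra columns (e.g. a
#' `source` provenance marker) are preserved.
#'
#' @param path file to read (CSV).
#' @param tol componentwise rounding tolerance for the sum check, kJ/mol.
#' @return Data frame with one row per residue.
#' @export
read_residue_decomposition <- function(path, tol = 0.05) {
  d <- read_table_csv(path)
  need <- c("residue", "e_mm", "e_polar", "e_nonpolar")
  if (!all(need %in% names(d)))
    stop("decomposition table must have columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(d$residue))
    stop("duplicate residue ids in ", path)
  s <- d$e_mm + d$e_polar + d$e_nonpolar
  if ("e_bind_res" %in% names(d)) {
    bad <- abs(d$e_bind_res - s) > tol
    if (any(bad))
      stop("component sum mismatch (> ", tol, " kJ/mol) for residues: ",
           paste(d$residue[bad], collapse = ", "))
  } else d$e_bind_res <- s
  d
}

#' Binding-pocket residues within a distance cutoff of the ligand
#'
#' Receptor residues having at least one heavy atom within `cutoff`
#' (inclusive) of at least one ligand heavy atom. Hydrogens are ignored on
#' both sides; coordinates are taken as given (typically a crystal
#' structure).
#'
#' @param pdb a `bio3d` `pdb` object or path to a PDB file
#'   (read with [bio3d::read.pdb()]).
#' @param ligand_resname residue name of the ligand (exactly one ligand
#'   residue is expected in the structure).
#' @param cutoff distance cutoff in Angstrom (default 5.0, inclusive).
#' @return Character vector of residue ids as `RESNNN` (e.g. "PHE168"),
#'   sorted by residue number, with class `pocket_set`.
#' @export
pocket_residues <- function(pdb, ligand_resname, cutoff = 5.0) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb)
  stopifnot(inherits(pdb, "pdb"), cutoff > 0)
  at <- pdb$atom
  heavy <- !(toupper(at$elesy) %in% "H") & !grepl("^[0-9]*H", toupper(at$elety))
  lig <- at$resid == ligand_resname & heavy
  rec <- at$resid != ligand_resname & heavy & at$type %in% c("ATOM", "HETATM")
  if (!any(lig)) stop("validation error: no ligand atoms with residue name ",
                      ligand_resname)
  if (!all(is.finite(as.matrix(at[heavy, c("x", "y", "z")]))))
    stop("validation error: non-finite coordinates")
  lxyz <- as.matrix(at[lig, c("x", "y", "z")])
  rxyz <- as.matrix(at[rec, c("x", "y", "z")])
  # min distance from each receptor atom to any ligand atom
  d2min <- rep(Inf, nrow(rxyz))
  for (i in seq_len(nrow(lxyz))) {
    d2 <- (rxyz[, 1] - lxyz[i, 1])^2 + (rxyz[, 2] - lxyz[i, 2])^2 +
          (rxyz[, 3] - lxyz[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  hit <- d2min <= cutoff^2
  resno <- at$resno[rec][hit]
  resid <- at$resid[rec][hit]
  u <- !duplicated(resno)
  ord <- order(resno[u])
  structure(paste0(resid[u], resno[u])[ord], class = "pocket_set")
}

#' @export
print.pocket_set <- function(x, ...) {
  cat("Binding-pocket residues (", length(x), "):\n  ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# numeric residue number from ids like "PHE168"
.res_number <- function(ids) as.integer(sub("^[A-Za-z]+", "", ids))

#' Classify hotspot and anti-hotspot residues across two ligand systems
#'
#' A hotspot is a residue present in the binding pockets of both systems
#' whose per-residue binding-energy contribution is below
#' `favorable_threshold` (strictly) in both; an anti-hotspot is a common
#' pocket residue with a strictly positive contribution in both. Per-system
#' rankings list each pocket's favourable residues sorted most-favourable
#' first (ties broken by residue number).
#'
#' @param decomp_a,decomp_b per-residue decomposition data frames (see
#'   [read_residue_decomposition()]) for systems A and B.
#' @param pocket_a,pocket_b character vectors of pocket residue ids
#'   (e.g. from [pocket_residues()]).
#' @param favorable_threshold kJ/mol; default -1.00.
#' @return List with `hotspots`, `anti_hotspots` (character vectors sorted
#'   by residue number) and `rankings` (list of two data frames `a`, `b`).
#' @export
classify_hotspots <- function(decomp_a, pocket_a, decomp_b, pocket_b,
                              favorable_threshold = -1.00) {
  lookup <- function(decomp, pocket, tag) {
    missing <- setdiff(pocket, decomp$residue)
    if (length(missing) > 0)
      warning("pocket residues absent from decomposition table ", tag,
              " (excluded): ", paste(missing, collapse = ", "))
    keep <- intersect(pocket, decomp$residue)
    e <- decomp$e_bind_res[match(keep, decomp$residue)]
    names(e) <- keep
    e
  }
  ea <- lookup(decomp_a, pocket_a, "A")
  eb <- lookup(decomp_b, pocket_b, "B")
  common <- intersect(names(ea), names(eb))
  hot <- common[ea[common] < favorable_threshold &
                eb[common] < favorable_threshold]
  anti <- common[ea[common] > 0 & eb[common] > 0]
  rank1 <- function(e) {
    fav <- e[e < favorable_threshold]
    ord <- order(fav, .res_number(names(fav)))
    data.frame(residue = names(fav)[ord], e_bind_res = unname(fav[ord]))
  }
  list(hotspots = hot[order(.res_number(hot))],
       anti_hotspots = anti[order(.res_number(anti))],
       rankings = list(a = rank1(ea), b = rank1(eb)))
}
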