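# Geometric hydrogen-bond detection from heavy-atom positions.
#
# Hydrogens are absent from the models this package targets, so detection
# uses a heavy-atom proxy: a donor-acceptor pair is accepted when the D-A
# distance is within an ideal value plus a slop, and the antecedent-donor-
# acceptor angle is within an ideal minus a slop of linearity's side. The
# slops (0.400 A, 20 deg) follow the published protocol; the single ideal
# D-A distance (3.3 A) and heavy-atom antecedent angle (120 deg) are this
# package's explicit approximation to per-chemistry criteria.

#' Hydrogen-bond detection parameters
#'
#' @param ideal_da_distance Ideal donor-acceptor distance, Angstrom.
#' @param distance_slop Distance tolerance added to the ideal, Angstrom.
#' @param ideal_antecedent_angle Ideal antecedent-donor-acceptor angle,
#'   degrees.
#' @param angle_slop Angle tolerance subtracted from the ideal, degrees;
#'   accepted angles run from \code{ideal - slop} to 180.
#' @param water_bridge_max Maximum water-partner distance for mediated
#'   bonds; defaults to \code{ideal + slop}.
#' @param donor_plane_max For sp2 nucleobase donors, whose hydrogen lies in
#'   the base plane, the maximum elevation (degrees) of the acceptor above
#'   that plane; rejects stacking contacts that satisfy the distance and
#'   antecedent-angle tests but could not be reached by the in-plane
#'   hydrogen. Set to 90 to disable.
#' @return list of class \code{hbond_params}.
#' @export
hbond_params <- function(ideal_da_distance = 3.3, distance_slop = 0.400,
                         ideal_antecedent_angle = 120, angle_slop = 20,
                         water_bridge_max = NULL, donor_plane_max = 35) {
  stopifnot(ideal_da_distance > 0, distance_slop >= 0,
            ideal_antecedent_angle > 0, angle_slop >= 0,
            donor_plane_max > 0)
  if (is.null(water_bridge_max))
    water_bridge_max <- ideal_da_distance + distance_slop
  structure(list(ideal_da_distance = ideal_da_distance,
                 distance_slop = distance_slop,
                 ideal_antecedent_angle = ideal_antecedent_angle,
                 angle_slop = angle_slop,
                 water_bridge_max = water_bridge_max,
                 donor_plane_max = donor_plane_max),
            class = "hbond_params")
}

# Chemistry tables. Each entry: donors (named by antecedent atom), acceptors.
# Atoms that both donate and accept (ribose O2', Ser OG, water O) appear in
# both lists.
.NUC_BASE <- list(
  A = list(donors = c(N6 = "C6"),
           acceptors = c("N1", "N3", "N7")),
  C = list(donors = c(N4 = "C4"),
           acceptors = c("O2", "N3")),
  G = list(donors = c(N1 = "C2", N2 = "C2"),
           acceptors = c("O6", "N3", "N7")),
  U = list(donors = c(N3 = "C2"),
           acceptors = c("O2", "O4"))
)

.NUC_BACKBONE <- list(donors = c("O2'" = "C1'"),
                      acceptors = c("OP1", "OP2", "O2'", "O4'"))

.AA_SIDE <- list(
  ARG = list(donors = c(NE = "CZ", NH1 = "CZ", NH2 = "CZ"), acceptors = character()),
  LYS = list(donors = c(NZ = "CE"), acceptors = character()),
  ASN = list(donors = c(ND2 = "CG"), acceptors = "OD1"),
  GLN = list(donors = c(NE2 = "CD"), acceptors = "OE1"),
  SER = list(donors = c(OG = "CB"), acceptors = "OG"),
  THR = list(donors = c(OG1 = "CB"), acceptors = "OG1"),
  TYR = list(donors = c(OH = "CZ"), acceptors = "OH"),
  ASP = list(donors = c(), acceptors = c("OD1", "OD2")),
  GLU = list(donors = c(), acceptors = c("OE1", "OE2")),
  HIS = list(donors = c(ND1 = "CG", NE2 = "CD2"), acceptors = c("ND1", "NE2")),
  TRP = list(donors = c(NE1 = "CD1"), acceptors = character()),
  ALA = list(donors = c(), acceptors = character()),
  GLY = list(donors = c(), acceptors = character()),
  VAL = list(donors = c(), acceptors = character()),
  LEU = list(donors = c(), acceptors = character()),
  ILE = list(donors = c(), acceptors = character()),
  PRO = list(donors = c(), acceptors = character()),
  PHE = list(donors = c(), acceptors = character()),
  MET = list(donors = c(), acceptors = character()),
  CYS = list(donors = c(SG = "CB"), acceptors = "SG")
)
.AA_BACKBONE <- list(donors = c(N = "CA"), acceptors = c("O", "OXT"))
.AA_NAMES <- names(.AA_SIDE)

#' Donor and acceptor atoms of a residue
#'
#' Deterministic chemistry lookup for RNA nucleotides, the 20 amino acids,
#' water, and (generically) ligands: for unlisted residue types every O is
#' treated as both donor and acceptor and every N as a donor, a documented
#' approximation that keeps ligands such as NAD visible to the detector.
#' Waters are both donor and acceptor and carry no antecedent.
#'
#' @param resid Residue name (\code{A}/\code{C}/\code{G}/\code{U},
#'   three-letter amino acid, \code{HOH}, ligand codes).
#' @param atoms Character vector of atom names present in the residue.
#' @return list(donors = named character vector donor -> antecedent atom
#'   (\code{NA} if none), acceptors = character vector).
#' @export
donors_acceptors <- function(resid, atoms) {
  atoms <- .normalize_atom_name(atoms)
  pick <- function(donors, acceptors) {
    d <- donors[names(donors) %in% atoms]
    # antecedent must exist too, else angle test is skipped (NA)
    d[!(unname(d) %in% atoms)] <- NA_character_
    list(donors = d, acceptors = intersect(acceptors, atoms))
  }
  if (resid %in% names(.NUC_BASE)) {
    base <- .NUC_BASE[[resid]]
    d <- c(base$donors, .NUC_BACKBONE$donors)
    a <- c(base$acceptors, .NUC_BACKBONE$acceptors)
    return(pick(d, a))
  }
  if (resid %in% .AA_NAMES) {
    side <- .AA_SIDE[[resid]]
    d <- c(side$donors, .AA_BACKBONE$donors)
    a <- c(side$acceptors, .AA_BACKBONE$acceptors)
    return(pick(d, a))
  }
  if (resid == "HOH") {
    o <- intersect(c("O", "OW"), atoms)
    d <- stats::setNames(rep(NA_character_, length(o)), o)
    return(list(donors = d, acceptors = o))
  }
  # generic ligand fallback (NAD, spermine, ...): O both, N donor+acceptor
  o <- atoms[startsWith(atoms, "O")]
  n <- atoms[startsWith(atoms, "N")]
  d <- stats::setNames(rep(NA_character_, length(o) + length(n)), c(o, n))
  if (!length(o) && !length(n))
    warning("no hydrogen-bond chemistry for residue type '", resid, "'")
  list(donors = d, acceptors = c(o, n))
}

# internal: donor/acceptor inventory for a model selection as data.frames
.hb_inventory <- function(model, rows) {
  at <- model$atom[rows, , drop = FALSE]
  key <- paste(at$chain, at$resno, sep = "\r")
  don <- list(); acc <- list()
  for (k in unique(key)) {
    sub <- at[key == k, , drop = FALSE]
    da <- donors_acceptors(sub$resid[1], sub$atom)
    if (length(da$donors)) {
      idx <- match(names(da$donors), sub$atom)
      ante <- match(unname(da$donors), sub$atom)
      don[[k]] <- data.frame(row = rows[key == k][idx],
                             ante_row = ifelse(is.na(ante), NA_integer_,
                                               rows[key == k][ante]),
                             stringsAsFactors = FALSE)
    }
    if (length(da$acceptors)) {
      idx <- match(da$acceptors, sub$atom)
      acc[[k]] <- data.frame(row = rows[key == k][idx],
                             stringsAsFactors = FALSE)
    }
  }
  list(donors = do.call(rbind, don), acceptors = do.call(rbind, acc))
}

.addr_of <- function(at, i) sprintf("%s:%d:%s", at$chain[i], at$resno[i], at$atom[i])

#' Detect direct hydrogen bonds
#'
#' Scans all donor-acceptor pairs in a selection and keeps those whose
#' heavy-atom geometry satisfies the distance and angle criteria of
#' \code{params}. Intra-residue pairs are always excluded; backbone-backbone
#' contacts between sequence-adjacent nucleotides are excluded by default.
#' The result is sorted by chain, residue and atom, and is independent of
#' scan order.
#'
#' @param model \code{structure_model}.
#' @param selection Optional chain ids or residue data.frame
#'   (\code{chain}, \code{resno}) restricting the scan; default all atoms.
#' @param params \code{\link{hbond_params}}.
#' @param exclude_adjacent_backbone Drop backbone-backbone donor/acceptor
#'   pairs between residues i and i+1 of the same chain (default TRUE).
#' @param include_water Include waters as donors/acceptors (default FALSE;
#'   water-mediated bonds are reported by
#'   \code{\link{find_water_bridges}}).
#' @return data.frame, one row per bond: donor, acceptor (addresses),
#'   distance, angle (NA when the donor has no unique antecedent), kind.
#' @export
find_hbonds <- function(model, selection = NULL, params = hbond_params(),
                        exclude_adjacent_backbone = TRUE,
                        include_water = FALSE) {
  at <- model$atom
  rows <- .selection_rows(model, selection)
  if (!include_water) rows <- rows[at$resid[rows] != "HOH"]
  if (!length(rows)) stop("empty selection", call. = FALSE)
  inv <- .hb_inventory(model, rows)
  if (is.null(inv$donors) || is.null(inv$acceptors)) return(.empty_hbonds())
  D <- inv$donors; A <- inv$acceptors
  dmax <- params$ideal_da_distance + params$distance_slop
  amin <- params$ideal_antecedent_angle - params$angle_slop
  P <- as.matrix(at[D$row, c("x", "y", "z")])
  Q <- as.matrix(at[A$row, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * (P %*% t(Q))
  d2[d2 < 0] <- 0
  hit <- which(d2 <= dmax^2, arr.ind = TRUE)
  out <- list()
  backbone_atoms <- c("OP1", "OP2", "O2'", "O4'", "O3'", "O5'", "P")
  for (k in seq_len(nrow(hit))) {
    di <- D$row[hit[k, 1]]; ai <- A$row[hit[k, 2]]
    if (at$chain[di] == at$chain[ai] && at$resno[di] == at$resno[ai]) next
    if (at$atom[di] == at$atom[ai] && di == ai) next
    if (exclude_adjacent_backbone &&
        at$chain[di] == at$chain[ai] &&
        abs(at$resno[di] - at$resno[ai]) == 1L &&
        at$atom[di] %in% backbone_atoms && at$atom[ai] %in% backbone_atoms) next
    # sp2 base donors: the acceptor must be reachable by the in-plane H
    if (at$resid[di] %in% names(.NUC_BASE) &&
        !(at$atom[di] %in% .RNA_BACKBONE_ATOMS)) {
      ring <- which(at$chain == at$chain[di] & at$resno == at$resno[di] &
                      !(at$atom %in% .RNA_BACKBONE_ATOMS))
      if (length(ring) >= 3L) {
        nrm <- .base_plane_normal(as.matrix(at[ring, c("x", "y", "z")]))
        v <- c(at$x[ai] - at$x[di], at$y[ai] - at$y[di], at$z[ai] - at$z[di])
        elev <- asin(min(1, abs(sum(v * nrm)) / sqrt(sum(v^2)))) * 180 / pi
        if (elev > params$donor_plane_max) next
      }
    }
    ang <- NA_real_
    ante <- D$ante_row[hit[k, 1]]
    if (!is.na(ante)) {
      v1 <- c(at$x[ante] - at$x[di], at$y[ante] - at$y[di], at$z[ante] - at$z[di])
      v2 <- c(at$x[ai] - at$x[di], at$y[ai] - at$y[di], at$z[ai] - at$z[di])
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < amin) next
    }
    out[[length(out) + 1L]] <- data.frame(
      donor = .addr_of(at, di), acceptor = .addr_of(at, ai),
      distance = sqrt(d2[hit[k, 1], hit[k, 2]]), angle = ang,
      kind = "direct", water = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_hbonds())
  res <- do.call(rbind, out)
  res <- res[!duplicated(paste(res$donor, res$acceptor)), , drop = FALSE]
  res[order(res$donor, res$acceptor), , drop = FALSE]
}

.empty_hbonds <- function() {
  data.frame(donor = character(), acceptor = character(),
             distance = numeric(), angle = numeric(), kind = character(),
             water = character(), stringsAsFactors = FALSE)
}

.selection_rows <- function(model, selection) {
  at <- model$atom
  if (is.null(selection)) return(seq_len(nrow(at)))
  if (is.data.frame(selection)) {
    key <- paste(at$chain, at$resno, sep = "\r")
    return(which(key %in% paste(selection$chain, selection$resno, sep = "\r")))
  }
  which(at$chain %in% selection)
}

#' Detect water-mediated hydrogen bonds
#'
#' Reports pairs (X, Y) of non-water atoms in different residues such that a
#' single water oxygen is hydrogen-bonded (distance criterion; waters skip
#' the angle test) to both X and Y.
#'
#' @inheritParams find_hbonds
#' @return data.frame as \code{\link{find_hbonds}} with kind
#'   \code{"water_mediated"} and the bridging water address in \code{water}.
#' @export
find_water_bridges <- function(model, selection = NULL,
                               params = hbond_params()) {
  at <- model$atom
  wat <- which(at$resid == "HOH" & at$atom %in% c("O", "OW"))
  if (!length(wat)) return(.empty_hbonds())
  rows <- .selection_rows(model, selection)
  rows <- rows[at$resid[rows] != "HOH"]
  inv <- .hb_inventory(model, rows)
  polar <- unique(c(if (!is.null(inv$donors)) inv$donors$row,
                    if (!is.null(inv$acceptors)) inv$acceptors$row))
  if (!length(polar)) return(.empty_hbonds())
  dmax <- params$water_bridge_max
  W <- as.matrix(at[wat, c("x", "y", "z"), drop = FALSE])
  P <- as.matrix(at[polar, c("x", "y", "z"), drop = FALSE])
  d2 <- outer(rowSums(W^2), rowSums(P^2), "+") - 2 * (W %*% t(P))
  d2[d2 < 0] <- 0
  out <- list()
  for (wi in seq_along(wat)) {
    near <- which(d2[wi, ] <= dmax^2)
    if (length(near) < 2L) next
    for (a in seq_along(near)) for (b in seq_along(near)) {
      if (a >= b) next
      i <- polar[near[a]]; j <- polar[near[b]]
      if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) next
      out[[length(out) + 1L]] <- data.frame(
        donor = .addr_of(at, i), acceptor = .addr_of(at, j),
        distance = sqrt(d2[wi, near[a]]) + sqrt(d2[wi, near[b]]),
        angle = NA_real_, kind = "water_mediated",
        water = .addr_of(at, wat[wi]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_hbonds())
  res <- do.call(rbind, out)
  res[order(res$donor, res$acceptor), , drop = FALSE]
}

# Base-mediated subset helper: bonds where either end is a base atom (not
# sugar/phosphate) of an RNA residue.
.RNA_BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                         "C3'", "O3'", "C2'", "O2'", "C1'")

#' Is an atom address a nucleobase atom?
#' @param model \code{structure_model}.
#' @param addr Atom address.
#' @return TRUE when the atom belongs to an RNA residue and is not a
#'   sugar/phosphate atom.
#' @export
is_base_atom <- function(model, addr) {
  a <- parse_address(addr)
  i <- .atom_row(model, addr)
  model$atom$resid[i] %in% names(.NUC_BASE) &&
    !(model$atom$atom[i] %in% .RNA_BACKBONE_ATOMS)
}
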