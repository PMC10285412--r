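# Synthetic structures with known ground truth.
#
# Ideal A-form duplexes (rise ~2.8 A, twist ~32.7 deg/bp) are assembled
# from idealized planar nucleobase templates; Watson-Crick and wobble
# pairs present canonical hydrogen-bond distances (2.8-3.0 A), planted
# mismatches displace the edges beyond the detection cutoff. Bridging
# waters are placed analytically, probe peptides at controlled minimum
# gaps. Only the designated hydrogen-bond distances are guaranteed, not
# full stereochemical realism: fixtures exercise detection logic, not
# force fields. Generation is seed-deterministic.

.RING_SIDE <- 1.39
.EXO_O <- 1.23
.EXO_N <- 1.34
.GLYCO <- 1.47

.hex <- function(names, angles_deg) {
  a <- angles_deg * pi / 180
  data.frame(atom = names, x = .RING_SIDE * cos(a), y = .RING_SIDE * sin(a),
             stringsAsFactors = FALSE)
}

.exo <- function(tpl, parent, name, reach) {
  p <- tpl[tpl$atom == parent, ]
  r <- sqrt(p$x^2 + p$y^2)
  rbind(tpl, data.frame(atom = name, x = p$x * (r + reach) / r,
                        y = p$y * (r + reach) / r, stringsAsFactors = FALSE))
}

# planar base template, Watson-Crick edge facing +x, 2D coords in A
.base_template <- function(base) {
  if (base %in% c("C", "U")) {
    tpl <- .hex(c("N1", "C2", "N3", "C4", "C5", "C6"),
                c(240, 300, 0, 60, 120, 180))
    tpl <- .exo(tpl, "C2", "O2", .EXO_O)
    tpl <- if (base == "C") .exo(tpl, "C4", "N4", .EXO_N)
           else .exo(tpl, "C4", "O4", .EXO_O)
    tpl <- .exo(tpl, "N1", "C1'", .GLYCO)
  } else {
    tpl <- .hex(c("N1", "C2", "N3", "C4", "C5", "C6"),
                c(0, 300, 240, 180, 120, 60))
    tpl <- if (base == "G") .exo(tpl, "C6", "O6", .EXO_O)
           else .exo(tpl, "C6", "N6", .EXO_N)
    if (base == "G") tpl <- .exo(tpl, "C2", "N2", .EXO_N)
    # fused five-membered ring on the C4-C5 edge
    c4 <- as.numeric(tpl[tpl$atom == "C4", c("x", "y")])
    c5 <- as.numeric(tpl[tpl$atom == "C5", c("x", "y")])
    m <- (c4 + c5) / 2
    u <- m / sqrt(sum(m^2))
    apothem <- .RING_SIDE / (2 * tan(pi / 5))
    r5 <- .RING_SIDE / (2 * sin(pi / 5))
    ctr <- m + apothem * u
    ang5 <- atan2(c5[2] - ctr[2], c5[1] - ctr[1])
    ang4 <- atan2(c4[2] - ctr[2], c4[1] - ctr[1])
    step <- (ang4 - ang5) %% (2 * pi)
    if (step > pi) step <- step - 2 * pi     # signed 72-degree step C5 -> C4
    step <- -sign(step) * 2 * pi / 5         # walk the long way: C5->N7->C8->N9->C4
    ring5 <- c("N7", "C8", "N9")
    for (k in 1:3) {
      a <- ang5 + k * step
      tpl <- rbind(tpl, data.frame(atom = ring5[k],
                                   x = ctr[1] + r5 * cos(a),
                                   y = ctr[2] + r5 * sin(a),
                                   stringsAsFactors = FALSE))
    }
    n9 <- as.numeric(tpl[tpl$atom == "N9", c("x", "y")])
    d <- n9 - ctr; d <- d / sqrt(sum(d^2))
    tpl <- rbind(tpl, data.frame(atom = "C1'", x = n9[1] + .GLYCO * d[1],
                                 y = n9[2] + .GLYCO * d[2],
                                 stringsAsFactors = FALSE))
  }
  tpl$element <- substr(tpl$atom, 1, 1)
  tpl
}

# hydrogen-bond anchor atoms per pair geometry (left base edge -> right)
.pair_anchors <- function(bl, br, type) {
  wc <- list("G:C" = list(L = c("O6", "N1", "N2"), R = c("N4", "N3", "O2"),
                          d = c(2.91, 2.95, 2.86)),
             "A:U" = list(L = c("N6", "N1"), R = c("O4", "N3"),
                          d = c(2.95, 2.82)))
  wob <- list("G:U" = list(L = c("O6", "N1"), R = c("N3", "O2"),
                           d = c(2.83, 2.79)))
  key <- paste(bl, br, sep = ":"); rkey <- paste(br, bl, sep = ":")
  if (type == "WC") {
    if (key %in% names(wc)) return(c(wc[[key]], flip = FALSE))
    if (rkey %in% names(wc)) {
      a <- wc[[rkey]]
      return(list(L = a$R, R = a$L, d = a$d, flip = TRUE))
    }
    stop(sprintf("pair type WC inconsistent with bases %s-%s", bl, br),
         call. = FALSE)
  }
  if (type == "wobble") {
    if (key %in% names(wob)) return(c(wob[[key]], flip = FALSE))
    if (rkey %in% names(wob)) {
      a <- wob[[rkey]]
      return(list(L = a$R, R = a$L, d = a$d, flip = TRUE))
    }
    stop(sprintf("pair type wobble inconsistent with bases %s-%s", bl, br),
         call. = FALSE)
  }
  # mismatch: first two Watson-Crick-edge atoms held apart
  edge <- list(G = c("O6", "N1"), A = c("N6", "N1"),
               C = c("N4", "N3"), U = c("O4", "N3"))
  list(L = edge[[bl]], R = edge[[br]], d = c(4.7, 4.7), flip = FALSE)
}

# least-squares 2D rigid alignment (rotation + translation, no reflection)
.align2d <- function(B, Tm) {
  bc <- colMeans(B); tc <- colMeans(Tm)
  B0 <- sweep(B, 2, bc); T0 <- sweep(Tm, 2, tc)
  H <- t(B0) %*% T0
  s <- svd(H)
  R <- s$u %*% diag(c(1, sign(det(s$v %*% t(s$u))))) %*% t(s$v)
  list(R = R, t = tc - bc %*% R)
}

# place bl and br as a pair in the z = 0 plane; returns list of two
# data.frames (atom, element, x, y, z)
.place_pair <- function(bl, br, type) {
  L <- .base_template(bl)
  R0 <- .base_template(br)
  R0$x <- -R0$x                       # flip about the y axis: edge faces -x
  anch <- .pair_anchors(bl, br, type)
  tL <- as.matrix(L[match(anch$L, L$atom), c("x", "y")])
  targets <- tL + cbind(anch$d, 0)
  bR <- as.matrix(R0[match(anch$R, R0$atom), c("x", "y")])
  tr <- .align2d(bR, targets)
  Rxy <- sweep(as.matrix(R0[, c("x", "y")]) %*% tr$R, 2, tr$t, "+")
  R0$x <- Rxy[, 1]; R0$y <- Rxy[, 2]
  # center the pair on the C1'-C1' midpoint
  c1l <- as.numeric(L[L$atom == "C1'", c("x", "y")])
  c1r <- as.numeric(R0[R0$atom == "C1'", c("x", "y")])
  mid <- (c1l + c1r) / 2
  L$x <- L$x - mid[1]; L$y <- L$y - mid[2]
  R0$x <- R0$x - mid[1]; R0$y <- R0$y - mid[2]
  L$z <- 0; R0$z <- 0
  list(L = L, R = R0)
}

.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Sugar/phosphate pseudo-backbone on an outer cylinder: the backbone atoms
# sit at the residue's angular position but well outside the base shell,
# so they carry donor/acceptor chemistry and usable positions without ever
# entering hydrogen-bond range of a base. Synthetic by design.
.BB_RADIUS <- c(o2 = 13.5, p = 15.5)
.add_backbone <- function(df, dirz) {
  c1 <- df[df$atom == "C1'", ]
  r <- sqrt(c1$x^2 + c1$y^2)
  u <- c(c1$x, c1$y) / max(r, 1e-9)
  o2 <- c(.BB_RADIUS[["o2"]] * u, c1$z + 0.5 * dirz)
  p  <- c(.BB_RADIUS[["p"]] * u, c1$z + 1.2 * dirz)
  rbind(df,
        data.frame(atom = "O2'", x = o2[1], y = o2[2], z = o2[3],
                   element = "O", stringsAsFactors = FALSE),
        data.frame(atom = "P", x = p[1], y = p[2], z = p[3],
                   element = "P", stringsAsFactors = FALSE),
        data.frame(atom = "OP1", x = p[1] + 1.2 * u[1], y = p[2] + 1.2 * u[2],
                   z = p[3] + 0.8 * dirz,
                   element = "O", stringsAsFactors = FALSE),
        data.frame(atom = "OP2", x = p[1] + 1.2 * u[1], y = p[2] + 1.2 * u[2],
                   z = p[3] - 0.8 * dirz,
                   element = "O", stringsAsFactors = FALSE))
}

#' Specify a synthetic duplex
#'
#' @param strand1 Character vector of bases, 5' to 3'.
#' @param strand2 Bases apposed to \code{strand1} (same length;
#'   \code{strand2[k]} faces \code{strand1[k]}). NA for unpaired
#'   \code{strand1} positions.
#' @param pair_types Per-position type: \code{"WC"}, \code{"wobble"},
#'   \code{"mismatch"}, \code{"unpaired"}.
#' @param chain Chain id for the RNA (single chain; both strands carry it).
#' @param resno1,resno2 Author numbers for the two strands
#'   (\code{resno2[k]} faces \code{resno1[k]}).
#' @param rise,twist Helical rise (A) and twist (degrees) per step.
#' @param displacement,dx Displacement of the pair plane from the helix
#'   axis (A), as in A-form helices where pairs wrap around the axis
#'   rather than stacking on it; keeps successive edges out of
#'   hydrogen-bond range of each other.
#' @param inclination Base-pair inclination against the helix axis,
#'   degrees (A-form-like tilt separating cross-strand diagonals).
#' @param seed Seed for the optional coordinate jitter.
#' @param jitter Gaussian coordinate noise sd (A), default 0.
#' @return list of class \code{duplex_spec}.
#' @export
duplex_spec <- function(strand1, strand2, pair_types = NULL, chain = "R",
                        resno1 = seq_along(strand1),
                        resno2 = NULL, rise = 2.8, twist = 32.7,
                        displacement = 5.8, dx = -1, inclination = 10,
                        seed = 1L, jitter = 0) {
  n <- length(strand1)
  stopifnot(length(strand2) == n)
  if (is.null(pair_types))
    pair_types <- ifelse(is.na(strand2), "unpaired", "WC")
  stopifnot(length(pair_types) == n)
  if (is.null(resno2)) resno2 <- seq(2L * n, n + 1L)
  for (k in seq_len(n)) {
    if (pair_types[k] == "unpaired") next
    key <- paste(.canon_rna(strand1[k]), .canon_rna(strand2[k]), sep = ":")
    if (pair_types[k] == "WC" && !key %in% .WC_SET)
      stop(sprintf("pair type WC inconsistent with %s at step %d", key, k),
           call. = FALSE)
    if (pair_types[k] == "wobble" && !key %in% .WOBBLE_SET)
      stop(sprintf("pair type wobble inconsistent with %s at step %d", key, k),
           call. = FALSE)
  }
  structure(list(strand1 = .canon_rna(strand1), strand2 = .canon_rna(strand2),
                 pair_types = pair_types, chain = chain, resno1 = resno1,
                 resno2 = resno2, rise = rise, twist = twist,
                 displacement = displacement, dx = dx,
                 inclination = inclination, seed = seed, jitter = jitter),
            class = "duplex_spec")
}

#' Build an idealized A-form duplex
#'
#' Assembles the specified duplex and emits the ground truth alongside it:
#' the planted pair list with classes, and the expected base-base
#' hydrogen-bond count per pair (verified on the generated coordinates at
#' build time; generation aborts if the planted geometry does not produce
#' its designated bond inventory).
#'
#' @param spec \code{\link{duplex_spec}}.
#' @return list(model = \code{structure_model}, truth = data.frame of
#'   planted pairs with \code{resno_i}, \code{resno_j}, \code{class},
#'   \code{n_bonds}).
#' @export
build_duplex <- function(spec) {
  stopifnot(inherits(spec, "duplex_spec"))
  n <- length(spec$strand1)
  out <- list(); truth <- list()
  for (k in seq_len(n)) {
    bl <- spec$strand1[k]
    type <- spec$pair_types[k]
    if (type == "unpaired") {
      L <- .base_template(bl)
      c1 <- as.numeric(L[L$atom == "C1'", c("x", "y")])
      L$x <- L$x - c1[1] - 5.2; L$y <- L$y - c1[2]
      L$z <- 0
      placed <- list(L = L, R = NULL)
    } else {
      placed <- .place_pair(bl, spec$strand2[k], type)
    }
    Rz <- .rot_z((k - 1) * spec$twist)
    lift <- function(df, resno, resid, dirz) {
      incl <- (if (is.null(spec$inclination)) 0 else spec$inclination) * pi / 180
      y2 <- df$y * cos(incl); z2 <- df$z + df$y * sin(incl)
      df$y <- y2; df$z <- z2
      df$x <- df$x + (if (is.null(spec$dx)) 0 else spec$dx)
      df$y <- df$y + spec$displacement
      df <- .add_backbone(df, dirz)
      xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(Rz)
      data.frame(chain = spec$chain, resno = resno, resid = resid,
                 atom = df$atom, element = df$element,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3] + (k - 1) * spec$rise,
                 occ = 1, stringsAsFactors = FALSE)
    }
    out[[length(out) + 1L]] <- lift(placed$L, spec$resno1[k], bl, +1)
    if (!is.null(placed$R)) {
      out[[length(out) + 1L]] <- lift(placed$R, spec$resno2[k],
                                      spec$strand2[k], -1)
      cls <- switch(type, WC = "watson_crick", wobble = "wobble",
                    mismatch = "mismatch")
      truth[[length(truth) + 1L]] <- data.frame(
        resno_i = min(spec$resno1[k], spec$resno2[k]),
        resno_j = max(spec$resno1[k], spec$resno2[k]),
        class = cls,
        n_bonds = switch(type, WC = if (bl %in% c("G", "C")) 3L else 2L,
                         wobble = 2L, mismatch = 0L),
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, out)
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$jitter)
  }
  atoms <- atoms[order(atoms$resno, atoms$atom), , drop = FALSE]
  model <- structure_model(atoms, "synthetic_duplex")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(resno_i = integer(), resno_j = integer(),
               class = character(), n_bonds = integer())
  if (spec$jitter == 0) .verify_duplex_truth(model, spec, truth)
  list(model = model, truth = truth)
}

.verify_duplex_truth <- function(model, spec, truth) {
  pp <- pairing_params()
  for (k in seq_len(nrow(truth))) {
    ri <- list(chain = spec$chain, resno = truth$resno_i[k])
    rj <- list(chain = spec$chain, resno = truth$resno_j[k])
    nb <- .base_base_bonds(model, ri, rj, pp)
    if (nb != truth$n_bonds[k])
      stop(sprintf("generator self-check failed: pair %d-%d has %d base-base bonds, expected %d",
                   truth$resno_i[k], truth$resno_j[k], nb, truth$n_bonds[k]),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Place a bridging water between two atoms
#'
#' The water oxygen is placed analytically on the perpendicular bisector of
#' the two target atoms so that both distances equal \code{dist}.
#' @param model \code{structure_model}.
#' @param a,b Atom addresses.
#' @param dist Target O-partner distance (default 2.8 A).
#' @param chain,resno Chain id and residue number for the water.
#' @return Updated \code{structure_model}.
#' @export
add_bridging_water <- function(model, a, b, dist = 2.8, chain = "W",
                               resno = 1L) {
  at <- model$atom
  i <- .atom_row(model, a); j <- .atom_row(model, b)
  p <- c(at$x[i], at$y[i], at$z[i]); q <- c(at$x[j], at$y[j], at$z[j])
  h <- sqrt(sum((q - p)^2)) / 2
  if (h >= dist)
    stop(sprintf("atoms %.2f A apart cannot both be %.2f A from one water",
                 2 * h, dist), call. = FALSE)
  m <- (p + q) / 2
  axis <- (q - p) / (2 * h)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- ref - sum(ref * axis) * axis
  perp <- perp / sqrt(sum(perp^2))
  o <- m + sqrt(dist^2 - h^2) * perp
  w <- data.frame(chain = chain, resno = resno, resid = "HOH", atom = "O",
                  element = "O", x = o[1], y = o[2], z = o[3], occ = 1,
                  stringsAsFactors = FALSE)
  structure_model(rbind(at, w), model$entry)
}

# tiny probe peptide: GLY-ARG-GLY backbone plus an Arg side chain
.probe_peptide <- function(chain = "P") {
  res <- list(
    list(resno = 1L, resid = "GLY",
         atoms = list(c("N", 0, 0, 0), c("CA", 1.46, 0, 0),
                      c("C", 2.0, 1.3, 0), c("O", 1.4, 2.35, 0))),
    list(resno = 2L, resid = "ARG",
         atoms = list(c("N", 3.3, 1.3, 0), c("CA", 4.1, 2.5, 0),
                      c("C", 5.5, 2.2, 0.4), c("O", 6.0, 1.1, 0.4),
                      c("CB", 4.1, 3.4, -1.2), c("CG", 4.9, 4.6, -1.3),
                      c("CD", 4.9, 5.4, -2.6), c("NE", 5.7, 6.6, -2.6),
                      c("CZ", 5.7, 7.5, -3.6), c("NH1", 4.9, 7.3, -4.6),
                      c("NH2", 6.5, 8.6, -3.6))),
    list(resno = 3L, resid = "GLY",
         atoms = list(c("N", 6.2, 3.2, 0.8), c("CA", 7.6, 3.1, 1.2),
                      c("C", 8.4, 4.3, 0.8), c("O", 7.9, 5.5, 0.9))))
  rows <- list()
  for (r in res) for (a in r$atoms) {
    rows[[length(rows) + 1L]] <- data.frame(
      chain = chain, resno = r$resno, resid = r$resid, atom = a[1],
      element = substr(a[1], 1, 1), x = as.numeric(a[2]),
      y = as.numeric(a[3]), z = as.numeric(a[4]), occ = 1,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Attach a probe peptide at a controlled minimum gap
#'
#' Places a small GLY-ARG-GLY peptide so that its minimum heavy-atom
#' distance to a named residue equals \code{target_gap} within 0.01 A. The
#' peptide approaches from the direction pointing away from the model
#' centroid, so the planted gap is also the global minimum to the model.
#'
#' @param model \code{structure_model}.
#' @param residue Residue address the gap is measured to.
#' @param target_gap Desired minimum heavy-atom distance, A (> 2.5).
#' @param chain Chain id of the probe.
#' @return Updated \code{structure_model}.
#' @export
attach_probe <- function(model, residue, target_gap, chain = "P") {
  if (target_gap <= 2.5)
    stop("placement error: target gap ", target_gap,
         " A is below the clash radius (2.5 A)", call. = FALSE)
  at <- model$atom
  ri <- .residue_rows(model, residue)
  ctr_res <- colMeans(at[ri, c("x", "y", "z")])
  ctr_all <- colMeans(at[, c("x", "y", "z")])
  d <- ctr_res - ctr_all
  nd <- sqrt(sum(d^2))
  d <- if (nd < 1e-6) c(1, 0, 0) else d / nd
  pep <- .probe_peptide(chain)
  pep_ctr <- colMeans(pep[, c("x", "y", "z")])
  for (k in c("x", "y", "z")) pep[[k]] <- pep[[k]] - pep_ctr[match(k, c("x", "y", "z"))]
  offset <- 12
  for (iter in 1:25) {
    trial <- pep
    trial$x <- pep$x + ctr_res[1] + offset * d[1]
    trial$y <- pep$y + ctr_res[2] + offset * d[2]
    trial$z <- pep$z + ctr_res[3] + offset * d[3]
    m2 <- structure_model(rbind(at, trial), model$entry)
    gap <- min_residue_distance(m2, residue, chain)$distance
    if (abs(gap - target_gap) < 0.005) return(m2)
    offset <- offset + (target_gap - gap)
  }
  stop("placement error: could not reach the target gap", call. = FALSE)
}

#' Attach a single-residue ligand or nucleotide near a target atom
#'
#' Places one residue (its \code{anchor} atom) at \code{dist} Angstrom
#' from the target atom along an outward direction, with the residue's
#' internal geometry taken from the supplied template; used to plant
#' tertiary partners and ligand contacts.
#' @param model \code{structure_model}.
#' @param target Atom address the contact is planted to.
#' @param template data.frame of atoms (atom, element, x, y, z) in a local
#'   frame with the anchor at the origin and the template plane free.
#' @param anchor Atom name placed at the planted distance.
#' @param dist Planted anchor-target distance, A.
#' @param chain,resno,resid Identity of the new residue.
#' @param direction Optional length-3 approach direction; default outward
#'   from the model centroid through the target atom.
#' @param tilt_deg Rotation of the template about the approach axis
#'   (degrees) applied before placement.
#' @return Updated \code{structure_model}.
#' @export
attach_contact_residue <- function(model, target, template, anchor, dist,
                                   chain, resno, resid, direction = NULL,
                                   tilt_deg = 0) {
  at <- model$atom
  i <- .atom_row(model, target)
  t0 <- c(at$x[i], at$y[i], at$z[i])
  if (is.null(direction)) {
    ctr <- colMeans(at[, c("x", "y", "z")])
    direction <- t0 - ctr
  }
  w <- direction / sqrt(sum(direction^2))
  # orthonormal frame around w
  ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * w) * w; u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  a <- tilt_deg * pi / 180
  # local +x (the Watson-Crick edge) points back toward the target, and the
  # template plane contains the approach axis, so a planted bond lies in
  # the attached base's plane
  R <- cbind(-w, cos(a) * u + sin(a) * v, -sin(a) * u + cos(a) * v)
  anchor_pos <- t0 + dist * w
  xyz <- as.matrix(template[, c("x", "y", "z")])
  anchor_local <- xyz[match(anchor, template$atom), ]
  xyz <- sweep(xyz, 2, anchor_local)
  placed <- sweep(xyz %*% t(R), 2, anchor_pos, "+")
  new <- data.frame(chain = chain, resno = resno, resid = resid,
                    atom = template$atom, element = template$element,
                    x = placed[, 1], y = placed[, 2], z = placed[, 3],
                    occ = 1, stringsAsFactors = FALSE)
  structure_model(rbind(at, new), model$entry)
}

#' Planar template of a single nucleobase (with glycosidic atoms)
#'
#' Local frame: the atom named by \code{origin_atom} sits at the origin,
#' the template lies in the local xy plane with the Watson-Crick edge
#' toward +x.
#' @param base A/C/G/U.
#' @param origin_atom Atom moved to the origin.
#' @return data.frame (atom, element, x, y, z).
#' @export
base_residue_template <- function(base, origin_atom = "C1'") {
  tpl <- .base_template(base)
  o <- as.numeric(tpl[tpl$atom == origin_atom, c("x", "y")])
  tpl$x <- tpl$x - o[1]; tpl$y <- tpl$y - o[2]
  tpl$z <- 0
  tpl[, c("atom", "element", "x", "y", "z")]
}

# --- end-to-end scenarios --------------------------------------------------

.SCENARIO_NAMES <- c("wc_disruption", "terminal_wobble", "tandem_wobble",
                     "tertiary_loss", "bridge_member", "ligand_contact",
                     "silent_heterologous", "disordered")

#' List the scenario catalogue
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() .SCENARIO_NAMES

.scenario_duplex <- function(s1, s2, pt, terminal = NULL) {
  n <- length(s1)
  resno1 <- 150L + seq_len(n) - 1L
  resno2 <- 255L - seq_len(n) + 1L
  sp <- duplex_spec(s1, s2, pt, chain = "R", resno1 = resno1,
                    resno2 = resno2)
  d <- build_duplex(sp)
  paired <- pt != "unpaired" & pt != "mismatch"
  map <- data.frame(i = resno1[paired], j = resno2[paired],
                    helix = "hS", terminal = 0L, stringsAsFactors = FALSE)
  if (is.null(terminal)) terminal <- c(min(map$i), max(map$i))
  map$terminal[map$i %in% terminal] <- 1L
  attr(map, "gene") <- "MT-RNR1"
  list(model = d$model, truth = d$truth, map = map,
       resno1 = resno1, resno2 = resno2)
}

.scenario_variant_row <- function(gene_pos, ref, alt, haplotype = 0L,
                                  het = NA_character_, disorder = 0L) {
  data.frame(label = sprintf("m.%d%s>%s", gene_pos + 647L, ref, alt),
             haplotype_marker = haplotype,
             frequency_count = NA_integer_, frequency_total = NA_integer_,
             heterologous_equiv_base = het, disorder_flag = disorder,
             stringsAsFactors = FALSE)
}

.scenario_registries <- function(chain_map = c("12S" = "R"),
                                 proteins = NULL, bridges = NULL,
                                 ligands = NULL) {
  list(
    chain_map = chain_map,
    proteins = if (is.null(proteins))
      data.frame(name = character(), fidelity_protein = integer(),
                 early_binding = integer(),
                 harbors_pathogenic_mutations = integer(),
                 notable_residues = character()) else proteins,
    bridges = if (is.null(bridges))
      data.frame(bridge = character(), component = character(),
                 positions = character()) else bridges,
    ligands = if (is.null(ligands)) data.frame(name = character())
              else ligands)
}

#' Build an end-to-end test scenario
#'
#' Each scenario is a small structure with planted features, a variant
#' table, registries and a secondary map whose pipeline verdict is known by
#' construction. When \code{dir} is given, the inputs are also written in
#' the pipeline's file dialects (mmCIF, TSV).
#'
#' @param name One of \code{scenario_names()}.
#' @param dir Optional output directory.
#' @return list(model, variants, registries, map, expected) where
#'   \code{expected} is a data.frame with \code{label}, \code{verdict},
#'   \code{categories}.
#' @export
make_scenario <- function(name, dir = NULL) {
  if (!name %in% .SCENARIO_NAMES)
    stop("unknown scenario '", name, "'; catalogue: ",
         paste(.SCENARIO_NAMES, collapse = ", "), call. = FALSE)
  reg <- .scenario_registries()
  sc <- switch(
    name,
    wc_disruption = {
      s <- .scenario_duplex(c("G", "A", "U", "C", "A", "G"),
                            c("C", "U", "A", "G", "U", "C"), rep("WC", 6))
      list(model = s$model, map = s$map,
           variants = .scenario_variant_row(152L, "U", "C"),
           registries = reg,
           expected = data.frame(label = "m.799U>C", verdict = "non_silent",
                                 categories = "SEC", stringsAsFactors = FALSE))
    },
    terminal_wobble = {
      s <- .scenario_duplex(c("C", "A", "U", "C", "A", "G"),
                            c("G", "U", "A", "G", "U", "C"), rep("WC", 6))
      list(model = s$model, map = s$map,
           variants = .scenario_variant_row(150L, "C", "U"),
           registries = reg,
           expected = data.frame(label = "m.797C>U", verdict = "non_silent",
                                 categories = "SEC", stringsAsFactors = FALSE))
    },
    tandem_wobble = {
      s <- .scenario_duplex(c("G", "U", "G", "C", "A", "G"),
                            c("C", "A", "U", "G", "U", "C"),
                            c("WC", "WC", "wobble", "WC", "WC", "WC"))
      list(model = s$model, map = s$map,
           variants = .scenario_variant_row(254L, "A", "G"),
           registries = reg,
           expected = data.frame(label = "m.901A>G", verdict = "non_silent",
                                 categories = "SEC", stringsAsFactors = FALSE))
    },
    tertiary_loss = {
      s <- .scenario_duplex(c("G", "C", "A", "U"),
                            c("C", "G", "U", "A"), rep("WC", 4))
      # plant a distal G whose N2 donates to the free minor-groove N3 of 252A
      at <- s$model$atom
      i <- which(at$chain == "R" & at$resno == 252L & at$atom == "N3")
      ctr <- colMeans(at[, c("x", "y", "z")])
      wdir <- c(at$x[i], at$y[i], at$z[i]) - ctr
      wdir <- wdir / sqrt(sum(wdir^2)) + c(0, 0, 1.2)
      model <- attach_contact_residue(
        s$model, "R:252:N3", base_residue_template("G", "N2"), "N2", 2.9,
        chain = "R", resno = 300L, resid = "G", direction = wdir,
        tilt_deg = 20)
      list(model = model, map = s$map,
           variants = .scenario_variant_row(300L, "G", "A"),
           registries = reg,
           expected = data.frame(label = "m.947G>A", verdict = "non_silent",
                                 categories = "TER", stringsAsFactors = FALSE))
    },
    bridge_member = {
      s <- .scenario_duplex(c("G", "C", "A", "U", "A"),
                            c("C", "G", "U", "A", NA),
                            c("WC", "WC", "WC", "WC", "unpaired"))
      reg$bridges <- data.frame(bridge = "mB7", component = "12S",
                                positions = "154", stringsAsFactors = FALSE)
      list(model = s$model, map = s$map,
           variants = .scenario_variant_row(154L, "A", "G"),
           registries = reg,
           expected = data.frame(label = "m.801A>G", verdict = "non_silent",
                                 categories = "BRG", stringsAsFactors = FALSE))
    },
    ligand_contact = {
      s <- .scenario_duplex(c("G", "C", "A", "U"),
                            c("C", "G", "U", "A"), rep("WC", 4))
      at <- s$model$atom
      n4 <- which(at$chain == "R" & at$resno == 151L & at$atom == "N4")
      c4 <- which(at$chain == "R" & at$resno == 151L & at$atom == "C4")
      ring <- which(at$chain == "R" & at$resno == 151L &
                      !(at$atom %in% .RNA_BACKBONE_ATOMS))
      out <- c(at$x[n4] - at$x[c4], at$y[n4] - at$y[c4], at$z[n4] - at$z[c4])
      out <- out / sqrt(sum(out^2))
      nrm <- .base_plane_normal(
        as.matrix(at[ring, c("x", "y", "z")]))
      # rotate the exocyclic direction 60 degrees within the base plane
      axis <- nrm / sqrt(sum(nrm^2))
      a <- 60 * pi / 180
      wdir <- out * cos(a) +
        c(axis[2] * out[3] - axis[3] * out[2],
          axis[3] * out[1] - axis[1] * out[3],
          axis[1] * out[2] - axis[2] * out[1]) * sin(a)
      lig_tpl <- data.frame(atom = c("O1", "C1", "O2"),
                            element = c("O", "C", "O"),
                            x = c(0, 1.4, 2.4), y = c(0, 0, 1.0), z = 0,
                            stringsAsFactors = FALSE)
      model <- attach_contact_residue(s$model, "R:151:N4", lig_tpl, "O1",
                                      2.85, chain = "N", resno = 1L,
                                      resid = "NAD", direction = wdir)
      reg$chain_map <- c("12S" = "R", "NAD" = "N")
      reg$ligands <- data.frame(name = "NAD", stringsAsFactors = FALSE)
      list(model = model, map = s$map,
           variants = .scenario_variant_row(151L, "C", "U"),
           registries = reg,
           expected = data.frame(label = "m.798C>U", verdict = "non_silent",
                                 categories = "LIG", stringsAsFactors = FALSE))
    },
    silent_heterologous = {
      s <- .scenario_duplex(c("G", "C", "A", "G", "U"),
                            c("C", "G", "U", "C", NA),
                            c("WC", "WC", "WC", "WC", "unpaired"))
      model <- add_bridging_water(s$model, "R:154:O4", "R:153:N7",
                                  dist = 3.0)
      list(model = model, map = s$map,
           variants = .scenario_variant_row(154L, "U", "C", het = "C"),
           registries = reg,
           expected = data.frame(label = "m.801U>C", verdict = "silent",
                                 categories = "TER",
                                 stringsAsFactors = FALSE))
    },
    disordered = {
      s <- .scenario_duplex(c("G", "C", "A", "U"),
                            c("C", "G", "U", "A"), rep("WC", 4))
      list(model = s$model, map = s$map,
           variants = .scenario_variant_row(157L, "A", "G", disorder = 1L),
           registries = reg,
           expected = data.frame(label = "m.804A>G", verdict = "unclear",
                                 categories = "", stringsAsFactors = FALSE))
    })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_mmcif(sc$model, file.path(dir, paste0(name, ".cif")))
    utils::write.table(sc$variants, file.path(dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sc$map, file.path(dir, "secondary_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(name = names(sc$registries$chain_map),
                 chain = unname(sc$registries$chain_map)),
      file.path(dir, "chain_map.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (f in c("proteins", "bridges", "ligands"))
      utils::write.table(sc$registries[[f]],
                         file.path(dir, paste0(f, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  sc
}
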