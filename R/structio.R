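# Coordinate model I/O and atomic geometry.
#
# Models are read from mmCIF (PDBx) via bio3d and held as a flat atom table
# using *author* chain ids and sequence numbers, which is the numbering the
# structural literature quotes. Altlocs are collapsed to the highest
# occupancy; unicode primes in atom names are normalized to ASCII.

#' Read an mmCIF coordinate file
#'
#' Parses the \code{atom_site} loop of a PDBx/mmCIF file into a
#' \code{structure_model}: a flat atom table keyed by author chain id and
#' author sequence number. Waters and ligands are retained. Duplicate
#' (chain, residue, atom) records arising from alternate locations are
#' collapsed to the highest-occupancy copy, with a warning.
#'
#' @param path Path to an mmCIF file.
#' @param entry_id Optional entry id to record; defaults to the file name.
#' @return Object of class \code{structure_model} with elements
#'   \code{entry} and \code{atom} (data.frame: \code{chain}, \code{resno},
#'   \code{resid}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{occ}).
#' @export
read_mmcif <- function(path, entry_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_txt <- readLines(path, n = 5000L, warn = FALSE)
  if (!any(grepl("_atom_site\\.", head_txt)))
    stop("not a coordinate mmCIF file (no atom_site loop): ", path,
         call. = FALSE)
  cif <- suppressWarnings(bio3d::read.cif(path))
  at <- cif$atom
  atom_name <- .normalize_atom_name(at$elety)
  atoms <- data.frame(
    chain   = as.character(at$chain),
    resno   = as.integer(at$resno),
    resid   = as.character(at$resid),
    atom    = atom_name,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(atom_name, 1L, 1L), as.character(at$elesy)),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    occ = ifelse(is.na(at$o), 1, as.numeric(at$o)),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (chain, residue, atom) records collapsed to highest occupancy")
    ord <- order(key, -atoms$occ)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom,
                                     sep = "\r")), , drop = FALSE]
    atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resno), ,
                   drop = FALSE]
  }
  rownames(atoms) <- NULL
  structure(list(entry = if (is.null(entry_id)) basename(path) else entry_id,
                 atom = atoms),
            class = "structure_model")
}

.normalize_atom_name <- function(x) {
  x <- gsub('^"|"$', "", as.character(x))
  x <- gsub("\u2032", "'", x)     # unicode prime -> ASCII
  x
}

#' Build a structure model from an atom table
#'
#' Internal constructor used by the synthetic-structure generator; the table
#' must carry the same columns \code{read_mmcif} produces.
#' @param atoms Atom data.frame.
#' @param entry_id Entry identifier.
#' @return \code{structure_model}.
#' @export
structure_model <- function(atoms, entry_id = "synthetic") {
  need <- c("chain", "resno", "resid", "atom", "element", "x", "y", "z", "occ")
  missing <- setdiff(need, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rownames(atoms) <- NULL
  structure(list(entry = entry_id, atom = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$atom$chain)
  cat(sprintf("<structure_model> %s: %d atoms, %d chains (%s)\n",
              x$entry, nrow(x$atom), length(ch),
              paste(utils::head(ch, 8), collapse = ", ")))
  invisible(x)
}

#' Write a structure model as mmCIF
#'
#' Minimal PDBx writer covering the \code{atom_site} loop; sufficient for
#' the synthetic fixtures to round-trip through \code{\link{read_mmcif}}.
#'
#' @param model \code{structure_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mmcif <- function(model, path) {
  at <- model$atom
  quote_name <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", model$entry)),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
            ifelse(at$resid %in% c("HOH"), "HETATM", "ATOM"),
            seq_len(nrow(at)), at$element, quote_name(at$atom), at$resid,
            at$chain, at$resno, at$x, at$y, at$z, at$occ, at$resno, at$resid,
            at$chain, quote_name(at$atom)),
    "#")
  writeLines(lines, path)
  invisible(path)
}

# --- addressing ------------------------------------------------------------

#' Parse an atom or residue address
#'
#' Addresses are \code{"chain:resno"} (residue) or \code{"chain:resno:atom"}
#' (atom); a list with fields \code{chain}, \code{resno} and optionally
#' \code{atom} is accepted as-is.
#' @param addr Address string or list.
#' @return list(chain, resno, atom or NULL)
#' @export
parse_address <- function(addr) {
  if (is.list(addr)) {
    stopifnot(!is.null(addr$chain), !is.null(addr$resno))
    return(list(chain = as.character(addr$chain),
                resno = as.integer(addr$resno),
                atom = if (is.null(addr$atom)) NULL
                       else .normalize_atom_name(addr$atom)))
  }
  parts <- strsplit(as.character(addr), ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || length(parts) > 3L)
    stop("bad address '", addr, "': use chain:resno[:atom]", call. = FALSE)
  list(chain = parts[1], resno = as.integer(parts[2]),
       atom = if (length(parts) == 3L) .normalize_atom_name(parts[3]) else NULL)
}

.atom_row <- function(model, addr) {
  a <- parse_address(addr)
  if (is.null(a$atom)) stop("address lacks an atom field", call. = FALSE)
  at <- model$atom
  i <- which(at$chain == a$chain & at$resno == a$resno & at$atom == a$atom)
  if (length(i) != 1L)
    stop(sprintf("cannot resolve atom %s:%d:%s (%d matches)",
                 a$chain, a$resno, a$atom, length(i)), call. = FALSE)
  i
}

.residue_rows <- function(model, addr) {
  a <- parse_address(addr)
  at <- model$atom
  i <- which(at$chain == a$chain & at$resno == a$resno)
  if (!length(i))
    stop(sprintf("cannot resolve residue %s:%d", a$chain, a$resno),
         call. = FALSE)
  i
}

#' Residue table of a model
#'
#' @param model \code{structure_model}.
#' @param chain Optional chain id filter.
#' @return data.frame \code{chain}, \code{resno}, \code{resid}, one row per
#'   residue in file order.
#' @export
model_residues <- function(model, chain = NULL) {
  at <- model$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  keep <- !duplicated(paste(at$chain, at$resno, sep = "\r"))
  out <- at[keep, c("chain", "resno", "resid")]
  rownames(out) <- NULL
  out
}

# --- geometry --------------------------------------------------------------

#' Euclidean distance between two atoms
#'
#' @param model \code{structure_model}.
#' @param a,b Atom addresses (\code{"chain:resno:atom"} or list form).
#' @return Distance in Angstrom.
#' @examples
#' \dontrun{atom_distance(m, "R:460:O2'", "R:290:OP1")}
#' @export
atom_distance <- function(model, a, b) {
  i <- .atom_row(model, a); j <- .atom_row(model, b)
  at <- model$atom
  sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 + (at$z[i] - at$z[j])^2)
}

.is_heavy <- function(atoms) toupper(atoms$element) != "H"

#' Minimum heavy-atom distance from a residue to a target
#'
#' Computes the minimum over all heavy-atom pairs between one residue and a
#' target chain or residue set, and reports the achieving pair.
#'
#' @param model \code{structure_model}.
#' @param residue Residue address (\code{"chain:resno"}).
#' @param target A chain id (character scalar) or a data.frame with columns
#'   \code{chain}, \code{resno}.
#' @param exclude_water Drop HOH from the target (default TRUE).
#' @return list(distance, from = atom address, to = atom address).
#' @export
min_residue_distance <- function(model, residue, target, exclude_water = TRUE) {
  ri <- .residue_rows(model, residue)
  at <- model$atom
  if (is.character(target) && length(target) == 1L && !grepl(":", target)) {
    ti <- which(at$chain == target)
  } else if (is.data.frame(target)) {
    key <- paste(at$chain, at$resno, sep = "\r")
    ti <- which(key %in% paste(target$chain, target$resno, sep = "\r"))
  } else {
    ti <- .residue_rows(model, target)
  }
  if (exclude_water) ti <- ti[at$resid[ti] != "HOH"]
  ti <- setdiff(ti, ri)
  ri <- ri[.is_heavy(at[ri, , drop = FALSE])]
  ti <- ti[.is_heavy(at[ti, , drop = FALSE])]
  if (!length(ti)) stop("empty target selection", call. = FALSE)
  if (!length(ri)) stop("residue has no heavy atoms", call. = FALSE)
  A <- as.matrix(at[ri, c("x", "y", "z")])
  B <- as.matrix(at[ti, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  k <- arrayInd(which.min(d2), dim(d2))
  i <- ri[k[1]]; j <- ti[k[2]]
  list(distance = sqrt(d2[k]),
       from = sprintf("%s:%d:%s", at$chain[i], at$resno[i], at$atom[i]),
       to   = sprintf("%s:%d:%s", at$chain[j], at$resno[j], at$atom[j]))
}

# Default selector for superposition: one backbone reference atom per
# residue (C1' for nucleotides, CA for amino acids).
.ref_atom_coords <- function(model, chain) {
  at <- model$atom[model$atom$chain == chain, , drop = FALSE]
  ref <- at[at$atom %in% c("C1'", "CA"), , drop = FALSE]
  ref <- ref[!duplicated(ref$resno), , drop = FALSE]
  ref
}

#' Rigid (Kabsch) superposition
#'
#' Least-squares rigid superposition of a mobile model onto a reference,
#' pairing one backbone reference atom per residue (C1' for nucleotides, CA
#' for amino acids) by author residue number within each chain pair.
#' The rotation is determinant-corrected so reflections are never returned.
#'
#' @param mobile,reference \code{structure_model}s.
#' @param chain_pairs data.frame with columns \code{mobile},
#'   \code{reference} naming the chains to pair.
#' @param atom_selector Optional character vector of atom names to use
#'   instead of the default backbone reference atoms.
#' @return list(rotation = 3x3 matrix, translation = length-3 vector,
#'   rmsd, n = number of paired atoms). Coordinates transform as
#'   \code{x R + t} (row vectors); see \code{\link{apply_transform}}.
#' @export
superpose_kabsch <- function(mobile, reference, chain_pairs,
                             atom_selector = NULL) {
  sel_coords <- function(model, chain) {
    if (is.null(atom_selector)) {
      .ref_atom_coords(model, chain)
    } else {
      at <- model$atom[model$atom$chain == chain &
                         model$atom$atom %in% atom_selector, , drop = FALSE]
      at[!duplicated(paste(at$resno, at$atom)), , drop = FALSE]
    }
  }
  P <- NULL; Q <- NULL
  for (k in seq_len(nrow(chain_pairs))) {
    a <- sel_coords(mobile, chain_pairs$mobile[k])
    b <- sel_coords(reference, chain_pairs$reference[k])
    common <- intersect(a$resno, b$resno)
    a <- a[match(common, a$resno), , drop = FALSE]
    b <- b[match(common, b$resno), , drop = FALSE]
    P <- rbind(P, as.matrix(a[, c("x", "y", "z")]))
    Q <- rbind(Q, as.matrix(b[, c("x", "y", "z")]))
  }
  if (is.null(P) || nrow(P) < 3L)
    stop("insufficient correspondence: need at least 3 paired atoms",
         call. = FALSE)
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)            # row-vector convention: y = x R
  t_vec <- qc - pc %*% R
  fitted <- sweep(P0 %*% R, 2, qc, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(t_vec), rmsd = rmsd,
       n = nrow(P))
}

#' Apply a rigid transform to a model
#'
#' Side-effect free: returns a new \code{structure_model} with transformed
#' coordinates.
#' @param model \code{structure_model}.
#' @param transform Result of \code{\link{superpose_kabsch}}.
#' @return Transformed \code{structure_model}.
#' @export
apply_transform <- function(model, transform) {
  xyz <- as.matrix(model$atom[, c("x", "y", "z")])
  new <- sweep(xyz %*% transform$rotation, 2, transform$translation, "+")
  out <- model
  out$atom$x <- new[, 1]; out$atom$y <- new[, 2]; out$atom$z <- new[, 3]
  out
}

#' Read a chain-map registry
#'
#' Key-value TSV translating logical component names (\code{12S},
#' \code{MRPS12}, \code{mRNA}, ...) to chain ids of a given structure, so
#' chain letters are never hardcoded.
#' @param path TSV with columns \code{name}, \code{chain}.
#' @return Named character vector (logical name -> chain id).
#' @export
read_chain_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("name", "chain") %in% names(df)))
  stats::setNames(as.character(df$chain), df$name)
}

#' Spot-check printed atomic distances against a local structure
#'
#' Compares a table of expected atomic distances (logical-name addresses,
#' resolved through a chain map) with distances measured in a coordinate
#' model. Address atoms may list alternatives separated by \code{"|"}; the
#' minimum distance over alternatives is compared. The packaged
#' expectations for the 2.2-A mito-ribosome model are used by default; the
#' structure itself is never distributed and must be supplied locally.
#'
#' @param model \code{structure_model} (e.g. a locally downloaded mmCIF
#'   read with \code{\link{read_mmcif}}).
#' @param chain_map Named vector translating logical chain names to the
#'   structure's chain ids (see \code{\link{read_chain_map}}).
#' @param checks data.frame with columns \code{from}, \code{to},
#'   \code{expected}, \code{tol}; default the packaged table.
#' @return data.frame with \code{measured} and \code{pass} columns added.
#' @export
spot_check_structure <- function(model, chain_map, checks = NULL) {
  if (is.null(checks)) {
    checks <- utils::read.delim(
      system.file("extdata", "spot_checks_8any.tsv",
                  package = "mitotriage", mustWork = TRUE),
      comment.char = "#", stringsAsFactors = FALSE)
  }
  resolve <- function(addr) {
    parts <- strsplit(addr, ":", fixed = TRUE)[[1]]
    ch <- if (parts[1] %in% names(chain_map)) chain_map[[parts[1]]]
          else parts[1]
    lapply(strsplit(parts[3], "|", fixed = TRUE)[[1]], function(a)
      sprintf("%s:%s:%s", ch, parts[2], a))
  }
  checks$measured <- NA_real_
  for (k in seq_len(nrow(checks))) {
    from <- resolve(checks$from[k]); to <- resolve(checks$to[k])
    d <- Inf
    for (a in from) for (b in to)
      d <- min(d, tryCatch(atom_distance(model, a, b), error = function(e) Inf))
    checks$measured[k] <- d
  }
  checks$pass <- is.finite(checks$measured) &
    abs(checks$measured - checks$expected) <= checks$tol
  checks
}
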