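# RNA base-pair detection and substitution effects.
#
# Pairs are detected from geometry (C1'-C1' distance, base-base hydrogen
# bonds, coplanarity), classified as Watson-Crick / wobble / non-canonical /
# mismatch, and partitioned into secondary vs tertiary against a
# secondary-structure map. The map is authoritative for what counts as
# "secondary"; every other base-mediated RNA-RNA contact is tertiary.

#' Base-pair detection parameters
#'
#' Thresholds accept canonical A-form geometry generously: C1'-C1' distance
#' window, minimum base-base hydrogen bonds (canonical vs wobble or
#' non-canonical candidates) and a coplanarity limit on the inter-base-plane
#' angle.
#' @param c1_min,c1_max C1'-C1' window, Angstrom.
#' @param min_bonds_canonical Minimum base-base bonds for a canonical call.
#' @param min_bonds_other Minimum bonds for wobble/non-canonical candidates.
#' @param max_plane_angle Maximum inter-base-plane angle, degrees.
#' @param hbond \code{\link{hbond_params}} used for the bond inventory.
#' @return list of class \code{pairing_params}.
#' @export
pairing_params <- function(c1_min = 8.5, c1_max = 12.0,
                           min_bonds_canonical = 2L, min_bonds_other = 1L,
                           max_plane_angle = 30, hbond = hbond_params()) {
  structure(list(c1_min = c1_min, c1_max = c1_max,
                 min_bonds_canonical = min_bonds_canonical,
                 min_bonds_other = min_bonds_other,
                 max_plane_angle = max_plane_angle, hbond = hbond),
            class = "pairing_params")
}

.WC_SET <- c("A:U", "U:A", "G:C", "C:G")
.WOBBLE_SET <- c("G:U", "U:G")

.pair_key <- function(a, b) paste(a, b, sep = ":")

#' Classify a base pair
#'
#' @param base_i,base_j Bases (\code{A}/\code{C}/\code{G}/\code{U}).
#' @param n_bonds Number of base-base hydrogen bonds observed.
#' @param clash Optional logical: purine-purine or pyrimidine-pyrimidine
#'   apposition with strained geometry.
#' @return One of \code{"watson_crick"}, \code{"wobble"},
#'   \code{"non_canonical"}, \code{"mismatch"}.
#' @export
classify_pair <- function(base_i, base_j, n_bonds, clash = FALSE) {
  stopifnot(base_i %in% c("A", "C", "G", "U"),
            base_j %in% c("A", "C", "G", "U"))
  key <- .pair_key(base_i, base_j)
  if (key %in% .WC_SET && n_bonds >= 2L && !clash) return("watson_crick")
  if (key %in% .WOBBLE_SET && n_bonds >= 1L) return("wobble")
  if (n_bonds >= 2L && !clash) return("non_canonical")
  "mismatch"
}

# predicted class of a hypothetical apposition, from identities alone
.predicted_class <- function(base_i, base_j) {
  key <- .pair_key(base_i, base_j)
  if (key %in% .WC_SET) return("watson_crick")
  if (key %in% .WOBBLE_SET) return("wobble")
  "mismatch"
}

.base_plane_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  svd(c0)$v[, 3]
}

# count base-base H-bonds between two residues (direct bonds only)
.base_base_bonds <- function(model, res_i, res_j, params) {
  sel <- data.frame(chain = c(res_i$chain, res_j$chain),
                    resno = c(res_i$resno, res_j$resno))
  hb <- find_hbonds(model, sel, params$hbond)
  if (!nrow(hb)) return(0L)
  keep <- vapply(seq_len(nrow(hb)), function(k) {
    d <- parse_address(hb$donor[k]); a <- parse_address(hb$acceptor[k])
    cross <- !(d$chain == a$chain && d$resno == a$resno)
    cross && is_base_atom(model, hb$donor[k]) &&
      is_base_atom(model, hb$acceptor[k])
  }, logical(1))
  sum(keep)
}

#' Detect base pairs in RNA chains
#'
#' Candidate pairs must have their C1'-C1' distance inside the configured
#' window, enough base-base hydrogen bonds, and near-coplanar bases. Each
#' residue joins at most one canonical pair; the best-scoring candidate
#' (more bonds, then C1'-C1' distance closest to 10.4) is kept.
#'
#' @param model \code{structure_model}.
#' @param chain RNA chain id(s).
#' @param params \code{\link{pairing_params}}.
#' @return data.frame: \code{chain_i,resno_i,base_i,chain_j,resno_j,base_j},
#'   \code{class}, \code{n_bonds}, \code{c1_dist}.
#' @export
detect_base_pairs <- function(model, chain, params = pairing_params()) {
  at <- model$atom
  res <- model_residues(model, chain)
  if (!nrow(res)) stop("no residues in chain ", paste(chain, collapse = ","),
                       call. = FALSE)
  if (!all(res$resid %in% c("A", "C", "G", "U")))
    stop("chain contains non-RNA residues; base-pair detection needs RNA",
         call. = FALSE)
  c1 <- at[at$chain %in% chain & at$atom == "C1'", , drop = FALSE]
  c1 <- c1[match(paste(res$chain, res$resno), paste(c1$chain, c1$resno)), ,
           drop = FALSE]
  n <- nrow(res)
  if (n < 2L) return(.empty_pairs())
  X <- as.matrix(c1[, c("x", "y", "z")])
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * (X %*% t(X))
  cand <- which(upper.tri(d2) & d2 >= params$c1_min^2 & d2 <= params$c1_max^2,
                arr.ind = TRUE)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (res$chain[i] == res$chain[j] && abs(res$resno[i] - res$resno[j]) < 2L)
      next
    # coplanarity
    bi <- at[at$chain == res$chain[i] & at$resno == res$resno[i] &
               !(at$atom %in% .RNA_BACKBONE_ATOMS), c("x", "y", "z")]
    bj <- at[at$chain == res$chain[j] & at$resno == res$resno[j] &
               !(at$atom %in% .RNA_BACKBONE_ATOMS), c("x", "y", "z")]
    if (nrow(bi) < 3L || nrow(bj) < 3L) next
    ang <- acos(min(1, abs(sum(.base_plane_normal(as.matrix(bi)) *
                                 .base_plane_normal(as.matrix(bj)))))) * 180 / pi
    if (ang > params$max_plane_angle) next
    nb <- .base_base_bonds(model, res[i, ], res[j, ], params)
    key <- .pair_key(res$resid[i], res$resid[j])
    need <- if (key %in% .WC_SET) params$min_bonds_canonical
            else params$min_bonds_other
    if (nb < need) next
    rows[[length(rows) + 1L]] <- data.frame(
      chain_i = res$chain[i], resno_i = res$resno[i], base_i = res$resid[i],
      chain_j = res$chain[j], resno_j = res$resno[j], base_j = res$resid[j],
      class = classify_pair(res$resid[i], res$resid[j], nb),
      n_bonds = nb, c1_dist = sqrt(d2[i, j]), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_pairs())
  pr <- do.call(rbind, rows)
  # one canonical pair per residue: greedy best-scoring
  pr <- pr[order(-pr$n_bonds, abs(pr$c1_dist - 10.4)), , drop = FALSE]
  used <- character(); keep <- logical(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    ki <- paste(pr$chain_i[k], pr$resno_i[k])
    kj <- paste(pr$chain_j[k], pr$resno_j[k])
    if (ki %in% used || kj %in% used) next
    keep[k] <- TRUE
    used <- c(used, ki, kj)
  }
  pr <- pr[keep, , drop = FALSE]
  pr <- pr[order(pr$chain_i, pr$resno_i), , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

.empty_pairs <- function() {
  data.frame(chain_i = character(), resno_i = integer(), base_i = character(),
             chain_j = character(), resno_j = integer(), base_j = character(),
             class = character(), n_bonds = integer(), c1_dist = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a secondary-structure pairing map
#'
#' CT files (six whitespace-separated columns, first line a header) or the
#' package's annotated TSV dialect (columns \code{i}, \code{j},
#' \code{helix}, \code{terminal}) are accepted. Positions are gene-relative.
#'
#' @param path Path to the map file.
#' @param gene Gene the map describes (recorded as an attribute).
#' @return data.frame \code{i}, \code{j}, \code{helix}, \code{terminal}
#'   with \code{i < j}, one row per pair; attribute \code{gene}.
#' @export
read_secondary_map <- function(path, gene = "MT-RNR1") {
  first <- readLines(path, n = 20L, warn = FALSE)
  first <- first[!grepl("^#", first) & nzchar(first)]
  is_tsv <- grepl("\ti\t|^i\t", paste0("\t", first[1]))
  if (is_tsv) {
    df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(all(c("i", "j") %in% names(df)))
    if (!"helix" %in% names(df)) df$helix <- NA_character_
    if (!"terminal" %in% names(df)) df$terminal <- 0L
  } else {
    # CT: index base prev next pair index
    ct <- utils::read.table(path, skip = 1L, stringsAsFactors = FALSE)
    paired <- ct[ct[[5]] > 0 & ct[[1]] < ct[[5]], , drop = FALSE]
    df <- data.frame(i = paired[[1]], j = paired[[5]],
                     helix = NA_character_, terminal = 0L,
                     stringsAsFactors = FALSE)
  }
  sw <- df$i > df$j
  tmp <- df$i[sw]; df$i[sw] <- df$j[sw]; df$j[sw] <- tmp
  if (anyDuplicated(c(df$i, df$j)))
    stop("secondary map assigns a position to more than one pair",
         call. = FALSE)
  df$terminal <- as.integer(df$terminal)
  attr(df, "gene") <- gene
  df
}

#' Look up the map pair of a position
#' @param map Secondary map (\code{\link{read_secondary_map}}).
#' @param position Gene-relative position.
#' @return The map row for the pair containing \code{position}, or NULL.
#' @export
map_pair_of <- function(map, position) {
  k <- which(map$i == position | map$j == position)
  if (!length(k)) return(NULL)
  map[k[1], , drop = FALSE]
}

#' Predict the structural effect of a base substitution on its pair
#'
#' Computes the new pair class from the partner base and the alternate base,
#' and scores the change: Watson-Crick to mismatch is disruptive;
#' Watson-Crick to wobble is tolerated inside a helix but disruptive at a
#' terminal pair or when it creates a U-G/G-U tandem wobble with the
#' adjacent pair (non-isosteric); wobble to Watson-Crick is tolerated;
#' wobble to mismatch is disruptive; a native mismatch replaced by a
#' canonical pair (the ototoxic configuration) is disruptive. When the
#' verdict flips with the neighbouring pair's state, the effect is
#' \code{context_dependent} and both context verdicts are reported.
#'
#' @param position Gene-relative position of the variant.
#' @param ref,alt Reference and alternate base (RNA alphabet).
#' @param partner_base Base paired with \code{position}, or NA if unpaired.
#' @param old_class Observed pair class (from detection or the map);
#'   defaults to the class predicted from identities.
#' @param terminal Logical: the pair closes a helix end or loop.
#' @param neighbor_classes Named character vector of adjacent pair classes,
#'   names are positions (e.g. \code{c("791" = "wobble")}).
#' @param neighbor_alt_classes Optional alternative adjacent classes under
#'   the other haplotype allele (same names).
#' @return list of class \code{substitution_effect}: \code{old_class},
#'   \code{new_class}, \code{disruption} (\code{disruptive}/
#'   \code{tolerated}/\code{context_dependent}), \code{resolved}
#'   (disruption under the observed/annotated context), \code{notes}.
#' @export
predict_substitution <- function(position, ref, alt, partner_base,
                                 old_class = NULL, terminal = FALSE,
                                 neighbor_classes = character(),
                                 neighbor_alt_classes = NULL) {
  ref <- .canon_rna(ref); alt <- .canon_rna(alt)
  .check_base(ref, "ref"); .check_base(alt, "alt")
  if (ref == alt) stop("ref and alt are identical", call. = FALSE)
  if (is.na(partner_base) || is.null(partner_base)) {
    return(structure(list(old_class = "none", new_class = "none",
                          disruption = "tolerated", resolved = "tolerated",
                          notes = "unpaired; effect restricted to lost tertiary bonds"),
                     class = "substitution_effect"))
  }
  partner_base <- .canon_rna(partner_base)
  if (is.null(old_class)) old_class <- .predicted_class(ref, partner_base)
  new_class <- .predicted_class(alt, partner_base)
  notes <- character()
  disruption <- "tolerated"
  if (old_class == "watson_crick") {
    if (new_class == "mismatch") {
      disruption <- "disruptive"
      notes <- sprintf("%s:%s Watson-Crick replaced by %s-%s mismatch",
                       ref, partner_base, alt, partner_base)
    } else if (new_class == "wobble") {
      tandem_now <- any(neighbor_classes == "wobble")
      tandem_alt <- if (is.null(neighbor_alt_classes)) tandem_now
                    else any(neighbor_alt_classes == "wobble")
      if (terminal) {
        disruption <- "disruptive"
        notes <- "wobble at a terminal base pair is structurally disfavored"
      } else if (tandem_now != tandem_alt) {
        disruption <- "context_dependent"
        notes <- "tandem wobble: non-isosteric with the adjacent wobble allele, tolerated with the adjacent Watson-Crick allele"
      } else if (tandem_now) {
        disruption <- "disruptive"
        notes <- "creates a highly non-isosteric U-G/G-U tandem wobble"
      } else {
        disruption <- "tolerated"
        notes <- "internal Watson-Crick to wobble exchange"
      }
    }
  } else if (old_class == "wobble") {
    if (new_class == "watson_crick") {
      disruption <- "tolerated"
      notes <- "wobble exchanged for a Watson-Crick base pair"
    } else if (new_class == "mismatch") {
      disruption <- "disruptive"
      notes <- sprintf("wobble replaced by a %s-%s mismatch", alt, partner_base)
    } else disruption <- "tolerated"
  } else { # mismatch / non_canonical natively
    if (new_class == "watson_crick") {
      disruption <- "disruptive"
      notes <- "native mismatch replaced by a canonical pair (non-isosteric stabilization)"
    } else {
      disruption <- "disruptive"
      notes <- "hydrogen-bonding pattern of the native non-canonical pair not maintained"
    }
  }
  resolved <- disruption
  if (disruption == "context_dependent") {
    resolved <- if (any(neighbor_classes == "wobble")) "disruptive" else "tolerated"
  }
  structure(list(old_class = old_class, new_class = new_class,
                 disruption = disruption, resolved = resolved,
                 notes = paste(notes, collapse = "; ")),
            class = "substitution_effect")
}

#' @export
print.substitution_effect <- function(x, ...) {
  cat(sprintf("<substitution_effect> %s -> %s (%s)\n%s\n",
              x$old_class, x$new_class, x$disruption, x$notes))
  invisible(x)
}

#' Partition RNA-RNA contacts into secondary vs tertiary
#'
#' A detected pair or base-mediated RNA-RNA hydrogen bond is secondary iff
#' its position pair is present in the secondary-structure map; every other
#' base-mediated RNA-RNA contact is tertiary. The partition is exhaustive
#' and disjoint.
#'
#' @param pairs Output of \code{\link{detect_base_pairs}}.
#' @param hbonds Optional base-mediated RNA-RNA hydrogen bonds (data.frame
#'   from \code{\link{find_hbonds}}) to partition alongside the pairs.
#' @param map Secondary map; positions compared against residue numbers.
#' @return list(secondary = pairs data.frame, tertiary = pairs data.frame,
#'   tertiary_bonds = hbond rows not explained by a secondary pair).
#' @export
partition_interactions <- function(pairs, hbonds = NULL, map) {
  in_map <- function(i, j) {
    any((map$i == i & map$j == j) | (map$i == j & map$j == i))
  }
  sec <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    sec[k] <- in_map(pairs$resno_i[k], pairs$resno_j[k])
  tert_bonds <- NULL
  if (!is.null(hbonds) && nrow(hbonds)) {
    keep <- vapply(seq_len(nrow(hbonds)), function(k) {
      d <- parse_address(hbonds$donor[k]); a <- parse_address(hbonds$acceptor[k])
      !in_map(d$resno, a$resno)
    }, logical(1))
    tert_bonds <- hbonds[keep, , drop = FALSE]
  }
  list(secondary = pairs[sec, , drop = FALSE],
       tertiary = pairs[!sec, , drop = FALSE],
       tertiary_bonds = if (is.null(tert_bonds)) .empty_hbonds() else tert_bonds)
}

#' GNRA tetraloop consensus test
#'
#' @param loop_seq Character: a 4-base loop sequence (vector of 4 bases or a
#'   single 4-character string).
#' @return TRUE iff the sequence matches G-N-R-A (R = purine).
#' @export
is_gnra <- function(loop_seq) {
  if (length(loop_seq) == 1L) loop_seq <- strsplit(loop_seq, "")[[1]]
  if (length(loop_seq) != 4L)
    stop("GNRA test needs exactly 4 bases, got ", length(loop_seq),
         call. = FALSE)
  s <- .canon_rna(loop_seq)
  s[1] == "G" && s[3] %in% c("A", "G") && s[4] == "A"
}

#' Packaged 12S secondary-structure map
#'
#' Pairs digitized for the positions the curated table uses; the
#' \code{provenance} column marks pairs whose helix membership is stated in
#' text vs read off the published map image.
#' @return Secondary map data.frame (see \code{\link{read_secondary_map}}).
#' @export
default_secondary_map <- function() {
  read_secondary_map(system.file("extdata", "secondary_map_12s.tsv",
                                 package = "mitotriage", mustWork = TRUE),
                     gene = "MT-RNR1")
}
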