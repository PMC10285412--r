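# Per-variant structural context: proximity tiers, protein/ligand/bridge
# registries, and the evidence bundle the triage rules consume.
#
# The tier cutoffs codify the distance language of structural descriptions
# ("hydrogen-bonding distance", "packs against", "in the neighborhood"):
# hbond <= 3.7 A, packing <= 4.5 A, proximity <= 6.0 A, neighborhood
# <= 15.0 A. All configurable; the curated-table reproduction pins the
# defaults.

#' Contact tier parameters
#' @param hbond,packing,proximity,neighborhood Nested cutoffs in Angstrom.
#' @return list of class \code{tier_params}.
#' @export
tier_params <- function(hbond = 3.7, packing = 4.5, proximity = 6.0,
                        neighborhood = 15.0) {
  stopifnot(hbond <= packing, packing <= proximity,
            proximity <= neighborhood)
  structure(list(hbond = hbond, packing = packing, proximity = proximity,
                 neighborhood = neighborhood), class = "tier_params")
}

#' Classify a distance into a contact tier
#' @param distance Distance in Angstrom (non-negative).
#' @param params \code{\link{tier_params}}.
#' @return One of \code{"hbond"}, \code{"packing"}, \code{"proximity"},
#'   \code{"neighborhood"}, \code{"none"}.
#' @export
contact_tier <- function(distance, params = tier_params()) {
  if (any(distance < 0)) stop("negative distance", call. = FALSE)
  cut <- c(hbond = params$hbond, packing = params$packing,
           proximity = params$proximity, neighborhood = params$neighborhood)
  vapply(distance, function(d) {
    k <- which(d <= cut)
    if (length(k)) names(cut)[k[1]] else "none"
  }, character(1))
}

.TIER_ORDER <- c(hbond = 1L, packing = 2L, proximity = 3L,
                 neighborhood = 4L, none = 5L)

#' Is tier a at least as tight as tier b?
#' @param a,b Tier names.
#' @return logical
#' @export
tier_within <- function(a, b) .TIER_ORDER[[a]] <= .TIER_ORDER[[b]]

# --- registries ------------------------------------------------------------

#' Read the protein registry
#'
#' TSV columns: \code{name} (logical, e.g. MRPS12/uS12m),
#' \code{fidelity_protein}, \code{early_binding},
#' \code{harbors_pathogenic_mutations} (0/1), \code{notable_residues}
#' (semicolon list, may be empty).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_protein_registry <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "fidelity_protein", "early_binding",
            "harbors_pathogenic_mutations")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("protein registry lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"notable_residues" %in% names(df)) df$notable_residues <- ""
  df
}

#' Read the bridge registry
#'
#' TSV columns: \code{bridge} (mB5, mB7, B7a, B7b, ...), \code{component}
#' (logical chain name, e.g. 12S, 16S, MRPL2), \code{positions}
#' (comma-separated author numbers; empty for protein components).
#' @param path TSV path.
#' @return data.frame, one row per (bridge, component).
#' @export
read_bridge_registry <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("bridge", "component", "positions") %in% names(df)))
  df
}

#' Read the ligand registry
#'
#' TSV columns: \code{name} (mRNA, A-tRNA, NAD, spermine, ...) resolved
#' through the chain map.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ligand_registry <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot("name" %in% names(df))
  df
}

#' Load a registry directory
#'
#' Reads \code{chain_map.tsv}, \code{proteins.tsv}, \code{bridges.tsv},
#' \code{ligands.tsv} from a directory. Any file may be absent, yielding an
#' empty component.
#' @param dir Directory path.
#' @return list(chain_map, proteins, bridges, ligands).
#' @export
load_registries <- function(dir) {
  rd <- function(f, reader, empty) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else empty
  }
  list(
    chain_map = rd("chain_map.tsv", read_chain_map, character()),
    proteins = rd("proteins.tsv", read_protein_registry,
                  data.frame(name = character(), fidelity_protein = integer(),
                             early_binding = integer(),
                             harbors_pathogenic_mutations = integer(),
                             notable_residues = character())),
    bridges = rd("bridges.tsv", read_bridge_registry,
                 data.frame(bridge = character(), component = character(),
                            positions = character())),
    ligands = rd("ligands.tsv", read_ligand_registry,
                 data.frame(name = character()))
  )
}

#' Packaged default registries for the 2.2-A mito-ribosome model
#'
#' Protein flags, bridge residue sets and ligand names for PDB entry 8ANY.
#' The chain-id map is a user-editable template: chain letters are never
#' hardcoded and must be checked against the local copy of the structure.
#' @return list as \code{\link{load_registries}}.
#' @export
default_registries <- function() {
  load_registries(system.file("extdata", "registry_8any",
                              package = "mitotriage", mustWork = TRUE))
}

#' Bridge membership of an rRNA position
#'
#' @param position Gene-relative position (12S unless \code{component}
#'   says otherwise).
#' @param bridges Bridge registry data.frame.
#' @param component Logical chain name to match (default \code{"12S"}).
#' @param model,chain_map Optional: when given, positions within the
#'   proximity tier of a member residue are reported as
#'   \code{"neighborhood"}.
#' @param tiers \code{\link{tier_params}}.
#' @return list(status = "member"/"neighborhood"/"none", bridge = name or
#'   NA).
#' @export
bridge_membership <- function(position, bridges, component = "12S",
                              model = NULL, chain_map = NULL,
                              tiers = tier_params()) {
  rel <- bridges[bridges$component == component & nzchar(bridges$positions), ,
                 drop = FALSE]
  for (k in seq_len(nrow(rel))) {
    pos <- as.integer(strsplit(rel$positions[k], ",")[[1]])
    if (position %in% pos)
      return(list(status = "member", bridge = rel$bridge[k]))
  }
  if (!is.null(model) && !is.null(chain_map) && component %in% names(chain_map)) {
    ch <- chain_map[[component]]
    have <- model_residues(model, ch)$resno
    if (position %in% have) {
      for (k in seq_len(nrow(rel))) {
        pos <- intersect(as.integer(strsplit(rel$positions[k], ",")[[1]]), have)
        if (!length(pos)) next
        d <- min_residue_distance(
          model, sprintf("%s:%d", ch, position),
          data.frame(chain = ch, resno = setdiff(pos, position)))$distance
        if (d <= tiers$proximity)
          return(list(status = "neighborhood", bridge = rel$bridge[k]))
      }
    }
  }
  list(status = "none", bridge = NA_character_)
}

# --- atom retention under a base substitution ------------------------------

.base_roles <- function(base) {
  tab <- .NUC_BASE[[base]]
  roles <- c(stats::setNames(rep("donor", length(tab$donors)), names(tab$donors)),
             stats::setNames(rep("acceptor", length(tab$acceptors)), tab$acceptors))
  both <- intersect(names(tab$donors), tab$acceptors)
  roles[both] <- "both"
  roles
}

#' Is a base-atom interaction retained after a substitution?
#'
#' A hydrogen bond made through a base atom survives a substitution only
#' when the alternate base carries the same atom in the same donor/acceptor
#' role. Backbone (sugar/phosphate) atoms are always retained: a base
#' change does not touch them.
#' @param atom Atom name.
#' @param ref,alt Reference and alternate base.
#' @return logical
#' @export
atom_retained <- function(atom, ref, alt) {
  atom <- .normalize_atom_name(atom)
  if (atom %in% .RNA_BACKBONE_ATOMS) return(TRUE)
  rr <- .base_roles(.canon_rna(ref)); ra <- .base_roles(.canon_rna(alt))
  if (!atom %in% names(rr)) return(TRUE)   # non-polar ring atom: no bond role
  (atom %in% names(ra)) && identical(unname(rr[atom]), unname(ra[atom]))
}

# --- evidence --------------------------------------------------------------

#' Construct a structural-evidence bundle
#'
#' Normally produced by \code{\link{collect_evidence}} (geometry mode) or
#' the curated-table replay; exposed so evidence can be built directly.
#' @param variant list with at least \code{label}, \code{gene},
#'   \code{gene_pos}, \code{ref}, \code{alt}, \code{subunit}.
#' @param pairing \code{substitution_effect} or NULL.
#' @param pairing_in_map Pair present in the secondary map.
#' @param ter_direct,ter_water Lost base-mediated tertiary bonds (direct /
#'   water-mediated counts).
#' @param quat_base Lost base-mediated protein bonds.
#' @param quat_altered Any flagged-protein contact at packing tier or
#'   tighter that the change may distort.
#' @param lig_affected Ligand contact (direct or water-mediated) at
#'   proximity tier or tighter involving the base or its lost bonds.
#' @param lig_backbone Backbone-only ligand contact.
#' @param bridge_status,bridge_name Bridge membership.
#' @param prox Within neighborhood tier of an early-binding or
#'   pathogenic-mutation-harboring protein.
#' @param annotations list: \code{haplotype_marker},
#'   \code{heterologous_tolerated}, \code{retained_only}, \code{disorder}.
#' @param contacts Optional data.frame of measured contacts (name, distance,
#'   tier, atom pair) for the report.
#' @param notes Free-text evidence notes.
#' @return object of class \code{structural_evidence}.
#' @export
structural_evidence <- function(variant, pairing = NULL,
                                pairing_in_map = FALSE,
                                ter_direct = 0L, ter_water = 0L,
                                quat_base = 0L, quat_altered = FALSE,
                                lig_affected = FALSE, lig_backbone = FALSE,
                                bridge_status = "none",
                                bridge_name = NA_character_,
                                prox = FALSE, annotations = list(),
                                contacts = NULL, notes = "") {
  ann <- utils::modifyList(list(haplotype_marker = FALSE,
                                heterologous_tolerated = FALSE,
                                retained_only = FALSE, disorder = FALSE),
                           annotations)
  structure(list(variant = variant, pairing = pairing,
                 pairing_in_map = isTRUE(pairing_in_map),
                 ter_direct = as.integer(ter_direct),
                 ter_water = as.integer(ter_water),
                 quat_base = as.integer(quat_base),
                 quat_altered = isTRUE(quat_altered),
                 lig_affected = isTRUE(lig_affected),
                 lig_backbone = isTRUE(lig_backbone),
                 bridge_status = bridge_status, bridge_name = bridge_name,
                 prox = isTRUE(prox), annotations = ann,
                 contacts = contacts, notes = notes),
            class = "structural_evidence")
}

#' @export
print.structural_evidence <- function(x, ...) {
  cat(sprintf("<structural_evidence> %s\n", x$variant$label))
  if (!is.null(x$pairing))
    cat(sprintf("  pairing: %s -> %s (%s)%s\n", x$pairing$old_class,
                x$pairing$new_class, x$pairing$disruption,
                if (x$pairing_in_map) " [secondary map]" else ""))
  cat(sprintf("  tertiary lost: %d direct, %d water-mediated\n",
              x$ter_direct, x$ter_water))
  cat(sprintf("  quaternary: %d base-mediated bonds lost%s\n", x$quat_base,
              if (x$quat_altered) ", contact altered" else ""))
  cat(sprintf("  ligand: %s; bridge: %s%s; flagged-protein proximity: %s\n",
              if (x$lig_affected) "base contact" else
                if (x$lig_backbone) "backbone contact" else "none",
              x$bridge_status,
              if (!is.na(x$bridge_name)) paste0(" (", x$bridge_name, ")") else "",
              x$prox))
  invisible(x)
}

#' Collect structural evidence for a variant from a coordinate model
#'
#' Geometry mode: detects the variant's base pair and predicts the
#' substitution effect, inventories direct and water-mediated hydrogen
#' bonds of the residue and classifies each as secondary, tertiary,
#' quaternary (protein) or ligand, applying the atom-retention rule to
#' decide which bonds the substitution loses; measures minimum distances to
#' every registered protein and ligand (the query neighborhood includes the
#' pair partner and the two sequence neighbors, and waters are excluded
#' from protein distances); and resolves bridge membership. Annotations
#' pass through unchanged. A variant position absent from the model yields
#' evidence with the disorder flag set and empty geometry fields.
#'
#' @param variant \code{gene_coordinate} or rCRS label; needs \code{ref}
#'   and \code{alt} (supply a parsed variant or \code{ref}/\code{alt}).
#' @param model \code{structure_model}.
#' @param registries list from \code{\link{load_registries}}.
#' @param map Secondary map for the gene.
#' @param annotations Variant annotations (haplotype flag, heterologous
#'   base, disorder flag), as from \code{\link{read_variant_table}} rows.
#' @param params list(tiers = \code{\link{tier_params}}, pairing =
#'   \code{\link{pairing_params}}).
#' @return \code{structural_evidence}.
#' @export
collect_evidence <- function(variant, model, registries, map,
                             annotations = list(),
                             params = list(tiers = tier_params(),
                                           pairing = pairing_params())) {
  tiers <- params$tiers; pp <- params$pairing
  if (is.character(variant)) variant <- parse_variant_label(variant)
  if (inherits(variant, "genomic_variant")) {
    gc <- genome_to_gene(variant$position)
    v <- list(label = dual_label(variant), gene = gc$gene,
              gene_pos = gc$position, genomic_pos = gc$genomic_position,
              ref = variant$ref, alt = variant$alt,
              subunit = if (gc$gene == "MT-RNR1") "SSU" else "LSU")
  } else v <- variant
  cm <- registries$chain_map
  rna_logical <- if (v$subunit == "SSU") "12S" else "16S"
  if (!rna_logical %in% names(cm))
    stop("chain map lacks an entry for ", rna_logical, call. = FALSE)
  rch <- cm[[rna_logical]]
  ann <- list(
    haplotype_marker = isTRUE(annotations$haplotype_marker == 1) ||
      isTRUE(annotations$haplotype_marker),
    heterologous_tolerated =
      (!is.null(annotations$heterologous_equiv_base) &&
         !is.na(annotations$heterologous_equiv_base) &&
         .canon_rna(annotations$heterologous_equiv_base) == v$alt),
    retained_only = FALSE,
    disorder = isTRUE(annotations$disorder_flag == 1) ||
      isTRUE(annotations$disorder_flag))

  res <- model_residues(model, rch)
  if (!v$gene_pos %in% res$resno) {
    ann$disorder <- TRUE
    return(structural_evidence(v, annotations = ann,
                               notes = "position not modeled (disordered)"))
  }
  ref_struct <- res$resid[match(v$gene_pos, res$resno)]

  # pairing ---------------------------------------------------------------
  pairs <- detect_base_pairs(model, rch, pp)
  prow <- pairs[(pairs$resno_i == v$gene_pos | pairs$resno_j == v$gene_pos), ,
                drop = FALSE]
  pairing <- NULL; in_map <- FALSE; partner_resno <- NA_integer_
  if (nrow(prow)) {
    prow <- prow[1, ]
    mine_is_i <- prow$resno_i == v$gene_pos
    partner_resno <- if (mine_is_i) prow$resno_j else prow$resno_i
    partner_base <- if (mine_is_i) prow$base_j else prow$base_i
    mp <- map_pair_of(map, v$gene_pos)
    in_map <- !is.null(mp) &&
      ((mp$i == v$gene_pos && mp$j == partner_resno) ||
         (mp$j == v$gene_pos && mp$i == partner_resno))
    terminal <- !is.null(mp) && isTRUE(mp$terminal == 1L)
    nb <- character()
    for (d in c(-1L, 1L)) {
      npair <- pairs[pairs$resno_i == v$gene_pos + d |
                       pairs$resno_j == v$gene_pos + d, , drop = FALSE]
      if (nrow(npair))
        nb[as.character(v$gene_pos + d)] <- npair$class[1]
    }
    pairing <- predict_substitution(v$gene_pos, ref_struct, v$alt,
                                    partner_base, old_class = prow$class,
                                    terminal = terminal,
                                    neighbor_classes = nb)
  }

  # hydrogen-bond inventory of the residue ---------------------------------
  me <- sprintf("%s:%d", rch, v$gene_pos)
  prot <- registries$proteins
  prot <- prot[prot$name %in% names(cm), , drop = FALSE]
  lig <- registries$ligands
  lig <- lig[lig$name %in% names(cm), , drop = FALSE]
  sel_chains <- unique(c(rch, unname(cm[prot$name]), unname(cm[lig$name])))
  hb <- find_hbonds(model, sel_chains, pp$hbond)
  wb <- find_water_bridges(model, sel_chains, pp$hbond)
  touch_me <- function(df) {
    if (!nrow(df)) return(df)
    keep <- vapply(seq_len(nrow(df)), function(k) {
      d <- parse_address(df$donor[k]); a <- parse_address(df$acceptor[k])
      (d$chain == rch && d$resno == v$gene_pos) ||
        (a$chain == rch && a$resno == v$gene_pos)
    }, logical(1))
    df[keep, , drop = FALSE]
  }
  hb <- touch_me(hb); wb <- touch_me(wb)
  side_of <- function(addr) { # my atom vs partner atom
    p <- parse_address(addr); p$chain == rch && p$resno == v$gene_pos
  }
  ter_direct <- 0L; ter_water <- 0L; quat_base <- 0L
  lig_affected <- FALSE; lig_backbone <- FALSE
  any_base_interaction <- FALSE; all_retained <- TRUE
  prot_chains <- stats::setNames(unname(cm[prot$name]), prot$name)
  lig_chains <- stats::setNames(unname(cm[lig$name]), lig$name)
  score_bond <- function(my_addr, other_addr, water) {
    my <- parse_address(my_addr); other <- parse_address(other_addr)
    my_atom_is_base <- is_base_atom(model, my_addr)
    lost <- !atom_retained(my$atom, ref_struct, v$alt)
    if (my_atom_is_base) any_base_interaction <<- TRUE
    if (my_atom_is_base && !lost) all_retained <<- all_retained && TRUE
    if (lost) all_retained <<- FALSE
    if (other$chain == rch) {
      if (!is.na(partner_resno) && other$resno == partner_resno) return()
      if (my_atom_is_base && lost) {
        if (water) ter_water <<- ter_water + 1L
        else ter_direct <<- ter_direct + 1L
      }
    } else if (other$chain %in% prot_chains) {
      if (my_atom_is_base && lost) quat_base <<- quat_base + 1L
    } else if (other$chain %in% lig_chains) {
      if (my_atom_is_base) lig_affected <<- TRUE else lig_backbone <<- TRUE
    }
  }
  for (k in seq_len(nrow(hb))) {
    if (side_of(hb$donor[k])) score_bond(hb$donor[k], hb$acceptor[k], FALSE)
    else score_bond(hb$acceptor[k], hb$donor[k], FALSE)
  }
  for (k in seq_len(nrow(wb))) {
    if (side_of(wb$donor[k])) score_bond(wb$donor[k], wb$acceptor[k], TRUE)
    else score_bond(wb$acceptor[k], wb$donor[k], TRUE)
  }

  # registry distances ------------------------------------------------------
  hood <- c(v$gene_pos - 1L, v$gene_pos, v$gene_pos + 1L, partner_resno)
  hood <- intersect(hood[!is.na(hood)], res$resno)
  contacts <- list(); prox <- FALSE; quat_altered <- quat_base > 0L
  for (k in seq_len(nrow(prot))) {
    ch <- cm[[prot$name[k]]]
    if (!ch %in% model$atom$chain) next
    best <- NULL
    for (p in hood) {
      d <- min_residue_distance(model, sprintf("%s:%d", rch, p), ch)
      if (is.null(best) || d$distance < best$distance) best <- d
    }
    tier <- contact_tier(best$distance, tiers)
    contacts[[length(contacts) + 1L]] <- data.frame(
      kind = "protein", name = prot$name[k], distance = best$distance,
      tier = tier, from = best$from, to = best$to, stringsAsFactors = FALSE)
    flagged <- prot$early_binding[k] == 1 ||
      prot$harbors_pathogenic_mutations[k] == 1
    if (flagged && tier != "none") prox <- TRUE
    # direct (not neighborhood) packing contact counts as alterable
    if (tier_within(tier, "packing")) {
      d_self <- min_residue_distance(model, me, ch)$distance
      if (d_self <= tiers$packing) quat_altered <- TRUE
    }
  }
  lig_tier_min <- "none"
  for (k in seq_len(nrow(lig))) {
    ch <- cm[[lig$name[k]]]
    if (!ch %in% model$atom$chain) next
    d <- min_residue_distance(model, me, ch)
    tier <- contact_tier(d$distance, tiers)
    contacts[[length(contacts) + 1L]] <- data.frame(
      kind = "ligand", name = lig$name[k], distance = d$distance,
      tier = tier, from = d$from, to = d$to, stringsAsFactors = FALSE)
    if (tier_within(tier, "proximity") &&
        .TIER_ORDER[[tier]] < .TIER_ORDER[[lig_tier_min]])
      lig_tier_min <- tier
  }
  if (lig_affected && !(lig_tier_min %in% c("hbond", "packing", "proximity")))
    lig_affected <- FALSE     # ligand bond must sit within the proximity tier

  br <- bridge_membership(v$gene_pos, registries$bridges,
                          component = rna_logical, model = model,
                          chain_map = cm, tiers = tiers)
  ann$retained_only <- any_base_interaction && all_retained &&
    ter_direct == 0L && ter_water == 0L && quat_base == 0L
  structural_evidence(
    v, pairing = pairing, pairing_in_map = in_map,
    ter_direct = ter_direct, ter_water = ter_water,
    quat_base = quat_base, quat_altered = quat_altered,
    lig_affected = lig_affected, lig_backbone = lig_backbone,
    bridge_status = br$status, bridge_name = br$bridge,
    prox = prox, annotations = ann,
    contacts = if (length(contacts)) do.call(rbind, contacts) else NULL)
}
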