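# rCRS <-> rRNA gene coordinate mapping and variant nomenclature.
#
# Genomic positions follow the revised Cambridge Reference Sequence (rCRS,
# NC_012920.1), 1-based. The two mitochondrial rRNA genes occupy fixed,
# closed intervals on it; gene-relative positions are 1-based.

RCRS_LENGTH <- 16569L

#' rRNA gene annotation on the rCRS
#'
#' Fixed spans of the two mitochondrial rRNA genes on the revised Cambridge
#' Reference Sequence: MT-RNR1 (12S mt-rRNA, SSU) and MT-RNR2 (16S mt-rRNA,
#' LSU). Closed 1-based intervals.
#'
#' @return A data.frame with columns \code{gene}, \code{start}, \code{end},
#'   \code{length}, \code{subunit}.
#' @export
rrna_genes <- function() {
  data.frame(
    gene    = c("MT-RNR1", "MT-RNR2"),
    start   = c(648L, 1671L),
    end     = c(1601L, 3229L),
    length  = c(954L, 1559L),
    subunit = c("SSU", "LSU"),
    stringsAsFactors = FALSE
  )
}

.canon_rna <- function(base) {
  base <- toupper(base)
  base[base == "T"] <- "U"
  base
}

.check_base <- function(base, what) {
  if (!all(toupper(base) %in% c("A", "C", "G", "T", "U")))
    stop(sprintf("invalid %s base '%s': must be one of A, C, G, T, U",
                 what, base), call. = FALSE)
  invisible(base)
}

#' Parse an HGVS-style mitochondrial variant label
#'
#' Accepts labels of the form \code{"m.<position><ref>><alt>"} (for example
#' \code{"m.1555A>G"}). DNA bases (T) are canonicalized to the RNA alphabet
#' (U) internally; the raw label is preserved.
#'
#' @param label Character scalar, e.g. \code{"m.1555A>G"}.
#' @return An object of class \code{genomic_variant}: a list with fields
#'   \code{position} (rCRS coordinate), \code{ref}, \code{alt} (RNA
#'   alphabet), and \code{raw_label}.
#' @examples
#' parse_variant_label("m.1555A>G")
#' @export
parse_variant_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  lab <- gsub("[[:space:]]+", "", label)
  m <- regmatches(lab, regexec("^m\\.([0-9]+)([ACGTUacgtu])>([ACGTUacgtu])$", lab))[[1]]
  if (length(m) != 4L) {
    tok <- sub("^m\\.", "", lab)
    stop(sprintf("malformed variant label '%s' (offending token '%s'): expected m.<position><ref>><alt>",
                 label, tok), call. = FALSE)
  }
  pos <- as.integer(m[2])
  if (is.na(pos) || pos < 1L || pos > RCRS_LENGTH)
    stop(sprintf("position %s outside rCRS range 1-%d", m[2], RCRS_LENGTH),
         call. = FALSE)
  ref <- .canon_rna(m[3]); alt <- .canon_rna(m[4])
  if (ref == alt)
    stop(sprintf("reference and alternate base are identical in '%s'", label),
         call. = FALSE)
  structure(list(position = pos, ref = ref, alt = alt, raw_label = label),
            class = "genomic_variant")
}

#' @export
print.genomic_variant <- function(x, ...) {
  cat(sprintf("<genomic_variant> m.%d%s>%s\n", x$position, x$ref, x$alt))
  invisible(x)
}

#' Map an rCRS position to an rRNA gene coordinate
#'
#' @param position Integer rCRS coordinate (1-based).
#' @return An object of class \code{gene_coordinate}: list with \code{gene},
#'   \code{position} (gene-relative, 1-based) and \code{genomic_position}.
#' @examples
#' genome_to_gene(1555)  # MT-RNR1 position 908
#' @export
genome_to_gene <- function(position) {
  stopifnot(length(position) == 1L, is.numeric(position))
  position <- as.integer(position)
  g <- rrna_genes()
  hit <- which(position >= g$start & position <= g$end)
  if (length(hit) != 1L)
    stop(sprintf(paste0("position m.%d is not an rRNA position: ",
                        "MT-RNR1 spans rCRS %d-%d, MT-RNR2 spans rCRS %d-%d"),
                 position, g$start[1], g$end[1], g$start[2], g$end[2]),
         call. = FALSE)
  structure(list(gene = g$gene[hit],
                 position = position - g$start[hit] + 1L,
                 genomic_position = position),
            class = "gene_coordinate")
}

#' @export
print.gene_coordinate <- function(x, ...) {
  cat(sprintf("<gene_coordinate> %s:%d (m.%d)\n", x$gene, x$position,
              x$genomic_position))
  invisible(x)
}

#' Map an rRNA gene coordinate back to the rCRS
#'
#' Inverse of \code{\link{genome_to_gene}} on its domain.
#'
#' @param gene \code{"MT-RNR1"} or \code{"MT-RNR2"}.
#' @param position Gene-relative 1-based position.
#' @return Integer rCRS coordinate.
#' @export
gene_to_genome <- function(gene, position) {
  g <- rrna_genes()
  row <- match(gene, g$gene)
  if (is.na(row))
    stop(sprintf("unknown rRNA gene '%s' (use MT-RNR1 or MT-RNR2)", gene),
         call. = FALSE)
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > g$length[row]))
    stop(sprintf("gene position out of range for %s (1-%d)",
                 gene, g$length[row]), call. = FALSE)
  position + g$start[row] - 1L
}

#' Dual (gene + genomic) variant label
#'
#' Formats a variant the way the field cites mt-rRNA changes: gene-relative
#' first, genomic in brackets, e.g. \code{"908A>G (m.1555A>G)"}. Output bases
#' use the alphabet of the input ref base (a DNA-labelled input keeps T).
#'
#' @param variant A \code{genomic_variant} (see
#'   \code{\link{parse_variant_label}}) or a character label.
#' @return Character scalar.
#' @examples
#' dual_label("m.1555A>G")
#' @export
dual_label <- function(variant) {
  if (is.character(variant)) variant <- parse_variant_label(variant)
  stopifnot(inherits(variant, "genomic_variant"))
  gc <- genome_to_gene(variant$position)
  # honor input alphabet: if the raw label used T, print T
  ref <- variant$ref; alt <- variant$alt
  raw <- gsub("[[:space:]]+", "", variant$raw_label)
  m <- regmatches(raw, regexec("^m\\.[0-9]+([ACGTUacgtu])>([ACGTUacgtu])$", raw))[[1]]
  if (length(m) == 3L) { ref <- toupper(m[2]); alt <- toupper(m[3]) }
  sprintf("%d%s>%s (m.%d%s>%s)", gc$position, ref, alt,
          variant$position, ref, alt)
}

#' Read a variant annotation table
#'
#' Tab-separated text with columns \code{label}, \code{haplotype_marker}
#' (0/1), \code{frequency_count}, \code{frequency_total},
#' \code{heterologous_equiv_base}, \code{disorder_flag}; \code{'#'} starts a
#' comment. Missing optional columns are filled with defaults.
#'
#' @param path Path to the TSV file.
#' @return A data.frame, one row per variant, with a parsed
#'   \code{position}/\code{ref}/\code{alt} alongside the annotations.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"label" %in% names(df))
    stop("variant table must have a 'label' column", call. = FALSE)
  defaults <- list(haplotype_marker = 0L, frequency_count = NA_integer_,
                   frequency_total = NA_integer_,
                   heterologous_equiv_base = NA_character_,
                   disorder_flag = 0L)
  for (nm in names(defaults))
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  parsed <- lapply(df$label, parse_variant_label)
  df$position <- vapply(parsed, `[[`, integer(1), "position")
  df$ref <- vapply(parsed, `[[`, character(1), "ref")
  df$alt <- vapply(parsed, `[[`, character(1), "alt")
  df
}

#' Dual labels printed in the source study
#'
#' The packaged fixture list of gene/genomic label pairs exhibited in the
#' study this package reproduces. Column \code{flagged} marks the one pair
#' recorded verbatim despite an apparent ref-base inconsistency in the
#' original text; it is excluded from round-trip checks.
#'
#' @return data.frame with columns \code{gene_label}, \code{genomic_label},
#'   \code{flagged}.
#' @export
paper_dual_labels <- function() {
  path <- system.file("extdata", "paper_dual_labels.tsv",
                      package = "mitotriage", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$flagged <- as.integer(df$flagged)
  df
}
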