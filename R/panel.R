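#' Hotspot panel definition
#'
#' A hotspot panel is the set of coding-sequence positions interrogated by
#' the assay: every base of codons 12, 13, 59, 61, 117 and 146 of KRAS and
#' NRAS and codon 600 of BRAF (13 codons, 39 positions). Positions are
#' 1-based CDS coordinates on the coding strand, labelled in the
#' `"KRAS 37G"` style (gene, position, reference base). Positions with
#' systematic sequencing artifacts can be marked non-evaluable; the default
#' panel excludes KRAS 37G, KRAS 175G and NRAS 351G.
#'
#' @param config Path to a YAML panel configuration, or an equivalent list.
#'   The configuration has a `genes` list (each entry: `gene`, `codons`,
#'   `codon_sequences` mapping codon number to reference triplet) and an
#'   optional `excluded_sites` character vector of site labels.
#' @return A data frame of class `"hotspot_panel"` with one row per coding
#'   position: `gene`, `coding_pos`, `ref`, `codon`, `codon_ref`,
#'   `evaluable`, `label`.
#' @examples
#' panel <- hotspot_panel()
#' nrow(panel)              # 39
#' sum(!panel$evaluable)    # 3
#' @export
hotspot_panel <- function(config = default_panel_config()) {
  load_panel(config)
}

#' @rdname hotspot_panel
#' @export
default_panel_config <- function() {
  system.file("extdata", "default_panel.yaml", package = "amplicall",
              mustWork = TRUE)
}

known_genes <- c("KRAS", "NRAS", "BRAF")

#' Expand a panel configuration into a per-position site table
#'
#' @inheritParams hotspot_panel
#' @return See [hotspot_panel()].
#' @export
load_panel <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$genes)) {
    stop("panel config must be a list with a 'genes' entry", call. = FALSE)
  }
  rows <- lapply(config$genes, function(g) {
    if (is.null(g$gene) || !g$gene %in% known_genes) {
      stop("unknown gene in panel config: ", deparse(g$gene), call. = FALSE)
    }
    codons <- as.integer(g$codons)
    seqs <- unlist(g$codon_sequences)
    if (!setequal(names(seqs), as.character(codons))) {
      stop("codon_sequences for ", g$gene,
           " do not match the listed codons", call. = FALSE)
    }
    seqs <- toupper(seqs[as.character(codons)])
    bad <- nchar(seqs) != 3L | grepl("[^ACGT]", seqs)
    if (any(bad)) {
      stop("codon sequence for ", g$gene, " codon ",
           paste(codons[bad], collapse = ", "),
           " is not a 3-base ACGT triplet", call. = FALSE)
    }
    do.call(rbind, lapply(seq_along(codons), function(i) {
      codon <- codons[i]
      bases <- strsplit(seqs[i], "")[[1]]
      pos <- (codon - 1L) * 3L + 1:3
      data.frame(gene = g$gene, coding_pos = pos, ref = bases,
                 codon = codon, codon_ref = unname(seqs[i]),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
  panel <- do.call(rbind, rows)
  panel$label <- sprintf("%s %d%s", panel$gene, panel$coding_pos, panel$ref)
  panel$evaluable <- TRUE
  excl <- config$excluded_sites
  if (!is.null(excl)) {
    unknown <- setdiff(excl, panel$label)
    if (length(unknown)) {
      stop("excluded_sites not in panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    panel$evaluable <- !panel$label %in% excl
  }
  rownames(panel) <- NULL
  panel <- panel[, c("gene", "coding_pos", "ref", "codon", "codon_ref",
                     "evaluable", "label")]
  class(panel) <- c("hotspot_panel", "data.frame")
  panel
}

site_key <- function(gene, coding_pos) paste(gene, coding_pos)

#' @export
print.hotspot_panel <- function(x, ...) {
  cat("Hotspot panel:", nrow(x), "coding positions in",
      length(unique(paste(x$gene, x$codon))), "codons\n")
  excl <- x$label[!x$evaluable]
  if (length(excl)) {
    cat("Non-evaluable positions:", paste(excl, collapse = ", "), "\n")
  }
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Annotate a single-base substitution at a panel position
#'
#' Produces the coding annotation (`"c.34G>A"`) and the protein annotation
#' obtained by translating the reference codon with the substituted base
#' under the standard genetic code (`"G12S"`; stop codons are written
#' `"*"`, synonymous changes repeat the amino acid, e.g. `"A146A"`).
#'
#' @param site One or more rows of a [hotspot_panel()] data frame.
#' @param alt_base Alternate nucleotide(s), recycled against rows of
#'   `site`; each must differ from the site's reference base.
#' @return A data frame with columns `cdna` and `protein`.
#' @examples
#' panel <- hotspot_panel()
#' kras34 <- panel[panel$gene == "KRAS" & panel$coding_pos == 34, ]
#' annotate_variant(kras34, "A")   # c.34G>A, G12S
#' @export
annotate_variant <- function(site, alt_base) {
  alt_base <- toupper(rep_len(alt_base, nrow(site)))
  if (any(!alt_base %in% c("A", "C", "G", "T"))) {
    stop("alt_base must be one of A, C, G, T", call. = FALSE)
  }
  if (any(alt_base == site$ref)) {
    stop("alt_base equals the reference base at ",
         paste(site$label[alt_base == site$ref], collapse = ", "),
         call. = FALSE)
  }
  offset <- (site$coding_pos - 1L) %% 3L + 1L
  alt_codon <- mapply(function(codon, off, alt) {
    substr(codon, off, off) <- alt
    codon
  }, site$codon_ref, offset, alt_base, USE.NAMES = FALSE)
  ref_aa <- translate_codon(site$codon_ref)
  alt_aa <- translate_codon(alt_codon)
  data.frame(
    cdna = sprintf("c.%d%s>%s", site$coding_pos, site$ref, alt_base),
    protein = sprintf("%s%d%s", ref_aa, site$codon, alt_aa),
    stringsAsFactors = FALSE
  )
}

# Standard genetic code, one-letter amino acids; stop codons -> "*".
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  if (anyNA(aa)) {
    stop("invalid codon: ", paste(codon[is.na(aa)], collapse = ", "),
         call. = FALSE)
  }
  unname(aa)
}
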