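# Gene models: exon/intron arithmetic on the coding strand, splicing,
# translation, intron metrics and CDS-frame insertion coordinates.
#
# An intron's insertion site in the spliced CDS is summarized as a codon
# index plus a phase: phase +1 means the intron interrupts the codon between
# nt 1 and nt 2, +2 between nt 2 and nt 3, and phase 0 means the intron sits
# on the boundary preceding the indicated codon.

#' Build a gene model from a species record
#'
#' Takes the exon structure from the record's CDS join and derives the
#' introns as the gaps between consecutive exons. Introns shorter than
#' `min_intron_nt` are rejected as annotation noise (real mitochondrial cox1
#' introns are large, typically >1 kbp).
#'
#' @param record A [species_record()] with a CDS feature.
#' @param genetic_code_id NCBI translation table id; default 4
#'   (mold/protozoan mitochondrial), the standard table for fungal
#'   mitochondria.
#' @param min_intron_nt Minimum credible intron length (default 30).
#' @return An object of class `gene_model` with fields `species_id`,
#'   `sequence`, `exons` (two-column matrix), `genetic_code_id`.
#' @export
build_gene_model <- function(record, genetic_code_id = 4L, min_intron_nt = 30L) {
  stopifnot(inherits(record, "species_record"))
  kinds <- vapply(record$features, `[[`, "", "kind")
  if (!any(kinds == "CDS")) stop("no gene model: record has no CDS feature")
  exons <- record$features[[which(kinds == "CDS")[1]]]$spans
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("inconsistent model: overlapping exons")
  len <- nchar(record$sequence)
  if (any(exons[, 1] < 1L) || any(exons[, 2] > len))
    stop("malformed feature: exon outside sequence")
  if (nrow(exons) > 1) {
    gaps <- exons[-1, 1] - exons[-nrow(exons), 2] - 1L
    if (any(gaps > 0L & gaps < min_intron_nt))
      stop("inconsistent model: intron shorter than ", min_intron_nt, " nt")
  }
  structure(
    list(species_id = record$species_id, sequence = record$sequence,
         exons = exons, genetic_code_id = as.integer(genetic_code_id)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  ints <- gene_introns(x)
  cat("<gene_model>", x$species_id, ":", nchar(x$sequence), "nt,",
      nrow(x$exons), "exons,", length(ints), "introns\n")
  invisible(x)
}

#' Intron records of a gene model
#'
#' Each intron is the gap between two consecutive exons, numbered 5' to 3'.
#' `insertion_cds_offset` is the number of spliced-CDS nucleotides upstream
#' of the intron; `group_label` is a lightweight terminal-nucleotide
#' heuristic (see [classify_intron_group()]).
#'
#' @param model A `gene_model`.
#' @return List of `intron_record` objects with fields `ordinal`, `start`,
#'   `end`, `length`, `insertion_cds_offset`, `seq`, `group_label`.
#' @export
gene_introns <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  if (nrow(ex) < 2) return(list())
  out <- vector("list", nrow(ex) - 1L)
  exon_len <- ex[, 2] - ex[, 1] + 1L
  for (i in seq_len(nrow(ex) - 1L)) {
    start <- ex[i, 2] + 1L
    end <- ex[i + 1L, 1] - 1L
    if (start > end) next
    iseq <- substr(model$sequence, start, end)
    out[[i]] <- structure(
      list(ordinal = i, start = start, end = end,
           length = end - start + 1L,
           insertion_cds_offset = sum(exon_len[seq_len(i)]),
           seq = iseq, group_label = classify_intron_group(iseq)),
      class = "intron_record"
    )
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Heuristic intron group classification
#'
#' A deliberately lightweight terminal-nucleotide heuristic: group I introns
#' end in G (the conserved omega-G of the splicing mechanism), group II
#' introns end in AC/AT (the AY terminus of domain VI). Anything else is
#' `"unknown"`. Full secondary-structure assignment is out of scope.
#'
#' @param seq Intron DNA string.
#' @return `"I"`, `"II"` or `"unknown"`.
#' @export
classify_intron_group <- function(seq) {
  last2 <- toupper(substr(seq, nchar(seq) - 1L, nchar(seq)))
  if (last2 %in% c("AC", "AT")) return("II")
  if (substr(last2, 2, 2) == "G") return("I")
  "unknown"
}

#' Splice a gene model into its CDS
#'
#' @param model A `gene_model`.
#' @return The spliced CDS (exons concatenated 5' to 3').
#' @export
splice_cds <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  paste(substring(model$sequence, model$exons[, 1], model$exons[, 2]),
        collapse = "")
}

#' Translate a CDS
#'
#' Translates under the given NCBI genetic code. A terminal stop is
#' stripped. An internal stop is not fatal — it is reported through the
#' `premature_stop` attribute because it is exactly the signal the
#' endonuclease-erosion caller feeds on.
#'
#' @param cds DNA string.
#' @param genetic_code_id NCBI translation table id (default 4).
#' @param on_partial What to do when the length is not a multiple of 3:
#'   `"error"` (default) or `"truncate"` (drop the trailing 1-2 nt with a
#'   warning).
#' @return Protein string with attribute `premature_stop` (logical).
#' @export
translate_cds <- function(cds, genetic_code_id = 4L,
                          on_partial = c("error", "truncate")) {
  on_partial <- match.arg(on_partial)
  cds <- toupper(cds)
  extra <- nchar(cds) %% 3L
  if (extra != 0L) {
    if (on_partial == "error")
      stop("CDS length ", nchar(cds), " is not a multiple of 3")
    warning("truncating ", extra, " trailing nt")
    cds <- substr(cds, 1L, nchar(cds) - extra)
  }
  prot <- paste(translate_codons(cds, genetic_code_id), collapse = "")
  if (endsWith(prot, "*")) prot <- substr(prot, 1L, nchar(prot) - 1L)
  attr(prot, "premature_stop") <- grepl("*", prot, fixed = TRUE)
  prot
}

# cached NCBI genetic code tables and a plain table-lookup translator
# (returns one amino acid per codon; unknown/ambiguous codons become "X")
.code_cache <- new.env(parent = emptyenv())

genetic_code_table <- function(genetic_code_id) {
  key <- as.character(genetic_code_id)
  if (is.null(.code_cache[[key]]))
    .code_cache[[key]] <- Biostrings::getGeneticCode(key)
  .code_cache[[key]]
}

translate_codons <- function(dna, genetic_code_id = 4L) {
  code <- genetic_code_table(genetic_code_id)
  n_codon <- nchar(dna) %/% 3L
  starts <- (seq_len(n_codon) - 1L) * 3L + 1L
  aa <- unname(code[substring(dna, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  aa
}

#' Summary metrics of a gene model
#'
#' @param model A `gene_model`.
#' @return List with `n_introns`, `total_intron_nt`, `total_gene_nt`,
#'   `intronic_fraction` (percent of the gene that is intronic, 1 decimal),
#'   `min_intron`, `max_intron`, `min_exon`, `max_exon`.
#' @export
intron_metrics <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex_len <- model$exons[, 2] - model$exons[, 1] + 1L
  ints <- gene_introns(model)
  int_len <- vapply(ints, `[[`, integer(1), "length")
  total_gene <- nchar(model$sequence)
  total_intron <- sum(int_len)
  list(
    n_introns = length(ints),
    total_intron_nt = total_intron,
    total_gene_nt = total_gene,
    intronic_fraction = round(100 * total_intron / total_gene, 1),
    min_intron = if (length(int_len)) min(int_len) else NA_integer_,
    max_intron = if (length(int_len)) max(int_len) else NA_integer_,
    min_exon = min(ex_len),
    max_exon = max(ex_len)
  )
}

#' Insertion site of an intron in CDS codon coordinates
#'
#' With `offset` = number of spliced-CDS nucleotides 5' of the intron, the
#' site is codon `offset %/% 3 + 1` at phase `offset %% 3`. Phase 0 sites
#' (offset divisible by 3) are attributed to the boundary preceding the
#' following codon.
#'
#' @param model A `gene_model`.
#' @param intron An `intron_record` from [gene_introns()] (or its 1-based
#'   ordinal).
#' @return Object of class `site_in_cds`: list with `codon_index`, `phase`.
#' @export
site_in_cds <- function(model, intron) {
  if (is.numeric(intron)) intron <- gene_introns(model)[[intron]]
  offset <- intron$insertion_cds_offset
  cds_len <- sum(model$exons[, 2] - model$exons[, 1] + 1L)
  if (offset < 0L || offset > cds_len)
    stop("insertion offset ", offset, " outside CDS [0, ", cds_len, "]")
  structure(list(codon_index = offset %/% 3L + 1L, phase = offset %% 3L),
            class = "site_in_cds")
}
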