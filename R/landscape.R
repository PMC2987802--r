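# The species x Pcl landscape matrix: rows are position classes ordered by
# descending member count, columns are species in taxonomy order; each cell
# records whether the species carries that intron and whether its heg is
# intact or eroded.

#' Build the species x Pcl landscape matrix
#'
#' Cells are `"absent"`, `"intact"` or `"eroded"` (an intron present with no
#' detectable or an eroded heg is recorded as `"eroded"`). Rows are ordered
#' by decreasing member count (fungal member count when `taxonomy` provides
#' kingdoms), ties broken by name; columns follow the input species order,
#' which carries the taxonomic ordering. Two introns of one species can
#' never share a Pcl — that would mean two introns at one exact site — so
#' duplicate placements are an error.
#'
#' @param pcls Named list of `pcl` objects (after [name_pcls()]).
#' @param species Character vector of species ids, taxonomy-ordered;
#'   intronless species appear as all-absent columns.
#' @param taxonomy Optional data frame (`species_id`, ..., `kingdom`) used
#'   for fungal-count row ordering.
#' @return Object of class `landscape_matrix`: character matrix with Pcl
#'   rownames and species colnames.
#' @export
build_landscape <- function(pcls, species, taxonomy = NULL) {
  pcl_names <- vapply(pcls, `[[`, "", "name")
  if (anyNA(pcl_names)) stop("pcls must be named first (see name_pcls)")
  m <- matrix("absent", nrow = length(pcls), ncol = length(species),
              dimnames = list(pcl_names, species))
  for (p in pcls) {
    mem <- p$members
    if (anyDuplicated(mem$species_id))
      stop("duplicate placement: species ",
           mem$species_id[duplicated(mem$species_id)][1],
           " has two introns in Pcl ", p$name)
    unknown <- setdiff(mem$species_id, species)
    if (length(unknown))
      stop("member species not in species list: ",
           paste(unknown, collapse = ", "))
    status <- ifelse(!is.na(mem$heg_status) & mem$heg_status == "intact",
                     "intact", "eroded")
    m[p$name, mem$species_id] <- status
  }
  counts <- member_counts(m, taxonomy)
  o <- order(-counts, rownames(m))
  structure(m[o, , drop = FALSE], class = "landscape_matrix")
}

member_counts <- function(m, taxonomy = NULL) {
  cols <- colnames(m)
  if (!is.null(taxonomy) && "kingdom" %in% names(taxonomy)) {
    kings <- taxonomy$kingdom[match(cols, taxonomy$species_id)]
    fungal <- !is.na(kings) & kings == "Fungi"
    if (any(fungal)) cols <- cols[fungal]
  }
  rowSums(unclass(m)[, cols, drop = FALSE] != "absent")
}

#' @export
print.landscape_matrix <- function(x, ...) {
  cat("<landscape_matrix>", nrow(x), "Pcls x", ncol(x), "species;",
      sum(unclass(x) != "absent"), "introns\n")
  invisible(x)
}

#' Summarize a landscape matrix
#'
#' All counts are computed from the cells alone. When `taxonomy` provides a
#' `kingdom` column, `pct_shared_with_other_kingdoms` is the percentage
#' (nearest integer) of Pcls that have at least one member outside the
#' Fungi kingdom.
#'
#' @param matrix A `landscape_matrix`.
#' @param taxonomy Optional taxonomy data frame with `species_id`, `kingdom`.
#' @return List: `n_species`, `n_pcls`, `n_introns`, `n_eroded`,
#'   `pct_shared_with_other_kingdoms` (or `NA`), `per_species_counts`
#'   (named integer vector).
#' @export
summarize_landscape <- function(matrix, taxonomy = NULL) {
  stopifnot(inherits(matrix, "landscape_matrix"))
  m <- unclass(matrix)
  present <- m != "absent"
  pct_shared <- NA_real_
  if (!is.null(taxonomy) && "kingdom" %in% names(taxonomy) && nrow(m)) {
    kings <- taxonomy$kingdom[match(colnames(m), taxonomy$species_id)]
    nonfungal <- !is.na(kings) & kings != "Fungi"
    shared <- rowSums(present[, nonfungal, drop = FALSE]) > 0
    pct_shared <- pct_int(sum(shared), nrow(m))
  }
  list(
    n_species = ncol(m),
    n_pcls = nrow(m),
    n_introns = sum(present),
    n_eroded = sum(m == "eroded"),
    pct_shared_with_other_kingdoms = pct_shared,
    per_species_counts = colSums(present)
  )
}

#' Integer percentage
#'
#' `round(100 * num / den)` — the rounding convention used for all reported
#' landscape percentages.
#'
#' @param num,den Numerator and denominator.
#' @return Integer-rounded percentage.
#' @export
pct_int <- function(num, den) round(100 * num / den)
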