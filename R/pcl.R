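# Position classes (Pcls): projection of each intron insertion site onto a
# single designated reference COX1 protein frame, clustering of identical
# sites, alphabetic naming 5' to 3', identity-structure validation and
# rarity labelling.
#
# A Pcl is the unit of intron orthology: the set of introns inserted at one
# exact (reference residue, codon phase) site. Projection is pairwise
# (species protein vs reference protein), which keeps the coordinate system
# independent of which other species are in the analysis.

#' Project an insertion site onto the reference protein frame
#'
#' The species residue hosting (phase +1/+2) or following (phase 0) the
#' insertion is mapped through a global protein alignment to the reference
#' residue index. If the reference has a gap at that column the nearest
#' aligned column is used and the site is flagged `gap_adjacent`.
#'
#' @param site A `site_in_cds` (from [site_in_cds()]).
#' @param species_protein Protein of the species' spliced CDS.
#' @param reference_protein The designated reference COX1 protein.
#' @param ... Passed to [global_align()].
#' @return Object of class `projected_site`: `ref_residue`, `phase`,
#'   `confidence` (`"aligned"` or `"gap_adjacent"`).
#' @export
project_site <- function(site, species_protein, reference_protein, ...) {
  stopifnot(inherits(site, "site_in_cds"))
  res <- min(site$codon_index, nchar(species_protein))
  if (identical(species_protein, reference_protein)) {
    return(structure(list(ref_residue = res, phase = site$phase,
                          confidence = "aligned"), class = "projected_site"))
  }
  aln <- global_align(species_protein, reference_protein, ...)
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  a_idx <- cumsum(a != "-")
  b_idx <- cumsum(b != "-")
  col <- match(TRUE, a_idx == res & a != "-")
  if (is.na(col)) stop("unmappable site: residue ", res, " not aligned")
  confidence <- "aligned"
  if (b[col] == "-") {
    aligned_cols <- which(b != "-" & a != "-")
    if (!length(aligned_cols)) stop("unmappable site: no aligned columns")
    col2 <- aligned_cols[which.min(abs(aligned_cols - col))]
    if (col2 > max(which(b != "-")) || col2 < min(which(b != "-")))
      stop("unmappable site: maps into a reference terminal gap")
    col <- col2
    confidence <- "gap_adjacent"
  }
  structure(list(ref_residue = b_idx[col], phase = site$phase,
                 confidence = confidence), class = "projected_site")
}

#' Cluster projected sites into position classes
#'
#' At the default tolerance 0, introns are grouped by exact
#' `(ref_residue, phase)` match. With `tolerance_residues = 1`, sites of
#' identical phase at most one residue apart are merged by single linkage
#' (for noisy projections).
#'
#' @param projected Data frame with columns `species_id`, `ordinal`,
#'   `ref_residue`, `phase` and optionally `heg_status`.
#' @param tolerance_residues 0 (exact, default) or a small integer.
#' @return List of `pcl` objects: `name` (unset until [name_pcls()]),
#'   `site` (list `ref_residue`, `phase`), `members` (data frame),
#'   `rarity` (unset until [label_rarity()]).
#' @export
cluster_pcls <- function(projected, tolerance_residues = 0L) {
  stopifnot(is.data.frame(projected),
            all(c("species_id", "ordinal", "ref_residue", "phase") %in%
                  names(projected)))
  if (!nrow(projected)) return(list())
  if (!"heg_status" %in% names(projected))
    projected$heg_status <- NA_character_
  key_order <- order(projected$ref_residue, projected$phase)
  projected <- projected[key_order, , drop = FALSE]
  if (tolerance_residues == 0L) {
    grp <- match(paste(projected$ref_residue, projected$phase),
                 unique(paste(projected$ref_residue, projected$phase)))
  } else {
    # single linkage within phase: merge runs of sites <= tolerance apart
    grp <- integer(nrow(projected))
    g <- 0L
    for (ph in sort(unique(projected$phase))) {
      idx <- which(projected$phase == ph)
      res <- projected$ref_residue[idx]
      new_grp <- c(TRUE, diff(res) > tolerance_residues)
      grp[idx] <- g + cumsum(new_grp)
      g <- max(grp[idx])
    }
  }
  lapply(split(seq_len(nrow(projected)), grp), function(ii) {
    mem <- projected[ii, , drop = FALSE]
    rownames(mem) <- NULL
    structure(
      list(name = NA_character_,
           site = list(ref_residue = min(mem$ref_residue),
                       phase = mem$phase[1]),
           members = mem, rarity = NA_character_),
      class = "pcl")
  })
}

#' Alphabetic Pcl names, 5' to 3'
#'
#' Classes sorted by `(ref_residue, phase)` are named A, B, ..., Z, AA,
#' AB, ... so that name order and 5'-to-3' site order agree.
#'
#' @param pcls List of `pcl` objects.
#' @return The same list, sorted by site, with `name` set.
#' @export
name_pcls <- function(pcls) {
  if (!length(pcls)) return(pcls)
  o <- order(vapply(pcls, function(p) p$site$ref_residue, numeric(1)),
             vapply(pcls, function(p) p$site$phase, numeric(1)))
  pcls <- pcls[o]
  for (i in seq_along(pcls)) pcls[[i]]$name <- alpha_name(i)
  names(pcls) <- vapply(pcls, `[[`, "", "name")
  pcls
}

# 1 -> "A", 26 -> "Z", 27 -> "AA", 35 -> "AI" (bijective base 26)
alpha_name <- function(i) {
  out <- character(0)
  while (i > 0L) {
    r <- (i - 1L) %% 26L
    out <- c(LETTERS[r + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  paste(out, collapse = "")
}

#' Validate that Pcls are sequence-identity classes
#'
#' The positional definition of a Pcl predicts an identity structure: every
#' intact HE should be more similar to the intact HE of its own Pcl than to
#' any HE of another Pcl. For each intact member with at least one intact
#' within-Pcl partner, the minimum within-Pcl identity and maximum
#' between-Pcl identity are computed from global alignments; a violation is
#' flagged when the latter reaches the former.
#'
#' @param pcls Named list of `pcl` objects (after [name_pcls()]).
#' @param heg_proteins Named character vector of intact HE proteins, keyed
#'   by `"<species_id>:<ordinal>"`.
#' @param ... Passed to [global_align()].
#' @return Data frame with one row per comparable member: `member`, `pcl`,
#'   `min_within_identity`, `max_between_identity`, `violation`.
#' @export
validate_identity_structure <- function(pcls, heg_proteins, ...) {
  keys <- lapply(pcls, function(p)
    intersect(paste0(p$members$species_id, ":", p$members$ordinal),
              names(heg_proteins)))
  names(keys) <- vapply(pcls, `[[`, "", "name")
  all_keys <- unlist(keys, use.names = FALSE)
  if (length(all_keys) < 2)
    return(data.frame(member = character(0), pcl = character(0),
                      min_within_identity = numeric(0),
                      max_between_identity = numeric(0),
                      violation = logical(0)))
  pid <- function(x, y) {
    identity_stats(global_align(heg_proteins[[x]], heg_proteins[[y]], ...))$pct_identity
  }
  rows <- list()
  for (pcl_name in names(keys)) {
    within <- keys[[pcl_name]]
    if (length(within) < 2) next
    between <- setdiff(all_keys, within)
    for (k in within) {
      w <- vapply(setdiff(within, k), pid, numeric(1), x = k)
      b <- if (length(between)) vapply(between, pid, numeric(1), x = k) else -Inf
      rows[[length(rows) + 1L]] <- data.frame(
        member = k, pcl = pcl_name,
        min_within_identity = min(w),
        max_between_identity = max(b),
        violation = max(b) >= min(w),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(member = character(0), pcl = character(0),
                      min_within_identity = numeric(0),
                      max_between_identity = numeric(0),
                      violation = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label a Pcl as rare or widespread
#'
#' Rare means: found in a single species, or in at most `max_rare_species`
#' species that all fall within one taxonomic unit at `rank` (default
#' order) — the formalization of "detected in a single species or shared by
#' closely related species".
#'
#' @param pcl A `pcl` object.
#' @param species_taxonomy Data frame with columns `species_id`, `genus`,
#'   `order`, `phylum`, `kingdom`.
#' @param max_rare_species Member-species cap for the closely-related rule.
#' @param rank Taxonomic rank (column name) defining "closely related".
#' @return `"rare"` or `"widespread"`.
#' @export
label_rarity <- function(pcl, species_taxonomy, max_rare_species = 4L,
                         rank = "order") {
  sp <- unique(pcl$members$species_id)
  miss <- setdiff(sp, species_taxonomy$species_id)
  if (length(miss)) stop("unknown taxon: ", paste(miss, collapse = ", "))
  if (length(sp) == 1L) return("rare")
  units <- species_taxonomy[[rank]][match(sp, species_taxonomy$species_id)]
  if (length(sp) <= max_rare_species && length(unique(units)) == 1L)
    return("rare")
  "widespread"
}
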