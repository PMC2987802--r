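# Homing endonuclease gene (heg) analysis inside introns: ORF discovery,
# family assignment by local protein alignment against a reference set,
# integrity calling (intact / eroded / absent), frameshift evidence, and
# detection of chimeric "invader" heg nested inside a recipient heg.
#
# The calling logic mirrors how eroded heg present in real mitochondrial
# introns look: the ancestral reading frame is still recognizable by
# homology but is split across frames (frameshifts) or interrupted by
# in-frame stops, or truncated. Thresholds are configuration, not biology:
# intact requires one ORF covering >= intact_cov of the family reference;
# eroded requires homology over >= eroded_cov of the reference but
# interrupted; anything else is absent.

#' Scan an intron for open reading frames
#'
#' Scans the three forward frames (introns are already on the coding
#' strand). In `"start"` mode an ORF runs from the first in-frame start
#' codon to the next stop; in `"fragment"` mode every stop-to-stop segment
#' is reported, which is what erosion evidence needs since eroded heg may
#' have lost their start.
#'
#' @param intron_seq Intron DNA (coding strand).
#' @param genetic_code_id NCBI translation table id (default 4).
#' @param min_aa Minimum ORF length in amino acids (default 100).
#' @param mode `"start"` or `"fragment"`.
#' @param start_codons Allowed start codons (default `"ATG"`).
#' @return List of `orf_hit` objects (fields `start`, `end` — 1-based nt in
#'   the intron, stop codon excluded —, `frame`, `protein`, `length_aa`),
#'   longest first.
#' @export
scan_orfs <- function(intron_seq, genetic_code_id = 4L, min_aa = 100L,
                      mode = c("start", "fragment"),
                      start_codons = "ATG") {
  mode <- match.arg(mode)
  intron_seq <- toupper(intron_seq)
  n <- nchar(intron_seq)
  out <- list()
  for (frame in 1:3) {
    n_codon <- (n - frame + 1L) %/% 3L
    if (n_codon < 1L) next
    fseq <- substr(intron_seq, frame, frame + n_codon * 3L - 1L)
    aa <- translate_codons(fseq, genetic_code_id)
    stops <- which(aa == "*")
    seg_start <- c(1L, stops + 1L)
    seg_end <- c(stops - 1L, length(aa))
    for (s in seq_along(seg_start)) {
      p1 <- seg_start[s]; p2 <- seg_end[s]
      if (p1 > p2) next
      if (mode == "start") {
        codons <- substring(fseq, (p1:p2 - 1L) * 3L + 1L, (p1:p2) * 3L)
        m <- match(TRUE, codons %in% start_codons)
        if (is.na(m)) next
        p1 <- p1 + m - 1L
      }
      len_aa <- p2 - p1 + 1L
      if (len_aa < min_aa) next
      out[[length(out) + 1L]] <- structure(
        list(start = frame + (p1 - 1L) * 3L, end = frame + p2 * 3L - 1L,
             frame = frame, protein = paste(aa[p1:p2], collapse = ""),
             length_aa = len_aa),
        class = "orf_hit")
    }
  }
  out[order(-vapply(out, `[[`, integer(1), "length_aa"))]
}

#' Assign a protein to a heg family by local alignment
#'
#' Aligns the query against every family reference and keeps the best hit,
#' provided its raw score clears `threshold` (default 80, the conventional
#' "clearly homologous" raw-score cutoff for these families;
#' [calibrate_family_threshold()] derives a data-driven one from shuffled
#' queries).
#'
#' @param protein Query protein string.
#' @param families Named character vector of family reference proteins.
#' @param threshold Minimum raw local-alignment score.
#' @param matrix,gap_open,gap_extend Passed to [local_align()].
#' @return `NULL` if no family clears the threshold, else a list with
#'   `family_id`, `score`, `margin` (best minus second-best score),
#'   `coverage` (fraction of the reference covered), `ref_span`, `query_span`.
#' @export
assign_family <- function(protein, families, threshold = 80,
                          matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  stopifnot(length(families) >= 1, !is.null(names(families)))
  # families as patterns against the query subject: one vectorized call,
  # valid because the substitution matrix is symmetric
  hits <- local_align_set(unname(families), protein, matrix = matrix,
                          gap_open = gap_open, gap_extend = gap_extend)
  best <- which.max(hits$score)
  if (hits$score[best] < threshold) return(NULL)
  second <- if (nrow(hits) > 1) max(hits$score[-best]) else 0
  ref_span <- c(hits$p_start[best], hits$p_end[best])
  list(family_id = names(families)[best],
       score = hits$score[best],
       margin = hits$score[best] - second,
       coverage = (ref_span[2] - ref_span[1] + 1) / nchar(families[[best]]),
       ref_span = ref_span,
       query_span = c(hits$s_start[best], hits$s_end[best]))
}

#' Calibrate the family-assignment score threshold on shuffled queries
#'
#' Shuffles each family reference `n_shuffles` times, aligns every shuffle
#' against every reference, and returns the requested quantile of the null
#' score distribution (default the 99th percentile).
#'
#' @param families Named character vector of family reference proteins.
#' @param n_shuffles Shuffles per family.
#' @param prob Quantile of the null distribution to return.
#' @param seed RNG seed.
#' @inheritParams assign_family
#' @return Numeric threshold.
#' @export
calibrate_family_threshold <- function(families, n_shuffles = 20L,
                                       prob = 0.99, seed = 1L,
                                       matrix = "BLOSUM62",
                                       gap_open = 10, gap_extend = 1) {
  withr_seed(seed)
  shufs <- unlist(lapply(families, function(f)
    replicate(n_shuffles,
              paste(sample(strsplit(f, "")[[1]]), collapse = ""))))
  null_scores <- unlist(lapply(families, function(ref)
    local_align_set(shufs, ref, matrix = matrix, gap_open = gap_open,
                    gap_extend = gap_extend)$score))
  as.numeric(quantile(null_scores, prob))
}

# local RNG scope helper: set seed without clobbering the caller's stream
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

# fragment-level homology hits of an intron against family references;
# the workhorse shared by erosion calling and frameshift detection
family_fragment_hits <- function(intron_seq, families, genetic_code_id = 4L,
                                 frag_min_aa = 30L, frag_threshold = 60,
                                 matrix = "BLOSUM62", gap_open = 10,
                                 gap_extend = 1) {
  frags <- scan_orfs(intron_seq, genetic_code_id, min_aa = frag_min_aa,
                     mode = "fragment")
  hits <- list()
  if (length(frags)) {
    prots <- vapply(frags, `[[`, "", "protein")
    for (fi in seq_along(families)) {
      al <- local_align_set(prots, families[[fi]], matrix = matrix,
                            gap_open = gap_open, gap_extend = gap_extend)
      keep <- which(al$score >= frag_threshold)
      for (k in keep) {
        fr <- frags[[k]]
        hits[[length(hits) + 1L]] <- data.frame(
          family_id = names(families)[fi], frame = fr$frame,
          score = al$score[k],
          q_start_nt = fr$start + (al$p_start[k] - 1L) * 3L,
          q_end_nt = fr$start + al$p_end[k] * 3L - 1L,
          ref_start = al$s_start[k], ref_end = al$s_end[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(family_id = character(0), frame = integer(0),
                      score = numeric(0), q_start_nt = integer(0),
                      q_end_nt = integer(0), ref_start = integer(0),
                      ref_end = integer(0)))
  do.call(rbind, hits)
}

# evidence codes from the sorted fragment hits of one family
derive_evidence <- function(hits, ref_len, intact_cov, overlap_tol_aa = 20L) {
  hits <- hits[order(hits$ref_start, hits$q_start_nt), , drop = FALSE]
  evidence <- character(0)
  detail <- list()
  if (nrow(hits) > 1) {
    for (i in seq_len(nrow(hits) - 1L)) {
      h1 <- hits[i, ]; h2 <- hits[i + 1L, ]
      collinear <- h2$ref_start >= h1$ref_start &&
        h2$ref_end > h1$ref_end &&
        h1$ref_end - h2$ref_start <= overlap_tol_aa &&
        h2$q_start_nt > h1$q_start_nt
      if (!collinear) next
      if (h2$frame != h1$frame) {
        evidence <- c(evidence, "frameshift")
        detail[[length(detail) + 1L]] <- list(
          type = "frameshift", intron_pos = h1$q_end_nt,
          frames = c(h1$frame, h2$frame))
      } else {
        evidence <- c(evidence, "premature_stop")
        detail[[length(detail) + 1L]] <- list(
          type = "premature_stop", intron_pos = h1$q_end_nt)
      }
    }
  }
  cov_union <- covered_fraction(hits$ref_start, hits$ref_end, ref_len)
  if (min(hits$ref_start) > 0.1 * ref_len ||
      max(hits$ref_end) < 0.9 * ref_len) {
    evidence <- c(evidence, "truncated_terminus")
    detail[[length(detail) + 1L]] <- list(type = "truncated_terminus")
  }
  if (!length(evidence) && cov_union < intact_cov) {
    evidence <- "low_coverage"
    detail <- list(list(type = "low_coverage", coverage = cov_union))
  }
  list(evidence = unique(evidence), detail = detail, coverage = cov_union)
}

covered_fraction <- function(starts, ends, ref_len) {
  if (!length(starts)) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1L) cur_e <- max(cur_e, ends[i])
    else { total <- total + cur_e - cur_s + 1L; cur_s <- starts[i]; cur_e <- ends[i] }
  }
  (total + cur_e - cur_s + 1L) / ref_len
}

#' Call the integrity status of an intron-encoded heg
#'
#' Status is `"intact"` when a single start-to-stop ORF covers at least
#' `intact_cov` of its best family reference, including the reference
#' C-terminal region; `"eroded"` when family homology covers at least
#' `eroded_cov` of the reference but is split across frames, interrupted by
#' stops, or truncated; `"absent"` otherwise.
#'
#' @param intron An `intron_record` (from [gene_introns()]) or a DNA string.
#' @param families Named character vector of family reference proteins.
#' @param genetic_code_id NCBI translation table id.
#' @param min_aa Minimum ORF length for the intact scan.
#' @param intact_cov Reference coverage an intact ORF must reach (default 0.8).
#' @param eroded_cov Minimum homology coverage for an eroded call (default 0.3).
#' @param threshold Family-assignment score threshold (see [assign_family()]).
#' @param frag_min_aa,frag_threshold Fragment scan parameters for erosion
#'   evidence.
#' @param cterm_tol Fraction of the reference C-terminus an intact ORF may
#'   miss (default 0.1).
#' @return An object of class `heg_call`: `status`, `family_id`, `evidence`
#'   (character codes among `premature_stop`, `frameshift`,
#'   `truncated_terminus`, `low_coverage`), `evidence_detail`,
#'   `coverage_fraction`.
#' @export
call_heg <- function(intron, families, genetic_code_id = 4L, min_aa = 100L,
                     intact_cov = 0.8, eroded_cov = 0.3, threshold = 80,
                     frag_min_aa = 30L, frag_threshold = 60,
                     cterm_tol = 0.1) {
  seq <- if (inherits(intron, "intron_record")) intron$seq else intron
  mk <- function(status, family = NA_character_, evidence = character(0),
                 detail = list(), coverage = 0)
    structure(list(status = status, family_id = family, evidence = evidence,
                   evidence_detail = detail, coverage_fraction = coverage),
              class = "heg_call")

  orfs <- scan_orfs(seq, genetic_code_id, min_aa = min_aa, mode = "start")
  for (orf in head(orfs, 3L)) {
    af <- assign_family(orf$protein, families, threshold = threshold)
    if (is.null(af)) next
    ref_len <- nchar(families[[af$family_id]])
    reaches_cterm <- af$ref_span[2] >= (1 - cterm_tol) * ref_len
    if (af$coverage >= intact_cov && reaches_cterm) {
      # guard: homology continuing past the ORF in another frame betrays a
      # frameshift near the end rather than a clean full-length gene
      hits <- family_fragment_hits(seq, families[af$family_id],
                                   genetic_code_id, frag_min_aa,
                                   frag_threshold)
      ev <- derive_evidence(hits, ref_len, intact_cov)
      if (!any(ev$evidence %in% c("frameshift", "premature_stop")))
        return(mk("intact", af$family_id, coverage = af$coverage))
    }
  }

  hits <- family_fragment_hits(seq, families, genetic_code_id,
                               frag_min_aa, frag_threshold)
  if (!nrow(hits)) return(mk("absent"))
  cov_by_family <- vapply(split(hits, hits$family_id), function(h)
    covered_fraction(h$ref_start, h$ref_end, nchar(families[[h$family_id[1]]])),
    numeric(1))
  fam <- names(which.max(cov_by_family))
  if (cov_by_family[[fam]] < eroded_cov) return(mk("absent"))
  fh <- hits[hits$family_id == fam, , drop = FALSE]
  # an eroded call still needs unambiguous homology: the best fragment of
  # the family must clear the same score bar as full-length assignment
  if (max(fh$score) < threshold) return(mk("absent"))
  ev <- derive_evidence(fh, nchar(families[[fam]]), intact_cov)
  mk("eroded", fam, ev$evidence, ev$detail, ev$coverage)
}

#' @export
print.heg_call <- function(x, ...) {
  cat("<heg_call>", x$status,
      if (!is.na(x$family_id)) paste0("family=", x$family_id),
      if (length(x$evidence)) paste0("[", paste(x$evidence, collapse = ","), "]"),
      sprintf("coverage=%.2f", x$coverage_fraction), "\n")
  invisible(x)
}

#' Detect frameshift evidence against one family reference
#'
#' Translates the intron's stop-to-stop fragments in all three frames,
#' aligns them locally to the family reference and reports a frameshift
#' wherever consecutive collinear hits (increasing reference coordinates)
#' sit in different frames.
#'
#' @param intron_seq Intron DNA.
#' @param family_ref Single family reference protein.
#' @inheritParams call_heg
#' @return List of evidence entries, each with `type = "frameshift"`,
#'   `intron_pos` (approximate nt position) and `frames`.
#' @export
detect_frameshift <- function(intron_seq, family_ref, genetic_code_id = 4L,
                              frag_min_aa = 30L, frag_threshold = 60) {
  hits <- family_fragment_hits(intron_seq, c(ref = family_ref),
                               genetic_code_id, frag_min_aa, frag_threshold)
  if (nrow(hits) < 2) return(list())
  ev <- derive_evidence(hits, nchar(family_ref), intact_cov = 1)
  Filter(function(e) e$type == "frameshift", ev$detail)
}

#' Detect a chimeric (invader-in-recipient) heg configuration
#'
#' A chimera is called when an internal segment of the ORF aligns to one
#' family (the invader) while the ORF's prefix and suffix both align to a
#' single different family (the recipient), all within one reading frame.
#' Two adjacent family segments without a recipient suffix are flagged as
#' `"tandem not chimera"` (attribute `reason` on the `NULL` return).
#'
#' @param orf An `orf_hit` (from [scan_orfs()]) or a protein string.
#' @param families Named character vector of family reference proteins.
#' @param threshold Score threshold for the invader segment.
#' @param flank_threshold Score threshold for each recipient flank.
#' @param margin_aa Minimum distance (aa) of the invader segment from the
#'   ORF termini for it to count as internal.
#' @return A `chimera_report` (fields `recipient_family`, `invader_family`,
#'   `invader_span` — nt, 1-based within the ORF —, `in_frame`) or `NULL`.
#' @export
detect_chimera <- function(orf, families, threshold = 80,
                           flank_threshold = 60, margin_aa = 15L) {
  protein <- if (inherits(orf, "orf_hit")) orf$protein else orf
  n <- nchar(protein)
  al <- local_align_set(unname(families), protein, matrix = "BLOSUM62")
  sig <- which(al$score >= threshold)
  if (length(sig) < 2) return(NULL)
  internal <- sig[al$s_start[sig] > margin_aa &
                    al$s_end[sig] < n - margin_aa]
  if (!length(internal)) return(NULL)
  inv <- internal[which.max(al$score[internal])]
  inv_id <- names(families)[inv]
  span_aa <- c(al$s_start[inv], al$s_end[inv])
  prefix <- substr(protein, 1L, span_aa[1] - 1L)
  suffix <- substr(protein, span_aa[2] + 1L, n)
  others <- families[names(families) != inv_id]
  pre_scores <- setNames(
    local_align_set(unname(others), prefix, matrix = "BLOSUM62")$score,
    names(others))
  suf_scores <- setNames(
    local_align_set(unname(others), suffix, matrix = "BLOSUM62")$score,
    names(others))
  both <- pmin(pre_scores, suf_scores)
  if (max(both) >= flank_threshold) {
    recip <- names(which.max(both))
    return(structure(
      list(recipient_family = recip, invader_family = inv_id,
           invader_span = c((span_aa[1] - 1L) * 3L + 1L, span_aa[2] * 3L),
           in_frame = TRUE),
      class = "chimera_report"))
  }
  if (max(pre_scores) >= flank_threshold || max(suf_scores) >= flank_threshold)
    return(structure(list(reason = "tandem not chimera"),
                     class = "chimera_none"))
  NULL
}

#' Test whether a [detect_chimera()] result is a chimera call
#' @param x Result of [detect_chimera()].
#' @return Logical.
#' @export
is_chimera <- function(x) inherits(x, "chimera_report")

#' @export
print.chimera_report <- function(x, ...) {
  cat("<chimera_report> invader", x$invader_family, "inside recipient",
      x$recipient_family, "at nt", x$invader_span[1], "-", x$invader_span[2],
      if (x$in_frame) "(in frame)", "\n")
  invisible(x)
}
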