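# Pairwise alignment and identity/similarity statistics.
#
# Global (Needleman-Wunsch) and local (Smith-Waterman) affine-gap alignment
# is delegated to Biostrings::pairwiseAlignment; this module fixes the
# scoring convention the rest of the pipeline relies on and adds the
# identity/similarity accounting. Convention: a gap of length L costs
# gap_open + L * gap_extend (both given as positive costs). An exhaustive
# enumeration scorer ([align_score_exhaustive()]) is exported as an
# independent reference for validating optimality on short sequences.

.similarity_groups_default <- c(
  "STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY", "FYW"
)

guess_alphabet <- function(seq) {
  if (grepl("^[ACGTUN]*$", toupper(seq))) "DNA" else "protein"
}

resolve_matrix <- function(matrix, alphabet) {
  if (is.matrix(matrix)) return(list(mat = matrix, id = "custom"))
  if (identical(matrix, "auto"))
    matrix <- if (alphabet == "DNA") "DNA" else "BLOSUM62"
  if (matrix %in% c("BLOSUM62", "BLOSUM45")) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    return(list(mat = env[[matrix]], id = matrix))
  }
  if (matrix == "DNA") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 5, mismatch = -4, baseOnly = FALSE)
    return(list(mat = mat, id = "DNA+5/-4"))
  }
  stop("unknown substitution matrix: ", matrix)
}

new_alignment <- function(aligned_a, aligned_b, score, matrix_id,
                          gap_open, gap_extend, type) {
  structure(
    list(aligned_a = aligned_a, aligned_b = aligned_b, score = score,
         matrix_id = matrix_id, gap_open = gap_open,
         gap_extend = gap_extend, type = type),
    class = "pair_alignment"
  )
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat("<pair_alignment>", x$type, "score", x$score,
      paste0("(", x$matrix_id, ", gap ", x$gap_open, "/", x$gap_extend, ")\n"))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

check_alphabet <- function(seq, mat) {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), rownames(mat))
  if (length(bad))
    stop("alphabet error: residue '", bad[1],
         "' not in the substitution matrix")
}

align_impl <- function(a, b, matrix, gap_open, gap_extend, type) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  # both sequences decide the alphabet jointly: DNA only if both look like
  # nucleotide strings (short peptides over {A,C,G,T,N} are ambiguous and a
  # residue check against the matrix catches real mismatches)
  alpha <- if (guess_alphabet(a) == "DNA" && guess_alphabet(b) == "DNA")
    "DNA" else "protein"
  rm <- resolve_matrix(matrix, alpha)
  check_alphabet(a, rm$mat)
  check_alphabet(b, rm$mat)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = rm$mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = type)
  sc <- Biostrings::score(pa)
  if (type == "local" && sc <= 0) {
    return(new_alignment("", "", 0, rm$id, gap_open, gap_extend, type))
  }
  aln <- new_alignment(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    sc, rm$id, gap_open, gap_extend, type)
  if (type == "local") {
    aln$a_span <- c(Biostrings::start(Biostrings::pattern(pa)),
                    Biostrings::end(Biostrings::pattern(pa)))
    aln$b_span <- c(Biostrings::start(Biostrings::subject(pa)),
                    Biostrings::end(Biostrings::subject(pa)))
  }
  aln
}

# many-vs-one local alignment in a single vectorized call; patterns and
# subject swap freely under a symmetric matrix. Returns one row per pattern
# with the score and both spans (0-width spans for non-positive scores).
local_align_set <- function(patterns, subject, matrix = "auto",
                            gap_open = 10, gap_extend = 1) {
  rm <- resolve_matrix(matrix, guess_alphabet(subject))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BStringSet(patterns), Biostrings::BString(subject),
    substitutionMatrix = rm$mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  data.frame(
    score = Biostrings::score(pa),
    p_start = Biostrings::start(Biostrings::pattern(pa)),
    p_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa)))
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' Optimal global alignment under affine gap costs; terminal gaps are
#' penalized. Default protein scoring is BLOSUM62 with gap open 10 and
#' extend 1 (given as positive costs); DNA defaults to match +5 /
#' mismatch -4.
#'
#' @param a,b Sequences (both DNA or both protein). With `matrix = "auto"`
#'   the pair is scored as DNA only when both strings are nucleotide-like;
#'   a residue absent from the chosen matrix raises an alphabet error.
#' @param matrix `"auto"`, `"BLOSUM62"`, `"BLOSUM45"`, `"DNA"` or a numeric
#'   substitution matrix with residue dimnames.
#' @param gap_open,gap_extend Positive gap costs; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return A `pair_alignment`: gapped strings `aligned_a`/`aligned_b`,
#'   `score`, and the scoring parameters.
#' @export
global_align <- function(a, b, matrix = "auto", gap_open = 10, gap_extend = 1) {
  align_impl(a, b, matrix, gap_open, gap_extend, "global")
}

#' Local (Smith-Waterman) pairwise alignment
#'
#' Optimal local alignment under the same scoring convention as
#' [global_align()]. If no segment pair scores above zero the result is the
#' empty alignment with score 0. For non-empty results the matched spans are
#' returned in `a_span`/`b_span` (1-based inclusive).
#'
#' @inheritParams global_align
#' @return A `pair_alignment` with `a_span` and `b_span` fields.
#' @export
local_align <- function(a, b, matrix = "auto", gap_open = 10, gap_extend = 1) {
  align_impl(a, b, matrix, gap_open, gap_extend, "local")
}

#' Identity and similarity of an alignment
#'
#' Identity is the percentage of scored columns with identical residues;
#' similarity additionally counts substitutions within a conservation group
#' (default: the standard strong groups STA, NEQK, NHQK, NDEQ, QHRK, MILV,
#' MILF, HY, FYW). Scored columns exclude terminal-gap columns; internal
#' gaps count as mismatches.
#'
#' @param alignment A `pair_alignment`.
#' @param similarity_groups Character vector of residue groups.
#' @return List with `pct_identity`, `pct_similarity`, `n_columns_scored`.
#' @export
identity_stats <- function(alignment,
                           similarity_groups = .similarity_groups_default) {
  stopifnot(inherits(alignment, "pair_alignment"))
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  n <- length(a)
  if (!n) stop("degenerate alignment: no columns")
  # terminal-gap columns: leading/trailing runs of gap in either row
  lead <- max(match(FALSE, a == "-", nomatch = n + 1L),
              match(FALSE, b == "-", nomatch = n + 1L)) - 1L
  trail <- max(match(FALSE, rev(a) == "-", nomatch = n + 1L),
               match(FALSE, rev(b) == "-", nomatch = n + 1L)) - 1L
  keep <- seq_len(n)
  keep <- keep[keep > lead & keep <= n - trail]
  if (!length(keep)) stop("degenerate alignment: zero scored columns")
  a <- a[keep]; b <- b[keep]
  ident <- a == b & a != "-"
  grp <- function(ch) which(vapply(similarity_groups,
                                   function(g) grepl(ch, g, fixed = TRUE),
                                   logical(1)))
  simil <- ident
  for (i in which(!ident)) {
    if (a[i] == "-" || b[i] == "-") next
    if (length(intersect(grp(a[i]), grp(b[i])))) simil[i] <- TRUE
  }
  list(pct_identity = 100 * sum(ident) / length(keep),
       pct_similarity = 100 * sum(simil) / length(keep),
       n_columns_scored = length(keep))
}

#' Exhaustive-enumeration alignment score (reference implementation)
#'
#' Scores `a` against `b` by enumerating every gapped alignment (every
#' monotone path of match/insert/delete moves) and returning the maximum
#' score. Exponential in sequence length — intended only as an independent
#' optimality reference for short sequences (lengths <= ~8).
#'
#' @inheritParams global_align
#' @param local If `TRUE`, maximize over all substring pairs (and the empty
#'   alignment, score 0), i.e. the Smith-Waterman optimum.
#' @return Numeric scalar, the optimal score.
#' @export
align_score_exhaustive <- function(a, b, matrix = "auto", gap_open = 10,
                                   gap_extend = 1, local = FALSE) {
  alpha <- if (guess_alphabet(a) == "DNA" && guess_alphabet(b) == "DNA")
    "DNA" else "protein"
  rm <- resolve_matrix(matrix, alpha)
  ai <- match(strsplit(a, "")[[1]], rownames(rm$mat)) - 1L
  bi <- match(strsplit(b, "")[[1]], colnames(rm$mat)) - 1L
  if (anyNA(ai) || anyNA(bi)) stop("residue not in substitution matrix")
  enumerate_align_score(ai, bi, rm$mat, gap_open, gap_extend, local)
}
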