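# Reading/writing the formats the pipeline touches: a GenBank flat-file
# subset, FASTA, and the landscape TSV. All coordinates are 1-based
# inclusive (GenBank convention); reverse-strand genes are
# reverse-complemented on ingest so downstream code only ever sees the
# coding strand.

#' Construct a species record
#'
#' A `species_record` holds one species' annotated gene region: the
#' (coding-strand) sequence and a list of features, each feature a list with
#' elements `kind` (e.g. `"CDS"`, `"intron"`), `spans` (two-column integer
#' matrix of 1-based inclusive intervals), `strand` (`"+"` or `"-"`, the
#' original orientation) and `qualifiers` (named list of strings).
#'
#' @param species_id Short species label.
#' @param accession Accession string (may be `NA`).
#' @param sequence DNA string, coding strand, uppercase.
#' @param features List of feature lists (see Details).
#' @return An object of class `species_record`.
#' @export
species_record <- function(species_id, accession, sequence, features = list()) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  for (ft in features) {
    sp <- ft$spans
    if (any(sp[, 1] < 1L) || any(sp[, 2] > len) || any(sp[, 1] > sp[, 2]))
      stop("malformed feature: interval outside sequence [1, ", len, "]")
  }
  structure(
    list(species_id = species_id, accession = accession,
         sequence = sequence, features = features),
    class = "species_record"
  )
}

#' @export
print.species_record <- function(x, ...) {
  cat("<species_record>", x$species_id,
      if (!is.na(x$accession)) paste0("(", x$accession, ")"), "\n")
  cat("  sequence:", nchar(x$sequence), "nt;",
      length(x$features), "features\n")
  invisible(x)
}

new_feature <- function(kind, spans, strand = "+", qualifiers = list()) {
  spans <- matrix(as.integer(spans), ncol = 2)
  o <- order(spans[, 1])
  list(kind = kind, spans = spans[o, , drop = FALSE],
       strand = strand, qualifiers = qualifiers)
}

# ---- GenBank flat-file subset ------------------------------------------

parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]]", "", loc)
  if (grepl("[<>]", loc))
    stop("fuzzy location not supported: ", loc)
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (!length(parts)) stop("malformed feature: empty location")
  spans <- t(vapply(parts, function(p) {
    if (grepl("^\\d+\\.\\.\\d+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^\\d+$", p)) {
      rep(as.integer(p), 2L)
    } else stop("malformed feature: cannot parse location part '", p, "'")
  }, integer(2)))
  dimnames(spans) <- NULL
  list(spans = spans, complement = complement)
}

#' Read a single-record GenBank flat file
#'
#' Parses the subset of the GenBank format the pipeline needs: `LOCUS`
#' length, `ACCESSION`, the `FEATURES` table (location joins and simple
#' `/key="value"` qualifiers) and the `ORIGIN` sequence. If the CDS lies on
#' the complement strand the whole record is reverse-complemented so the
#' returned record is on the coding strand; the original orientation is kept
#' in each feature's `strand` field.
#'
#' @param path Path to a single-record GenBank flat file.
#' @param species_id Label for the record; defaults to the LOCUS name.
#' @return A [species_record()].
#' @export
read_genbank <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS line)")
  locus_fields <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  locus_name <- locus_fields[2]
  acc_i <- grep("^ACCESSION", lines)
  accession <- if (length(acc_i))
    strsplit(trimws(lines[acc_i[1]]), "\\s+")[[1]][2] else locus_name

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("no ORIGIN sequence in ", path)
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  seq_lines <- lines[(orig_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("no sequences in ORIGIN block")

  features <- list()
  if (length(feat_i)) {
    flines <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    # a feature key sits at column 6; qualifier/continuation lines at col 22
    key_at <- grepl("^ {5}\\S", flines)
    starts <- which(key_at)
    for (k in seq_along(starts)) {
      blk <- flines[starts[k]:(if (k < length(starts)) starts[k + 1L] - 1L
                               else length(flines))]
      kind <- sub("^ {5}(\\S+).*$", "\\1", blk[1])
      rest <- sub("^ {5}\\S+\\s*", "", blk[1])
      cont <- blk[-1]
      qual_start <- grep("^\\s*/", cont)
      loc_extra <- if (length(qual_start)) head(cont, qual_start[1] - 1L) else cont
      loc <- paste(c(rest, trimws(loc_extra)), collapse = "")
      quals <- list()
      if (length(qual_start)) {
        qlines <- trimws(cont[qual_start[1]:length(cont)])
        qtext <- paste(qlines, collapse = " ")
        for (m in regmatches(qtext, gregexpr('/[A-Za-z_]+(="[^"]*"|=[^ /]+)?', qtext))[[1]]) {
          key <- sub("^/([A-Za-z_]+).*$", "\\1", m)
          val <- if (grepl("=", m, fixed = TRUE))
            gsub('^"|"$', "", sub("^/[A-Za-z_]+=", "", m)) else TRUE
          quals[[key]] <- val
        }
      }
      pl <- parse_gb_location(loc)
      strand <- if (pl$complement) "-" else "+"
      features[[length(features) + 1L]] <-
        new_feature(kind, pl$spans, strand, quals)
    }
  }
  if (!any(vapply(features, function(f) f$kind == "CDS", logical(1))))
    stop("no gene model: record has no CDS feature")

  len <- nchar(sequence)
  for (ft in features)
    if (any(ft$spans[, 2] > len) || any(ft$spans[, 1] < 1L))
      stop("malformed feature: interval outside sequence [1, ", len, "]")

  cds <- features[[which(vapply(features, function(f) f$kind == "CDS",
                                logical(1)))[1]]]
  if (cds$strand == "-") {
    sequence <- revcomp(sequence)
    features <- lapply(features, function(ft) {
      sp <- ft$spans
      flipped <- cbind(len - sp[, 2] + 1L, len - sp[, 1] + 1L)
      new_feature(ft$kind, flipped, ft$strand, ft$qualifiers)
    })
  }
  species_record(species_id %||% locus_name, accession, sequence, features)
}

#' Write a species record as a GenBank-subset flat file
#'
#' Emits LOCUS, ACCESSION, FEATURES (CDS join plus any intron features) and
#' ORIGIN blocks; the counterpart of [read_genbank()] for simulator output.
#'
#' @param record A [species_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  len <- nchar(record$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA",
                     record$species_id, len), con)
  writeLines(sprintf("ACCESSION   %s",
                     if (is.na(record$accession)) record$species_id
                     else record$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (ft in record$features) {
    iv <- apply(ft$spans, 1, function(r)
      if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "..", r[2]))
    loc <- if (length(iv) > 1) paste0("join(", paste(iv, collapse = ","), ")")
           else iv
    writeLines(sprintf("     %-16s%s", ft$kind, loc), con)
    for (qk in names(ft$qualifiers)) {
      qv <- ft$qualifiers[[qk]]
      writeLines(if (isTRUE(qv)) sprintf("                     /%s", qk)
                 else sprintf('                     /%s="%s"', qk, qv), con)
    }
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    starts <- seq(p, min(p + 59L, len), by = 10L)
    chunk <- substring(record$sequence, starts, pmin(starts + 9L, len))
    writeLines(sprintf("%9d %s", p, tolower(paste(chunk, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---- FASTA --------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Ids are taken up to the first whitespace; sequences are uppercased and
#' gap characters (`-`, `.`) are stripped.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("no sequences in ", path))
  if (!length(set) || all(Biostrings::width(set) == 0L))
    stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate id in ", path, ": ", ids[duplicated(ids)][1])
  seqs <- toupper(gsub("[-.]", "", as.character(set)))
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- landscape TSV ------------------------------------------------------

#' Write a landscape matrix as TSV
#'
#' One row per position class, one column per species; cells are `"."`
#' (absent), `"intact"` or `"eroded"`. The writer and [read_landscape_tsv()]
#' round-trip bit-exactly.
#'
#' @param matrix A `landscape_matrix` (see [build_landscape()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "landscape_matrix"))
  m <- unclass(matrix)
  cells <- ifelse(m == "absent", ".", m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# intronscape landscape matrix; coordinates 1-based inclusive", con)
  writeLines(paste(c("pcl", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], cells[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a landscape matrix TSV written by [write_landscape_tsv()]
#'
#' @param path Path to the TSV.
#' @return A `landscape_matrix`.
#' @export
read_landscape_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  species <- fields[[1]][-1]
  rows <- fields[-1]
  m <- matrix("absent", nrow = length(rows), ncol = length(species),
              dimnames = list(vapply(rows, `[[`, "", 1L), species))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1]
    m[i, ] <- ifelse(vals == ".", "absent", vals)
  }
  structure(m, class = "landscape_matrix")
}

# ---- small sequence utilities ------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#' @param seq DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
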