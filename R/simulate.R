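# Phylogeny-driven synthetic-data generator. It emulates the generative
# process the comparative analysis assumes: a reference cox1-like gene whose
# CDS drifts along a species tree while site-specific intron families are
# gained (lateral-transfer semantics: a fresh, drifted copy of the family's
# ancestral sequence), lost (precise excision restoring the exon junction),
# eroded (frameshifts / premature stops injected into the heg) and, rarely,
# invaded by a heg of foreign-gene origin (chimera). Every event is logged,
# so each tip comes with complete ground truth.

.bases <- c("A", "C", "G", "T")

random_coding_dna <- function(n_codons_protein, genetic_code_id = 4L) {
  code <- genetic_code_table(genetic_code_id)
  sense <- names(code)[code != "*"]
  paste0("ATG",
         paste(sample(sense, n_codons_protein - 1L, replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Mutate a sequence by i.i.d. per-site substitution
#'
#' Each site is hit with probability `rate`; a hit redraws the base
#' uniformly from all four, so the expected mismatch fraction is
#' `3/4 * rate` (the one-shot Jukes-Cantor draw). With `synonymous_only`,
#' only substitutions that preserve the encoded protein are applied (the
#' sequence must then be an in-frame CDS).
#'
#' @param seq DNA string.
#' @param rate Per-site hit probability in `[0, 1]`.
#' @param seed Optional RNG seed; `NULL` uses the current RNG stream.
#' @param synonymous_only Restrict to protein-preserving substitutions.
#' @param genetic_code_id NCBI translation table for `synonymous_only`.
#' @return Mutated DNA string.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL, synonymous_only = FALSE,
                            genetic_code_id = 4L) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) withr_seed(seed)
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (!n || rate == 0) return(seq)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(seq)
  new <- sample(.bases, length(hit), replace = TRUE)
  if (!synonymous_only) {
    s[hit] <- new
    return(paste(s, collapse = ""))
  }
  stopifnot(n %% 3L == 0L)
  code <- genetic_code_table(genetic_code_id)
  for (k in seq_along(hit)) {
    i <- hit[k]
    ci <- (i - 1L) %/% 3L
    old_codon <- paste(s[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    cand <- s
    cand[i] <- new[k]
    new_codon <- paste(cand[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    if (code[[new_codon]] == code[[old_codon]]) s[i] <- new[k]
  }
  paste(s, collapse = "")
}

# drift an in-frame CDS without breaking it: substitutions that would create
# a premature stop are reverted, and the start codon is preserved
drift_coding <- function(dna, rate, genetic_code_id = 4L) {
  if (rate <= 0) return(dna)
  code <- genetic_code_table(genetic_code_id)
  mut <- mutate_sequence(dna, rate, genetic_code_id = genetic_code_id)
  n_codon <- nchar(dna) %/% 3L
  starts <- (seq_len(n_codon) - 1L) * 3L + 1L
  old_c <- substring(dna, starts, starts + 2L)
  new_c <- substring(mut, starts, starts + 2L)
  stop_made <- code[new_c] == "*" & code[old_c] != "*"
  new_c[stop_made] <- old_c[stop_made]
  new_c[1L] <- old_c[1L]
  paste(new_c, collapse = "")
}

#' Inject heg erosion
#'
#' `"frameshift"` applies a 1-2 nt indel, `"stop"` converts one internal
#' codon to TAA, `"both"` does both. Positions are drawn uniformly over the
#' central window of the gene (default the 10-80% span): an indel in the
#' last few codons neither functionally erodes an endonuclease nor leaves a
#' recognizable erosion signature, so the generator plants events that are
#' interpretable as erosion. Event positions are attached as the `events`
#' attribute.
#'
#' @param heg In-frame heg DNA (length >= 60 nt, multiple of 3).
#' @param mode `"frameshift"`, `"stop"` or `"both"`.
#' @param seed Optional RNG seed.
#' @param window Fractional position window for event placement.
#' @return Mutated DNA string with attribute `events` (list of
#'   `list(type, position)`; positions are nt in the input frame).
#' @export
inject_erosion <- function(heg, mode = c("frameshift", "stop", "both"),
                           seed = NULL, window = c(0.1, 0.8)) {
  mode <- match.arg(mode)
  if (!is.null(seed)) withr_seed(seed)
  n <- nchar(heg)
  stopifnot(n >= 60L, n %% 3L == 0L)
  events <- list()
  out <- heg
  if (mode %in% c("stop", "both")) {
    n_codon <- n %/% 3L
    j <- sample(seq(max(2L, ceiling(window[1] * n_codon)),
                    floor(window[2] * n_codon)), 1L)
    pos <- (j - 1L) * 3L + 1L
    out <- paste0(substr(out, 1L, pos - 1L), "TAA",
                  substr(out, pos + 3L, nchar(out)))
    events[[length(events) + 1L]] <- list(type = "stop", position = pos)
  }
  if (mode %in% c("frameshift", "both")) {
    pos <- sample(seq(max(2L, ceiling(window[1] * n)),
                      floor(window[2] * n)), 1L)
    k <- sample(1:2, 1L)
    if (runif(1) < 0.5) {
      out <- paste0(substr(out, 1L, pos - 1L),
                    substr(out, pos + k, nchar(out)))          # deletion
    } else {
      out <- paste0(substr(out, 1L, pos - 1L),
                    paste(sample(.bases, k, replace = TRUE), collapse = ""),
                    substr(out, pos, nchar(out)))              # insertion
    }
    events[[length(events) + 1L]] <- list(type = "frameshift", position = pos)
  }
  attr(out, "events") <- events
  out
}

#' Plant an invader heg inside a recipient heg, in frame
#'
#' Inserts the invader at a uniformly drawn internal codon boundary of the
#' recipient (at least 20 codons from either end). Both sequences must be
#' in frame (length divisible by 3); the caller supplies the invader
#' without its terminal stop so the composite stays one open reading frame.
#'
#' @param recipient_heg,invader_heg In-frame DNA strings.
#' @param seed Optional RNG seed.
#' @return Composite DNA string (length = sum of input lengths) with
#'   attribute `insert_at_nt`, the recipient nt count preceding the invader.
#' @export
plant_chimera <- function(recipient_heg, invader_heg, seed = NULL) {
  if (!is.null(seed)) withr_seed(seed)
  nr <- nchar(recipient_heg)
  stopifnot(nr %% 3L == 0L, nchar(invader_heg) %% 3L == 0L,
            nr >= 41L * 3L)
  j <- sample(seq(20L, nr %/% 3L - 21L), 1L)   # codon boundary
  at <- j * 3L
  out <- paste0(substr(recipient_heg, 1L, at), invader_heg,
                substr(recipient_heg, at + 1L, nr))
  attr(out, "insert_at_nt") <- at
  out
}

#' Insert intron sequences into a CDS
#'
#' The inverse of [splice_cds()]: introns are placed after the given CDS
#' offsets, and the resulting exon structure is returned so a
#' [species_record()] can be annotated.
#'
#' @param cds CDS string.
#' @param offsets Integer vector, number of CDS nt 5' of each intron.
#' @param seqs Character vector of intron sequences (same length).
#' @return List: `sequence` (gene with introns), `exons` (two-column
#'   matrix, gene coordinates), `intron_spans` (two-column matrix, in input
#'   order).
#' @export
insert_introns <- function(cds, offsets, seqs) {
  stopifnot(length(offsets) == length(seqs),
            all(offsets >= 0), all(offsets <= nchar(cds)),
            !anyDuplicated(offsets))
  o <- order(offsets)
  offsets <- offsets[o]; seqs_s <- seqs[o]
  bounds <- c(0L, offsets, nchar(cds))
  pieces <- substring(cds, head(bounds, -1) + 1L, bounds[-1])
  gene <- pieces[1]
  exons <- matrix(c(1L, nchar(pieces[1])), ncol = 2)
  spans <- matrix(integer(0), ncol = 2)
  for (i in seq_along(seqs_s)) {
    s0 <- nchar(gene)
    gene <- paste0(gene, seqs_s[i])
    spans <- rbind(spans, c(s0 + 1L, nchar(gene)))
    e0 <- nchar(gene)
    gene <- paste0(gene, pieces[i + 1L])
    exons <- rbind(exons, c(e0 + 1L, nchar(gene)))
  }
  # exons of zero length (adjacent introns) are impossible here because
  # offsets are distinct; but a trailing empty piece can occur if an intron
  # sits at the very end of the CDS
  keep <- exons[, 2] >= exons[, 1]
  list(sequence = gene, exons = exons[keep, , drop = FALSE],
       intron_spans = spans[order(o), , drop = FALSE])
}

#' Default simulation configuration
#'
#' The defaults define the study conditions all simulation-based validation
#' runs under: 50 species, 20 cox1 intron families plus 2 foreign-origin
#' (cob-like) invader families, a loss-dominated regime
#' (loss 0.5 / gain 0.15 / erosion 0.3 events per branch-length unit on a
#' coalescent tree rescaled to depth 1), 5% per-site substitution pressure
#' per unit branch length, and a low chimera rate.
#'
#' @param n_species,n_families,n_foreign_families Cohort dimensions.
#' @param gain_rate,loss_rate,erosion_rate Events per branch-length unit.
#' @param substitution_rate Per-site hit probability per branch-length unit.
#' @param chimera_rate Chimera events per branch-length unit.
#' @param gain_divergence Drift applied to the ancestral copy on a gain.
#' @param ref_len_aa Reference protein length (COX1-like, default 520 aa).
#' @param heg_len_aa Family heg length (default 250 aa).
#' @param tree Optional `phylo` or newick string/file; default a random
#'   coalescent tree.
#' @param tree_depth Height the tree is rescaled to.
#' @param seed RNG seed fixing all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 50L, n_families = 20L,
                       n_foreign_families = 2L,
                       gain_rate = 0.15, loss_rate = 0.5,
                       erosion_rate = 0.3, substitution_rate = 0.05,
                       chimera_rate = 0.01, gain_divergence = 0.05,
                       ref_len_aa = 520L, heg_len_aa = 250L,
                       tree = NULL, tree_depth = 1.0, seed = 1L) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, erosion_rate >= 0,
            substitution_rate >= 0, chimera_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

read_config_tree <- function(tree, n_species) {
  if (is.null(tree)) {
    tr <- ape::rcoal(n_species, tip.label = sprintf("sp%02d",
                                                    seq_len(n_species)))
  } else if (inherits(tree, "phylo")) {
    tr <- tree
  } else if (file.exists(tree)) {
    tr <- ape::read.tree(tree)
  } else {
    tr <- ape::read.tree(text = tree)
  }
  tr
}

make_intron_families <- function(config) {
  n <- config$n_families
  nf <- config$n_foreign_families
  residues <- sample(seq(10L, config$ref_len_aa - 10L), n)
  phases <- sample(0:2, n, replace = TRUE)
  if (anyDuplicated(paste(residues, phases)))
    stop("site collision in family sites")
  fams <- vector("list", n + nf)
  for (i in seq_len(n + nf)) {
    heg <- random_coding_dna(config$heg_len_aa)
    foreign <- i > n
    fams[[i]] <- list(
      family_id = if (foreign) sprintf("COB%02d", i - n)
                  else sprintf("F%02d", i),
      site = if (foreign) NULL
             else list(ref_residue = residues[i], phase = phases[i]),
      group_label = "I",
      gene_of_origin = if (foreign) "cob" else "cox1",
      ancestral_heg = heg,
      core5 = paste(sample(.bases, 90L, replace = TRUE), collapse = ""),
      core3 = paste0(paste(sample(.bases, 59L, replace = TRUE),
                           collapse = ""), "G"))
  }
  names(fams) <- vapply(fams, `[[`, "", "family_id")
  fams
}

#' Simulate an intron landscape on a phylogeny
#'
#' Gains, losses, erosions and chimera invasions are placed per branch with
#' Poisson event counts (`rate * branch length`); sequences drift by
#' per-site substitution, with reading frames of intact heg and of the CDS
#' protected (a drifted intact heg stays an open reading frame). Identical
#' seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_landscape`: `records` (list of
#'   [species_record()]), `tip_cds` (named vector of the spliced CDS each
#'   tip should yield), `truth` (list with `tips` and `events` data
#'   frames), `families`, `family_proteins` (named vector, foreign families
#'   included), `reference` (list `cds`, `protein`), `taxonomy`, `tree`,
#'   `config`.
#' @export
simulate_landscape <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed)
  tree <- read_config_tree(config$tree, config$n_species)
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth > 0) tree$edge.length <- tree$edge.length / depth * config$tree_depth
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)

  families <- make_intron_families(config)
  planted <- Filter(function(f) !is.null(f$site), families)
  foreign <- Filter(function(f) is.null(f$site), families)
  root_cds <- random_coding_dna(config$ref_len_aa)

  root_state <- list(
    cds = root_cds,
    fam = lapply(planted, function(f)
      list(present = TRUE, status = "intact", chimera = FALSE,
           invader = NA_character_,
           heg = f$ancestral_heg, core5 = f$core5, core3 = f$core3))
  )

  events <- list()
  log_event <- function(node, fam, type) {
    events[[length(events) + 1L]] <<- data.frame(
      node = node, family_id = fam, event = type, stringsAsFactors = FALSE)
  }

  evolve <- function(state, bl, child_node) {
    for (fid in names(state$fam)) {
      fs <- state$fam[[fid]]
      if (fs$present && rpois(1L, config$loss_rate * bl) > 0L) {
        fs$present <- FALSE
        log_event(child_node, fid, "loss")
      }
      if (!fs$present && rpois(1L, config$gain_rate * bl) > 0L) {
        f <- planted[[fid]]
        fs <- list(present = TRUE, status = "intact", chimera = FALSE,
                   invader = NA_character_,
                   heg = drift_coding(f$ancestral_heg,
                                      config$gain_divergence),
                   core5 = mutate_sequence(f$core5, config$gain_divergence),
                   core3 = keep_terminal_g(
                     mutate_sequence(f$core3, config$gain_divergence)))
        log_event(child_node, fid, "gain")
      }
      if (fs$present && fs$status == "intact" &&
          rpois(1L, config$erosion_rate * bl) > 0L) {
        mode <- sample(c("frameshift", "stop", "both"), 1L)
        fs$heg <- strip_attrs(inject_erosion(fs$heg, mode))
        fs$status <- "eroded"
        log_event(child_node, fid, paste0("erosion_", mode))
      }
      if (fs$present && fs$status == "intact" && !fs$chimera &&
          length(foreign) &&
          runif(1L) < 1 - exp(-config$chimera_rate * bl)) {
        inv <- foreign[[sample(length(foreign), 1L)]]
        inv_core <- substr(inv$ancestral_heg, 1L,
                           nchar(inv$ancestral_heg) - 3L)
        fs$heg <- strip_attrs(plant_chimera(fs$heg, inv_core))
        fs$chimera <- TRUE
        fs$invader <- inv$family_id
        log_event(child_node, fid, paste0("chimera_", inv$family_id))
      }
      state$fam[[fid]] <- fs
    }
    # sequence drift
    sub <- config$substitution_rate * bl
    state$cds <- drift_coding(state$cds, sub)
    for (fid in names(state$fam)) {
      fs <- state$fam[[fid]]
      if (!fs$present) next
      fs$heg <- if (fs$status == "intact") drift_coding(fs$heg, sub)
                else mutate_sequence(fs$heg, sub)
      fs$core5 <- mutate_sequence(fs$core5, sub)
      fs$core3 <- keep_terminal_g(mutate_sequence(fs$core3, sub))
      state$fam[[fid]] <- fs
    }
    state
  }

  states <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  states[[root]] <- root_state
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    states[[child]] <- evolve(states[[parent]], tree$edge.length[e], child)
  }

  records <- list()
  truth_rows <- list()
  tip_cds <- character(0)
  for (tip in seq_len(n_tip)) {
    sp <- tree$tip.label[tip]
    st <- states[[tip]]
    pres <- Filter(function(fid) st$fam[[fid]]$present, names(st$fam))
    offsets <- vapply(pres, function(fid) {
      s <- planted[[fid]]$site
      (s$ref_residue - 1L) * 3L + s$phase
    }, integer(1))
    iseqs <- vapply(pres, function(fid) {
      fs <- st$fam[[fid]]
      paste0(fs$core5, fs$heg, fs$core3)
    }, character(1))
    if (length(pres)) {
      ins <- insert_introns(st$cds, offsets, iseqs)
      o <- order(offsets)
      feats <- c(list(new_feature("CDS", ins$exons)),
                 lapply(seq_along(o), function(k) {
                   new_feature("intron",
                               ins$intron_spans[o[k], , drop = FALSE],
                               qualifiers = list(number = as.character(k)))
                 }))
      rec <- species_record(sp, NA_character_, ins$sequence, feats)
      spans <- ins$intron_spans
    } else {
      rec <- species_record(sp, NA_character_, st$cds,
                            list(new_feature("CDS",
                                             matrix(c(1L, nchar(st$cds)),
                                                    ncol = 2))))
      spans <- NULL
    }
    records[[sp]] <- rec
    tip_cds[[sp]] <- st$cds
    for (fid in names(st$fam)) {
      fs <- st$fam[[fid]]
      k <- match(fid, pres)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        species_id = sp, family_id = fid, present = fs$present,
        heg_status = if (fs$present) fs$status else NA_character_,
        chimera = fs$present && fs$chimera,
        invader = if (fs$present) fs$invader else NA_character_,
        intron_start = if (!is.na(k)) spans[k, 1] else NA_integer_,
        intron_end = if (!is.na(k)) spans[k, 2] else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }

  family_proteins <- vapply(families, function(f)
    strip_attrs(translate_cds(f$ancestral_heg)), character(1))
  structure(
    list(records = records,
         tip_cds = tip_cds,
         truth = list(
           tips = do.call(rbind, truth_rows),
           events = if (length(events)) do.call(rbind, events)
                    else data.frame(node = integer(0),
                                    family_id = character(0),
                                    event = character(0))),
         families = families,
         family_proteins = family_proteins,
         reference = list(cds = root_cds,
                          protein = strip_attrs(translate_cds(root_cds))),
         taxonomy = synth_taxonomy(tree),
         tree = tree, config = config),
    class = "sim_landscape")
}

keep_terminal_g <- function(seq) {
  paste0(substr(seq, 1L, nchar(seq) - 1L), "G")
}

strip_attrs <- function(x) { attributes(x) <- NULL; x }

#' Synthetic taxonomy for a simulated cohort
#'
#' Tips are assigned to two kingdoms by the root split (the larger clade is
#' labelled Fungi), and to phyla/orders by average-linkage clustering of
#' the cophenetic distances — a stand-in taxonomy consistent with the tree,
#' for rarity labelling and cross-kingdom summaries.
#'
#' @param tree A `phylo` object.
#' @return Data frame: `species_id`, `genus`, `order`, `phylum`, `kingdom`.
#' @export
synth_taxonomy <- function(tree) {
  n <- length(tree$tip.label)
  kingdom <- rep("Fungi", n)
  if (n >= 4 && tree$Nnode >= 2) {
    root <- n + 1L
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    clades <- lapply(kids, function(k)
      if (k <= n) k else ape::prop.part(tree) |>
        (function(pp) which(seq_len(n) %in% pp[[k - n]]))())
    sizes <- lengths(clades)
    small <- clades[[which.min(sizes)]]
    if (length(small) < n) kingdom[small] <- "Viridiplantae"
  }
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  hc <- stats::hclust(d, method = "average")
  n_ord <- max(2L, round(n / 6))
  n_phy <- max(2L, round(n / 12))
  data.frame(
    species_id = tree$tip.label,
    genus = tree$tip.label,
    order = sprintf("ord%02d", stats::cutree(hc, k = min(n_ord, n))),
    phylum = sprintf("phy%02d", stats::cutree(hc, k = min(n_phy, n))),
    kingdom = kingdom,
    stringsAsFactors = FALSE)
}
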