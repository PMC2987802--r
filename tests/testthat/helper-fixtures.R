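# Shared fixtures, all built in code at test time.

withr_local_file <- function(name) {
  tempfile(pattern = paste0(sub("\\.[^.]*$", "", name), "-"),
           fileext = sub("^[^.]*", "", name))
}

# a handcrafted 300-nt GenBank record with CDS join(1..60,161..300)
toy_genbank_text <- function(cds_loc = "join(1..60,161..300)",
                             seq_len = 300L, seed = 11L) {
  set.seed(seed)
  s <- paste(sample(c("a", "c", "g", "t"), seq_len, replace = TRUE),
             collapse = "")
  c("LOCUS       TOY001 300 bp    DNA     linear   UNA",
    "ACCESSION   TOY001",
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             %s", cds_loc),
    '                     /gene="cox1"',
    "ORIGIN",
    vapply(seq(1L, seq_len, by = 60L), function(p) {
      starts <- seq(p, min(p + 59L, seq_len), by = 10L)
      sprintf("%9d %s", p,
              paste(substring(s, starts, pmin(starts + 9L, seq_len)),
                    collapse = " "))
    }, character(1)),
    "//")
}

write_toy_genbank <- function(path, ...) {
  writeLines(toy_genbank_text(...), path)
  path
}

# random protein / DNA helpers
random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# an in-frame heg-like gene: ATG + stop-free codons + TAA
random_heg <- function(n_aa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::getGeneticCode("4")
  sense <- names(code)[code != "*"]
  paste0("ATG", paste(sample(sense, n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

# wrap a heg in intron context: random core flanks, group-I terminal G
wrap_intron <- function(heg, core5 = 90L, core3 = 60L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(random_dna(core5),
         heg,
         paste0(substr(random_dna(core3), 1L, core3 - 1L), "G"))
}

# small simulated cohort, computed once per test run
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_landscape(sim_config(n_species = 10L,
                                              n_families = 6L, seed = 301L))
    cache
  }
})

# truth-derived pcl list (no alignment): one pcl per family with present
# members, named by site order
truth_pcls <- function(sim) {
  tp <- sim$truth$tips[sim$truth$tips$present, ]
  fams <- sim$families[unique(tp$family_id)]
  proj <- do.call(rbind, lapply(seq_len(nrow(tp)), function(i) {
    s <- fams[[tp$family_id[i]]]$site
    data.frame(species_id = tp$species_id[i], ordinal = NA_integer_,
               ref_residue = s$ref_residue, phase = s$phase,
               heg_status = tp$heg_status[i],
               stringsAsFactors = FALSE)
  }))
  name_pcls(cluster_pcls(proj))
}
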