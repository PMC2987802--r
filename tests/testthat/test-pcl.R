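mk_site <- function(codon, phase) {
  structure(list(codon_index = codon, phase = phase), class = "site_in_cds")
}

test_that("site projection maps through protein alignments", {
  ref <- random_protein(100, seed = 81)
  # identical proteins: identity mapping
  ps <- project_site(mk_site(60L, 1L), ref, ref)
  expect_equal(ps$ref_residue, 60L)
  expect_equal(ps$phase, 1L)
  expect_equal(ps$confidence, "aligned")
  # a 5-residue insertion upstream shifts the mapping by -5
  species <- paste0(substr(ref, 1, 20), "WWWWW", substr(ref, 21, 100))
  ps2 <- project_site(mk_site(60L, 2L), species, ref)
  expect_equal(ps2$ref_residue, 55L)
  expect_equal(ps2$phase, 2L)
  # a site inside the inserted block has no reference column: nearest
  # aligned column, flagged
  ps3 <- project_site(mk_site(23L, 0L), species, ref)
  expect_equal(ps3$confidence, "gap_adjacent")
  expect_true(ps3$ref_residue %in% c(20L, 21L))
})

test_that("pcl clustering groups exact sites and respects phase", {
  proj <- data.frame(
    species_id = c("a", "b", "c", "d"),
    ordinal = 1L,
    ref_residue = c(50L, 50L, 50L, 120L),
    phase = c(1L, 1L, 2L, 0L))
  pcls <- cluster_pcls(proj)
  expect_length(pcls, 3L)
  sizes <- sort(unname(vapply(pcls, function(p) nrow(p$members),
                              integer(1))))
  expect_equal(sizes, c(1L, 1L, 2L))
  # one intron, one pcl
  expect_length(cluster_pcls(proj[1, ]), 1L)
  # tolerance 1 merges adjacent same-phase sites
  proj2 <- data.frame(species_id = c("a", "b"), ordinal = 1L,
                      ref_residue = c(50L, 51L), phase = 1L)
  expect_length(cluster_pcls(proj2, tolerance_residues = 0L), 2L)
  expect_length(cluster_pcls(proj2, tolerance_residues = 1L), 1L)
})

test_that("pcl names run A..Z then AA.. in site order", {
  proj <- data.frame(species_id = sprintf("s%02d", 1:35), ordinal = 1L,
                     ref_residue = sample(seq(5, 500, length.out = 35)),
                     phase = 0L)
  pcls <- name_pcls(cluster_pcls(proj))
  expect_equal(names(pcls)[1], "A")
  expect_equal(names(pcls)[26], "Z")
  expect_equal(names(pcls)[27], "AA")
  expect_equal(names(pcls)[35], "AI")
  # name order agrees with 5'->3' site order
  sites <- vapply(pcls, function(p) p$site$ref_residue, numeric(1))
  expect_true(all(diff(sites) > 0))
})

test_that("pcl partition is invariant under input order and labels", {
  sim <- sim_small()
  tp <- sim$truth$tips[sim$truth$tips$present, ]
  fams <- sim$families
  proj <- data.frame(
    species_id = tp$species_id, ordinal = seq_len(nrow(tp)),
    ref_residue = vapply(tp$family_id,
                         function(f) fams[[f]]$site$ref_residue, integer(1)),
    phase = vapply(tp$family_id,
                   function(f) fams[[f]]$site$phase, integer(1)))
  key <- function(pcls) {
    lapply(pcls, function(p)
      sort(paste(p$members$species_id, p$members$ordinal)))
  }
  p1 <- name_pcls(cluster_pcls(proj))
  set.seed(82)
  p2 <- name_pcls(cluster_pcls(proj[sample(nrow(proj)), ]))
  expect_identical(key(p1), key(p2))
})

test_that("identity structure validation flags mislabeled members only", {
  set.seed(83)
  # three families, two intact members each, members ~10% diverged
  fams <- replicate(3, random_heg(120))
  prot <- function(d) intronscape:::strip_attrs(translate_cds(d))
  members <- list()
  proj <- list()
  for (i in 1:3) {
    for (j in 1:2) {
      key <- paste0("sp", i, j, ":1")
      members[[key]] <- prot(intronscape:::drift_coding(fams[[i]], 0.1))
      proj[[length(proj) + 1L]] <- data.frame(
        species_id = paste0("sp", i, j), ordinal = 1L,
        ref_residue = i * 50L, phase = 0L,
        heg_status = "intact")
    }
  }
  proj <- do.call(rbind, proj)
  pcls <- name_pcls(cluster_pcls(proj))
  rep_clean <- validate_identity_structure(pcls, unlist(members))
  expect_equal(nrow(rep_clean), 6L)
  expect_false(any(rep_clean$violation))
  # move one member of family 3 into the family-1 pcl
  proj_bad <- proj
  proj_bad$ref_residue[proj_bad$species_id == "sp32"] <- 50L
  pcls_bad <- name_pcls(cluster_pcls(proj_bad))
  rep_bad <- validate_identity_structure(pcls_bad, unlist(members))
  expect_true(rep_bad$violation[rep_bad$member == "sp32:1"])
  # single-member pcls are not comparable
  one <- cluster_pcls(proj[c(1, 3, 5), ])
  expect_equal(nrow(validate_identity_structure(name_pcls(one),
                                                unlist(members))), 0L)
})

test_that("rarity labelling follows the single-species / one-order rule", {
  tax <- data.frame(
    species_id = c("a", "b", "c", "d", "e"),
    genus = letters[1:5],
    order = c("o1", "o1", "o1", "o1", "o2"),
    phylum = c("p1", "p1", "p1", "p1", "p2"),
    kingdom = c("Fungi", "Fungi", "Fungi", "Fungi", "Viridiplantae"))
  mk_pcl <- function(sp) {
    structure(list(name = "A",
                   site = list(ref_residue = 10L, phase = 0L),
                   members = data.frame(species_id = sp, ordinal = 1L,
                                        ref_residue = 10L, phase = 0L,
                                        heg_status = "intact"),
                   rarity = NA_character_), class = "pcl")
  }
  expect_equal(label_rarity(mk_pcl("a"), tax), "rare")
  expect_equal(label_rarity(mk_pcl(c("a", "b", "c", "d")), tax), "rare")
  expect_equal(label_rarity(mk_pcl(c("a", "e")), tax), "widespread")
  expect_error(label_rarity(mk_pcl("zz"), tax), "unknown taxon")
})
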