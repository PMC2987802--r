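test_that("zero rates leave every tip identical to the root state", {
  cfg <- sim_config(n_species = 6L, n_families = 4L, gain_rate = 0,
                    loss_rate = 0, erosion_rate = 0,
                    substitution_rate = 0, chimera_rate = 0, seed = 101L)
  sim <- simulate_landscape(cfg)
  tp <- sim$truth$tips
  expect_true(all(tp$present))
  expect_true(all(tp$heg_status == "intact"))
  expect_false(any(tp$chimera))
  seqs <- vapply(sim$records, `[[`, "", "sequence")
  expect_length(unique(seqs), 1L)
  expect_equal(nrow(sim$truth$events), 0L)
})

test_that("identical seeds reproduce identical cohorts", {
  cfg <- sim_config(n_species = 6L, n_families = 4L, seed = 102L)
  s1 <- simulate_landscape(cfg)
  s2 <- simulate_landscape(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$records, `[[`, "sequence"),
                   lapply(s2$records, `[[`, "sequence"))
  s3 <- simulate_landscape(sim_config(n_species = 6L, n_families = 4L,
                                      seed = 103L))
  expect_false(identical(s1$truth$tips, s3$truth$tips))
})

test_that("intron loss accumulates with the loss rate", {
  frac_intronless <- function(loss_rate, seed) {
    cfg <- sim_config(n_species = 8L, n_families = 5L, gain_rate = 0.02,
                      loss_rate = loss_rate, erosion_rate = 0,
                      substitution_rate = 0, chimera_rate = 0,
                      tree_depth = 2, seed = seed)
    tp <- simulate_landscape(cfg)$truth$tips
    pc <- tapply(tp$present, tp$species_id, sum)
    mean(pc == 0)
  }
  seeds <- 1:20
  f_low <- mean(vapply(seeds, function(s) frac_intronless(0.3, s), 0))
  f_mid <- mean(vapply(seeds, function(s) frac_intronless(1.5, s), 0))
  f_high <- mean(vapply(seeds, function(s) frac_intronless(6, s), 0))
  expect_lte(f_low, f_mid)
  expect_lte(f_mid, f_high)
  expect_gt(f_high, f_low)
})

test_that("per-site mutation hits the expected mismatch fraction", {
  s <- random_dna(9000, seed = 104)
  expect_identical(mutate_sequence(s, 0), s)
  set.seed(105)
  m <- mutate_sequence(s, 0.2)
  mism <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  # a hit redraws uniformly over 4 bases: expected mismatch = 0.15
  sigma <- sqrt(0.15 * 0.85 / 9000)
  expect_lt(abs(mism - 0.15), 3 * sigma)
  # synonymous-only mutation never changes the protein
  heg <- random_heg(200, seed = 106)
  syn <- mutate_sequence(heg, 0.3, seed = 107, synonymous_only = TRUE)
  expect_identical(intronscape:::strip_attrs(translate_cds(syn)),
                   intronscape:::strip_attrs(translate_cds(heg)))
  expect_false(identical(syn, heg))
})

test_that("erosion injection leaves the advertised signature", {
  heg <- random_heg(150, seed = 108)
  fs <- inject_erosion(heg, "frameshift", seed = 109)
  ev <- attr(fs, "events")
  expect_equal(ev[[1]]$type, "frameshift")
  expect_true(abs(nchar(fs) - nchar(heg)) %in% 1:2)
  # downstream translation differs from the original
  pos <- ev[[1]]$position
  expect_false(identical(substr(fs, pos, pos + 60), substr(heg, pos, pos + 60)))

  st <- inject_erosion(heg, "stop", seed = 110)
  expect_equal(nchar(st), nchar(heg))
  p_old <- translate_cds(heg)
  p_new <- translate_cds(intronscape:::strip_attrs(st))
  expect_false(attr(p_old, "premature_stop"))
  expect_true(attr(p_new, "premature_stop"))
  # exactly one new internal stop
  expect_equal(sum(strsplit(p_new, "")[[1]] == "*"), 1L)
})

test_that("chimera planting conserves length and the open frame", {
  rec <- random_heg(150, seed = 111)
  inv_full <- random_heg(130, seed = 112)
  inv <- substr(inv_full, 1, nchar(inv_full) - 3)
  comp <- plant_chimera(rec, inv, seed = 113)
  expect_equal(nchar(comp), nchar(rec) + nchar(inv))
  # still one open reading frame end-to-end
  p <- translate_cds(intronscape:::strip_attrs(comp))
  expect_false(attr(p, "premature_stop"))
  at <- attr(comp, "insert_at_nt")
  expect_equal(substr(comp, at + 1, at + nchar(inv)), inv,
               ignore_attr = TRUE)
})

test_that("simulated records splice back to the drifted tip CDS", {
  sim <- sim_small()
  for (sp in names(sim$records)) {
    m <- build_gene_model(sim$records[[sp]])
    expect_identical(splice_cds(m), sim$tip_cds[[sp]])
  }
  # and the insert/splice round trip is the identity on arbitrary sets
  cds <- sim$reference$cds
  set.seed(114)
  offs <- sample(seq(3, nchar(cds) - 3, by = 3), 4)
  ins <- insert_introns(cds, offs, vapply(1:4, function(i)
    wrap_intron(random_heg(40)), ""))
  rec <- species_record("rt", NA, ins$sequence,
                        list(intronscape:::new_feature("CDS", ins$exons)))
  expect_identical(splice_cds(build_gene_model(rec)), cds)
})

test_that("truth intron spans line up with the annotated gene models", {
  sim <- sim_small()
  tp <- sim$truth$tips[sim$truth$tips$present, ]
  for (sp in unique(tp$species_id)) {
    m <- build_gene_model(sim$records[[sp]])
    spans <- vapply(gene_introns(m), function(i) c(i$start, i$end),
                    integer(2))
    ts <- tp[tp$species_id == sp, ]
    expect_setequal(spans[1, ], ts$intron_start)
    expect_setequal(spans[2, ], ts$intron_end)
  }
})
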