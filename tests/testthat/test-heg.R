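# Fixtures: three divergent heg families of 150 aa (small, to keep
# alignments cheap); introns wrap a heg in random core flanks.
heg_families <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(41)
      hegs <- replicate(3, random_heg(150))
      cache <<- list(
        dna = setNames(hegs, c("F1", "F2", "F3")),
        prot = setNames(vapply(hegs, function(h) {
          p <- translate_cds(h); attributes(p) <- NULL; p
        }, character(1)), c("F1", "F2", "F3")))
    }
    cache
  }
})

test_that("planted ORFs are recovered exactly", {
  fam <- heg_families()
  set.seed(42)
  intron <- wrap_intron(fam$dna[["F1"]])
  orfs <- scan_orfs(intron, min_aa = 100)
  expect_gte(length(orfs), 1L)
  top <- orfs[[1]]
  # the ORF may extend upstream to an earlier in-frame ATG in the core, but
  # it must end exactly at the heg stop and contain the full heg protein
  expect_equal(top$end, 90L + 453L - 3L)
  expect_gte(top$length_aa, 150L)
  expect_true(endsWith(top$protein, fam$prot[["F1"]]))
})

test_that("stop-riddled sequences yield no ORFs", {
  allstop <- paste(rep("TAA", 120), collapse = "")
  expect_length(scan_orfs(allstop, min_aa = 100), 0L)
})

test_that("a frameshift splits an ORF into sub-ORFs", {
  fam <- heg_families()
  heg <- fam$dna[["F1"]]
  broken <- paste0(substr(heg, 1, 225), substr(heg, 227, nchar(heg)))
  frs <- scan_orfs(broken, min_aa = 30, mode = "fragment")
  expect_gte(length(frs), 2L)
  expect_true(all(vapply(frs, `[[`, integer(1), "length_aa") < 150L))
})

test_that("family assignment finds true members and rejects shuffles", {
  fam <- heg_families()
  hit <- assign_family(fam$prot[["F2"]], fam$prot)
  expect_equal(hit$family_id, "F2")
  expect_gt(hit$margin, 0)
  expect_equal(hit$coverage, 1, tolerance = 0.02)
  # drifted member (20% per-site substitution pressure, reading frame
  # preserved) is still assigned with margin
  set.seed(43)
  drifted_dna <- intronscape:::drift_coding(fam$dna[["F2"]], 0.2)
  drifted_prot <- intronscape:::strip_attrs(translate_cds(drifted_dna))
  best <- assign_family(drifted_prot, fam$prot)
  expect_equal(best$family_id, "F2")
  expect_gt(best$margin, 0)
  # shuffled query clears no family at the default threshold
  set.seed(44)
  shuf <- paste(sample(strsplit(fam$prot[["F1"]], "")[[1]]), collapse = "")
  expect_null(assign_family(shuf, fam$prot))
  # and the calibrated null threshold sits below true-member scores
  thr <- calibrate_family_threshold(fam$prot, n_shuffles = 3, seed = 45)
  expect_lt(thr, hit$score)
})

test_that("heg calling separates intact, eroded and absent", {
  fam <- heg_families()
  set.seed(46)
  intact <- wrap_intron(fam$dna[["F1"]])
  call_i <- call_heg(intact, fam$prot, min_aa = 100)
  expect_equal(call_i$status, "intact")
  expect_equal(call_i$family_id, "F1")
  expect_length(call_i$evidence, 0L)
  expect_gte(call_i$coverage_fraction, 0.8)

  eroded_fs <- wrap_intron(intronscape:::strip_attrs(
    inject_erosion(fam$dna[["F1"]], "frameshift", seed = 47)))
  call_f <- call_heg(eroded_fs, fam$prot, min_aa = 100)
  expect_equal(call_f$status, "eroded")
  expect_true("frameshift" %in% call_f$evidence)

  eroded_st <- wrap_intron(intronscape:::strip_attrs(
    inject_erosion(fam$dna[["F1"]], "stop", seed = 48)))
  call_s <- call_heg(eroded_st, fam$prot, min_aa = 100)
  expect_equal(call_s$status, "eroded")
  expect_true("premature_stop" %in% call_s$evidence)

  empty <- wrap_intron(random_dna(453, seed = 49))
  expect_equal(call_heg(empty, fam$prot, min_aa = 100)$status, "absent")
})

test_that("heg calls are idempotent and label-independent", {
  fam <- heg_families()
  set.seed(50)
  intron <- wrap_intron(fam$dna[["F3"]])
  c1 <- call_heg(intron, fam$prot)
  c2 <- call_heg(intron, fam$prot)
  expect_identical(c1, c2)
  relabeled <- setNames(fam$prot, c("x1", "x2", "x3"))
  expect_equal(call_heg(intron, relabeled)$status, c1$status)
})

test_that("intact status survives synonymous-only mutation", {
  fam <- heg_families()
  for (s in 1:3) {
    set.seed(60 + s)
    syn <- mutate_sequence(fam$dna[["F1"]], 0.3, synonymous_only = TRUE)
    expect_identical(intronscape:::strip_attrs(translate_cds(syn)),
                     fam$prot[["F1"]])
    intron <- wrap_intron(syn)
    expect_equal(call_heg(intron, fam$prot)$status, "intact")
  }
})

test_that("frameshift evidence localizes planted indels", {
  fam <- heg_families()
  heg <- fam$dna[["F1"]]
  # single 1-nt deletion mid-gene
  pos <- 226L
  broken <- paste0(substr(heg, 1, pos - 1), substr(heg, pos + 1, nchar(heg)))
  ev <- detect_frameshift(broken, fam$prot[["F1"]])
  expect_gte(length(ev), 1L)
  expect_lte(abs(ev[[1]]$intron_pos - pos), 15L * 3L)
  expect_false(ev[[1]]$frames[1] == ev[[1]]$frames[2])
  # intact gene yields none
  expect_length(detect_frameshift(heg, fam$prot[["F1"]]), 0L)
  # two planted indels yield two frame transitions
  b2 <- paste0(substr(broken, 1, 330), substr(broken, 332, nchar(broken)))
  ev2 <- detect_frameshift(b2, fam$prot[["F1"]])
  expect_gte(length(ev2), 2L)
})

test_that("chimeric heg are detected with the correct family pair", {
  fam <- heg_families()
  recipient <- fam$dna[["F1"]]
  invader_core <- substr(fam$dna[["F2"]], 1, nchar(fam$dna[["F2"]]) - 3)
  comp <- plant_chimera(recipient, invader_core, seed = 70)
  at <- attr(comp, "insert_at_nt")
  orfs <- scan_orfs(wrap_intron(intronscape:::strip_attrs(comp), seed = 71),
                    min_aa = 100)
  expect_gte(length(orfs), 1L)
  rep <- detect_chimera(orfs[[1]], fam$prot)
  expect_true(is_chimera(rep))
  expect_equal(rep$invader_family, "F2")
  expect_equal(rep$recipient_family, "F1")
  expect_true(rep$in_frame)
  expect_lte(abs(rep$invader_span[1] - (at + 1L)), 30L)
  # a single-family ORF is not a chimera
  plain <- scan_orfs(wrap_intron(fam$dna[["F3"]], seed = 72), min_aa = 100)
  expect_null(detect_chimera(plain[[1]], fam$prot))
  # tandem (recipient prefix + invader, no recipient suffix) is flagged,
  # not called
  tandem_prot <- paste0(substr(fam$prot[["F1"]], 1, 75),
                        fam$prot[["F2"]],
                        random_protein(40, seed = 73))
  res <- detect_chimera(tandem_prot, fam$prot)
  expect_false(is_chimera(res))
  expect_s3_class(res, "chimera_none")
  expect_equal(res$reason, "tandem not chimera")
})
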