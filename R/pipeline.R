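# Pipeline orchestration. Stages communicate through files (TSV/JSON) in a
# single output directory so each stage is independently runnable,
# inspectable and resumable: simulate -> extract -> classify -> landscape ->
# dynamics. The effective configuration is echoed into the output directory.

stage_require <- function(out_dir, ...) {
  for (f in c(...)) {
    p <- file.path(out_dir, f)
    if (!file.exists(p))
      stop("stage order: missing upstream artifact ", p)
  }
}

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the simulation stage
#'
#' Writes per-species GenBank-subset records, the truth tables, family and
#' reference FASTAs, the taxonomy TSV, the tree and the echoed
#' configuration into `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [simulate_landscape()] result, invisibly.
#' @export
stage_simulate <- function(config, out_dir) {
  dir.create(file.path(out_dir, "records"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_landscape(config)
  for (sp in names(sim$records))
    write_genbank(sim$records[[sp]], file.path(out_dir, "records",
                                               paste0(sp, ".gb")))
  write_tsv(sim$truth$tips, file.path(out_dir, "truth_tips.tsv"),
            "simulator ground truth; coordinates 1-based inclusive")
  write_tsv(sim$truth$events, file.path(out_dir, "truth_events.tsv"),
            "simulator event log (node = child node of the branch)")
  write_fasta(sim$family_proteins, file.path(out_dir, "families.faa"))
  write_fasta(c(reference = sim$reference$protein),
              file.path(out_dir, "reference.faa"))
  write_fasta(c(reference_cds = sim$reference$cds),
              file.path(out_dir, "reference_cds.fna"))
  write_tsv(sim$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  ape::write.tree(sim$tree, file.path(out_dir, "tree.nwk"))
  cfg <- sim$config
  cfg$tree <- NULL
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Run the gene-model extraction stage
#'
#' Reads every GenBank record under `records/`, builds gene models and
#' writes `gene_models.tsv` (one row per species) and `introns.tsv` (one
#' row per intron: span, length, group, CDS offset, codon site).
#'
#' @param out_dir Pipeline directory holding `records/`.
#' @param genetic_code_id NCBI translation table id.
#' @return List with both data frames, invisibly.
#' @export
stage_extract <- function(out_dir, genetic_code_id = 4L) {
  rec_dir <- file.path(out_dir, "records")
  if (!dir.exists(rec_dir))
    stop("stage order: missing upstream artifact ", rec_dir)
  paths <- list.files(rec_dir, pattern = "\\.gb$", full.names = TRUE)
  gm_rows <- list(); intron_rows <- list()
  for (p in paths) {
    rec <- read_genbank(p, species_id = sub("\\.gb$", "", basename(p)))
    model <- build_gene_model(rec, genetic_code_id)
    met <- intron_metrics(model)
    gm_rows[[length(gm_rows) + 1L]] <- data.frame(
      species_id = model$species_id, gene_nt = met$total_gene_nt,
      n_exons = nrow(model$exons), n_introns = met$n_introns,
      cds_nt = nchar(splice_cds(model)),
      intronic_pct = met$intronic_fraction, stringsAsFactors = FALSE)
    for (intr in gene_introns(model)) {
      site <- site_in_cds(model, intr)
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        species_id = model$species_id, ordinal = intr$ordinal,
        start = intr$start, end = intr$end, length = intr$length,
        group = intr$group_label, cds_offset = intr$insertion_cds_offset,
        codon_index = site$codon_index, phase = site$phase,
        stringsAsFactors = FALSE)
    }
  }
  gene_models <- do.call(rbind, gm_rows)
  introns <- if (length(intron_rows)) do.call(rbind, intron_rows) else
    data.frame(species_id = character(0), ordinal = integer(0),
               start = integer(0), end = integer(0), length = integer(0),
               group = character(0), cds_offset = integer(0),
               codon_index = integer(0), phase = integer(0))
  write_tsv(gene_models, file.path(out_dir, "gene_models.tsv"),
            "coordinates 1-based inclusive")
  write_tsv(introns, file.path(out_dir, "introns.tsv"),
            "coordinates 1-based inclusive")
  invisible(list(gene_models = gene_models, introns = introns))
}

#' Run the classification stage
#'
#' For every extracted intron: call the heg status against the family
#' references, project the insertion site onto the reference protein, and
#' write `heg_calls.tsv` and `projections.tsv`.
#'
#' @param out_dir Pipeline directory (after [stage_extract()]; needs
#'   `families.faa` and `reference.faa`).
#' @param genetic_code_id NCBI translation table id.
#' @param heg_threshold Family-assignment score threshold.
#' @return List with both data frames, invisibly.
#' @export
stage_classify <- function(out_dir, genetic_code_id = 4L,
                           heg_threshold = 80) {
  stage_require(out_dir, "introns.tsv", "families.faa", "reference.faa")
  families <- read_fasta(file.path(out_dir, "families.faa"))
  reference <- read_fasta(file.path(out_dir, "reference.faa"))[[1]]
  rec_dir <- file.path(out_dir, "records")
  paths <- list.files(rec_dir, pattern = "\\.gb$", full.names = TRUE)
  call_rows <- list(); proj_rows <- list()
  for (p in paths) {
    rec <- read_genbank(p, species_id = sub("\\.gb$", "", basename(p)))
    model <- build_gene_model(rec, genetic_code_id)
    protein <- strip_attrs(translate_cds(splice_cds(model),
                                         genetic_code_id))
    for (intr in gene_introns(model)) {
      hc <- call_heg(intr, families, genetic_code_id,
                     threshold = heg_threshold)
      ps <- project_site(site_in_cds(model, intr), protein, reference)
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        species_id = model$species_id, ordinal = intr$ordinal,
        status = hc$status, family_id = hc$family_id,
        evidence = paste(hc$evidence, collapse = ","),
        coverage = round(hc$coverage_fraction, 3),
        stringsAsFactors = FALSE)
      proj_rows[[length(proj_rows) + 1L]] <- data.frame(
        species_id = model$species_id, ordinal = intr$ordinal,
        ref_residue = ps$ref_residue, phase = ps$phase,
        confidence = ps$confidence, heg_status = hc$status,
        stringsAsFactors = FALSE)
    }
  }
  heg_calls <- do.call(rbind, call_rows)
  projections <- do.call(rbind, proj_rows)
  write_tsv(heg_calls, file.path(out_dir, "heg_calls.tsv"))
  write_tsv(projections, file.path(out_dir, "projections.tsv"))
  invisible(list(heg_calls = heg_calls, projections = projections))
}

#' Run the landscape stage
#'
#' Clusters the projected sites into named Pcls, labels rarity, builds the
#' species x Pcl matrix and writes `pcl_table.tsv`, `landscape.tsv` and
#' `summary.json`.
#'
#' @param out_dir Pipeline directory (after [stage_classify()]).
#' @param tolerance_residues Pcl clustering tolerance.
#' @return The `landscape_matrix`, invisibly.
#' @export
stage_landscape <- function(out_dir, tolerance_residues = 0L) {
  stage_require(out_dir, "projections.tsv", "gene_models.tsv")
  projections <- read_tsv(file.path(out_dir, "projections.tsv"))
  species <- read_tsv(file.path(out_dir, "gene_models.tsv"))$species_id
  tax_path <- file.path(out_dir, "taxonomy.tsv")
  taxonomy <- if (file.exists(tax_path)) read_tsv(tax_path) else NULL
  pcls <- name_pcls(cluster_pcls(projections, tolerance_residues))
  if (!is.null(taxonomy))
    for (i in seq_along(pcls))
      pcls[[i]]$rarity <- label_rarity(pcls[[i]], taxonomy)
  mat <- build_landscape(pcls, species, taxonomy)
  pcl_table <- data.frame(
    pcl = vapply(pcls, `[[`, "", "name"),
    ref_residue = vapply(pcls, function(p) p$site$ref_residue, numeric(1)),
    phase = vapply(pcls, function(p) p$site$phase, numeric(1)),
    n_members = vapply(pcls, function(p) nrow(p$members), integer(1)),
    rarity = vapply(pcls, `[[`, "", "rarity"),
    stringsAsFactors = FALSE)
  write_tsv(pcl_table, file.path(out_dir, "pcl_table.tsv"),
            "sites are 1-based residues in the reference protein")
  write_landscape_tsv(mat, file.path(out_dir, "landscape.tsv"))
  summ <- summarize_landscape(mat, taxonomy)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mat)
}

#' Run the dynamics stage
#'
#' Computes the species-per-intron-count histogram from the landscape
#' matrix, fits the logarithmic decay model and writes `histogram.tsv` and
#' `dynamics_fit.json`.
#'
#' @param out_dir Pipeline directory (after [stage_landscape()]).
#' @param x_policy Passed to [fit_log_model()].
#' @return The `dynamics_fit`, invisibly.
#' @export
stage_dynamics <- function(out_dir, x_policy = "exclude_zero") {
  stage_require(out_dir, "landscape.tsv")
  mat <- read_landscape_tsv(file.path(out_dir, "landscape.tsv"))
  hist <- intron_count_histogram(mat)
  write_tsv(hist, file.path(out_dir, "histogram.tsv"))
  fit <- fit_log_model(hist, x_policy)
  jsonlite::write_json(unclass(fit), file.path(out_dir, "dynamics_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Run the whole pipeline on a simulated cohort
#'
#' Chains [stage_simulate()], [stage_extract()], [stage_classify()],
#' [stage_landscape()] and [stage_dynamics()]; all randomness is fixed by
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param x_policy Dynamics fit policy.
#' @return List: `sim`, `landscape`, `fit`, `summary`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, x_policy = "exclude_zero") {
  sim <- stage_simulate(config, out_dir)
  stage_extract(out_dir)
  stage_classify(out_dir)
  mat <- stage_landscape(out_dir)
  fit <- tryCatch(stage_dynamics(out_dir, x_policy), error = function(e) {
    if (grepl("degenerate fit", conditionMessage(e))) NULL else stop(e)
  })
  invisible(list(sim = sim, landscape = mat, fit = fit,
                 summary = summarize_landscape(mat, sim$taxonomy)))
}
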