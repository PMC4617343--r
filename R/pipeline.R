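# End-to-end orchestration: simulate/load -> filter -> annotate -> DE ->
# compare -> enrich -> report, with per-stage record-count logging and
# conservation assertions.

#' Pipeline configuration
#'
#' @param seed master seed for the synthetic bundles.
#' @param outdir output directory.
#' @param n_genes_a,n_genes_b genes to simulate for the two species.
#' @param alpha DE significance threshold.
#' @param bh Benjamini-Hochberg adjustment flag.
#' @param cpm_threshold,min_samples read-support filter parameters.
#' @param arm_type ARM conditioning-type label.
#' @param thresholds an [annotation_thresholds()].
#' @param exclude optional character vector of transcript ids to drop
#'   before filtering (e.g. contaminants).
#' @param simulate generate the synthetic bundles (`TRUE`) or read them
#'   from `input_a`/`input_b` directories written by [write_bundle()].
#' @param input_a,input_b bundle directories when `simulate = FALSE`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("memorydiff_"),
                            n_genes_a = 800L, n_genes_b = 600L,
                            alpha = 0.05, bh = FALSE,
                            cpm_threshold = 1, min_samples = 3L,
                            arm_type = "Glo-ARM",
                            thresholds = annotation_thresholds(),
                            exclude = NULL, simulate = TRUE,
                            input_a = NULL, input_b = NULL) {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 n_genes_a = as.integer(n_genes_a),
                 n_genes_b = as.integer(n_genes_b),
                 alpha = alpha, bh = bh, cpm_threshold = cpm_threshold,
                 min_samples = as.integer(min_samples),
                 arm_type = arm_type, thresholds = thresholds,
                 exclude = exclude, simulate = simulate,
                 input_a = input_a, input_b = input_b),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments (`thresholds` given as a mapping of threshold names).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds))
    y$thresholds <- do.call(annotation_thresholds, y$thresholds)
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Class-fraction and time-point overlap report tables
#'
#' Produces per-species structural class fractions over all transcripts
#' and over DE transcripts (zero denominators are flagged, not divided
#' by), and per conditioning type a 3-set time-point Venn of up- and
#' downregulated transcripts.
#'
#' @param annotations an [annotate_transcriptome()] data.frame.
#' @param calls a [fit_and_test()] data.frame.
#' @param species species label carried into the tables.
#' @return list with `class_fractions` and `timepoint_venn` data.frames.
#' @export
report_fractions <- function(annotations, calls, species = "species") {
  lv <- c("sense", "antisense", "lncRNA", "unknown")
  frac_tab <- function(ids, scope) {
    cl <- factor(annotations$structural_class[
      annotations$transcript_id %in% ids], levels = lv)
    n <- as.integer(table(cl))
    tot <- sum(n)
    data.frame(species = species, scope = scope, class = lv, n = n,
               fraction = if (tot > 0) n / tot else rep(NA_real_, 4),
               empty_denominator = tot == 0, stringsAsFactors = FALSE)
  }
  de_tx <- unique(calls$transcript_id[calls$significant])
  cf <- rbind(frac_tab(annotations$transcript_id, "all"),
              frac_tab(de_tx, "de"))
  sig <- calls[calls$significant, , drop = FALSE]
  venns <- list()
  for (ty in unique(sig$conditioning_type))
    for (dr in c("up", "down")) {
      s <- sig[sig$conditioning_type == ty & sig$direction == dr, ,
               drop = FALSE]
      sets <- split(s$transcript_id, s$time_point)
      if (!length(sets)) next
      v <- compute_overlaps(sets)
      venns[[length(venns) + 1L]] <-
        cbind(species = species, conditioning_type = ty, direction = dr, v,
              stringsAsFactors = FALSE)
    }
  list(class_fractions = cf,
       timepoint_venn = if (length(venns)) do.call(rbind, venns) else
         data.frame(species = character(0), conditioning_type = character(0),
                    direction = character(0), region = character(0),
                    count = integer(0)))
}

antisense_report <- function(annotations, species) {
  an <- annotations[annotations$structural_class == "antisense", ,
                    drop = FALSE]
  link <- data.frame(species = species,
                     category = c("antisense_to_protein_only",
                                  "antisense_to_sense_only", "both"),
                     count = c(sum(an$antisense_to_protein & !an$antisense_to_sense),
                               sum(!an$antisense_to_protein & an$antisense_to_sense),
                               sum(an$antisense_to_protein & an$antisense_to_sense)),
                     stringsAsFactors = FALSE)
  zs <- an$zone_set[an$antisense_to_sense & nzchar(an$zone_set)]
  zones <- data.frame(species = species,
                      zone_set = names(table(zs)),
                      count = as.integer(table(zs)),
                      stringsAsFactors = FALSE)
  list(links = link, zones = zones)
}

run_species <- function(bundle, cfg, summary_log) {
  sp <- bundle$samples$species[1]
  log_add <- function(stage, n_in, n_out) {
    md_log(paste0(sp, ":", stage), "in=", n_in, " out=", n_out)
    rbind(summary_log, data.frame(species = sp, stage = stage,
                                  records_in = n_in, records_out = n_out,
                                  stringsAsFactors = FALSE))
  }
  tx2gene <- bundle$ref$tx2gene

  filtered <- run_stage("filter", filter_low_support(
    bundle$counts, cfg$cpm_threshold, cfg$min_samples, cfg$exclude))
  stopifnot(nrow(filtered) <= nrow(bundle$counts),
            ncol(filtered) == ncol(bundle$counts))
  summary_log <- log_add("filter", nrow(bundle$counts), nrow(filtered))

  ann <- run_stage("annotate", annotate_transcriptome(
    bundle$hits, tx2gene, cfg$thresholds, bundle$ref$transcripts))
  stopifnot(nrow(ann) == nrow(tx2gene))
  summary_log <- log_add("annotate", nrow(bundle$hits), nrow(ann))

  design <- run_stage("de", build_design(bundle$samples))
  disp <- run_stage("de", estimate_dispersions(filtered, design))
  calls <- run_stage("de", fit_and_test(filtered, design, disp,
                                        alpha = cfg$alpha, bh = cfg$bh))
  expected <- (nrow(filtered) - length(attr(calls, "nonconverged"))) *
    length(design$contrasts)
  stopifnot(nrow(calls) == expected)
  summary_log <- log_add("de", nrow(filtered), nrow(calls))

  summ <- run_stage("compare", summarize_gene_de(calls, tx2gene))
  summary_log <- log_add("compare", nrow(calls), nrow(summ))

  list(species = sp, tx2gene = tx2gene, annotations = ann, calls = calls,
       summary = summ, filtered = filtered, design = design,
       dispersion = disp, log = summary_log)
}

#' Run the whole pipeline
#'
#' Executes filter, annotation, differential expression, the LTM-vs-ARM
#' comparison and term enrichment for both species, then writes the
#' report bundle (class fractions, antisense link/zone tables, per
#' time-point up/down Venns, candidate genes, enrichment, run summary)
#' under `config$outdir`. Any stage error aborts with the failing stage
#' named. Reruns on the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return list of report tables, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log0 <- data.frame(species = character(0), stage = character(0),
                     records_in = integer(0), records_out = integer(0))

  if (isTRUE(config$simulate)) {
    cfg_a <- sim_config(seed = stage_seed(config$seed, "species_a"),
                        n_genes = config$n_genes_a,
                        design = design_glomerata())
    cfg_b <- sim_config(seed = stage_seed(config$seed, "species_b"),
                        n_genes = config$n_genes_b,
                        design = design_rubecula())
    bundle_a <- run_stage("simulate", simulate_bundle(cfg_a))
    bundle_b <- run_stage("simulate", simulate_bundle(cfg_b))
    write_bundle(bundle_a, file.path(config$outdir, "fixtures", "species_a"))
    write_bundle(bundle_b, file.path(config$outdir, "fixtures", "species_b"))
  } else {
    bundle_a <- run_stage("load", read_bundle(config$input_a))
    bundle_b <- run_stage("load", read_bundle(config$input_b))
  }
  stopifnot(nrow(bundle_a$counts) == length(bundle_a$ref$transcripts))
  stopifnot(nrow(bundle_b$counts) == length(bundle_b$ref$transcripts))

  res_a <- run_species(bundle_a, config, log0)
  res_b <- run_species(bundle_b, config, log0)
  logs <- rbind(res_a$log, res_b$log)

  # within-species three-rule filter (species A holds the ARM control)
  ltm_a <- setdiff(unique(res_a$summary$conditioning_type), config$arm_type)
  cand_a <- run_stage("compare",
                      apply_ltm_filter(res_a$summary, ltm_a, config$arm_type))

  # cross-species: ortholog-level comparison, no splice-variant rule
  orth <- simulate_orthologs(unique(res_a$tx2gene$gene_id),
                             unique(res_b$tx2gene$gene_id),
                             seed = config$seed)
  proj <- function(g) {
    m <- match(g, orth$gene_id)
    ifelse(is.na(m), g, orth$ortholog_group[m])
  }
  arm_groups <- proj(unique(res_a$summary$gene_id[
    res_a$summary$conditioning_type == config$arm_type]))
  rub_genes <- unique(res_b$summary$gene_id)
  cand_b <- data.frame(gene_id = rub_genes,
                       ltm_type = unique(res_b$summary$conditioning_type)[1] %||% NA,
                       rule = "absent_in_arm",
                       ltm_evidence = "", arm_evidence = "",
                       stringsAsFactors = FALSE)[
    !proj(rub_genes) %in% arm_groups, , drop = FALSE]
  candidates <- rbind(cand_a, if (nrow(cand_b)) cand_b)

  # cross-species DE-gene overlap at ortholog level
  de_genes <- function(res) unique(res$summary$gene_id)
  venn_sp <- compute_overlaps(list(Cglom = de_genes(res_a),
                                   Crub = de_genes(res_b)), orth)

  # enrichment per (conditioning type, time point, direction)
  onto <- simulate_ontology(c(unique(res_a$tx2gene$gene_id),
                              unique(res_b$tx2gene$gene_id)),
                            seed = config$seed)
  slim_ann <- map_to_slim(onto$annotations, onto$ontology, onto$slim)
  enr <- list()
  for (res in list(res_a, res_b)) {
    pop <- unique(res$tx2gene$gene_id[
      res$tx2gene$transcript_id %in% rownames(res$filtered)])
    sig <- res$calls[res$calls$significant, , drop = FALSE]
    sig$gene_id <- res$tx2gene$gene_id[
      match(sig$transcript_id, res$tx2gene$transcript_id)]
    strata <- unique(sig[, c("conditioning_type", "time_point", "direction")])
    for (i in seq_len(nrow(strata))) {
      s <- strata[i, ]
      study <- unique(sig$gene_id[
        sig$conditioning_type == s$conditioning_type &
          sig$time_point == s$time_point & sig$direction == s$direction])
      e <- fisher_enrichment(intersect(study, pop), pop, slim_ann,
                             alpha = config$alpha)
      if (nrow(e))
        enr[[length(enr) + 1L]] <- cbind(species = res$species, s, e,
                                         row.names = NULL)
    }
  }
  enrichment <- if (length(enr)) do.call(rbind, enr) else NULL

  rep_a <- report_fractions(res_a$annotations, res_a$calls, res_a$species)
  rep_b <- report_fractions(res_b$annotations, res_b$calls, res_b$species)
  anti_a <- antisense_report(res_a$annotations, res_a$species)
  anti_b <- antisense_report(res_b$annotations, res_b$species)

  out <- list(class_fractions = rbind(rep_a$class_fractions,
                                      rep_b$class_fractions),
              timepoint_venn = rbind(rep_a$timepoint_venn,
                                     rep_b$timepoint_venn),
              antisense_links = rbind(anti_a$links, anti_b$links),
              antisense_zones = rbind(anti_a$zones, anti_b$zones),
              candidates = candidates, species_venn = venn_sp,
              enrichment = enrichment, run_summary = logs)
  for (nm in names(out))
    if (!is.null(out[[nm]]))
      write_tsv(out[[nm]], file.path(config$outdir, paste0(nm, ".tsv")))
  md_log("report", "written to ", config$outdir)
  invisible(c(out, list(species_a = res_a, species_b = res_b,
                        orthologs = orth)))
}

#' Read a fixture bundle written by [write_bundle()]
#' @param dir bundle directory.
#' @return list shaped like a [simulate_bundle()] result.
#' @export
read_bundle <- function(dir) {
  truth <- read_tsv(file.path(dir, "truth.tsv"))
  list(ref = list(
         proteins = Biostrings::readAAStringSet(file.path(dir, "proteins.fasta")),
         transcripts = Biostrings::readDNAStringSet(file.path(dir, "transcripts.fasta")),
         tx2gene = truth[, c("transcript_id", "gene_id", "length")],
         truth = truth),
       hits = read_hits(file.path(dir, "hits.tsv")),
       counts = read_counts(file.path(dir, "counts.tsv")),
       samples = read_samples(file.path(dir, "samples.tsv")))
}
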