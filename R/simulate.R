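# Synthetic fixture generation: a planted transcriptome with known
# structural classes and splice variants, alignment tables consistent with
# the planted classes, and NB-distributed counts with replicate block
# effects and condition-specific fold changes.

CLASSES <- c("sense", "antisense_to_protein", "antisense_to_sense",
             "lncRNA", "unknown")

# codons without stops, for planting ORFs free of premature termination
non_stop_codons <- function() {
  b <- c("A", "C", "G", "T")
  cod <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

rand_cds <- function(n_codons) {
  paste0("ATG", paste(sample(non_stop_codons(), n_codons, replace = TRUE),
                      collapse = ""), "TAA")
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# contrast labels "type|tp" for every non-reference group of a design
design_contrasts <- function(design) {
  unlist(lapply(design$conditioning_types, function(ty)
    paste(ty, design$time_points[[ty]], sep = "|")), use.names = FALSE)
}

zone_subsets <- list("three_prime_utr",
                     c("cds", "three_prime_utr"),
                     "five_prime_utr",
                     c("five_prime_utr", "cds"),
                     "cds",
                     c("five_prime_utr", "cds", "three_prime_utr"))
# weights echo the observed predominance of 3'UTR-overlapping antisense
zone_weights <- c(0.30, 0.25, 0.12, 0.10, 0.13, 0.10)

# choose a window [a, b) on a sense transcript hitting exactly `zones`
zone_window <- function(zones, cs, ce, len) {
  u3 <- len - ce
  if (setequal(zones, "five_prime_utr")) {
    a <- 0L; b <- max(20L, cs - 5L)
  } else if (setequal(zones, "cds")) {
    a <- cs + 5L; b <- ce - 5L
  } else if (setequal(zones, "three_prime_utr")) {
    a <- ce + 2L; b <- len - 2L
  } else if (setequal(zones, c("five_prime_utr", "cds"))) {
    a <- max(0L, cs %/% 2L); b <- cs + max(30L, (ce - cs) %/% 3L)
  } else if (setequal(zones, c("cds", "three_prime_utr"))) {
    a <- ce - max(30L, (ce - cs) %/% 3L); b <- ce + max(2L, u3 %/% 2L)
  } else {
    a <- cs %/% 2L; b <- ce + max(2L, u3 %/% 2L)
  }
  c(a, b)
}

#' Generate the planted reference: proteins, transcripts and ground truth
#'
#' Draws a structural class for every transcript, builds sequences
#' accordingly (sense transcripts carry a planted CDS with nonempty UTRs;
#' antisense-to-sense transcripts reverse-complement a window of a sense
#' partner chosen to cover a planted UTR/CDS zone set), assigns planted
#' fold-change roles to genes, and appends near-threshold decoy
#' transcripts flagged in the truth table.
#'
#' @param config a [sim_config()].
#' @return list with `proteins` (AAStringSet), `transcripts` (DNAStringSet),
#'   `tx2gene` (data.frame transcript_id/gene_id/length), `truth`
#'   (data.frame, one row per transcript) and `logfc` (transcript x
#'   contrast matrix of planted log2 fold changes).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, "reference", {
    ng <- config$n_genes
    gene_ids <- sprintf("g%05d", seq_len(ng))
    multi <- runif(ng) < config$multi_transcript_fraction
    n_tx_per_gene <- ifelse(multi, 2L + (runif(ng) < 0.25), 1L)
    gene_of_tx <- rep(gene_ids, n_tx_per_gene)
    tx_index <- unlist(lapply(n_tx_per_gene, seq_len))
    tx_ids <- sprintf("%s_t%d", gene_of_tx, tx_index)
    ntx <- length(tx_ids)

    class <- sample(CLASSES, ntx, replace = TRUE,
                    prob = config$class_proportions)
    # antisense-to-sense needs at least one sense transcript to pair with
    if (!any(class == "sense") && any(class == "antisense_to_sense"))
      class[class == "antisense_to_sense"] <- "unknown"

    seqs <- character(ntx)
    cds_start <- cds_end <- rep(NA_integer_, ntx)
    gene_core <- setNames(vapply(gene_ids, function(g) rand_nt(200L), ""),
                          gene_ids)

    sense_idx <- which(class == "sense")
    for (i in sense_idx) {
      u5 <- sample(30:150, 1)
      m <- sample(50:300, 1)
      u3 <- sample(50:200, 1)
      cds <- rand_cds(m)
      seqs[i] <- paste0(rand_nt(u5), cds, rand_nt(u3))
      cds_start[i] <- u5
      cds_end[i] <- u5 + nchar(cds)
      if (n_tx_per_gene[match(gene_of_tx[i], gene_ids)] > 1L)
        seqs[i] <- paste0(seqs[i], gene_core[gene_of_tx[i]])
    }

    partner <- rep(NA_character_, ntx)
    zone_set <- rep(NA_character_, ntx)
    a2s_s_start <- a2s_s_end <- rep(NA_integer_, ntx)
    a2s_qcov <- rep(NA_real_, ntx)
    marg <- config$boundary_margin
    for (i in which(class == "antisense_to_sense")) {
      p <- sample(sense_idx, 1)
      zi <- sample(length(zone_subsets), 1, prob = zone_weights)
      zones <- zone_subsets[[zi]]
      w <- zone_window(zones, cds_start[p], cds_end[p], nchar(seqs[p]))
      f <- runif(1, 0.8 + marg, 0.99)
      total_len <- max(w[2] - w[1], floor((w[2] - w[1]) / f))
      pad <- total_len - (w[2] - w[1])
      seqs[i] <- paste0(revcomp_chr(substr(seqs[p], w[1] + 1L, w[2])),
                        if (pad > 0) rand_nt(pad) else "")
      partner[i] <- tx_ids[p]
      zone_set[i] <- paste(zones, collapse = ",")
      a2s_s_start[i] <- w[1]
      a2s_s_end[i] <- w[2]
      a2s_qcov[i] <- (w[2] - w[1]) / total_len
    }

    other <- which(class %in% c("antisense_to_protein", "lncRNA", "unknown"))
    for (i in other) {
      len <- sample(300:1200, 1)
      seqs[i] <- rand_nt(len)
      if (class[i] != "antisense_to_sense" &&
          n_tx_per_gene[match(gene_of_tx[i], gene_ids)] > 1L)
        seqs[i] <- paste0(seqs[i], gene_core[gene_of_tx[i]])
      # a minority of non-coding transcripts carries a embedded long ORF
      if (class[i] %in% c("lncRNA", "unknown") && runif(1) < 0.2) {
        ins <- rand_cds(sample(35:80, 1))
        pos <- sample(0:nchar(seqs[i]), 1)
        seqs[i] <- paste0(substr(seqs[i], 1, pos), ins,
                          substr(seqs[i], pos + 1, nchar(seqs[i])))
      }
    }

    # decoy transcripts probing the strict-inequality thresholds
    nd <- config$n_decoys
    decoy_kinds <- rep(c("sense_at", "sense_above", "a2p_at", "a2p_above",
                         "a2s_at", "a2s_above", "lnc_at", "lnc_above"),
                       length.out = nd)
    if (nd > 0) {
      d_gene <- sprintf("gD%04d", seq_len(nd))
      d_tx <- paste0(d_gene, "_t1")
      d_class <- ifelse(grepl("_at$", decoy_kinds), "unknown",
                        c(sense_at = "sense", sense_above = "sense",
                          a2p_at = "antisense_to_protein",
                          a2p_above = "antisense_to_protein",
                          a2s_at = "antisense_to_sense",
                          a2s_above = "antisense_to_sense",
                          lnc_at = "lncRNA",
                          lnc_above = "lncRNA")[decoy_kinds])
      d_seqs <- vapply(seq_len(nd), function(i) rand_nt(sample(300:600, 1)), "")
      gene_of_tx <- c(gene_of_tx, d_gene)
      tx_ids <- c(tx_ids, d_tx)
      seqs <- c(seqs, d_seqs)
      class <- c(class, d_class)
      cds_start <- c(cds_start, rep(NA_integer_, nd))
      cds_end <- c(cds_end, rep(NA_integer_, nd))
      partner <- c(partner, ifelse(grepl("^a2s", decoy_kinds),
                                   tx_ids[sense_idx[1]], NA_character_))
      zone_set <- c(zone_set, rep(NA_character_, nd))
      a2s_s_start <- c(a2s_s_start, rep(NA_integer_, nd))
      a2s_s_end <- c(a2s_s_end, rep(NA_integer_, nd))
      a2s_qcov <- c(a2s_qcov, rep(NA_real_, nd))
      ntx <- length(tx_ids)
    }
    is_decoy <- grepl("^gD", gene_of_tx)
    decoy_kind <- rep(NA_character_, ntx)
    if (nd > 0) decoy_kind[is_decoy] <- decoy_kinds

    # proteins: the translated CDS of every sense transcript, plus external
    # subjects for antisense-to-protein hits
    prot <- list()
    for (i in which(class == "sense" & !is_decoy)) {
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(seqs[i], cds_start[i] + 1L, cds_end[i])),
        no.init.codon = FALSE))
      prot[[paste0("P_", tx_ids[i])]] <- sub("\\*$", "", aa)
    }
    for (i in which(class == "antisense_to_protein" | grepl("^a2p|^sense",
                                                            decoy_kind))) {
      prot[[paste0("P_ext_", tx_ids[i])]] <-
        paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                     sample(100:400, 1), replace = TRUE), collapse = "")
    }

    # planted fold-change roles at gene level
    contrasts <- design_contrasts(config$design)
    logfc <- matrix(0, ntx, length(contrasts),
                    dimnames = list(tx_ids, contrasts))
    role <- setNames(rep("null", ng), gene_ids)
    arm <- grep("ARM", config$design$conditioning_types, value = TRUE)
    multi_genes <- gene_ids[n_tx_per_gene > 1L]
    single_pool <- sample(gene_ids)
    multi_pool <- sample(multi_genes)
    take <- function(pool, used, n) setdiff(pool, used)[seq_len(n)]
    used <- character(0)
    contr_of <- function(types, tps) {
      keep <- contrasts[sub("\\|.*", "", contrasts) %in% types]
      if (!is.null(tps)) keep <- keep[sub(".*\\|", "", keep) %in% tps]
      keep
    }
    for (e in config$planted_effects) {
      pool <- if (e$role == "splice_specific") multi_pool else single_pool
      gs <- take(pool, used, min(e$n_genes, length(setdiff(pool, used))))
      used <- c(used, gs)
      for (g in gs) {
        role[g] <- e$role
        txs <- tx_ids[gene_of_tx == g]
        s <- sample(c(-1, 1), 1)
        lc <- contr_of(e$types, e$time_points)
        ac <- if (length(arm)) contr_of(arm, NULL) else character(0)
        switch(e$role,
          ltm_only = { logfc[txs, lc] <- s * e$log2fc },
          arm_only = { logfc[txs, ac] <- s * e$log2fc },
          shared_same_direction = {
            logfc[txs, c(lc, ac)] <- s * e$log2fc },
          opposing = {
            logfc[txs, lc] <- s * e$log2fc
            logfc[txs, ac] <- -s * e$log2fc },
          splice_specific = {
            logfc[txs[1], ac] <- s * e$log2fc
            logfc[txs[-1], lc] <- s * e$log2fc })
      }
    }

    truth <- data.frame(transcript_id = tx_ids, gene_id = gene_of_tx,
                        class = class, role = role[gene_of_tx],
                        is_decoy = is_decoy, decoy_kind = decoy_kind,
                        partner = partner, zone_set = zone_set,
                        cds_start = cds_start, cds_end = cds_end,
                        a2s_s_start = a2s_s_start, a2s_s_end = a2s_s_end,
                        a2s_qcov = a2s_qcov,
                        length = nchar(seqs),
                        stringsAsFactors = FALSE)
    truth$role[is_decoy] <- "null"

    list(proteins = Biostrings::AAStringSet(unlist(prot)),
         transcripts = Biostrings::DNAStringSet(setNames(seqs, tx_ids)),
         tx2gene = data.frame(transcript_id = tx_ids, gene_id = gene_of_tx,
                              length = nchar(seqs),
                              stringsAsFactors = FALSE),
         truth = truth, logfc = logfc)
  })
}

one_hit <- function(q, s, db, orient, ident, qcov, scov, qs, qe, ss, se) {
  data.frame(query_id = q, subject_id = s, subject_db = db,
             orientation = orient, identity = ident, query_cov = qcov,
             subject_cov = scov, q_start = qs, q_end = qe,
             s_start = ss, s_end = se, stringsAsFactors = FALSE)
}

#' Generate an alignment table consistent with the planted classes
#'
#' For each transcript, emits hits whose orientation, coverages and
#' identity put it on the correct side of every classification threshold
#' by at least the configured boundary margin (identity margins are capped
#' just below 1). Decoy transcripts receive hits exactly at, or just
#' above, a threshold to probe the strict-inequality rules; unknown-class
#' transcripts receive no qualifying hit (half of them get a clearly
#' sub-threshold hit to exercise the sieve).
#'
#' @param ref output of [generate_reference()].
#' @param config the same [sim_config()].
#' @return data.frame in the hits-table dialect (one row per hit).
#' @export
generate_alignment_table <- function(ref, config) {
  truth <- ref$truth
  marg <- config$boundary_margin
  prot_len <- setNames(Biostrings::width(ref$proteins), names(ref$proteins))
  with_stage_seed(config$seed, "alignments", {
    rows <- vector("list", nrow(truth) * 2L)
    k <- 0L
    add <- function(h) { k <<- k + 1L; rows[[k]] <<- h }
    hi_ident <- function(thr) runif(1, min(thr + marg, 0.995), 0.999)

    for (i in seq_len(nrow(truth))) {
      tx <- truth$transcript_id[i]
      len <- truth$length[i]
      cl <- truth$class[i]
      if (truth$is_decoy[i]) {
        kind <- truth$decoy_kind[i]
        at <- grepl("_at$", kind)
        if (kind %in% c("sense_at", "sense_above")) {
          p <- paste0("P_ext_", tx)
          cov <- if (at) 0.60 else 0.60 + marg / 4
          add(one_hit(tx, p, "proteome", "sense", hi_ident(0.7), 0.5, cov,
                      0L, len %/% 2L, 0L, round(cov * prot_len[[p]])))
        } else if (kind %in% c("a2p_at", "a2p_above")) {
          p <- paste0("P_ext_", tx)
          cov <- if (at) 0.50 else 0.50 + marg / 4
          add(one_hit(tx, p, "nr", "antisense", hi_ident(0.7), 0.5, cov,
                      0L, len %/% 2L, 0L, round(cov * prot_len[[p]])))
        } else if (kind %in% c("a2s_at", "a2s_above")) {
          qc <- if (at) 0.80 else 0.80 + marg / 4
          add(one_hit(tx, truth$partner[i], "self_transcriptome",
                      "antisense", hi_ident(0.95), qc, NA_real_,
                      0L, round(qc * len), 10L, 10L + round(qc * len)))
        } else {
          qc <- if (at) 0.80 else 0.80 + marg / 4
          add(one_hit(tx, "scaffold_1", "genome", "sense", hi_ident(0.95),
                      qc, NA_real_, 0L, round(qc * len),
                      1000L, 1000L + round(qc * len)))
        }
        next
      }
      if (cl == "sense") {
        p <- paste0("P_", tx)
        cov <- runif(1, 0.60 + marg, 1)
        add(one_hit(tx, p, "proteome", "sense", hi_ident(0.7),
                    (truth$cds_end[i] - truth$cds_start[i]) / len, cov,
                    truth$cds_start[i], truth$cds_end[i],
                    0L, round(cov * prot_len[[p]])))
      } else if (cl == "antisense_to_protein") {
        p <- paste0("P_ext_", tx)
        cov <- runif(1, 0.50 + marg, 1)
        add(one_hit(tx, p, "nr", "antisense", hi_ident(0.7), 0.6, cov,
                    0L, round(0.6 * len), 0L, round(cov * prot_len[[p]])))
      } else if (cl == "antisense_to_sense") {
        add(one_hit(tx, truth$partner[i], "self_transcriptome", "antisense",
                    hi_ident(0.95), truth$a2s_qcov[i], NA_real_,
                    0L, truth$a2s_s_end[i] - truth$a2s_s_start[i],
                    truth$a2s_s_start[i], truth$a2s_s_end[i]))
        # a fraction additionally qualifies as antisense-to-protein
        if (runif(1) < 0.15) {
          p <- names(prot_len)[startsWith(names(prot_len), "P_ext_")][1]
          if (!is.na(p))
            add(one_hit(tx, p, "nr", "antisense", hi_ident(0.7), 0.5,
                        runif(1, 0.50 + marg, 1), 0L, len %/% 2L,
                        0L, prot_len[[p]] %/% 2L))
        }
      } else if (cl == "lncRNA") {
        qc <- runif(1, 0.80 + marg, 1)
        db <- if (runif(1) < 0.5) "genome" else "nt"
        add(one_hit(tx, paste0(db, "_subj_", i), db, "sense",
                    hi_ident(0.95), qc, NA_real_, 0L, round(qc * len),
                    500L, 500L + round(qc * len)))
      } else { # unknown: at most a clearly sub-threshold hit
        if (runif(1) < 0.5)
          add(one_hit(tx, "P_junk", "nr", "sense", runif(1, 0.3, 0.6),
                      0.2, runif(1, 0.05, 0.60 - marg),
                      0L, len %/% 5L, 0L, 40L))
      }
    }
    hits <- do.call(rbind, rows[seq_len(k)])
    rownames(hits) <- NULL
    hits
  })
}

#' Simulate NB counts with replicate blocking and planted fold changes
#'
#' Counts follow `NB(mean = libsize * q * 2^logFC * exp(block),
#' dispersion = phi0 + a/mean)`. Library sizes are drawn log-uniformly
#' from the configured range; the replicate block effect is a log-scale
#' normal shared by all samples of one biological replicate.
#'
#' @param ref output of [generate_reference()].
#' @param config the same [sim_config()].
#' @return list with `counts` (integer matrix, transcripts x samples) and
#'   `samples` (data.frame: sample_id, species, conditioning_type,
#'   time_point, replicate).
#' @export
generate_counts <- function(ref, config) {
  d <- config$design
  groups <- c("unconditioned"[d$unconditioned], design_contrasts(d))
  samples <- do.call(rbind, lapply(groups, function(g) {
    ty <- sub("\\|.*", "", g)
    tp <- if (g == "unconditioned") "none" else sub(".*\\|", "", g)
    data.frame(sample_id = sprintf("%s.%s.%s.R%d", d$species,
                                   ty, tp, seq_len(d$n_replicates)),
               species = d$species, conditioning_type = ty,
               time_point = tp, replicate = sprintf("R%d", seq_len(d$n_replicates)),
               group = g, stringsAsFactors = FALSE)
  }))
  tx <- ref$tx2gene$transcript_id
  G <- length(tx); S <- nrow(samples)
  with_stage_seed(config$seed, "counts", {
    q <- exp(rnorm(G, 0, config$baseline_logmean_sd))
    q <- q / sum(q)
    L <- exp(runif(S, log(config$library_size_range[1]),
                   log(config$library_size_range[2])))
    block <- setNames(rnorm(d$n_replicates, 0, config$block_effect_sd),
                      sprintf("R%d", seq_len(d$n_replicates)))
    lfc <- matrix(0, G, S)
    in_contrast <- samples$group != "unconditioned"
    if (any(in_contrast))
      lfc[, in_contrast] <- ref$logfc[, samples$group[in_contrast], drop = FALSE]
    mu <- (q %o% L) * 2^lfc *
      matrix(exp(block[samples$replicate]), G, S, byrow = TRUE)
    phi <- config$dispersion_phi0 + config$dispersion_a / pmax(mu, 1e-8)
    counts <- matrix(rnbinom(G * S, mu = mu, size = 1 / phi), G, S,
                     dimnames = list(tx, samples$sample_id))
    storage.mode(counts) <- "integer"
    attr(counts, "lib_sizes") <- setNames(L, samples$sample_id)
    list(counts = counts, samples = samples[, c("sample_id", "species",
                                                "conditioning_type",
                                                "time_point", "replicate")])
  })
}

#' Forced DE calls from the planted truth
#'
#' Bypasses the stochastic DE stage: every (transcript, contrast) with a
#' nonzero planted fold change is marked significant with its planted
#' direction. Useful for testing downstream comparison logic in
#' isolation.
#'
#' @param ref output of [generate_reference()].
#' @return a `de_calls`-shaped data.frame.
#' @export
truth_calls <- function(ref) {
  lf <- ref$logfc
  long <- data.frame(transcript_id = rep(rownames(lf), ncol(lf)),
                     contrast = rep(colnames(lf), each = nrow(lf)),
                     logFC = as.vector(lf), stringsAsFactors = FALSE)
  long$conditioning_type <- sub("\\|.*", "", long$contrast)
  long$time_point <- sub(".*\\|", "", long$contrast)
  long$p_value <- ifelse(long$logFC != 0, 0, 1)
  long$direction <- ifelse(long$logFC < 0, "down", "up")
  long$significant <- long$logFC != 0
  structure(long[, c("transcript_id", "conditioning_type", "time_point",
                     "logFC", "p_value", "direction", "significant")],
            class = c("de_calls", "data.frame"), alpha = 0.05, bh = FALSE,
            nonconverged = character(0))
}

#' Generate the full fixture bundle for one species
#'
#' @param config a [sim_config()].
#' @return list with elements `ref`, `hits`, `counts`, `samples` plus the
#'   config used.
#' @export
simulate_bundle <- function(config) {
  ref <- generate_reference(config)
  hits <- generate_alignment_table(ref, config)
  cnt <- generate_counts(ref, config)
  list(config = config, ref = ref, hits = hits,
       counts = cnt$counts, samples = cnt$samples)
}

#' Simulate a small is_a ontology with a slim subset and gene annotations
#'
#' Builds a three-level DAG per namespace (root, mid-level slim terms,
#' leaves), assigns each gene 1-3 leaf terms, and returns the pieces the
#' enrichment stage consumes.
#'
#' @param genes character vector of gene ids to annotate.
#' @param n_terms leaf terms per namespace.
#' @param seed integer seed.
#' @return list with `ontology` (see [read_obo()]), `slim` (term ids) and
#'   `annotations` (data.frame gene_id/term_id).
#' @export
simulate_ontology <- function(genes, n_terms = 30L, seed = 1L) {
  with_stage_seed(seed, "ontology", {
    ns <- "biological_process"
    root <- "GO:0000001"
    mids <- sprintf("GO:%07d", 2:7)
    leaves <- sprintf("GO:%07d", 100 + seq_len(n_terms))
    terms <- data.frame(id = c(root, mids, leaves),
                        name = c("root", paste0("slim_", mids),
                                 paste0("leaf_", leaves)),
                        namespace = ns, stringsAsFactors = FALSE)
    edges <- rbind(data.frame(child = mids, parent = root,
                              stringsAsFactors = FALSE),
                   data.frame(child = leaves,
                              parent = sample(mids, n_terms, replace = TRUE),
                              stringsAsFactors = FALSE))
    ann <- do.call(rbind, lapply(genes, function(g) {
      data.frame(gene_id = g,
                 term_id = sample(leaves, sample(1:3, 1)),
                 stringsAsFactors = FALSE)
    }))
    list(ontology = list(terms = terms, edges = edges),
         slim = c(root, mids), annotations = ann)
  })
}

#' Simulate an ortholog map between two gene sets
#'
#' Pairs a fraction of genes of species A with genes of species B under a
#' shared ortholog-group id; unpaired genes stay species-unique.
#'
#' @param genes_a,genes_b gene id vectors.
#' @param fraction fraction of the smaller set that is shared.
#' @param seed integer seed.
#' @return data.frame gene_id / ortholog_group.
#' @export
simulate_orthologs <- function(genes_a, genes_b, fraction = 0.78, seed = 1L) {
  with_stage_seed(seed, "orthologs", {
    n <- round(fraction * min(length(genes_a), length(genes_b)))
    pa <- sample(genes_a, n)
    pb <- sample(genes_b, n)
    og <- sprintf("OG%05d", seq_len(n))
    rbind(data.frame(gene_id = pa, ortholog_group = og,
                     stringsAsFactors = FALSE),
          data.frame(gene_id = pb, ortholog_group = og,
                     stringsAsFactors = FALSE))
  })
}

#' Write a fixture bundle to a directory of plain-text files
#'
#' Emits proteins.fasta, transcripts.fasta, hits.tsv, counts.tsv,
#' samples.tsv and truth.tsv.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$ref$proteins,
                              file.path(dir, "proteins.fasta"))
  Biostrings::writeXStringSet(bundle$ref$transcripts,
                              file.path(dir, "transcripts.fasta"))
  write_tsv(bundle$hits, file.path(dir, "hits.tsv"))
  cnt <- data.frame(transcript_id = rownames(bundle$counts),
                    bundle$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(cnt, file.path(dir, "counts.tsv"))
  write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  truth <- cbind(bundle$ref$truth,
                 setNames(as.data.frame(bundle$ref$logfc),
                          paste0("logfc.", colnames(bundle$ref$logfc))))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
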