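# Shared fixtures and independent oracles used across the suite.

# two-group, three-replicate metadata (one conditioned group vs control)
two_group_meta <- function(n_rep = 3L) {
  data.frame(sample_id = paste0("s", seq_len(2 * n_rep)), species = "A",
             conditioning_type = rep(c("unconditioned", "T"), each = n_rep),
             time_point = rep(c("none", "1h"), each = n_rep),
             replicate = rep(paste0("R", seq_len(n_rep)), 2),
             stringsAsFactors = FALSE)
}

small_config <- function(seed = 1L, n_genes = 150L, ...) {
  sim_config(seed = seed, n_genes = n_genes, ...)
}

# map planted 5-way classes onto the annotator's 4-way output
class4 <- function(cls) {
  c(sense = "sense", antisense_to_protein = "antisense",
    antisense_to_sense = "antisense", lncRNA = "lncRNA",
    unknown = "unknown")[cls]
}

# independent ORF oracle: every ATG paired with its next in-frame stop,
# keeping per stop only the earliest ATG, then applying the length cutoff
orf_oracle <- function(s, min_aa) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (f in 0:2) {
    pos <- seq(f, n - 3, by = 3)
    if (!length(pos)) next
    cod <- substring(s, pos + 1, pos + 3)
    atg <- pos[cod == "ATG"]
    stp <- pos[cod %in% stops]
    cand <- lapply(atg, function(a) {
      nx <- stp[stp > a]
      if (!length(nx)) return(NULL)
      c(a, min(nx))
    })
    cand <- do.call(rbind, cand)
    if (is.null(cand)) next
    # earliest ATG per stop
    keep <- !duplicated(cand[, 2])
    cand <- cand[keep, , drop = FALSE]
    aa <- (cand[, 2] - cand[, 1]) / 3
    ok <- aa >= min_aa
    if (any(ok))
      found[[length(found) + 1]] <-
        data.frame(frame = f, start = cand[ok, 1], end = cand[ok, 2] + 3,
                   length_aa = aa[ok])
  }
  if (!length(found))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), length_aa = integer(0)))
  do.call(rbind, found)
}

# independent classifier oracle: literal rule-by-rule evaluation per
# transcript, with the sense set fixed from protein evidence first
annotate_oracle <- function(hits, tx2gene, th = annotation_thresholds()) {
  txs <- tx2gene$transcript_id
  sense_set <- character(0)
  for (t in txs) {
    h <- hits[hits$query_id == t, , drop = FALSE]
    ok <- FALSE
    for (i in seq_len(nrow(h)))
      if (h$subject_db[i] %in% c("proteome", "nr") &&
          h$orientation[i] == "sense" && !is.na(h$subject_cov[i]) &&
          h$subject_cov[i] > th$sense_protein_cov) ok <- TRUE
    if (ok) sense_set <- c(sense_set, t)
  }
  cls <- character(length(txs))
  for (j in seq_along(txs)) {
    h <- hits[hits$query_id == txs[j], , drop = FALSE]
    cls[j] <- classify_transcript(h, th, sense_set,
                                  transcript_id = txs[j])$structural_class
  }
  cls
}

# random small hits table exercising every rule region
random_hits <- function(n_tx, seed) {
  set.seed(seed)
  txs <- paste0("x", seq_len(n_tx))
  rows <- lapply(txs, function(t) {
    k <- sample(0:3, 1)
    if (!k) return(NULL)
    data.frame(query_id = t,
               subject_id = sample(c(paste0("P", 1:5), txs), k, replace = TRUE),
               subject_db = sample(c("proteome", "nr", "self_transcriptome",
                                     "genome", "nt"), k, replace = TRUE),
               orientation = sample(c("sense", "antisense"), k, replace = TRUE),
               identity = runif(k, 0.85, 1),
               query_cov = runif(k, 0.5, 1),
               subject_cov = runif(k, 0.3, 1),
               q_start = 0L, q_end = 100L, s_start = 0L, s_end = 100L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# hypergeometric upper-tail by direct log-binomial enumeration
hyper_tail_oracle <- function(x, K, N, n) {
  ks <- seq(max(0, n - (N - K)), min(n, K))
  pmf <- exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n))
  sum(pmf[ks >= x])
}
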