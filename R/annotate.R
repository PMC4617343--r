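# Structural annotation: the sequential sieve classifying transcripts as
# sense, antisense (to protein and/or to a sense transcript), lncRNA or
# unknown, plus UTR-zone assignment of antisense-to-sense transcripts.

#' Classification thresholds
#'
#' All comparisons in the classifier are strict ("more than"). Defaults:
#' sense requires >60\% protein alignment length in coding orientation;
#' antisense-to-protein >50\% protein alignment length in reverse
#' orientation; antisense-to-sense >80\% antisense transcript alignment
#' length and >95\% sequence identity against a sense transcript of the
#' same transcriptome; lncRNA >80\% alignment length and >95\% identity
#' against genome or nt; UTR-zone analysis restricted to sense partners
#' with >90\% protein coverage; putative ORFs span at least 30 amino
#' acids from a start codon to an in-frame stop.
#'
#' @param sense_protein_cov,antisense_protein_cov,antisense_sense_query_cov,antisense_sense_identity,lnc_cov,lnc_identity,zone_protein_cov fractions in (0, 1].
#' @param orf_min_aa,translate_min_aa minimum ORF lengths (amino acids).
#' @return an object of class `annotation_thresholds`.
#' @export
annotation_thresholds <- function(sense_protein_cov = 0.60,
                                  antisense_protein_cov = 0.50,
                                  antisense_sense_query_cov = 0.80,
                                  antisense_sense_identity = 0.95,
                                  lnc_cov = 0.80,
                                  lnc_identity = 0.95,
                                  zone_protein_cov = 0.90,
                                  orf_min_aa = 30L,
                                  translate_min_aa = 60L) {
  th <- list(sense_protein_cov = sense_protein_cov,
             antisense_protein_cov = antisense_protein_cov,
             antisense_sense_query_cov = antisense_sense_query_cov,
             antisense_sense_identity = antisense_sense_identity,
             lnc_cov = lnc_cov, lnc_identity = lnc_identity,
             zone_protein_cov = zone_protein_cov,
             orf_min_aa = as.integer(orf_min_aa),
             translate_min_aa = as.integer(translate_min_aa))
  fr <- unlist(th[1:7])
  if (any(fr <= 0 | fr > 1)) stop("threshold fractions must lie in (0, 1]")
  if (th$orf_min_aa < 1L) stop("orf_min_aa must be >= 1")
  structure(th, class = "annotation_thresholds")
}

PROTEIN_DBS <- c("proteome", "nr")

#' Classify one transcript from its alignment hits
#'
#' Applies the sequential sieve: (1) sense if any coding-orientation
#' protein hit exceeds the sense coverage threshold; (2) else antisense if
#' a reverse-orientation protein hit exceeds the antisense protein
#' coverage threshold (antisense-to-protein) and/or a reverse-orientation
#' hit against an established sense transcript exceeds the coverage and
#' identity thresholds (antisense-to-sense; both flags may be set);
#' (3) else lncRNA on genome, else nt, evidence above the lncRNA
#' thresholds; (4) else unknown. All comparisons are strict.
#'
#' @param hits data.frame of alignment hits for a single transcript (may
#'   have zero rows); columns as in the hits-table dialect.
#' @param thresholds an [annotation_thresholds()].
#' @param sense_set character vector of transcript ids already established
#'   as sense.
#' @param transcript_id the query id (required when `hits` is empty).
#' @return one-row data.frame: transcript_id, structural_class,
#'   antisense_to_protein, antisense_to_sense, sense_partners
#'   (comma-joined).
#' @export
classify_transcript <- function(hits, thresholds = annotation_thresholds(),
                                sense_set = character(0),
                                transcript_id = NULL) {
  if (nrow(hits)) {
    ids <- unique(hits$query_id)
    if (length(ids) != 1L) stop("hits mix multiple query_ids")
    transcript_id <- ids
  } else if (is.null(transcript_id)) {
    stop("transcript_id required when hits is empty")
  }
  th <- thresholds
  res <- function(cl, a2p = FALSE, a2s = FALSE, partners = character(0)) {
    data.frame(transcript_id = transcript_id, structural_class = cl,
               antisense_to_protein = a2p, antisense_to_sense = a2s,
               sense_partners = paste(sort(unique(partners)), collapse = ","),
               stringsAsFactors = FALSE)
  }
  if (!nrow(hits)) return(res("unknown"))
  prot <- hits$subject_db %in% PROTEIN_DBS
  if (any(prot & hits$orientation == "sense" &
          hits$subject_cov > th$sense_protein_cov, na.rm = TRUE))
    return(res("sense"))
  anti <- hits$orientation == "antisense"
  a2p <- any(prot & anti & hits$subject_cov > th$antisense_protein_cov,
             na.rm = TRUE)
  a2s_rows <- anti & hits$subject_id %in% sense_set &
    !is.na(hits$query_cov) & hits$query_cov > th$antisense_sense_query_cov &
    !is.na(hits$identity) & hits$identity > th$antisense_sense_identity
  if (a2p || any(a2s_rows))
    return(res("antisense", a2p, any(a2s_rows),
               hits$subject_id[a2s_rows]))
  lnc_ok <- function(db) any(hits$subject_db == db &
                               !is.na(hits$query_cov) &
                               hits$query_cov > th$lnc_cov &
                               !is.na(hits$identity) &
                               hits$identity > th$lnc_identity)
  if (lnc_ok("genome") || lnc_ok("nt")) return(res("lncRNA"))
  res("unknown")
}

zone_order <- c("five_prime_utr", "cds", "three_prime_utr")

#' Assign an antisense interval to UTR/CDS zones of its sense partner
#'
#' Zones on the sense transcript are 5'UTR = `[0, cds_start)`, CDS =
#' `[cds_start, cds_end)`, 3'UTR = `[cds_end, length)`; every zone whose
#' intersection with the antisense interval is nonempty is returned.
#' Intervals are 0-based half-open.
#'
#' @param antisense_interval length-2 integer vector (projected interval
#'   on the sense transcript).
#' @param cds_interval length-2 integer vector.
#' @param transcript_length length of the sense transcript.
#' @return character vector, subset of
#'   `c("five_prime_utr", "cds", "three_prime_utr")`.
#' @export
classify_antisense_zones <- function(antisense_interval, cds_interval,
                                     transcript_length) {
  a <- antisense_interval[1]; b <- antisense_interval[2]
  cs <- cds_interval[1]; ce <- cds_interval[2]
  if (!(cs >= 0 && cs < ce && ce <= transcript_length))
    stop("invalid CDS interval")
  if (!(a >= 0 && a < b && b <= transcript_length))
    stop("antisense interval outside the transcript")
  zones <- character(0)
  if (min(b, cs) > max(a, 0)) zones <- c(zones, "five_prime_utr")
  if (min(b, ce) > max(a, cs)) zones <- c(zones, "cds")
  if (min(b, transcript_length) > max(a, ce))
    zones <- c(zones, "three_prime_utr")
  zones
}

#' Annotate a whole transcriptome from an alignment table
#'
#' Two-pass evaluation: pass 1 fixes the sense set from coding-orientation
#' protein hits; pass 2 classifies the remaining transcripts against that
#' frozen sense set, so the outcome does not depend on processing order.
#' Antisense-to-sense transcripts whose partner aligns to a protein with
#' coverage above the zone threshold additionally receive the set of
#' 5'UTR/CDS/3'UTR zones their projected interval overlaps (the partner's
#' protein-hit query interval stands in for the CDS). When transcript
#' sequences are supplied, lncRNA and unknown transcripts are scanned for
#' putative ORFs.
#'
#' @param hits data.frame in the hits-table dialect (see [read_hits()]).
#' @param tx2gene data.frame with transcript_id, gene_id and (for zone
#'   assignment) length columns; defines the transcript universe.
#' @param thresholds an [annotation_thresholds()].
#' @param sequences optional named DNAStringSet (or character vector) of
#'   transcript sequences for ORF scanning.
#' @return data.frame with one row per transcript: transcript_id, gene_id,
#'   structural_class, antisense_to_protein, antisense_to_sense,
#'   sense_partners, zone_set (comma-joined), has_putative_orf.
#' @export
annotate_transcriptome <- function(hits, tx2gene,
                                   thresholds = annotation_thresholds(),
                                   sequences = NULL) {
  th <- thresholds
  txs <- tx2gene$transcript_id
  if (nrow(hits) && !all(hits$query_id %in% txs))
    stop("hits reference transcripts absent from the gene map: ",
         paste(head(setdiff(hits$query_id, txs), 5), collapse = ", "))

  prot <- hits$subject_db %in% PROTEIN_DBS
  sense_hit <- prot & hits$orientation == "sense" &
    !is.na(hits$subject_cov) & hits$subject_cov > th$sense_protein_cov
  sense_set <- unique(hits$query_id[sense_hit])

  a2p_set <- unique(hits$query_id[prot & hits$orientation == "antisense" &
                                    !is.na(hits$subject_cov) &
                                    hits$subject_cov > th$antisense_protein_cov])
  a2s_rows <- which(hits$orientation == "antisense" &
                      hits$subject_id %in% sense_set &
                      !is.na(hits$query_cov) &
                      hits$query_cov > th$antisense_sense_query_cov &
                      !is.na(hits$identity) &
                      hits$identity > th$antisense_sense_identity)
  a2s_set <- unique(hits$query_id[a2s_rows])
  lnc_set <- unique(hits$query_id[hits$subject_db %in% c("genome", "nt") &
                                    !is.na(hits$query_cov) &
                                    hits$query_cov > th$lnc_cov &
                                    !is.na(hits$identity) &
                                    hits$identity > th$lnc_identity])

  cls <- rep("unknown", length(txs))
  names(cls) <- txs
  cls[txs %in% lnc_set] <- "lncRNA"
  cls[txs %in% c(a2p_set, a2s_set)] <- "antisense"
  cls[txs %in% sense_set] <- "sense"
  is_anti <- cls == "antisense"

  partners <- setNames(rep("", length(txs)), txs)
  if (length(a2s_rows)) {
    pl <- split(hits$subject_id[a2s_rows], hits$query_id[a2s_rows])
    pl <- vapply(pl, function(p) paste(sort(unique(p)), collapse = ","), "")
    partners[names(pl)[names(pl) %in% txs[is_anti]]] <-
      pl[names(pl) %in% txs[is_anti]]
  }

  # zone assignment: partner CDS taken from its best >90%-coverage protein hit
  zone_set <- setNames(rep("", length(txs)), txs)
  elig <- which(sense_hit & hits$subject_cov > th$zone_protein_cov)
  if (length(elig) && length(a2s_rows)) {
    best <- elig[order(hits$query_id[elig], -hits$subject_cov[elig])]
    best <- best[!duplicated(hits$query_id[best])]
    cds_of <- setNames(best, hits$query_id[best])
    len_of <- setNames(tx2gene$length, tx2gene$transcript_id)
    for (r in a2s_rows) {
      q <- hits$query_id[r]
      if (cls[q] != "antisense") next
      p <- hits$subject_id[r]
      if (is.na(cds_of[p])) next
      cr <- cds_of[[p]]
      z <- classify_antisense_zones(c(hits$s_start[r], hits$s_end[r]),
                                    c(hits$q_start[cr], hits$q_end[cr]),
                                    len_of[[p]])
      old <- strsplit(zone_set[[q]], ",", fixed = TRUE)[[1]]
      zone_set[q] <- paste(intersect(zone_order, union(old, z)),
                           collapse = ",")
    }
  }

  has_orf <- rep(NA, length(txs))
  if (!is.null(sequences)) {
    sq <- as.character(sequences)
    scan <- which(cls %in% c("lncRNA", "unknown") & txs %in% names(sq))
    has_orf[scan] <- vapply(txs[scan], function(t)
      nrow(find_orfs(sq[[t]], th$orf_min_aa)) > 0, NA)
  }

  data.frame(transcript_id = txs, gene_id = tx2gene$gene_id,
             structural_class = unname(cls),
             antisense_to_protein = txs %in% a2p_set & is_anti,
             antisense_to_sense = txs %in% a2s_set & is_anti,
             sense_partners = unname(partners),
             zone_set = unname(zone_set),
             has_putative_orf = has_orf,
             stringsAsFactors = FALSE)
}

#' Read / write the hits-table dialect
#'
#' Tab-separated with a header row: query_id, subject_id, subject_db,
#' orientation, identity, query_cov, subject_cov, q_start, q_end, s_start,
#' s_end — BLAST-tabular-like, extended with explicit orientation and
#' fractional coverages.
#'
#' @param path file path.
#' @return data.frame of hits.
#' @export
read_hits <- function(path) {
  h <- read_tsv(path)
  need <- c("query_id", "subject_id", "subject_db", "orientation",
            "identity", "query_cov", "subject_cov", "q_start", "q_end",
            "s_start", "s_end")
  if (!all(need %in% names(h)))
    stop("hits table missing columns: ",
         paste(setdiff(need, names(h)), collapse = ", "))
  h
}

#' @rdname read_hits
#' @param annotations data.frame from [annotate_transcriptome()].
#' @export
write_annotations <- function(annotations, path) write_tsv(annotations, path)
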