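# Gene-level comparison framework: pooling significant transcripts over
# time points per conditioning type, the three-rule LTM-vs-ARM filter,
# and Venn overlap accounting.

#' Pool significant DE calls to gene level per conditioning type
#'
#' Per gene and conditioning type, the union over time points of
#' significant (transcript, direction) pairs, with the contributing time
#' points recorded.
#'
#' @param calls a [fit_and_test()] result (or any data.frame with
#'   transcript_id, conditioning_type, time_point, direction,
#'   significant).
#' @param tx2gene data.frame with transcript_id and gene_id.
#' @return data.frame: gene_id, conditioning_type, transcript_id,
#'   direction, time_points (comma-joined).
#' @export
summarize_gene_de <- function(calls, tx2gene) {
  sig <- calls[calls$significant, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), conditioning_type = character(0),
                      transcript_id = character(0), direction = character(0),
                      time_points = character(0), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  g <- tx2gene$gene_id[match(sig$transcript_id, tx2gene$transcript_id)]
  if (anyNA(g))
    stop("transcripts without gene mapping: ",
         paste(head(unique(sig$transcript_id[is.na(g)]), 5), collapse = ", "))
  key <- paste(g, sig$conditioning_type, sig$transcript_id, sig$direction,
               sep = "\r")
  tp <- vapply(split(sig$time_point, key),
               function(x) paste(sort(unique(x)), collapse = ","), "")
  parts <- strsplit(names(tp), "\r", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1),
                    conditioning_type = vapply(parts, `[`, "", 2),
                    transcript_id = vapply(parts, `[`, "", 3),
                    direction = vapply(parts, `[`, "", 4),
                    time_points = unname(tp), stringsAsFactors = FALSE)
  out[order(out$gene_id, out$conditioning_type, out$transcript_id), ,
      drop = FALSE]
}

dirs_of <- function(summary, type, tx) {
  unique(summary$direction[summary$conditioning_type == type &
                             summary$transcript_id == tx])
}

#' Does one gene show an opposing expression pattern between two types?
#'
#' TRUE iff the gene has significant transcripts in both conditioning
#' types, at least one transcript is shared, and every shared transcript
#' changes in strictly opposite directions (a transcript reported in both
#' directions within one type blocks the predicate).
#'
#' @param summary rows of [summarize_gene_de()] for a single gene.
#' @param type_a,type_b conditioning-type labels.
#' @return logical.
#' @export
detect_opposing <- function(summary, type_a, type_b) {
  in_a <- unique(summary$transcript_id[summary$conditioning_type == type_a])
  in_b <- unique(summary$transcript_id[summary$conditioning_type == type_b])
  if (!length(in_a) || !length(in_b)) return(FALSE)
  shared <- intersect(in_a, in_b)
  if (!length(shared)) return(FALSE)
  all(vapply(shared, function(tx) {
    da <- dirs_of(summary, type_a, tx)
    db <- dirs_of(summary, type_b, tx)
    length(da) == 1L && length(db) == 1L && da != db
  }, NA))
}

#' The three-rule LTM-vs-ARM candidate filter
#'
#' A gene significant in an LTM conditioning type is retained for that
#' type iff (1) none of its transcripts is DE in the ARM type
#' (`absent_in_arm`); or (2) every transcript DE in both that LTM type and
#' ARM changes in opposite directions (`opposing`); or (3) the DE
#' transcript sets of the LTM type and ARM are disjoint sets of splice
#' variants (`splice_variant`). Genes failing all three for a given LTM
#' type are excluded for that type. When several rules apply the recorded
#' rule follows the precedence absent_in_arm > opposing > splice_variant
#' (retention itself is the disjunction).
#'
#' @param summaries a [summarize_gene_de()] data.frame.
#' @param ltm_types character vector of LTM conditioning-type labels.
#' @param arm_type the ARM conditioning-type label.
#' @return data.frame of retained candidates: gene_id, ltm_type, rule,
#'   ltm_evidence, arm_evidence ("transcript:direction" lists).
#' @export
apply_ltm_filter <- function(summaries, ltm_types, arm_type) {
  out <- list()
  ev <- function(d) paste(sort(paste(d$transcript_id, d$direction, sep = ":")),
                          collapse = ",")
  for (g in unique(summaries$gene_id)) {
    sg <- summaries[summaries$gene_id == g, , drop = FALSE]
    arm <- sg[sg$conditioning_type == arm_type, , drop = FALSE]
    for (ty in ltm_types) {
      ltm <- sg[sg$conditioning_type == ty, , drop = FALSE]
      if (!nrow(ltm)) next
      rule <- if (!nrow(arm)) "absent_in_arm"
        else if (detect_opposing(sg, ty, arm_type)) "opposing"
        else if (!length(intersect(ltm$transcript_id, arm$transcript_id)))
          "splice_variant"
        else NA_character_
      if (!is.na(rule))
        out[[length(out) + 1L]] <-
          data.frame(gene_id = g, ltm_type = ty, rule = rule,
                     ltm_evidence = ev(ltm), arm_evidence = ev(arm),
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), ltm_type = character(0),
                      rule = character(0), ltm_evidence = character(0),
                      arm_evidence = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Inclusion-exclusion region counts for labelled gene sets
#'
#' Cross-species comparisons resolve gene ids through an ortholog map
#' before the set algebra: mapped genes are replaced by their
#' ortholog-group id (one-to-many entries project both genes to the
#' group), unmapped genes stay species-unique.
#'
#' @param sets named list of character vectors.
#' @param orthologs optional data.frame gene_id / ortholog_group.
#' @return data.frame `region` (labels joined by "&") / `count`, one row
#'   per nonempty label subset; counts sum to the size of the union.
#' @export
compute_overlaps <- function(sets, orthologs = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  if (!is.null(orthologs)) {
    proj <- function(x) {
      m <- match(x, orthologs$gene_id)
      unique(ifelse(is.na(m), x, orthologs$ortholog_group[m]))
    }
    sets <- lapply(sets, proj)
  } else sets <- lapply(sets, unique)
  labs <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, labs))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(labs)))[-1, ,
                                                                  drop = FALSE]
  names(subsets) <- labs
  region <- apply(subsets, 1L, function(p) paste(labs[as.logical(p)],
                                                 collapse = "&"))
  count <- apply(subsets, 1L, function(p) {
    if (!length(universe)) return(0L)
    sum(apply(member, 1L, function(m) all(m == as.logical(p))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}
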