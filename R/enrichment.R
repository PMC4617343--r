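# Term enrichment over an is_a DAG with GO-slim projection and one-sided
# Fisher exact tests.

#' Read a minimal OBO ontology
#'
#' Parses `[Term]` stanzas, keeping id, name, namespace and `is_a` edges
#' (comments after `!` stripped, obsolete terms dropped). Only the
#' subset of OBO needed for slim projection is supported.
#'
#' @param path OBO file path.
#' @return list with `terms` (data.frame id/name/namespace) and `edges`
#'   (data.frame child/parent).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); edges <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<-
        data.frame(id = cur$id, name = cur$name %||% "",
                   namespace = cur$namespace %||% "", stringsAsFactors = FALSE)
      for (p in cur$parents)
        edges[[length(edges) + 1L]] <<-
          data.frame(child = cur$id, parent = p, stringsAsFactors = FALSE)
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:"))
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_a:"))
      cur$parents <- c(cur$parents,
                       trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
    else if (startsWith(ln, "is_obsolete: true")) cur$obsolete <- TRUE
  }
  flush()
  list(terms = if (length(terms)) do.call(rbind, terms) else
         data.frame(id = character(0), name = character(0),
                    namespace = character(0)),
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(child = character(0), parent = character(0)))
}

#' All is_a ancestors of a term (not including the term itself)
#' @param ontology list as returned by [read_obo()].
#' @param id term id.
#' @return character vector of ancestor ids.
#' @export
term_ancestors <- function(ontology, id) {
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    parents <- unique(ontology$edges$parent[ontology$edges$child %in% frontier])
    parents <- setdiff(parents, seen)
    seen <- c(seen, parents)
    frontier <- parents
  }
  seen
}

#' Project gene annotations onto a slim subset
#'
#' Each gene's term set is replaced by the slim terms that are the term
#' itself or any of its is_a ancestors.
#'
#' @param annotations data.frame gene_id / term_id.
#' @param ontology list as returned by [read_obo()].
#' @param slim character vector of slim term ids (must be ontology terms).
#' @return data.frame gene_id / term_id restricted to slim terms.
#' @export
map_to_slim <- function(annotations, ontology, slim) {
  unknown <- setdiff(unique(annotations$term_id), ontology$terms$id)
  if (length(unknown))
    stop("unknown term ids: ", paste(head(unknown, 10), collapse = ", "))
  stopifnot(all(slim %in% ontology$terms$id))
  uterms <- unique(annotations$term_id)
  slim_of <- lapply(uterms, function(t)
    intersect(slim, c(t, term_ancestors(ontology, t))))
  names(slim_of) <- uterms
  out <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    st <- slim_of[[annotations$term_id[i]]]
    if (!length(st)) return(NULL)
    data.frame(gene_id = annotations$gene_id[i], term_id = st,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(gene_id = character(0),
                                      term_id = character(0))
  unique(out)
}

#' One-sided Fisher exact over-representation test per term
#'
#' For every term annotated in the population, tests over-representation
#' of the term among study genes with the hypergeometric upper tail of
#' the 2x2 table (study hits, study misses, remaining hits, remaining
#' misses).
#'
#' @param study character vector of study gene ids (subset of
#'   population).
#' @param population character vector of background gene ids.
#' @param annotations data.frame gene_id / term_id (slim-projected or
#'   not).
#' @param alpha significance threshold.
#' @return data.frame ordered by p-value: term_id, study_hit, study_n,
#'   pop_hit, pop_n, p_value, enriched.
#' @export
fisher_enrichment <- function(study, population, annotations, alpha = 0.05) {
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population)) stop("study genes outside the population")
  ann <- unique(annotations[annotations$gene_id %in% population, ,
                            drop = FALSE])
  pop_n <- length(population); study_n <- length(study)
  terms <- unique(ann$term_id)
  pop_hit <- vapply(terms, function(t)
    length(unique(ann$gene_id[ann$term_id == t])), 0L)
  study_hit <- vapply(terms, function(t)
    sum(unique(ann$gene_id[ann$term_id == t]) %in% study), 0L)
  p <- phyper(study_hit - 1L, pop_hit, pop_n - pop_hit, study_n,
              lower.tail = FALSE)
  out <- data.frame(term_id = terms, study_hit = study_hit,
                    study_n = study_n, pop_hit = pop_hit, pop_n = pop_n,
                    p_value = p, enriched = p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
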