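# Read-support filtering of the count matrix.

#' Counts per million
#'
#' `cpm(t, s) = count(t, s) / library_size(s) * 1e6`, where the library
#' size is the column sum of the matrix as given.
#'
#' @param counts nonnegative integer matrix, transcripts x samples.
#' @return real-valued matrix of the same shape.
#' @export
cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("zero library size")
  t(t(counts) / libsize) * 1e6
}

#' Filter transcripts with too little read support
#'
#' Keeps exactly the transcripts with CPM strictly above `cpm_threshold`
#' in at least `min_samples` samples ("more than one read count per
#' million reads for at least three samples"). When an exclusion list is
#' supplied (e.g. contaminant transcripts), those rows are dropped first
#' and library sizes recomputed before the CPM rule is evaluated.
#'
#' @param counts nonnegative integer matrix, transcripts x samples.
#' @param cpm_threshold CPM cutoff (strict).
#' @param min_samples minimum number of samples above the cutoff.
#' @param exclude character vector of transcript ids to remove up front.
#' @return the filtered count matrix (same columns).
#' @export
filter_low_support <- function(counts, cpm_threshold = 1, min_samples = 3L,
                               exclude = NULL) {
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(exclude))
    counts <- counts[!rownames(counts) %in% exclude, , drop = FALSE]
  keep <- rowSums(cpm(counts) > cpm_threshold) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Read / write count and sample tables
#'
#' `counts.tsv` has transcript_id as its first column and one integer
#' column per sample; `samples.tsv` has sample_id, species,
#' conditioning_type, time_point, replicate.
#'
#' @param path file path.
#' @return `read_counts`: integer matrix with transcript rownames;
#'   `read_samples`: data.frame.
#' @export
read_counts <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_counts
#' @export
read_samples <- function(path) {
  s <- read_tsv(path)
  need <- c("sample_id", "species", "conditioning_type", "time_point",
            "replicate")
  if (!all(need %in% names(s)))
    stop("samples table missing columns: ",
         paste(setdiff(need, names(s)), collapse = ", "))
  key <- paste(s$species, s$conditioning_type, s$time_point, s$replicate)
  if (anyDuplicated(key))
    stop("duplicate (species, conditioning_type, time_point, replicate)")
  s
}
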