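#' Find putative open reading frames on one strand
#'
#' Scans the three forward frames for maximal start-to-stop ORFs: from the
#' first ATG after the preceding in-frame stop to the next in-frame stop,
#' requiring at least `min_aa` codons between start codon and stop (the
#' start codon counts, the stop does not). ORFs without an in-frame stop
#' are not reported. Intervals are 0-based half-open on the input strand
#' and include the stop codon.
#'
#' @param sequence nucleotide string over A, C, G, T, N (case-insensitive).
#'   Codons containing N are treated as ordinary non-start, non-stop
#'   codons.
#' @param min_aa minimum ORF length in amino acids (default 30).
#' @return data.frame with columns frame (0-2), start, end, length_aa;
#'   zero rows when no ORF qualifies.
#' @export
find_orfs <- function(sequence, min_aa = 30L) {
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-nucleotide characters")
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L)
    cod <- substring(s, starts + 1L, starts + 3L)
    atg_open <- NA_integer_
    for (j in seq_len(ncod)) {
      if (cod[j] %in% stops) {
        if (!is.na(atg_open)) {
          aa <- j - atg_open
          if (aa >= min_aa)
            out[[length(out) + 1L]] <-
              data.frame(frame = frame, start = starts[atg_open],
                         end = starts[j] + 3L, length_aa = aa)
        }
        atg_open <- NA_integer_
      } else if (is.na(atg_open) && cod[j] == "ATG") {
        atg_open <- j
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), length_aa = integer(0)))
  do.call(rbind, out)
}
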