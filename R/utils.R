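# Internal helpers: deterministic sub-stream seeds, logging, TSV io.

# Derive a deterministic per-stage seed (< 2^31) from a master seed and a
# stage label, so each pipeline stage consumes an independent stream.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

md_log <- function(stage, ...) {
  message(sprintf("[memorydiff] %s | %s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
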