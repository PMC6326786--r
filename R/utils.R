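# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL runs code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` reproducible sub-seeds from one master seed. Sub-streams for
# independent components (simulation, shuffle, rewiring, sampling) are drawn
# from here so that each component is reproducible in isolation.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Read a TSV with '#' comment lines, keeping original line numbers so parse
# errors can point at the offending line.
read_tsv_lines <- function(path) {
  if (!file.exists(path))
    stop("cannot open file '", path, "': no such file")
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], numbers = which(keep))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
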