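# Shared internal helpers.

# Deterministic TSV writer: fixed column order as given, no quoting surprises,
# "." decimal, LF line endings. Used by every report writer so that repeated
# runs of the pipeline produce byte-identical outputs.
write_tsv_det <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x, path, eol = "\n", progress = FALSE)
  invisible(path)
}

write_json_det <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Draw from a seeded local RNG without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label; keeps all
# randomness attributable to one top-level seed while decoupling stages.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 100003L)
}
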