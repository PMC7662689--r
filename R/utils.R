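# internal helpers shared across modules

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
}

# Derive a child seed for a generator stage from the study seed. Keeps the
# result strictly below 2^31 so it is a valid R integer seed.
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 100000L) * 19937L + as.integer(stage)
}

# canonical identifier conventions: miRNA ids lowercase, gene symbols upper
canonical_mirna <- function(x) tolower(trimws(x))
canonical_gene <- function(x) toupper(trimws(x))

paste_sources <- function(x) {
  paste(sort(unique(unlist(strsplit(x, ";", fixed = TRUE)))), collapse = ";")
}
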