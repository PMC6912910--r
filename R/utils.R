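#' @keywords internal
"_PACKAGE"

# Canonical taxon-name form: trimmed, internal whitespace runs and
# underscores unified to a single underscore. Matching is exact on the
# canonical form; no fuzzy matching.
canonical_name <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ _]+", "_", x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. Keeps all package randomness
# flowing from explicit seeds instead of hidden global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a hash of a character scalar, returned as a nonnegative
# integer-valued double < 2^31. Used to derive per-plot child seeds from
# plot ids (order-independent) and to fingerprint run configs.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # multiplication kept exact in doubles by splitting into 16-bit halves
    hi <- floor(h / 65536)
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h %% 2147483647
}

# Deterministic child seed from a master seed and a string key.
child_seed <- function(seed, key) {
  as.integer((as.numeric(seed) + fnv1a32(key)) %% 2147483647) + 1L
}

config_hash <- function(config) {
  sprintf("%08x", fnv1a32(paste(deparse(config), collapse = "\n")))
}

# Write a data.frame as CSV with a '#'-comment header carrying seed and
# config hash, so every output file is self-describing and byte-stable.
write_output_csv <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed) || !is.null(hash)) {
    writeLines(sprintf("# seed=%s config=%s",
                       if (is.null(seed)) "NA" else seed,
                       if (is.null(hash)) "NA" else hash), con)
  }
  utils::write.csv(format(df, trim = TRUE, digits = 15), con,
                   row.names = FALSE, quote = FALSE)
}

read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
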