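# internal helpers shared across modules

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# 32-bit modular multiply, exact in double precision (16-bit split)
mulmod32 <- function(x, y) {
  lo <- y %% 65536
  hi <- y %/% 65536
  ((x * lo) %% 4294967296 + ((x * hi) %% 65536) * 65536) %% 4294967296
}

# 32-bit xor on doubles (bitwXor only accepts values below 2^31)
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 +
    bitwXor(a %% 65536, b %% 65536)
}

# FNV-1a 32-bit hash of character input, as 8 hex digits.
# Used only to stamp pipeline reports with a config fingerprint.
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

read_tsv_strict <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
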