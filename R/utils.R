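# Small internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

vec_norm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise softmax with optional mask (FALSE entries get probability 0).
# Rows with no unmasked entry come back as all zeros.
softmax_rows <- function(x, mask = NULL) {
  if (!is.null(mask)) x[!mask] <- -Inf
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  e <- exp(x - m)
  e[!is.finite(e)] <- 0
  s <- rowSums(e)
  out <- e / ifelse(s > 0, s, 1)
  out
}

# FNV-1a over a character scalar; used to fingerprint the feature dictionary
# so checkpoints refuse to load against an incompatible featurization.
# Arithmetic kept in doubles below 2^53 so the mod-2^32 state stays exact.
fnv1a_hash <- function(x) {
  mul32 <- function(a, b) {
    a_hi <- floor(a / 65536)
    a_lo <- a %% 65536
    ((a_lo * b) %% 4294967296 + ((a_hi * b) %% 65536) * 65536) %% 4294967296
  }
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

NUCLEOTIDES <- c("A", "U", "C", "G")
SS_SYMBOLS <- c(".", "(", ")")
BACKBONE_ATOMS <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")
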