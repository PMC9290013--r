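# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) logsumexp(x) - log(length(x))

# Deterministic child seeds: keeps every stream independent of the others
# while staying inside the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + offs * 69621) %% 2147483587L) + 1L
}

# Run code under a local RNG state so package internals never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Content fingerprint for "same data" checks between fits; hashes the
# serialized object so any numeric or label change is detected.
data_fingerprint <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # simple 64-bit FNV-1a over the serialized payload
  h <- 14695981039346656037
  p <- 1099511628211
  m <- 2^64
  v <- as.integer(raw)
  # fold in chunks to keep the loop cheap
  for (i in seq(1L, length(v), by = 8L)) {
    chunk <- v[i:min(i + 7L, length(v))]
    word <- sum(chunk * 256^(seq_along(chunk) - 1))
    h <- ((bitwXor64(h, word)) * p) %% m
  }
  sprintf("%.0f", h)
}

# xor for doubles holding 64-bit unsigned values (R lacks 64-bit ints).
bitwXor64 <- function(a, b) {
  ah <- a %/% 2^32; al <- a %% 2^32
  bh <- b %/% 2^32; bl <- b %% 2^32
  xh <- bitwXor(as.integer(ah %% 2^31), as.integer(bh %% 2^31)) +
    2^31 * (abs((ah %/% 2^31) - (bh %/% 2^31)) %% 2)
  xl <- bitwXor(as.integer(al %% 2^31), as.integer(bl %% 2^31)) +
    2^31 * (abs((al %/% 2^31) - (bl %/% 2^31)) %% 2)
  xh * 2^32 + xl
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

stop_ms <- function(fmt, ..., class = "multistep_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

warn_ms <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
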