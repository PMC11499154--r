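# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table data.table as.data.table is.data.table setkey
#'   setkeyv setorder setorderv := .N .SD fread fwrite setnames copy
#'   rbindlist setDT setattr rleid
NULL

# Vectorised Hamming distance between equal-length strings.
hamming_dist <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer(0))
  la <- nchar(a)
  if (any(la != nchar(b))) stop("hamming_dist: unequal string lengths")
  L <- la[1L]
  if (any(la != L)) stop("hamming_dist: strings must all have equal length")
  d <- integer(length(a))
  for (i in seq_len(L)) {
    d <- d + (substr(a, i, i) != substr(b, i, i))
  }
  d
}

# Random fixed-length DNA strings.
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n, ncol = len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# Random amino-acid strings of the given lengths.
random_aa <- function(lens) {
  vapply(lens, function(L) {
    paste0(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Centered moving average; the window shrinks symmetrically at the edges.
moving_average <- function(v, window) {
  if (window <= 1L) return(v)
  h <- window %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

# Deterministic per-stage seed derived from a master seed; kept under 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Deterministic string hash -> uniform-ish value in [0, 1).
hash_unit <- function(strings, seed = 0L) {
  p <- 2147483647
  vapply(strings, function(s) {
    h <- 7
    for (b in utf8ToInt(s)) h <- (h * 131 + b) %% p
    (((h + 1) * 48271 + (as.numeric(seed) * 69621)) %% p) / p
  }, numeric(1), USE.NAMES = FALSE)
}

stop_invariant <- function(name, detail) {
  stop(sprintf("invariant violated: %s (%s)", name, detail), call. = FALSE)
}
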