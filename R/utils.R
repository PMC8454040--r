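# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive `n` child seeds from one master seed, each < 2^31.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# All permutations of seq_len(n), rows in lexicographic order.
permutationsOf <- function(n) {
  stopifnot(n >= 1L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

# EC number truncated to its first `digits` dotted fields.
ecPrefix <- function(ec, digits) {
  vapply(strsplit(ec, ".", fixed = TRUE), function(f)
    paste(f[seq_len(min(digits, length(f)))], collapse = "."), character(1))
}

# Does each EC number start with the dotted-field prefix `prefix`?
ecMatchesPrefix <- function(ec, prefix) {
  pf <- strsplit(prefix, ".", fixed = TRUE)[[1]]
  vapply(strsplit(ec, ".", fixed = TRUE), function(f)
    length(f) >= length(pf) && all(f[seq_along(pf)] == pf), logical(1))
}

# Lossless decimal rendering of doubles for JSON serialization: 17
# significant digits round-trip any IEEE double exactly.
numToChar <- function(x) sprintf("%.17g", as.numeric(x))
charToNum <- function(x) as.numeric(x)
matToChar <- function(m) list(dim = dim(m), values = numToChar(m))
charToMat <- function(obj) matrix(charToNum(obj$values), obj$dim[1], obj$dim[2])

# Mutant binarization: components at or above one half become 1, else 0.
binarize05 <- function(v) as.numeric(v >= 0.5)

stopDim <- function(msg) stop("dimension-error: ", msg, call. = FALSE)
stopParam <- function(msg) stop("parameter-error: ", msg, call. = FALSE)
stopFormat <- function(msg) stop("format-error: ", msg, call. = FALSE)
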