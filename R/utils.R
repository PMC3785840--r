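# Internal numerical and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' Folds a master seed and an arbitrary sequence of string/integer tags into
#' a single seed below 2^31, so every random draw site in the package can be
#' given its own deterministic stream derived from one user-facing seed.
#'
#' @param master integer master seed.
#' @param ... tags (character or integer) identifying the substream.
#' @return a single integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) as.integer(unlist(lapply(p, utf8ToInt))) else as.integer(p)
  }), use.names = FALSE)
  m <- 2147483647 # 2^31 - 1, prime; products stay below 2^53 in doubles
  s <- as.numeric(master) %% m
  for (v in parts) s <- (s * 69069 + as.numeric(v) + 1) %% m
  as.integer(s)
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Pairwise squared Euclidean distances between rows of A (m x d) and B (n x d).
sqdist <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  D <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

# Row-wise log-sum-exp; rows that are all -Inf stay -Inf (no NaN).
row_logsumexp <- function(M) {
  M <- as.matrix(M)
  mx <- apply(M, 1L, max)
  out <- rep(-Inf, nrow(M))
  ok <- is.finite(mx)
  if (any(ok)) {
    out[ok] <- mx[ok] + log(rowSums(exp(M[ok, , drop = FALSE] - mx[ok])))
  }
  out
}

# Format numbers for text artifacts: 12 significant digits keeps checksums
# stable across platforms with identical FP arithmetic.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
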