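`%||%` <- function(a, b) if (is.null(a)) b else a

fsq <- function(x) sum(x * x)  # squared Frobenius norm

## identity on the leading square block, zero elsewhere
eye_pad <- function(nrow, ncol) {
  out <- matrix(0, nrow, ncol)
  k <- min(nrow, ncol)
  if (k > 0) out[cbind(seq_len(k), seq_len(k))] <- 1
  out
}

## ridge-guarded symmetric solve: X = solve(S, B); falls back to S + ridge*I
solve_sym <- function(S, B, ridge = 0) {
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  out <- tryCatch(solve(S, B), error = function(e) NULL)
  if (is.null(out)) {
    warning("singular operator; adding ridge", call. = FALSE)
    out <- solve(S + diag(max(1e-8, ridge), nrow(S)), B)
  }
  out
}

## 32-bit FNV-1a hash of a character scalar, as hex; used to stamp result rows
## so a row can be regenerated from its config alone
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 0x811c9dc5
  for (b in bytes) {
    ## xor only touches the low byte (b < 256); keeps h a double in 0..2^32
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## h * 16777619 mod 2^32, split (16777619 = 403 + 2^24) to stay exact in doubles
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  ## format as hex; h may exceed .Machine$integer.max, so split into two halves
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## deterministic sub-seed derived from a base seed and small indices (< 2^31)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i) %% 2147483647
  as.integer(s)
}

## random matrix with orthonormal columns (nrow >= ncol)
rorth <- function(nrow, ncol) {
  qr.Q(qr(matrix(rnorm(nrow * ncol), nrow, ncol)))[, seq_len(ncol), drop = FALSE]
}
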