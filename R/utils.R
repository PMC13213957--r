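# Internal helpers shared across modules.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa321 <- function(res3) {
  out <- AA1[match(res3, AA3)]
  out[is.na(out)] <- "X"
  out
}

aa123 <- function(res1) {
  out <- AA3[match(res1, AA1)]
  out[is.na(out)] <- "UNK"
  out
}

# All pairwise Euclidean distances between the rows of two n x 3 matrices.
crossDist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Fold an arbitrary integer key into the valid set.seed range.
seedKey <- function(...) {
  parts <- as.numeric(c(...))
  key <- 0
  for (p in parts) key <- (key * 7919 + p) %% 2147483629
  as.integer(key)
}

normalize3 <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-8) stop("degenerate ", what, ": zero length")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

siluGrad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}
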