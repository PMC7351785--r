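# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementation.

# Eq.-by-the-book average precision
oracleAP <- function(y, yk) {
  K <- length(yk)
  matches <- sum(yk == y)
  if (matches == 0) return(0)
  s <- 0
  for (k in seq_len(K)) {
    if (yk[k] == y) s <- s + sum(yk[seq_len(k)] == y) / k
  }
  s / matches
}

# exact 1-D optimal transport between equal-size samples by enumerating all
# assignments (the LP optimum for the discrete problem); n <= 7
oracleW1 <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) <= 7)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_along(v)))
    best <- min(best, mean(abs(u - v[p])))
  best
}

# exhaustive k-NN scan
oracleKnn <- function(ref, q, k) {
  d <- apply(ref, 1, function(r) sqrt(sum((r - q)^2)))
  order(d, seq_along(d))[seq_len(k)]
}

# double-loop mutual nearest neighbors
oracleMNN <- function(a, b, k) {
  da <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  nnA <- lapply(seq_len(nrow(a)), function(i) {
    d <- vapply(seq_len(nrow(b)), function(j) da(i, j), numeric(1))
    order(d, seq_along(d))[seq_len(min(k, nrow(b)))]
  })
  nnB <- lapply(seq_len(nrow(b)), function(j) {
    d <- vapply(seq_len(nrow(a)), function(i) da(i, j), numeric(1))
    order(d, seq_along(d))[seq_len(min(k, nrow(a)))]
  })
  out <- list()
  for (i in seq_len(nrow(a)))
    for (j in nnA[[i]])
      if (i %in% nnB[[j]]) out[[length(out) + 1]] <- c(i, j)
  if (!length(out)) return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, out)
  data.frame(a = m[, 1], b = m[, 2])
}

# write a small OBO file and return its path
writeOboFixture <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}
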