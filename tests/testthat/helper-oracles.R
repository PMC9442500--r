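# Independent brute-force oracles: deliberately naive, loop-based, and
# sharing no code with the package implementation.

oracle_count_kmers <- function(residues, k, ambiguity = character(0)) {
  n <- nchar(residues)
  words <- character(0)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(residues, i, i + k - 1)
      if (!any(strsplit(w, "")[[1]] %in% ambiguity))
        words <- c(words, w)
    }
  }
  out <- table(words)
  structure(as.integer(out), names = as.character(names(out)))
}

oracle_count_kmers_masked <- function(residues, pos, k = 3L,
                                      ambiguity = character(0)) {
  n <- nchar(residues)
  words <- character(0)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      win <- strsplit(substr(residues, i, i + k - 1), "")[[1]]
      if (!any(win %in% ambiguity))
        words <- c(words, paste(win[pos], collapse = ""))
    }
  }
  out <- table(words)
  structure(as.integer(out), names = as.character(names(out)))
}

# dense count vector of a sequence over an explicit word list
oracle_dense <- function(residues, k, words, ambiguity = character(0)) {
  cnt <- oracle_count_kmers(residues, k, ambiguity)
  out <- numeric(length(words))
  names(out) <- words
  out[names(cnt)] <- cnt
  out
}

oracle_metric <- function(which, x, y) {
  # x, y: dense count vectors over the same word list
  fx <- if (sum(x) > 0) x / sum(x) else x
  fy <- if (sum(y) > 0) y / sum(y) else y
  switch(which,
    d2raw = sum(x * y),
    d2 = {
      cosv <- sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
      0.5 * (1 - cosv)
    },
    euclid = sqrt(sum((fx - fy)^2)),
    manh = sum(abs(fx - fy)),
    cheby = max(abs(fx - fy)),
    ncanb = {
      keep <- (fx + fy) > 0
      sum(abs(fx[keep] - fy[keep]) / (fx[keep] + fy[keep])) / sum(keep)
    },
    bc = 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y)),
    ngd = (max(sum(x), sum(y)) - sum(pmin(x, y))) /
          (sum(x) + sum(y) - min(sum(x), sum(y))))
}

oracle_d2star_d2s <- function(res_r, res_q, k) {
  words <- character(0)
  grid <- rep(list(c("A", "C", "G", "T")), k)
  g <- expand.grid(grid, stringsAsFactors = FALSE)
  words <- do.call(paste0, g)
  x <- oracle_dense(res_r, k, words)
  y <- oracle_dense(res_q, k, words)
  lp <- function(s) {
    ch <- strsplit(s, "")[[1]]
    vapply(c("A", "C", "G", "T"), function(a) mean(ch == a), 0)
  }
  pr <- lp(res_r); pq <- lp(res_q)
  nr <- sum(x); nq <- sum(y)
  num <- nx <- ny <- 0; numS <- nxS <- nyS <- 0
  for (i in seq_along(words)) {
    ch <- strsplit(words[i], "")[[1]]
    pwr <- prod(pr[ch]); pwq <- prod(pq[ch])
    X <- x[i] - nr * pwr; Y <- y[i] - nq * pwq
    if (pwr > 0 && pwq > 0) {
      num <- num + X * Y / (sqrt(nr * nq) * sqrt(pwr * pwq))
      nx <- nx + X^2 / (nr * pwr)
      ny <- ny + Y^2 / (nq * pwq)
    }
    den <- sqrt(X^2 + Y^2)
    if (den > 0) {
      numS <- numS + X * Y / den
      nxS <- nxS + X^2 / den
      nyS <- nyS + Y^2 / den
    }
  }
  c(d2star = unname(0.5 * (1 - num / (sqrt(nx) * sqrt(ny)))),
    d2s = unname(0.5 * (1 - numS / (sqrt(nxS) * sqrt(nyS)))))
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(alphabet("aa")$symbols, n, replace = TRUE), collapse = "")
}
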