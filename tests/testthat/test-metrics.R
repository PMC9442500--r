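count1 <- function(s, alpha = "dna", k = 1L)
  count_kmers(seq_record("x", s, alpha), kmer_spec(alpha, k))
freq1 <- function(s, alpha = "dna", k = 1L) to_frequencies(count1(s, alpha, k))

test_that("count-based metrics match hand-computed worked examples", {
  ca <- count1("AA"); cb <- count1("AAC")
  expect_equal(d2_raw(ca, cb), 4)
  expect_equal(cosine_similarity(ca, cb), 4 / (2 * sqrt(5)))
  expect_equal(d2_distance(ca, cb), 0.5 * (1 - 4 / (2 * sqrt(5))))
  expect_equal(bray_curtis(ca, cb), 0.2)    # 1 - 2*2/(2+3)
  expect_equal(ngd(ca, cb), 1 / 3)          # (3-2)/(5-2)
  # disjoint word sets
  cg <- count1("GG")
  expect_equal(d2_raw(ca, cg), 0)
  expect_equal(cosine_similarity(ca, cg), 0)
  expect_equal(d2_distance(ca, cg), 0.5)
  expect_equal(bray_curtis(ca, cg), 1)
  # self comparison
  expect_equal(d2_raw(cb, cb), sum(as.numeric(cb$counts)^2))
  expect_equal(cosine_similarity(cb, cb), 1)
  expect_equal(bray_curtis(cb, cb), 0)
  expect_equal(ngd(cb, cb), 0)
})

test_that("frequency metrics match hand-computed worked examples", {
  fa <- freq1("AA"); fb <- freq1("AAC")  # {A:1} vs {A:2/3, C:1/3}
  expect_equal(minkowski_family(fa, fb, "cheby"), 1 / 3)
  expect_equal(minkowski_family(fa, fb, "manh"), 2 / 3)
  expect_equal(minkowski_family(fa, fb, "euclid"), sqrt(2) / 3)
  expect_equal(normalised_canberra(fa, fb), 0.6)
  expect_equal(minkowski_family(fa, fa, "manh"), 0)
  expect_equal(normalised_canberra(fa, fa), 0)
  expect_equal(normalised_canberra(freq1("AA"), freq1("GG")), 1)
})

test_that("degenerate zero-total vectors raise rather than return", {
  empty <- count_kmers(seq_record("x", "A", "dna"), kmer_spec("dna", 3))
  expect_error(cosine_similarity(empty, empty), "empty|undefined")
  expect_error(bray_curtis(empty, empty), "empty")
  expect_error(ngd(empty, empty), "empty")
  mismatch <- count_kmers(seq_record("x", "ACG", "dna"),
                          kmer_spec("dna", 2))
  expect_error(d2_raw(mismatch, count1("AC", k = 1L)), "spec")
})

test_that("d2star and d2s match an independent brute-force oracle", {
  # frozen from a straight-line evaluation of the formulas (external
  # script over the full 4^k word space)
  r <- seq_record("r", "ACGTACGT", "dna")
  q <- seq_record("q", "ACGTACGA", "dna")
  sp <- kmer_spec("dna", 2)
  cr <- count_kmers(r, sp); cq <- count_kmers(q, sp)
  br <- fit_background(r); bq <- fit_background(q)
  expect_equal(d2star(cr, br, cq, bq), 0.028733310326, tolerance = 1e-9)
  expect_equal(d2s(cr, br, cq, bq), 0.082363398974, tolerance = 1e-9)
  # identity
  expect_equal(d2star(cr, br, cr, br), 0)
  expect_equal(d2s(cr, br, cr, br), 0, tolerance = 1e-12)
  # in-test oracle on random pairs
  set.seed(5)
  for (i in 1:25) {
    sr <- random_dna(sample(30:120, 1))
    sq <- random_dna(sample(30:120, 1))
    # at k = 1 the order-0 background reproduces the counts exactly and
    # the centred vectors vanish; k >= 2 is where the statistics exist
    k <- sample(2:3, 1)
    spk <- kmer_spec("dna", k)
    rr <- seq_record("r", sr, "dna"); qq <- seq_record("q", sq, "dna")
    want <- oracle_d2star_d2s(sr, sq, k)
    expect_equal(d2star(count_kmers(rr, spk), fit_background(rr),
                        count_kmers(qq, spk), fit_background(qq)),
                 unname(want["d2star"]), tolerance = 1e-9)
    expect_equal(d2s(count_kmers(rr, spk), fit_background(rr),
                     count_kmers(qq, spk), fit_background(qq)),
                 unname(want["d2s"]), tolerance = 1e-9)
  }
})

test_that("unrelated long iid sequences centre d2star and d2s near 0.5", {
  set.seed(99)
  n_pairs <- 200
  sp <- kmer_spec("dna", 3)
  vals <- vapply(seq_len(n_pairs), function(i) {
    a <- seq_record("a", random_dna(600), "dna")
    b <- seq_record("b", random_dna(600), "dna")
    ca <- count_kmers(a, sp); cb <- count_kmers(b, sp)
    c(d2star(ca, fit_background(a), cb, fit_background(b)),
      d2s(ca, fit_background(a), cb, fit_background(b)))
  }, c(0, 0))
  expect_lt(abs(mean(vals[1, ]) - 0.5), 0.02)
  expect_lt(abs(mean(vals[2, ]) - 0.5), 0.02)
})

test_that("every metric matches its brute-force oracle on random pairs", {
  set.seed(1234)
  pure <- c("d2raw", "d2", "euclid", "manh", "cheby", "ncanb", "bc", "ngd")
  n_pairs <- 1000
  for (i in seq_len(n_pairs)) {
    dna <- i %% 2 == 0
    alpha <- if (dna) "dna" else "aa"
    k <- sample(1:3, 1)
    sa <- if (dna) random_dna(sample(k:50, 1)) else
      random_aa(sample(k:50, 1))
    sb <- if (dna) random_dna(sample(k:50, 1)) else
      random_aa(sample(k:50, 1))
    ca <- count1(sa, alpha, k); cb <- count1(sb, alpha, k)
    words <- union(names(ca$counts), names(cb$counts))
    x <- oracle_dense(sa, k, words)
    y <- oracle_dense(sb, k, words)
    fa <- to_frequencies(ca); fb <- to_frequencies(cb)
    m <- pure[(i %% length(pure)) + 1L]
    got <- switch(m,
      d2raw = d2_raw(ca, cb),
      d2 = d2_distance(ca, cb),
      euclid = minkowski_family(fa, fb, "euclid"),
      manh = minkowski_family(fa, fb, "manh"),
      cheby = minkowski_family(fa, fb, "cheby"),
      ncanb = normalised_canberra(fa, fb),
      bc = bray_curtis(ca, cb),
      ngd = ngd(ca, cb))
    want <- oracle_metric(m, x, y)
    expect_equal(got, want, tolerance = 1e-9,
                 label = paste(m, "on pair", i))
  }
})

test_that("metrics are symmetric, zero on identity, and in range", {
  set.seed(77)
  ranges <- list(d2 = c(0, 1), euclid = c(0, sqrt(2)), manh = c(0, 2),
                 cheby = c(0, 1), ncanb = c(0, 1), bc = c(0, 1),
                 ngd = c(0, 1), d2star = c(0, 1), d2s = c(0, 1))
  sp2 <- kmer_spec("dna", 2)
  for (i in 1:60) {
    a <- seq_record("a", random_dna(sample(10:150, 1)), "dna")
    b <- seq_record("b", random_dna(sample(10:150, 1)), "dna")
    for (m in names(ranges)) {
      sab <- score_pair(a, b, sp2, m)
      sba <- score_pair(b, a, sp2, m)
      saa <- score_pair(a, a, sp2, m)
      expect_equal(sab, sba, tolerance = 1e-12,
                   label = paste("symmetry", m))
      expect_equal(saa, 0, tolerance = 1e-12,
                   label = paste("identity", m))
      expect_gte(sab, ranges[[m]][1])
      expect_lte(sab, ranges[[m]][2] + 1e-12)
    }
  }
})

test_that("cosine equals d2raw over the product of vector norms", {
  set.seed(8)
  for (i in 1:100) {
    ca <- count1(random_dna(sample(5:80, 1)), k = 2L)
    cb <- count1(random_dna(sample(5:80, 1)), k = 2L)
    norm2 <- function(cv) sqrt(sum(as.numeric(cv$counts)^2))
    expect_equal(cosine_similarity(ca, cb),
                 d2_raw(ca, cb) / (norm2(ca) * norm2(cb)),
                 tolerance = 1e-12)
  }
})

test_that("ngd obeys its length-imbalance lower bound", {
  set.seed(14)
  for (i in 1:30) {
    short <- count1(random_dna(40), k = 2L)
    long <- count1(random_dna(2000), k = 2L)
    bound <- (long$total - short$total) / long$total
    expect_gte(ngd(short, long), bound - 1e-12)
  }
})

test_that("metric_info declares input kinds and the ncamb alias", {
  expect_identical(metric_info("ncamb")$name, "ncanb")
  expect_identical(metric_info("bc")$input, "counts")
  expect_identical(metric_info("euclid")$input, "freqs")
  expect_identical(metric_info("d2s")$input, "counts+background")
  expect_false(metric_info("d2raw")$lower_is_similar)
  expect_error(metric_info("nope"))
})

test_that("protein input is rejected by the Markov metrics", {
  p <- seq_record("p", "MKLVMKLV", "aa")
  expect_error(score_pair(p, p, kmer_spec("aa", 2), "d2star"), "DNA")
})
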