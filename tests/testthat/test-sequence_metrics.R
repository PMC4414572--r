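test_that("compliance check applies the barcode data standard thresholds", {
  cfg <- qc_config()
  ds <- make_ds(
    c("full", "short", "ambig", "noseq", "nospecies", "edge501"),
    c("A b", "A b", "A b", "A b", "", "A b"),
    c(strrep("A", 658),
      strrep("A", 480),
      paste0(strrep("N", 7), strrep("A", 643)),  # 7/650 > 1%
      "",
      strrep("A", 658),
      strrep("A", 501))
  )
  res <- compliance_check(ds, cfg)
  expect_true(res$pass[res$process_id == "full"])
  expect_equal(res$reasons[[2]], "TOO_SHORT")
  expect_equal(res$reasons[[3]], "TOO_AMBIGUOUS")
  expect_true(all(c("NO_SEQUENCE", "TOO_SHORT") %in% res$reasons[[4]]))
  expect_equal(res$reasons[[5]], "NO_SPECIES")
  expect_true(res$pass[res$process_id == "edge501"])  # strict: 501 passes

  # boundary: exactly 500 bp fails, exactly 1% ambiguity fails
  b <- make_ds(c("b500", "b1pct"), c("A b", "A b"),
               c(strrep("A", 500), paste0(strrep("N", 6), strrep("A", 594))))
  resb <- compliance_check(b, cfg)
  expect_equal(resb$reasons[[1]], "TOO_SHORT")
  expect_equal(resb$reasons[[2]], "TOO_AMBIGUOUS")
  # determinism/totality: same record, same verdict
  expect_identical(compliance_check(ds, cfg), res)
})

test_that("p-distance counts mismatches under pairwise deletion", {
  a <- strrep("A", 100)
  expect_equal(p_distance(a, a)$p_dist, 0)
  b <- paste0(strrep("A", 97), "GGG")
  expect_equal(p_distance(a, b)$p_dist, 0.03)
  # 10 N-sites excluded; 9 of the remaining 90 differ -> 0.10
  c1 <- paste0(strrep("N", 10), strrep("A", 90))
  c2 <- paste0(strrep("A", 10), strrep("A", 81), strrep("G", 9))
  r <- p_distance(c1, c2)
  expect_equal(r$comparable_sites, 90L)
  expect_equal(r$p_dist, 0.10)
  expect_error(p_distance("ACGT", "ACGTA"), "equal length")
  expect_error(p_distance("NNNN", "ACGT"), "comparable")
})

test_that("p-distance agrees with a character-level oracle on random pairs", {
  set.seed(7)
  for (i in 1:25) {
    a <- random_seq(120, c("A", "C", "G", "T", "N", "-"))
    b <- random_seq(120, c("A", "C", "G", "T", "N", "-"))
    ora <- bf_p_distance(a, b)
    if (is.nan(ora)) next
    got <- p_distance(a, b)
    expect_equal(got$p_dist, ora)
    # symmetry
    expect_equal(p_distance(b, a)$p_dist, got$p_dist)
  }
})

test_that("K2P matches the closed form and classifies substitution types", {
  expect_equal(k2p_distance(strrep("A", 50), strrep("A", 50))$k2p_dist, 0)
  # P = 0.10 (A->G transitions), Q = 0.05 (A->T transversions) over 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("T", 5), strrep("A", 85))
  r <- k2p_distance(a, b)
  expect_equal(r$transitions, 10L)
  expect_equal(r$transversions, 5L)
  expect_equal(r$k2p_dist, -0.5 * log(0.75 * sqrt(0.90)), tolerance = 1e-12)
  # P = 0.01, Q = 0
  b2 <- paste0("G", strrep("A", 99))
  expect_equal(k2p_distance(a, b2)$k2p_dist, -0.5 * log(0.98),
               tolerance = 1e-12)
  # transitions are A<->G and C<->T only
  expect_equal(p_distance("AC", "GT")$transitions, 2L)
  expect_equal(p_distance("AC", "CA")$transversions, 2L)
})

test_that("K2P saturation is flagged undefined, not infinite", {
  # P = 0.5, Q = 0 -> log(0) domain violation
  a <- strrep("AG", 20)
  b <- strrep("GA", 20)
  expect_warning(r <- k2p_distance(a, b),
                 class = "barcodelib_saturated_distance")
  expect_true(is.na(r$k2p_dist))
})

test_that("K2P agrees with ape::dist.dna under pairwise deletion", {
  set.seed(11)
  base <- random_seq(300)
  seqs <- vapply(1:6, function(i) mutate_seq(base, 12), "")
  names(seqs) <- paste0("S", 1:6)
  got <- distance_matrix(seqs, metric = "k2p")
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(s, "")[[1]])))
  ora <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(got), unname(ora[names(seqs), names(seqs)]),
               tolerance = 1e-10)
})

test_that("distance matrix is symmetric, zero-diagonal, and matches pairwise calls", {
  set.seed(3)
  base <- random_seq(200)
  seqs <- c(A = base, B = mutate_seq(base, 15), C = mutate_seq(base, 30))
  m <- distance_matrix(seqs, metric = "p")
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(m[i, j], p_distance(seqs[[i]], seqs[[j]])$p_dist)
  expect_equal(distance_matrix(seqs[1]), matrix(0, 1, 1,
               dimnames = list("A", "A")))
  # K2P correction never shrinks a distance
  mk <- distance_matrix(seqs, metric = "k2p")
  expect_true(all(mk >= m))
})

test_that("K2P/p ratio approaches 1 as divergence vanishes", {
  set.seed(13)
  for (i in 1:10) {
    a <- random_seq(1000)
    b <- mutate_seq(a, sample(1:10, 1))  # P+Q <= 0.01
    r <- k2p_distance(a, b)
    expect_lt(r$k2p_dist / r$p_dist, 1.01)
    expect_gte(r$k2p_dist, r$p_dist)
  }
})

test_that("intraspecific summaries follow the pairwise-observation definitions", {
  # single specimen: stats undefined
  one <- intraspecific_stats(list("A b" = c(x = strrep("A", 100))))
  expect_equal(one$n_pairs, 0L)
  expect_true(is.na(one$mean))
  # two specimens at p = 0.04: mean = min = max, se = 0
  a <- strrep("A", 100)
  two <- intraspecific_stats(
    list("A b" = c(x = a, y = paste0(strrep("T", 4), strrep("A", 96)))),
    metric = "p")
  expect_equal(two$mean, 0.04)
  expect_equal(two$min, 0.04)
  expect_equal(two$max, 0.04)
  expect_equal(two$se, 0)
  # three specimens with pairwise p {0.01, 0.02, 0.03}:
  # x-y differ at 1 site, x-z at 2, y-z at 3 (disjoint site blocks)
  x <- a
  y <- paste0("T", strrep("A", 99))                      # site 1
  z <- paste0("A", "TT", strrep("A", 97))                # sites 2,3
  tri <- intraspecific_stats(list("A b" = c(x = x, y = y, z = z)),
                             metric = "p")
  expect_equal(tri$n_pairs, 3L)
  expect_equal(tri$mean, 0.02)
  expect_equal(tri$min, 0.01)
  expect_equal(tri$max, 0.03)
  expect_equal(tri$se, 0.01 / sqrt(3), tolerance = 1e-12)
})

test_that("high-divergence flagging is strict and sorted", {
  s <- data.frame(species = c("a", "b", "c", "d"),
                  n_specimens = c(3, 3, 3, 1), n_pairs = c(3, 3, 3, 0),
                  mean = c(0.021, 0.020, 0.05, NA),
                  se = 0, min = 0, max = 0.06)
  expect_equal(flag_high_divergence(s), c("c", "a"))
})
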