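test_that("consensus construction follows the merge rule", {
  sets <- list(A = iv(0, 100), B = iv(50, 150))
  sh <- build_consensus(sets)
  expect_equal(nrow(sh$consensus), 1)
  expect_equal(sh$consensus$start, 0)
  expect_equal(sh$consensus$end, 150)
  expect_true(all(sh$matrix))

  disj <- build_consensus(list(A = iv(0, 100), B = iv(500, 600)))
  expect_equal(nrow(disj$consensus), 2)
  expect_equal(sum(disj$matrix), 2)
  expect_equal(unname(rowSums(disj$matrix)), c(1, 1))

  # chained overlaps are transitive by construction
  chain <- build_consensus(list(A = iv(0, 100), B = iv(90, 200),
                                C = iv(190, 300)))
  expect_equal(nrow(chain$consensus), 1)
  expect_true(all(chain$matrix[, 1]))

  # idempotence: consensus of the consensus is itself
  again <- build_consensus(list(x = sh$consensus, y = sh$consensus))
  expect_equal(again$consensus, sh$consensus)
})

test_that("sharing-set counts and private fraction", {
  m <- matrix(c(TRUE, FALSE,   # {A}
                TRUE, FALSE,   # {A}
                TRUE, TRUE),   # {A,B}
              nrow = 2, dimnames = list(c("A", "B"), NULL))
  cs <- count_sharing_sets(m)
  expect_equal(cs$counts$n[cs$counts$subset == "A"], 2)
  expect_equal(cs$counts$n[cs$counts$subset == "A+B"], 1)
  expect_equal(cs$private_fraction, 2 / 3)
  expect_equal(sum(cs$counts$n), ncol(m))

  all_true <- matrix(TRUE, 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  cs2 <- count_sharing_sets(all_true)
  expect_equal(nrow(cs2$counts), 1)
  expect_equal(cs2$counts$subset, "A+B+C")
})

test_that("ubiquitous hotspots match brute-force column sums", {
  set.seed(77)
  m <- matrix(runif(500) < 0.4, 10, 50,
              dimnames = list(paste0("p", 1:10), NULL))
  cons <- iv(seq(0, by = 1000, length.out = 50),
             seq(500, by = 1000, length.out = 50))
  sh <- structure(list(consensus = cons, matrix = m),
                  class = "sharing_matrix")
  for (mp in c(1, 8, 11)) {
    u <- ubiquitous_hotspots(sh, min_pops = mp)
    expect_equal(nrow(u), sum(colSums(m) >= mp))
  }
  expect_equal(nrow(ubiquitous_hotspots(sh, min_pops = 1)), 50)
  expect_equal(nrow(ubiquitous_hotspots(sh, min_pops = 11)), 0)
})

test_that("fisher overlap: identity case, oracle, symmetry", {
  layout <- genome_layout(c(chr1 = 1e6))
  A <- iv(c(1000, 5000, 9000), c(2000, 6000, 10000))
  fo <- fisher_overlap(A, A, layout)
  expect_equal(fo$table["inA", "notB"], 0)
  expect_equal(fo$table["notA", "inB"], 0)
  # minimal p for these margins: compare against every other n11
  tab <- fo$table
  p_alt <- vapply(0:2, function(k) {
    t2 <- tab; t2[1, 1] <- k; t2[1, 2] <- 3 - k; t2[2, 1] <- 3 - k
    stats::fisher.test(t2, alternative = "greater")$p.value
  }, 0)
  expect_true(all(fo$p <= p_alt))

  # right tail of (10,5,4,100) against direct hypergeometric summation
  expect_equal(stats::fisher.test(matrix(c(10, 5, 4, 100), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               hyper_right_tail(10, 5, 4, 100), tolerance = 1e-12)

  B <- iv(c(1500, 40000), c(2500, 41000))
  fab <- fisher_overlap(A, B, layout)
  fba <- fisher_overlap(B, A, layout)
  expect_equal(fab$table["inA", "inB"], fba$table["inA", "inB"])
  expect_equal(fab$table["inA", "notB"], fba$table["notA", "inB"])
  expect_equal(fab$table["notA", "notB"], fba$table["notA", "notB"])

  expect_error(fisher_overlap(iv(numeric(0), numeric(0)), A, layout),
               "non-empty")
})

test_that("fisher overlap is calibrated under independent placement", {
  layout <- genome_layout(c(chr1 = 1e7))
  set.seed(55)
  ps <- vapply(1:200, function(i) {
    a <- sort(sample.int(1e7 - 2000, 30))
    b <- sort(sample.int(1e7 - 2000, 30))
    fisher_overlap(iv(a, a + 2000), iv(b, b + 2000), layout)$p
  }, 0)
  # at the Bonferroni cutoff the false-positive count should be ~0.22;
  # allow a single Poisson fluctuation
  expect_lte(sum(ps <= 0.0011), 1)
})

test_that("jaccard distances: formulae and metric axioms", {
  m <- matrix(c(TRUE, TRUE, FALSE,
                TRUE, FALSE, TRUE), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(jaccard_distance_matrix(m)["a", "b"], 1 - 1 / 3)

  same <- rbind(a = c(TRUE, FALSE), b = c(TRUE, FALSE))
  expect_equal(jaccard_distance_matrix(same)["a", "b"], 0)
  disj <- rbind(a = c(TRUE, FALSE), b = c(FALSE, TRUE))
  expect_equal(jaccard_distance_matrix(disj)["a", "b"], 1)
  zz <- rbind(a = c(FALSE, FALSE), b = c(FALSE, FALSE))
  expect_warning(jaccard_distance_matrix(zz), "all-false")

  set.seed(31)
  mm <- matrix(runif(8 * 30) < 0.5, 8, 30,
               dimnames = list(paste0("p", 1:8), NULL))
  d <- jaccard_distance_matrix(mm)
  expect_equal(d, t(d))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(d[i, j], jaccard_brute(mm[i, ], mm[j, ]))
  # triangle inequality
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("mantel test: affine invariance and exhaustive enumeration", {
  set.seed(3)
  x <- matrix(rnorm(12), 6)
  d1 <- as.matrix(dist(x))
  mt <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)

  # n = 4: sampled p converges to the 24-permutation exhaustive value
  d4a <- as.matrix(dist(matrix(c(0, 0, 1, 0, 0, 1, 2, 2), 4, byrow = TRUE)))
  d4b <- as.matrix(dist(matrix(c(0, 0, 1, 1, 0, 2, 3, 1), 4, byrow = TRUE)))
  lt <- lower.tri(d4a)
  r_obs <- cor(d4a[lt], d4b[lt])
  perms <- gtools_permutations4()
  r_all <- apply(perms, 1, function(p) cor(d4a[lt], d4b[p, p][lt]))
  p_exact <- mean(r_all >= r_obs)
  mt4 <- mantel_test(d4a, d4b, n_perm = 9999, seed = 7)
  expect_lt(abs(mt4$p - p_exact), 0.02)

  expect_error(mantel_test(d4a[1:3, 1:3], d4b[1:3, 1:3]), "at least 4")
})

test_that("mantel r agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  d1 <- as.matrix(dist(matrix(rnorm(14), 7)))
  d2 <- as.matrix(dist(matrix(rnorm(14), 7)))
  mt <- mantel_test(d1, d2, n_perm = 999, seed = 5)
  vg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-10)
})

test_that("hotspot count regression matches the shared OLS path", {
  Ne <- c(a = 1000, b = 2000, c = 3000, d = 4000)
  counts <- 3 * Ne
  f <- hotspot_count_regression(counts, Ne)
  expect_equal(f$slope, 3)
  expect_lt(f$slope_p, 1e-10)
  # name-matching reorders the predictor
  f2 <- hotspot_count_regression(counts, Ne[c("d", "b", "a", "c")])
  expect_equal(f2$slope, 3)
})
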