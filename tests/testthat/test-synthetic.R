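test_that("hotspot landscape limits: no turnover and total loss", {
  two_tip <- ape::read.tree(text = "(A:0.5,B:0.5):0;")
  cfg0 <- sim_config(seed = 2, chrom_length = 2e6, hotspot_per_mb = 20,
                     gain_rate = 0, loss_rate = 0, birth_rate = 0)
  cfg0$tree <- two_tip
  land0 <- simulate_hotspot_landscape(cfg0)
  expect_true(all(land0$presence))
  expect_equal(land0$tips$A, land0$tips$B)
  expect_equal(nrow(merge_intervals(land0$ancestral)), nrow(land0$tips$A))

  cfgInf <- cfg0
  cfgInf$loss_rate <- Inf
  landInf <- simulate_hotspot_landscape(cfgInf)
  expect_false(any(landInf$presence))
  expect_equal(nrow(landInf$tips$A), 0)
})

test_that("ancestral retention follows the two-state Markov closed form", {
  # gain 0, loss mu, branch t: P(retain) = exp(-mu t)
  two_tip <- ape::read.tree(text = "(A:0.5,B:0.5):0;")
  cfg <- sim_config(seed = 41, chrom_length = 1e8, hotspot_per_mb = 10,
                    gain_rate = 0, loss_rate = 1.0, birth_rate = 0)
  cfg$tree <- two_tip
  land <- simulate_hotspot_landscape(cfg)
  n <- nrow(land$presence)
  expect_gt(n, 500)
  p_true <- exp(-1.0 * 0.5)
  se <- sqrt(p_true * (1 - p_true) / n)
  for (tip in c("A", "B"))
    expect_lt(abs(mean(land$presence[, tip]) - p_true), 3 * se)
})

test_that("rate map generator: intensity, determinism, validation", {
  hs <- iv(seq(5e4, 9e5, by = 5e4), seq(5e4, 9e5, by = 5e4) + 10000)
  cfg <- sim_config(seed = 13, chrom_length = 1e6, bg_autocorr_bp = 0,
                    bg_log_sd = 0.5)

  # multiplier 1: hotspot and background means agree within sampling error
  cfg1 <- cfg; cfg1$hotspot_intensity <- 1
  m1 <- simulate_ratemap(cfg1, hs)
  mid <- (m1$positions[-1] + m1$positions[-length(m1$positions)]) / 2
  inside <- rep(FALSE, length(mid))
  for (j in seq_len(nrow(hs)))
    inside <- inside | (mid >= hs$start[j] & mid < hs$end[j])
  expect_equal(mean(m1$rho[inside]), mean(m1$rho[!inside]), tolerance = 0.1)

  # multiplier 10 with long hotspots: inside/outside ratio ~ 10 (20%)
  cfg10 <- cfg; cfg10$hotspot_intensity <- 10
  m10 <- simulate_ratemap(cfg10, hs)
  mid10 <- (m10$positions[-1] + m10$positions[-length(m10$positions)]) / 2
  in10 <- rep(FALSE, length(mid10))
  for (j in seq_len(nrow(hs)))
    in10 <- in10 | (mid10 >= hs$start[j] & mid10 < hs$end[j])
  ratio <- mean(m10$rho[in10]) / mean(m10$rho[!in10])
  expect_gt(ratio, 8); expect_lt(ratio, 12)

  # fixed seed -> identical output
  expect_identical(simulate_ratemap(cfg10, hs, trace = TRUE),
                   simulate_ratemap(cfg10, hs, trace = TRUE))

  long <- iv(0, 2e6)
  expect_error(simulate_ratemap(cfg, long), "longer than chromosome")
})

test_that("annotation generator: coverage, structure, empty case", {
  cfg <- sim_config(seed = 31, chrom_length = 1e7,
                    repeat_fractions = c(retroelement = 0.10))
  anno <- simulate_annotations(cfg)
  realized <- total_bp(anno$repeats) / 1e7
  expect_lt(abs(realized - 0.10), 0.02)

  cfg0 <- sim_config(seed = 31, chrom_length = 1e6, gene_per_mb = 0)
  anno0 <- simulate_annotations(cfg0)
  expect_equal(nrow(anno0$genes), 0)

  # exon/intron structure survives a GFF3 round trip via the io reader
  cfg2 <- sim_config(seed = 32, chrom_length = 5e5)
  anno2 <- simulate_annotations(cfg2)
  expect_gt(nrow(anno2$genes), 10)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff_genes(anno2$genes, anno2$exons, f)
  back <- read_gff_genes(f)
  expect_equal(nrow(back$genes), nrow(anno2$genes))
  expect_equal(sort(back$introns$start), sort(anno2$introns$start))
  # genes non-overlapping
  expect_equal(nrow(merge_intervals(anno2$genes)), nrow(anno2$genes))

  expect_error(sim_config(repeat_fractions = c(retroelement = 0.9,
                                               dna_transposon = 0.2)),
               "exceeds the genome")
})

test_that("genotype table generator: null effects and construction", {
  cfg <- sim_config(seed = 61, glm_betas = c(0, 0, 0), glm_sigma = 0.25)
  g <- simulate_genotype_table(cfg)
  expect_true(all(g$freq >= 0 & g$freq <= 1))
  expect_lt(abs(mean(g$median_r) - cfg$glm_beta0), 4 * 0.25 / sqrt(10))
  expect_identical(simulate_genotype_table(cfg)$freq, g$freq)
})

test_that("tip Jaccard similarity decays with tree distance", {
  cors <- vapply(1:10, function(i) {
    cfg <- sim_config(seed = 500 + i, chrom_length = 5e6,
                      hotspot_per_mb = 20)
    land <- simulate_hotspot_landscape(cfg)
    sh <- build_consensus(land$tips)
    jac <- jaccard_distance_matrix(sh)
    d <- ape::cophenetic.phylo(land$tree)[rownames(jac), colnames(jac)]
    lt <- lower.tri(jac)
    cor(jac[lt], d[lt])
  }, 0)
  # Jaccard *distance* increases with drift distance in nearly all reps
  expect_gte(mean(cors > 0), 0.9)
  expect_gt(mean(cors), 0.2)
})

test_that("fst proxy is a bounded monotone map of drift distance", {
  tree <- simulate_drift_tree(6, seed = 3)
  f <- fst_proxy(tree)
  d <- ape::cophenetic.phylo(tree)[rownames(f), colnames(f)]
  expect_true(all(f >= 0 & f < 1))
  expect_equal(unname(diag(f)), rep(0, 6))
  lt <- lower.tri(f)
  expect_equal(order(f[lt]), order(d[lt]))
})

test_that("simulate_study writes a consistent file bundle", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 4, chrom_length = 3e5, n_populations = 5,
                    hotspot_per_mb = 30)
  out <- simulate_study(cfg, dir)
  expect_true(file.exists(file.path(dir, "tree.nwk")))
  tree <- read_newick_tree(file.path(dir, "tree.nwk"),
                           populations = out$tree$tip.label)
  meta <- read_population_meta(file.path(dir, "meta.tsv"))
  expect_setequal(meta$population, tree$tip.label)
  fst <- read_matrix_tsv(file.path(dir, "fst.tsv"))
  expect_equal(fst, fst[rownames(fst), colnames(fst)])
  rates <- list.files(dir, pattern = "^rates_")
  expect_length(rates, 5)
  rm1 <- read_ldhat_rates(file.path(dir, rates[1]))
  rho_orig <- out$maps[[sub("rates_(.*)\\.txt", "\\1", rates[1])]]$rho
  expect_lt(max(abs(rm1$rho - rho_orig) / rho_orig), 5e-6)
  geno <- read_genotype_freq_table(file.path(dir, "genotypes.tsv"))
  expect_equal(dim(geno), c(5, length(cfg$glm_betas)))
})
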