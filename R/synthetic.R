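#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale world with the statistical structure the
#' downstream analyses assume: ten populations related by a drift tree,
#' a 1 Mb chromosome with Poisson SNP spacing at 1 SNP / 200 bp, a
#' log-normal autocorrelated background recombination landscape with
#' magnitudes matching population-scaled rates (rho ~ 4e-3 Morgans/bp),
#' hotspots of ~2 kb at 10x background intensity that are gained and lost
#' along the tree, optional placement bias into gene-flank (TSS/TTS)
#' regions, narrow per-site MCMC-trace noise, and a linear recessive
#' genotype effect on median rate.
#'
#' @param seed RNG seed (integer)
#' @param n_populations number of populations (tree tips)
#' @param tree optional `phylo` drift tree; simulated when `NULL`
#' @param chrom_length chromosome length in bp
#' @param chrom_name chromosome name
#' @param snp_density expected SNPs per bp
#' @param bg_log_mean,bg_log_sd mean and sd of log background rho (M/bp)
#' @param bg_autocorr_bp autocorrelation length of the log-rate field
#'   (0 = independent intervals)
#' @param hotspot_per_mb ancestral hotspot birth density per Mb
#' @param hotspot_len_mean,hotspot_len_sd hotspot length distribution (bp)
#' @param hotspot_intensity multiplicative rate increase inside hotspots
#' @param gain_rate,loss_rate per-drift-unit two-state Markov rates for
#'   hotspot presence along branches
#' @param birth_rate branch-specific new-hotspot births per Mb per drift
#'   unit
#' @param p_tss probability that a hotspot is seeded inside a gene-flank
#'   region (used only when gene models are supplied)
#' @param trace_n number of emulated MCMC trace samples per interval
#' @param trace_rel_width relative width of the per-site 95% credibility
#'   interval of the trace
#' @param glm_beta0,glm_betas,glm_sigma intercept, per-mutation effects and
#'   residual sd for the synthetic genotype/rate model
#' @param gene_per_mb,repeat_fractions annotation densities;
#'   `repeat_fractions` is a named vector of target genome fractions
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_populations = 10L,
                       tree = NULL,
                       chrom_length = 1e6,
                       chrom_name = "chr1",
                       snp_density = 1 / 200,
                       bg_log_mean = log(4e-3),
                       bg_log_sd = 0.75,
                       bg_autocorr_bp = 10000,
                       hotspot_per_mb = 10,
                       hotspot_len_mean = 2000,
                       hotspot_len_sd = 500,
                       hotspot_intensity = 10,
                       gain_rate = 0.1,
                       loss_rate = 1.5,
                       birth_rate = 2,
                       p_tss = 0,
                       trace_n = 100L,
                       trace_rel_width = 0.1,
                       glm_beta0 = 2,
                       glm_betas = c(5, 2, 0),
                       glm_sigma = 0.5,
                       gene_per_mb = 100,
                       repeat_fractions = c(retroelement = 0.11,
                                            dna_transposon = 0.011,
                                            other = 0.01)) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(chrom_length >= 1, snp_density > 0, bg_log_sd >= 0,
              bg_autocorr_bp >= 0, hotspot_per_mb >= 0,
              hotspot_len_mean > 0, hotspot_intensity > 0,
              gain_rate >= 0, loss_rate >= 0, birth_rate >= 0,
              p_tss >= 0, p_tss <= 1, trace_n >= 2,
              trace_rel_width >= 0, glm_sigma >= 0,
              all(repeat_fractions >= 0))
  })
  if (sum(cfg$repeat_fractions) > 1)
    stop("requested repeat coverage exceeds the genome")
  structure(cfg, class = "sim_config")
}

#' Simulate a drift tree over the populations
#'
#' Random topology with exponential branch lengths (mean `mean_branch`
#' drift units), labelled `pop01`, `pop02`, ...
#'
#' @param n_populations number of tips
#' @param mean_branch mean branch length in drift units
#' @param seed RNG seed
#' @return a `phylo` tree
#' @export
simulate_drift_tree <- function(n_populations, mean_branch = 0.2, seed = 1L) {
  set.seed(seed)
  tree <- ape::rtree(n_populations, rooted = TRUE,
                     tip.label = sprintf("pop%02d", seq_len(n_populations)))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / mean_branch)
  tree
}

resolve_tree <- function(config) {
  if (!is.null(config$tree)) return(config$tree)
  simulate_drift_tree(config$n_populations, seed = config$seed + 77L)
}

# Draw one hotspot interval; optionally biased into gene-flank regions.
draw_hotspot <- function(config, flanks = NULL) {
  len <- max(200, round(stats::rnorm(1, config$hotspot_len_mean,
                                     config$hotspot_len_sd)))
  L <- config$chrom_length
  if (len > L) stop("hotspot longer than chromosome")
  if (!is.null(flanks) && nrow(flanks) > 0 &&
      stats::runif(1) < config$p_tss) {
    f <- flanks[sample.int(nrow(flanks), 1), ]
    center <- f$start + floor(stats::runif(1) * (f$end - f$start))
    start <- min(max(0, center - len %/% 2), L - len)
  } else {
    start <- floor(stats::runif(1) * (L - len + 1))
  }
  c(start, start + len)
}

#' Simulate tree-structured hotspot landscapes
#'
#' Ancestral hotspots are a Poisson process along the chromosome
#' (optionally seeded into TSS/TTS flanks with probability `p_tss` when
#' gene models are supplied). Presence then evolves along each branch as a
#' two-state Markov process with the configured gain/loss rates; each
#' branch additionally gives birth to new hotspots at `birth_rate` per Mb
#' per drift unit. Each tip emits its present hotspots as merged intervals.
#'
#' @param config a [sim_config()]
#' @param genes optional gene-model list (from [simulate_annotations()] or
#'   [read_gff_genes()]) used for TSS/TTS placement bias
#' @return list with `tips` (named list of interval data frames),
#'   `ancestral` (interval data frame), `presence` (loci x tips logical
#'   matrix over all loci ever born), `loci` (registry of all loci) and
#'   `tree`
#' @export
simulate_hotspot_landscape <- function(config, genes = NULL) {
  set.seed(config$seed)
  tree <- resolve_tree(config)
  L <- config$chrom_length
  flanks <- NULL
  if (!is.null(genes) && config$p_tss > 0) {
    fl <- derive_flanks(genes$genes, layout =
                          genome_layout(stats::setNames(L, config$chrom_name)))
    flanks <- rbind(fl$tss, fl$tts)
  }
  n_anc <- stats::rpois(1, config$hotspot_per_mb * L / 1e6)
  anc <- t(vapply(seq_len(max(n_anc, 0)), function(i)
    draw_hotspot(config, flanks), numeric(2)))
  if (n_anc == 0) anc <- matrix(numeric(0), 0, 2)
  loci <- data.frame(chrom = rep(config$chrom_name, n_anc),
                     start = anc[, 1], end = anc[, 2],
                     origin = rep("ancestral", n_anc),
                     stringsAsFactors = FALSE)
  lam <- config$gain_rate; mu <- config$loss_rate
  transition <- function(present, t) {
    tot <- lam + mu
    if (tot == 0) return(present)
    if (is.infinite(mu)) return(rep(FALSE, length(present)))
    p11 <- (lam + mu * exp(-tot * t)) / tot
    p01 <- lam / tot * (1 - exp(-tot * t))
    keep <- stats::runif(length(present)) <
      ifelse(present, p11, p01)
    keep
  }
  n_node <- max(tree$edge)
  root <- ape::Ntip(tree) + 1L
  states <- vector("list", n_node)
  states[[root]] <- rep(TRUE, n_anc)
  # preorder traversal so parents are visited before children
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(ord))) {
    parent <- ord[k, 1]; child <- ord[k, 2]
    t <- tree$edge.length[which(tree$edge[, 1] == parent &
                                  tree$edge[, 2] == child)]
    st <- states[[parent]]
    # pad states for loci born after this parent's state was fixed
    if (length(st) < nrow(loci)) st <- c(st, rep(FALSE, nrow(loci) - length(st)))
    st <- transition(st, t)
    nb <- stats::rpois(1, config$birth_rate * t * L / 1e6)
    if (nb > 0) {
      born <- t(vapply(seq_len(nb), function(i) draw_hotspot(config, flanks),
                       numeric(2)))
      loci <- rbind(loci,
                    data.frame(chrom = rep(config$chrom_name, nb),
                               start = born[, 1], end = born[, 2],
                               origin = rep("birth", nb),
                               stringsAsFactors = FALSE))
      st <- c(st, rep(TRUE, nb))
    }
    states[[child]] <- st
  }
  n_loci <- nrow(loci)
  tips <- stats::setNames(vector("list", ape::Ntip(tree)), tree$tip.label)
  presence <- matrix(FALSE, n_loci, ape::Ntip(tree),
                     dimnames = list(NULL, tree$tip.label))
  for (i in seq_len(ape::Ntip(tree))) {
    st <- states[[i]]
    if (length(st) < n_loci) st <- c(st, rep(FALSE, n_loci - length(st)))
    presence[, i] <- st
    iv <- loci[st, c("chrom", "start", "end"), drop = FALSE]
    tips[[tree$tip.label[i]]] <- if (nrow(iv)) merge_intervals(iv) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
  }
  ancestral <- loci[loci$origin == "ancestral",
                    c("chrom", "start", "end"), drop = FALSE]
  rownames(ancestral) <- NULL
  list(tips = tips, ancestral = ancestral, presence = presence,
       loci = loci, tree = tree)
}

#' Simulate an LDhat-like recombination rate map
#'
#' SNP counts are Poisson with the configured density and positions
#' uniform; the background log-rate is an AR(1) Gaussian field with
#' correlation `exp(-d / bg_autocorr_bp)` between interval midpoints
#' (`bg_autocorr_bp = 0` gives independent intervals); intervals whose
#' midpoint falls inside a hotspot have their rate multiplied by
#' `hotspot_intensity`. Optionally emulates an MCMC trace: log-normal
#' samples around each point estimate whose 95% interval has the
#' configured relative width.
#'
#' @param config a [sim_config()]
#' @param hotspots interval data frame of true hotspots (may be empty)
#' @param population label for the resulting map
#' @param trace emit a trace matrix? (attached as attribute `"trace"`)
#' @param seed RNG seed (defaults to `config$seed`)
#' @return a [rate_map()]; when `trace = TRUE` it carries a numeric
#'   matrix attribute `"trace"` (intervals x samples)
#' @export
simulate_ratemap <- function(config, hotspots = NULL,
                             population = NA_character_, trace = FALSE,
                             seed = config$seed) {
  set.seed(seed)
  L <- config$chrom_length
  if (!is.null(hotspots) && nrow(hotspots) &&
      any(hotspots$end - hotspots$start > L))
    stop("hotspot longer than chromosome")
  n <- max(2L, stats::rpois(1, L * config$snp_density))
  positions <- sort(sample.int(L - 1L, min(n, L - 1L)))
  k <- length(positions) - 1
  mid <- (positions[-1] + positions[-length(positions)]) / 2
  z <- numeric(k)
  z[1] <- stats::rnorm(1, 0, config$bg_log_sd)
  if (k > 1) {
    d <- diff(mid)
    phi <- if (config$bg_autocorr_bp > 0) exp(-d / config$bg_autocorr_bp)
           else rep(0, k - 1)
    innov <- stats::rnorm(k - 1, 0, config$bg_log_sd * sqrt(1 - phi^2))
    for (i in 2:k) z[i] <- phi[i - 1] * z[i - 1] + innov[i - 1]
  }
  rho <- exp(config$bg_log_mean + z)
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    inside <- rep(FALSE, k)
    for (j in seq_len(nrow(hotspots)))
      inside <- inside | (mid >= hotspots$start[j] & mid < hotspots$end[j])
    rho[inside] <- rho[inside] * config$hotspot_intensity
  }
  rm <- rate_map(config$chrom_name, positions, rho, population)
  if (trace) {
    s <- config$trace_rel_width / 3.92
    tr <- rho * exp(matrix(stats::rnorm(k * config$trace_n, 0, s),
                           k, config$trace_n))
    attr(rm, "trace") <- tr
  }
  rm
}

#' Simulate gene models and a repeat track
#'
#' Genes are placed without overlap, each with a random exon/intron
#' structure; repeats are placed uniformly per class until the expected
#' coverage matches the configured genome fraction (realized coverage is
#' slightly below target because within-class overlaps are merged).
#'
#' @param config a [sim_config()]
#' @param seed RNG seed (defaults to `config$seed`)
#' @return list with `genes` (chrom/start/end/name/strand), `exons`
#'   (chrom/start/end/gene/strand), `introns`, and `repeats`
#'   (chrom/start/end/class)
#' @export
simulate_annotations <- function(config, seed = config$seed) {
  set.seed(seed)
  L <- config$chrom_length
  n_genes <- round(config$gene_per_mb * L / 1e6)
  genes <- exons <- introns <- list()
  if (n_genes > 0) {
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
    gi <- 0
    for (i in seq_len(n_genes * 4)) {           # oversample, then stop
      if (gi >= n_genes) break
      n_ex <- 1 + stats::rpois(1, 2)
      ex_len <- round(stats::runif(n_ex, 150, 600))
      in_len <- if (n_ex > 1) round(stats::runif(n_ex - 1, 100, 800)) else
        numeric(0)
      glen <- sum(ex_len) + sum(in_len)
      if (glen >= L) next
      s <- floor(stats::runif(1) * (L - glen))
      cand <- data.frame(chrom = config$chrom_name, start = s, end = s + glen)
      if (nrow(placed) && any(overlaps_any(cand, placed))) next
      placed <- rbind(placed, cand)
      gi <- gi + 1
      name <- sprintf("g%04d", gi)
      strand <- sample(c("+", "-"), 1)
      genes[[gi]] <- data.frame(chrom = config$chrom_name, start = s,
                                end = s + glen, name = name,
                                strand = strand, stringsAsFactors = FALSE)
      es <- s + cumsum(c(0, utils::head(ex_len, -1) + in_len))
      exons[[gi]] <- data.frame(chrom = config$chrom_name, start = es,
                                end = es + ex_len, gene = name,
                                strand = strand, stringsAsFactors = FALSE)
      if (n_ex > 1)
        introns[[gi]] <- data.frame(chrom = config$chrom_name,
                                    start = es[-n_ex] + ex_len[-n_ex],
                                    end = es[-1], gene = name,
                                    stringsAsFactors = FALSE)
    }
  }
  bind0 <- function(lst, cols) {
    if (length(lst)) {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    } else {
      stats::setNames(
        data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
    }
  }
  reps <- list()
  for (cls in names(config$repeat_fractions)) {
    f <- config$repeat_fractions[[cls]]
    if (f == 0) next
    mean_len <- 500
    n_rep <- round(f * L / mean_len)
    lens <- pmax(50, round(stats::rexp(n_rep, 1 / mean_len)))
    lens <- pmin(lens, L - 1)
    starts <- floor(stats::runif(n_rep) * (L - lens))
    reps[[cls]] <- data.frame(chrom = config$chrom_name, start = starts,
                              end = starts + lens, class = cls,
                              stringsAsFactors = FALSE)
  }
  repeats <- bind0(reps, c("chrom", "start", "end", "class"))
  if (nrow(repeats)) repeats <- sort_intervals(repeats)
  list(genes = bind0(genes, c("chrom", "start", "end", "name", "strand")),
       exons = bind0(exons, c("chrom", "start", "end", "gene", "strand")),
       introns = bind0(introns, c("chrom", "start", "end", "gene")),
       repeats = repeats)
}

#' Simulate a homozygosity-frequency table with injected rate effects
#'
#' Per-mutation homozygous-alternative frequencies are tree-correlated
#' (Brownian motion on a logistic scale); the population response is
#' `y = beta0 + X beta + eps` with `eps ~ N(0, glm_sigma^2)`.
#'
#' @param config a [sim_config()]
#' @param tree optional `phylo`; resolved from the config when `NULL`
#' @param seed RNG seed (defaults to `config$seed`)
#' @return list with `freq` (populations x mutations matrix), `median_r`
#'   (named response vector), `beta0`, `betas`, `sigma`
#' @export
simulate_genotype_table <- function(config, tree = NULL,
                                    seed = config$seed) {
  set.seed(seed)
  if (is.null(tree)) tree <- resolve_tree(config)
  n_mut <- length(config$glm_betas)
  pops <- tree$tip.label
  C <- ape::vcv(tree)
  Ch <- chol(C + diag(1e-10, nrow(C)))
  X <- matrix(0, length(pops), n_mut,
              dimnames = list(pops, sprintf("mut%02d", seq_len(n_mut))))
  for (j in seq_len(n_mut)) {
    z <- stats::rnorm(1, 0, 1) + t(Ch) %*% stats::rnorm(length(pops))
    X[, j] <- stats::plogis(as.numeric(z))
  }
  y <- config$glm_beta0 + as.numeric(X %*% config$glm_betas) +
    stats::rnorm(length(pops), 0, config$glm_sigma)
  names(y) <- pops
  list(freq = X, median_r = y, beta0 = config$glm_beta0,
       betas = config$glm_betas, sigma = config$glm_sigma)
}

#' Differentiation proxy from a drift tree
#'
#' Maps patristic drift distance d to a bounded differentiation measure
#' `1 - exp(-d)`, a monotone stand-in for pairwise F_ST in synthetic runs.
#'
#' @param tree a `phylo` tree
#' @return symmetric matrix over tips with zero diagonal
#' @export
fst_proxy <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  f <- 1 - exp(-d)
  diag(f) <- 0
  f[tree$tip.label, tree$tip.label]
}

#' Generate a complete synthetic study on disk
#'
#' Writes everything the other pipeline stages consume: drift tree
#' (newick), genome layout, population metadata, F_ST proxy matrix,
#' per-population LDhat-style rate files and true-hotspot BEDs, gene
#' models (GFF3), repeat track (BED) and the genotype table (TSV).
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list of generated in-memory objects
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- resolve_tree(config)
  config$tree <- tree
  anno <- simulate_annotations(config, seed = config$seed + 11L)
  land <- simulate_hotspot_landscape(config, genes = anno)
  set.seed(config$seed + 23L)
  pops <- tree$tip.label
  meta <- data.frame(population = pops,
                     Ne = round(stats::rlnorm(length(pops), log(3e4), 0.5)),
                     F = round(stats::runif(length(pops), 0, 0.8), 3),
                     n = sample(5:26, length(pops), replace = TRUE))
  layout <- genome_layout(stats::setNames(config$chrom_length,
                                          config$chrom_name))
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  write_genome_layout(layout, file.path(dir, "layout.tsv"))
  utils::write.table(meta, file.path(dir, "meta.tsv"), quote = FALSE,
                     row.names = FALSE, sep = "\t")
  write_matrix_tsv(fst_proxy(tree), file.path(dir, "fst.tsv"))
  maps <- list()
  for (i in seq_along(pops)) {
    p <- pops[i]
    rm <- simulate_ratemap(config, land$tips[[p]], population = p,
                           seed = config$seed + 1000L + i)
    maps[[p]] <- rm
    write_ldhat_rates(rm, file.path(dir, paste0("rates_", p, ".txt")))
    if (nrow(land$tips[[p]]))
      write_bed(land$tips[[p]], file.path(dir, paste0("hotspots_", p, ".bed")))
  }
  write_gff_genes(anno$genes, anno$exons, file.path(dir, "genes.gff3"))
  if (nrow(anno$repeats))
    write_bed(data.frame(anno$repeats[c("chrom", "start", "end")],
                         name = anno$repeats$class),
              file.path(dir, "repeats.bed"))
  geno <- simulate_genotype_table(config, tree, seed = config$seed + 31L)
  write_matrix_tsv(geno$freq, file.path(dir, "genotypes.tsv"))
  utils::write.table(
    data.frame(population = names(geno$median_r),
               median_r = geno$median_r),
    file.path(dir, "median_r.tsv"), quote = FALSE, row.names = FALSE,
    sep = "\t")
  invisible(list(tree = tree, meta = meta, landscape = land, maps = maps,
                 annotations = anno, genotypes = geno, layout = layout))
}
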