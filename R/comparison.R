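#' Build the consensus hotspot set and Boolean sharing matrix
#'
#' The consensus is the merged union (>= 1 bp overlap, or abutting,
#' merges) of all populations' hotspots. The sharing matrix has one row
#' per population and one column per consensus interval; an entry is
#' `TRUE` iff that population has at least one hotspot overlapping
#' (>= 1 bp) the consensus interval. Two hotspots of different populations
#' are "shared" when both overlap the same consensus interval.
#'
#' @param hotspot_sets named list of interval data frames, one per
#'   population
#' @return object of class `sharing_matrix`: list with `consensus`
#'   (interval data frame) and `matrix` (logical populations x consensus)
#' @export
build_consensus <- function(hotspot_sets) {
  if (length(hotspot_sets) < 2) stop("need at least 2 populations")
  pops <- names(hotspot_sets)
  all_iv <- do.call(rbind, lapply(pops, function(p)
    hotspot_sets[[p]][, c("chrom", "start", "end"), drop = FALSE]))
  consensus <- merge_intervals(all_iv)
  m <- matrix(FALSE, length(pops), nrow(consensus),
              dimnames = list(pops, NULL))
  for (p in pops) {
    hs <- hotspot_sets[[p]]
    if (nrow(hs) == 0) next
    m[p, ] <- overlaps_any(consensus, hs)
  }
  structure(list(consensus = consensus, matrix = m),
            class = "sharing_matrix")
}

#' Count consensus hotspots per population subset
#'
#' Upset-style counts: for each distinct presence pattern across
#' populations, the number of consensus hotspots with exactly that
#' pattern, plus the fraction of consensus hotspots private to a single
#' population.
#'
#' @param sharing a [build_consensus()] result (or a logical matrix)
#' @return list with `counts` (data frame `subset`, `n`, sorted by `n`),
#'   `private_fraction` and `n_consensus`
#' @export
count_sharing_sets <- function(sharing) {
  m <- if (inherits(sharing, "sharing_matrix")) sharing$matrix else sharing
  pats <- apply(m, 2, function(col)
    paste(rownames(m)[col], collapse = "+"))
  pats[pats == ""] <- "(none)"
  tab <- table(pats)
  counts <- data.frame(subset = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n), , drop = FALSE]
  rownames(counts) <- NULL
  private <- sum(colSums(m) == 1)
  list(counts = counts, private_fraction = private / ncol(m),
       n_consensus = ncol(m))
}

#' Consensus hotspots present in at least `min_pops` populations
#'
#' @param sharing a [build_consensus()] result
#' @param min_pops presence threshold (default 8, the "ubiquitous" set)
#' @return interval data frame of qualifying consensus intervals with a
#'   `n_pops` column
#' @export
ubiquitous_hotspots <- function(sharing, min_pops = 8) {
  if (min_pops > nrow(sharing$matrix) + 1)
    stop("min_pops exceeds the number of populations + 1")
  n <- colSums(sharing$matrix)
  out <- sharing$consensus[n >= min_pops, , drop = FALSE]
  out$n_pops <- n[n >= min_pops]
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for hotspot overlap between two populations
#'
#' Contingency semantics follow `bedtools fisher`: with A and B merged,
#' n11 is the number of distinct overlap events between them (symmetric),
#' n12 = |A| - n11, n21 = |B| - n11, and n22 fills the genome in units of
#' the mean merged-union interval length:
#' `n22 = max(0, round(G / mean_len) - n11 - n12 - n21)`. The p-value is
#' the hypergeometric right tail (enrichment).
#'
#' @param hotspots_a,hotspots_b interval data frames (non-empty)
#' @param layout a [genome_layout()]
#' @return list with `table` (2x2 matrix), `p` (right-tail) and
#'   `n22_clamped` flag
#' @export
fisher_overlap <- function(hotspots_a, hotspots_b, layout) {
  if (nrow(hotspots_a) == 0 || nrow(hotspots_b) == 0)
    stop("both hotspot sets must be non-empty")
  a <- merge_intervals(hotspots_a)
  b <- merge_intervals(hotspots_b)
  n11 <- count_overlap_events(a, b)
  n12 <- max(0L, nrow(a) - n11)
  n21 <- max(0L, nrow(b) - n11)
  un <- merge_intervals(rbind(a, b))
  mean_len <- mean(un$end - un$start)
  G <- sum(as.numeric(layout))
  n22_raw <- round(G / mean_len) - n11 - n12 - n21
  clamped <- n22_raw < 0
  if (clamped) warning("n22 clamped to 0")
  n22 <- max(0, n22_raw)
  tab <- matrix(c(n11, n12, n21, n22), 2, 2, byrow = TRUE,
                dimnames = list(c("inA", "notA"), c("inB", "notB")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p = p, n22_clamped = clamped)
}

#' Pairwise Fisher overlap tests over all population pairs
#'
#' @param hotspot_sets named list of interval data frames
#' @param layout a [genome_layout()]
#' @return symmetric matrix of right-tail p-values (diagonal `NA`)
#' @export
pairwise_fisher <- function(hotspot_sets, layout) {
  pops <- names(hotspot_sets)
  k <- length(pops)
  out <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- fisher_overlap(hotspot_sets[[i]], hotspot_sets[[j]], layout)$p
    out[i, j] <- out[j, i] <- p
  }
  out
}

#' Jaccard distance matrix over Boolean sharing rows
#'
#' d(p, q) = 1 - |p AND q| / |p OR q| over consensus columns; two
#' all-false rows have distance 0 (with a warning).
#'
#' @param sharing a [build_consensus()] result or logical matrix
#' @return symmetric distance matrix with zero diagonal
#' @export
jaccard_distance_matrix <- function(sharing) {
  m <- if (inherits(sharing, "sharing_matrix")) sharing$matrix else sharing
  k <- nrow(m)
  out <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    u <- sum(m[i, ] | m[j, ])
    if (u == 0) {
      if (!warned) { warning("all-false row pair; distance set to 0")
        warned <- TRUE }
      d <- 0
    } else {
      d <- 1 - sum(m[i, ] & m[j, ]) / u
    }
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles; significance by
#' simultaneous row/column permutation of the second matrix, with
#' `p = (1 + #{perm r >= r_obs}) / (1 + n_perm)` (right tail).
#'
#' @param d1,d2 symmetric matrices over the same populations, same order
#' @param n_perm number of permutations (default 9999)
#' @param seed RNG seed
#' @return list with `r`, `p`, `n_perm`
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (n < 4) stop("Mantel test needs at least 4 populations")
  stopifnot(all(dim(d1) == dim(d2)))
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("matrices must be over the same populations in the same order")
  lt <- lower.tri(d1)
  r_obs <- stats::cor(d1[lt], d2[lt])
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_p <- stats::cor(d1[lt], d2[perm, perm][lt])
    if (r_p >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

#' Regress per-population hotspot counts on a confound
#'
#' Thin wrapper over [confound_regression()] for hotspot counts versus
#' e.g. effective population size or sample size.
#'
#' @param counts named numeric vector of hotspot counts
#' @param x named numeric predictor (matched by name when both are named)
#' @return as [confound_regression()]
#' @export
hotspot_count_regression <- function(counts, x) {
  if (!is.null(names(counts)) && !is.null(names(x)))
    x <- x[names(counts)]
  confound_regression(as.numeric(counts), as.numeric(x))
}
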