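#' Recombination rate map for one chromosome of one population
#'
#' Holds strictly increasing SNP positions (bp) and one population-scaled
#' recombination rate rho (Morgans/bp) per inter-SNP interval, so
#' `length(rho) == length(positions) - 1`.
#'
#' @param chrom chromosome name
#' @param positions integer-valued bp positions, strictly increasing,
#'   length >= 2
#' @param rho non-negative rates in Morgans/bp, one per inter-SNP interval
#' @param population population label
#' @return object of class `rate_map` (a list)
#' @export
rate_map <- function(chrom, positions, rho, population = NA_character_) {
  positions <- as.numeric(positions)
  rho <- as.numeric(rho)
  if (length(positions) < 2) stop("a rate map needs at least 2 SNP positions")
  if (any(diff(positions) <= 0))
    stop("SNP positions must be strictly increasing")
  if (length(rho) != length(positions) - 1)
    stop("need one rate per inter-SNP interval (n positions -> n-1 rates)")
  if (any(rho < 0)) stop("rates must be non-negative")
  structure(list(chrom = chrom, positions = positions, rho = rho,
                 population = population), class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %s %s: %d SNPs, span %.0f bp, mean rho %.3g M/bp\n",
              ifelse(is.na(x$population), "?", x$population), x$chrom,
              length(x$positions), diff(range(x$positions)), mean(x$rho)))
  invisible(x)
}

#' Plan overlapping SNP-index windows for per-window rate estimation
#'
#' Windows of `window` SNPs are laid down with stride `window - overlap`
#' (starts 1, 1501, 3001, ... for the defaults). The final window always
#' covers the last `window` SNPs, which makes its overlap with the
#' second-to-last window variable but never less than `overlap`. With
#' `n_snps <= window` a single window covers everything.
#'
#' The plan also records, per window, the range of inter-SNP interval
#' indices it contributes to the stitched map after trimming `trim` SNPs
#' from each side of every overlap (the final overlap loses exactly `trim`
#' SNPs from the second-to-last window's end, the last window contributing
#' the remainder). Contribution ranges partition `1:(n_snps - 1)`.
#'
#' @param n_snps number of SNPs on the chromosome (>= 2)
#' @param window SNPs per window (default 2000)
#' @param overlap minimum overlap between consecutive windows (default 500)
#' @param trim SNPs trimmed from each window at an overlap (default 250)
#' @return object of class `window_plan`: data frame with columns
#'   `start`, `end` (1-based SNP indices, inclusive) and `from`, `to`
#'   (contributed inter-SNP interval indices)
#' @export
plan_windows <- function(n_snps, window = 2000, overlap = 500, trim = 250) {
  stopifnot(n_snps >= 2, window > 2 * trim, overlap >= 2 * trim)
  if (n_snps <= window) {
    plan <- data.frame(start = 1, end = n_snps, from = 1, to = n_snps - 1)
    return(structure(plan, class = c("window_plan", "data.frame"),
                     n_snps = n_snps, trim = trim))
  }
  stride <- window - overlap
  starts <- seq(1, n_snps, by = stride)
  starts <- starts[starts + window - 1 <= n_snps]
  final_start <- n_snps - window + 1
  if (starts[length(starts)] != final_start) starts <- c(starts, final_start)
  ends <- starts + window - 1
  k <- length(starts)
  # boundary after window i sits `trim` SNPs before that window's end;
  # window i contributes intervals up to the boundary, window i+1 onward
  cuts <- ends[-k] - trim
  from <- c(1, cuts + 1)
  to <- c(cuts, n_snps - 1)
  plan <- data.frame(start = starts, end = ends, from = from, to = to)
  ov <- plan$end[-k] - plan$start[-1] + 1
  stopifnot(all(ov >= overlap), all(plan$from <= plan$to))
  structure(plan, class = c("window_plan", "data.frame"),
            n_snps = n_snps, trim = trim)
}

#' Stitch per-window rate estimates into one chromosome-wide map
#'
#' @param per_window_rates list of numeric vectors; element `i` holds the
#'   inter-SNP interval rates for window `i` of `plan` (length
#'   `end - start`)
#' @param plan a [plan_windows()] result
#' @param positions SNP positions (bp) for the whole chromosome
#' @param chrom,population labels for the resulting map
#' @return a [rate_map()] with exactly `n_snps - 1` rates
#' @export
stitch_windows <- function(per_window_rates, plan, positions,
                           chrom = "chr1", population = NA_character_) {
  if (length(per_window_rates) != nrow(plan))
    stop("got ", length(per_window_rates), " windows of rates for a plan of ",
         nrow(plan), " windows")
  n_snps <- attr(plan, "n_snps")
  if (length(positions) != n_snps)
    stop("positions length does not match the plan's SNP count")
  out <- numeric(n_snps - 1)
  for (i in seq_len(nrow(plan))) {
    v <- per_window_rates[[i]]
    if (length(v) != plan$end[i] - plan$start[i])
      stop("window ", i, " has ", length(v), " rates; expected ",
           plan$end[i] - plan$start[i])
    idx <- plan$from[i]:plan$to[i]
    out[idx] <- v[idx - plan$start[i] + 1]
  }
  rate_map(chrom, positions, out, population)
}

#' Convert population-scaled rho to per-generation rate r
#'
#' rho = 4*Ne*r with rho in Morgans/bp, so r = rho / (4 Ne) Morgans/bp,
#' reported in cM/Mb (x 1e8).
#'
#' @param rho rates in Morgans/bp (non-negative)
#' @param Ne effective population size (> 0)
#' @return r in cM/Mb
#' @export
rho_to_r <- function(rho, Ne) {
  if (any(Ne <= 0)) stop("Ne must be positive")
  if (any(rho < 0)) stop("rho must be non-negative")
  rho / (4 * Ne) * 1e8
}

#' Inverse of [rho_to_r()]
#' @param r rate in cM/Mb
#' @param Ne effective population size
#' @return rho in Morgans/bp
#' @export
r_to_rho <- function(r, Ne) r * 4 * Ne / 1e8

#' Per-population summary of recombination rate maps
#'
#' Each inter-SNP interval contributes one (unweighted) observation of
#' r = rho/(4 Ne) in cM/Mb. The 95% CI of the mean is a seeded
#' nonparametric bootstrap over intervals.
#'
#' @param ratemaps list of [rate_map()]s (one or more chromosomes),
#'   or a list of such lists keyed by population
#' @param meta data frame as from [read_population_meta()]
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return data frame with columns `population`, `mean_rho`, `Ne`,
#'   `mean_r`, `median_r`, `ci_lower`, `ci_upper`, `n_intervals`
#' @export
summarize_ratemap <- function(ratemaps, meta, n_boot = 1000, seed = 1L) {
  if (inherits(ratemaps, "rate_map")) ratemaps <- list(ratemaps)
  if (all(vapply(ratemaps, inherits, TRUE, "rate_map"))) {
    pops <- vapply(ratemaps, function(m) m$population, "")
    ratemaps <- split(ratemaps, pops)
  }
  set.seed(seed)
  rows <- lapply(names(ratemaps), function(p) {
    maps <- ratemaps[[p]]
    rho <- unlist(lapply(maps, function(m) m$rho))
    if (length(rho) == 0) stop("empty rate map for population ", p)
    Ne <- meta$Ne[match(p, meta$population)]
    if (is.na(Ne)) stop("no metadata for population ", p)
    r <- rho_to_r(rho, Ne)
    if (stats::var(r) == 0) {
      ci <- c(mean(r), mean(r))
    } else {
      boots <- vapply(seq_len(n_boot), function(i)
        mean(r[sample.int(length(r), replace = TRUE)]), 0)
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
    data.frame(population = p, mean_rho = mean(rho), Ne = Ne,
               mean_r = mean(r), median_r = stats::median(r),
               ci_lower = ci[1], ci_upper = ci[2],
               n_intervals = length(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare per-site MCMC-trace uncertainty to genome-wide rate spread
#'
#' The per-site 95% credibility interval is the 2.5/97.5 percentile of the
#' trace at each inter-SNP interval; its median width across sites is
#' compared with the width of the 95% interval of the point estimates
#' across the genome.
#'
#' @param trace matrix of trace samples, rows = inter-SNP intervals,
#'   columns = post-burn-in MCMC samples
#' @param ratemap the matching [rate_map()]
#' @return list with `site_cri` (median lower, median upper, median
#'   width), `genome_interval` (lower, upper, width) and `width_ratio`
#'   (genome width / median per-site width)
#' @export
trace_uncertainty <- function(trace, ratemap) {
  trace <- as.matrix(trace)
  if (nrow(trace) != length(ratemap$rho))
    stop("trace rows must match the map's inter-SNP intervals")
  if (any(trace < 0)) stop("trace samples must be non-negative")
  if (ncol(trace) < 40)
    warning("fewer than 40 trace samples; percentile estimates unstable")
  qs <- t(apply(trace, 1, stats::quantile, probs = c(0.025, 0.975)))
  site_width <- qs[, 2] - qs[, 1]
  genome <- unname(stats::quantile(ratemap$rho, c(0.025, 0.975)))
  gw <- genome[2] - genome[1]
  mw <- stats::median(site_width)
  list(site_cri = c(lower = stats::median(qs[, 1]),
                    upper = stats::median(qs[, 2]), width = mw),
       genome_interval = c(lower = genome[1], upper = genome[2], width = gw),
       width_ratio = if (mw > 0) gw / mw else Inf)
}

#' Nonparametric comparison of recombination rates between populations
#'
#' Kruskal-Wallis across all populations, then pairwise two-sided Wilcoxon
#' rank-sum tests on per-interval r values. Exact p-values are used when
#' both samples have at most `exact_max` observations (and no ties);
#' otherwise the normal approximation with tie correction. The Bonferroni
#' cutoff is `alpha / choose(k, 2)`.
#'
#' @param r_by_population named list of numeric vectors of per-interval r
#' @param alpha family-wise error rate (default 0.05)
#' @param exact_max sample-size bound for exact Wilcoxon (default 10)
#' @return list with `kruskal_p`, `pairwise_p` (symmetric matrix),
#'   `bonferroni_cutoff`, `n_comparisons`
#' @export
compare_rates <- function(r_by_population, alpha = 0.05, exact_max = 10) {
  k <- length(r_by_population)
  if (k < 2) stop("need at least 2 populations")
  sizes <- lengths(r_by_population)
  if (any(sizes < 2))
    stop("population(s) with fewer than 2 intervals: ",
         paste(names(r_by_population)[sizes < 2], collapse = ", "))
  grp <- factor(rep(names(r_by_population), sizes),
                levels = names(r_by_population))
  kw <- stats::kruskal.test(unlist(r_by_population), grp)
  pw <- matrix(NA_real_, k, k,
               dimnames = list(names(r_by_population),
                               names(r_by_population)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    x <- r_by_population[[i]]; y <- r_by_population[[j]]
    ex <- length(x) <= exact_max && length(y) <= exact_max
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = ex, correct = !ex)$p.value)
    pw[i, j] <- pw[j, i] <- p
  }
  n_comp <- choose(k, 2)
  list(kruskal_p = kw$p.value, pairwise_p = pw,
       bonferroni_cutoff = alpha / n_comp, n_comparisons = n_comp)
}

#' Simple confound regression: y on one predictor, OLS
#'
#' @param y response, one value per population
#' @param x predictor, same length and order
#' @return list with `intercept`, `slope`, `slope_p` (two-sided t-test),
#'   `r_squared` and the underlying `lm` fit
#' @export
confound_regression <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 3) stop("need at least 3 populations")
  if (any(is.na(x)) || any(is.na(y))) stop("missing values not allowed")
  if (stats::var(x) == 0) stop("constant predictor: slope undefined")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       slope_p = unname(co[2, 4]),
       r_squared = summary(fit)$r.squared, fit = fit)
}
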