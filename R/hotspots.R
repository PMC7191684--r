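#' Call recombination hotspots from a rate map
#'
#' Rate-map-level analogue of the LDhot single- vs two-distribution test.
#' The chromosome is scanned in `window_bp` windows (step `step_bp`,
#' non-overlapping by default). For each window the statistic is its
#' genetic length, T = sum(rho_i * len_i) over the inter-SNP intervals it
#' covers (partial intervals pro-rated). The single-distribution null is a
#' gamma distribution fitted by the method of moments to the per-interval
#' rates of the +/- `flank_bp` background around the window; `nsims`
#' replicate windows with the same SNP configuration are drawn from it and
#' the empirical p-value is `(1 + #{T_sim >= T_obs}) / (1 + nsims)`.
#' Windows with `p <= alpha` are kept and overlapping or abutting
#' significant windows are merged into hotspots; each hotspot carries the
#' minimum p over its constituent windows.
#'
#' Windows with fewer than 10 background intervals in their flanks, or a
#' degenerate all-zero background, are skipped with a warning. A
#' zero-variance (constant) background yields a point-mass null: such
#' windows are significant only if their genetic length strictly exceeds
#' the deterministic null value (within floating-point tolerance), which
#' makes a constant-rate map produce no calls.
#'
#' @param ratemap a [rate_map()]
#' @param window_bp test window size (default 1000)
#' @param step_bp scan step (default `window_bp`)
#' @param flank_bp background flank on each side (default 50000)
#' @param nsims null simulations per window (default 1000)
#' @param alpha refinement level (default 0.001)
#' @param seed RNG seed
#' @return object of class `hotspot_set`: interval data frame with
#'   columns `chrom`, `start`, `end`, `p`, `mean_rho`, `flank_mean_rho`;
#'   attributes `population`, `window_p` (per-window data frame, for
#'   calibration checks) and `alpha`
#' @export
call_hotspots <- function(ratemap, window_bp = 1000, step_bp = window_bp,
                          flank_bp = 50000, nsims = 1000, alpha = 0.001,
                          seed = 1L) {
  stopifnot(inherits(ratemap, "rate_map"), nsims >= 1, alpha > 0)
  set.seed(seed)
  pos <- ratemap$positions
  rho <- ratemap$rho
  span <- c(pos[1], pos[length(pos)])
  if (diff(span) < window_bp + 2 * flank_bp)
    stop("map span must be at least window_bp + 2*flank_bp")
  starts <- seq(span[1], span[2] - window_bp, by = step_bp)
  istart <- pos[-length(pos)]
  iend <- pos[-1]
  n_skipped <- 0L
  res <- data.frame(start = starts, end = starts + window_bp,
                    T_obs = NA_real_, p = NA_real_)
  for (w in seq_along(starts)) {
    ws <- starts[w]; we <- ws + window_bp
    sel <- which(iend > ws & istart < we)
    if (length(sel) == 0) next
    lens <- pmin(we, iend[sel]) - pmax(ws, istart[sel])
    T_obs <- sum(rho[sel] * lens)
    bg <- which((iend > ws - flank_bp & istart < ws) |
                  (iend > we & istart < we + flank_bp))
    bg <- setdiff(bg, sel)
    if (length(bg) < 10) { n_skipped <- n_skipped + 1L; next }
    b <- rho[bg]
    mb <- mean(b); vb <- stats::var(b)
    if (mb == 0) { n_skipped <- n_skipped + 1L; next }
    if (vb == 0) {
      # point-mass null: every simulated window equals the background value
      T_null <- mb * sum(lens)
      p <- if (T_obs > T_null * (1 + 1e-12)) 1 / (1 + nsims) else 1
    } else {
      shape <- mb^2 / vb
      rate <- mb / vb
      sims <- matrix(stats::rgamma(length(sel) * nsims, shape = shape,
                                   rate = rate), nrow = length(sel))
      T_sim <- as.numeric(crossprod(sims, lens))
      p <- (1 + sum(T_sim >= T_obs)) / (1 + nsims)
    }
    res$T_obs[w] <- T_obs
    res$p[w] <- p
  }
  if (n_skipped > 0)
    warning(n_skipped, " window(s) skipped (insufficient or degenerate ",
            "background)")
  sig <- res[!is.na(res$p) & res$p <= alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    hs <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), p = numeric(), mean_rho = numeric(),
                     flank_mean_rho = numeric(), stringsAsFactors = FALSE)
  } else {
    iv <- data.frame(chrom = ratemap$chrom, start = sig$start,
                     end = sig$end, stringsAsFactors = FALSE)
    merged <- merge_intervals(iv)
    hs <- merged
    hs$p <- vapply(seq_len(nrow(merged)), function(i) {
      min(sig$p[sig$start < merged$end[i] & sig$end > merged$start[i]])
    }, 0)
    hs$mean_rho <- vapply(seq_len(nrow(merged)), function(i)
      region_mean_rho(ratemap, merged$start[i], merged$end[i]), 0)
    hs$flank_mean_rho <- vapply(seq_len(nrow(merged)), function(i)
      flank_mean_rho(ratemap, merged$start[i], merged$end[i], 5000), 0)
  }
  structure(hs, class = c("hotspot_set", "data.frame"),
            population = ratemap$population, alpha = alpha,
            window_p = res)
}

# length-weighted mean rho over [s, e), pro-rating partial intervals
region_mean_rho <- function(ratemap, s, e) {
  istart <- ratemap$positions[-length(ratemap$positions)]
  iend <- ratemap$positions[-1]
  sel <- which(iend > s & istart < e)
  if (length(sel) == 0) return(NA_real_)
  lens <- pmin(e, iend[sel]) - pmax(s, istart[sel])
  sum(ratemap$rho[sel] * lens) / sum(lens)
}

flank_mean_rho <- function(ratemap, s, e, flank_bp) {
  left <- region_mean_rho(ratemap, s - flank_bp, s)
  right <- region_mean_rho(ratemap, e, e + flank_bp)
  w <- c(!is.na(left), !is.na(right))
  if (!any(w)) return(NA_real_)
  mean(c(left, right)[w])
}

#' Contrast hotspot rates with genome-wide and flanking rates
#'
#' Length-weighted mean rho inside hotspot bp versus (a) the length-
#' weighted genome-wide mean over all inter-SNP intervals and (b) the
#' +/- `flank_bp` flanking regions.
#'
#' @param hotspots interval data frame (e.g. a [call_hotspots()] result)
#' @param ratemap the matching [rate_map()]
#' @param flank_bp flank width (default 5000)
#' @return list with `hotspot_mean`, `genome_mean`, `flank_mean`,
#'   `genome_ratio`, `flank_ratio` and the per-hotspot table; an empty
#'   hotspot set yields an empty table and `NA` ratios
#' @export
hotspot_rate_contrast <- function(hotspots, ratemap, flank_bp = 5000) {
  lens <- diff(ratemap$positions)
  genome_mean <- sum(ratemap$rho * lens) / sum(lens)
  if (nrow(hotspots) == 0) {
    return(list(hotspot_mean = NA_real_, genome_mean = genome_mean,
                flank_mean = NA_real_, genome_ratio = NA_real_,
                flank_ratio = NA_real_,
                per_hotspot = data.frame(start = numeric(), end = numeric(),
                                         mean_rho = numeric(),
                                         flank_mean_rho = numeric())))
  }
  per <- data.frame(start = hotspots$start, end = hotspots$end)
  per$mean_rho <- vapply(seq_len(nrow(per)), function(i)
    region_mean_rho(ratemap, per$start[i], per$end[i]), 0)
  per$flank_mean_rho <- vapply(seq_len(nrow(per)), function(i)
    flank_mean_rho(ratemap, per$start[i], per$end[i], flank_bp), 0)
  drop <- is.na(per$mean_rho)
  if (any(drop)) {
    warning(sum(drop), " hotspot(s) without SNP intervals excluded")
    per <- per[!drop, , drop = FALSE]
  }
  w <- per$end - per$start
  hot_mean <- sum(per$mean_rho * w) / sum(w)
  fl <- !is.na(per$flank_mean_rho)
  flank_mean <- if (any(fl)) sum(per$flank_mean_rho[fl] * w[fl]) / sum(w[fl])
                else NA_real_
  list(hotspot_mean = hot_mean, genome_mean = genome_mean,
       flank_mean = flank_mean,
       genome_ratio = hot_mean / genome_mean,
       flank_ratio = hot_mean / flank_mean,
       per_hotspot = per)
}
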