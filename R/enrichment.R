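#' Derive TSS/TTS flank tracks from gene models
#'
#' For a + strand gene `[s, e)` the TSS flank is `[s - flank, s)` and the
#' TTS flank `[e, e + flank)`; strands are swapped for - genes. Flanks are
#' clipped to chromosome bounds (with a warning) and zero-width flanks are
#' dropped.
#'
#' @param genes interval data frame with a `strand` column
#' @param flank flank width in bp (default 500)
#' @param layout a [genome_layout()] used for clipping
#' @return list with interval data frames `tss` and `tts`
#' @export
derive_flanks <- function(genes, flank = 500, layout) {
  if (nrow(genes) == 0) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
    return(list(tss = empty, tts = empty))
  }
  plus <- genes$strand == "+"
  up <- data.frame(chrom = genes$chrom,
                   start = genes$start - flank, end = genes$start,
                   stringsAsFactors = FALSE)
  down <- data.frame(chrom = genes$chrom,
                     start = genes$end, end = genes$end + flank,
                     stringsAsFactors = FALSE)
  tss <- rbind(up[plus, ], down[!plus, ])
  tts <- rbind(down[plus, ], up[!plus, ])
  clip <- function(x) {
    lens <- layout[x$chrom]
    clipped <- any(x$start < 0) || any(x$end > lens)
    x$start <- pmax(x$start, 0)
    x$end <- pmin(x$end, lens)
    if (clipped) warning("flank(s) clipped at chromosome boundary")
    x <- x[x$end > x$start, , drop = FALSE]
    rownames(x) <- NULL
    x
  }
  list(tss = clip(tss), tts = clip(tts))
}

#' Draw a size- and count-matched random hotspot set
#'
#' One simulated interval per template interval, on the same chromosome,
#' with start uniform on the feasible range. Intervals that overlap an
#' already-placed simulated interval are resampled (up to `max_attempts`
#' each), so the returned set is mutually non-overlapping.
#'
#' @param template interval data frame whose sizes/chromosomes are matched
#' @param layout a [genome_layout()]
#' @param seed optional RNG seed (`NULL` leaves the RNG stream alone, for
#'   use inside larger seeded simulations)
#' @param max_attempts rejection cap per interval (default 1e4)
#' @return interval data frame, same row count as `template`
#' @export
random_hotspot_set <- function(template, layout, seed = NULL,
                               max_attempts = 1e4) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(template)
  lens <- template$end - template$start
  if (any(lens > layout[template$chrom]))
    stop("template interval longer than its chromosome")
  starts <- numeric(n); chroms <- template$chrom
  for (i in seq_len(n)) {
    L <- layout[[chroms[i]]]
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      s <- floor(stats::runif(1) * (L - lens[i] + 1))
      e <- s + lens[i]
      prev <- seq_len(i - 1)
      same <- prev[chroms[prev] == chroms[i]]
      if (!length(same) ||
          !any(starts[same] < e & (starts[same] + lens[same]) > s)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place interval ", i, " without overlap after ",
                  max_attempts, " attempts")
    starts[i] <- s
  }
  data.frame(chrom = chroms, start = starts, end = starts + lens,
             stringsAsFactors = FALSE)
}

#' Feature-overlap enrichment test with a matched resampling null
#'
#' The observed statistic is the number of hotspots intersecting (>= 1 bp)
#' at least one feature interval; a hotspot touching several features
#' still counts once. The null redraws the hotspot set `nsims` times with
#' [random_hotspot_set()] (same counts and sizes, uniform placement) and
#' recomputes the count. Reported are the proportion of simulations
#' strictly below the observed count (the direction-explicit summary) and
#' a conventional enrichment p, `(1 + #{sim >= obs}) / (1 + nsims)`.
#'
#' @param hotspots,features non-empty interval data frames
#' @param layout a [genome_layout()]
#' @param nsims number of null draws (default 1000)
#' @param seed RNG seed
#' @return list with `observed`, `null_counts`, `prop_below`
#'   (P(sim < observed)) and `p_enrich`
#' @export
feature_overlap_test <- function(hotspots, features, layout, nsims = 1000,
                                 seed = 1L) {
  if (nrow(hotspots) == 0 || nrow(features) == 0)
    stop("hotspots and features must be non-empty")
  set.seed(seed)
  observed <- sum(overlaps_any(hotspots, features))
  null_counts <- vapply(seq_len(nsims), function(b) {
    sim <- random_hotspot_set(hotspots, layout, seed = NULL)
    sum(overlaps_any(sim, features))
  }, 0)
  list(observed = observed, null_counts = null_counts,
       prop_below = mean(null_counts < observed),
       p_enrich = (1 + sum(null_counts >= observed)) / (1 + nsims))
}

#' Repeat-content test with a matched resampling null
#'
#' The observed statistic is the percentage of hotspot base pairs covered
#' by the repeat class; the null redraws size/count-matched uniform
#' interval sets. Reported are the observed percentage, the mean simulated
#' percentage, and the percentage of simulations exceeding the observed
#' value (values near 100 indicate depletion, near 0 enrichment).
#'
#' @param hotspots interval data frame
#' @param repeats interval data frame for one repeat class
#' @param layout a [genome_layout()]
#' @param nsims number of null draws (default 1000)
#' @param seed RNG seed
#' @return list with `observed_pct`, `null_mean_pct`, `pct_sim_above`,
#'   `null_pct` (all simulated percentages)
#' @export
repeat_content_test <- function(hotspots, repeats, layout, nsims = 1000,
                                seed = 1L) {
  set.seed(seed)
  hot_bp <- sum(hotspots$end - hotspots$start)
  pct <- function(set) {
    if (nrow(repeats) == 0) return(0)
    100 * sum(covered_bp(set, repeats)) / hot_bp
  }
  observed <- pct(hotspots)
  null_pct <- vapply(seq_len(nsims), function(b)
    pct(random_hotspot_set(hotspots, layout, seed = NULL)), 0)
  list(observed_pct = observed, null_mean_pct = mean(null_pct),
       pct_sim_above = 100 * mean(null_pct > observed),
       null_pct = null_pct)
}
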