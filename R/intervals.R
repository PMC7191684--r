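#' Genomic interval utilities
#'
#' Intervals throughout the package are plain data frames with columns
#' `chrom` (character), `start` and `end` (integer-valued, 0-based
#' half-open), plus any extra columns callers care to add. All set
#' operations here are coordinate-convention aware and assume (but also
#' verify) `0 <= start < end`.
#'
#' @param chrom character vector of chromosome names
#' @param start,end numeric vectors, 0-based half-open coordinates
#' @param ... further equal-length columns (e.g. `name`, `score`, `strand`)
#' @return a validated interval data frame
#' @export
intervals <- function(chrom = character(), start = numeric(),
                      end = numeric(), ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval data frame
#'
#' @param x interval data frame
#' @param layout optional genome layout (see [genome_layout()]); when given,
#'   intervals must fall inside their chromosome
#' @return `x`, invisibly
#' @export
validate_intervals <- function(x, layout = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop("interval coordinates must not be NA")
  if (any(x$start < 0)) stop("interval start < 0")
  bad <- which(x$start >= x$end)
  if (length(bad))
    stop("interval start >= end at row(s): ", paste(bad, collapse = ", "))
  if (!is.null(layout)) {
    unknown <- setdiff(unique(x$chrom), names(layout))
    if (length(unknown))
      stop("intervals on chromosomes absent from layout: ",
           paste(unknown, collapse = ", "))
    if (any(x$end > layout[x$chrom]))
      stop("interval end exceeds chromosome length")
  }
  invisible(x)
}

#' Genome layout constructor
#'
#' @param lengths named numeric vector, chromosome name -> length in bp
#' @return named numeric vector of class `genome_layout`
#' @export
genome_layout <- function(lengths) {
  lengths <- unlist(lengths)
  if (is.null(names(lengths)) || any(names(lengths) == ""))
    stop("genome layout requires chromosome names")
  if (anyDuplicated(names(lengths))) stop("duplicate chromosome names")
  if (any(lengths < 1)) stop("chromosome lengths must be >= 1")
  structure(as.numeric(lengths), names = names(lengths),
            class = "genome_layout")
}

sort_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Merge overlapping or abutting intervals
#'
#' Intervals that overlap by at least 1 bp, or that abut exactly
#' (`end == start`), are fused into one.
#'
#' @param x interval data frame
#' @return merged, sorted interval data frame (chrom/start/end only)
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  x <- sort_intervals(x)
  out <- do.call(rbind, lapply(split(x, x$chrom), function(cx) {
    s <- cx$start; e <- cx$end
    keep_start <- s[1]; res_s <- numeric(); res_e <- numeric()
    cur_e <- e[1]
    if (nrow(cx) > 1) {
      for (i in 2:nrow(cx)) {
        if (s[i] <= cur_e) {
          cur_e <- max(cur_e, e[i])
        } else {
          res_s <- c(res_s, keep_start); res_e <- c(res_e, cur_e)
          keep_start <- s[i]; cur_e <- e[i]
        }
      }
    }
    res_s <- c(res_s, keep_start); res_e <- c(res_e, cur_e)
    data.frame(chrom = cx$chrom[1], start = res_s, end = res_e,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  sort_intervals(out)
}

#' Which query intervals overlap any subject interval?
#'
#' Overlap means an intersection of at least 1 bp (half-open semantics:
#' abutting intervals do not overlap).
#'
#' @param query,subject interval data frames
#' @return logical vector, one element per row of `query`
#' @export
overlaps_any <- function(query, subject) {
  validate_intervals(query); validate_intervals(subject)
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  out <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sub <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    o <- order(sub$start)
    ss <- sub$start[o]
    cmx <- cummax(sub$end[o])
    # a subject with start < q_end exists at index idx; among those, some
    # subject has end > q_start iff the running max end exceeds q_start
    idx <- findInterval(query$end[qi] - 0.5, ss)
    hit <- idx >= 1
    hit[hit] <- cmx[idx[hit]] > query$start[qi][hit]
    out[qi] <- hit
  }
  out
}

#' Count overlap events between two merged interval sets
#'
#' Both inputs are merged first; the result is the number of contiguous
#' intersection pieces, which is symmetric in its arguments.
#'
#' @param a,b interval data frames
#' @return integer count of intersection events
#' @export
count_overlap_events <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  n <- 0L
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ax <- a[a$chrom == ch, ]; bx <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(ax))) {
      n <- n + sum(bx$start < ax$end[i] & bx$end > ax$start[i])
    }
  }
  n
}

#' Base pairs of each query interval covered by a subject set
#'
#' @param query,subject interval data frames
#' @return numeric vector of covered bp, one per query row
#' @export
covered_bp <- function(query, subject) {
  validate_intervals(query)
  subject <- merge_intervals(subject)
  if (nrow(query) == 0) return(numeric(0))
  out <- numeric(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sub <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (j in qi) {
      qs <- query$start[j]; qe <- query$end[j]
      ov <- pmin(qe, sub$end) - pmax(qs, sub$start)
      out[j] <- sum(ov[ov > 0])
    }
  }
  out
}

#' Total width of an interval set
#' @param x interval data frame
#' @return total bp spanned (after merging)
#' @export
total_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}
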