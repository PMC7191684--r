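#' Homozygous-alternative genotype frequencies
#'
#' @param genotypes named list: per population, a list/matrix of genotype
#'   code vectors per mutation. Codes: `"0/0"` (hom-ref), `"0/1"`/`"1/0"`
#'   (het), `"1/1"` (hom-alt), `"./."` (missing). A data frame or matrix
#'   with individuals as rows and mutations as columns is accepted per
#'   population.
#' @return matrix populations x mutations of hom-alt frequencies among
#'   non-missing genotypes
#' @export
homozygosity_frequencies <- function(genotypes) {
  pops <- names(genotypes)
  muts <- colnames(as.matrix(genotypes[[1]]))
  out <- matrix(NA_real_, length(pops), length(muts),
                dimnames = list(pops, muts))
  for (p in pops) {
    g <- as.matrix(genotypes[[p]])
    for (j in seq_len(ncol(g))) {
      v <- g[, j]
      nonmiss <- v %in% c("0/0", "0/1", "1/0", "1/1")
      bad <- !nonmiss & !(v %in% c("./.", NA))
      if (any(bad)) stop("unrecognized genotype code: ", v[bad][1])
      if (!any(nonmiss))
        stop("all genotypes missing for population ", p, ", mutation ",
             muts[j])
      out[p, j] <- sum(v[nonmiss] == "1/1") / sum(nonmiss)
    }
  }
  out
}

#' Drop mutations in (near-)complete correlation
#'
#' Greedy left-to-right scan: a column is dropped when its squared Pearson
#' correlation with any already-retained column reaches the threshold
#' (within 1e-12); zero-variance columns are dropped with a warning.
#' Keep-first tie-breaking makes the result order-dependent by contract;
#' re-running on the pruned table is a no-op.
#'
#' @param table numeric matrix, populations x mutations
#' @param r2_threshold squared-correlation threshold (default 1)
#' @return list with `table` (pruned), `kept`, `dropped` (named character
#'   vector: dropped column -> retained column it duplicated, or
#'   `"zero-variance"`)
#' @export
prune_correlated <- function(table, r2_threshold = 1.0) {
  stopifnot(ncol(table) >= 1)
  kept <- character(0)
  dropped <- character(0)
  for (j in seq_len(ncol(table))) {
    nm <- colnames(table)[j]
    if (stats::var(table[, j]) == 0) {
      warning("zero-variance column dropped: ", nm)
      dropped[nm] <- "zero-variance"
      next
    }
    dup <- NULL
    for (k in kept) {
      r2 <- stats::cor(table[, j], table[, k])^2
      if (r2 >= r2_threshold - 1e-12) { dup <- k; break }
    }
    if (is.null(dup)) kept <- c(kept, nm) else dropped[nm] <- dup
  }
  list(table = table[, kept, drop = FALSE], kept = kept, dropped = dropped)
}

#' Recessive-model Gaussian GLM of median recombination rate
#'
#' Ordinary least squares (identity-link Gaussian GLM) of the population
#' median recombination rate on the retained homozygosity columns plus an
#' intercept, with two-sided t-tests on the coefficients. With zero
#' predictor columns the fit reduces to the intercept = mean(y).
#'
#' @param table numeric matrix populations x mutations (typically the
#'   pruned output of [prune_correlated()])
#' @param median_r named numeric vector of median recombination rates;
#'   matched to rownames of `table` when named
#' @return list with `coefficients` (estimate, std. error, t, p per term),
#'   `residual_df`, `fit`
#' @export
recessive_glm <- function(table, median_r) {
  table <- as.matrix(table)
  if (!is.null(names(median_r)) && !is.null(rownames(table))) {
    if (!setequal(names(median_r), rownames(table)))
      stop("population names of response and table do not match")
    median_r <- median_r[rownames(table)]
  }
  n <- nrow(table)
  p <- ncol(table)
  if (p > 0 && n <= p)
    stop("need more populations (", n, ") than retained mutations (", p,
         "); prune further")
  df <- data.frame(y = as.numeric(median_r))
  if (p > 0) {
    qrX <- qr(cbind(1, table))
    if (qrX$rank < p + 1) {
      cols <- colnames(table)[qrX$pivot[seq_len(qrX$rank)][-1]]
      stop("design matrix rank-deficient; collinear column(s): ",
           paste(setdiff(colnames(table), cols), collapse = ", "))
    }
    df <- cbind(df, as.data.frame(table))
  }
  fit <- stats::lm(y ~ ., data = df)
  co <- summary(fit)$coefficients
  colnames(co) <- c("estimate", "std_error", "t", "p")
  list(coefficients = co, residual_df = fit$df.residual, fit = fit)
}
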