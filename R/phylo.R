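#' Multiple correspondence analysis of a Boolean sharing matrix
#'
#' Each Boolean column is expanded into a two-category indicator pair
#' (present / absent), giving the complete disjunctive table. Row
#' (population) principal coordinates come from the standard
#' correspondence-analysis SVD of the standardized residuals of the
#' correspondence matrix. Constant columns carry no information and are
#' dropped with a warning. At most `n - 1` non-degenerate dimensions
#' exist for `n` rows.
#'
#' @param boolean_matrix logical (or 0/1) matrix, populations x items
#' @param n_dims dimensions to retain (default 9); truncated with a
#'   warning when fewer are available
#' @return list with `coords` (populations x dims), `inertia`
#'   (eigenvalues per retained dimension), `total_inertia`
#' @export
mca <- function(boolean_matrix, n_dims = 9) {
  B <- boolean_matrix * 1
  if (nrow(B) < 2 || ncol(B) < 2)
    stop("need at least 2 rows and 2 columns")
  keep <- apply(B, 2, function(col) stats::var(col) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant column(s) dropped")
    B <- B[, keep, drop = FALSE]
  }
  if (ncol(B) < 1) stop("no varying columns left")
  Z <- cbind(B, 1 - B)                      # complete disjunctive coding
  P <- Z / sum(Z)
  r <- rowSums(P); c <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, c)) %*% diag(1 / sqrt(c))
  sv <- svd(S)
  pos <- which(sv$d > 1e-12)
  avail <- length(pos)
  if (n_dims > avail) {
    warning("only ", avail, " non-degenerate dimension(s) available")
    n_dims <- avail
  }
  dims <- pos[seq_len(n_dims)]
  coords <- diag(1 / sqrt(r)) %*% sv$u[, dims, drop = FALSE] %*%
    diag(sv$d[dims], nrow = n_dims)
  rownames(coords) <- rownames(boolean_matrix)
  colnames(coords) <- paste0("dim", seq_len(n_dims))
  list(coords = coords, inertia = sv$d[dims]^2,
       total_inertia = sum(sv$d^2))
}

# shared-path (vcv) and patristic matrices for a tree, tips ordered as y
tree_matrices <- function(tree) {
  C <- ape::vcv(tree)
  D <- ape::cophenetic.phylo(tree)[rownames(C), colnames(C)]
  list(C = C, D = D)
}

gls_mean <- function(y, Vinv) {
  one <- rep(1, length(y))
  as.numeric((one %*% Vinv %*% y) / (one %*% Vinv %*% one))
}

mvn_lnl <- function(y, mean, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  res <- y - mean
  q <- sum(backsolve(ch, res, transpose = TRUE)^2)
  -0.5 * (n * log(2 * pi) + logdet + q)
}

#' Maximum-likelihood Brownian-motion fit of a tip trait
#'
#' Tip covariance is `sigma2 * C` with `C[i, j]` the shared root-to-MRCA
#' path length. The root state mu and sigma2 have closed-form MLEs; the
#' log-likelihood is the multivariate-normal density at the optimum.
#'
#' @param tree a `phylo` tree with branch lengths
#' @param y named trait vector over the tips
#' @return list with `mu`, `sigma2`, `lnL`, `k = 2`
#' @export
fit_brownian <- function(tree, y) {
  tm <- tree_matrices(tree)
  C <- tm$C
  if (!setequal(rownames(C), names(y))) stop("trait names must match tips")
  y <- y[rownames(C)]
  n <- length(y)
  Cr <- C
  Cinv <- tryCatch(solve(Cr), error = function(e) {
    warning("singular phylogenetic covariance; ridged")
    solve(Cr + diag(1e-10, n))
  })
  mu <- gls_mean(y, Cinv)
  s2 <- as.numeric(t(y - mu) %*% Cinv %*% (y - mu)) / n
  if (s2 < 1e-12) {
    warning("trait is (near-)constant; sigma2 floored")
    s2 <- 1e-12
  }
  lnL <- mvn_lnl(y, mu, s2 * Cr)
  list(mu = mu, sigma2 = s2, lnL = lnL, k = 2)
}

ou_correlation <- function(alpha, C, D) {
  # stationary-start Hansen covariance up to the factor sigma2 / (2 alpha)
  exp(-alpha * D) * (1 - exp(-2 * alpha * C))
}

ou_profile_lnl <- function(alpha, y, C, D) {
  R <- ou_correlation(alpha, C, D)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) return(list(lnL = -Inf))
  Rinv <- chol2inv(ch)
  theta <- gls_mean(y, Rinv)
  n <- length(y)
  v <- as.numeric(t(y - theta) %*% Rinv %*% (y - theta)) / n
  v <- max(v, 1e-300)
  logdet <- 2 * sum(log(diag(ch)))
  lnL <- -0.5 * (n * log(2 * pi) + n * log(v) + logdet + n)
  list(lnL = lnL, theta = theta, v = v)
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit of a tip trait
#'
#' Hansen-model covariance
#' `V[i,j] = sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_a))`
#' with `t_a` the shared root-path length and `d_ij` the patristic
#' distance; the root state is at the optimum theta (stationary start).
#' Given alpha, theta and sigma2 profile out analytically; alpha itself is
#' found by bounded 1-D search over `[1e-8, 50 / tree depth]` (on a log
#' scale). As alpha -> 0 the model collapses to Brownian motion.
#'
#' @param tree a `phylo` tree
#' @param y named trait vector over the tips
#' @return list with `theta`, `sigma2`, `alpha`, `lnL`, `k = 3`,
#'   `boundary` (TRUE when the optimum sits at the search boundary)
#' @export
fit_ou <- function(tree, y) {
  tm <- tree_matrices(tree)
  C <- tm$C; D <- tm$D
  if (!setequal(rownames(C), names(y))) stop("trait names must match tips")
  y <- y[rownames(C)]
  depth <- max(diag(C))
  lo <- 1e-8; hi <- 50 / depth
  obj <- function(la) -ou_profile_lnl(exp(la), y, C, D)$lnL
  opt <- stats::optimize(obj, c(log(lo), log(hi)), tol = 1e-8)
  alpha <- exp(opt$minimum)
  prof <- ou_profile_lnl(alpha, y, C, D)
  boundary <- opt$minimum < log(lo) + 1e-4 || opt$minimum > log(hi) - 1e-4
  list(theta = prof$theta, sigma2 = 2 * alpha * prof$v, alpha = alpha,
       lnL = prof$lnL, k = 3, boundary = boundary)
}

#' Compare Brownian-motion and Ornstein-Uhlenbeck fits by AIC
#'
#' Each trait dimension is fitted independently under both models;
#' log-likelihoods are summed across dimensions, the parameter count is
#' per-dimension k times the number of dimensions, and
#' `AIC = 2k - 2 lnL`. The smaller AIC wins.
#'
#' @param tree a `phylo` tree
#' @param trait_matrix populations x dimensions matrix (e.g. MCA coords)
#' @return list with `aic_bm`, `aic_ou`, `lnl_bm`, `lnl_ou`, `preferred`
#'   (`"BM"` or `"OU"`), and per-dimension fit lists
#' @export
compare_models <- function(tree, trait_matrix) {
  trait_matrix <- as.matrix(trait_matrix)
  if (ncol(trait_matrix) < 1) stop("need at least one trait dimension")
  bm <- apply(trait_matrix, 2, function(y) {
    names(y) <- rownames(trait_matrix); fit_brownian(tree, y)
  }, simplify = FALSE)
  ou <- apply(trait_matrix, 2, function(y) {
    names(y) <- rownames(trait_matrix); fit_ou(tree, y)
  }, simplify = FALSE)
  lnl_bm <- sum(vapply(bm, `[[`, 0, "lnL"))
  lnl_ou <- sum(vapply(ou, `[[`, 0, "lnL"))
  d <- ncol(trait_matrix)
  aic_bm <- 2 * 2 * d - 2 * lnl_bm
  aic_ou <- 2 * 3 * d - 2 * lnl_ou
  list(aic_bm = aic_bm, aic_ou = aic_ou, lnl_bm = lnl_bm, lnl_ou = lnl_ou,
       preferred = if (aic_bm <= aic_ou) "BM" else "OU",
       fits_bm = bm, fits_ou = ou)
}
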