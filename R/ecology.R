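#' Count-zero multiplicative replacement
#'
#' Replaces zeros in each sample (column) with a small positive value —
#' \code{delta_frac} times the sample's smallest nonzero proportion, on the
#' sample's own total — and multiplicatively rescales the nonzero parts so
#' each sample keeps its original total. Output is strictly positive and
#' every replacement stays strictly below the smallest observed nonzero
#' value.
#'
#' @param table species x sample matrix of non-negative abundances
#' @param delta_frac fraction of the minimum nonzero proportion used as the
#'   replacement (default 0.65, the method family's conventional choice)
#' @return strictly positive matrix with unchanged column sums
#' @export
czm_zero_replace <- function(table, delta_frac = 0.65) {
  m <- as.matrix(table)
  assert_that(all(m >= 0), "abundances must be non-negative")
  assert_that(all(colSums(m) > 0), "a sample is entirely zero")
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    z <- x == 0
    if (!any(z)) next
    tot <- sum(x)
    delta <- delta_frac * min(x[!z])
    out[z, j] <- delta
    out[!z, j] <- x[!z] * (1 - sum(z) * delta / tot)
  }
  out
}

#' Centered log-ratio transform
#'
#' Per sample (column): \code{log(x) - mean(log(x))}; column sums of the
#' transform are 0 and the transform is invariant to per-sample scaling.
#'
#' @param table strictly positive species x sample matrix
#' @return CLR-transformed matrix
#' @export
clr <- function(table) {
  m <- as.matrix(table)
  if (any(m <= 0)) {
    stop("nonpositive entries: apply czm_zero_replace() first", call. = FALSE)
  }
  lm <- log(m)
  sweep(lm, 2, colMeans(lm), "-")
}

#' Proportionality rho between CLR profiles
#'
#' \code{rho(i, j) = 1 - var(clr_i - clr_j) / (var(clr_i) + var(clr_j))}
#' across samples (sample variance, denominator n-1). Symmetric, bounded in
#' [-1, 1], with \code{rho(x, x) = 1}. Species with zero variance give NA for
#' their pairs (logged).
#'
#' @param clr_table CLR matrix (species x samples, at least 3 samples)
#' @return list with \code{matrix} (species x species) and \code{pairs}
#'   (long data.frame species_a, species_b, rho)
#' @export
proportionality_rho <- function(clr_table) {
  m <- as.matrix(clr_table)
  assert_that(ncol(m) >= 3, "rho needs at least 3 samples")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    sp_log("ecology", sum(v == 0), " zero-variance species: rho undefined ",
           "for their pairs")
  }
  S <- nrow(m)
  cv <- stats::cov(t(m))
  denom <- outer(v, v, "+")
  rho <- 1 - (outer(v, v, "+") - 2 * cv) / denom
  rho[outer(v == 0, v == 0, "|")] <- NA_real_
  diag(rho) <- ifelse(v == 0, NA_real_, 1)
  dimnames(rho) <- list(rownames(m), rownames(m))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  pairs <- data.frame(species_a = rownames(m)[idx[, 1]],
                      species_b = rownames(m)[idx[, 2]],
                      rho = rho[idx], stringsAsFactors = FALSE)
  list(matrix = rho, pairs = pairs)
}

#' Co-occurrence network edges with permutation FDR
#'
#' Edges are species pairs with rho above \code{cutoff}. The FDR at each
#' cutoff is estimated by permuting every species' sample labels
#' independently, recomputing rho, and taking (mean permuted count above the
#' cutoff) / (observed count above the cutoff). Node weight is the species'
#' mean CLR abundance.
#'
#' @param clr_table CLR matrix (species x samples)
#' @param cutoff rho retention cutoff (default 0.56)
#' @param fdr_target target FDR for the flag column of the FDR table
#'   (default 0.05)
#' @param n_perm permutations (default 1000)
#' @param seed random seed
#' @param cutoff_grid cutoffs tabulated in the FDR table
#' @return list: edges (source, target, rho), fdr_table (cutoff, n_observed,
#'   mean_null, fdr, meets_target), nodes (species, mean_clr), fdr_at_cutoff
#' @export
network_edges <- function(clr_table, cutoff = 0.56, fdr_target = 0.05,
                          n_perm = 1000, seed = 1,
                          cutoff_grid = seq(0.05, 0.95, by = 0.05)) {
  m <- as.matrix(clr_table)
  obs <- proportionality_rho(m)
  grid <- sort(unique(c(cutoff_grid, cutoff)))
  n_obs <- vapply(grid, function(ct) sum(obs$pairs$rho > ct, na.rm = TRUE),
                  numeric(1))
  set.seed(stage_seed(seed, 7L))
  null_counts <- matrix(0, nrow = n_perm, ncol = length(grid))
  for (k in seq_len(n_perm)) {
    perm <- t(apply(m, 1, sample))
    pr <- proportionality_rho(perm)$pairs$rho
    null_counts[k, ] <- vapply(grid, function(ct) sum(pr > ct, na.rm = TRUE),
                               numeric(1))
  }
  fdr <- colMeans(null_counts) / pmax(n_obs, 1)
  fdr[n_obs == 0] <- NA_real_
  fdr_table <- data.frame(cutoff = grid, n_observed = n_obs,
                          mean_null = colMeans(null_counts), fdr = fdr,
                          meets_target = !is.na(fdr) & fdr < fdr_target)
  sel <- obs$pairs[!is.na(obs$pairs$rho) & obs$pairs$rho > cutoff, ,
                   drop = FALSE]
  edges <- data.frame(source = sel$species_a, target = sel$species_b,
                      rho = sel$rho, stringsAsFactors = FALSE)
  at <- fdr_table$fdr[fdr_table$cutoff == cutoff]
  if (nrow(edges) == 0) sp_log("ecology", "no pair above cutoff ", cutoff)
  list(edges = edges, fdr_table = fdr_table,
       nodes = data.frame(species = rownames(m), mean_clr = rowMeans(m),
                          stringsAsFactors = FALSE, row.names = NULL),
       fdr_at_cutoff = at)
}

#' Species richness above an abundance threshold
#'
#' @param table species x sample matrix of relative abundances in percent
#' @param threshold strict lower bound in percent (default 0.5)
#' @return integer count per sample
#' @export
richness <- function(table, threshold = 0.5) {
  m <- as.matrix(table)
  colSums(m > threshold)
}
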