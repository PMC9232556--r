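#' Log density transform
#'
#' Elementwise `ln(1 + x)`, the standard variance-stabilizing transform
#' applied to organism densities before computing community
#' dissimilarities.
#'
#' @param x Non-negative numeric vector or matrix.
#' @return Object of the same shape with `log1p` applied.
#' @export
log_density_transform <- function(x) {
  if (any(x < 0)) stop("densities must be non-negative")
  log1p(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between sample rows,
#' d(i,j) = sum|x_ik - x_jk| / sum(x_ik + x_jk), computed with
#' [vegan::vegdist()]. A pair of all-zero samples has an undefined
#' ratio; it is defined here as 0 (identical emptiness) with a warning,
#' a case synthetic data can produce even though field data should not.
#'
#' @param x Community matrix (samples in rows, taxa in columns),
#'   non-negative values.
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 samples are required")
  if (any(x < 0)) stop("community matrix must be non-negative")
  empty <- rowSums(x) == 0
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (sum(empty) >= 2) {
    warning("pair(s) of all-zero samples: Bray-Curtis defined as 0")
    m <- as.matrix(d)
    m[empty, empty] <- 0
    diag(m) <- 0
    d <- stats::as.dist(m)
  }
  d
}

# all distinct assignments of the multiset of labels `g` (columns)
.label_assignments <- function(g, limit = 1e5) {
  g <- as.character(g)
  lev <- unique(g)
  counts <- table(factor(g, levels = lev))
  n_distinct <- factorial(length(g)) / prod(factorial(counts))
  if (n_distinct > limit)
    stop("exact enumeration infeasible: ", n_distinct, " assignments")
  rec <- function(remaining) {
    n <- sum(remaining)
    if (n == 0) return(matrix(character(0), nrow = 0, ncol = 1))
    out <- NULL
    for (l in names(remaining)[remaining > 0]) {
      r2 <- remaining
      r2[l] <- r2[l] - 1
      sub <- rec(r2)
      out <- cbind(out, rbind(rep(l, ncol(sub)), sub))
    }
    out
  }
  rec(counts)  # n x n_distinct character matrix
}

# R statistic from pair ranks and a within-group indicator
.anosim_R <- function(ranks, within, n) {
  (mean(ranks[!within]) - mean(ranks[within])) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test comparing between-group with within-group
#' community dissimilarities. The statistic is Clarke's
#' R = (mean rank between - mean rank within) / (n(n-1)/4), with average
#' ranks for ties, so R lies in \[-1, 1\] and equals 1 when every
#' between-group dissimilarity exceeds every within-group one. The
#' p-value uses the (b+1)/(m+1) permutation estimator; with
#' `exact = TRUE` all distinct label assignments are enumerated instead
#' and the p-value is the exact proportion of assignments with
#' permuted R >= observed R (the observed assignment included).
#'
#' @param d Dissimilarity: a `dist` object or symmetric matrix.
#' @param grouping Group label per sample; at least 2 groups, each with
#'   at least 2 members.
#' @param permutations Number of random label permutations (default 999;
#'   ignored when `exact = TRUE`).
#' @param seed Optional integer seed for the permutation draw.
#' @param exact Enumerate all distinct label assignments (small n only).
#' @return Object of class `hsc_anosim`: list with `statistic` (R), `p`,
#'   `permutations`, `exact`, `grouping`, `group_sizes`, `seed`.
#' @export
anosim_test <- function(d, grouping, permutations = 999, seed = NULL,
                        exact = FALSE) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  grouping <- as.character(grouping)
  if (length(grouping) != n)
    stop("grouping length (", length(grouping),
         ") does not match number of samples (", n, ")")
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("at least 2 groups are required")
  if (any(sizes < 2))
    stop("every group needs >= 2 members; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))

  dv <- as.vector(d)
  if (max(dv) - min(dv) < .Machine$double.eps^0.5)
    warning("constant dissimilarity matrix; R = 0")
  ranks <- rank(dv)  # average ranks for ties
  # row/column index of each pair in the dist vector
  ii <- unlist(lapply(seq_len(n - 1), function(j) seq(j + 1, n)))
  jj <- rep(seq_len(n - 1), times = (n - 1):1)

  r_obs <- .anosim_R(ranks, grouping[ii] == grouping[jj], n)
  eps <- sqrt(.Machine$double.eps)

  if (exact) {
    perms <- .label_assignments(grouping)
    r_perm <- apply(perms, 2, function(g) .anosim_R(ranks, g[ii] == g[jj], n))
    p <- mean(r_perm >= r_obs - eps)
    n_perm <- ncol(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(permutations), function(k) {
      g <- sample(grouping)
      .anosim_R(ranks, g[ii] == g[jj], n)
    }, numeric(1))
    p <- (sum(r_perm >= r_obs - eps) + 1) / (permutations + 1)
    n_perm <- permutations
  }
  structure(list(statistic = r_obs, p = p, permutations = n_perm,
                 exact = exact, grouping = grouping,
                 group_sizes = as.list(sizes), seed = seed),
            class = "hsc_anosim")
}

#' @export
print.hsc_anosim <- function(x, ...) {
  cat("ANOSIM: R =", signif(x$statistic, 4), ", p =", signif(x$p, 4),
      if (x$exact) "(exact," else "(permutational,",
      x$permutations, "assignments)\n")
  invisible(x)
}

#' Serialize an ANOSIM result to JSON
#'
#' @param x An `hsc_anosim` object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_anosim <- function(x, path) {
  stopifnot(inherits(x, "hsc_anosim"))
  jsonlite::write_json(
    list(R = x$statistic, p = x$p, n_permutations = x$permutations,
         exact = x$exact, seed = x$seed, group_sizes = x$group_sizes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Shannon-Wiener diversity index
#'
#' H = -sum p_i ln(p_i) over taxa with positive counts, where p_i is the
#' share of taxon i in the total count. Computed with
#' [vegan::diversity()].
#'
#' @param counts Non-negative count vector.
#' @return H (natural log units), >= 0.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("total count must be positive")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Count EPT individuals in a sample
#'
#' Sums individuals of taxa whose taxonomic order is Ephemeroptera,
#' Plecoptera or Trichoptera, the pollution-sensitive orders used as a
#' water-quality indicator.
#'
#' @param counts Named count vector (taxon -> count).
#' @param traits An `hsc_traits` data frame covering all taxa in
#'   `counts`.
#' @return Non-negative integer.
#' @export
ept_count <- function(counts, traits) {
  taxa <- names(counts)
  ord <- traits$order[match(taxa, traits$taxon)]
  if (anyNA(ord))
    stop("taxa missing from traits: ",
         paste(taxa[is.na(ord)], collapse = ", "))
  sum(counts[ord %in% c("Ephemeroptera", "Plecoptera", "Trichoptera")])
}
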