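# Independent brute-force reference implementations. Deliberately
# loop-based and self-contained (no shared code with the package paths
# they validate).

# proportion of weight per bin; half-open bins, last bin closed
oracle_bin_tally <- function(values, weights, edges = NULL,
                             categories = NULL) {
  if (!is.null(categories)) {
    out <- numeric(length(categories))
    for (i in seq_along(values)) {
      j <- which(categories == values[i])
      out[j] <- out[j] + weights[i]
    }
  } else {
    n <- length(edges) - 1
    out <- numeric(n)
    for (i in seq_along(values)) {
      for (j in seq_len(n)) {
        lo <- edges[j]; hi <- edges[j + 1]
        hit <- if (j < n) (values[i] >= lo && values[i] < hi)
               else (values[i] >= lo && values[i] <= hi)
        if (hit) out[j] <- out[j] + weights[i]
      }
    }
  }
  out / sum(out)
}

# average ranks by direct counting (no base rank())
oracle_ranks <- function(v) {
  sapply(seq_along(v), function(k)
    sum(v < v[k]) + (sum(v == v[k]) + 1) / 2)
}

oracle_anosim_R <- function(dmat, g) {
  n <- nrow(dmat)
  dv <- c(); within <- c()
  for (j in 1:(n - 1)) for (i in (j + 1):n) {
    dv <- c(dv, dmat[i, j])
    within <- c(within, g[i] == g[j])
  }
  r <- oracle_ranks(dv)
  (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
}

# exhaustive two-group label enumeration
oracle_anosim_exact <- function(dmat, g) {
  n <- nrow(dmat)
  lev <- unique(g)
  k <- sum(g == lev[1])
  r_obs <- oracle_anosim_R(dmat, g)
  combos <- utils::combn(n, k)
  rs <- apply(combos, 2, function(idx) {
    gp <- rep(lev[2], n); gp[idx] <- lev[1]
    oracle_anosim_R(dmat, gp)
  })
  list(R = r_obs, p = mean(rs >= r_obs - 1e-12), n_assign = ncol(combos))
}

oracle_shannon <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p))
}

# small fixed trait table used across tests
mini_traits <- function() {
  as_traits(data.frame(
    taxon = c("Baetis sp.", "Chironomidae", "Simuliidae",
              "Erpobdella sp.", "Limnephilus sp."),
    order = c("Ephemeroptera", "Diptera", "Diptera",
              "Arhynchobdellida", "Trichoptera"),
    family = c("Baetidae", "Chironomidae", "Simuliidae",
               "Erpobdellidae", "Limnephilidae"),
    gra = c(4, 2, 0, 0, 2), shr = c(0, 0, 0, 0, 6),
    gat = c(6, 6, 0, 0, 2), ff = c(0, 2, 10, 0, 0),
    pre = c(0, 0, 0, 10, 0), par = 0, oth = 0,
    stringsAsFactors = FALSE))
}

# random small dataset on the mini trait table
rand_dataset <- function(n_samples, seed, n_campaigns = 2) {
  set.seed(seed)
  traits <- mini_traits()
  env <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    campaign_id = sample(paste0("c", seq_len(n_campaigns)), n_samples,
                         replace = TRUE),
    velocity_m_s = round(runif(n_samples, 0, 0.6), 3),
    depth_m = round(runif(n_samples, 0.05, 0.6), 3),
    substrate = sample(substrate_codes(), n_samples, replace = TRUE),
    area_m2 = round(runif(n_samples, 0.5, 2), 2),
    stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    cbind(env[i, ], data.frame(taxon = traits$taxon,
                               count = rpois(nrow(traits), 3),
                               stringsAsFactors = FALSE),
          row.names = NULL)
  }))
  validate_dataset(as_samples(long), traits)
}
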