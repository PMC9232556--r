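#' Construct a bin scheme for a habitat parameter
#'
#' Continuous parameters (velocity, depth) use half-open bins
#' `[lo, hi)` with the last bin closed, which prevents double counting
#' at shared edges. Substrate is categorical.
#'
#' @param parameter One of `"velocity"`, `"depth"`, `"substrate"`.
#' @param edges Strictly increasing numeric edges (continuous; >= 2).
#' @param categories Ordered unique category codes (categorical).
#' @return Object of class `hsc_bins`: list with `parameter`, `kind`
#'   (`"continuous"`/`"categorical"`), `edges` or `categories`,
#'   `labels`, `n`.
#' @export
bin_scheme <- function(parameter, edges = NULL, categories = NULL) {
  parameter <- match.arg(parameter, c("velocity", "depth", "substrate"))
  if (!is.null(edges)) {
    if (length(edges) < 2 || any(diff(edges) <= 0))
      stop("edges must be >= 2 strictly increasing values")
    n <- length(edges) - 1
    labels <- sprintf("[%.3g,%.3g%s", edges[-length(edges)], edges[-1],
                      c(rep(")", n - 1), "]"))
    out <- list(parameter = parameter, kind = "continuous", edges = edges,
                labels = labels, n = n)
  } else if (!is.null(categories)) {
    if (length(categories) == 0 || anyDuplicated(categories))
      stop("categories must be non-empty and unique")
    out <- list(parameter = parameter, kind = "categorical",
                categories = as.character(categories),
                labels = as.character(categories), n = length(categories))
  } else stop("provide either edges or categories")
  structure(out, class = "hsc_bins")
}

#' Default bin scheme for a habitat parameter
#'
#' Velocity and depth use 0.05-unit bins from 0 up to the data maximum
#' rounded up to the next bin edge (matching the conventional 0.05 m/s
#' velocity intervals of habitat-curve practice); substrate uses the six
#' category codes.
#'
#' @inheritParams bin_scheme
#' @param values Observed parameter values (continuous parameters) used
#'   to set the upper edge; alternatively give `max_value`.
#' @param max_value Upper data value; ignored when `values` is given.
#' @param width Bin width (m/s or m), default 0.05.
#' @param categories Substrate codes, default [substrate_codes()].
#' @return An `hsc_bins` object.
#' @export
default_bins <- function(parameter, values = NULL, max_value = NULL,
                         width = 0.05, categories = substrate_codes()) {
  parameter <- match.arg(parameter, c("velocity", "depth", "substrate"))
  if (parameter == "substrate")
    return(bin_scheme(parameter, categories = categories))
  if (!is.null(values)) max_value <- max(values)
  if (is.null(max_value) || !is.finite(max_value) || max_value < 0)
    stop("a finite non-negative max_value (or values) is required")
  upper <- max(width, ceiling(max_value / width - 1e-9) * width)
  bin_scheme(parameter, edges = seq(0, upper, by = width))
}

#' Assign parameter values to bins
#'
#' @param values Numeric values (continuous) or category codes
#'   (categorical).
#' @param bins An `hsc_bins` object.
#' @return Integer bin index per value (1-based).
#' @export
bin_index <- function(values, bins) {
  stopifnot(inherits(bins, "hsc_bins"))
  if (bins$kind == "categorical") {
    idx <- match(as.character(values), bins$categories)
    if (anyNA(idx))
      stop("value(s) outside bin categories: ",
           paste(unique(values[is.na(idx)]), collapse = ", "))
    return(idx)
  }
  e <- bins$edges
  if (any(values < e[1]) || any(values > e[length(e)]))
    stop("value(s) outside bin range [", e[1], ", ", e[length(e)], "]")
  findInterval(values, e, rightmost.closed = TRUE)
}

# parameter values of the samples of an env table
.param_values <- function(env, bins) {
  switch(bins$parameter,
         velocity = env$velocity,
         depth = env$depth,
         substrate = env$substrate)
}

#' Standardize group abundance by campaign
#'
#' Each sample's group-projected abundance is divided by the highest
#' abundance of that group recorded in the same measurement campaign,
#' removing between-campaign differences in overall abundance before
#' campaigns are compared or pooled. A campaign where the group is
#' entirely absent contributes zeros, with a warning.
#'
#' @param dataset An `hsc_dataset`.
#' @param membership An `ffg_membership` object.
#' @param group Group label.
#' @return Named vector (by sample id) of standardized abundances in
#'   \[0, 1\].
#' @export
standardize_by_campaign <- function(dataset, membership, group) {
  ab <- group_abundance(dataset, membership, group)
  campaign <- dataset$env$campaign_id
  out <- ab
  for (cmp in unique(campaign)) {
    sel <- campaign == cmp
    m <- max(ab[sel])
    if (m == 0) {
      warning("group ", group, " absent from campaign ", cmp,
              "; standardized abundances set to 0")
      out[sel] <- 0
    } else {
      out[sel] <- ab[sel] / m
    }
  }
  out
}

#' Habitat availability curve (HAC)
#'
#' P\[E\](i) = a_i / sum(a_i), where a_i is the sampled habitat area
#' falling in bin i. With the equal-effort default area of 1 m^2 per
#' sample this is the sample-frequency distribution of available
#' habitat.
#'
#' @param env Sample table (the `env` element of an `hsc_dataset`), or
#'   an `hsc_dataset`.
#' @param bins An `hsc_bins` object.
#' @return Numeric vector of per-bin availability proportions (sums
#'   to 1).
#' @export
availability_curve <- function(env, bins) {
  if (inherits(env, "hsc_dataset") || inherits(env, "hsc_samples"))
    env <- env$env
  if (nrow(env) == 0) stop("no samples")
  idx <- bin_index(.param_values(env, bins), bins)
  a <- vapply(seq_len(bins$n), function(i) sum(env$area[idx == i]),
              numeric(1))
  a / sum(a)
}

#' Habitat utilization curve (HUC)
#'
#' P\[E/F\](i) = u_i / sum(u_i), where u_i is the total (standardized)
#' abundance of the group in habitat-parameter bin i.
#'
#' @inheritParams availability_curve
#' @param abundance Named abundance per sample (typically from
#'   [standardize_by_campaign()]), aligned with `env$sample_id`.
#' @param group Group label used in the error message when total
#'   abundance is zero.
#' @return Numeric vector of per-bin use proportions (sums to 1).
#' @export
utilization_curve <- function(env, bins, abundance, group = "group") {
  if (inherits(env, "hsc_dataset") || inherits(env, "hsc_samples"))
    env <- env$env
  if (!is.null(names(abundance))) abundance <- abundance[env$sample_id]
  if (length(abundance) != nrow(env))
    stop("abundance must have one value per sample")
  if (sum(abundance) <= 0)
    stop("total abundance of ", group, " is zero; no utilization curve")
  idx <- bin_index(.param_values(env, bins), bins)
  u <- vapply(seq_len(bins$n), function(i) sum(abundance[idx == i]),
              numeric(1))
  u / sum(u)
}

#' Habitat preference curve (HPC)
#'
#' The use/availability ratio P_r(i) = P\[E/F\](i) / P\[E\](i).
#' Preference is unknowable where no habitat was available: bins with
#' zero availability are masked (`NA`), never imputed as zero. Use
#' recorded where availability is zero is inconsistent input and raises
#' an error.
#'
#' @param huc Utilization proportions P\[E/F\] per bin.
#' @param hac Availability proportions P\[E\] per bin (same bin scheme).
#' @return Numeric vector of preference ratios, `NA` on masked bins.
#' @export
preference_curve <- function(huc, hac) {
  if (length(huc) != length(hac))
    stop("huc and hac must share one bin scheme")
  if (any(hac == 0 & huc > 0))
    stop("use recorded in bin(s) with zero availability: ",
         paste(which(hac == 0 & huc > 0), collapse = ", "))
  hpc <- rep(NA_real_, length(hac))
  ok <- hac > 0
  hpc[ok] <- huc[ok] / hac[ok]
  hpc
}

#' Rescale a curve to a suitability index
#'
#' SI(i) = value(i) / max over defined bins, so the best bin scores 1.
#' Masked (`NA`) bins stay masked.
#'
#' @param values Per-bin curve values (HUC or HPC), `NA` where
#'   undefined.
#' @param defined Logical mask of defined bins; defaults to
#'   `!is.na(values)`.
#' @return Numeric SI vector in \[0, 1\] with `NA` on masked bins.
#' @export
to_si <- function(values, defined = !is.na(values)) {
  if (!any(defined)) stop("no defined bins")
  m <- max(values[defined])
  if (m <= 0) stop("all defined values are zero; SI undefined")
  si <- rep(NA_real_, length(values))
  si[defined] <- values[defined] / m
  si
}

#' Availability-use excess diagnostic
#'
#' Per-bin signed difference P\[E\] - P\[E/F\]. Bins where availability
#' exceeds use are candidate true low-preference troughs: the habitat
#' was on offer but organisms were scarce, so a dip (e.g. the trough of
#' a bimodal curve) reflects preference rather than unsampled habitat.
#' Bins with use but essentially no availability are flagged separately
#' as suspect.
#'
#' @inheritParams preference_curve
#' @return List with `difference` (hac - huc per bin), `troughs`
#'   (indices with availability strictly above use) and
#'   `unavailable_use` (indices with use but near-zero availability).
#' @export
huc_hac_excess <- function(hac, huc) {
  if (length(huc) != length(hac))
    stop("huc and hac must share one bin scheme")
  diff <- hac - huc
  list(difference = diff,
       troughs = which(diff > 0),
       unavailable_use = which(huc > 0 & hac <= 1e-12))
}

#' Build the full curve set for one group, parameter and campaign scope
#'
#' Computes HAC, HUC and HPC plus their SI rescalings on a shared bin
#' scheme. Availability is computed from the samples in scope;
#' standardized abundances are always computed per campaign on the full
#' dataset, then restricted to the scope, so that single-campaign and
#' combined analyses use identical standardization.
#'
#' @param dataset An `hsc_dataset`.
#' @param membership An `ffg_membership` object.
#' @param group Group label.
#' @param parameter `"velocity"`, `"depth"` or `"substrate"`.
#' @param bins An `hsc_bins` object; default bins from the full dataset
#'   when `NULL`.
#' @param campaign A campaign id, or `"combined"` (default) for all
#'   samples pooled.
#' @return Object of class `hsc_curveset`: list with `parameter`,
#'   `group`, `campaign`, `bins`, `hac`, `huc`, `hpc`, `si_huc`,
#'   `si_hpc`, `defined` (availability > 0 mask).
#' @export
suitability_curves <- function(dataset, membership, group, parameter,
                               bins = NULL, campaign = "combined") {
  if (is.null(bins))
    bins <- default_bins(parameter,
                         values = .param_values(dataset$env,
                                                list(parameter = parameter)))
  std <- standardize_by_campaign(dataset, membership, group)
  env <- dataset$env
  if (!identical(campaign, "combined")) {
    if (!(campaign %in% env$campaign_id))
      stop("unknown campaign: ", campaign)
    keep <- env$campaign_id == campaign
    env <- env[keep, , drop = FALSE]
    std <- std[env$sample_id]
  }
  hac <- availability_curve(env, bins)
  huc <- utilization_curve(env, bins, std, group = group)
  hpc <- preference_curve(huc, hac)
  defined <- hac > 0
  structure(list(parameter = parameter, group = group, campaign = campaign,
                 bins = bins, hac = hac, huc = huc, hpc = hpc,
                 si_huc = to_si(huc, defined), si_hpc = to_si(hpc, defined),
                 defined = defined),
            class = "hsc_curveset")
}

#' Combine suitability-index vectors across campaigns
#'
#' `pointwise_max` takes, per bin, the maximum SI over all supplied
#' vectors, treating masked bins as absent (a bin masked everywhere
#' stays masked). `envelope_fill` (continuous parameters only)
#' additionally sets SI = 1 on every bin between the first and last bin
#' whose pointwise maximum reaches `fill_threshold`, bridging the
#' trough between campaign-specific optima into the widened SI = 1
#' plateau that pooled multi-campaign criteria exhibit, then rescales so
#' the maximum is 1. Both strategies are idempotent and `envelope_fill`
#' never falls below `pointwise_max`.
#'
#' @param si_list List of SI vectors on a shared bin scheme (`NA` =
#'   masked).
#' @param strategy `"envelope_fill"` (default) or `"pointwise_max"`.
#' @param fill_threshold SI level a bin must reach to anchor the filled
#'   plateau; default 0.8.
#' @param continuous Is the parameter continuous? `envelope_fill` on a
#'   categorical parameter is an error (no between-bin ordering to
#'   bridge).
#' @return List with `si` (combined vector) and `defined` mask.
#' @export
combine_si <- function(si_list, strategy = c("envelope_fill", "pointwise_max"),
                       fill_threshold = 0.8, continuous = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(length(si_list) >= 1)
  lens <- lengths(si_list)
  if (length(unique(lens)) != 1)
    stop("SI vectors must share one bin scheme")
  mat <- do.call(rbind, si_list)
  si <- suppressWarnings(apply(mat, 2, max, na.rm = TRUE))
  si[!is.finite(si)] <- NA_real_
  if (strategy == "envelope_fill") {
    if (!continuous)
      stop("envelope_fill is only defined for continuous parameters")
    anchor <- which(!is.na(si) & si >= fill_threshold)
    if (length(anchor)) {
      si[min(anchor):max(anchor)] <- 1
      si <- si / max(si, na.rm = TRUE)
    }
  }
  list(si = si, defined = !is.na(si))
}

#' Combine per-campaign curve sets into a final habitat suitability curve
#'
#' For each campaign, a bin's candidate SI is the larger of its SI-HUC
#' and SI-HPC values (final criteria must honour both curves); these
#' candidates are then combined across campaigns with [combine_si()].
#'
#' @param curvesets List of `hsc_curveset` objects on a shared bin
#'   scheme (one per campaign, or a single combined set).
#' @inheritParams combine_si
#' @return Object of class `hsc_final`: list with `parameter`, `group`,
#'   `bins`, `si`, `defined`, `strategy`, `fill_threshold`.
#' @export
combine_campaigns <- function(curvesets,
                              strategy = c("envelope_fill", "pointwise_max"),
                              fill_threshold = 0.8) {
  strategy <- match.arg(strategy)
  stopifnot(length(curvesets) >= 1,
            all(vapply(curvesets, inherits, logical(1), "hsc_curveset")))
  b <- curvesets[[1]]$bins
  params <- vapply(curvesets, function(cs) cs$parameter, character(1))
  ns <- vapply(curvesets, function(cs) as.integer(cs$bins$n), integer(1))
  if (length(unique(params)) != 1 || length(unique(ns)) != 1)
    stop("curve sets must share one parameter and bin scheme")
  si_list <- unlist(lapply(curvesets, function(cs)
    list(cs$si_huc, cs$si_hpc)), recursive = FALSE)
  comb <- combine_si(si_list, strategy = strategy,
                     fill_threshold = fill_threshold,
                     continuous = b$kind == "continuous")
  structure(list(parameter = b$parameter, group = curvesets[[1]]$group,
                 bins = b, si = comb$si, defined = comb$defined,
                 strategy = strategy, fill_threshold = fill_threshold),
            class = "hsc_final")
}

#' Curve set as a data frame
#'
#' @param x An `hsc_curveset` or `hsc_final` object.
#' @param ... Unused.
#' @return Data frame with one row per bin.
#' @export
as.data.frame.hsc_curveset <- function(x, ...) {
  b <- x$bins
  out <- data.frame(parameter = x$parameter, group = x$group,
                    campaign = x$campaign, bin = b$labels,
                    stringsAsFactors = FALSE)
  if (b$kind == "continuous") {
    out$bin_lo <- b$edges[-length(b$edges)]
    out$bin_hi <- b$edges[-1]
  } else {
    out$category <- b$categories
  }
  out$hac <- x$hac; out$huc <- x$huc; out$hpc <- x$hpc
  out$si_huc <- x$si_huc; out$si_hpc <- x$si_hpc
  out$defined <- x$defined
  out
}

#' @rdname as.data.frame.hsc_curveset
#' @export
as.data.frame.hsc_final <- function(x, ...) {
  b <- x$bins
  out <- data.frame(parameter = x$parameter, group = x$group,
                    bin = b$labels, si = x$si, defined = x$defined,
                    stringsAsFactors = FALSE)
  out
}

#' @export
print.hsc_curveset <- function(x, ...) {
  cat("hsc_curveset:", x$group, "/", x$parameter, "/", x$campaign,
      "(", x$bins$n, "bins )\n")
  print(as.data.frame(x)[, -(1:3)], digits = 3)
  invisible(x)
}

#' @export
print.hsc_final <- function(x, ...) {
  cat("final HSC:", x$group, "/", x$parameter, "( strategy", x$strategy, ")\n")
  print(as.data.frame(x)[, -(1:2)], digits = 3)
  invisible(x)
}
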