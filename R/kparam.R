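#' Per-microhabitat components of the K suitability coefficient
#'
#' For each sample: `n_fam` = number of distinct macroinvertebrate
#' families present, `shannon` = Shannon-Wiener diversity of its taxon
#' counts (0 for an empty microhabitat), `ept` = number of
#' Ephemeroptera/Plecoptera/Trichoptera individuals, `density` = total
#' individuals per m^2 of sampled area.
#'
#' @param dataset An `hsc_dataset`.
#' @return Data frame: `sample_id`, `n_fam`, `shannon`, `ept`,
#'   `density`.
#' @export
k_components <- function(dataset) {
  comm <- dataset$comm
  traits <- dataset$traits
  fam <- traits$family[match(colnames(comm), traits$taxon)]
  ords <- traits$order[match(colnames(comm), traits$taxon)]
  ept_taxa <- ords %in% c("Ephemeroptera", "Plecoptera", "Trichoptera")
  n_fam <- apply(comm, 1, function(cts) length(unique(fam[cts > 0])))
  H <- apply(comm, 1, function(cts)
    if (sum(cts) > 0) shannon_index(cts) else 0)
  ept <- rowSums(comm[, ept_taxa, drop = FALSE])
  density <- rowSums(comm) / dataset$env$area
  data.frame(sample_id = dataset$env$sample_id, n_fam = as.numeric(n_fam),
             shannon = as.numeric(H), ept = as.numeric(ept),
             density = as.numeric(density), stringsAsFactors = FALSE)
}

#' K suitability coefficient per microhabitat
#'
#' The composite suitability coefficient combines family richness,
#' Shannon diversity, EPT abundance and organism density with fixed
#' weights:
#' `k_raw = 0.4 n + 0.3 H + 0.2 EPT + 0.1 density`,
#' normalized by the maximum over the whole dataset so k is in
#' \[0, 1\] and the best microhabitat scores exactly 1. The components
#' enter unscaled by default, exactly as the coefficient is defined,
#' even though density can dominate numerically;
#' `normalize_components = TRUE` divides each component by its dataset
#' maximum before weighting for users who want commensurate components.
#'
#' @param components Data frame from [k_components()].
#' @param normalize_components Rescale each component to \[0, 1\] by
#'   its dataset maximum before weighting; default `FALSE`.
#' @return Data frame of class `hsc_krecords`: the component columns
#'   plus `k_raw` and normalized `k`.
#' @export
k_values <- function(components, normalize_components = FALSE) {
  stopifnot(nrow(components) >= 1)
  comp <- components[c("n_fam", "shannon", "ept", "density")]
  if (normalize_components) {
    for (col in names(comp)) {
      m <- max(comp[[col]])
      if (m > 0) comp[[col]] <- comp[[col]] / m
    }
  }
  w <- c(0.4, 0.3, 0.2, 0.1)
  k_raw <- as.numeric(as.matrix(comp) %*% w)
  k_max <- max(k_raw)
  if (k_max == 0) {
    warning("all microhabitats empty; k set to 0")
    k <- rep(0, length(k_raw))
  } else {
    k <- k_raw / k_max
  }
  out <- cbind(components, k_raw = k_raw, k = k)
  class(out) <- c("hsc_krecords", "data.frame")
  out
}

#' K coefficients straight from a dataset
#'
#' Convenience wrapper: [k_components()] then [k_values()].
#'
#' @inheritParams k_components
#' @inheritParams k_values
#' @return An `hsc_krecords` data frame.
#' @export
k_coefficients <- function(dataset, normalize_components = FALSE) {
  k_values(k_components(dataset), normalize_components)
}

#' Binned upper envelope of K values
#'
#' For each habitat-parameter bin, the maximum k among the
#' microhabitats falling in it (masked `NA` when the bin holds no
#' sample). When an SI-HUC vector is supplied, the per-bin absolute
#' difference between the envelope and the curve is attached, to
#' quantify how closely the utilization curve tracks the upper limit of
#' the K coefficient.
#'
#' @param krecords An `hsc_krecords` data frame (or any data frame with
#'   `sample_id` and `k`).
#' @param env Sample table (`env` element of an `hsc_dataset`, or the
#'   dataset itself).
#' @param bins An `hsc_bins` object.
#' @param si_huc Optional SI-HUC vector on the same bins.
#' @return List with `envelope` (per-bin max k, `NA` if empty),
#'   `defined`, and (if `si_huc` given) `abs_diff`.
#' @export
k_upper_envelope <- function(krecords, env, bins, si_huc = NULL) {
  if (inherits(env, "hsc_dataset") || inherits(env, "hsc_samples"))
    env <- env$env
  k <- krecords$k[match(env$sample_id, krecords$sample_id)]
  if (anyNA(k))
    stop("krecords missing sample(s): ",
         paste(env$sample_id[is.na(k)], collapse = ", "))
  idx <- bin_index(.param_values(env, bins), bins)
  envp <- vapply(seq_len(bins$n), function(i)
    if (any(idx == i)) max(k[idx == i]) else NA_real_, numeric(1))
  out <- list(envelope = envp, defined = !is.na(envp))
  if (!is.null(si_huc)) {
    if (length(si_huc) != bins$n)
      stop("si_huc must share the bin scheme")
    out$abs_diff <- abs(envp - si_huc)
  }
  out
}
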