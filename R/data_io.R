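#' Substrate category codes
#'
#' The six substrate categories used in the sandy lowland stream survey
#' scheme: `a` fine sand, `c` medium sand, `ae` fine sand with gravel,
#' `ce` medium sand with gravel, `e` gravel, `f` silt. The category list
#' is configurable throughout the package so the pipeline can be reused
#' on rivers with a different substrate classification.
#'
#' @return Character vector of category codes, in conventional order.
#' @export
substrate_codes <- function() c("a", "c", "ae", "ce", "e", "f")

#' Functional feeding group labels
#'
#' Guild labels of the 10-point trait allocation scheme: grazers/scrapers
#' (GRA), shredders (SHR), gatherers/collectors (GAT), filter feeders
#' (FF), predators (PRE), parasites (PAR) and others (OTH).
#'
#' @return Character vector of the seven FFG labels.
#' @export
ffg_labels <- function() c("GRA", "SHR", "GAT", "FF", "PRE", "PAR", "OTH")

.sample_cols <- c("sample_id", "campaign_id", "velocity_m_s", "depth_m",
                  "substrate", "area_m2", "taxon", "count")
.trait_cols <- c("taxon", "order", "family",
                 "gra", "shr", "gat", "ff", "pre", "par", "oth")

#' Read microhabitat samples from a long-format CSV
#'
#' One row per (sample, taxon). Columns (ordered): `sample_id`,
#' `campaign_id`, `velocity_m_s`, `depth_m`, `substrate`, `area_m2`,
#' `taxon`, `count`. `area_m2` is optional; when the column is absent
#' every sample is assigned an area of 1.0 m^2 (equal sampling effort),
#' which turns the availability curve into a sample-frequency estimate.
#' Rows with count 0 are retained as explicit zeros. Rows sharing a
#' `sample_id` must agree on the habitat measurements and are merged
#' into one record.
#'
#' @param path Path to the CSV file (UTF-8, `.` decimal separator,
#'   header required).
#' @param substrate_levels Allowed substrate category codes; defaults to
#'   [substrate_codes()].
#' @return An object of class `hsc_samples`: a list with `env` (one row
#'   per sample: `sample_id`, `campaign_id`, `velocity`, `depth`,
#'   `substrate`, `area`) and `comm` (sample-by-taxon count matrix with
#'   explicit zeros), both in canonical order (sorted by sample id and
#'   taxon).
#' @export
read_samples <- function(path, substrate_levels = substrate_codes()) {
  if (!file.exists(path)) stop("samples file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  as_samples(raw, substrate_levels = substrate_levels)
}

#' Build an `hsc_samples` object from a long-format data frame
#'
#' @param x Data frame with the `samples.csv` columns (`area_m2`
#'   optional).
#' @inheritParams read_samples
#' @return An `hsc_samples` object; see [read_samples()].
#' @export
as_samples <- function(x, substrate_levels = substrate_codes()) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!("area_m2" %in% names(x))) x$area_m2 <- rep(1.0, nrow(x))
  missing_cols <- setdiff(.sample_cols, names(x))
  if (length(missing_cols) && nrow(x) > 0)
    stop("samples table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(x) > 0) x <- x[.sample_cols]
  for (col in intersect(c("velocity_m_s", "depth_m", "area_m2"), names(x)))
    x[[col]] <- as.numeric(x[[col]])
  x$count <- suppressWarnings(as.numeric(x$count))
  if (nrow(x) == 0) {
    return(structure(
      list(env = data.frame(sample_id = character(), campaign_id = character(),
                            velocity = numeric(), depth = numeric(),
                            substrate = character(), area = numeric(),
                            stringsAsFactors = FALSE),
           comm = matrix(0, 0, 0)),
      substrate_levels = substrate_levels, class = "hsc_samples"))
  }

  bad_sub <- !(x$substrate %in% substrate_levels)
  if (any(bad_sub))
    stop("unknown substrate code(s) ",
         paste(unique(x$substrate[bad_sub]), collapse = ", "),
         " in row(s) ", paste(which(bad_sub), collapse = ", "),
         "; allowed: ", paste(substrate_levels, collapse = ", "))
  if (any(!is.finite(x$velocity_m_s)) || any(x$velocity_m_s < 0))
    stop("velocity_m_s must be finite and >= 0")
  if (any(!is.finite(x$depth_m)) || any(x$depth_m <= 0))
    stop("depth_m must be finite and > 0")
  if (any(!is.finite(x$area_m2)) || any(x$area_m2 <= 0))
    stop("area_m2 must be finite and > 0")
  if (any(!is.finite(x$count)) || any(x$count < 0) ||
      any(x$count != round(x$count)))
    stop("count must be a non-negative integer")
  dup <- duplicated(x[c("sample_id", "taxon")])
  if (any(dup))
    stop("duplicate (sample_id, taxon) pair(s): ",
         paste(unique(paste0(x$sample_id[dup], "/", x$taxon[dup])),
               collapse = ", "))

  # habitat measurements must be constant within a sample_id
  env_cols <- c("campaign_id", "velocity_m_s", "depth_m", "substrate", "area_m2")
  env <- unique(x[c("sample_id", env_cols)])
  if (anyDuplicated(env$sample_id))
    stop("inconsistent habitat measurements within sample_id: ",
         paste(unique(env$sample_id[duplicated(env$sample_id)]),
               collapse = ", "))
  env <- env[order(env$sample_id), ]
  names(env) <- c("sample_id", "campaign_id", "velocity", "depth",
                  "substrate", "area")
  rownames(env) <- NULL

  taxa <- sort(unique(x$taxon))
  comm <- matrix(0, nrow(env), length(taxa),
                 dimnames = list(env$sample_id, taxa))
  comm[cbind(match(x$sample_id, env$sample_id), match(x$taxon, taxa))] <-
    x$count
  structure(list(env = env, comm = comm),
            substrate_levels = substrate_levels, class = "hsc_samples")
}

#' Write microhabitat samples to the long-format CSV schema
#'
#' Every sample-by-taxon cell is written, including zeros, so that a
#' write/read round trip reproduces the object field-for-field.
#'
#' @param samples An `hsc_samples` object or an `hsc_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  env <- samples$env
  comm <- samples$comm
  long <- data.frame(
    sample_id = rep(env$sample_id, each = ncol(comm)),
    campaign_id = rep(env$campaign_id, each = ncol(comm)),
    velocity_m_s = rep(env$velocity, each = ncol(comm)),
    depth_m = rep(env$depth, each = ncol(comm)),
    substrate = rep(env$substrate, each = ncol(comm)),
    area_m2 = rep(env$area, each = ncol(comm)),
    taxon = rep(colnames(comm), nrow(env)),
    count = as.vector(t(comm)),
    stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the taxon trait table
#'
#' Columns: `taxon`, `order`, `family`, then the seven 10-point FFG
#' allocation columns `gra`, `shr`, `gat`, `ff`, `pre`, `par`, `oth`
#' (integers 0-10). The allocation of each taxon must sum to exactly 10.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `hsc_traits`, sorted by taxon.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("traits file not found: ", path)
  as_traits(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build an `hsc_traits` table from a data frame
#'
#' @param x Data frame with the `traits.csv` columns.
#' @return A data frame of class `hsc_traits`; see [read_traits()].
#' @export
as_traits <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.trait_cols, names(x))
  if (length(missing_cols))
    stop("traits table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  x <- x[.trait_cols]
  alloc_cols <- tolower(ffg_labels())
  for (col in alloc_cols) {
    v <- x[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 10) || any(v != round(v)))
      stop("allocation column '", col, "' must contain integers in 0..10")
    x[[col]] <- as.integer(v)
  }
  if (anyDuplicated(x$taxon))
    stop("duplicate taxon in traits: ",
         paste(unique(x$taxon[duplicated(x$taxon)]), collapse = ", "))
  sums <- rowSums(x[alloc_cols])
  bad <- sums != 10L
  if (any(bad))
    stop("FFG allocation must sum to 10: ",
         paste0(x$taxon[bad], " sums to ", sums[bad], collapse = "; "))
  x <- x[order(x$taxon), ]
  rownames(x) <- NULL
  class(x) <- c("hsc_traits", "data.frame")
  x
}

#' Write the taxon trait table
#'
#' @param traits An `hsc_traits` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(as.data.frame(traits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Cross-validate samples against traits and seal a dataset
#'
#' Checks that every taxon occurring in the samples has exactly one
#' trait record. An empty sample table is allowed (with a warning) so
#' that configuration can be validated before data arrive.
#'
#' @param samples An `hsc_samples` object (see [read_samples()]).
#' @param traits An `hsc_traits` data frame (see [read_traits()]).
#' @return An object of class `hsc_dataset`: list with `env`, `comm`
#'   and `traits`.
#' @export
validate_dataset <- function(samples, traits) {
  stopifnot(inherits(samples, "hsc_samples"), inherits(traits, "hsc_traits"))
  taxa <- colnames(samples$comm)
  missing_taxa <- setdiff(taxa, traits$taxon)
  if (length(missing_taxa))
    stop("taxa present in samples but missing from traits: ",
         paste(missing_taxa, collapse = ", "))
  if (nrow(samples$env) == 0)
    warning("dataset contains zero samples")
  structure(list(env = samples$env, comm = samples$comm, traits = traits),
            substrate_levels = attr(samples, "substrate_levels"),
            class = "hsc_dataset")
}

#' Read and validate a dataset from the two CSV schemas
#'
#' @param samples_path Path to `samples.csv`.
#' @param traits_path Path to `traits.csv`.
#' @inheritParams read_samples
#' @return An `hsc_dataset`; see [validate_dataset()].
#' @export
read_dataset <- function(samples_path, traits_path,
                         substrate_levels = substrate_codes()) {
  validate_dataset(read_samples(samples_path, substrate_levels),
                   read_traits(traits_path))
}

#' @export
print.hsc_dataset <- function(x, ...) {
  cat("hsc_dataset:", nrow(x$env), "microhabitat samples,",
      ncol(x$comm), "taxa,",
      length(unique(x$env$campaign_id)), "campaign(s)\n")
  cat("  campaigns:", paste(sort(unique(x$env$campaign_id)), collapse = ", "),
      "\n")
  cat("  total individuals:", sum(x$comm), "\n")
  invisible(x)
}

#' @export
print.hsc_samples <- function(x, ...) {
  cat("hsc_samples:", nrow(x$env), "samples,", ncol(x$comm), "taxa\n")
  invisible(x)
}
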