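#' Classify taxa into functional feeding groups
#'
#' A taxon belongs to a feeding group when its 10-point allocation for
#' that group reaches `threshold` (default 3). Membership is binary and
#' may overlap: a taxon allocated (GAT 6, GRA 4) is both a gatherer and
#' a grazer and contributes its full abundance to both groups. Taxa
#' whose allocation is spread so thinly that no group reaches the
#' threshold (possible from 4+ groups, e.g. 2+2+2+2+2) receive an empty
#' membership set; they are reported via the `empty` attribute and a
#' message, and still count towards the whole community.
#'
#' @param traits An `hsc_traits` data frame.
#' @param threshold Minimum allocation (1-10) for membership; default 3.
#' @return An object of class `ffg_membership`: a named list mapping
#'   each taxon to a character vector of FFG labels, with attributes
#'   `threshold` and `empty` (taxa with no membership).
#' @export
assign_ffg <- function(traits, threshold = 3) {
  stopifnot(inherits(traits, "hsc_traits"))
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold < 1 || threshold > 10)
    stop("threshold must be a single value in 1..10")
  labels <- ffg_labels()
  alloc <- as.matrix(traits[tolower(labels)])
  colnames(alloc) <- labels
  membership <- lapply(seq_len(nrow(alloc)), function(i)
    labels[alloc[i, ] >= threshold])
  names(membership) <- traits$taxon
  empty <- names(membership)[lengths(membership) == 0]
  if (length(empty))
    message("taxa with no FFG membership at threshold ", threshold,
            " (counted only in COMMUNITY): ", paste(empty, collapse = ", "))
  structure(membership, threshold = threshold, empty = empty,
            class = "ffg_membership")
}

#' Organism groups analysed by the pipeline
#'
#' By default the whole macroinvertebrate community plus the five
#' trophic FFGs. Parasites and "others" are excluded: parasites because
#' they are typically represented by very few taxa, "others" because the
#' label pools taxa with heterogeneous feeding mechanisms. Both can be
#' re-included via `include`.
#'
#' @param include Extra labels to append (e.g. `"PAR"`).
#' @param exclude Labels to drop from the default list.
#' @return Ordered character vector of group labels, starting with
#'   `"COMMUNITY"`.
#' @export
analysis_groups <- function(include = character(), exclude = character()) {
  groups <- c("COMMUNITY", "GRA", "SHR", "GAT", "FF", "PRE")
  groups <- c(setdiff(groups, exclude), setdiff(include, groups))
  bad <- setdiff(groups, c("COMMUNITY", ffg_labels()))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  groups
}

#' Project a sample's counts onto an organism group
#'
#' `COMMUNITY` sums all counts; an FFG label sums the counts of taxa
#' whose membership set contains that label. A taxon belonging to two
#' groups contributes its full count to both (binary membership, no
#' split weighting).
#'
#' @param counts Named non-negative count vector (taxon -> count).
#' @param membership An `ffg_membership` object covering the taxa.
#' @param group `"COMMUNITY"` or an FFG label.
#' @return Single non-negative number.
#' @export
project_counts <- function(counts, membership, group) {
  if (!(group %in% c("COMMUNITY", ffg_labels())))
    stop("unknown group label: ", group)
  if (group == "COMMUNITY") return(sum(counts))
  taxa <- names(counts)
  missing_taxa <- setdiff(taxa, names(membership))
  if (length(missing_taxa))
    stop("taxa without membership record: ",
         paste(missing_taxa, collapse = ", "))
  in_group <- vapply(membership[taxa], function(m) group %in% m, logical(1))
  sum(counts[in_group])
}

#' Per-sample abundance of an organism group
#'
#' Applies [project_counts()] across all samples of a dataset.
#'
#' @param dataset An `hsc_dataset`.
#' @param membership An `ffg_membership` object.
#' @param group Group label (see [analysis_groups()]).
#' @return Named numeric vector, one abundance per sample id.
#' @export
group_abundance <- function(dataset, membership, group) {
  if (!(group %in% c("COMMUNITY", ffg_labels())))
    stop("unknown group label: ", group)
  comm <- dataset$comm
  if (group == "COMMUNITY") {
    out <- rowSums(comm)
  } else {
    in_group <- vapply(membership[colnames(comm)],
                       function(m) group %in% m, logical(1))
    out <- rowSums(comm[, in_group, drop = FALSE])
  }
  names(out) <- rownames(comm)
  out
}

#' @export
print.ffg_membership <- function(x, ...) {
  cat("ffg_membership for", length(x), "taxa (threshold",
      attr(x, "threshold"), ")\n")
  tab <- table(factor(unlist(x), levels = ffg_labels()))
  print(tab)
  if (length(attr(x, "empty")))
    cat("  no membership:", paste(attr(x, "empty"), collapse = ", "), "\n")
  invisible(x)
}
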