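#' Smooth suitability bump
#'
#' One Gaussian-shaped component of a true suitability curve.
#'
#' @param center Location of the optimum (m/s or m).
#' @param width Spread (standard-deviation-like, same units).
#' @param height Peak suitability in (0, 1\].
#' @return List of class `hsc_bump`.
#' @export
suitability_bump <- function(center, width, height = 1) {
  stopifnot(width > 0, height > 0, height <= 1)
  structure(list(center = center, width = width, height = height),
            class = "hsc_bump")
}

#' Evaluate a true suitability curve
#'
#' A curve is a list of 0-2 [suitability_bump()]s; the value at `x` is
#' the bump sum clipped to \[0, 1\]. An empty bump list encodes a flat
#' curve (suitability 1 everywhere).
#'
#' @param bumps List of `hsc_bump` objects (possibly empty).
#' @param x Parameter values.
#' @return Suitability in \[0, 1\] per value of `x`.
#' @export
eval_truth_curve <- function(bumps, x) {
  if (length(bumps) == 0) return(rep(1, length(x)))
  v <- rowSums(vapply(bumps, function(b)
    b$height * exp(-(x - b$center)^2 / (2 * b$width^2)), numeric(length(x))))
  pmin(1, v)
}

#' True suitability of one organism group
#'
#' Ground truth used by the synthetic generator: a velocity curve, a
#' depth curve (each a mixture of up to two bumps; empty = flat) and a
#' named vector of substrate suitability weights in (0, 1\].
#'
#' @param velocity,depth Lists of [suitability_bump()]s.
#' @param substrate Named weights over the substrate codes; defaults to
#'   1 for every code in [substrate_codes()].
#' @return Object of class `hsc_truth`.
#' @export
true_suitability <- function(velocity = list(), depth = list(),
                             substrate = NULL) {
  if (is.null(substrate)) {
    substrate <- rep(1, length(substrate_codes()))
    names(substrate) <- substrate_codes()
  }
  stopifnot(all(substrate > 0), all(substrate <= 1),
            !is.null(names(substrate)))
  structure(list(velocity = velocity, depth = depth, substrate = substrate),
            class = "hsc_truth")
}

#' Composite suitability of a taxon's group at sampled habitat values
#'
#' @param truth An `hsc_truth` object.
#' @param velocity,depth Numeric habitat values.
#' @param substrate Substrate codes.
#' @return Product of the three component suitabilities, in \[0, 1\].
#' @export
truth_at <- function(truth, velocity, depth, substrate) {
  eval_truth_curve(truth$velocity, velocity) *
    eval_truth_curve(truth$depth, depth) *
    as.numeric(truth$substrate[substrate])
}

#' Generator configuration
#'
#' Study-design side of a synthetic scenario: per-campaign sample sizes
#' and habitat availability distributions, substrate availability
#' weights, the taxon roster, and the count model.
#'
#' Availability of velocity and depth is modelled as campaign-specific
#' normal distributions truncated at zero; the low-flow campaign's
#' distributions sit at lower velocities and depths, reproducing the
#' availability shift between a medium-flow and a low-flow survey.
#' Counts are negative binomial (overdispersed, as field
#' macroinvertebrate counts are) with mean
#' `base abundance x area x composite suitability`;
#' `dispersion = Inf` gives the Poisson limit.
#'
#' @param n_samples Named integer vector: samples per campaign.
#' @param availability Named list (per campaign) of lists with
#'   `velocity = c(mean, sd)` and `depth = c(mean, sd)`.
#' @param substrate_weights Named availability weights over substrate
#'   codes (need not sum to 1).
#' @param taxa Taxon roster: an `hsc_traits`-schema data frame with an
#'   extra `base` column (expected count per unit area at perfect
#'   suitability).
#' @param dispersion Negative binomial size parameter; default 2.
#' @param area Sampled area per microhabitat (m^2); default 1.
#' @param ffg_threshold Allocation threshold used to pick each taxon's
#'   responding group; default 3.
#' @return List of class `hsc_genconfig`.
#' @export
generator_config <- function(n_samples, availability, substrate_weights,
                             taxa, dispersion = 2, area = 1,
                             ffg_threshold = 3) {
  stopifnot(!is.null(names(n_samples)),
            all(names(n_samples) %in% names(availability)),
            nrow(taxa) >= 1, "base" %in% names(taxa))
  structure(list(n_samples = n_samples, availability = availability,
                 substrate_weights = substrate_weights, taxa = taxa,
                 dispersion = dispersion, area = area,
                 ffg_threshold = ffg_threshold),
            class = "hsc_genconfig")
}

# primary responding group of each roster taxon: trophic FFG with the
# largest allocation if it reaches the threshold, else the community curve
.taxon_groups <- function(taxa, threshold) {
  trophic <- c("GRA", "SHR", "GAT", "FF", "PRE")
  alloc <- as.matrix(taxa[tolower(trophic)])
  vapply(seq_len(nrow(alloc)), function(i) {
    a <- alloc[i, ]
    if (max(a) >= threshold) trophic[which.max(a)] else "COMMUNITY"
  }, character(1))
}

.rtruncnorm <- function(n, mean, sd, lower = 0) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

#' Generate a synthetic microhabitat dataset with known ground truth
#'
#' Draws, per campaign, habitat conditions from the availability
#' distributions (velocity and depth from truncated normals, substrate
#' from the availability weights), then per-taxon counts from the
#' negative binomial count model with mean proportional to the taxon's
#' group suitability at the sampled habitat. Truth curves are evaluated
#' pointwise at each sample, with no binning, so the generator shares
#' no code path with the curve estimators it is used to validate.
#' Fully deterministic given `seed`.
#'
#' @param config An `hsc_genconfig` object.
#' @param truth Named list of [true_suitability()] objects per group;
#'   must contain `"COMMUNITY"` (fallback for taxa outside the trophic
#'   groups).
#' @param seed Integer seed.
#' @return List of class `hsc_generated`: `dataset` (an
#'   `hsc_dataset`), `truth` and `config` echoes, `seed`.
#' @export
generate <- function(config, truth, seed) {
  stopifnot(inherits(config, "hsc_genconfig"), "COMMUNITY" %in% names(truth))
  if (nrow(config$taxa) == 0) stop("empty taxon roster")
  set.seed(seed)
  taxa <- config$taxa
  groups <- .taxon_groups(taxa, config$ffg_threshold)
  codes <- names(config$substrate_weights)
  rows <- list()
  for (cmp in names(config$n_samples)) {
    n <- config$n_samples[[cmp]]
    av <- config$availability[[cmp]]
    vel <- round(.rtruncnorm(n, av$velocity[1], av$velocity[2], 0), 4)
    dep <- round(.rtruncnorm(n, av$depth[1], av$depth[2], 0.01), 4)
    sub <- sample(codes, n, replace = TRUE,
                  prob = config$substrate_weights)
    ids <- sprintf("%s_%02d", cmp, seq_len(n))
    for (t in seq_len(nrow(taxa))) {
      tr <- truth[[groups[t]]]
      if (is.null(tr)) tr <- truth[["COMMUNITY"]]
      mu <- taxa$base[t] * config$area * truth_at(tr, vel, dep, sub)
      cts <- if (is.infinite(config$dispersion)) stats::rpois(n, mu)
             else stats::rnbinom(n, size = config$dispersion, mu = mu)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids, campaign_id = cmp, velocity_m_s = vel,
        depth_m = dep, substrate = sub, area_m2 = config$area,
        taxon = taxa$taxon[t], count = cts, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  traits <- as_traits(taxa[setdiff(names(taxa), "base")])
  dataset <- validate_dataset(
    as_samples(long, substrate_levels = codes), traits)
  structure(list(dataset = dataset, truth = truth, config = config,
                 seed = seed),
            class = "hsc_generated")
}

#' Default synthetic scenario
#'
#' A packaged scenario emulating a two-campaign survey of a sandy
#' lowland stream: 20 samples at medium flow and 30 at low flow, with
#' the low-flow campaign's availability shifted towards lower
#' velocities and depths; a roster of 21 taxa spanning all feeding
#' groups (including three Ephemeroptera, one Plecoptera and two
#' Trichoptera taxa, and Chironomidae/Simuliidae as the most abundant
#' taxa); bimodal community preference over velocity and depth; and a
#' narrow unimodal filter-feeder velocity preference centred near
#' 0.30 m/s.
#'
#' @return List with `config` (an `hsc_genconfig`) and `truth` (named
#'   list of `hsc_truth` objects).
#' @export
default_scenario <- function() {
  taxa <- default_roster()
  config <- generator_config(
    n_samples = c("2018" = 20L, "2019" = 30L),
    availability = list(
      "2018" = list(velocity = c(0.30, 0.15), depth = c(0.30, 0.13)),
      "2019" = list(velocity = c(0.12, 0.08), depth = c(0.18, 0.09))),
    substrate_weights = c(a = 0.20, c = 0.25, ae = 0.15, ce = 0.15,
                          e = 0.15, f = 0.10),
    taxa = taxa, dispersion = 2, area = 1)
  truth <- list(
    COMMUNITY = true_suitability(
      velocity = list(suitability_bump(0.08, 0.06, 1),
                      suitability_bump(0.45, 0.08, 0.9)),
      depth = list(suitability_bump(0.18, 0.08, 1),
                   suitability_bump(0.45, 0.10, 0.8)),
      substrate = c(a = 1, c = 0.6, ae = 0.6, ce = 0.9, e = 1, f = 0.9)),
    GRA = true_suitability(
      velocity = list(suitability_bump(0.08, 0.06, 1),
                      suitability_bump(0.45, 0.08, 0.9)),
      depth = list(suitability_bump(0.15, 0.08, 1),
                   suitability_bump(0.45, 0.10, 0.6)),
      substrate = c(a = 0.9, c = 0.5, ae = 0.7, ce = 0.8, e = 1, f = 0.8)),
    SHR = true_suitability(
      velocity = list(suitability_bump(0.10, 0.07, 1),
                      suitability_bump(0.40, 0.10, 0.7)),
      depth = list(suitability_bump(0.25, 0.10, 1)),
      substrate = c(a = 0.8, c = 1, ae = 0.7, ce = 0.6, e = 0.5, f = 0.9)),
    GAT = true_suitability(
      velocity = list(suitability_bump(0.06, 0.05, 1),
                      suitability_bump(0.50, 0.08, 0.8)),
      depth = list(suitability_bump(0.20, 0.08, 1),
                   suitability_bump(0.50, 0.08, 0.7)),
      substrate = c(a = 1, c = 0.6, ae = 0.6, ce = 0.8, e = 0.9, f = 1)),
    FF = true_suitability(
      velocity = list(suitability_bump(0.30, 0.05, 1)),
      depth = list(suitability_bump(0.27, 0.08, 1)),
      substrate = c(a = 0.9, c = 0.9, ae = 0.9, ce = 0.9, e = 1, f = 0.8)),
    PRE = true_suitability(
      velocity = list(suitability_bump(0.25, 0.10, 1)),
      depth = list(suitability_bump(0.30, 0.12, 1)),
      substrate = c(a = 0.7, c = 1, ae = 0.7, ce = 0.7, e = 0.7, f = 0.7)))
  list(config = config, truth = truth)
}

#' Default taxon roster for synthetic scenarios
#'
#' 21 benthic taxa typical of a sandy lowland stream, with 10-point FFG
#' allocations and baseline abundances. Chironomidae and Simuliidae are
#' the most abundant taxa; Ephemeroptera, Plecoptera and Trichoptera
#' are all represented; one parasite taxon (water mites) is included.
#'
#' @return Data frame in the traits schema plus a `base` column.
#' @export
default_roster <- function() {
  roster <- utils::read.csv(text =
"taxon,order,family,gra,shr,gat,ff,pre,par,oth,base
Baetis sp.,Ephemeroptera,Baetidae,4,0,6,0,0,0,0,4
Caenis sp.,Ephemeroptera,Caenidae,0,0,8,2,0,0,0,3
Ephemerella sp.,Ephemeroptera,Ephemerellidae,4,0,6,0,0,0,0,2
Nemoura sp.,Plecoptera,Nemouridae,1,6,3,0,0,0,0,1.5
Limnephilus sp.,Trichoptera,Limnephilidae,2,6,2,0,0,0,0,2
Hydropsyche sp.,Trichoptera,Hydropsychidae,0,0,2,6,2,0,0,2
Simuliidae,Diptera,Simuliidae,0,0,0,10,0,0,0,8
Chironomidae,Diptera,Chironomidae,2,0,6,2,0,0,0,12
Gammarus sp.,Amphipoda,Gammaridae,2,4,4,0,0,0,0,3
Asellus aquaticus,Isopoda,Asellidae,1,4,5,0,0,0,0,2
Lymnaea sp.,Basommatophora,Lymnaeidae,5,5,0,0,0,0,0,2
Planorbis sp.,Basommatophora,Planorbidae,7,3,0,0,0,0,0,1.5
Elmis sp.,Coleoptera,Elmidae,8,0,2,0,0,0,0,2
Ancylus fluviatilis,Basommatophora,Ancylidae,10,0,0,0,0,0,0,1.5
Erpobdella sp.,Arhynchobdellida,Erpobdellidae,0,0,0,0,10,0,0,1.5
Sialis sp.,Megaloptera,Sialidae,0,0,0,0,10,0,0,1
Aeshna sp.,Odonata,Aeshnidae,0,0,0,0,10,0,0,0.8
Pisidium sp.,Veneroida,Sphaeriidae,0,0,2,8,0,0,0,2
Hydrachnidia,Trombidiformes,Hydrachnidae,0,0,0,0,2,8,0,0.5
Oligochaeta,Haplotaxida,Tubificidae,0,0,8,0,0,0,2,4
Tipula sp.,Diptera,Tipulidae,0,6,2,0,0,0,2,1",
    stringsAsFactors = FALSE)
  roster
}

#' Null scenario: no campaign effect
#'
#' Identical truth for both campaigns and a shared availability
#' distribution, so community structure does not differ between
#' campaigns. Used to calibrate the ANOSIM pre-check (its p-values
#' should be uniform or conservative under this scenario).
#'
#' @return List with `config` and `truth` as in [default_scenario()].
#' @export
null_scenario <- function() {
  sc <- default_scenario()
  sc$config$availability[["2019"]] <- sc$config$availability[["2018"]]
  sc
}

#' Single-bump scenario for recovery experiments
#'
#' All groups share one unimodal velocity preference; depth and
#' substrate are flat. Recovering the known optimum bin from generated
#' data exercises the whole curve pipeline.
#'
#' @param center Optimum velocity (m/s), default 0.30.
#' @param width Bump width, default 0.05.
#' @param n_per_campaign Samples per campaign, default 200.
#' @return List with `config` and `truth`.
#' @export
single_bump_scenario <- function(center = 0.30, width = 0.05,
                                 n_per_campaign = 200L) {
  sc <- default_scenario()
  sc$config$n_samples <- c("2018" = n_per_campaign, "2019" = n_per_campaign)
  one <- true_suitability(
    velocity = list(suitability_bump(center, width, 1)))
  sc$truth <- stats::setNames(
    rep(list(one), length(sc$truth)), names(sc$truth))
  sc
}

#' Write a generated scenario to disk
#'
#' Emits `samples.csv` and `traits.csv` in the package schemas plus
#' `truth.json` (curve parameters and seed).
#'
#' @param g An `hsc_generated` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_generated <- function(g, dir) {
  stopifnot(inherits(g, "hsc_generated"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_samples(g$dataset, file.path(dir, "samples.csv"))
  write_traits(g$dataset$traits, file.path(dir, "traits.csv"))
  jsonlite::write_json(
    list(seed = g$seed,
         truth = lapply(g$truth, function(tr) list(
           velocity = lapply(tr$velocity, unclass),
           depth = lapply(tr$depth, unclass),
           substrate = as.list(tr$substrate)))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
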