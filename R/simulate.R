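## Synthetic community generator with known ground truth.
##
## The generator emulates the study design the pipeline is built for: four
## paired comparison sites, each with a strip field (10-12% reconstructed
## prairie) and a 100%-crop control field, sampled four times per season
## (May-Aug) over two years; 89 bee taxa (one of them a pooled Lasioglossum
## (Dialictus) assemblage) and 55 blooming forb taxa (27 native prairie, 28
## exotic/weedy).  Bee counts are Poisson on a log link; plant cover follows
## a Dirichlet-like scheme; planted bee-on-plant couplings and a visitation
## matrix consistent with them provide recoverable ground truth.

# family compositions scaled from the study community
BEE_FAMILIES <- c(Halictidae = 28, Apidae = 27, Andrenidae = 17,
                  Colletidae = 8, Megachilidae = 9)
PLANT_FAMILIES <- list(
  Asteraceae = c(P = 12, EW = 9), Fabaceae = c(P = 6, EW = 4),
  Amaranthaceae = c(P = 0, EW = 3), Polygonaceae = c(P = 0, EW = 2),
  Lamiaceae = c(P = 1, EW = 0), Apiaceae = c(P = 2, EW = 2),
  Plantaginaceae = c(P = 0, EW = 1), Onagraceae = c(P = 1, EW = 0),
  Brassicaceae = c(P = 0, EW = 2), Malvaceae = c(P = 0, EW = 1),
  Apocynaceae = c(P = 3, EW = 0), Rosaceae = c(P = 1, EW = 0),
  Oxalidaceae = c(P = 0, EW = 1), Urticaceae = c(P = 0, EW = 1),
  Scrophulariaceae = c(P = 0, EW = 1), Ranunculaceae = c(P = 1, EW = 0),
  Euphorbiaceae = c(P = 0, EW = 1))

#' Build the default synthetic taxon registry
#'
#' 89 bee taxa spread over the five families found in tallgrass-prairie bee
#' communities (Halictidae, Apidae, Andrenidae, Colletidae, Megachilidae),
#' including one pooled Halictidae taxon standing for the *Lasioglossum*
#' (Dialictus) assemblage, plus 55 forb taxa (27 native prairie, 28
#' exotic/weedy) over seventeen plant families.  Deterministic: no RNG.
#'
#' @return a [taxon_registry()].
#' @export
synthetic_registry <- function() {
  bee <- do.call(rbind, lapply(names(BEE_FAMILIES), function(f) {
    n <- BEE_FAMILIES[[f]]
    data.frame(taxon = sprintf("bee_%s_%02d", f, seq_len(n)),
               role = "bee", family = f, origin = "not_applicable",
               pooled = FALSE)
  }))
  bee$taxon[1] <- "bee_Halictidae_pooled_Dialictus"
  bee$pooled[1] <- TRUE
  plant <- do.call(rbind, lapply(names(PLANT_FAMILIES), function(f) {
    n <- PLANT_FAMILIES[[f]]
    org <- rep(c("native_prairie", "exotic_weedy"), c(n[["P"]], n[["EW"]]))
    data.frame(taxon = sprintf("plant_%s_%02d", f, seq_along(org)),
               role = "plant", family = f, origin = org, pooled = FALSE)
  }))
  taxon_registry(rbind(bee, plant))
}

#' Define the ground truth of a synthetic scenario
#'
#' Fixes every parameter of the generative model so that downstream stages
#' can be tested for recovery of planted structure.  Bee log-baselines are
#' drawn lognormally so realized relative abundances straddle the 1%
#' common/uncommon boundary; the pooled taxon is the sum of several latent
#' species and dominates the community the way the Dialictus assemblage does.
#'
#' @param registry a [taxon_registry()], typically [synthetic_registry()].
#' @param n_sites,n_years design size (default 4 sites x 2 years; with 2
#'   treatments and 4 months this gives 64 sampling events).
#' @param treatment_effect additive effect of the strip treatment on the
#'   log mean bee count (default `log(1.6)`, a 1.6-fold abundance increase).
#' @param month_effects named additive log-scale effects for May/Jun/Jul/Aug
#'   (default peaks in July).
#' @param coupling bee x plant matrix of effect sizes (log-mean increase per
#'   unit proportional cover); default all zero.  Use [plant_couplings()] to
#'   plant links.
#' @param coupling_month optional single month name restricting the coupling
#'   to that month's samples (for phenology-recovery tests).
#' @param bee_base_meanlog,bee_base_sdlog lognormal parameters of per-species
#'   baseline abundance per event.
#' @param pooled_latent number of latent species summed into the pooled
#'   taxon.
#' @param pooled_meanlog log-baseline of each latent pooled component.
#' @param total_cover total blooming forb cover per event (proportion of
#'   ground area, all species summed).
#' @param plant_shape Dirichlet-like gamma shape heterogeneity (lognormal
#'   sd of per-species cover propensities).
#' @param commonness_target intended fraction of bee species above the 1%
#'   boundary (documentation of intent; realized fraction is stochastic).
#' @param visit_rate scale of expected visitation counts per positive
#'   coupling.
#' @param seed integer seed fixing the truth draw and all generated data.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(registry = synthetic_registry(),
                            n_sites = 4, n_years = 2,
                            treatment_effect = log(1.6),
                            month_effects = c(May = -0.3, Jun = 0,
                                              Jul = 0.4, Aug = 0.1),
                            coupling = NULL,
                            coupling_month = NULL,
                            bee_base_meanlog = -3.5,
                            bee_base_sdlog = 2.6,
                            pooled_latent = 6,
                            pooled_meanlog = 1.0,
                            total_cover = 0.5,
                            plant_shape = 1,
                            commonness_target = 0.1,
                            visit_rate = 40,
                            seed = 1) {
  if (n_sites < 1 || n_years < 1) stop("non-positive design dimensions")
  bees <- registry$taxon[registry$role == "bee"]
  plants <- registry$taxon[registry$role == "plant"]
  if (length(bees) < 2 || length(plants) < 2)
    stop("registry must contain at least 2 bee and 2 plant taxa")
  if (!setequal(names(month_effects), SURVEY_MONTHS))
    stop("month_effects must be named May/Jun/Jul/Aug")
  if (!is.null(coupling_month) && !coupling_month %in% SURVEY_MONTHS)
    stop("coupling_month must be one of ", paste(SURVEY_MONTHS, collapse = ", "))
  if (is.null(coupling)) {
    coupling <- matrix(0, length(bees), length(plants),
                       dimnames = list(bees, plants))
  } else {
    coupling <- as.matrix(coupling)
    if (!identical(dim(coupling), c(length(bees), length(plants))))
      stop("coupling must be a ", length(bees), " x ", length(plants),
           " bee-by-plant matrix")
    dimnames(coupling) <- list(bees, plants)
  }
  set.seed(as.integer(seed) %% 2147483647L)
  bee_base <- rnorm(length(bees), bee_base_meanlog, bee_base_sdlog)
  names(bee_base) <- bees
  pooled_id <- registry$taxon[registry$role == "bee" & registry$pooled]
  plant_concentration <- rlnorm(length(plants), 0, plant_shape)
  names(plant_concentration) <- plants
  structure(list(
    coupling = coupling, coupling_month = coupling_month,
    bee_base = bee_base, plant_concentration = plant_concentration,
    treatment_effect = treatment_effect,
    month_effects = month_effects[SURVEY_MONTHS],
    n_sites = as.integer(n_sites), n_years = as.integer(n_years),
    pooled_id = if (length(pooled_id)) pooled_id else NULL,
    pooled_latent = pooled_latent, pooled_meanlog = pooled_meanlog,
    total_cover = total_cover, plant_shape = plant_shape,
    commonness_target = commonness_target, visit_rate = visit_rate,
    seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' Plant couplings into a truth object
#'
#' Convenience constructor for the coupling matrix: sets `beta` for the given
#' bee/plant index pairs (recycled) and returns the matrix.
#'
#' @param registry a [taxon_registry()].
#' @param bees,plants taxon ids (or integer indices into the bee/plant lists).
#' @param beta effect size(s), log-mean increase per unit cover.
#' @return bee x plant coupling matrix.
#' @export
plant_couplings <- function(registry, bees, plants, beta) {
  bee_ids <- registry$taxon[registry$role == "bee"]
  plant_ids <- registry$taxon[registry$role == "plant"]
  if (is.numeric(bees)) bees <- bee_ids[bees]
  if (is.numeric(plants)) plants <- plant_ids[plants]
  m <- matrix(0, length(bee_ids), length(plant_ids),
              dimnames = list(bee_ids, plant_ids))
  idx <- cbind(match(bees, bee_ids), match(plants, plant_ids))
  if (anyNA(idx)) stop("unknown bee or plant taxon in coupling definition")
  m[idx] <- beta
  m
}

#' Construct a truth with controlled planted couplings
#'
#' Builds a [synthetic_truth()] in which `n_pairs` distinct bee-plant pairs
#' are coupled at effect size `beta`, and the planted bees and plants are
#' given fixed baseline abundance and cover propensity so the per-pair
#' detection power is a controlled quantity rather than a draw.  Planted
#' bees are taken across families (skipping the pooled taxon); planted
#' plants alternate native and exotic taxa across families.
#'
#' @param seed integer seed.
#' @param n_pairs number of coupled pairs.
#' @param beta coupling effect size (log-mean increase per unit cover).
#' @param coupling_month optional month restricting the coupling.
#' @param base log-baseline abundance given to the planted bees.
#' @param concentration cover propensity given to the planted plants (the
#'   remaining plants keep their lognormal draws around 1).
#' @param registry a [taxon_registry()].
#' @param ... further arguments passed to [synthetic_truth()].
#' @return a `synthetic_truth` whose `coupling` has `n_pairs` planted links.
#' @export
planted_scenario <- function(seed, n_pairs = 8, beta = 30,
                             coupling_month = NULL, base = 0.5,
                             concentration = 8,
                             registry = synthetic_registry(), ...) {
  bee_ids <- registry$taxon[registry$role == "bee" & !registry$pooled]
  plant_ids <- registry$taxon[registry$role == "plant"]
  if (n_pairs > min(length(bee_ids), length(plant_ids)))
    stop("n_pairs exceeds available taxa")
  # spread planted taxa across families deterministically
  bees <- bee_ids[round(seq(1, length(bee_ids), length.out = n_pairs))]
  plants <- plant_ids[round(seq(1, length(plant_ids), length.out = n_pairs))]
  coupling <- plant_couplings(registry, bees, plants, beta)
  truth <- synthetic_truth(registry = registry, coupling = coupling,
                           coupling_month = coupling_month, seed = seed, ...)
  truth$bee_base[bees] <- base
  truth$plant_concentration[plants] <- concentration
  truth$planted <- data.frame(bee = bees, plant = plants, beta = beta)
  truth
}

#' Generate a full synthetic dataset
#'
#' Draws plant cover per strip sampling event from a Dirichlet-like scheme
#' (gamma propensities normalized and scaled to `total_cover`), then bee
#' counts per event as Poisson with
#' `log mean = base_b + treatment_effect * strip + month_effect + sum_p
#' beta_bp * cover_p` (the cover term acting in strip fields, and only in
#' `coupling_month` when one is set).  The pooled taxon is the sum of several
#' latent Poisson species.  Visitation counts are Poisson with mean
#' `visit_rate * max(beta, 0) * mean cover`, i.e. consistent with the planted
#' couplings.  Fully deterministic given `truth$seed`.
#'
#' @param truth a [synthetic_truth()].
#' @param registry the matching [taxon_registry()].
#' @return list with class `prairie_sim`: `bees` and `plants`
#'   ([survey_table()]s), `visits` ([visitation_matrix()]), `truth`.
#' @export
generate_dataset <- function(truth, registry = synthetic_registry()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  bees <- names(truth$bee_base)
  plants <- names(truth$plant_concentration)
  set.seed(truth$seed %% 2147483647L + 1L)
  events <- expand.grid(site = sprintf("site%d", seq_len(truth$n_sites)),
                        treatment = TREATMENTS,
                        year = 2016L + seq_len(truth$n_years) - 1L,
                        month = SURVEY_MONTHS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  strip_ev <- which(events$treatment == "strip")
  # plant cover: strip events only
  cover <- matrix(0, nrow(events), length(plants),
                  dimnames = list(NULL, plants))
  for (i in strip_ev) {
    g <- rgamma(length(plants), shape = truth$plant_concentration)
    cover[i, ] <- g / sum(g) * truth$total_cover
  }
  # bee counts
  latent <- NULL
  counts <- matrix(0L, nrow(events), length(bees),
                   dimnames = list(NULL, bees))
  me <- truth$month_effects[events$month]
  te <- truth$treatment_effect * (events$treatment == "strip")
  couple_on <- if (is.null(truth$coupling_month)) rep(TRUE, nrow(events))
               else events$month == truth$coupling_month
  for (b in seq_along(bees)) {
    cterm <- as.numeric(cover %*% truth$coupling[b, ]) * couple_on
    if (!is.null(truth$pooled_id) && bees[b] == truth$pooled_id) {
      lam <- exp(outer(truth$pooled_meanlog +
                         rnorm(truth$pooled_latent, 0, 0.5), me + te + cterm, "+"))
      counts[, b] <- as.integer(colSums(matrix(rpois(length(lam), lam),
                                               nrow = truth$pooled_latent)))
    } else {
      lam <- exp(truth$bee_base[b] + me + te + cterm)
      counts[, b] <- rpois(nrow(events), lam)
    }
  }
  bee_long <- data.frame(events[rep(seq_len(nrow(events)), length(bees)), ],
                         taxon = rep(bees, each = nrow(events)),
                         value = as.numeric(counts), row.names = NULL)
  bee_long <- bee_long[bee_long$value > 0, , drop = FALSE]
  plant_long <- data.frame(events[rep(strip_ev, length(plants)), ],
                           taxon = rep(plants, each = length(strip_ev)),
                           value = as.numeric(cover[strip_ev, ]),
                           row.names = NULL)
  plant_long <- plant_long[plant_long$value > 0, , drop = FALSE]
  mean_cover <- colMeans(cover[strip_ev, , drop = FALSE])
  lam_v <- truth$visit_rate * pmax(truth$coupling, 0) *
    matrix(mean_cover, length(bees), length(plants), byrow = TRUE)
  visits <- matrix(rpois(length(lam_v), lam_v), length(bees), length(plants),
                   dimnames = list(bees, plants))
  structure(list(bees = survey_table(bee_long, registry),
                 plants = survey_table(plant_long, registry),
                 visits = visitation_matrix(visits, registry),
                 truth = truth),
            class = "prairie_sim")
}

#' @export
print.prairie_sim <- function(x, ...) {
  cat("Synthetic prairie-strip survey (seed ", x$truth$seed, ")\n", sep = "")
  cat("  design: ", x$truth$n_sites, " sites x 2 treatments x ",
      x$truth$n_years, " years x 4 months\n", sep = "")
  cat("  bees:   ", sum(x$bees$value), " individuals, ",
      length(unique(x$bees$taxon)), " taxa\n", sep = "")
  cat("  plants: ", length(unique(x$plants$taxon)), " taxa surveyed\n",
      sep = "")
  cat("  planted couplings: ", sum(x$truth$coupling != 0), "\n", sep = "")
  invisible(x)
}

#' Generate synthetic land-cover profiles
#'
#' Each field receives a profile of land-cover category proportions within a
#' 3-km radius: two crop categories (corn, soybean) and `n_categories - 2`
#' non-crop categories.  The realized non-crop proportion is uniform over
#' `noncrop_range` (the study landscapes spanned 8-69% non-crop area); within
#' the crop and non-crop blocks, proportions follow a Dirichlet-like split.
#'
#' @param n_fields number of fields.
#' @param noncrop_range length-2 numeric, `0 <= low <= high <= 1`.
#' @param n_categories total number of categories (>= 2).
#' @param seed integer seed.
#' @return a [land_cover()] table covering all fields.
#' @export
generate_landcover <- function(n_fields, noncrop_range = c(0.08, 0.69),
                               n_categories = 8, seed = 1) {
  if (length(noncrop_range) != 2 || noncrop_range[1] > noncrop_range[2] ||
      noncrop_range[1] < 0 || noncrop_range[2] > 1)
    stop("noncrop_range must be (low, high) with 0 <= low <= high <= 1")
  if (n_categories < 2) stop("need at least 2 categories")
  set.seed(as.integer(seed) %% 2147483647L)
  n_crop <- 2L
  n_nc <- n_categories - n_crop
  crop_names <- c("corn", "soybean")
  nc_names <- c("grassland", "forest", "wetland", "developed", "pasture",
                "alfalfa", "water", "barren", "shrubland", "fallow")
  nc_names <- rep_len(nc_names, n_nc)
  nc_names <- make.unique(nc_names, sep = "_")
  out <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    nc_total <- runif(1, noncrop_range[1], noncrop_range[2])
    g_nc <- rgamma(n_nc, shape = 1)
    g_cr <- rgamma(n_crop, shape = 4)
    p_nc <- if (n_nc > 0) g_nc / sum(g_nc) * nc_total else numeric(0)
    p_cr <- g_cr / sum(g_cr) * (1 - nc_total)
    # force exact unit sum against accumulated rounding
    p_cr[1] <- 1 - sum(p_nc) - sum(p_cr[-1])
    out[[i]] <- data.frame(field = sprintf("field%02d", i),
                           category = c(crop_names, nc_names),
                           proportion = c(p_cr, p_nc),
                           noncrop = rep(c(FALSE, TRUE), c(n_crop, n_nc)))
  }
  land_cover(do.call(rbind, out))
}
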