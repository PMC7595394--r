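## Pipeline orchestration: simulate (or read) -> diversity -> community
## comparison -> co-occurrence network, as one reproducible, seeded run
## writing every stage artifact plus a machine-readable report.

#' Assemble a pipeline run configuration
#'
#' Either `inputs` (paths to existing CSV artifacts) or `truth` (a
#' [synthetic_truth()] to simulate from) must be supplied.  One master seed
#' determines every stochastic stage: per-stage seeds are derived from it by
#' a fixed stage-name hashing scheme, so stages rerun standalone reproduce
#' the pipeline exactly.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed.
#' @param truth optional [synthetic_truth()] for a simulated run.
#' @param inputs optional named list of paths: `bees`, `plants`, `registry`,
#'   `visits` (optional), `landcover` (optional).
#' @param alpha link-selection level.
#' @param threshold commonness boundary.
#' @param n_perm MRPP permutations.
#' @param n_boot rarefaction bootstrap resamples.
#' @param n_fields number of land-cover profiles to simulate (simulated runs).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, truth = NULL, inputs = NULL,
                       alpha = 0.05, threshold = 0.01,
                       n_perm = 999, n_boot = 100, n_fields = 8) {
  if (is.null(truth) && is.null(inputs))
    stop("provide either a synthetic truth or input paths")
  structure(list(out_dir = out_dir, seed = as.integer(seed), truth = truth,
                 inputs = inputs, alpha = alpha, threshold = threshold,
                 n_perm = n_perm, n_boot = n_boot, n_fields = n_fields),
            class = "run_config")
}

#' Validate pipeline inputs without running any analysis
#'
#' Runs every structural invariant check from the data model on the
#' configured inputs and reports all violations; nothing is analyzed.
#'
#' @param config a [run_config()] with `inputs` set (simulated runs have
#'   nothing to validate and return an empty report).
#' @return data frame `stage, message`, zero rows when clean.
#' @export
validate_inputs <- function(config) {
  violations <- data.frame(stage = character(), message = character())
  add <- function(stage, e) rbind(violations,
                                  data.frame(stage = stage,
                                             message = conditionMessage(e)))
  if (is.null(config$inputs)) return(violations)
  ins <- config$inputs
  registry <- tryCatch(read_registry(ins$registry), error = function(e) e)
  if (inherits(registry, "error"))
    return(add("registry", registry))
  for (tab in c("bees", "plants")) {
    if (is.null(ins[[tab]])) next
    res <- tryCatch(read_survey(ins[[tab]], registry), error = function(e) e)
    if (inherits(res, "error")) violations <- add(tab, res)
  }
  if (!is.null(ins$visits)) {
    res <- tryCatch(read_visitation(ins$visits, registry),
                    error = function(e) e)
    if (inherits(res, "error")) violations <- add("visits", res)
  }
  if (!is.null(ins$landcover)) {
    res <- tryCatch(read_landcover(ins$landcover), error = function(e) e)
    if (inherits(res, "error")) violations <- add("landcover", res)
  }
  violations
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> diversity -> community comparison ->
#' co-occurrence network, writes every stage artifact into `out_dir`
#' (survey CSVs, `curves.csv`, `cooccurrence.csv`, `family_proportions.csv`,
#' `origin_ratios.csv`, `monthly_edges.csv`, `landcover.csv`, `config.json`,
#' `report.json`) and returns the report.  Deterministic under a fixed
#' master seed.
#'
#' @param config a [run_config()].
#' @return the report, invisibly (also serialized as `report.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  ## stage: data
  if (!is.null(config$truth)) {
    sim <- generate_dataset(config$truth)
    registry <- synthetic_registry()
    bees <- sim$bees; plants <- sim$plants; visits <- sim$visits
    lc <- generate_landcover(config$n_fields,
                             seed = derive_seed(config$seed, "landcover"))
    write_survey(bees, out("bees.csv"))
    write_survey(plants, out("plants.csv"))
    write_registry(registry, out("registry.csv"))
    write_visitation(visits, out("visits.csv"))
    write_landcover(lc, out("landcover.csv"))
    utils::write.csv(data.frame(bee = rownames(sim$truth$coupling),
                                sim$truth$coupling, check.names = FALSE),
                     out("truth_coupling.csv"), row.names = FALSE)
  } else {
    bad <- validate_inputs(config)
    if (nrow(bad))
      stop("input validation failed at stage '", bad$stage[1], "': ",
           bad$message[1])
    registry <- read_registry(config$inputs$registry)
    bees <- read_survey(config$inputs$bees, registry)
    plants <- read_survey(config$inputs$plants, registry)
    visits <- if (!is.null(config$inputs$visits))
      read_visitation(config$inputs$visits, registry) else NULL
    lc <- if (!is.null(config$inputs$landcover))
      read_landcover(config$inputs$landcover) else NULL
  }

  ## stage: diversity (rarefaction per treatment, q = 0, 1, 2)
  div_seed <- derive_seed(config$seed, "diversity")
  curves <- list()
  for (tr in intersect(TREATMENTS, unique(bees$treatment))) {
    cts <- tapply(bees$value[bees$treatment == tr],
                  bees$taxon[bees$treatment == tr], sum)
    for (q in 0:2) {
      cv <- rarefaction_curve(as.integer(cts), q, n_boot = config$n_boot,
                              seed = div_seed)
      curves[[paste(tr, q)]] <- data.frame(group = tr, as.data.frame(cv))
    }
  }
  curves <- do.call(rbind, curves)
  rownames(curves) <- NULL
  cw <- curves
  for (col in c("estimate", "lo95", "hi95")) cw[[col]] <- num_chr(cw[[col]])
  write.csv(cw, out("curves.csv"), row.names = FALSE, quote = FALSE)

  ## stage: community comparison per partition
  part8 <- classify_commonness(bees, registry, config$threshold,
                               "exclude_pooled")
  part9 <- classify_commonness(bees, registry, config$threshold,
                               "include_pooled")
  taxa_sets <- list(
    all = unique(bees$taxon),
    common8 = part8$taxon[part8$class == "common"],
    common9 = part9$taxon[part9$class == "common"],
    uncommon = part9$taxon[part9$class == "uncommon"])
  mrpp_seed <- derive_seed(config$seed, "mrpp")
  comparison <- list()
  for (nm in names(taxa_sets)) {
    taxa <- taxa_sets[[nm]]
    res <- tryCatch({
      sub_tab <- bees[bees$taxon %in% taxa & bees$value > 0, , drop = FALSE]
      d <- bray_curtis_matrix(sub_tab, taxa = taxa)
      grp <- sub("\\|.*$", "",
                 sub("^[^|]*\\|", "", attr(d, "Labels")))  # treatment field
      mr <- mrpp(d, grp, n_perm = config$n_perm, seed = mrpp_seed)
      dp <- multivariate_dispersion(d, grp)
      list(T = mr$T, A = mr$A, p = mr$p,
           F = dp$F, p_disp = dp$p,
           group_mean_dispersion = as.list(dp$means))
    }, error = function(e) list(error = conditionMessage(e)))
    comparison[[nm]] <- res
  }

  ## stage: co-occurrence network
  net <- build_cooccurrence(bees, plants, registry)
  net <- select_links(net, alpha = config$alpha, use_adjusted = FALSE)
  long <- data.frame(bee = rownames(net$r)[row(net$r)],
                     plant = colnames(net$r)[col(net$r)],
                     r = as.numeric(net$r), p = as.numeric(net$p),
                     p_adj = as.numeric(net$p_adj),
                     n = as.integer(net$n),
                     significant = as.logical(net$sig))
  long <- long[order(long$bee, long$plant), ]
  for (col in c("r", "p", "p_adj"))
    long[[col]] <- ifelse(is.na(long[[col]]), "NA", num_chr(long[[col]]))
  write.csv(long, out("cooccurrence.csv"), row.names = FALSE, quote = FALSE)

  fp <- suppressWarnings(family_proportions(net, registry))
  fp_df <- data.frame(plant_family = rownames(fp$prop),
                      round(fp$prop, 6), Total = round(fp$row_totals, 6),
                      check.names = FALSE)
  write.csv(fp_df, out("family_proportions.csv"), row.names = FALSE,
            quote = FALSE)
  ratios <- origin_ratios(net, registry, part9)
  write.csv(ratios, out("origin_ratios.csv"), row.names = FALSE,
            quote = FALSE)
  edges <- suppressWarnings(monthly_networks(bees, plants, registry,
                                             alpha = config$alpha))
  write.csv(edges, out("monthly_edges.csv"), row.names = FALSE, quote = FALSE)
  validation <- if (!is.null(visits))
    tryCatch(suppressWarnings(validate_vs_visitation(net, visits)),
             error = function(e) list(r = NA, p = NA,
                                      error = conditionMessage(e)))
  else NULL

  ## stage: landscape
  landscape <- if (!is.null(lc)) landcover_summary(lc) else NULL
  if (!is.null(landscape))
    write.csv(landscape, out("landscape_summary.csv"), row.names = FALSE,
              quote = FALSE)

  report <- list(
    seed = config$seed,
    alpha = config$alpha,
    n_common_8 = sum(part8$class == "common"),
    n_common_9 = sum(part9$class == "common"),
    n_uncommon = sum(part9$class == "uncommon"),
    comparison = comparison,
    network = list(n_defined = sum(net$defined),
                   n_selected = sum(net$sig),
                   n_events = length(net$events)),
    validation = validation,
    monthly_edges = nrow(edges),
    landscape = if (!is.null(landscape))
      list(H_mean = mean(landscape$H),
           noncrop_min = min(landscape$noncrop),
           noncrop_max = max(landscape$noncrop)) else NULL)
  cfg <- config
  cfg$truth <- if (!is.null(cfg$truth))
    cfg$truth[c("n_sites", "n_years", "seed", "treatment_effect",
                "total_cover", "visit_rate")] else NULL
  jsonlite::write_json(unclass(cfg), out("config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}
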