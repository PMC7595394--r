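## Correlation-based bee-plant co-occurrence network.
##
## For every bee x plant pair, the bee's abundance series and the plant's
## proportional-cover series are aligned on shared (site, month, year)
## sampling events in strip fields (absences as zeros) and screened by
## pairwise Pearson correlation.  Links are selected by r > 0 and p < alpha;
## Benjamini-Hochberg adjusted p-values are carried alongside.  Derived
## outputs: validation against the observed visitation network, the
## plant-family x bee-family proportion table, native/exotic affinity
## ratios, and monthly bipartite edge lists.

#' Pearson correlation with a two-sided t-test p-value
#'
#' Sample Pearson r with `p` from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom, two-sided.  `|r| = 1` reports the limiting
#' `p = 0`.  Constant series or `n < 3` yield an undefined-flag result
#' (`r = NA`), not an error: such cells are recorded and never significant.
#'
#' @param x,y numeric vectors of equal length.
#' @return list `(r, p, n, defined)`.
#' @examples
#' pearson_r_p(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8, p ~ 0.2
#' @export
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  r <- cor(x, y)
  p <- r_to_p(r, n)
  list(r = r, p = p, n = n, defined = TRUE)
}

r_to_p <- function(r, n) {
  r2 <- pmin(r^2, 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r2, 0))
  p <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  p
}

#' Build the bee-plant co-occurrence network
#'
#' Aligns every bee abundance series against every plant cover series over
#' the union of (by default) strip-field (site, month, year) sampling events
#' present in either table, with absences entered as zeros, and computes
#' pairwise Pearson correlations.  Cells with fewer than 3 events or a
#' constant series are flagged undefined.
#'
#' @param bees bee [survey_table()] (counts per event).
#' @param plants plant [survey_table()] (proportional cover per event).
#' @param registry [taxon_registry()] fixing the bee and plant taxon sets
#'   (taxa never observed give undefined cells).
#' @param pairing key columns identifying a sampling event.
#' @param treatment which treatment's records enter (default `"strip"`,
#'   where the plant community exists; `NULL` keeps all).
#' @return object of class `cooccurrence`: matrices `r`, `p`, `n`,
#'   `defined`; `events` (the pairing keys used); `pairing`; after
#'   [select_links()] also `p_adj`, `sig`, `alpha`, `use_adjusted`.
#' @export
build_cooccurrence <- function(bees, plants, registry,
                               pairing = c("site", "month", "year"),
                               treatment = "strip") {
  if (!is.null(treatment)) {
    bees <- bees[bees$treatment %in% treatment, , drop = FALSE]
    plants <- plants[plants$treatment %in% treatment, , drop = FALSE]
  }
  bee_ids <- registry$taxon[registry$role == "bee"]
  plant_ids <- registry$taxon[registry$role == "plant"]
  key_of <- function(df) do.call(paste, c(lapply(pairing, function(k)
    as.character(df[[k]])), sep = "|"))
  events <- sort(unique(c(key_of(bees), key_of(plants))))
  if (length(events) < 3)
    stop("bee and plant tables share fewer than 3 pairing keys (",
         length(events), ")")
  series <- function(df, ids) {
    k <- key_of(df)
    keep <- df$taxon %in% ids
    tab <- xtabs(value ~ e + t,
                 data = data.frame(value = df$value[keep],
                                   e = factor(k[keep], levels = events),
                                   t = factor(df$taxon[keep], levels = ids)))
    matrix(as.numeric(tab), length(events), length(ids),
           dimnames = list(events, ids))
  }
  bm <- series(bees, bee_ids)
  pm <- series(plants, plant_ids)
  n <- length(events)
  const_b <- apply(bm, 2, sd) == 0
  const_p <- apply(pm, 2, sd) == 0
  r <- suppressWarnings(cor(bm, pm))
  r[const_b, ] <- NA
  r[, const_p] <- NA
  defined <- !is.na(r)
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  p[defined] <- r_to_p(r[defined], n)
  nmat <- matrix(n, nrow(r), ncol(r), dimnames = dimnames(r))
  structure(list(r = r, p = p, n = nmat, defined = defined,
                 events = events, pairing = pairing,
                 p_adj = NULL, sig = NULL, alpha = NULL,
                 use_adjusted = NULL),
            class = "cooccurrence")
}

#' Benjamini-Hochberg step-up adjustment of a p-value matrix
#'
#' Standard BH false-discovery-rate adjustment applied to the defined cells
#' of a p-value matrix (undefined cells stay `NA` and do not enter `m`).
#'
#' @param p numeric matrix (or vector) of p-values, `NA` for undefined.
#' @return matrix of adjusted p-values, `p_adj >= p`, capped at 1.
#' @export
bh_adjust <- function(p) {
  out <- p
  idx <- which(!is.na(p))
  out[idx] <- p.adjust(p[idx], method = "BH")
  out
}

#' Select significant positive links
#'
#' Applies the selection rule `r > 0` and `p < alpha` (strict inequalities)
#' using either the raw or the BH-adjusted p-values; undefined cells are
#' never selected.  The unadjusted network is the default working network;
#' the adjusted variant is kept for sensitivity analysis.
#'
#' @param net a [build_cooccurrence()] network.
#' @param alpha significance level (default 0.05).
#' @param use_adjusted select on BH-adjusted p-values instead of raw.
#' @return the network with `sig` (logical mask), `p_adj`, `alpha`,
#'   `use_adjusted` filled in.
#' @export
select_links <- function(net, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(inherits(net, "cooccurrence"))
  net$p_adj <- bh_adjust(net$p)
  pm <- if (use_adjusted) net$p_adj else net$p
  sig <- net$defined & !is.na(net$r) & net$r > 0 & !is.na(pm) & pm < alpha
  sig[!net$defined] <- FALSE
  net$sig <- sig
  net$alpha <- alpha
  net$use_adjusted <- use_adjusted
  net
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat("Bee-plant co-occurrence network\n")
  cat("  ", nrow(x$r), " bee taxa x ", ncol(x$r), " plant taxa over ",
      length(x$events), " sampling events (", paste(x$pairing, collapse = ","),
      ")\n", sep = "")
  cat("  defined cells: ", sum(x$defined), " / ", length(x$defined), "\n",
      sep = "")
  if (!is.null(x$sig))
    cat("  selected links (r > 0, ",
        if (x$use_adjusted) "BH-adjusted " else "", "p < ", x$alpha, "): ",
        sum(x$sig), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cooccurrence <- function(object, ...) {
  def <- object$r[object$defined]
  out <- list(n_bees = nrow(object$r), n_plants = ncol(object$r),
              n_events = length(object$events),
              n_defined = sum(object$defined),
              r_range = if (length(def)) range(def) else c(NA, NA),
              n_selected = if (is.null(object$sig)) NA_integer_
                           else sum(object$sig),
              alpha = object$alpha, use_adjusted = object$use_adjusted)
  class(out) <- "summary.cooccurrence"
  out
}

#' @export
print.summary.cooccurrence <- function(x, ...) {
  cat("Co-occurrence network: ", x$n_bees, " bees x ", x$n_plants,
      " plants, ", x$n_events, " events\n", sep = "")
  cat("  defined ", x$n_defined, " cells; r in [",
      sprintf("%.3f", x$r_range[1]), ", ", sprintf("%.3f", x$r_range[2]),
      "]\n", sep = "")
  if (!is.na(x$n_selected))
    cat("  selected links: ", x$n_selected, " at alpha = ", x$alpha, "\n",
        sep = "")
  invisible(x)
}

#' @export
plot.cooccurrence <- function(x, ...) {
  z <- x$r
  z[!x$defined] <- NA
  image(t(z)[, rev(seq_len(nrow(z))), drop = FALSE], axes = FALSE,
        col = grDevices::hcl.colors(31, "Blue-Red 3", rev = TRUE),
        zlim = c(-1, 1), xlab = "plants", ylab = "bees",
        main = "Pairwise bee-plant Pearson r")
  invisible(x)
}

#' Validate the co-occurrence network against observed visitation
#'
#' Pearson correlation between the flattened network and the flattened
#' observed bee-plant visitation matrix over cells where the network is
#' defined.  `mode = "r"` correlates the raw correlation coefficients with
#' visitation counts; `mode = "mask"` uses the binary significance mask
#' instead (requires [select_links()] first).
#'
#' @param net a [build_cooccurrence()] network.
#' @param visits a [visitation_matrix()] with matching labels.
#' @param mode `"r"` (default) or `"mask"`.
#' @return list `(r, p, n_cells)`; `r = NA` with a warning when the
#'   visitation vector is constant over the defined cells.
#' @export
validate_vs_visitation <- function(net, visits, mode = c("r", "mask")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "cooccurrence"))
  if (!setequal(rownames(net$r), rownames(visits)) ||
      !setequal(colnames(net$r), colnames(visits)))
    stop("network and visitation matrix labels do not match")
  v <- unclass(visits)[rownames(net$r), colnames(net$r)]
  idx <- which(net$defined)
  if (length(idx) < 3) stop("fewer than 3 defined cells")
  x <- if (mode == "r") net$r[idx] else {
    if (is.null(net$sig)) stop("mode='mask' requires select_links() first")
    as.numeric(net$sig[idx])
  }
  y <- as.numeric(v[idx])
  if (sd(y) == 0 || sd(x) == 0) {
    warning("constant vector over defined cells; validation undefined")
    return(list(r = NA_real_, p = NA_real_, n_cells = length(idx)))
  }
  res <- pearson_r_p(x, y)
  list(r = res$r, p = res$p, n_cells = res$n)
}

#' Plant-family by bee-family proportions of selected links
#'
#' Distributes the selected positive links over plant-family x bee-family
#' cells as proportions of the total number of selected links, with row and
#' column totals.  Totals are computed from unrounded proportions; round
#' last when printing.
#'
#' @param net a network after [select_links()].
#' @param registry [taxon_registry()] supplying the family of each taxon.
#' @return object of class `family_proportions`: `prop` (plant rows x bee
#'   columns), `row_totals`, `col_totals`, `counts`, `n_links`.
#' @export
family_proportions <- function(net, registry) {
  stopifnot(inherits(net, "cooccurrence"))
  if (is.null(net$sig)) stop("run select_links() first")
  bee_fam <- setNames(registry$family, registry$taxon)[rownames(net$sig)]
  plant_fam <- setNames(registry$family, registry$taxon)[colnames(net$sig)]
  idx <- which(net$sig, arr.ind = TRUE)
  pf_levels <- unique(registry$family[registry$role == "plant"])
  bf_levels <- unique(registry$family[registry$role == "bee"])
  counts <- table(factor(plant_fam[idx[, 2]], levels = pf_levels),
                  factor(bee_fam[idx[, 1]], levels = bf_levels))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  n_links <- sum(counts)
  if (n_links == 0) {
    warning("no selected links; proportion table is empty")
    prop <- counts * 0
  } else prop <- counts / n_links
  structure(list(prop = prop, counts = counts,
                 row_totals = rowSums(prop), col_totals = colSums(prop),
                 n_links = n_links),
            class = "family_proportions")
}

#' @export
print.family_proportions <- function(x, digits = 3, ...) {
  cat("Proportion of selected positive links by plant family (rows) and",
      "bee family (columns);", x$n_links, "links total\n")
  m <- cbind(x$prop, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, sum(x$prop)))
  print(round(m, digits))
  invisible(x)
}

#' Native-to-exotic affinity ratio for a bee group
#'
#' Number of selected links from the group's bee taxa to native prairie
#' plants divided by the number to exotic/weedy plants.  Ratios above 1
#' indicate greater affinity with native prairie vegetation, below 1 with
#' exotic/weedy vegetation.  A zero denominator with a positive numerator
#' gives `Inf`; zero links in both classes give `NaN` (undefined).
#'
#' @param net a network after [select_links()].
#' @param registry [taxon_registry()].
#' @param bee_group a bee family name, or `"common"`/`"uncommon"` (which
#'   require `partition`).
#' @param partition a [classify_commonness()] result, needed for the
#'   abundance-class groups.
#' @return list `(group, ratio, n_native, n_exotic)`.
#' @export
origin_ratio <- function(net, registry, bee_group, partition = NULL) {
  stopifnot(inherits(net, "cooccurrence"))
  if (is.null(net$sig)) stop("run select_links() first")
  bee_fams <- unique(registry$family[registry$role == "bee"])
  if (bee_group %in% c("common", "uncommon")) {
    if (is.null(partition))
      stop("bee_group '", bee_group, "' requires a commonness partition")
    members <- partition$taxon[partition$class == bee_group]
  } else if (bee_group %in% bee_fams) {
    members <- registry$taxon[registry$role == "bee" &
                                registry$family == bee_group]
  } else stop("unknown bee group: '", bee_group, "'")
  if (!length(members)) stop("bee group '", bee_group, "' is empty")
  rows <- rownames(net$sig) %in% members
  origin <- setNames(registry$origin, registry$taxon)[colnames(net$sig)]
  n_native <- sum(net$sig[rows, origin == "native_prairie", drop = FALSE])
  n_exotic <- sum(net$sig[rows, origin == "exotic_weedy", drop = FALSE])
  ratio <- if (n_native == 0 && n_exotic == 0) NaN else n_native / n_exotic
  list(group = bee_group, ratio = ratio,
       n_native = n_native, n_exotic = n_exotic)
}

#' Affinity ratios for the standard bee groups
#'
#' @param net a network after [select_links()].
#' @param registry [taxon_registry()].
#' @param partition a [classify_commonness()] result.
#' @return data frame `group, ratio, n_native, n_exotic` over the five bee
#'   families plus the common and uncommon classes.
#' @export
origin_ratios <- function(net, registry, partition) {
  groups <- c(unique(registry$family[registry$role == "bee"]),
              "common", "uncommon")
  do.call(rbind, lapply(groups, function(g) {
    as.data.frame(origin_ratio(net, registry, g, partition))
  }))
}

#' Monthly bipartite co-occurrence edge lists
#'
#' Rebuilds the co-occurrence network separately for each survey month
#' (pairing on site x year within the month), selects links with unadjusted
#' `r > 0, p < alpha`, and aggregates the selected species-level links into
#' plant-family x bee-family edge weights.  Months with fewer than 3
#' sampling events are skipped with a warning.
#'
#' @param bees,plants [survey_table()]s.
#' @param registry [taxon_registry()].
#' @param alpha selection level (default 0.05).
#' @return data frame of class `bipartite_edges` with columns
#'   `month, plant_family, bee_family, weight` (positive integer counts of
#'   selected species-level links).
#' @export
monthly_networks <- function(bees, plants, registry, alpha = 0.05) {
  out <- list()
  for (m in SURVEY_MONTHS) {
    b <- bees[bees$month == m, , drop = FALSE]
    p <- plants[plants$month == m, , drop = FALSE]
    net <- tryCatch(
      build_cooccurrence(b, p, registry, pairing = c("site", "year")),
      error = function(e) e)
    if (inherits(net, "error")) {
      warning("month ", m, " skipped: ", conditionMessage(net))
      next
    }
    net <- select_links(net, alpha = alpha, use_adjusted = FALSE)
    fp <- suppressWarnings(family_proportions(net, registry))
    idx <- which(fp$counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    out[[m]] <- data.frame(month = m,
                           plant_family = rownames(fp$counts)[idx[, 1]],
                           bee_family = colnames(fp$counts)[idx[, 2]],
                           weight = fp$counts[idx])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(month = character(), plant_family = character(),
               bee_family = character(), weight = integer())
  rownames(res) <- NULL
  res$month <- factor(res$month, levels = SURVEY_MONTHS, ordered = TRUE)
  class(res) <- c("bipartite_edges", "data.frame")
  res
}
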