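## Data model, validation and plain-CSV readers/writers shared by every stage.
##
## Long (tidy) format is canonical: one row per (site, treatment, year, month,
## taxon) with a value that is a bee count or a plant proportional cover.
## Wide matrices are always derived views.  Missing combinations are implicit
## zeros (trap and quadrat surveys record absences implicitly).

SURVEY_COLS <- c("site", "treatment", "year", "month", "taxon", "value")
TREATMENTS <- c("strip", "control")

#' Construct and validate a taxon registry
#'
#' The registry carries per-taxon metadata used throughout the pipeline: the
#' role (bee or plant), the family, the plant origin class (native prairie vs
#' exotic/weedy), and a flag marking the single pooled taxon (the
#' taxonomically intractable *Lasioglossum* subgenus *Dialictus*, treated as
#' one taxon).
#'
#' @param df data frame with columns `taxon`, `role`, `family`, `origin`,
#'   `pooled`.  `role` is `"bee"` or `"plant"`; `origin` must be
#'   `"not_applicable"` for bees and `"native_prairie"` or `"exotic_weedy"`
#'   for plants; `pooled` is logical and may be `TRUE` for at most one taxon.
#' @return the validated data frame with class `taxon_registry`.
#' @export
taxon_registry <- function(df) {
  need <- c("taxon", "role", "family", "origin", "pooled")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$taxon <- as.character(df$taxon)
  df$pooled <- as.logical(df$pooled)
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon id(s) in registry: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  if (!all(df$role %in% c("bee", "plant")))
    stop("registry role must be 'bee' or 'plant'")
  bad_bee <- df$role == "bee" & df$origin != "not_applicable"
  bad_plant <- df$role == "plant" &
    !df$origin %in% c("native_prairie", "exotic_weedy")
  if (any(bad_bee))
    stop("bee taxa must have origin 'not_applicable': ",
         paste(df$taxon[bad_bee], collapse = ", "))
  if (any(bad_plant))
    stop("plant taxa must have origin 'native_prairie' or 'exotic_weedy': ",
         paste(df$taxon[bad_plant], collapse = ", "))
  if (sum(df$pooled, na.rm = TRUE) > 1L)
    stop("at most one pooled taxon is allowed")
  class(df) <- c("taxon_registry", "data.frame")
  df
}

#' Construct and validate a long-format survey table
#'
#' A survey table holds either bee abundance counts per sampling event
#' (60-m transect, all trap types pooled) or plant proportional cover per
#' species (pre-averaged over the ten 1-m^2 quadrats).  Validation is total:
#' any invariant breach is rejected with a located error, never repaired.
#'
#' @param df data frame with columns `site`, `treatment`, `year`, `month`,
#'   `taxon`, `value`.
#' @param registry a [taxon_registry()]; every `taxon` must resolve in it.
#'   Bee values must be non-negative integers; plant values must lie in
#'   \[0, 1\].
#' @return the validated table, months as an ordered factor
#'   (May < Jun < Jul < Aug), with class `survey_table`.
#' @export
survey_table <- function(df, registry) {
  miss <- setdiff(SURVEY_COLS, names(df))
  if (length(miss))
    stop("survey table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[SURVEY_COLS]
  df$site <- as.character(df$site)
  df$taxon <- as.character(df$taxon)
  df$treatment <- as.character(df$treatment)
  row_id <- function(i) paste0("row ", i)
  bad <- which(!df$treatment %in% TREATMENTS)
  if (length(bad))
    stop("invalid treatment at ", row_id(bad[1]), ": '", df$treatment[bad[1]],
         "' (must be one of ", paste(TREATMENTS, collapse = ", "), ")")
  bad <- which(!df$month %in% SURVEY_MONTHS)
  if (length(bad))
    stop("invalid month at ", row_id(bad[1]), ": '", df$month[bad[1]], "'")
  if (!is.numeric(df$year) || any(df$year %% 1 != 0))
    stop("year must be integer")
  df$year <- as.integer(df$year)
  if (!is.numeric(df$value) || anyNA(df$value))
    stop("value must be numeric and non-missing")
  bad <- which(df$value < 0)
  if (length(bad))
    stop("negative value at ", row_id(bad[1]))
  unknown <- setdiff(df$taxon, registry$taxon)
  if (length(unknown))
    stop("taxon id(s) not in registry: ", paste(unknown, collapse = ", "))
  role <- registry$role[match(df$taxon, registry$taxon)]
  bad <- which(role == "bee" & df$value %% 1 != 0)
  if (length(bad))
    stop("non-integer bee count at ", row_id(bad[1]),
         " (taxon ", df$taxon[bad[1]], ")")
  bad <- which(role == "plant" & df$value > 1)
  if (length(bad))
    stop("plant cover above 1 at ", row_id(bad[1]),
         " (taxon ", df$taxon[bad[1]], ")")
  key <- do.call(paste, c(df[c("site", "treatment", "year", "month", "taxon")],
                          sep = "\r"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (site, treatment, year, month, taxon) key: ",
         gsub("\r", "/", d, fixed = TRUE))
  }
  df$month <- factor(df$month, levels = SURVEY_MONTHS, ordered = TRUE)
  rownames(df) <- NULL
  class(df) <- c("survey_table", "data.frame")
  df
}

canonical_order <- function(df) {
  order(df$site, df$treatment, df$year, df$month, df$taxon)
}

#' Read a long-format survey CSV
#'
#' @param path CSV with header `site,treatment,year,month,taxon,value`
#'   (UTF-8, "." decimal).
#' @param registry a [taxon_registry()] used to validate taxa and roles.
#' @return a [survey_table()].
#' @export
read_survey <- function(path, registry) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = c(site = "character", taxon = "character",
                                      treatment = "character",
                                      month = "character"))
  miss <- setdiff(SURVEY_COLS, names(df))
  if (length(miss))
    stop("malformed header in ", path, ": missing ",
         paste(miss, collapse = ", "))
  if (!is.numeric(df$value) || anyNA(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$value)))))
    stop("parse error in ", path, " at data line ",
         if (length(bad)) bad[1] else "?", ": non-numeric value")
  }
  survey_table(df, registry)
}

#' Write a survey table as canonical CSV
#'
#' Output has deterministic column order and rows sorted by
#' (site, treatment, year, month, taxon), so the same table always produces
#' a byte-identical file.
#'
#' @param table a [survey_table()].
#' @param path output path.
#' @export
write_survey <- function(table, path) {
  df <- as.data.frame(table)[SURVEY_COLS]
  df <- df[canonical_order(df), , drop = FALSE]
  df$month <- as.character(df$month)
  df$value <- num_chr(df$value)
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

# round-trip-safe decimal formatting (17 significant digits)
num_chr <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  int <- !is.na(x) & x %% 1 == 0 & abs(x) < 2^31
  out[int] <- formatC(x[int], format = "d")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Read / write a taxon registry CSV (`taxon,role,family,origin,pooled`)
#' @param path CSV path.
#' @return [taxon_registry()] for the reader.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = "character")
  df$pooled <- df$pooled %in% c("TRUE", "true", "1")
  taxon_registry(df)
}

#' @rdname read_registry
#' @param registry a [taxon_registry()].
#' @export
write_registry <- function(registry, path) {
  df <- as.data.frame(registry)
  df$pooled <- ifelse(df$pooled, "TRUE", "FALSE")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a land-cover profile table
#'
#' One row per (field, category) with the proportional abundance of that
#' vegetation category within a 3-km radius of the field, and a flag marking
#' non-crop categories.  Proportions sum to 1 per field (tolerance 1e-9).
#'
#' @param df data frame with columns `field`, `category`, `proportion`,
#'   `noncrop`.
#' @return validated data frame with class `land_cover`.
#' @export
land_cover <- function(df) {
  need <- c("field", "category", "proportion", "noncrop")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("land cover table is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$field <- as.character(df$field)
  df$noncrop <- as.logical(df$noncrop)
  if (any(df$proportion < 0 | df$proportion > 1))
    stop("land-cover proportions must lie in [0, 1]")
  sums <- tapply(df$proportion, df$field, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad))
    stop("land-cover proportions do not sum to 1 for field(s): ",
         paste(bad, collapse = ", "))
  class(df) <- c("land_cover", "data.frame")
  df
}

#' Read / write land-cover profiles (`field,category,proportion,noncrop`)
#' @param path CSV path.
#' @export
read_landcover <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, colClasses = c(field = "character",
                                      category = "character"))
  df$noncrop <- as.logical(df$noncrop)
  land_cover(df)
}

#' @rdname read_landcover
#' @param lc a [land_cover()] table.
#' @export
write_landcover <- function(lc, path) {
  df <- as.data.frame(lc)
  df$proportion <- num_chr(df$proportion)
  df$noncrop <- ifelse(df$noncrop, "TRUE", "FALSE")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a bee-by-plant visitation matrix
#'
#' Observed flower-visit captures: non-negative integer counts with bee taxa
#' as rows and plant taxa as columns.
#'
#' @param mat numeric matrix with bee row names and plant column names.
#' @param registry optional [taxon_registry()]; when given, dimensions and
#'   labels must match its bee and plant taxa.
#' @return integer matrix with class `visitation_matrix`.
#' @export
visitation_matrix <- function(mat, registry = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("visitation matrix needs bee row names and plant column names")
  if (any(mat < 0) || any(mat %% 1 != 0))
    stop("visitation counts must be non-negative integers")
  if (!is.null(registry)) {
    bees <- registry$taxon[registry$role == "bee"]
    plants <- registry$taxon[registry$role == "plant"]
    if (!setequal(rownames(mat), bees) || !setequal(colnames(mat), plants))
      stop("visitation matrix labels do not match registry bee/plant taxa")
    mat <- mat[bees, plants, drop = FALSE]
  }
  storage.mode(mat) <- "integer"
  class(mat) <- c("visitation_matrix", class(matrix()))
  mat
}

#' Read / write a visitation matrix CSV (bee rows, plant columns)
#' @param path CSV path; first column holds the bee taxon ids.
#' @param registry optional [taxon_registry()] for label validation.
#' @export
read_visitation <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- as.character(df[[1]])
  visitation_matrix(mat, registry)
}

#' @rdname read_visitation
#' @param visits a [visitation_matrix()].
#' @export
write_visitation <- function(visits, path) {
  df <- data.frame(bee = rownames(visits), as.data.frame(unclass(visits)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Shifted natural-log transform for small counts
#'
#' `ln(x + 0.5)`, the transform applied to bee abundance and richness before
#' Gaussian modelling; strictly increasing and defined at zero.
#'
#' @param x non-negative numeric vector.
#' @return `log(x + 0.5)`.
#' @examples
#' ln_shift(c(0, 0.5, 4.5))
#' @export
ln_shift <- function(x) {
  if (any(x < 0)) stop("ln_shift requires x >= 0")
  log(x + 0.5)
}

#' Derive a wide community matrix from a long survey table
#'
#' Sampling units (rows) are defined by `unit_keys`; absent (unit, taxon)
#' combinations become zeros.
#'
#' @param table a [survey_table()].
#' @param unit_keys character vector of key columns defining a sampling unit.
#' @param taxa optional character vector fixing the column set (defaults to
#'   the taxa present in the table).
#' @return numeric matrix, units x taxa, with informative row names.
#' @export
community_matrix <- function(table,
                             unit_keys = c("site", "treatment", "year", "month"),
                             taxa = NULL) {
  stopifnot(all(unit_keys %in% SURVEY_COLS))
  df <- as.data.frame(table)
  unit <- do.call(paste, c(lapply(unit_keys, function(k) as.character(df[[k]])),
                           sep = "|"))
  if (is.null(taxa)) taxa <- sort(unique(df$taxon))
  units <- unique(unit)
  keep <- df$taxon %in% taxa
  tab <- xtabs(value ~ u + t,
               data = data.frame(value = df$value[keep],
                                 u = factor(unit[keep], levels = units),
                                 t = factor(df$taxon[keep], levels = taxa)))
  mat <- matrix(as.numeric(tab), nrow = length(units), ncol = length(taxa),
                dimnames = list(units, taxa))
  mat
}
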