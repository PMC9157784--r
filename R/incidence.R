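# Incidence data model: species and sample-unit tables, unit x species
# presence matrices, and the unit-level richness endpoints computed from them.

SPECIES_ORIGINS <- c("native", "non_native")
GROWTH_FORMS <- c("submerged", "emergent", "floating", "free_floating", "other")

#' Validate a species attribute table
#'
#' A species table has one row per taxon with columns `code` (short unique
#' identifier), `name`, `origin` (`"native"` or `"non_native"`) and
#' `growth_form` (`"submerged"`, `"emergent"`, `"floating"`,
#' `"free_floating"` or `"other"`).
#'
#' @param species data frame with at least columns `code` and `origin`;
#'   missing `name`/`growth_form` columns are filled with defaults.
#' @return the validated (and completed) species data frame.
#' @export
species_table <- function(species) {
  species <- as.data.frame(species)
  if (!all(c("code", "origin") %in% names(species))) {
    stop("species table needs columns 'code' and 'origin'")
  }
  species$code <- as.character(species$code)
  if (anyDuplicated(species$code)) {
    stop("duplicated species codes: ",
         paste(unique(species$code[duplicated(species$code)]), collapse = ", "))
  }
  if (!all(species$origin %in% SPECIES_ORIGINS)) {
    stop("species origin must be one of: ", paste(SPECIES_ORIGINS, collapse = ", "))
  }
  if (is.null(species$name)) species$name <- species$code
  if (is.null(species$growth_form)) species$growth_form <- "other"
  if (!all(species$growth_form %in% GROWTH_FORMS)) {
    stop("growth_form must be one of: ", paste(GROWTH_FORMS, collapse = ", "))
  }
  rownames(species) <- NULL
  species
}

#' Validate a sample-unit attribute table
#'
#' @param units data frame with columns `unit_id`, and optionally `x`, `y`
#'   (planar metres), `zone`, `mean_depth`, `max_depth` and further habitat
#'   columns. Depths must be non-negative.
#' @return validated data frame.
#' @export
unit_table <- function(units) {
  units <- as.data.frame(units)
  if (!"unit_id" %in% names(units)) stop("unit table needs a 'unit_id' column")
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) {
    stop("duplicated unit ids: ",
         paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", "))
  }
  for (d in intersect(c("mean_depth", "max_depth"), names(units))) {
    if (any(units[[d]] < 0, na.rm = TRUE)) stop(d, " must be non-negative")
  }
  rownames(units) <- NULL
  units
}

#' Build an incidence matrix from long-format detection records
#'
#' Station-level detection records (one row per detection) are collapsed to
#' unit-level presence/absence: a species counts at most once per sample
#' unit, whatever the number of stations or rake tosses that produced it.
#' Units listed in `units` with no detections are retained as all-absent
#' rows; they are part of the sample size `m`.
#'
#' @param records data frame (or CSV path) with columns `unit_id`,
#'   `species_code` and optionally `station_id`; one row per detection.
#' @param species species attribute table (see [species_table()]).
#' @param units sample-unit table (see [unit_table()]); defines the full set
#'   of surveyed units, including plant-free ones.
#' @return an object of class `incidence_matrix`: a list with `presence`
#'   (logical unit x species matrix), `units` and `species` data frames.
#' @export
read_incidence <- function(records, species, units) {
  if (is.character(records) && length(records) == 1) {
    records <- read.csv(records, stringsAsFactors = FALSE)
  }
  if (is.character(species) && length(species) == 1) {
    species <- read.csv(species, stringsAsFactors = FALSE)
  }
  if (is.character(units) && length(units) == 1) {
    units <- read.csv(units, stringsAsFactors = FALSE)
  }
  species <- species_table(species)
  units <- unit_table(units)
  records <- as.data.frame(records)
  if (nrow(records) > 0) {
    if (!all(c("unit_id", "species_code") %in% names(records))) {
      stop("records need columns 'unit_id' and 'species_code'")
    }
    records$unit_id <- as.character(records$unit_id)
    records$species_code <- as.character(records$species_code)
    bad_sp <- setdiff(records$species_code, species$code)
    if (length(bad_sp)) stop("unknown species code(s): ", paste(bad_sp, collapse = ", "))
    bad_un <- setdiff(records$unit_id, units$unit_id)
    if (length(bad_un)) stop("unknown unit id(s): ", paste(bad_un, collapse = ", "))
  }
  presence <- matrix(FALSE, nrow = nrow(units), ncol = nrow(species),
                     dimnames = list(units$unit_id, species$code))
  if (nrow(records) > 0) {
    presence[cbind(records$unit_id, records$species_code)] <- TRUE
  }
  incidence_matrix(presence, species, units)
}

#' Construct an incidence matrix from a wide presence table
#'
#' @param presence logical or 0/1 matrix (units x species) with dimnames, or
#'   a data frame with a `unit_id` column plus one 0/1 column per species.
#' @param species,units attribute tables; generated minimally when `NULL`.
#' @return `incidence_matrix` object.
#' @export
incidence_matrix <- function(presence, species = NULL, units = NULL) {
  if (is.data.frame(presence) && "unit_id" %in% names(presence)) {
    ids <- as.character(presence$unit_id)
    presence <- as.matrix(presence[, setdiff(names(presence), "unit_id"), drop = FALSE])
    rownames(presence) <- ids
  }
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  if (is.null(rownames(presence))) rownames(presence) <- paste0("u", seq_len(nrow(presence)))
  if (is.null(colnames(presence))) colnames(presence) <- paste0("sp", seq_len(ncol(presence)))
  if (is.null(species)) {
    species <- data.frame(code = colnames(presence), origin = "native",
                          stringsAsFactors = FALSE)
  }
  species <- species_table(species)
  if (is.null(units)) {
    units <- data.frame(unit_id = rownames(presence), stringsAsFactors = FALSE)
  }
  units <- unit_table(units)
  if (!identical(sort(rownames(presence)), sort(units$unit_id))) {
    stop("presence rownames do not match unit table")
  }
  if (!identical(sort(colnames(presence)), sort(species$code))) {
    stop("presence colnames do not match species table")
  }
  presence <- presence[units$unit_id, species$code, drop = FALSE]
  structure(list(presence = presence, species = species, units = units),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("incidence_matrix:", nrow(x$presence), "sample units x",
      ncol(x$presence), "species;", sum(x$presence), "incidences\n")
  invisible(x)
}

#' Tally incidence counts for a survey
#'
#' Computes the inputs of the incidence-based richness estimators: the
#' number of sample units `m`, the total incidence tally, per-species
#' incidence frequencies, observed richness `Sobs`, and the number of
#' uniques (`Q1`, species found in exactly one unit) and duplicates (`Q2`,
#' exactly two units).
#'
#' @param x an `incidence_matrix`, or a logical/0-1 unit x species matrix.
#' @return object of class `incidence_counts` with fields `m`, `incidences`,
#'   `per_species` (named frequency vector), `Sobs`, `Q1`, `Q2`.
#' @export
tally_counts <- function(x) {
  presence <- if (inherits(x, "incidence_matrix")) x$presence else {
    m <- as.matrix(x); mode(m) <- "logical"; m
  }
  if (nrow(presence) == 0 || ncol(presence) == 0) stop("empty incidence matrix")
  freq <- colSums(presence)
  incidence_counts(m = nrow(presence), per_species = freq)
}

#' Construct incidence counts directly
#'
#' Either supply the per-species frequency vector, or the summary counts
#' (`Sobs`, `Q1`, `Q2`, `incidences`) as printed in survey reports.
#'
#' @param m number of sample units (> 0).
#' @param per_species named integer vector of per-species incidence
#'   frequencies (0 entries allowed and dropped from `Sobs`).
#' @param Sobs,Q1,Q2,incidences summary counts, used when `per_species` is
#'   not given.
#' @param m_infreq number of sample units containing at least one infrequent
#'   species (frequency <= 10); needed exactly by [ice_cv()]. Computed from
#'   matrices by [tally_counts()]; defaults to `m` otherwise.
#' @return object of class `incidence_counts`.
#' @export
incidence_counts <- function(m, per_species = NULL, Sobs = NULL, Q1 = NULL,
                             Q2 = NULL, incidences = NULL, m_infreq = NULL) {
  m <- as.integer(m)
  if (m <= 0) stop("m must be a positive integer")
  if (!is.null(per_species)) {
    if (any(per_species < 0) || any(per_species > m)) {
      stop("per-species frequencies must lie in [0, m]")
    }
    Sobs <- sum(per_species >= 1)
    Q1 <- sum(per_species == 1)
    Q2 <- sum(per_species == 2)
    incidences <- as.integer(sum(per_species))
  } else {
    if (is.null(Sobs) || is.null(Q1) || is.null(Q2)) {
      stop("need per_species, or Sobs, Q1 and Q2")
    }
    if (Q1 + Q2 > Sobs) stop("Q1 + Q2 cannot exceed Sobs")
    if (is.null(incidences)) incidences <- NA_integer_
  }
  structure(list(m = m, incidences = incidences, per_species = per_species,
                 Sobs = Sobs, Q1 = Q1, Q2 = Q2,
                 m_infreq = if (is.null(m_infreq)) m else m_infreq),
            class = "incidence_counts")
}

#' @export
print.incidence_counts <- function(x, ...) {
  cat(sprintf("incidence_counts: m=%d incidences=%s Sobs=%d Q1=%d Q2=%d\n",
              x$m, format(x$incidences), x$Sobs, x$Q1, x$Q2))
  invisible(x)
}

# m_infreq from a matrix: units containing at least one infrequent species
counts_with_minfreq <- function(matrix) {
  cts <- tally_counts(matrix)
  presence <- matrix$presence
  infreq <- cts$per_species >= 1 & cts$per_species <= 10
  cts$m_infreq <- sum(rowSums(presence[, infreq, drop = FALSE]) > 0)
  cts
}

#' Per-unit richness endpoint summary
#'
#' Mean (over sample units) of total richness, rare-species richness and
#' non-native richness. A species is *rare* at fraction `f` when its
#' incidence frequency is strictly less than `f` times the total incidence
#' tally of the survey (the 5% rule; a parallel 20% threshold is reported
#' alongside it).
#'
#' @param matrix an `incidence_matrix`.
#' @param species optional species table overriding the one embedded in
#'   `matrix`.
#' @param rare_fractions numeric vector of rarity thresholds in (0,1).
#' @return data frame with one row per endpoint (`total`,
#'   `rare_<percent>`, `non_native`) and columns `endpoint`, `mean_richness`.
#' @export
endpoint_summary <- function(matrix, species = NULL,
                             rare_fractions = c(0.05, 0.20)) {
  if (any(rare_fractions <= 0 | rare_fractions >= 1)) {
    stop("rare fractions must lie strictly inside (0, 1)")
  }
  if (is.null(species)) species <- matrix$species
  species <- species_table(species)
  presence <- matrix$presence[, species$code, drop = FALSE]
  freq <- colSums(presence)
  total_inc <- sum(freq)
  if (total_inc == 0) stop("no incidences: endpoint means undefined")
  rows <- data.frame(endpoint = "total",
                     mean_richness = mean(rowSums(presence)),
                     stringsAsFactors = FALSE)
  for (f in rare_fractions) {
    rare <- freq < f * total_inc & freq >= 1
    rows <- rbind(rows, data.frame(
      endpoint = sprintf("rare_%g", 100 * f),
      mean_richness = mean(rowSums(presence[, rare, drop = FALSE]))))
  }
  nn <- species$origin == "non_native"
  rows <- rbind(rows, data.frame(
    endpoint = "non_native",
    mean_richness = mean(rowSums(presence[, nn, drop = FALSE]))))
  rows
}

#' Native vs non-native richness relationship
#'
#' Per-unit native and non-native richness and their product-moment
#' correlation (the native--exotic richness relationship at the sample-unit
#' scale). With zero variance in either series the correlation is reported
#' as `NA` (undefined), never coerced to 0.
#'
#' @param matrix an `incidence_matrix`.
#' @param species optional species table override.
#' @return list with `r` (correlation or `NA`) and `pairs` (data frame
#'   `unit_id`, `native`, `non_native`).
#' @export
native_nonnative_relationship <- function(matrix, species = NULL) {
  if (is.null(species)) species <- matrix$species
  species <- species_table(species)
  presence <- matrix$presence[, species$code, drop = FALSE]
  if (nrow(presence) < 3) stop("need at least 3 sample units")
  native <- rowSums(presence[, species$origin == "native", drop = FALSE])
  nonnat <- rowSums(presence[, species$origin == "non_native", drop = FALSE])
  r <- if (sd(native) == 0 || sd(nonnat) == 0) NA_real_ else cor(native, nonnat)
  list(r = r,
       pairs = data.frame(unit_id = rownames(presence), native = native,
                          non_native = nonnat, row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Euphotic-zone depth from Secchi transparency
#'
#' Rule-of-thumb estimate of the maximum depth of plant growth as 2--3
#' times the Secchi depth.
#'
#' @param secchi_m Secchi depth in metres (> 0).
#' @param factor multiplier, conventionally in \[2, 3\]; values outside the
#'   range are computed with a warning.
#' @return estimated euphotic-zone depth in metres.
#' @export
euphotic_depth <- function(secchi_m, factor = 2.5) {
  if (any(secchi_m <= 0)) stop("secchi_m must be positive")
  if (any(factor < 2 | factor > 3)) {
    warning("euphotic factor outside the conventional [2, 3] range")
  }
  secchi_m * factor
}
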