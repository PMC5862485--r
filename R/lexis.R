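#' @title Canonical category levels for death records
#' @description Default label maps for the record-level covariates. Each
#'   element maps input strings (matched case-insensitively after trimming)
#'   to a canonical level; anything unmatched becomes `"unknown"`.
#' @keywords internal
default_label_maps <- function() {
  idmap <- function(levels) stats::setNames(levels, levels)
  list(
    schooling = idmap(c("none", "primary", "secondary", "high_school",
                        "professional", "unknown")),
    marginalization = idmap(c("very_high", "high", "medium", "low",
                              "very_low", "unknown")),
    medical_care = idmap(c("yes", "no", "unknown")),
    affiliation = idmap(c("yes", "no", "unknown"))
  )
}

covariate_levels <- function() {
  lapply(default_label_maps(), function(m) unname(m))
}

#' Read record-level maternal death data
#'
#' Reads a CSV of individual maternal deaths (one row per death) with
#' columns `age`, `year`, `schooling`, `marginalization`, `medical_care`
#' and `affiliation`. Category strings are matched case-insensitively
#' against `label_maps`; unmatched strings are recoded to `"unknown"` and
#' counted. Rows whose age or year fail to parse as integers are rejected
#' and tallied (attribute `n_rejected`).
#'
#' @param path path to a comma-separated, UTF-8, headered file.
#' @param label_maps named list of named character vectors mapping input
#'   labels to canonical levels; defaults cover the canonical levels
#'   themselves. Extend to absorb source-specific spellings, e.g.
#'   `c(PROFESIONAL = "professional")`.
#' @return data.frame with columns `age`, `year`, `schooling`,
#'   `marginalization`, `medical_care`, `affiliation`; attributes
#'   `n_rejected` (unparsable rows) and `n_unknown` (relabelled cells).
#' @export
read_death_records <- function(path, label_maps = default_label_maps()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("age", "year", "schooling", "marginalization",
                "medical_care", "affiliation")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  maps <- default_label_maps()
  for (nm in intersect(names(label_maps), names(maps)))
    maps[[nm]] <- c(maps[[nm]], label_maps[[nm]])

  age <- suppressWarnings(as.integer(trimws(raw$age)))
  year <- suppressWarnings(as.integer(trimws(raw$year)))
  bad <- is.na(age) | is.na(year)
  n_rejected <- sum(bad)
  if (n_rejected > 0L)
    warning(n_rejected, " row(s) rejected: unparsable age or year")

  n_unknown <- 0L
  recode <- function(values, map) {
    key <- tolower(trimws(values))
    names(map) <- tolower(trimws(names(map)))
    out <- unname(map[key])
    miss <- is.na(out)
    n_unknown <<- n_unknown + sum(miss & !bad)
    out[miss] <- "unknown"
    out
  }
  rec <- data.frame(
    age = age[!bad], year = year[!bad],
    schooling = recode(raw$schooling, maps$schooling)[!bad],
    marginalization = recode(raw$marginalization, maps$marginalization)[!bad],
    medical_care = recode(raw$medical_care, maps$medical_care)[!bad],
    affiliation = recode(raw$affiliation, maps$affiliation)[!bad],
    stringsAsFactors = FALSE
  )
  if (n_unknown > 0L)
    warning(n_unknown, " category cell(s) recoded to 'unknown'")
  attr(rec, "n_rejected") <- n_rejected
  attr(rec, "n_unknown") <- n_unknown
  rec
}

#' Read live-birth denominators
#'
#' Reads a CSV of live-birth counts with columns `mother_age`, `year`,
#' `births` (one row per age-year cell).
#'
#' @param path path to a comma-separated, headered file.
#' @return data.frame with integer `mother_age`, `year` and numeric
#'   non-negative `births`.
#' @export
read_birth_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mother_age", "year", "births")
  missing_cols <- setdiff(required, names(b))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  b$mother_age <- as.integer(b$mother_age)
  b$year <- as.integer(b$year)
  b$births <- as.numeric(b$births)
  if (any(is.na(b$mother_age) | is.na(b$year) | is.na(b$births)))
    stop("unparsable mother_age/year/births values")
  if (any(b$births < 0)) stop("births must be non-negative")
  b
}

#' Construct and validate a Lexis table
#'
#' A Lexis table is the age x period grid the APC model consumes: one row
#' per (age, period) cell with the death count, the live-birth exposure and
#' the derived birth cohort `cohort = period - age`.
#'
#' @param df data.frame with columns `age`, `period`, `cohort`, `deaths`,
#'   `exposure`.
#' @return the validated data.frame with class `lexis_table`.
#' @export
lexis_table <- function(df) {
  required <- c("age", "period", "cohort", "deaths", "exposure")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("lexis_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df$cohort != df$period - df$age))
    stop("lexis_table: cohort != period - age")
  if (any(df$deaths < 0)) stop("lexis_table: negative deaths")
  if (any(df$exposure <= 0))
    stop("lexis_table: cells with exposure <= 0 must be dropped upstream")
  if (anyDuplicated(df[, c("age", "period")]))
    stop("lexis_table: duplicate (age, period) cells")
  rownames(df) <- NULL
  class(df) <- c("lexis_table", "data.frame")
  df
}

#' Tabulate death records onto the Lexis grid
#'
#' Cross-tabulates record-level deaths and live-birth denominators into
#' one row per (age, period) cell within the requested ranges. The birth
#' cohort of a cell is `period - age`. Cells without a positive birth
#' denominator cannot carry a rate (the log-exposure offset is undefined)
#' and are dropped with a warning; any deaths falling in such cells are
#' reported in the warning.
#'
#' @param deaths data.frame of death records (from [read_death_records()]
#'   or [simulate_lexis()]), needing columns `age` and `year`.
#' @param births data.frame of birth counts with columns `mother_age`,
#'   `year`, `births`; at most one row per (age, year).
#' @param age_range integer length-2 vector `c(lo, hi)`, inclusive.
#' @param period_range integer length-2 vector `c(lo, hi)`, inclusive.
#' @return a [lexis_table()] with attribute `dropped_cells` (data.frame of
#'   zero-exposure cells that were excluded, possibly empty).
#' @export
build_lexis <- function(deaths, births, age_range, period_range) {
  stopifnot(length(age_range) == 2L, length(period_range) == 2L,
            age_range[1] <= age_range[2],
            period_range[1] <= period_range[2])
  ages <- seq.int(age_range[1], age_range[2])
  periods <- seq.int(period_range[1], period_range[2])

  if (anyDuplicated(births[, c("mother_age", "year")]))
    stop("duplicate (mother_age, year) keys in births")

  din <- deaths$age %in% ages & deaths$year %in% periods
  if (!any(din))
    stop("no death records fall inside the requested age/period ranges")

  grid <- expand.grid(age = ages, period = periods, KEEP.OUT.ATTRS = FALSE)
  dcount <- as.data.frame(table(age = factor(deaths$age[din], levels = ages),
                                period = factor(deaths$year[din],
                                                levels = periods)),
                          stringsAsFactors = FALSE)
  dcount$age <- as.integer(dcount$age)
  dcount$period <- as.integer(dcount$period)
  grid <- merge(grid, dcount, by = c("age", "period"), all.x = TRUE)
  names(grid)[names(grid) == "Freq"] <- "deaths"

  bkey <- births[births$mother_age %in% ages & births$year %in% periods,
                 c("mother_age", "year", "births")]
  names(bkey) <- c("age", "period", "exposure")
  grid <- merge(grid, bkey, by = c("age", "period"), all.x = TRUE)
  grid$exposure[is.na(grid$exposure)] <- 0

  drop <- grid$exposure <= 0
  if (any(drop)) {
    lost <- sum(grid$deaths[drop])
    warning(sum(drop), " cell(s) with zero live-birth exposure dropped (",
            lost, " death(s) in those cells excluded)")
  }
  out <- grid[!drop, , drop = FALSE]
  out <- out[order(out$period, out$age), ]
  out$cohort <- out$period - out$age
  out <- out[, c("age", "period", "cohort", "deaths", "exposure")]
  tab <- lexis_table(out)
  attr(tab, "dropped_cells") <- grid[drop, c("age", "period", "deaths")]
  tab
}

#' Crude maternal mortality ratios
#'
#' Aggregates a Lexis table into crude rates per 100,000 live births,
#' optionally stratified by one grid dimension. A grand-total row labelled
#' `"total"` is always included. Strata with zero total exposure get an
#' `NA` rate (undefined, never reported as 0).
#'
#' @param table a [lexis_table()].
#' @param by `"total"` for the overall MMR only, or one of `"age"`,
#'   `"period"`, `"cohort"`.
#' @param scale rate multiplier, 100,000 by convention.
#' @return data.frame with columns `stratum`, `deaths`, `live_births`,
#'   `rate`.
#' @examples
#' tab <- lexis_table(data.frame(age = 20, period = 2005, cohort = 1985,
#'                               deaths = 2, exposure = 10000))
#' crude_mmr(tab)  # rate 20 per 100,000
#' @export
crude_mmr <- function(table, by = c("total", "age", "period", "cohort"),
                      scale = 1e5) {
  by <- match.arg(by)
  stopifnot(inherits(table, "lexis_table"), nrow(table) > 0)
  rate_row <- function(label, d, n) {
    data.frame(stratum = as.character(label), deaths = d, live_births = n,
               rate = if (n > 0) d / n * scale else NA_real_,
               stringsAsFactors = FALSE)
  }
  total <- rate_row("total", sum(table$deaths), sum(table$exposure))
  if (by == "total") return(total)
  parts <- lapply(split(table, table[[by]]), function(g)
    rate_row(g[[by]][1L], sum(g$deaths), sum(g$exposure)))
  out <- do.call(rbind, c(parts, list(total)))
  rownames(out) <- NULL
  out
}

#' @export
print.lexis_table <- function(x, ...) {
  cat(sprintf(paste0(
    "Lexis table: %d cells, ages %d-%d, periods %d-%d, ",
    "%d deaths / %.0f births\n"),
    nrow(x), min(x$age), max(x$age), min(x$period), max(x$period),
    sum(x$deaths), sum(x$exposure)))
  NextMethod()
}
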