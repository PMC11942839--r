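#' Read a life-table CSV of individually reared insects
#'
#' Parses a comma-separated life table (UTF-8, header required, `.` decimal
#' separator) into a validated record set. Two layouts are supported:
#'
#' * `format = "individuals"` (canonical): one row per reared individual with
#'   columns `species, sex, temperature_C, dev_time_days, emerged, replicate`.
#' * `format = "means"`: one row per rearing cell with columns
#'   `species, sex, temperature_C, mean_dev_time_days, n` (published life
#'   tables usually report only cell means). With `expand = TRUE` each cell is
#'   expanded into `n` identical pseudo-individuals flagged as aggregated, so
#'   downstream fits weight cells by their sample size.
#'
#' Rows are validated individually: a malformed row (non-numeric temperature
#' or development time, emerged individuals without a development time,
#' non-positive development times) is rejected and reported, not fatal.
#' Cells with no emergence (`mean_dev_time` empty in the means layout) carry
#' no rate information for curve fitting; they are recorded separately in the
#' `"non_developing"` attribute rather than injected as zero-rate
#' observations, which would bias both rate models.
#'
#' @param path Path to the CSV file.
#' @param format `"individuals"` or `"means"` (see above).
#' @param columns Optional named character vector remapping canonical field
#'   names (`species`, `sex`, `temperature`, `dev_time`, `emerged`,
#'   `replicate`; for means: `mean_dev_time`, `n`) to the file's column
#'   headers. Unnamed fields keep their defaults.
#' @param expand For `format = "means"`: expand each cell into `n`
#'   pseudo-individuals (default `TRUE`). With `FALSE` each cell becomes a
#'   single record with a `weight` column equal to `n`.
#'
#' @return A `data.frame` of class `"lifetable"` with columns `species`,
#'   `sex` (one of `"female"`, `"male"`, `"unknown"`), `temperature` (deg C),
#'   `dev_time` (days; `NA` when not emerged), `emerged` (logical),
#'   `replicate` (integer), `aggregated` (logical), `weight` (numeric).
#'   Attributes: `"rejected"` — data frame of row numbers and messages for
#'   rows that failed validation; `"non_developing"` — data frame
#'   (species, sex, temperature) of zero-emergence cells.
#' @seealso [rates_from_records()], [write_lifetable()], [parasitoid_devtimes()]
#' @export
read_lifetable <- function(path, format = c("individuals", "means"),
                           columns = NULL, expand = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("life-table file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, comment.char = "#")
  map <- .column_map(format, columns)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (format == "individuals") {
    .parse_individual_rows(raw, map)
  } else {
    .parse_mean_rows(raw, map, expand = expand)
  }
}

.column_map <- function(format, columns) {
  defaults <- if (format == "individuals") {
    c(species = "species", sex = "sex", temperature = "temperature_C",
      dev_time = "dev_time_days", emerged = "emerged", replicate = "replicate")
  } else {
    c(species = "species", sex = "sex", temperature = "temperature_C",
      mean_dev_time = "mean_dev_time_days", n = "n")
  }
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), names(defaults))
    if (length(bad) > 0)
      stop("unknown field(s) in column mapping: ", paste(bad, collapse = ", "))
    defaults[names(columns)] <- columns
  }
  defaults
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

.parse_sex <- function(x) {
  s <- tolower(trimws(x))
  s[s %in% c("f", "female")] <- "female"
  s[s %in% c("m", "male")] <- "male"
  s[s == "" | is.na(s)] <- "unknown"
  s
}

.parse_individual_rows <- function(raw, map) {
  n <- nrow(raw)
  rejected <- list()
  keep <- logical(n)
  temperature <- dev_time <- numeric(n)
  emerged <- logical(n)
  replicate <- integer(n)
  sex <- character(n)
  for (i in seq_len(n)) {
    errs <- character()
    tv <- .num_or_na(raw[[map[["temperature"]]]][i])
    if (is.na(tv) || !is.finite(tv)) errs <- c(errs, "non-numeric temperature")
    em_raw <- tolower(trimws(raw[[map[["emerged"]]]][i]))
    em <- em_raw %in% c("true", "t", "1", "yes")
    if (!em_raw %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
      errs <- c(errs, "unrecognised 'emerged' value")
    dt_raw <- raw[[map[["dev_time"]]]][i]
    dt <- .num_or_na(dt_raw)
    if (em) {
      if (trimws(dt_raw) == "" || is.na(dt))
        errs <- c(errs, "emerged individual without a numeric dev_time")
      else if (dt <= 0)
        errs <- c(errs, "dev_time must be strictly positive")
    } else if (trimws(dt_raw) != "") {
      errs <- c(errs, "dev_time given for a non-emerged individual")
    }
    rep_i <- .num_or_na(raw[[map[["replicate"]]]][i])
    if (is.na(rep_i) || rep_i < 1 || rep_i != round(rep_i))
      errs <- c(errs, "replicate must be an integer >= 1")
    s <- .parse_sex(raw[[map[["sex"]]]][i])
    if (!s %in% c("female", "male", "unknown"))
      errs <- c(errs, "sex must be female, male or unknown")
    if (length(errs) > 0) {
      rejected[[length(rejected) + 1]] <-
        data.frame(row = i, message = paste(errs, collapse = "; "))
      next
    }
    keep[i] <- TRUE
    temperature[i] <- tv
    dev_time[i] <- if (em) dt else NA_real_
    emerged[i] <- em
    replicate[i] <- as.integer(rep_i)
    sex[i] <- s
  }
  out <- data.frame(
    species = raw[[map[["species"]]]][keep],
    sex = sex[keep],
    temperature = temperature[keep],
    dev_time = dev_time[keep],
    emerged = emerged[keep],
    replicate = replicate[keep],
    aggregated = FALSE,
    weight = 1,
    stringsAsFactors = FALSE
  )
  .as_lifetable(out,
                rejected = do.call(rbind, rejected),
                non_developing = .find_non_developing(out))
}

.parse_mean_rows <- function(raw, map, expand) {
  n <- nrow(raw)
  rejected <- list()
  records <- list()
  non_dev <- list()
  for (i in seq_len(n)) {
    tv <- .num_or_na(raw[[map[["temperature"]]]][i])
    if (is.na(tv) || !is.finite(tv)) {
      rejected[[length(rejected) + 1]] <-
        data.frame(row = i, message = "non-numeric temperature")
      next
    }
    sp <- raw[[map[["species"]]]][i]
    s <- .parse_sex(raw[[map[["sex"]]]][i])
    nn <- .num_or_na(raw[[map[["n"]]]][i])
    mdt_raw <- trimws(raw[[map[["mean_dev_time"]]]][i])
    if (mdt_raw == "" || mdt_raw %in% c("--", "NA")) {
      non_dev[[length(non_dev) + 1]] <-
        data.frame(species = sp, sex = s, temperature = tv)
      next
    }
    mdt <- .num_or_na(mdt_raw)
    if (is.na(mdt) || mdt <= 0) {
      rejected[[length(rejected) + 1]] <-
        data.frame(row = i, message = "mean dev_time must be positive")
      next
    }
    if (is.na(nn) || nn < 1) {
      rejected[[length(rejected) + 1]] <-
        data.frame(row = i, message = "'n' must be a positive integer")
      next
    }
    reps <- if (expand) as.integer(nn) else 1L
    records[[length(records) + 1]] <- data.frame(
      species = sp, sex = s, temperature = tv,
      dev_time = mdt, emerged = TRUE,
      replicate = seq_len(reps), aggregated = TRUE,
      weight = if (expand) 1 else nn,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(records) > 0) do.call(rbind, records) else
    data.frame(species = character(), sex = character(),
               temperature = numeric(), dev_time = numeric(),
               emerged = logical(), replicate = integer(),
               aggregated = logical(), weight = numeric())
  .as_lifetable(out,
                rejected = do.call(rbind, rejected),
                non_developing = do.call(rbind, non_dev))
}

.find_non_developing <- function(records) {
  if (nrow(records) == 0) return(NULL)
  cells <- unique(records[, c("species", "sex", "temperature")])
  dev <- unique(records[records$emerged, c("species", "sex", "temperature")])
  key <- function(d) paste(d$species, d$sex, d$temperature, sep = "\r")
  nd <- cells[!key(cells) %in% key(dev), , drop = FALSE]
  if (nrow(nd) == 0) NULL else { rownames(nd) <- NULL; nd }
}

.as_lifetable <- function(df, rejected = NULL, non_developing = NULL) {
  rownames(df) <- NULL
  structure(df,
            rejected = rejected,
            non_developing = non_developing,
            class = c("lifetable", "data.frame"))
}

#' Write a life table back to CSV
#'
#' Inverse of [read_lifetable()] for the individual-row layout; reading the
#' written file back yields the same records field for field.
#'
#' @param records A `"lifetable"` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(records, path) {
  stopifnot(inherits(records, "lifetable"))
  out <- data.frame(
    species = records$species,
    sex = records$sex,
    temperature_C = records$temperature,
    dev_time_days = ifelse(records$emerged, records$dev_time, ""),
    emerged = ifelse(records$emerged, "true", "false"),
    replicate = records$replicate
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Development rates from life-table records
#'
#' Converts emerged individuals into `(temperature, rate)` observations with
#' `rate = 1 / dev_time` (1/day) at full floating precision. Non-emerged
#' records carry no rate and are excluded; their count is attached as the
#' `"excluded"` attribute, and zero-emergence cells are carried through in
#' `"non_developing"`.
#'
#' @param records A `"lifetable"` data frame from [read_lifetable()] or
#'   [simulate_lifetable()].
#' @return A data frame of class `"rate_obs"` with columns `species`, `sex`,
#'   `temperature`, `rate`, `weight`.
#' @examples
#' lt <- simulate_lifetable(sim_config(seed = 1))
#' head(rates_from_records(lt))
#' @export
rates_from_records <- function(records) {
  stopifnot(inherits(records, "lifetable"))
  emerged <- records[records$emerged, , drop = FALSE]
  obs <- data.frame(
    species = emerged$species,
    sex = emerged$sex,
    temperature = emerged$temperature,
    rate = 1 / emerged$dev_time,
    weight = emerged$weight,
    stringsAsFactors = FALSE
  )
  rownames(obs) <- NULL
  structure(obs,
            excluded = sum(!records$emerged),
            non_developing = attr(records, "non_developing"),
            class = c("rate_obs", "data.frame"))
}

#' Read a daily mean temperature series
#'
#' Accepts either a `day,t_mean_C` layout or a `date,t_min_C,t_max_C` layout,
#' in which case the daily mean is the min/max midpoint. Day indices must be
#' strictly increasing with no gaps (consecutive integers starting anywhere
#' at or above 1).
#'
#' @param path CSV path.
#' @return Data frame of class `"temperature_series"` with columns `day`
#'   (integer) and `t_mean` (deg C), plus `date` when present in the input.
#' @seealso [accumulate_degree_days()]
#' @export
read_temperature_series <- function(path) {
  if (!file.exists(path)) stop("temperature-series file not found: ", path)
  raw <- utils::read.csv(path, strip.white = TRUE, comment.char = "#")
  if (all(c("day", "t_mean_C") %in% names(raw))) {
    out <- data.frame(day = raw$day, t_mean = raw$t_mean_C)
    if ("date" %in% names(raw)) out$date <- raw$date
  } else if (all(c("date", "t_min_C", "t_max_C") %in% names(raw))) {
    out <- data.frame(day = seq_len(nrow(raw)),
                      t_mean = (raw$t_min_C + raw$t_max_C) / 2,
                      date = raw$date)
  } else {
    stop("expected columns day,t_mean_C or date,t_min_C,t_max_C")
  }
  temperature_series(out$day, out$t_mean,
                     date = if ("date" %in% names(out)) out$date else NULL)
}

#' Construct a daily temperature series
#'
#' @param day Integer day indices, strictly increasing, no gaps, first >= 1.
#' @param t_mean Daily mean temperatures, deg C.
#' @param date Optional calendar dates, recycled along `day`.
#' @return Data frame of class `"temperature_series"`.
#' @export
temperature_series <- function(day, t_mean, date = NULL) {
  day <- as.integer(day)
  stopifnot(length(day) == length(t_mean), all(is.finite(t_mean)))
  if (length(day) == 0) stop("temperature series must be non-empty")
  if (day[1] < 1) stop("day indices must start at 1 or later")
  if (length(day) > 1 && any(diff(day) != 1L))
    stop("day indices must be consecutive integers (strictly increasing, no gaps)")
  out <- data.frame(day = day, t_mean = as.numeric(t_mean))
  if (!is.null(date)) out$date <- date
  class(out) <- c("temperature_series", "data.frame")
  out
}

#' Published mean development times of two fall-webworm pupal parasitoids
#'
#' Loads the packaged life table of egg-to-adult mean development times
#' (days, n = 50 per cell) of the pupal parasitoids *Chouioia cunea* and
#' *Psychophagus omnivorus* reared at constant temperatures of 10, 15, 20,
#' 25 and 30 deg C. *C. cunea* develops at 15-30 deg C, *P. omnivorus* only
#' at 20-30 deg C; cells without emergence are reported in the
#' `"non_developing"` attribute. Only cell means are published, so the
#' records are aggregated pseudo-individuals (see [read_lifetable()]).
#'
#' @param expand Expand each cell into `n` pseudo-individuals (default) or
#'   keep one weighted record per cell.
#' @return A `"lifetable"` data frame (14 developing cells across 2 species
#'   x 2 sexes).
#' @examples
#' lt <- parasitoid_devtimes()
#' aggregate(dev_time ~ species + temperature, data = lt, FUN = mean)
#' @export
parasitoid_devtimes <- function(expand = TRUE) {
  path <- system.file("extdata", "parasitoid_devtimes.csv",
                      package = "thermaldev", mustWork = TRUE)
  read_lifetable(path, format = "means", expand = expand)
}
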