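# Delimited-table readers and writers. All tables are RFC 4180 CSV with a
# header row, decimal points, and ISO-8601 timestamps/dates in UTC.

iso_format <- "%Y-%m-%dT%H:%M:%SZ"

format_iso <- function(ts) format(ts, iso_format, tz = "UTC")

parse_iso <- function(x, path, column) {
  ts <- as.POSIXct(x, format = iso_format, tz = "UTC")
  alt <- is.na(ts)
  if (any(alt))
    ts[alt] <- as.POSIXct(x[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  if (anyNA(ts))
    stop("unparseable ", column, " timestamp(s) in '", path, "' at row(s): ",
         paste(utils::head(which(is.na(ts)), 5), collapse = ", "),
         call. = FALSE)
  ts
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read and write 15-min light logger tables
#'
#' Columns: `timestamp` (ISO-8601), `ppfd`; optional `sensor`, `species`,
#' `position`. Negative PPFD rows are rejected with their row numbers; an
#' empty table yields an empty series with a warning.
#'
#' @param path CSV file path.
#' @return [read_light_csv()]: a [light_series()]; writers return the path
#'   invisibly.
#' @export
read_light_csv <- function(path) {
  df <- read_table_checked(path, c("timestamp", "ppfd"))
  if (nrow(df) == 0L) {
    warning("empty light table: '", path, "'", call. = FALSE)
    return(light_series(as.POSIXct(character(), tz = "UTC"), numeric()))
  }
  bad <- which(!is.finite(df$ppfd) | df$ppfd < 0)
  if (length(bad))
    stop("negative or non-finite ppfd in '", path, "' at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  light_series(parse_iso(df$timestamp, path, "timestamp"), df$ppfd,
               sensor = if ("sensor" %in% names(df)) df$sensor[1] else NA_character_,
               species = if ("species" %in% names(df)) df$species[1] else NA_character_,
               position = if ("position" %in% names(df)) df$position[1] else NA_character_)
}

#' @rdname read_light_csv
#' @param series A [light_series()].
#' @export
write_light_csv <- function(series, path) {
  df <- data.frame(timestamp = format_iso(series$timestamp),
                   ppfd = series$ppfd,
                   sensor = attr(series, "sensor"),
                   species = attr(series, "species"),
                   position = attr(series, "position"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write hourly temperature tables
#'
#' Columns: `timestamp` (ISO-8601), `temp_c`.
#'
#' @param path CSV file path.
#' @return [read_temperature_csv()]: a [temperature_series()].
#' @export
read_temperature_csv <- function(path) {
  df <- read_table_checked(path, c("timestamp", "temp_c"))
  if (nrow(df) == 0L) {
    warning("empty temperature table: '", path, "'", call. = FALSE)
    return(temperature_series(as.POSIXct(character(), tz = "UTC"), numeric()))
  }
  temperature_series(parse_iso(df$timestamp, path, "timestamp"), df$temp_c)
}

#' @rdname read_temperature_csv
#' @param series A [temperature_series()].
#' @export
write_temperature_csv <- function(series, path) {
  df <- data.frame(timestamp = format_iso(series$timestamp),
                   temp_c = series$temp_c)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write gas-exchange tables
#'
#' Columns: `curve_id`, `species`, `position`, `ppfd`, `pn`; one file can
#' hold many curves.
#'
#' @param path CSV file path.
#' @return [read_gas_exchange_csv()]: a named list of
#'   [gas_exchange_curve()] objects, one per `curve_id`.
#' @export
read_gas_exchange_csv <- function(path) {
  df <- read_table_checked(path, c("curve_id", "species", "position",
                                   "ppfd", "pn"))
  if (nrow(df) == 0L) {
    warning("empty gas-exchange table: '", path, "'", call. = FALSE)
    return(list())
  }
  bad <- which(!is.finite(df$ppfd) | df$ppfd < 0)
  if (length(bad))
    stop("negative or non-finite ppfd in '", path, "' at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  lapply(split(df, df$curve_id), function(d) {
    gas_exchange_curve(d$ppfd, d$pn, species = d$species[1],
                       position = d$position[1], curve_id = d$curve_id[1])
  })
}

#' @rdname read_gas_exchange_csv
#' @param curves A list of [gas_exchange_curve()] objects.
#' @export
write_gas_exchange_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(curve_id = attr(cv, "curve_id"), species = attr(cv, "species"),
               position = attr(cv, "position"), ppfd = cv$ppfd, pn = cv$pn)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write branch tables
#'
#' Columns: `tree_id`, `species`, `position`, `leaf_area_m2`, `leaf_mass_g`,
#' `twig_mass_g`, `leaf_c_frac`, `twig_c_frac`, `budbreak`, `discoloration`,
#' `habit`, `lifespan_years`. Dates ISO-8601 (`YYYY-MM-DD`); `discoloration`
#' and `lifespan_years` may be empty where the leaf habit does not define
#' them.
#'
#' @param path CSV file path.
#' @return [read_branch_csv()]: a list of [branch_record()] objects.
#' @export
read_branch_csv <- function(path) {
  cols <- c("tree_id", "species", "position", "leaf_area_m2", "leaf_mass_g",
            "twig_mass_g", "leaf_c_frac", "twig_c_frac", "budbreak",
            "discoloration", "habit", "lifespan_years")
  df <- read_table_checked(path, cols)
  if (nrow(df) == 0L) {
    warning("empty branch table: '", path, "'", call. = FALSE)
    return(list())
  }
  blank <- function(x) is.na(x) | as.character(x) == ""
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    tryCatch(
      branch_record(r$tree_id, r$species, r$position, r$leaf_area_m2,
                    r$leaf_mass_g, r$twig_mass_g, r$leaf_c_frac,
                    r$twig_c_frac, as.Date(r$budbreak),
                    as.Date(if (blank(r$discoloration)) NA
                            else as.character(r$discoloration)),
                    habit = r$habit,
                    lifespan_years = if (blank(r$lifespan_years))
                      NA_integer_ else as.integer(r$lifespan_years)),
      error = function(e)
        stop("invalid branch record in '", path, "' at row ", i, ": ",
             conditionMessage(e), call. = FALSE)
    )
  })
}

branch_records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(tree_id = r$tree_id, species = r$species,
               position = r$position, leaf_area_m2 = r$leaf_area_m2,
               leaf_mass_g = r$leaf_mass_g, twig_mass_g = r$twig_mass_g,
               leaf_c_frac = r$leaf_c_frac, twig_c_frac = r$twig_c_frac,
               budbreak = format(r$budbreak),
               discoloration = ifelse(is.na(r$discoloration), "",
                                      format(r$discoloration)),
               habit = r$habit,
               lifespan_years = ifelse(is.na(r$lifespan_years), "",
                                       as.character(r$lifespan_years)))
  }))
}

#' @rdname read_branch_csv
#' @param records A list of [branch_record()] objects.
#' @export
write_branch_csv <- function(records, path) {
  utils::write.csv(branch_records_to_df(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write starch tables
#'
#' Columns: `tree_id` (or species-level id), `species`, `position`, `basis`,
#' `amplitude_g_per_g`, `window_start`, `window_end`, `tissue_mass_g`.
#'
#' @param path CSV file path.
#' @return [read_starch_csv()]: a list of [starch_dynamics()] objects.
#' @export
read_starch_csv <- function(path) {
  cols <- c("species", "position", "basis", "amplitude_g_per_g",
            "window_start", "window_end", "tissue_mass_g")
  df <- read_table_checked(path, cols)
  if (nrow(df) == 0L) {
    warning("empty starch table: '", path, "'", call. = FALSE)
    return(list())
  }
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    tryCatch(
      starch_dynamics(r$amplitude_g_per_g, as.Date(r$window_start),
                      as.Date(r$window_end), basis = r$basis,
                      tissue_mass_g = r$tissue_mass_g, species = r$species,
                      position = r$position),
      error = function(e)
        stop("invalid starch record in '", path, "' at row ", i, ": ",
             conditionMessage(e), call. = FALSE)
    )
  })
}

#' @rdname read_starch_csv
#' @param dynamics A list of [starch_dynamics()] objects.
#' @export
write_starch_csv <- function(dynamics, path) {
  df <- do.call(rbind, lapply(dynamics, function(d) {
    data.frame(species = d$species, position = d$position, basis = d$basis,
               amplitude_g_per_g = d$amplitude,
               window_start = format(d$window_start),
               window_end = format(d$window_end),
               tissue_mass_g = d$tissue_mass_g)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
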