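catch_cols <- c("year", "month", "fleet", "species_code", "lat", "lon",
                "depth_m", "catch_t", "days_at_sea", "fishing_days", "hauls")
catch_required <- c("year", "fleet", "species_code", "catch_t")

#' Read a landing-record table
#'
#' CSV dialect: UTF-8, "." decimal, one row per landing record with columns
#' `year, month, fleet, species_code, lat, lon, depth_m, catch_t,
#' days_at_sea, fishing_days, hauls` (coordinates in signed decimal
#' degrees, south/west negative). Rows with a missing year, a missing or
#' negative catch, or an unknown fleet are rejected; their line numbers are
#' returned in attribute `"rejected"`.
#'
#' @param path CSV file path.
#' @param fleets Allowed fleet codes, default `c("VIC", "VRB")`.
#' @return Data frame of typed records with attribute `"rejected"` (integer
#'   file line numbers of dropped rows).
#' @export
read_catch_table <- function(path, fleets = c("VIC", "VRB")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(catch_required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(catch_cols, names(df))) df[[col]] <- NA
  suppress_to_na <- function(x) suppressWarnings(as.numeric(x))
  df$year <- suppress_to_na(df$year)
  df$catch_t <- suppress_to_na(df$catch_t)
  for (col in c("month", "lat", "lon", "depth_m", "days_at_sea",
                "fishing_days", "hauls")) {
    df[[col]] <- suppress_to_na(df[[col]])
  }
  bad <- is.na(df$year) | is.na(df$catch_t) | df$catch_t < 0 |
    !(df$fleet %in% fleets)
  out <- df[!bad, catch_cols, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad) + 1L   # header is line 1
  out
}

#' Write a landing-record table
#'
#' @param records Data frame of landing records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_catch_table <- function(records, path) {
  utils::write.csv(records[, intersect(catch_cols, names(records)),
                           drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a diet-composition matrix from CSV
#'
#' Dialect: first column `prey` holds prey codes, remaining columns are
#' predator codes, cells are diet fractions; an optional `IMPORT` prey row
#' gives the diet fraction taken from outside the system.
#'
#' @param path CSV file path.
#' @param roles Named role vector (`producer`/`consumer`/`detritus`) per
#'   group code; by default every all-zero column is a producer unless its
#'   code is `DET` (detritus), and every other group a consumer.
#' @return A [diet_matrix()].
#' @export
read_diet_csv <- function(path, roles = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "prey") stop("first column must be 'prey'",
                                   call. = FALSE)
  prey <- df$prey
  mat <- as.matrix(df[, -1, drop = FALSE])
  imp_row <- which(prey == "IMPORT")
  import <- NULL
  if (length(imp_row) == 1L) {
    import <- mat[imp_row, ]
    mat <- mat[-imp_row, , drop = FALSE]
    prey <- prey[-imp_row]
  }
  if (!setequal(prey, colnames(mat))) {
    stop("prey and predator codes must coincide", call. = FALSE)
  }
  mat <- mat[match(colnames(mat), prey), , drop = FALSE]
  rownames(mat) <- colnames(mat)
  if (is.null(roles)) {
    zero <- colSums(mat) + (if (is.null(import)) 0 else import) == 0
    roles <- ifelse(zero & colnames(mat) == "DET", "detritus",
                    ifelse(zero, "producer", "consumer"))
  } else {
    roles <- roles[colnames(mat)]
  }
  diet_matrix(mat, unname(roles), import = import)
}

#' Write a diet-composition matrix to CSV
#'
#' @param diet A [diet_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diet_csv <- function(diet, path) {
  stopifnot(inherits(diet, "diet_matrix"))
  df <- data.frame(prey = diet$codes, diet$dc, check.names = FALSE)
  if (any(diet$import > 0)) {
    imp <- data.frame(prey = "IMPORT", t(diet$import), check.names = FALSE)
    df <- rbind(df, imp)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a functional-group parameter table from CSV
#'
#' Columns `code, name, role, B, PB, QB, EE, catch, export` (missing
#' `role` is inferred: `DET` is detritus, groups with `QB` are consumers,
#' the rest producers; missing `catch` defaults to `VIC + VRB` columns when
#' present, else 0).
#'
#' @param path CSV file path.
#' @return A [group_params()] table.
#' @export
read_groups_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"code" %in% names(df)) stop("missing required column: code",
                                   call. = FALSE)
  if (!"role" %in% names(df)) {
    df$role <- ifelse(df$code == "DET", "detritus",
                      ifelse(!is.na(df$QB), "consumer", "producer"))
  }
  if (!"catch" %in% names(df)) {
    vic <- if ("VIC" %in% names(df)) ifelse(is.na(df$VIC), 0, df$VIC) else 0
    vrb <- if ("VRB" %in% names(df)) ifelse(is.na(df$VRB), 0, df$VRB) else 0
    df$catch <- vic + vrb
  }
  if (!"export" %in% names(df)) df$export <- 0
  if (!"name" %in% names(df)) df$name <- df$code
  group_params(code = df$code, role = df$role, B = df$B, PB = df$PB,
               QB = df$QB, EE = df$EE, catch = df$catch,
               export = df$export, name = df$name)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' subcommand, input paths, seed, parameters, package version and R
#' version.
#'
#' @param path Output JSON path.
#' @param subcommand Name of the pipeline step.
#' @param inputs Named list/vector of input paths.
#' @param seed Integer seed (or `NULL`).
#' @param params Named list of tunable parameters.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, inputs = list(), seed = NULL,
                           params = list()) {
  manifest <- list(
    subcommand = subcommand,
    inputs = inputs,
    seed = seed,
    params = params,
    package_version = as.character(utils::packageVersion("fishweb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
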