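#' Read a cancer-registry case table
#'
#' Parses a delimited text file (tab or comma, auto-detected from the header
#' line) with one row per diagnosed case. Required columns: `case_id`,
#' `tract_key`, `address_type`, `age_dx`, `year_dx`, `stage`, `gleason`,
#' `race`. Empty cells and the literal string `NA` are read as missing.
#'
#' @param path Path to the registry file.
#' @return A `data.frame` with one row per input row (order preserved) and the
#'   columns above; `age_dx`, `year_dx`, `stage`, `gleason` are numeric with
#'   `NA` for missing, the rest character.
#' @export
read_registry <- function(path) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", na.strings = c("", "NA"),
                          quote = "\"", comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("case_id", "tract_key", "address_type", "age_dx", "year_dx",
                "stage", "gleason", "race")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("registry file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  for (col in c("age_dx", "year_dx", "stage", "gleason")) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop("non-numeric ", col, " in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    df[[col]] <- val
  }
  bad_stage <- which(!is.na(df$stage) & !(df$stage %in% 1:4))
  if (length(bad_stage)) {
    stop("stage outside 1..4 in row(s): ",
         paste(utils::head(bad_stage, 10L), collapse = ", "), call. = FALSE)
  }
  bad_gl <- which(!is.na(df$gleason) & (df$gleason < 2 | df$gleason > 10))
  if (length(bad_gl)) {
    stop("gleason outside 2..10 in row(s): ",
         paste(utils::head(bad_gl, 10L), collapse = ", "), call. = FALSE)
  }
  bad_addr <- which(!is.na(df$address_type) &
                      !(df$address_type %in% c("street", "po_box")))
  if (length(bad_addr)) {
    stop("address_type must be 'street' or 'po_box'; bad row(s): ",
         paste(utils::head(bad_addr, 10L), collapse = ", "), call. = FALSE)
  }
  df
}

#' Construct an exposure table
#'
#' An exposure table holds one row per census tract and one column per
#' area-level variable, together with a missingness mask and optional
#' human-readable variable descriptions.
#'
#' @param values Numeric matrix, tracts in rows, variables in columns. `NA`
#'   entries are missing.
#' @param tract_keys Character vector of tract keys (row identity).
#' @param variable_ids Character vector of variable identifiers (column
#'   identity).
#' @param variable_meta Optional named character vector mapping variable id to
#'   description.
#' @return An object of class `exposure_table` with elements `tract_keys`,
#'   `variable_ids`, `values` (finite where not masked), `missing_mask`,
#'   `variable_meta`.
#' @export
exposure_table <- function(values, tract_keys, variable_ids,
                           variable_meta = NULL) {
  values <- as.matrix(values)
  if (anyDuplicated(tract_keys)) {
    stop("duplicate tract keys: ",
         paste(unique(tract_keys[duplicated(tract_keys)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(variable_ids)) {
    stop("duplicate variable ids", call. = FALSE)
  }
  stopifnot(nrow(values) == length(tract_keys),
            ncol(values) == length(variable_ids))
  mask <- is.na(values)
  if (any(!is.finite(values[!mask]))) {
    stop("non-finite exposure values outside the missing mask", call. = FALSE)
  }
  dimnames(values) <- list(tract_keys, variable_ids)
  structure(list(tract_keys = as.character(tract_keys),
                 variable_ids = as.character(variable_ids),
                 values = values,
                 missing_mask = mask,
                 variable_meta = variable_meta),
            class = "exposure_table")
}

#' @export
print.exposure_table <- function(x, ...) {
  cat(sprintf("Exposure table: %d tracts x %d variables (%.1f%% missing)\n",
              length(x$tract_keys), length(x$variable_ids),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.exposure_table <- function(x) dim(x$values)

#' Read an exposure table from a delimited file
#'
#' The first column must hold the tract key; every remaining column is an
#' area-level variable. Empty cells and `NA` are missing.
#'
#' @param path Path to the file.
#' @return An [exposure_table()].
#' @export
read_exposures <- function(path) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          na.strings = c("", "NA"), quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("exposure file needs a key column plus >=1 variable",
                          call. = FALSE)
  keys <- as.character(df[[1L]])
  vals <- as.matrix(df[-1L])
  storage.mode(vals) <- "double"
  exposure_table(vals, keys, colnames(df)[-1L])
}

#' Write an exposure table
#'
#' Rows are written sorted by tract key so output is diff-stable; missing
#' entries are written as empty cells.
#'
#' @param x An [exposure_table()].
#' @param path Output path; tab-delimited.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(x, path) {
  ord <- order(x$tract_keys)
  vals <- x$values[ord, , drop = FALSE]
  df <- data.frame(tract_key = x$tract_keys[ord], vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read study geography: tract-to-county map and county adjacency
#'
#' @param tract_map_path Two-column delimited file `tract_key`, `county_key`.
#' @param adjacency_path Text file with one undirected county pair per line
#'   (whitespace- or comma-separated). Pairs listed in both directions collapse
#'   to a single edge; self-loops are an error. Counties appearing only in the
#'   tract map are retained as islands (degree 0).
#' @return An object of class `geography`: `tract_to_county` (named character
#'   vector), `counties`, `edges` (2-column character matrix, each undirected
#'   edge once), `n_neighbors` (named integer vector).
#' @export
read_geography <- function(tract_map_path, adjacency_path) {
  delim <- detect_delim(tract_map_path)
  tm <- utils::read.table(tract_map_path, header = TRUE, sep = delim,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tm) < 2L) stop("tract map needs two columns", call. = FALSE)
  lines <- readLines(adjacency_path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  edges <- if (length(lines)) {
    parts <- strsplit(lines, "[,\t ]+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) stop("malformed adjacency line(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "),
                          call. = FALSE)
    do.call(rbind, parts)
  } else {
    matrix(character(0), ncol = 2L)
  }
  geography(tract_to_county = stats::setNames(tm[[2L]], tm[[1L]]),
            edges = edges)
}

#' Construct a geography object
#'
#' @param tract_to_county Named character vector: names are tract keys, values
#'   county keys.
#' @param edges Two-column character matrix of undirected county pairs (either
#'   direction; duplicates collapse).
#' @return A `geography` object; see [read_geography()].
#' @export
geography <- function(tract_to_county, edges) {
  edges <- matrix(as.character(edges), ncol = 2L)
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("adjacency contains self-loop(s): ",
         paste(unique(edges[edges[, 1L] == edges[, 2L], 1L]), collapse = ", "),
         call. = FALSE)
  }
  # canonical order inside each pair, then dedupe: symmetric closure
  key <- ifelse(edges[, 1L] < edges[, 2L],
                paste(edges[, 1L], edges[, 2L], sep = "\r"),
                paste(edges[, 2L], edges[, 1L], sep = "\r"))
  keep <- !duplicated(key)
  edges <- edges[keep, , drop = FALSE]
  swap <- edges[, 1L] > edges[, 2L]
  edges[swap, ] <- edges[swap, c(2L, 1L)]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  counties <- sort(unique(c(unname(tract_to_county), as.vector(edges))))
  deg <- table(factor(as.vector(edges), levels = counties))
  structure(list(tract_to_county = tract_to_county,
                 counties = counties,
                 edges = edges,
                 n_neighbors = stats::setNames(as.integer(deg), counties)),
            class = "geography")
}

#' @export
print.geography <- function(x, ...) {
  cat(sprintf("Geography: %d tracts, %d counties, %d adjacency edges\n",
              length(x$tract_to_county), length(x$counties), nrow(x$edges)))
  invisible(x)
}

#' Write geography files
#'
#' @param x A `geography` object.
#' @param tract_map_path,adjacency_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_geography <- function(x, tract_map_path, adjacency_path) {
  tm <- data.frame(tract_key = names(x$tract_to_county),
                   county_key = unname(x$tract_to_county))
  tm <- tm[order(tm$tract_key), ]
  utils::write.table(tm, tract_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste(x$edges[, 1L], x$edges[, 2L], sep = "\t"), adjacency_path)
  invisible(c(tract_map_path, adjacency_path))
}

#' Link registry cases to tract exposures and county geography
#'
#' Every case's `tract_key` must be present in both the exposure table and the
#' tract-to-county map; unmatched keys are a hard error (never a silent drop),
#' so any case loss is auditable through the preprocessing exclusion log. The
#' county of a case is the geography lookup of its tract key; by the FIPS
#' convention this equals the first five characters of the key.
#'
#' @param records Registry `data.frame` (already filtered and labeled; must
#'   carry an `outcome` column with values `"aggressive"`/`"non_aggressive"`,
#'   see [label_outcome()]).
#' @param exposures An [exposure_table()].
#' @param geo A `geography` object.
#' @return An object of class `linked_dataset`: `y` (0/1 integer, 1 =
#'   aggressive), `age_dx`, `year_dx`, `tract` and `county` (integer indices),
#'   `tract_keys`, `county_keys` (index level orders), `exposures` (the
#'   exposure table, unchanged), `case_id`.
#' @export
link_by_key <- function(records, exposures, geo) {
  if (!"outcome" %in% names(records)) {
    records$outcome <- label_outcome(records)
  }
  unmatched <- setdiff(unique(records$tract_key), exposures$tract_keys)
  if (length(unmatched)) {
    stop("tract key(s) absent from exposure table: ",
         paste(utils::head(sort(unmatched), 10L), collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(unique(records$tract_key), names(geo$tract_to_county))
  if (length(unmapped)) {
    stop("tract key(s) absent from geography: ",
         paste(utils::head(sort(unmapped), 10L), collapse = ", "),
         call. = FALSE)
  }
  tract_levels <- exposures$tract_keys
  tract <- match(records$tract_key, tract_levels)
  county_of_tract <- unname(geo$tract_to_county[tract_levels])
  county_levels <- geo$counties
  county <- match(county_of_tract, county_levels)[tract]
  structure(list(y = as.integer(records$outcome == "aggressive"),
                 age_dx = records$age_dx,
                 year_dx = records$year_dx,
                 tract = tract,
                 county = county,
                 tract_keys = tract_levels,
                 county_keys = county_levels,
                 exposures = exposures,
                 case_id = records$case_id),
            class = "linked_dataset")
}

#' @export
print.linked_dataset <- function(x, ...) {
  cat(sprintf(
    "Linked dataset: %d cases (%d aggressive) in %d tracts / %d counties; %d variables\n",
    length(x$y), sum(x$y), length(unique(x$tract)),
    length(unique(x$county)), length(x$exposures$variable_ids)))
  invisible(x)
}
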