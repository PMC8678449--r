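#' Trap-count datasets
#'
#' A `trap_data` object is a validated long-format data frame of trap counts:
#' one row per trap x observation date x instar. It is the common input to
#' every analysis stage (dispersion summaries, patchiness regression,
#' temporal correlation, power tables).
#'
#' Required columns:
#' \describe{
#'   \item{site}{site label.}
#'   \item{plot}{plot label within site.}
#'   \item{trap_id}{trap (tree) label, unique within plot.}
#'   \item{date}{observation date (`Date`; serialized ISO-8601).}
#'   \item{instar}{one of `"1"`, `"2"`, `"3"`, `"4"`, `"combined"`.}
#'   \item{count}{non-negative integer nymph count.}
#' }
#' Optional columns: `dbh_cm` (tree diameter at breast height, cm, > 0),
#' `band_width_cm` (exposed sticky band width, cm, > 0), `foam_width_cm`
#' (width of the foam spacer between film and bark, cm, >= 0), and
#' `treatment` (arm label, e.g. `"control"`).
#'
#' @param x data frame with the columns above.
#' @param metadata optional named list of free-form metadata (units,
#'   location, year); stored as an attribute and preserved by
#'   [write_trap_csv()]/[read_trap_csv()] round trips only in memory.
#' @return `trap_data` object (a data frame).
#' @examples
#' df <- data.frame(site = "A", plot = "p1", trap_id = c("t1", "t2"),
#'                  date = as.Date("2020-06-11"), instar = "combined",
#'                  count = c(10L, 3L))
#' ds <- trap_data(df)
#' nrow(ds)
#' @export
trap_data <- function(x, metadata = list()) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("site", "plot", "trap_id", "date", "instar", "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$site <- as.character(x$site)
  x$plot <- as.character(x$plot)
  x$trap_id <- as.character(x$trap_id)
  if (!inherits(x$date, "Date")) {
    d <- as.Date(as.character(x$date), format = "%Y-%m-%d")
    if (anyNA(d) && !anyNA(x$date)) {
      stop("column 'date' is not ISO-8601 (YYYY-MM-DD); first bad row: ",
           which(is.na(d))[1L])
    }
    x$date <- d
  }
  x$instar <- as.character(x$instar)
  bad_instar <- !x$instar %in% c("1", "2", "3", "4", "combined")
  if (any(bad_instar)) {
    stop("invalid instar value(s) in row(s): ",
         paste(utils::head(which(bad_instar), 5L), collapse = ", "),
         " (allowed: 1, 2, 3, 4, combined)")
  }
  cnt <- suppressWarnings(as.numeric(x$count))
  bad <- is.na(cnt) | cnt < 0 | cnt != floor(cnt)
  if (any(bad)) {
    stop("column 'count' must be a non-negative integer; bad row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  x$count <- as.integer(cnt)
  for (col in c("dbh_cm", "band_width_cm", "foam_width_cm")) {
    if (col %in% names(x)) x[[col]] <- as.numeric(x[[col]])
  }
  if ("dbh_cm" %in% names(x) && any(!is.na(x$dbh_cm) & x$dbh_cm <= 0)) {
    stop("dbh_cm must be > 0 where present")
  }
  key <- paste(x$site, x$plot, x$trap_id, x$date, x$instar, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (site, plot, trap_id, date, instar) key; first at row ",
         which(duplicated(key))[1L])
  }
  rownames(x) <- NULL
  structure(x, metadata = metadata, class = c("trap_data", "data.frame"))
}

#' @export
as.data.frame.trap_data <- function(x, ...) {
  attr(x, "metadata") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.trap_data <- function(x, ...) {
  cat(sprintf(
    "trap_data: %d records, %d site(s), %d date(s), instars: %s\n",
    nrow(x), length(unique(x$site)), length(unique(x$date)),
    paste(sort(unique(x$instar)), collapse = ", ")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

# Canonical column order for serialized trap CSVs.
trap_csv_columns <- function() {
  c("site", "plot", "trap_id", "date", "instar", "count",
    "dbh_cm", "band_width_cm", "foam_width_cm", "treatment")
}

#' Read a trap-count CSV
#'
#' Reads an RFC-4180 CSV of long-format trap counts and validates it into a
#' [trap_data] object. Columns with non-canonical names can be mapped via
#' `schema`; dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' @param path path to an existing CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(trap_id = "tree", count = "nymphs")`.
#' @return [trap_data] object.
#' @seealso [write_trap_csv()], which this inverts exactly.
#' @export
read_trap_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == "")) {
      stop("schema must be a fully named character vector")
    }
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("schema maps '", canonical, "' to missing column '", src, "'")
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  required <- c("site", "plot", "trap_id", "date", "instar", "count")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(trap_csv_columns(), names(raw))
  trap_data(raw[keep], metadata = list(source = path))
}

#' Write a trap-count CSV
#'
#' Serializes a [trap_data] object as RFC-4180 CSV with the fixed column
#' order `site, plot, trap_id, date, instar, count, dbh_cm, band_width_cm,
#' foam_width_cm, treatment` (optional columns omitted when absent). Dates
#' are written ISO-8601. [read_trap_csv()] inverts this exactly.
#'
#' @param ds [trap_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trap_csv <- function(ds, path) {
  stopifnot(inherits(ds, "trap_data"))
  cols <- intersect(trap_csv_columns(), names(ds))
  out <- as.data.frame(ds)[, cols, drop = FALSE]
  out$date <- format(out$date, "%Y-%m-%d")
  status <- try(utils::write.csv(out, path, row.names = FALSE,
                                 quote = TRUE), silent = TRUE)
  if (inherits(status, "try-error")) {
    stop("cannot write trap CSV to ", path, ": ",
         attr(status, "condition")$message)
  }
  invisible(path)
}

#' Add combined-instar rows
#'
#' Ensures the dataset carries `"combined"` instar rows for every
#' (site, plot, trap_id, date). Where explicit `"combined"` rows exist they
#' win; derived rows (the sum of the per-instar counts) fill the rest. If a
#' dataset mixes explicit and derived totals a warning is issued.
#'
#' @param ds [trap_data] object.
#' @return [trap_data] object containing `"combined"` rows for every trap
#'   x date present.
#' @export
with_combined_instar <- function(ds) {
  stopifnot(inherits(ds, "trap_data"))
  per_instar <- ds[ds$instar != "combined", , drop = FALSE]
  explicit <- ds[ds$instar == "combined", , drop = FALSE]
  if (nrow(per_instar) == 0L) return(ds)
  key <- function(d) paste(d$site, d$plot, d$trap_id, d$date, sep = "\r")
  agg <- stats::aggregate(count ~ site + plot + trap_id + date,
                          data = as.data.frame(per_instar), FUN = sum)
  agg$instar <- "combined"
  extra <- setdiff(c("dbh_cm", "band_width_cm", "foam_width_cm", "treatment"),
                   names(agg))
  extra <- intersect(extra, names(ds))
  if (length(extra) > 0L) {
    meta <- as.data.frame(per_instar)[!duplicated(key(per_instar)),
                                      c("site", "plot", "trap_id", "date",
                                        extra), drop = FALSE]
    agg <- merge(agg, meta, by = c("site", "plot", "trap_id", "date"),
                 sort = FALSE)
  }
  if (nrow(explicit) > 0L) {
    dup <- key(agg) %in% key(explicit)
    if (any(dup)) {
      warning("explicit 'combined' rows present for ", sum(dup),
              " trap-date(s); they take precedence over derived sums")
      agg <- agg[!dup, , drop = FALSE]
    }
  }
  out <- rbind(as.data.frame(ds)[names(ds)],
               as.data.frame(agg)[, names(ds), drop = FALSE])
  out <- out[order(out$site, out$plot, out$trap_id, out$date, out$instar), ]
  trap_data(out, metadata = attr(ds, "metadata"))
}
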