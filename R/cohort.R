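#' Canonical measurement columns of a specimen cohort
#'
#' Internal registry of the canonical column names, their physical quantity
#' class and their canonical unit. All analysis functions operate on these
#' names; [read_cohort()] maps arbitrary source headers onto them.
#'
#' @keywords internal
#' @noRd
.cohort_schema <- function() {
  data.frame(
    field = c("specimen_id", "cbl", "msw", "iw",
              "v_cav", "v_mal", "v_inc", "v_stp", "v_lab",
              "a_tm", "a_fp", "d1", "d2", "malleus_length",
              "cochlear_turns", "role"),
    class = c("id", "length", "length", "length",
              "volume", "volume", "volume", "volume", "volume",
              "area", "area", "length", "length", "length",
              "count", "flag"),
    unit = c(NA, "mm", "mm", "mm",
             "mm^3", "mm^3", "mm^3", "mm^3", "mm^3",
             "mm^2", "mm^2", "mm", "mm", "mm",
             "turns", NA),
    stringsAsFactors = FALSE
  )
}

#' Names of the measurement (numeric) cohort columns
#' @keywords internal
#' @noRd
.measurement_fields <- function() {
  s <- .cohort_schema()
  s$field[s$class %in% c("length", "volume", "area")]
}

#' Default ear traits entering the scaling analysis
#'
#' The seven ear measurements regressed on skull size: middle-ear cavity,
#' malleus, incus, stapes and bony-labyrinth volumes, plus tympanic-membrane
#' and stapes-footplate areas.
#'
#' @return Character vector of canonical trait names.
#' @export
ear_traits <- function() {
  c("v_cav", "v_mal", "v_inc", "v_stp", "v_lab", "a_tm", "a_fp")
}

#' Unit conversion factors to canonical mm-based units
#' @keywords internal
#' @noRd
.unit_factor <- function(unit, field) {
  factors <- c("mm" = 1, "mm^2" = 1, "mm^3" = 1, "mm2" = 1, "mm3" = 1,
               "mL" = 1000, "ml" = 1000, "turns" = 1)
  if (!unit %in% names(factors)) {
    stop(sprintf("unknown unit '%s' for column '%s'", unit, field),
         call. = FALSE)
  }
  if (unit %in% c("mL", "ml") && !startsWith(field, "v_")) {
    stop(sprintf("unit 'mL' is only valid for volume columns, not '%s'",
                 field), call. = FALSE)
  }
  unname(factors[unit])
}

#' Construct a specimen cohort
#'
#' Assembles a validated cohort from a data frame of per-specimen skull and
#' ear measurements, already in canonical units (lengths mm, areas mm^2,
#' volumes mm^3). Missing optional columns are added as `NA`; `role` defaults
#' to `"fit"`. Specimens marked `role = "projected"` (e.g. a mongrel or wolf
#' kept for comparison) are excluded from all regression fitting but can be
#' projected onto fitted lines afterwards.
#'
#' @param data Data frame with at least `specimen_id` and `cbl` columns; any
#'   subset of the canonical measurement columns (see [ear_traits()], plus
#'   `msw`, `iw`, `d1`, `d2`, `malleus_length`, `cochlear_turns`).
#' @param source Free-text provenance label.
#' @param unit_system Optional named character vector recording the original
#'   unit of each source column (informational; values are assumed canonical).
#' @return An object of class `ear_cohort` (a data frame subclass).
#' @examples
#' ch <- cohort(data.frame(specimen_id = c("a", "b"), cbl = c(90, 240),
#'                         v_cav = c(320, 4540)))
#' nrow(ch)
#' @export
cohort <- function(data, source = "in-memory", unit_system = NULL) {
  stopifnot(is.data.frame(data))
  schema <- .cohort_schema()
  if (!"specimen_id" %in% names(data)) {
    stop("cohort requires a 'specimen_id' column", call. = FALSE)
  }
  unknown <- setdiff(names(data), schema$field)
  if (length(unknown)) {
    stop("unknown cohort columns: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(specimen_id = as.character(data$specimen_id),
                    stringsAsFactors = FALSE)
  for (f in setdiff(schema$field, c("specimen_id", "role"))) {
    out[[f]] <- if (f %in% names(data)) as.numeric(data[[f]]) else NA_real_
  }
  out$role <- if ("role" %in% names(data)) as.character(data$role) else "fit"
  out$role[is.na(out$role)] <- "fit"
  class(out) <- c("ear_cohort", "data.frame")
  attr(out, "source") <- source
  attr(out, "unit_system") <- unit_system
  validate_cohort(out)
  out
}

#' Validate a cohort
#'
#' Checks the structural invariants: unique specimen identifiers, strictly
#' positive measurements where present, tympanic-membrane area exceeding
#' footplate area when both are present, and roles restricted to
#' `fit`/`projected`.
#'
#' @param x An `ear_cohort`.
#' @return `x`, invisibly, or an error naming the offending row and column.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "ear_cohort"))
  if (anyDuplicated(x$specimen_id)) {
    dup <- unique(x$specimen_id[duplicated(x$specimen_id)])
    stop("duplicate specimen_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(x$role), c("fit", "projected"))
  if (length(bad_role)) {
    stop("invalid role value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  for (f in .measurement_fields()) {
    v <- x[[f]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive value in column '%s', specimen '%s'",
                   f, x$specimen_id[bad[1]]), call. = FALSE)
    }
  }
  both <- !is.na(x$a_tm) & !is.na(x$a_fp)
  if (any(both & x$a_tm <= x$a_fp)) {
    bad <- x$specimen_id[which(both & x$a_tm <= x$a_fp)[1]]
    stop(sprintf(
      "tympanic membrane area must exceed footplate area (specimen '%s')",
      bad), call. = FALSE)
  }
  ct <- x$cochlear_turns
  if (any(!is.na(ct) & ct <= 0)) {
    stop("cochlear_turns must be positive where present", call. = FALSE)
  }
  invisible(x)
}

#' Traits missing for each specimen
#'
#' @param x An `ear_cohort`.
#' @return Named list mapping each specimen_id to the character vector of
#'   measurement fields that are absent (`NA`) for it.
#' @export
missing_traits <- function(x) {
  stopifnot(inherits(x, "ear_cohort"))
  fields <- .measurement_fields()
  out <- lapply(seq_len(nrow(x)), function(i) {
    fields[vapply(fields, function(f) is.na(x[[f]][i]), logical(1))]
  })
  names(out) <- x$specimen_id
  out
}

#' Specimens used for regression fitting
#' @param x An `ear_cohort`.
#' @return The subset of `x` with `role == "fit"`.
#' @export
fit_specimens <- function(x) {
  stopifnot(inherits(x, "ear_cohort"))
  x[x$role == "fit", , drop = FALSE]
}

#' Read a cohort from a delimited text file
#'
#' Reads a delimiter-separated measurement table (comma by default, one header
#' row, RFC-4180 quoting as handled by [utils::read.csv()]) and maps its
#' columns onto the canonical cohort fields. Units declared per column are
#' normalized on input: lengths to mm, areas to mm^2, volumes to mm^3
#' (`1 mL = 1000 mm^3`; mL is accepted on input only). Cells that do not parse
#' as numbers become missing values for that specimen/trait.
#'
#' @param path Path to the delimited file.
#' @param schema A list describing the source layout:
#'   \describe{
#'     \item{columns}{named character vector, canonical field -> source
#'       header. Must include `specimen_id` and `cbl`.}
#'     \item{units}{optional named character vector, canonical field -> unit
#'       of that source column (`mm`, `mm^2`, `mm^3`, `mL`). Defaults to the
#'       canonical unit.}
#'     \item{roles}{optional named character vector, specimen_id -> role
#'       (`fit` or `projected`); unlisted specimens default to `fit`.}
#'   }
#'   May be produced from a YAML config file by [read_cohort_config()].
#' @param sep Field delimiter (default comma).
#' @return An `ear_cohort`.
#' @seealso [write_cohort()], [read_cohort_config()]
#' @export
read_cohort <- function(path, schema, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(schema$columns) || !is.character(schema$columns)) {
    stop("schema$columns must be a named character vector", call. = FALSE)
  }
  raw <- tryCatch(
    utils::read.csv(path, sep = sep, check.names = FALSE,
                    colClasses = "character", strip.white = TRUE),
    error = function(e) stop("schema error reading '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    stop("schema error: '", path, "' contains no data rows", call. = FALSE)
  }
  cols <- schema$columns
  mandatory <- c("specimen_id", "cbl")
  if (!all(mandatory %in% names(cols))) {
    stop("schema error: column mapping must include ",
         paste(setdiff(mandatory, names(cols)), collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(unname(cols), names(raw))
  if (length(absent)) {
    stop("schema error: mapped column(s) not in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(specimen_id = raw[[cols[["specimen_id"]]]],
                    stringsAsFactors = FALSE)
  units <- character(0)
  for (f in setdiff(names(cols), c("specimen_id", "role"))) {
    vals <- raw[[cols[[f]]]]
    num <- suppressWarnings(as.numeric(vals))
    # blank / sentinel / unparseable cells become missing traits
    unit <- if (!is.null(schema$units) && f %in% names(schema$units)) {
      schema$units[[f]]
    } else {
      .cohort_schema()$unit[.cohort_schema()$field == f]
    }
    if (f %in% .measurement_fields()) {
      num <- num * .unit_factor(unit, f)
      units[f] <- unit
    }
    bad <- which(!is.na(num) & num <= 0 & f %in% .measurement_fields())
    if (length(bad)) {
      stop(sprintf("validation error: non-positive '%s' in row %d (%s)",
                   f, bad[1], out$specimen_id[bad[1]]), call. = FALSE)
    }
    out[[f]] <- num
  }
  if ("role" %in% names(cols)) {
    out$role <- as.character(raw[[cols[["role"]]]])
  }
  if (!is.null(schema$roles)) {
    if (is.null(out$role)) out$role <- "fit"
    known <- intersect(names(schema$roles), out$specimen_id)
    out$role[match(known, out$specimen_id)] <- unname(schema$roles[known])
  }
  cohort(out, source = path, unit_system = units)
}

#' Read a cohort schema from a YAML config file
#'
#' The config is a key-value file with top-level keys `columns`, `units` and
#' `roles`, mirroring the `schema` argument of [read_cohort()].
#'
#' @param path Path to the YAML file.
#' @return A schema list suitable for [read_cohort()].
#' @export
read_cohort_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("columns", "units", "roles")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- unlist(cfg[[k]])
  }
  cfg
}

#' Write a cohort to a delimited text file
#'
#' Columns are written in the fixed canonical order with one header row;
#' missing values are encoded by the single sentinel token `NA`; numbers are
#' written with full precision (>= 6 significant digits) so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param x An `ear_cohort`.
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, sep = ",") {
  validate_cohort(x)
  schema <- .cohort_schema()
  extra <- setdiff(names(x), schema$field)   # derived columns, kept last
  out <- as.data.frame(x)[, c(schema$field, extra), drop = FALSE]
  for (f in names(out)) {
    if (is.numeric(out[[f]])) {
      out[[f]] <- ifelse(is.na(out[[f]]), NA,
                         sprintf("%.17g", out[[f]]))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = which(names(out) %in% c("specimen_id", "role")),
                       na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write '", path, "'", call. = FALSE)
  invisible(path)
}

#' Default schema matching write_cohort output
#'
#' Identity column mapping for files produced by [write_cohort()].
#' @return A schema list.
#' @export
canonical_schema <- function() {
  fields <- .cohort_schema()$field
  list(columns = stats::setNames(fields, fields))
}

#' @export
print.ear_cohort <- function(x, ...) {
  cat(sprintf("<ear_cohort> %d specimens (%d fit, %d projected), source: %s\n",
              nrow(x), sum(x$role == "fit"), sum(x$role == "projected"),
              attr(x, "source") %||% "unknown"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
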