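# Farm accounting records: schema, validation, delimited-text I/O and
# size-class assignment.
#
# A farm table is a plain data.frame, one row per farm. The mandatory columns
# are the four DEA inputs and the output; revenue components and per-ewe
# techno-economic fields are optional and encoded as NA when unavailable
# (never as zero -- a zero is a measured value).

.required_cols <- c("farm_id", "farm_type", "ewes", "labor",
                    "variable_cost", "fixed_cost", "gross_revenue")
.component_cols <- c("lambs_meat", "lambs_breeding", "culls",
                     "subsidies", "wool_other")
.technical_cols <- c("lambs_sold", "alu", "feed_kg_dm_per_ewe",
                     "labor_cost", "feed_cost", "purchased_feed",
                     "homegrown_feed", "variable_capital_cost",
                     "fixed_capital_cost")
.numeric_cols <- setdiff(c(.required_cols, .component_cols, .technical_cols),
                         c("farm_id", "farm_type"))

#' Recognised farm types
#'
#' The four production systems handled by the package: extensive and
#' intensive sheep meat farms in France, semi-intensive farms in Spain and
#' extensive farms in the UK. Each type is benchmarked against its own
#' frontier; farms of different types are never pooled into one DEA model.
#'
#' @return Character vector of the four farm type codes.
#' @export
#' @examples
#' farm_types()
farm_types <- function() {
  c("french_extensive", "french_intensive",
    "spanish_semi_intensive", "uk_extensive")
}

#' Validate a farm table
#'
#' Checks the schema and the per-record invariants: positive gross revenue,
#' at least one ewe, nonnegative inputs with at least one strictly positive,
#' and -- when all five revenue components are present -- that the components
#' sum to gross revenue within a relative tolerance of 1e-3. Subsidies may be
#' NA (unavailable, as for UK farms) without triggering the sum check.
#'
#' @param records data.frame with at least the mandatory columns
#'   `farm_id`, `farm_type`, `ewes`, `labor`, `variable_cost`, `fixed_cost`,
#'   `gross_revenue`.
#' @param component_tol relative tolerance for the revenue-component sum.
#' @return The validated data.frame, invisibly.
#' @export
validate_farm_table <- function(records, component_tol = 1e-3) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.required_cols, names(records))
  if (length(missing_cols)) {
    stop("farm table schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) return(invisible(records))

  bad_type <- !records$farm_type %in% farm_types()
  if (any(bad_type)) {
    stop("row ", which(bad_type)[1L], ": unknown farm_type '",
         records$farm_type[which(bad_type)[1L]], "'", call. = FALSE)
  }
  row_fail <- function(cond, msg) {
    if (any(cond)) stop("row ", which(cond)[1L], ": ", msg, call. = FALSE)
  }
  row_fail(is.na(records$ewes) | records$ewes < 1, "ewes must be >= 1")
  row_fail(is.na(records$gross_revenue) | records$gross_revenue <= 0,
           "gross_revenue must be > 0")
  for (col in c("labor", "variable_cost", "fixed_cost")) {
    row_fail(is.na(records[[col]]) | records[[col]] < 0,
             paste0(col, " must be >= 0"))
  }
  row_fail(records$labor + records$variable_cost + records$fixed_cost +
             records$ewes <= 0, "at least one input must be > 0")

  comp <- records[, intersect(.component_cols, names(records)), drop = FALSE]
  if (ncol(comp) == length(.component_cols)) {
    full <- stats::complete.cases(comp)
    if (any(full)) {
      rel <- abs(rowSums(comp[full, , drop = FALSE]) -
                   records$gross_revenue[full]) /
        records$gross_revenue[full]
      if (any(rel > component_tol)) {
        stop("row ", which(full)[which(rel > component_tol)[1L]],
             ": revenue components do not sum to gross_revenue ",
             "(relative error > ", component_tol, ")", call. = FALSE)
      }
    }
  }
  invisible(records)
}

#' Read a farm table from delimited text
#'
#' Reads a UTF-8, comma-separated farm table with a mandatory header row and
#' '.' as the decimal mark. Empty fields are read as NA (absent), never as
#' zero. Records are validated on the way in.
#'
#' @param path path to the file.
#' @param farm_type optional farm type applied to every row when the file has
#'   no `farm_type` column (one-file-per-type layout).
#' @return data.frame of validated farm records, in file order.
#' @export
read_farm_table <- function(path, farm_type = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(farm_type)) {
    farm_type <- match.arg(farm_type, farm_types())
    if (!"farm_type" %in% names(raw)) {
      raw$farm_type <- if (nrow(raw)) farm_type else character(0)
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop("farm table schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(.numeric_cols, names(raw))) {
    x <- raw[[col]]
    x[!nzchar(x)] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad)) {
      stop("row ", which(bad)[1L], ": unparseable numeric value '",
           x[which(bad)[1L]], "' in column '", col, "'", call. = FALSE)
    }
    raw[[col]] <- v
  }
  validate_farm_table(raw)
  raw
}

#' Write a farm table to delimited text
#'
#' Serializes numeric fields in fixed decimal notation at full double
#' precision, so that a write/read round trip reproduces every value exactly.
#' NA values are written as empty fields.
#'
#' @param records farm table (validated on the way out).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_farm_table <- function(records, path) {
  validate_farm_table(records)
  out <- records
  for (col in intersect(.numeric_cols, names(out))) {
    v <- out[[col]]
    s <- vapply(v, function(z) {
      if (is.na(z)) "" else format(z, scientific = FALSE, digits = 17,
                                   trim = TRUE)
    }, character(1))
    out[[col]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Size-class scheme for a farm type
#'
#' Flock-size cut points separating small, medium and large farms. A farm is
#' small strictly below `small_upper` ewes, large strictly above `large_lower`
#' ewes, and medium on the closed interval in between (boundary flocks go to
#' medium, matching interval labels such as "350-450").
#'
#' Defaults by farm type: 350/450 ewes for both French types, 600/1000 for
#' Spanish semi-intensive, 400/900 for UK extensive.
#'
#' @param farm_type one of [farm_types()], used to pick default cut points.
#' @param small_upper,large_lower optional overrides (ewes).
#' @return An object of class `size_class_scheme`.
#' @export
#' @examples
#' size_class_scheme("french_extensive")
#' size_class_scheme("uk_extensive", small_upper = 300, large_lower = 800)
size_class_scheme <- function(farm_type, small_upper = NULL,
                              large_lower = NULL) {
  farm_type <- match.arg(farm_type, farm_types())
  defaults <- list(
    french_extensive       = c(350, 450),
    french_intensive       = c(350, 450),
    spanish_semi_intensive = c(600, 1000),
    uk_extensive           = c(400, 900)
  )[[farm_type]]
  small_upper <- if (is.null(small_upper)) defaults[1] else small_upper
  large_lower <- if (is.null(large_lower)) defaults[2] else large_lower
  stopifnot(is.numeric(small_upper), is.numeric(large_lower),
            small_upper <= large_lower)
  structure(list(farm_type = farm_type,
                 small_upper = small_upper,
                 large_lower = large_lower),
            class = "size_class_scheme")
}

#' @export
print.size_class_scheme <- function(x, ...) {
  cat(sprintf("size classes (%s): small < %g ewes, medium %g-%g, large > %g\n",
              x$farm_type, x$small_upper, x$small_upper, x$large_lower,
              x$large_lower))
  invisible(x)
}

#' Assign flock-size classes
#'
#' @param ewes numeric vector of flock sizes (>= 1).
#' @param scheme a [size_class_scheme()].
#' @return factor with levels `small`, `medium`, `large`.
#' @export
#' @examples
#' sc <- size_class_scheme("french_extensive")
#' assign_size_class(c(300, 350, 450, 451), sc)
assign_size_class <- function(ewes, scheme) {
  stopifnot(inherits(scheme, "size_class_scheme"), all(ewes >= 1))
  cls <- ifelse(ewes < scheme$small_upper, "small",
                ifelse(ewes > scheme$large_lower, "large", "medium"))
  factor(cls, levels = c("small", "medium", "large"))
}
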