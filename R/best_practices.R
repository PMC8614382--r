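# Best-practice catalog and adoption tabulations. Efficient farmers flag the
# management and production practices they implement at full potential; the
# tabulations count, per category and per practice, how many efficient farms
# of a type flagged each one.

.default_catalog <- function() {
  data.frame(
    category = c(
      rep("Feeding", 5),
      rep("Breeding", 4),
      rep("Gadgets and Applications", 2),
      rep("Product marketing", 2),
      rep("Information and training", 2),
      rep("Reproduction", 2),
      rep("Human resources organization", 2),
      "Health",
      rep("Product processing", 2)
    ),
    practice = c(
      "Understanding of matching animal requirements and supply",
      "Increased forage quality",
      "Innovative grazing practices",
      "Increased pasture quality",
      "Use of by-products to replace conventional feeds",
      "Use of elite flocks",
      "System/criteria to choose best animals for replacement",
      "Routine data collection (i.e., milk yield/quality)",
      "DNA data collection and use in programs",
      "Electronic identification systems",
      "On-farm data collection linked to animal ID for decision making",
      "Certification of products",
      "Branding of products for more local and direct markets",
      "Access to abattoir feedback on carcass quality and health",
      "Computer farm management programs",
      "Assisted reproduction techniques",
      "Improved rams and reproduction plans",
      "Staff training courses/regular meetings to get feedback",
      "Monitorization of labour costs/efficiency",
      "Scientific proven use of antibiotic alternatives in feeding",
      "On-farm product processing",
      "New packaging and cuts"
    ),
    stringsAsFactors = FALSE
  )
}

.category_order <- c("Feeding", "Breeding", "Gadgets and Applications",
                     "Product marketing", "Information and training",
                     "Reproduction", "Human resources organization",
                     "Health", "Product processing")

#' Catalog of best practices and innovations
#'
#' The catalog groups named practices under nine categories (feeding,
#' breeding, gadgets and applications, product marketing, information and
#' training, reproduction, human resources organization, health, product
#' processing). The default ships with 22 practices; pass your own
#' data.frame to extend or replace it.
#'
#' @param practices optional data.frame with columns `category` and
#'   `practice`. Category names must be unique per practice and practice
#'   names unique within a category. Row order defines the tie-break order
#'   of all rankings.
#' @return data.frame of class `practice_catalog`.
#' @export
#' @examples
#' cat9 <- practice_catalog()
#' table(cat9$category)
practice_catalog <- function(practices = NULL) {
  cat_df <- if (is.null(practices)) .default_catalog() else practices
  stopifnot(is.data.frame(cat_df),
            all(c("category", "practice") %in% names(cat_df)))
  if (anyDuplicated(cat_df[, c("category", "practice")]))
    stop("practice names must be unique within a category", call. = FALSE)
  cat_df <- cat_df[, c("category", "practice")]
  class(cat_df) <- c("practice_catalog", "data.frame")
  cat_df
}

.practice_key <- function(catalog) {
  paste(catalog$category, catalog$practice, sep = ".")
}

#' Build a practice-selection table
#'
#' @param farm_id character vector of farm ids.
#' @param flags logical matrix (rows = farms, columns = catalog entries in
#'   catalog order) of selections.
#' @param catalog a [practice_catalog()].
#' @return data.frame of class `practice_selection`: `farm_id` plus one
#'   logical column per catalog entry, named `"<category>.<practice>"`.
#' @export
practice_selection <- function(farm_id, flags, catalog = practice_catalog()) {
  flags <- as.matrix(flags)
  stopifnot(length(farm_id) == nrow(flags),
            ncol(flags) == nrow(catalog), is.logical(flags) || all(flags %in%
                                                                     c(0, 1)))
  out <- data.frame(farm_id = as.character(farm_id),
                    stringsAsFactors = FALSE)
  keys <- .practice_key(catalog)
  for (j in seq_along(keys)) out[[keys[j]]] <- as.logical(flags[, j])
  class(out) <- c("practice_selection", "data.frame")
  attr(out, "catalog") <- catalog
  out
}

# map selection columns onto catalog rows; unknown columns are an error
.selection_matrix <- function(selections, catalog) {
  keys <- setdiff(names(selections), "farm_id")
  unknown <- setdiff(keys, .practice_key(catalog))
  if (length(unknown))
    stop("selection references unknown practice(s): ",
         paste(unknown, collapse = "; "), call. = FALSE)
  m <- matrix(FALSE, nrow(selections), nrow(catalog),
              dimnames = list(selections$farm_id, .practice_key(catalog)))
  for (k in keys) m[, k] <- as.logical(selections[[k]]) %in% TRUE
  m
}

#' Read a practice-selection matrix from delimited text
#'
#' Expects a `farm_id` column plus one 0/1 or TRUE/FALSE column per practice,
#' named `"<category>.<practice>"` as produced by [write_practice_matrix()].
#'
#' @param path input path.
#' @param catalog a [practice_catalog()] the columns must belong to.
#' @return a `practice_selection` data.frame.
#' @export
read_practice_matrix <- function(path, catalog = practice_catalog()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"farm_id" %in% names(raw))
    stop("practice matrix needs a farm_id column", call. = FALSE)
  m <- .selection_matrix(raw, catalog)
  practice_selection(as.character(raw$farm_id), m, catalog)
}

#' Write a practice-selection matrix
#'
#' @param selections a `practice_selection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_practice_matrix <- function(selections, path) {
  out <- as.data.frame(selections)
  for (k in setdiff(names(out), "farm_id")) out[[k]] <- as.integer(out[[k]])
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Category-level adoption among efficient farms
#'
#' Per category: how many of the (efficient) farms in `selections` flagged at
#' least one practice of that category, and how many distinct practices of
#' the category were flagged at least once. Rows are ordered by descending
#' adopting-farm count, ties in catalog category order.
#'
#' @param selections a `practice_selection` covering the efficient farms of
#'   one farm type.
#' @param catalog a [practice_catalog()].
#' @return data.frame with columns `category`, `n_farms_selecting`,
#'   `n_farms_total`, `n_practices_selected`.
#' @export
category_adoption <- function(selections, catalog = practice_catalog()) {
  m <- .selection_matrix(selections, catalog)
  cats <- unique(catalog$category)
  rows <- lapply(cats, function(cc) {
    cols <- which(catalog$category == cc)
    sub <- m[, cols, drop = FALSE]
    data.frame(category = cc,
               n_farms_selecting = sum(rowSums(sub) > 0),
               n_farms_total = nrow(m),
               n_practices_selected = sum(colSums(sub) > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_farms_selecting), , drop = FALSE]
}

#' Ranking of individual practices by adoption
#'
#' Pools the selections of efficient farms (across farm types if desired) and
#' ranks each catalog practice by the number of adopting farms. Ties keep
#' catalog order (stable sort).
#'
#' @param selections a `practice_selection` of efficient farms.
#' @param catalog a [practice_catalog()].
#' @return data.frame with columns `category`, `practice`, `n_farms`,
#'   `n_farms_total`, `share_pct`, ranked by descending `n_farms`.
#' @export
practice_frequency_ranking <- function(selections,
                                       catalog = practice_catalog()) {
  if (nrow(catalog) == 0L) {
    return(data.frame(category = character(0), practice = character(0),
                      n_farms = integer(0), n_farms_total = integer(0),
                      share_pct = numeric(0), stringsAsFactors = FALSE))
  }
  m <- .selection_matrix(selections, catalog)
  counts <- colSums(m)
  out <- data.frame(category = catalog$category,
                    practice = catalog$practice,
                    n_farms = as.integer(counts),
                    n_farms_total = nrow(m),
                    share_pct = 100 * counts / max(nrow(m), 1L),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_farms), , drop = FALSE]   # stable: ties keep order
  rownames(out) <- NULL
  out
}
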