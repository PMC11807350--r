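#' The two-level SAL type taxonomy
#'
#' The limitation-type data model is a fixed two-level categorization: 15
#' top-level categories (e.g. `UnderpoweredStudy`, `Population`, `Funding`)
#' and 24 fine-grained categories, each attached to exactly one parent
#' (e.g. `SampleSize` under `UnderpoweredStudy`). The taxonomy ships as a
#' human-readable TSV inside the package so that specialty extensions can
#' supply their own file.
#'
#' @param path Path to a taxonomy TSV with columns `name`, `level`
#'   (`top`/`fine`), `parent` and `description`. Defaults to the bundled
#'   data model.
#' @return An object of class `sal_taxonomy`: a list with `top` (character
#'   vector of 15 names), `fine` (24 names), `parent` (named character
#'   vector mapping fine to top), `description` (named character vector),
#'   and `table` (the raw data frame).
#' @examples
#' tax <- load_taxonomy()
#' length(tax$top)            # 15
#' length(tax$fine)           # 24
#' tax$parent[["SampleSize"]] # "UnderpoweredStudy"
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sal_taxonomy.tsv", package = "salmine")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("taxonomy definition not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  needed <- c("name", "level", "parent", "description")
  if (!all(needed %in% names(tab))) {
    stop("taxonomy file is corrupted: missing columns ",
         paste(setdiff(needed, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$name)) {
    stop("taxonomy file is corrupted: duplicated category names", call. = FALSE)
  }
  if (!all(tab$level %in% c("top", "fine"))) {
    stop("taxonomy file is corrupted: level must be 'top' or 'fine'",
         call. = FALSE)
  }
  top <- tab$name[tab$level == "top"]
  fine <- tab$name[tab$level == "fine"]
  parent <- tab$parent[tab$level == "fine"]
  names(parent) <- fine
  if (!all(parent %in% top)) {
    stop("taxonomy file is corrupted: fine category with unknown parent: ",
         paste(setdiff(parent, top), collapse = ", "), call. = FALSE)
  }
  if (any(tab$parent[tab$level == "top"] != "")) {
    stop("taxonomy file is corrupted: top-level category with a parent",
         call. = FALSE)
  }
  desc <- tab$description
  names(desc) <- tab$name
  structure(
    list(top = top, fine = fine, parent = parent, description = desc,
         table = tab, version = "1.0"),
    class = "sal_taxonomy"
  )
}

#' @export
print.sal_taxonomy <- function(x, ...) {
  cat("SAL type taxonomy (version ", x$version, "): ",
      length(x$top), " top-level, ", length(x$fine),
      " fine-grained categories\n", sep = "")
  invisible(x)
}

#' Construct a label set
#'
#' A label set is a deduplicated set of category names at a stated
#' granularity. At `fine` granularity top-level names are also admitted,
#' because a sentence may carry only a top-level label when no
#' fine-grained category applies.
#'
#' @param labels Character vector of category names (may be empty).
#' @param granularity `"top"` or `"fine"`.
#' @param taxonomy A `sal_taxonomy`.
#' @return Sorted character vector of class `sal_labelset` with attribute
#'   `granularity`.
#' @export
label_set <- function(labels, granularity = c("top", "fine"),
                      taxonomy = load_taxonomy()) {
  granularity <- match.arg(granularity)
  labels <- unique(as.character(labels))
  bad <- labels[!vapply(labels, validate_label, logical(1),
                        granularity = granularity, taxonomy = taxonomy)]
  if (length(bad) > 0L) {
    stop("invalid label(s) at granularity '", granularity, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(sort(labels), granularity = granularity, class = "sal_labelset")
}

#' Validate a category name at a granularity
#'
#' @param name Category name.
#' @param granularity `"top"` or `"fine"`. Fine granularity admits both
#'   fine-grained and top-level names.
#' @param taxonomy A `sal_taxonomy`.
#' @return `TRUE` or `FALSE`; never errors.
#' @export
validate_label <- function(name, granularity = c("top", "fine"),
                           taxonomy = load_taxonomy()) {
  granularity <- match.arg(granularity)
  if (!is.character(name) || length(name) != 1L || is.na(name)) return(FALSE)
  if (granularity == "top") {
    name %in% taxonomy$top
  } else {
    name %in% taxonomy$top || name %in% taxonomy$fine
  }
}

#' Coarsen a label set to top-level granularity
#'
#' Replaces every fine-grained label by its parent top-level category;
#' top-level labels pass through; duplicates merge. Idempotent, never
#' increases cardinality.
#'
#' @param labels Character vector of valid labels (fine or top).
#' @param taxonomy A `sal_taxonomy`.
#' @return Sorted character vector of top-level labels.
#' @examples
#' coarsen(c("SampleSize", "Population"))  # UnderpoweredStudy, Population
#' @export
coarsen <- function(labels, taxonomy = load_taxonomy()) {
  labels <- as.character(labels)
  if (length(labels) == 0L) return(character(0))
  out <- vapply(labels, function(l) {
    if (l %in% taxonomy$top) return(l)
    if (l %in% taxonomy$fine) return(unname(taxonomy$parent[[l]]))
    stop("unknown label: ", l, call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
  sort(unique(out))
}
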