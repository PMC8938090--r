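# Feature-table I/O: per-subject feature records to CSV and back, and the
# cohort table (subjects x features + binary group label) consumed by the
# statistical stage.

#' Write per-subject feature records to CSV
#'
#' @param records a data.frame (or list of named lists sharing a schema)
#'   with a `subject_id` column/entry
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (!length(records)) {
      records <- data.frame(subject_id = character(0))
    } else {
      nm <- names(records[[1]])
      bad <- vapply(records, function(r) !identical(names(r), nm),
                    logical(1))
      if (any(bad)) {
        stop("records do not share a common feature schema", call. = FALSE)
      }
      records <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    }
  }
  if ("subject_id" %in% names(records) &&
      anyDuplicated(records$subject_id)) {
    stop("duplicate subject_id in feature records", call. = FALSE)
  }
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table (subjects x features with a binary group label)
#'
#' @param path CSV path
#' @param group_col name of the group column (must have exactly two levels)
#' @return a data.frame with `group_col` as a factor; attribute
#'   `group_levels` records the level order (first level = reference)
#' @export
read_cohort_table <- function(path, group_col = "group") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df, group_col)
}

#' @keywords internal
validate_cohort_table <- function(df, group_col = "group") {
  if (!group_col %in% names(df)) {
    stop("cohort table lacks group column '", group_col, "'", call. = FALSE)
  }
  g <- factor(df[[group_col]])
  if (nlevels(g) != 2L) {
    stop("group column must have exactly 2 levels, found ", nlevels(g),
         call. = FALSE)
  }
  if (anyDuplicated(names(df))) {
    stop("duplicate feature names in cohort table", call. = FALSE)
  }
  df[[group_col]] <- g
  attr(df, "group_levels") <- levels(g)
  df
}
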