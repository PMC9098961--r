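#' Regional intensity tables
#'
#' The pipeline's central exchange format: one row per subject, one numeric
#' column per brain region (mean regional uptake, arbitrary units), plus
#' `subject_id` and `group` columns. All downstream stages (covariance
#' networks, permutation tests, laterality) consume this object.
#'
#' @param values numeric matrix, subjects x regions; column names are region
#'   names (kept in atlas order).
#' @param group character/factor vector of group labels, one per subject.
#' @param subject_id optional subject identifiers (default `"s001"`, ...).
#' @return a data frame of class `intensity_table`.
#' @examples
#' m <- matrix(rnorm(4 * 6, 100, 10), 4, 6,
#'             dimnames = list(NULL, paste0("roi", 1:6)))
#' tab <- intensity_table(m, group = rep(c("g1", "g2"), each = 2))
#' intensity_matrix(tab, group = "g1")
#' @export
intensity_table <- function(values, group, subject_id = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("region%03d", seq_len(ncol(values)))
  if (is.null(subject_id))
    subject_id <- sprintf("s%03d", seq_len(nrow(values)))
  df <- data.frame(subject_id = as.character(subject_id),
                   group = as.character(group),
                   values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_intensity_table(df)
}

#' Coerce a data frame to an intensity table
#'
#' @param df data frame with `subject_id`, `group` and numeric region columns.
#' @return validated `intensity_table`.
#' @export
as_intensity_table <- function(df) validate_intensity_table(as.data.frame(df))

validate_intensity_table <- function(df) {
  for (col in c("subject_id", "group"))
    if (!col %in% names(df))
      stop("intensity table is missing required column '", col, "'", call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  regions <- setdiff(names(df), c("subject_id", "group"))
  if (length(regions) == 0L)
    stop("intensity table has no region columns", call. = FALSE)
  vals <- df[regions]
  bad <- regions[!vapply(vals, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric region column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyNA(vals))
    stop("intensity table contains missing values", call. = FALSE)
  class(df) <- c("intensity_table", "data.frame")
  df
}

#' @export
print.intensity_table <- function(x, ...) {
  rn <- region_names(x)
  cat("Regional intensity table: ", nrow(x), " subjects x ", length(rn),
      " regions\n", sep = "")
  tab <- table(x$group)
  cat("Groups: ", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                        collapse = ", "), "\n", sep = "")
  cat("Regions: ", paste(head(rn, 4), collapse = ", "),
      if (length(rn) > 4) ", ...", "\n", sep = "")
  invisible(x)
}

#' Region names of an intensity table
#' @param x an `intensity_table`.
#' @return character vector of region names, in atlas order.
#' @export
region_names <- function(x) setdiff(names(x), c("subject_id", "group"))

#' Extract the numeric subjects x regions matrix
#'
#' @param x an `intensity_table`.
#' @param group optional single group label to subset to.
#' @return numeric matrix with subject ids as row names.
#' @export
intensity_matrix <- function(x, group = NULL) {
  if (!is.null(group)) {
    if (!group %in% x$group) stop("group '", group, "' not present", call. = FALSE)
    x <- x[x$group == group, , drop = FALSE]
  }
  m <- as.matrix(x[region_names(x)])
  rownames(m) <- x$subject_id
  m
}

#' Global intensity normalization
#'
#' Proportional scaling: each subject's row is divided by that subject's
#' grand mean across regions and rescaled by 100, removing inter-subject
#' global differences (injected dose, weight) before correlation. `none`
#' returns the table unchanged.
#'
#' @param table an `intensity_table`.
#' @param mode `"proportional"` or `"none"`.
#' @return normalized `intensity_table`.
#' @export
normalize_global <- function(table, mode = c("proportional", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(table)
  m <- intensity_matrix(table)
  gm <- rowMeans(m)
  if (any(gm == 0))
    stop("zero grand mean for subject(s): ",
         paste(table$subject_id[gm == 0], collapse = ", "), call. = FALSE)
  m <- sweep(m, 1, gm, "/") * 100
  out <- table
  out[region_names(table)] <- m
  out
}

#' Read / write intensity tables as CSV
#'
#' CSV schema: `subject_id`, `group`, then one numeric column per region.
#' The round trip is lossless to at least 12 significant digits.
#'
#' @param path file path.
#' @return `read_intensity_table` returns an `intensity_table`.
#' @export
read_intensity_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  if ("group" %in% names(df)) df$group <- as.character(df$group)
  validate_intensity_table(df)
}

#' @param table an `intensity_table` to write.
#' @rdname read_intensity_table
#' @export
write_intensity_table <- function(table, path) {
  stopifnot(inherits(table, "intensity_table"))
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
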