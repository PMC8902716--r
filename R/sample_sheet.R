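#' Sample sheets
#'
#' The sample sheet ties every VCF sample to a population/group label, a sex
#' (`F`, `M`, or `U` for unknown), and a role: `natural` for population
#' samples, or `parent_female` / `parent_male` / `F1` for cross designs. A
#' cross design must contain exactly one parent of each sex.
#'
#' @param sample_id,group,sex,role character vectors of equal length.
#' @return A data frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, group, sex, role = "natural") {
  x <- data.frame(sample_id = as.character(sample_id),
                  group = as.character(group),
                  sex = as.character(sex),
                  role = as.character(rep_len(role, length(sample_id))),
                  stringsAsFactors = FALSE)
  validate_sample_sheet(x)
}

validate_sample_sheet <- function(x) {
  req <- c("sample_id", "group", "sex", "role")
  if (!all(req %in% names(x))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) {
    stop("sample sheet: duplicated sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  }
  if (!all(x$sex %in% c("F", "M", "U"))) {
    stop("sample sheet: sex must be one of F, M, U")
  }
  roles <- c("natural", "parent_female", "parent_male", "F1")
  if (!all(x$role %in% roles)) {
    stop("sample sheet: role must be one of ", paste(roles, collapse = ", "))
  }
  if (any(x$role %in% c("parent_female", "parent_male", "F1"))) {
    if (sum(x$role == "parent_female") != 1 || sum(x$role == "parent_male") != 1) {
      stop("sample sheet: a cross design needs exactly one parent_female and one parent_male")
    }
  }
  class(x) <- c("sample_sheet", "data.frame")
  x
}

#' Read a sample sheet TSV
#' @param path TSV with header columns `sample_id`, `group`, `sex`, `role`.
#' @return A validated `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_sample_sheet(x)
}

#' Write a sample sheet TSV
#' @param sheet a `sample_sheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select sample ids from a sheet
#'
#' Returns sample ids matching any combination of sex, group and role
#' filters, in sheet order.
#'
#' @param sheet a [sample_sheet()].
#' @param sex,group,role optional character filters (`NULL` = no filter).
#' @return Character vector of sample ids.
#' @export
sheet_samples <- function(sheet, sex = NULL, group = NULL, role = NULL) {
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(sex)) keep <- keep & sheet$sex %in% sex
  if (!is.null(group)) keep <- keep & sheet$group %in% group
  if (!is.null(role)) keep <- keep & sheet$role %in% role
  sheet$sample_id[keep]
}
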