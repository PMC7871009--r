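#' Read a fragment-counts CSV
#'
#' Schema: `variety, growth_stage, ear_id, lemma_id, fragment_count` with a
#' header, UTF-8. Counts must be integers >= 1.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_counts_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .require_columns(d, c("variety", "growth_stage", "ear_id", "lemma_id",
                        "fragment_count"), path)
  bad <- which(!is.finite(d$fragment_count) | d$fragment_count < 1 |
                 d$fragment_count != round(d$fragment_count))
  if (length(bad))
    stop("invalid fragment_count (must be integer >= 1) at row(s): ",
         paste(bad, collapse = ", "))
  d
}

#' Read a fragment-areas CSV
#'
#' Schema: `variety, growth_stage, lemma_id, fragment_area_px`.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_areas_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .require_columns(d, c("variety", "growth_stage", "lemma_id",
                        "fragment_area_px"), path)
  bad <- which(!is.finite(d$fragment_area_px) | d$fragment_area_px <= 0)
  if (length(bad))
    stop("invalid fragment_area_px (must be positive) at row(s): ",
         paste(bad, collapse = ", "))
  d
}

#' Read a structural-trait CSV
#'
#' Schema: `variety, growth_stage, ear_id, region, trait, value` with
#' `region` in {central, mid, lateral} and trait names from the controlled
#' vocabulary (thickness_min_um, thickness_max_um, vein_diameter_um,
#' cell_area_um2).
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_structure_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  .require_columns(d, c("variety", "growth_stage", "ear_id", "region",
                        "trait", "value"), path)
  bad_region <- which(!d$region %in% c("central", "mid", "lateral"))
  if (length(bad_region))
    stop("unknown region at row(s): ", paste(bad_region, collapse = ", "))
  traits <- c("thickness_min_um", "thickness_max_um", "vein_diameter_um",
              "cell_area_um2")
  bad_trait <- which(!d$trait %in% traits)
  if (length(bad_trait))
    stop("unknown trait at row(s): ", paste(bad_trait, collapse = ", "))
  if (any(d$value <= 0)) stop("trait values must be positive")
  d
}

.require_columns <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss))
    stop("'", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Write a data frame as UTF-8 CSV with header
#'
#' @param d data frame.
#' @param path output path.
#' @export
write_table_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
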