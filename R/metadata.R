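#' Build a population panel from per-sample metadata
#'
#' Aggregates per-sample records into one row per population, carrying the
#' altitude (metres), region and language annotations. Populations at
#' 2,500 m or above are flagged `high_altitude`, the conventional cut-off
#' for hypoxic selection studies.
#'
#' @param samples data frame with columns `sample_id`, `population`,
#'   `altitude_m`, and optionally `region` and `language`.
#' @return a tibble (class `population_panel`) with columns `code`,
#'   `altitude_m`, `region`, `language`, `n_samples`, `high_altitude`, and
#'   the per-sample table in attribute `"sample_map"`.
#' @export
population_panel <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "population", "altitude_m")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste("metadata missing columns:",
                                paste(miss, collapse = ", ")))
  if (!"region" %in% names(samples)) samples$region <- NA_character_
  if (!"language" %in% names(samples)) samples$language <- NA_character_
  if (any(samples$altitude_m < 0, na.rm = TRUE)) {
    abort("altitude_m must be >= 0")
  }
  conflicts <- samples |>
    dplyr::summarise(n_alt = dplyr::n_distinct(.data$altitude_m),
                     .by = "population") |>
    dplyr::filter(.data$n_alt > 1)
  if (nrow(conflicts)) {
    abort(paste("conflicting altitudes within population(s):",
                paste(conflicts$population, collapse = ", ")))
  }
  pops <- samples |>
    dplyr::summarise(
      altitude_m = dplyr::first(.data$altitude_m),
      region = dplyr::first(.data$region),
      language = dplyr::first(.data$language),
      n_samples = dplyr::n(),
      .by = "population"
    ) |>
    dplyr::rename(code = "population") |>
    dplyr::mutate(high_altitude = .data$altitude_m >= 2500)
  attr(pops, "sample_map") <- samples
  class(pops) <- c("population_panel", class(pops))
  pops
}

#' Read a sample/population metadata table
#'
#' Reads a tab-separated file with header columns `sample_id`, `population`,
#' `altitude_m` and optionally `region`, `language`, then aggregates it with
#' [population_panel()]. When a genotype panel is supplied, every genotyped
#' sample must appear in the metadata.
#'
#' @param tsv_path path to the TSV file.
#' @param panel optional [genotype_panel()] to validate sample coverage
#'   against.
#' @return a `population_panel` tibble.
#' @export
read_metadata <- function(tsv_path, panel = NULL) {
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  pops <- population_panel(tab)
  if (!is.null(panel)) {
    absent <- setdiff(panel$samples$sample_id, tab$sample_id)
    if (length(absent)) {
      abort(paste("genotyped sample(s) absent from metadata:",
                  paste(absent, collapse = ", ")))
    }
  }
  pops
}

#' Write metadata for a panel
#' @param populations a `population_panel`.
#' @param tsv_path output path.
#' @return `tsv_path`, invisibly.
#' @export
write_metadata <- function(populations, tsv_path) {
  sm <- attr(populations, "sample_map")
  utils::write.table(sm, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}

#' Per-sample altitude vector for a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param populations a `population_panel`.
#' @return numeric vector of altitudes (metres), one per sample, in panel
#'   sample order.
#' @export
sample_altitudes <- function(panel, populations) {
  idx <- match(panel$samples$population, populations$code)
  if (anyNA(idx)) {
    abort(paste("population(s) missing from panel:",
                paste(unique(panel$samples$population[is.na(idx)]),
                      collapse = ", ")))
  }
  populations$altitude_m[idx]
}
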