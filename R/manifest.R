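#' Read a sample manifest
#'
#' The manifest maps every sequenced individual to its population,
#' geographical region, source dataset, and the population's admixture
#' fraction (the proportion of its ancestry *not* native to the assigned
#' region, used to relax regional frequency thresholds).
#'
#' @param path Path to a TSV or CSV file with header columns `sample`,
#'   `population`, `region`, `dataset`, `admixture` (extra columns are
#'   kept). Delimiter is chosen from the file extension (`.csv` vs
#'   anything else = tab).
#' @return A tibble with one row per sample. Sample ids must be unique
#'   within a dataset; admixture must lie in `[0, 1]`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "sample\tpopulation\tregion\tdataset\tadmixture",
#'   "s1\tYRI\tAFR\td1\t0",
#'   "s2\tCLM\tAMR\td1\t0.45"
#' ), tf)
#' read_manifest(tf)
#' @export
read_manifest <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  m <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(as_tibble(m))
}

validate_manifest <- function(m) {
  required <- c("sample", "population", "region", "dataset", "admixture")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0) {
    abort(paste0(
      "Manifest format error: missing column(s) ",
      paste(missing, collapse = ", "), "."
    ))
  }
  if (!is.numeric(m$admixture)) {
    abort("Manifest format error: `admixture` must be numeric.")
  }
  bad <- which(is.na(m$admixture) | m$admixture < 0 | m$admixture > 1)
  if (length(bad) > 0) {
    abort(paste0(
      "Manifest validation error: admixture outside [0, 1] in row(s) ",
      paste(utils::head(bad, 5), collapse = ", "),
      " (sample ", paste(utils::head(m$sample[bad], 5), collapse = ", "), ")."
    ))
  }
  dup <- m |>
    dplyr::count(.data$dataset, .data$sample) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Manifest validation error: duplicate sample id(s) within a dataset: ",
      paste(utils::head(paste0(dup$dataset, "/", dup$sample), 5),
            collapse = ", "), "."
    ))
  }
  m
}

#' Regional panels of a dataset
#'
#' Summarises the manifest into one row per region for a given dataset:
#' panel size and count-weighted mean admixture fraction (each sample
#' contributes its population's admixture, so the mean is automatically
#' weighted by population size). The mean admixture feeds
#' [adjusted_threshold()] at the validation stages.
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @param dataset Dataset id to summarise.
#' @return Tibble with columns `region`, `n_individuals`,
#'   `mean_admixture`.
#' @export
region_panels <- function(manifest, dataset) {
  m <- filter(manifest, .data$dataset == .env$dataset)
  if (nrow(m) == 0) {
    abort(paste0("No samples for dataset '", dataset, "' in manifest."))
  }
  m |>
    group_by(region = .data$region) |>
    summarise(
      n_individuals = dplyr::n(),
      mean_admixture = mean(.data$admixture),
      .groups = "drop"
    )
}

#' Rest-of-world exclusion policy
#'
#' When testing region R for a region-specific allele, regions that share
#' substantial recent admixture with R are removed from the rest-of-world
#' pool (otherwise alleles leaked by admixture would defeat the world
#' near-absence/ratio rules). A policy is a tibble with columns `region`
#' (the target) and `excluded_region` (removed from R's world pool). A
#' region never excludes itself; self-exclusions are rejected.
#'
#' @param ... Named character vectors: `EUR = c("SAS", "AMR")` means SAS
#'   and AMR are dropped from the world pool when EUR is the target.
#' @return Tibble with columns `region`, `excluded_region`.
#' @examples
#' exclusion_policy(EUR = c("SAS", "AMR"), AFR = "AMR")
#' @export
exclusion_policy <- function(...) {
  lst <- list(...)
  if (length(lst) == 0) {
    return(tibble(region = character(), excluded_region = character()))
  }
  pol <- tibble(
    region = rep(names(lst), lengths(lst)),
    excluded_region = unlist(lst, use.names = FALSE)
  )
  if (any(pol$region == pol$excluded_region)) {
    abort("A region cannot exclude itself from its own panel.")
  }
  pol
}

#' Default ARSA exclusion policy
#'
#' European targets drop South Asia and the Americas from the world pool
#' (both carry substantial European ancestry); African targets drop the
#' Americas (African ancestry in admixed American panels).
#'
#' @return An exclusion-policy tibble.
#' @export
default_exclusion_policy <- function() {
  exclusion_policy(EUR = c("SAS", "AMR"), AFR = "AMR")
}

#' Default RACA exclusion policy
#'
#' For the regional-absence scan, European targets drop South Asia and the
#' Americas from the world pool. African and East Asian targets use the
#' full complement.
#'
#' @return An exclusion-policy tibble.
#' @export
default_raca_policy <- function() {
  exclusion_policy(EUR = c("SAS", "AMR"))
}

excluded_regions_for <- function(policy, target_region) {
  if (is.null(policy) || nrow(policy) == 0) {
    return(character())
  }
  policy$excluded_region[policy$region == target_region]
}
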