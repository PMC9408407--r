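#' Detect regional absences of common alleles (RACA)
#'
#' Scans one large cohort for alleles that are common worldwide yet
#' nearly missing from one region: an allele is called when its copy
#' count in the target region is below 10 (`raca_in_region_max_count`,
#' default 9) and its pooled copy count in the rest of the world, after
#' removing policy-excluded regions, exceeds 1000
#' (`raca_world_min_count`, default 1001). Both thresholds are operative
#' as *counts*, not frequencies: shrinking the world pool below 1001
#' chromosomes yields no calls regardless of frequency. Both alleles of a
#' site are tested independently (the regionally absent common allele can
#' be REF or ALT); at most one call per allele per site.
#'
#' Absence can only be asserted against a large panel, so the scan runs
#' on a single big cohort (hundreds of individuals per region). Regions
#' whose panels are heavily admixed cannot support the scan and are
#' refused unless `force = TRUE`; by default only Africa, Europe and East
#' Asia are permitted targets.
#'
#' @param counts Site-count tibble from [scan_sites()] with region
#'   grouping, covering the whole cohort.
#' @param target_region Region in which absence is tested.
#' @param policy Exclusion-policy tibble (default [default_raca_policy()]:
#'   SAS and AMR dropped from the world pool for EUR targets).
#' @param cfg A [threshold_config()].
#' @param force Allow targets outside `allowed_regions`.
#' @param allowed_regions Regions for which the scan is considered
#'   statistically meaningful.
#' @return A tibble of calls: `chrom`, `pos`, `site_id`, `ref`, `alt`,
#'   `region`, `allele` (the regionally absent common base),
#'   `in_region_count`, `world_count`, `world_freq`.
#' @export
detect_raca <- function(counts, target_region,
                        policy = default_raca_policy(),
                        cfg = threshold_config(),
                        force = FALSE,
                        allowed_regions = c("AFR", "EUR", "EAS")) {
  if (!force && !target_region %in% allowed_regions) {
    abort(paste0(
      "RACA is not computed for region '", target_region, "': heavily ",
      "admixed panels make regional absence unverifiable. Allowed: ",
      paste(allowed_regions, collapse = ", "),
      ". Use force = TRUE to override."
    ))
  }
  excl <- excluded_regions_for(policy, target_region)
  if (target_region %in% excl) {
    abort("Configuration error: target region is among its own exclusions.")
  }
  if (!target_region %in% unique(counts$group)) {
    abort(paste0("No panel for region '", target_region, "' in counts."))
  }

  region_rows <- counts |>
    filter(.data$group == .env$target_region) |>
    select("chrom", "pos", "site_id", "ref", "alt",
           r_ref = "ref_count", r_alt = "alt_count")
  world <- counts |>
    filter(!.data$group %in% c(.env$target_region, .env$excl)) |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      w_ref = sum(.data$ref_count), w_alt = sum(.data$alt_count),
      w_an = sum(.data$ref_count + .data$alt_count), .groups = "drop"
    )
  j <- inner_join(region_rows, world, by = c("chrom", "pos"))

  one_allele <- function(rc, wc, base) {
    j |>
      mutate(in_region_count = {{ rc }}, world_count = {{ wc }},
             allele = {{ base }}) |>
      filter(
        .data$in_region_count <= cfg$raca_in_region_max_count,
        .data$world_count >= cfg$raca_world_min_count
      ) |>
      mutate(
        region = .env$target_region,
        world_freq = .data$world_count / .data$w_an
      ) |>
      select("chrom", "pos", "site_id", "ref", "alt", "region", "allele",
             "in_region_count", "world_count", "world_freq")
  }
  bind_rows(
    one_allele(.data$r_alt, .data$w_alt, .data$alt),
    one_allele(.data$r_ref, .data$w_ref, .data$ref)
  ) |>
    arrange(.data$chrom, .data$pos, .data$allele)
}
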