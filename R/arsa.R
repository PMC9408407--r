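#' Discovery-stage scan for abundant region-specific alleles
#'
#' Stage 1 of the ARSA chain, run on the small minimally admixed discovery
#' cohort. A site+allele is called for `target_region` when its allele
#' count in the region's panel reaches the minimal count threshold
#' (`ceiling(base_fraction * 2N)`, see [min_count_threshold()]) and its
#' pooled count across all other discovery panels (minus policy
#' exclusions) does not exceed the near-absence ceiling
#' (`step1_world_max_count`, default 1 copy). The discovery panels are too
#' small for a frequency-ratio test; the 40x world-ratio rule is enforced
#' at the validation stages. Both the reference and the alternative allele
#' of a site are tested; a site yields at most one call per allele.
#'
#' @param counts Long site-count tibble from [scan_sites()] with
#'   region-level groups (the discovery dataset).
#' @param panels Regional panel tibble from [region_panels()] for the
#'   discovery dataset.
#' @param target_region Region id to scan.
#' @param cfg A [threshold_config()].
#' @param policy Exclusion-policy tibble (see [exclusion_policy()]).
#' @return A tibble of stage-1 calls: `chrom`, `pos`, `site_id`, `ref`,
#'   `alt`, `region`, `allele` (the region-specific base),
#'   `region_freq`, `world_freq`, `stage` (1).
#' @export
step1_discover <- function(counts, panels, target_region,
                           cfg = threshold_config(),
                           policy = default_exclusion_policy()) {
  panel <- filter(panels, .data$region == .env$target_region)
  if (nrow(panel) != 1 || panel$n_individuals < 1) {
    abort(paste0(
      "Configuration error: no discovery panel for region '",
      target_region, "'."
    ))
  }
  k <- min_count_threshold(panel$n_individuals, cfg$base_fraction)
  excl <- excluded_regions_for(policy, target_region)

  region_rows <- filter(counts, .data$group == .env$target_region)
  other <- counts |>
    filter(!.data$group %in% c(.env$target_region, .env$excl)) |>
    group_by(.data$chrom, .data$pos, .data$site_id) |>
    summarise(
      o_ref = sum(.data$ref_count), o_alt = sum(.data$alt_count),
      o_an = sum(.data$ref_count + .data$alt_count), .groups = "drop"
    )
  joined <- left_join(region_rows, other,
    by = c("chrom", "pos", "site_id")
  ) |>
    mutate(
      o_ref = dplyr::coalesce(.data$o_ref, 0L),
      o_alt = dplyr::coalesce(.data$o_alt, 0L),
      o_an = dplyr::coalesce(.data$o_an, 0L),
      an = .data$ref_count + .data$alt_count
    )

  one_allele <- function(cnt, ocnt, base) {
    joined |>
      mutate(rc = {{ cnt }}, oc = {{ ocnt }}, allele = {{ base }}) |>
      filter(.data$rc >= .env$k, .data$oc <= cfg$step1_world_max_count,
             .data$an > 0) |>
      mutate(
        region = .env$target_region,
        region_freq = .data$rc / .data$an,
        world_freq = if_else(.data$o_an > 0, .data$oc / .data$o_an, 0),
        stage = 1L
      ) |>
      select("chrom", "pos", "site_id", "ref", "alt", "region", "allele",
             "region_freq", "world_freq", "stage")
  }
  bind_rows(
    one_allele(.data$alt_count, .data$o_alt, .data$alt),
    one_allele(.data$ref_count, .data$o_ref, .data$ref)
  ) |>
    arrange(.data$chrom, .data$pos, .data$allele)
}

# A policy is shared across cohorts and targets, so entries for other
# targets may reference regions unsampled here; only the exclusions that
# apply to the current target must name known groups.
check_policy <- function(policy, known_regions, target_region) {
  unknown <- setdiff(excluded_regions_for(policy, target_region),
                     known_regions)
  if (length(unknown) > 0) {
    abort(paste0(
      "Configuration error: exclusion policy for region '", target_region,
      "' references unknown region(s): ",
      paste(unknown, collapse = ", "), "."
    ))
  }
  invisible(NULL)
}

# Shared stage-2/3 machinery: re-test candidate calls on an independent
# cohort. Allele identity is matched by base (ref/alt roles may swap
# between VCF sources); sites absent from the cohort fail validation and
# are logged as untestable.
validate_stage <- function(calls, counts, panels, policy, cfg, stage) {
  if (nrow(calls) == 0) {
    return(structure(calls, dropped = empty_dropped()))
  }
  for (R in unique(calls$region)) {
    check_policy(policy, c(unique(counts$group), panels$region), R)
  }

  site_info <- distinct(
    counts, .data$chrom, .data$pos,
    val_ref = .data$ref, val_alt = .data$alt
  )
  dup <- dplyr::count(site_info, .data$chrom, .data$pos) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn("Validation cohort has multiple records at one position; first kept.")
    site_info <- distinct(site_info, .data$chrom, .data$pos, .keep_all = TRUE)
  }

  kept <- list()
  dropped <- list()
  for (R in unique(calls$region)) {
    calls_R <- filter(calls, .data$region == .env$R) |>
      select("chrom", "pos", "site_id", "ref", "alt", "region", "allele") |>
      left_join(site_info, by = c("chrom", "pos"))

    absent <- filter(calls_R, is.na(.data$val_ref))
    calls_R <- filter(calls_R, !is.na(.data$val_ref))
    mismatch <- filter(calls_R, .data$allele != .data$val_ref &
                         .data$allele != .data$val_alt)
    calls_R <- filter(calls_R, .data$allele == .data$val_ref |
                        .data$allele == .data$val_alt)
    dropped[[length(dropped) + 1]] <- bind_rows(
      mutate(select(absent, "site_id", "region"), reason = "absent"),
      mutate(select(mismatch, "site_id", "region"), reason = "allele_mismatch")
    )

    excl <- excluded_regions_for(policy, R)
    pool <- counts |>
      filter(!.data$group %in% c(.env$R, .env$excl)) |>
      group_by(.data$chrom, .data$pos) |>
      summarise(
        w_ref = sum(.data$ref_count), w_alt = sum(.data$alt_count),
        w_an = sum(.data$ref_count + .data$alt_count), .groups = "drop"
      )
    total <- counts |>
      group_by(.data$chrom, .data$pos) |>
      summarise(
        t_ref = sum(.data$ref_count), t_alt = sum(.data$alt_count),
        .groups = "drop"
      )
    region_rows <- counts |>
      filter(.data$group == .env$R) |>
      select("chrom", "pos",
             r_ref = "ref_count", r_alt = "alt_count")

    j <- calls_R |>
      left_join(pool, by = c("chrom", "pos")) |>
      left_join(total, by = c("chrom", "pos")) |>
      left_join(region_rows, by = c("chrom", "pos")) |>
      mutate(
        is_alt = .data$allele == .data$val_alt,
        w_cnt = if_else(.data$is_alt, .data$w_alt, .data$w_ref),
        t_cnt = if_else(.data$is_alt, .data$t_alt, .data$t_ref),
        r_cnt = if_else(.data$is_alt, .data$r_alt, .data$r_ref),
        r_an = .data$r_ref + .data$r_alt
      )

    region_present <- R %in% panels$region && R %in% unique(counts$group)
    if (region_present) {
      adm <- panels$mean_admixture[panels$region == R][1]
      thr <- adjusted_threshold(cfg$base_fraction, adm)
      j <- j |>
        mutate(
          region_freq = if_else(.data$r_an > 0,
                                .data$r_cnt / .data$r_an, NA_real_),
          world_freq = if_else(.data$w_an > 0,
                               .data$w_cnt / .data$w_an, 0),
          pass_freq = !is.na(.data$region_freq) & .data$region_freq >= thr,
          # ratio rule cross-multiplied: never divides, world count 0
          # passes trivially
          pass_ratio = .data$r_cnt * .data$w_an >=
            cfg$world_ratio * .data$w_cnt * .data$r_an,
          pass = .data$pass_freq & .data$pass_ratio,
          reason = dplyr::case_when(
            .data$pass ~ NA_character_,
            !.data$pass_freq ~ "below_region_threshold",
            TRUE ~ "world_ratio"
          )
        )
    } else if (identical(R, cfg$oceania_region)) {
      # region unsampled in this cohort: the frequency and ratio rules
      # cannot be evaluated; enforce the strict whole-cohort copy ceiling
      j <- j |>
        mutate(
          region_freq = NA_real_,
          world_freq = if_else(.data$w_an > 0, .data$w_cnt / .data$w_an, 0),
          pass = .data$t_cnt <= cfg$oceania_world_max_count,
          reason = if_else(.data$pass, NA_character_, "absent_region_ceiling")
        )
    } else {
      j <- j |>
        mutate(
          region_freq = NA_real_,
          world_freq = if_else(.data$w_an > 0, .data$w_cnt / .data$w_an, 0),
          pass = TRUE, reason = NA_character_
        )
    }

    dropped[[length(dropped) + 1]] <- j |>
      filter(!.data$pass) |>
      select("site_id", "region", "reason")
    kept[[length(kept) + 1]] <- j |>
      filter(.data$pass) |>
      mutate(stage = as.integer(stage)) |>
      select("chrom", "pos", "site_id", "ref", "alt", "region", "allele",
             "region_freq", "world_freq", "stage")
  }
  out <- bind_rows(kept) |> arrange(.data$chrom, .data$pos, .data$allele)
  structure(out, dropped = bind_rows(empty_dropped(), bind_rows(dropped)))
}

empty_dropped <- function() {
  tibble(site_id = character(), region = character(), reason = character())
}

#' Validate candidate ARSA calls on an independent cohort (stage 2)
#'
#' Retains a candidate call iff (a) its frequency in the region's
#' validation panel reaches the admixture-adjusted threshold
#' ([adjusted_threshold()] with the panel's count-weighted mean
#' admixture), and (b) the pooled rest-of-world frequency (after removing
#' policy-excluded regions) is at least `world_ratio` times lower,
#' compared by cross-multiplication so a world count of zero passes
#' trivially. For a region with no panel in this cohort (Oceania in
#' 1000-Genomes-style data) rules (a) and (b) are replaced by the strict
#' whole-cohort ceiling: at most `oceania_world_max_count` allele copies
#' across all individuals. Sites absent from the cohort, or whose alleles
#' match neither the cohort's REF nor ALT base, fail validation and are
#' recorded as untestable in the `"dropped"` attribute.
#'
#' @param calls Candidate calls from [step1_discover()] (or a previous
#'   stage).
#' @param counts Site counts of the validation cohort (region grouping).
#' @param panels [region_panels()] of the validation cohort.
#' @param policy Exclusion-policy tibble.
#' @param cfg A [threshold_config()].
#' @return Retained calls with refreshed `region_freq`/`world_freq` and
#'   `stage = 2`; dropped calls (with reasons) in attribute `"dropped"`.
#' @export
step2_validate <- function(calls, counts, panels,
                           policy = default_exclusion_policy(),
                           cfg = threshold_config()) {
  validate_stage(calls, counts, panels, policy, cfg, stage = 2L)
}

#' Re-validate ARSA calls on a second independent cohort (stage 3)
#'
#' Identical contract to [step2_validate()] with this cohort's panels and
#' `stage = 3`. If the cohort samples a region missing from the stage-2
#' cohort (Oceania in the second validation panel), the regional
#' frequency rule is enforced here.
#'
#' @inheritParams step2_validate
#' @return Retained calls with `stage = 3`.
#' @export
step3_validate <- function(calls, counts, panels,
                           policy = default_exclusion_policy(),
                           cfg = threshold_config()) {
  validate_stage(calls, counts, panels, policy, cfg, stage = 3L)
}

#' Run the full three-stage ARSA pipeline
#'
#' Chains [step1_discover()], [step2_validate()] and [step3_validate()]
#' over three cohorts for a set of target regions and tabulates per-region
#' candidate counts after each stage (counts are non-increasing across
#' stages by construction).
#'
#' @param counts A list of three site-count tibbles (discovery,
#'   validation, second validation), each from [scan_sites()] with region
#'   grouping and consistent site keying by chromosome and position.
#' @param panels A list of three [region_panels()] tibbles matching
#'   `counts`.
#' @param regions Character vector of target regions; defaults to the
#'   discovery-panel regions intersected with the canonical five
#'   continental targets (AFR, AMR, EAS, EUR, OCE).
#' @param policy Exclusion-policy tibble shared by all stages.
#' @param cfg A [threshold_config()].
#' @return An object of class `"arsa_result"`: a list with `calls` (final
#'   stage-3 calls, with per-stage frequencies in `region_freq_1..3`,
#'   `world_freq_1..3`), `stage_counts` (region x stage table), and
#'   `dropped` (per-stage drop log). Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
run_arsa <- function(counts, panels, regions = NULL,
                     policy = default_exclusion_policy(),
                     cfg = threshold_config()) {
  stopifnot(length(counts) == 3, length(panels) == 3)
  if (is.null(regions)) {
    regions <- intersect(panels[[1]]$region,
                         c("AFR", "AMR", "EAS", "EUR", "OCE"))
    if (length(regions) == 0) regions <- panels[[1]]$region
  }

  s1 <- purrr::map(regions, function(R) {
    step1_discover(counts[[1]], panels[[1]], R, cfg = cfg, policy = policy)
  }) |> bind_rows()
  s2 <- step2_validate(s1, counts[[2]], panels[[2]], policy, cfg)
  s3 <- step3_validate(s2, counts[[3]], panels[[3]], policy, cfg)

  key <- c("site_id", "region", "allele")
  freqs_of <- function(s, i) {
    s |>
      select(dplyr::all_of(key), "region_freq", "world_freq") |>
      dplyr::rename_with(~ paste0(.x, "_", i),
                         c("region_freq", "world_freq"))
  }
  calls <- s3 |>
    select("chrom", "pos", "site_id", "ref", "alt", "region", "allele") |>
    left_join(freqs_of(s1, 1), by = key) |>
    left_join(freqs_of(s2, 2), by = key) |>
    left_join(freqs_of(s3, 3), by = key)

  tally <- function(s, nm) {
    s |>
      dplyr::count(.data$region, name = nm)
  }
  stage_counts <- tibble(region = regions) |>
    left_join(tally(s1, "stage1"), by = "region") |>
    left_join(tally(s2, "stage2"), by = "region") |>
    left_join(tally(s3, "stage3"), by = "region") |>
    mutate(across(dplyr::starts_with("stage"),
                  ~ dplyr::coalesce(.x, 0L)))

  structure(
    list(
      calls = calls,
      stage_counts = stage_counts,
      dropped = bind_rows(
        mutate(attr(s2, "dropped"), stage = 2L),
        mutate(attr(s3, "dropped"), stage = 3L)
      ),
      cfg = cfg,
      regions = regions
    ),
    class = "arsa_result"
  )
}

#' @export
print.arsa_result <- function(x, ...) {
  cat("Abundant region-specific allele (ARSA) scan\n")
  cat("Regions:", paste(x$regions, collapse = ", "), "\n")
  cat("Per-stage candidate counts:\n")
  print(as.data.frame(x$stage_counts), row.names = FALSE)
  cat("Final calls:", nrow(x$calls), "\n")
  invisible(x)
}

#' @describeIn run_arsa Final calls as a tibble (one row per site, region
#'   and allele, with per-stage frequencies).
#' @param x An `arsa_result`.
#' @param ... Unused.
#' @export
tidy.arsa_result <- function(x, ...) {
  x$calls
}

#' @describeIn run_arsa One-row summary: regions scanned, candidates per
#'   stage, final call count.
#' @export
glance.arsa_result <- function(x, ...) {
  tibble(
    n_regions = length(x$regions),
    n_stage1 = sum(x$stage_counts$stage1),
    n_stage2 = sum(x$stage_counts$stage2),
    n_stage3 = sum(x$stage_counts$stage3),
    n_calls = nrow(x$calls)
  )
}

#' @describeIn run_arsa Bar chart of per-region candidate counts across
#'   the three filter stages.
#' @param object An `arsa_result`.
#' @export
autoplot.arsa_result <- function(object, ...) {
  df <- object$stage_counts |>
    tidyr::pivot_longer(dplyr::starts_with("stage"),
                        names_to = "stage", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Region", y = "Candidate ARSA SNPs", fill = "Stage") +
    ggplot2::theme_minimal()
}
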