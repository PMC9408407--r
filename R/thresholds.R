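#' Numeric rules of the region-specific allele scan
#'
#' Bundles every tunable numeric rule of the ARSA/RACA pipeline into one
#' validated configuration object. Defaults reproduce the published
#' protocol exactly.
#'
#' @param base_fraction Regional abundance threshold as a fraction of
#'   called chromosomes (default 0.18, i.e. an allele must reach 18%
#'   frequency in its region).
#' @param world_ratio Minimum fold-difference between the regional and the
#'   pooled rest-of-world frequency at the validation stages (default 40).
#' @param step1_world_max_count Near-absence ceiling at the discovery
#'   stage: maximum number of allele copies tolerated in the pooled
#'   non-target discovery panels (default 1). The discovery panels are too
#'   small for a ratio test, so a hard copy ceiling is used; the
#'   `world_ratio` rule takes over at validation.
#' @param raca_in_region_max_count Maximum allele copies in the target
#'   region for a RACA call (default 9, i.e. "fewer than 10").
#' @param raca_world_min_count Minimum allele copies in the rest-of-world
#'   pool for a RACA call (default 1001, i.e. "more than 1000").
#' @param oceania_world_max_count For a region absent from a validation
#'   cohort (Oceania in 1000-Genomes-style panels): maximum allele copies
#'   tolerated across *all* individuals of that cohort (default 6, i.e.
#'   "fewer than 7").
#' @param oceania_region Region id to which the strict absent-region rule
#'   applies (default `"OCE"`).
#' @param cluster_gap_bp Maximum distance in base pairs between
#'   neighbouring called SNPs joined into one cluster (default 5000;
#'   strictly-less-than joins).
#'
#' @return A list of class `"threshold_config"`.
#' @examples
#' cfg <- threshold_config()
#' cfg$base_fraction
#' @export
threshold_config <- function(base_fraction = 0.18,
                             world_ratio = 40,
                             step1_world_max_count = 1L,
                             raca_in_region_max_count = 9L,
                             raca_world_min_count = 1001L,
                             oceania_world_max_count = 6L,
                             oceania_region = "OCE",
                             cluster_gap_bp = 5000L) {
  stopifnot(
    is.numeric(base_fraction), length(base_fraction) == 1,
    base_fraction > 0, base_fraction < 1,
    is.numeric(world_ratio), world_ratio > 1,
    step1_world_max_count >= 0,
    raca_in_region_max_count >= 0,
    raca_world_min_count >= 0,
    oceania_world_max_count >= 0,
    cluster_gap_bp > 0
  )
  structure(
    list(
      base_fraction = base_fraction,
      world_ratio = world_ratio,
      step1_world_max_count = as.integer(step1_world_max_count),
      raca_in_region_max_count = as.integer(raca_in_region_max_count),
      raca_world_min_count = as.integer(raca_world_min_count),
      oceania_world_max_count = as.integer(oceania_world_max_count),
      oceania_region = oceania_region,
      cluster_gap_bp = as.integer(cluster_gap_bp)
    ),
    class = "threshold_config"
  )
}

#' Minimal allele-count threshold for a regional panel
#'
#' Smallest number of allele copies `k` such that `k / (2N) >=
#' base_fraction` for a panel of `N` diploid individuals, i.e.
#' `k = ceiling(base_fraction * 2N)`. The boundary is inclusive: when the
#' product is an exact integer that count itself already satisfies the
#' threshold. A single ceiling rule reproduces all published regional
#' thresholds (47 -> 17, 8 -> 3, 19 -> 7, 22 -> 8, 41 -> 15 at 18%).
#'
#' @param n_individuals Number of diploid individuals in the panel
#'   (vectorised).
#' @param base_fraction Frequency threshold as a fraction (default 0.18).
#' @return Integer vector of minimal allele counts.
#' @examples
#' min_count_threshold(c(47, 8, 19, 22, 41))
#' @export
min_count_threshold <- function(n_individuals, base_fraction = 0.18) {
  if (any(!is.finite(n_individuals)) || any(n_individuals < 1)) {
    abort("`n_individuals` must be positive.")
  }
  if (any(base_fraction <= 0) || any(base_fraction >= 1)) {
    abort("`base_fraction` must be in (0, 1).")
  }
  x <- base_fraction * 2 * n_individuals
  # tolerate floating error at exact-integer boundaries (0.18 * 50 etc.)
  k <- ceiling(x - 1e-9)
  storage.mode(k) <- "integer"
  k
}

#' Frequency percentage implied by a count threshold
#'
#' The discrete panel sizes make only certain frequency cutoffs
#' realisable; this returns the actual percentage implied by the minimal
#' count, `100 * k / (2N)`. E.g. 17 copies out of 47 people is an 18.09%
#' (printed 18.1%) cutoff; 3 out of 8 people is 18.75%.
#'
#' @inheritParams min_count_threshold
#' @return Numeric vector of percentages.
#' @examples
#' implied_frequency_pct(c(47, 8, 19, 22, 41))
#' @export
implied_frequency_pct <- function(n_individuals, base_fraction = 0.18) {
  k <- min_count_threshold(n_individuals, base_fraction)
  100 * k / (2 * n_individuals)
}

#' Admixture-adjusted frequency threshold
#'
#' Relaxes the regional abundance threshold for admixed validation panels:
#' a population whose ancestry is a fraction `admixture_fraction` non-native
#' dilutes a region-specific allele proportionally, so the cutoff becomes
#' `base_fraction * (1 - admixture_fraction)`. With 40% admixture the 18%
#' base threshold becomes 10.8%. The multiplicative form (rather than
#' subtracting percentage points) degrades gracefully to 0 at complete
#' admixture.
#'
#' @param base_fraction Base frequency threshold as a fraction.
#' @param admixture_fraction Fraction of non-native ancestry in `[0, 1]`
#'   (vectorised).
#' @return Adjusted threshold(s) as fraction(s).
#' @examples
#' adjusted_threshold(0.18, 0.40) # 0.108
#' @export
adjusted_threshold <- function(base_fraction, admixture_fraction) {
  if (any(admixture_fraction < 0) || any(admixture_fraction > 1)) {
    abort("`admixture_fraction` must be in [0, 1].")
  }
  if (any(base_fraction <= 0) || any(base_fraction >= 1)) {
    abort("`base_fraction` must be in (0, 1).")
  }
  base_fraction * (1 - admixture_fraction)
}
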