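no_policy <- function() exclusion_policy()

test_that("discovery stage calls the published African boundary case", {
  # 17 copies out of 47 people (94 chromosomes), absent elsewhere
  counts <- dplyr::bind_rows(
    count_row("AFR", ref_count = 77, alt_count = 17),
    count_row("EUR", ref_count = 82, alt_count = 0)
  )
  panels <- dplyr::bind_rows(panel_row("AFR", 47), panel_row("EUR", 41))
  calls <- step1_discover(counts, panels, "AFR", policy = no_policy())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$allele, "G")
  expect_equal(calls$region_freq, 17 / 94)
  expect_equal(calls$stage, 1L)

  # one copy fewer falls below ceiling(0.18 * 94) = 17
  counts16 <- dplyr::bind_rows(
    count_row("AFR", ref_count = 78, alt_count = 16),
    count_row("EUR", ref_count = 82, alt_count = 0)
  )
  expect_equal(nrow(step1_discover(counts16, panels, "AFR",
                                   policy = no_policy())), 0)

  # near-absence ceiling: 2 copies in the rest of the world is too many
  counts_leak <- dplyr::bind_rows(
    count_row("AFR", ref_count = 77, alt_count = 17),
    count_row("EUR", ref_count = 80, alt_count = 2)
  )
  expect_equal(nrow(step1_discover(counts_leak, panels, "AFR",
                                   policy = no_policy())), 0)
  expect_error(step1_discover(counts, panels, "OCE", policy = no_policy()),
               "no discovery panel")
})

test_that("either allele of a site can be region-specific", {
  # the REF base is abundant in AFR and absent elsewhere (everyone else
  # is homozygous ALT)
  counts <- dplyr::bind_rows(
    count_row("AFR", ref_count = 30, alt_count = 64),
    count_row("EUR", ref_count = 0, alt_count = 82)
  )
  panels <- dplyr::bind_rows(panel_row("AFR", 47), panel_row("EUR", 41))
  calls <- step1_discover(counts, panels, "AFR", policy = no_policy())
  expect_equal(calls$allele, "A")
  expect_equal(calls$region_freq, 30 / 94)
})

test_that("validation enforces the 40-fold world ratio", {
  call <- tibble::tibble(
    chrom = "1", pos = 100L, site_id = "s1", ref = "A", alt = "G",
    region = "AFR", allele = "G"
  )
  panels <- dplyr::bind_rows(panel_row("AFR", 500), panel_row("EUR", 2500))
  # region 0.20 vs world 0.004: ratio 50 >= 40, retained
  counts_ok <- dplyr::bind_rows(
    count_row("AFR", ref_count = 800, alt_count = 200),
    count_row("EUR", ref_count = 4980, alt_count = 20)
  )
  kept <- step2_validate(call, counts_ok, panels, policy = no_policy())
  expect_equal(nrow(kept), 1)
  expect_equal(kept$region_freq, 0.2)
  expect_equal(kept$world_freq, 0.004)
  expect_equal(kept$stage, 2L)

  # region 0.20 vs world 0.01: ratio 20 < 40, dropped
  counts_bad <- dplyr::bind_rows(
    count_row("AFR", ref_count = 800, alt_count = 200),
    count_row("EUR", ref_count = 4950, alt_count = 50)
  )
  dropped <- step2_validate(call, counts_bad, panels, policy = no_policy())
  expect_equal(nrow(dropped), 0)
  expect_equal(attr(dropped, "dropped")$reason, "world_ratio")

  # below the admixture-adjusted regional threshold
  panels_adm <- dplyr::bind_rows(panel_row("AFR", 500, mean_admixture = 0.4),
                                 panel_row("EUR", 2500))
  counts_low <- dplyr::bind_rows(
    count_row("AFR", ref_count = 900, alt_count = 100), # freq 0.10 < 0.108
    count_row("EUR", ref_count = 5000, alt_count = 0)
  )
  out <- step2_validate(call, counts_low, panels_adm, policy = no_policy())
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped")$reason, "below_region_threshold")
  # 0.108 itself passes (inclusive boundary)
  counts_at <- dplyr::bind_rows(
    count_row("AFR", ref_count = 892, alt_count = 108),
    count_row("EUR", ref_count = 5000, alt_count = 0)
  )
  expect_equal(nrow(step2_validate(call, counts_at, panels_adm,
                                   policy = no_policy())), 1)
})

test_that("regions absent from a cohort obey the strict whole-cohort ceiling", {
  call <- tibble::tibble(
    chrom = "1", pos = 100L, site_id = "s1", ref = "A", alt = "G",
    region = "OCE", allele = "G"
  )
  panels <- dplyr::bind_rows(panel_row("AFR", 500), panel_row("EUR", 500))
  mk <- function(n_copies) {
    dplyr::bind_rows(
      count_row("AFR", ref_count = 1000 - n_copies, alt_count = n_copies),
      count_row("EUR", ref_count = 1000, alt_count = 0)
    )
  }
  # fewer than 7 copies across all individuals: retained
  expect_equal(nrow(step2_validate(call, mk(6), panels,
                                   policy = no_policy())), 1)
  # exactly 7: dropped
  out <- step2_validate(call, mk(7), panels, policy = no_policy())
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped")$reason, "absent_region_ceiling")
})

test_that("sites missing from a validation cohort fail as untestable", {
  call <- tibble::tibble(
    chrom = "1", pos = c(100L, 999L), site_id = c("s1", "s2"),
    ref = "A", alt = "G", region = "AFR", allele = "G"
  )
  counts <- dplyr::bind_rows(
    count_row("AFR", ref_count = 700, alt_count = 300),
    count_row("EUR", ref_count = 1000, alt_count = 0)
  )
  panels <- dplyr::bind_rows(panel_row("AFR", 500), panel_row("EUR", 500))
  out <- step2_validate(call, counts, panels, policy = no_policy())
  expect_equal(out$site_id, "s1")
  drop <- attr(out, "dropped")
  expect_equal(drop$site_id, "s2")
  expect_equal(drop$reason, "absent")
})

test_that("alleles are matched by base across cohorts with swapped REF/ALT", {
  call <- tibble::tibble(
    chrom = "1", pos = 100L, site_id = "s1", ref = "A", alt = "G",
    region = "AFR", allele = "G"
  )
  # validation cohort encodes the same site as REF=G, ALT=A
  counts <- dplyr::bind_rows(
    count_row("AFR", ref_count = 300, alt_count = 700, ref = "G", alt = "A"),
    count_row("EUR", ref_count = 0, alt_count = 1000, ref = "G", alt = "A")
  )
  panels <- dplyr::bind_rows(panel_row("AFR", 500), panel_row("EUR", 500))
  kept <- step2_validate(call, counts, panels, policy = no_policy())
  expect_equal(nrow(kept), 1)
  expect_equal(kept$region_freq, 0.3)

  # a site whose alleles match neither base is untestable
  counts_mm <- dplyr::mutate(counts, ref = "C", alt = "T")
  out <- step2_validate(call, counts_mm, panels, policy = no_policy())
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped")$reason, "allele_mismatch")
})

test_that("exclusion policies remove admixed regions from the world pool", {
  call <- tibble::tibble(
    chrom = "1", pos = 100L, site_id = "s1", ref = "A", alt = "G",
    region = "EUR", allele = "G"
  )
  # the allele leaked into SAS via admixture; without the exclusion the
  # ratio test fails, with it the pool is AFR-only and clean
  counts <- dplyr::bind_rows(
    count_row("EUR", ref_count = 700, alt_count = 300),
    count_row("SAS", ref_count = 900, alt_count = 100),
    count_row("AFR", ref_count = 1000, alt_count = 0)
  )
  panels <- dplyr::bind_rows(panel_row("EUR", 500), panel_row("SAS", 500),
                             panel_row("AFR", 500))
  expect_equal(nrow(step2_validate(call, counts, panels,
                                   policy = no_policy())), 0)
  expect_equal(nrow(step2_validate(call, counts, panels,
                                   policy = exclusion_policy(EUR = "SAS"))),
               1)
  expect_error(
    step2_validate(call, counts, panels,
                   policy = exclusion_policy(EUR = "XXX")),
    "unknown region"
  )
  expect_error(exclusion_policy(EUR = "EUR"), "exclude itself")
})

test_that("threshold sharpness: one copy below the minimum removes the call", {
  panels <- dplyr::bind_rows(panel_row("AFR", 47), panel_row("AMR", 8),
                             panel_row("EUR", 41))
  for (n in c(47, 8, 41)) {
    region <- c("47" = "AFR", "8" = "AMR", "41" = "EUR")[as.character(n)]
    k <- min_count_threshold(n)
    at <- dplyr::bind_rows(
      count_row(region, ref_count = 2 * n - k, alt_count = k),
      count_row(setdiff(c("AFR", "AMR", "EUR"), region)[1],
                ref_count = 100, alt_count = 0)
    )
    below <- dplyr::mutate(at, alt_count = ifelse(group == region,
                                                  k - 1L, alt_count),
                           ref_count = ifelse(group == region,
                                              2L * n - k + 1L, ref_count))
    expect_equal(nrow(step1_discover(at, panels, region,
                                     policy = no_policy())), 1)
    expect_equal(nrow(step1_discover(below, panels, region,
                                     policy = no_policy())), 0)
  }
})

test_that("stage-1 results are invariant to record and group order", {
  withr::local_seed(99)
  counts <- dplyr::bind_rows(lapply(1:30, function(i) {
    alt <- sample(0:94, 1)
    dplyr::bind_rows(
      count_row("AFR", ref_count = 94 - alt, alt_count = alt,
                pos = i * 50, site_id = paste0("s", i)),
      count_row("EUR", ref_count = 82, alt_count = 0,
                pos = i * 50, site_id = paste0("s", i))
    )
  }))
  panels <- dplyr::bind_rows(panel_row("AFR", 47), panel_row("EUR", 41))
  ordered <- step1_discover(counts, panels, "AFR", policy = no_policy())
  shuffled <- step1_discover(counts[sample(nrow(counts)), ], panels, "AFR",
                             policy = no_policy())
  expect_equal(ordered, shuffled)
})
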