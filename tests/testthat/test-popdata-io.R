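test_that("manifests are parsed and validated", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tpopulation\tregion\tdataset\tadmixture",
    "s1\tYRI\tAFR\td1\t0",
    "s2\tYRI\tAFR\td1\t0",
    "s3\tCLM\tAMR\td1\t0.4"
  ), tf)
  m <- read_manifest(tf)
  expect_equal(nrow(m), 3)
  expect_equal(m$admixture, c(0, 0, 0.4))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tpopulation\tregion\tdataset\tadmixture",
    "s1\tYRI\tAFR\td1\t1.2"
  ), bad)
  expect_error(read_manifest(bad), "admixture outside")

  nocol <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tpopulation\tregion\tdataset", "s1\tY\tAFR\td1"),
             nocol)
  expect_error(read_manifest(nocol), "missing column")
})

test_that("sample ids must be unique per dataset but may recur across datasets", {
  shared <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tpopulation\tregion\tdataset\tadmixture",
    "s1\tYRI\tAFR\td1\t0",
    "s1\tYRI\tAFR\td2\t0"
  ), shared)
  expect_equal(nrow(read_manifest(shared)), 2)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\tpopulation\tregion\tdataset\tadmixture",
    "s1\tYRI\tAFR\td1\t0",
    "s1\tLWK\tAFR\td1\t0"
  ), dup)
  expect_error(read_manifest(dup), "duplicate sample")
})

test_that("genotype tallies follow the missing-data conventions", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(tf, paste0("s", 1:4), c(
    vcf_record("1", 100, "rs1", "A", "G", c("0/0", "0/1", "1/1", "./.")),
    vcf_record("1", 200, "rs2", "C", "T", c("0|0", "0|1", "1|1", ".|.")),
    vcf_record("1", 300, "rs3", "C", "T", c("0/.", "1/.", "0/1", "0"))
  ))
  man <- test_manifest(paste0("s", 1:4), "P1", "AFR")
  counts <- scan_sites(tf, man, "d1")
  r1 <- counts[counts$pos == 100, ]
  expect_equal(c(r1$ref_count, r1$alt_count, r1$missing_count), c(3, 3, 2))
  # phased separators are equivalent to unphased
  r2 <- counts[counts$pos == 200, ]
  expect_equal(c(r2$ref_count, r2$alt_count, r2$missing_count), c(3, 3, 2))
  # half-calls and haploid calls contribute one called + one missing copy
  r3 <- counts[counts$pos == 300, ]
  expect_equal(c(r3$ref_count, r3$alt_count, r3$missing_count), c(3, 2, 3))
  # conservation: ref + alt + missing = 2N for each site
  expect_true(all(counts$ref_count + counts$alt_count +
                    counts$missing_count == 8))
})

test_that("non-conforming records are skipped and logged", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(tf, paste0("s", 1:2), c(
    vcf_record("1", 100, "ok", "A", "G", c("0/0", "0/1")),
    vcf_record("1", 200, "multi", "A", "G,T", c("0/0", "0/2")),
    vcf_record("1", 300, "indel", "AT", "A", c("0/0", "0/1")),
    vcf_record("X", 400, "sexchrom", "A", "G", c("0/0", "0/1"))
  ))
  man <- test_manifest(paste0("s", 1:2), "P1", "AFR")
  counts <- scan_sites(tf, man, "d1")
  expect_equal(unique(counts$site_id), "ok")
  log <- skip_log(counts)
  expect_equal(nrow(log), 3)
  expect_setequal(log$reason, c("multiallelic", "non_snv", "excluded_chrom"))

  badgt <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(badgt, paste0("s", 1:2), c(
    vcf_record("1", 100, "ok", "A", "G", c("0/0", "0/1")),
    vcf_record("1", 200, "bad", "A", "G", c("0/x", "0/1"))
  ))
  expect_warning(counts2 <- scan_sites(badgt, man, "d1"), "malformed")
  expect_equal(unique(counts2$site_id), "ok")
  expect_true("malformed_gt" %in% skip_log(counts2)$reason)
})

test_that("manifest samples absent from the VCF are a hard error", {
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(tf, c("s1", "s2"),
                 vcf_record("1", 100, "rs1", "A", "G", c("0/0", "0/1")))
  man <- test_manifest(c("s1", "s2", "s9"), "P1", "AFR")
  expect_error(scan_sites(tf, man, "d1"), "s9")
})

test_that("counts match an independent per-genotype tally on random fixtures", {
  withr::local_seed(421)
  for (rep in 1:20) {
    n_samp <- sample(4:10, 1)
    n_site <- sample(3:6, 1)
    samples <- paste0("s", seq_len(n_samp))
    groups <- sample(c("AFR", "EUR"), n_samp, replace = TRUE)
    gts <- matrix(
      paste0(sample(c("0", "1", "."), n_site * n_samp, replace = TRUE),
             sample(c("/", "|"), n_site * n_samp, replace = TRUE),
             sample(c("0", "1", "."), n_site * n_samp, replace = TRUE)),
      nrow = n_site
    )
    tf <- withr::local_tempfile(fileext = ".vcf")
    write_test_vcf(tf, samples, vapply(seq_len(n_site), function(i) {
      vcf_record("1", i * 100, paste0("r", i), "A", "C", gts[i, ])
    }, character(1)))
    man <- test_manifest(samples, groups, groups)
    counts <- scan_sites(tf, man, "d1")
    for (i in seq_len(n_site)) {
      for (g in unique(groups)) {
        want <- oracle_tally(gts[i, groups == g])
        got <- counts[counts$pos == i * 100 & counts$group == g, ]
        expect_equal(got$ref_count, unname(want["ref"]))
        expect_equal(got$alt_count, unname(want["alt"]))
        expect_equal(got$missing_count, unname(want["missing"]))
        expect_equal(got$ref_count + got$alt_count + got$missing_count,
                     2 * sum(groups == g))
      }
    }
  }
})

test_that("region counts equal the sum of population counts, and scans are idempotent", {
  withr::local_seed(77)
  samples <- paste0("s", 1:12)
  pops <- rep(c("YRI", "LWK", "CEU"), each = 4)
  regions <- rep(c("AFR", "AFR", "EUR"), each = 4)
  gts <- matrix(sample(c("0/0", "0/1", "1/1", "./."), 5 * 12,
                       replace = TRUE), nrow = 5)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(tf, samples, vapply(1:5, function(i) {
    vcf_record("1", i * 10, ".", "A", "G", gts[i, ])
  }, character(1)))
  man <- test_manifest(samples, pops, regions)

  by_region <- scan_sites(tf, man, "d1", grouping = "region")
  by_pop <- scan_sites(tf, man, "d1", grouping = "population")
  pop2region <- c(YRI = "AFR", LWK = "AFR", CEU = "EUR")
  rolled <- by_pop |>
    dplyr::mutate(group = unname(pop2region[group])) |>
    dplyr::group_by(chrom, pos, site_id, ref, alt, group) |>
    dplyr::summarise(dplyr::across(c(ref_count, alt_count, missing_count),
                                   sum), .groups = "drop") |>
    dplyr::arrange(pos, group)
  region_cmp <- by_region |>
    dplyr::select(chrom, pos, site_id, ref, alt, group,
                  ref_count, alt_count, missing_count) |>
    dplyr::arrange(pos, group)
  attr(region_cmp, "skip_log") <- NULL
  expect_equal(rolled, region_cmp)
  # site ids without an rsID fall back to chrom:pos:ref:alt
  expect_true(all(grepl("^1:\\d+:A:G$", by_region$site_id)))
  expect_identical(scan_sites(tf, man, "d1"), by_region)
})

test_that("ancestral annotations are parsed across dialects", {
  out <- parse_ancestral(c(
    "AC=12;AA=T;DP=99", "AA=.", "AA=g|||", "DP=3", "AA=-", "AA=N",
    "AA=c", "XAA=G"
  ))
  expect_equal(out$ancestral,
               c("T", NA, "G", NA, NA, NA, "C", NA))
  expect_equal(out$confidence,
               c("high", "unknown", "low", "unknown", "unknown",
                 "unknown", "low", "unknown"))
})
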