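#' Configuration for the synthetic three-cohort generator
#'
#' Builds a deterministic specification of three cohorts emulating the
#' study design: a small discovery panel of minimally admixed populations
#' (47/8/19/22/41 individuals for AFR/AMR/OCE/EAS/EUR plus a South Asian
#' panel), a large partly admixed validation cohort in 1000-Genomes
#' style (600/347/504/503/489 for AFR/AMR/EAS/EUR/SAS, no Oceania), and a
#' medium second validation cohort in EGDP style (402 individuals
#' including 51 Oceanians). Admixed populations (American and South
#' Asian panels) draw a fraction of their haplotypes from a donor region
#' under a haplotype-level admixture model.
#'
#' Planted sites come in five kinds: `arsa_plant` (abundant in one region,
#' absent elsewhere), `raca_plant` (common worldwide, absent in one
#' region), `decoy_discovery_only` (region-specific in the discovery
#' cohort only — validation must eliminate it), `cosmopolitan` (same
#' frequency everywhere), and `monomorphic`. Default plant frequencies
#' are set by power analysis so that every plant sits several binomial
#' standard deviations clear of the filter thresholds even in the
#' smallest panel (8 diploids), making exact-recovery assertions fair;
#' see the package vignette.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @param n_arsa_per_region Region-specific plants per target region
#'   (targets cycle AFR, AMR, EAS, EUR, OCE).
#' @param n_raca_per_region Regional-absence plants per target region
#'   (targets cycle AFR, EUR, EAS).
#' @param n_decoy_per_region Discovery-only decoys per region.
#' @param n_cosmopolitan,n_monomorphic Background site counts.
#' @param arsa_region_freq In-region frequency of ARSA plants: a named
#'   vector per target region or a single number. The defaults place each
#'   plant several binomial standard deviations above its own count
#'   threshold at the smallest panel *and* below the regional-absence
#'   world-count rule in every other region's pool; the European default
#'   is lower because the large European panel plus admixture spillover
#'   into South Asian and American panels would otherwise push a
#'   European plant's worldwide copy count near the 1000-copy
#'   regional-absence rule (see the vignette).
#' @param raca_world_freq Worldwide frequency of RACA plants (default
#'   0.60).
#' @param decoy_discovery_freq,decoy_background_freq Decoy frequency in
#'   the discovery target panel vs everywhere in the validation cohorts.
#' @param cosmo_freq_range Range of cosmopolitan frequencies (spread
#'   evenly).
#' @param validation2_n_per_region If set, overrides the EGDP-style
#'   panel sizes with this many individuals per region (used for
#'   large-validation experiments).
#' @param ld_twins If `TRUE`, each ARSA plant gets a twin site ~1.8 kb
#'   away carrying an identical genotype column, emulating perfect
#'   linkage disequilibrium to exercise proximity clustering.
#' @param n_invalid Number of deliberately non-conforming VCF records
#'   (multi-allelic, indel) appended to each cohort to exercise the
#'   skip log (0, 1 or 2).
#' @param chrom_length Nominal chromosome length written to the VCF
#'   header.
#' @param populations Optional custom population roster (tibble with
#'   columns `dataset`, `population`, `region`, `n`, `admixture`,
#'   `source`) replacing the default three-cohort design. Plants whose
#'   target region is absent from the roster fall back to their
#'   world frequency everywhere.
#' @return A list of class `"synth_config"` with elements `populations`
#'   (tibble: dataset, population, region, n, admixture, source) and
#'   `sites` (tibble: site_id, kind, target_region, region_freq,
#'   world_freq, chrom, pos, ref, alt, ancestral_choice, swap, copy_of),
#'   plus the scalar settings.
#' @export
synth_config <- function(seed = 1L,
                         n_arsa_per_region = 4L,
                         n_raca_per_region = 5L,
                         n_decoy_per_region = 2L,
                         n_cosmopolitan = 145L,
                         n_monomorphic = 10L,
                         arsa_region_freq = c(AFR = 0.70, AMR = 0.70,
                                              EAS = 0.70, EUR = 0.45,
                                              OCE = 0.70),
                         raca_world_freq = 0.60,
                         decoy_discovery_freq = 0.25,
                         decoy_background_freq = 0.05,
                         cosmo_freq_range = c(0.05, 0.5),
                         validation2_n_per_region = NULL,
                         ld_twins = FALSE,
                         n_invalid = 2L,
                         chrom_length = 5e6,
                         populations = NULL) {
  stopifnot(
    arsa_region_freq > 0, arsa_region_freq <= 1,
    raca_world_freq > 0, raca_world_freq <= 1,
    length(cosmo_freq_range) == 2, all(cosmo_freq_range >= 0),
    all(cosmo_freq_range <= 1), n_invalid %in% 0:2
  )

  pops <- if (is.null(populations)) {
    synth_populations(validation2_n_per_region)
  } else {
    stopifnot(all(c("dataset", "population", "region", "n",
                    "admixture", "source") %in% names(populations)))
    as_tibble(populations)
  }

  arsa_targets <- rep(c("AFR", "AMR", "EAS", "EUR", "OCE"),
                      each = n_arsa_per_region)
  arsa_freq_of <- if (length(arsa_region_freq) == 1 &&
                      is.null(names(arsa_region_freq))) {
    setNames(rep(arsa_region_freq, length(unique(arsa_targets))),
             unique(arsa_targets))
  } else {
    arsa_region_freq
  }
  if (!all(unique(arsa_targets) %in% names(arsa_freq_of))) {
    abort("`arsa_region_freq` must name every ARSA target region.")
  }
  raca_targets <- rep(c("AFR", "EUR", "EAS"), each = n_raca_per_region)
  decoy_targets <- rep(c("AFR", "AMR", "EAS", "EUR", "OCE"),
                       each = n_decoy_per_region)
  cosmo_freq <- if (n_cosmopolitan > 0) {
    seq(cosmo_freq_range[1], cosmo_freq_range[2],
        length.out = n_cosmopolitan)
  } else {
    numeric()
  }

  sites <- bind_rows(
    tibble(kind = "arsa_plant", target_region = arsa_targets,
           region_freq = unname(arsa_freq_of[arsa_targets]),
           world_freq = 0),
    tibble(kind = "raca_plant", target_region = raca_targets,
           region_freq = 0, world_freq = raca_world_freq),
    tibble(kind = "decoy_discovery_only", target_region = decoy_targets,
           region_freq = decoy_discovery_freq,
           world_freq = decoy_background_freq),
    tibble(kind = "cosmopolitan", target_region = NA_character_,
           region_freq = cosmo_freq, world_freq = cosmo_freq),
    tibble(kind = "monomorphic", target_region = NA_character_,
           region_freq = 0, world_freq = 0)[
             rep(1, n_monomorphic), , drop = FALSE]
  )

  # deterministic interleaving: plants scattered among background sites
  n <- nrow(sites)
  sites <- sites[order(rep_len(seq_len(7), n), seq_len(n)), ]

  base_pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                     c("A", "C"), c("G", "T"))
  pair <- base_pairs[rep_len(seq_along(base_pairs), n)]
  gaps <- rep_len(c(1500L, 3200L, 8000L, 25000L, 6000L, 12000L), n)
  sites <- sites |>
    mutate(
      site_id = sprintf("s%03d", seq_len(n)),
      chrom = "1",
      pos = 10000L + cumsum(gaps),
      ref = purrr::map_chr(pair, 1),
      alt = purrr::map_chr(pair, 2),
      ancestral_choice = rep_len(c("alt", "ref", "unknown"), n),
      swap = seq_len(n) %% 7L == 0L,
      copy_of = NA_character_
    )

  if (ld_twins) {
    twins <- sites |>
      filter(.data$kind == "arsa_plant") |>
      mutate(
        copy_of = .data$site_id,
        site_id = paste0(.data$site_id, "t"),
        pos = .data$pos + 1800L
      )
    sites <- bind_rows(sites, twins) |> arrange(.data$pos)
  }

  structure(
    list(
      seed = as.integer(seed),
      populations = pops,
      sites = sites,
      n_invalid = as.integer(n_invalid),
      chrom_length = chrom_length
    ),
    class = "synth_config"
  )
}

# Panel rosters for the three emulated cohorts. Discovery panels are pure
# (zero admixture); the large validation cohort carries the strongly
# admixed American and South Asian panels; the EGDP-style cohort is
# medium-sized with an Oceania panel.
synth_populations <- function(validation2_n_per_region = NULL) {
  p <- function(dataset, population, region, n, admixture = 0,
                source = NA_character_) {
    tibble(dataset = dataset, population = population, region = region,
           n = as.integer(n), admixture = admixture, source = source)
  }
  discovery <- bind_rows(
    p("discovery", "S_AFR1", "AFR", 16), p("discovery", "S_AFR2", "AFR", 16),
    p("discovery", "S_AFR3", "AFR", 15),
    p("discovery", "S_AMR1", "AMR", 4), p("discovery", "S_AMR2", "AMR", 4),
    p("discovery", "S_OCE1", "OCE", 10), p("discovery", "S_OCE2", "OCE", 9),
    p("discovery", "S_EAS1", "EAS", 11), p("discovery", "S_EAS2", "EAS", 11),
    p("discovery", "S_EUR1", "EUR", 21), p("discovery", "S_EUR2", "EUR", 20),
    p("discovery", "S_SAS1", "SAS", 25)
  )
  validation1 <- bind_rows(
    p("validation1", "G_AFR1", "AFR", 200),
    p("validation1", "G_AFR2", "AFR", 200),
    p("validation1", "G_AFR3", "AFR", 200),
    p("validation1", "G_AMR1", "AMR", 94, 0.45, "EUR"),
    p("validation1", "G_AMR2", "AMR", 64, 0.45, "EUR"),
    p("validation1", "G_AMR3", "AMR", 85, 0.30, "EUR"),
    p("validation1", "G_AMR4", "AMR", 104, 0.45, "AFR"),
    p("validation1", "G_EAS1", "EAS", 252),
    p("validation1", "G_EAS2", "EAS", 252),
    p("validation1", "G_EUR1", "EUR", 252),
    p("validation1", "G_EUR2", "EUR", 251),
    p("validation1", "G_SAS1", "SAS", 245, 0.30, "EUR"),
    p("validation1", "G_SAS2", "SAS", 244, 0.30, "EUR")
  )
  validation2 <- if (is.null(validation2_n_per_region)) {
    bind_rows(
      p("validation2", "E_AFR1", "AFR", 50),
      p("validation2", "E_AMR1", "AMR", 15, 0.10, "EUR"),
      p("validation2", "E_EAS1", "EAS", 80),
      p("validation2", "E_EUR1", "EUR", 120),
      p("validation2", "E_OCE1", "OCE", 51),
      p("validation2", "E_SAS1", "SAS", 86, 0.20, "EUR")
    )
  } else {
    nn <- as.integer(validation2_n_per_region)
    bind_rows(
      p("validation2", "E_AFR1", "AFR", nn),
      p("validation2", "E_AMR1", "AMR", nn, 0.10, "EUR"),
      p("validation2", "E_EAS1", "EAS", nn),
      p("validation2", "E_EUR1", "EUR", nn),
      p("validation2", "E_OCE1", "OCE", nn),
      p("validation2", "E_SAS1", "SAS", nn, 0.20, "EUR")
    )
  }
  bind_rows(discovery, validation1, validation2)
}

# Nominal alternative-allele frequency per region for one dataset,
# from each site's kind: a matrix sites x regions.
nominal_freqs <- function(cfg, dataset) {
  regions <- sort(unique(cfg$populations$region))
  s <- cfg$sites
  f <- matrix(rep(s$world_freq, length(regions)),
              nrow = nrow(s), ncol = length(regions),
              dimnames = list(s$site_id, regions))
  is_decoy <- s$kind == "decoy_discovery_only"
  if (dataset == "discovery") {
    # decoys are region-private in the discovery cohort only
    f[is_decoy, ] <- 0
    tgt <- which(!is.na(s$target_region) & s$target_region %in% regions)
    f[cbind(tgt, match(s$target_region[tgt], regions))] <-
      s$region_freq[tgt]
  } else {
    # validation cohorts: decoys are uniformly rare everywhere
    tgt <- which(!is.na(s$target_region) & !is_decoy &
                   s$target_region %in% regions)
    f[cbind(tgt, match(s$target_region[tgt], regions))] <-
      s$region_freq[tgt]
  }
  f
}

# Expected alternative-allele frequency per population after haplotype-
# level admixture: (1 - a) * f[region] + a * f[donor region].
population_freqs <- function(cfg, dataset) {
  f <- nominal_freqs(cfg, dataset)
  pops <- filter(cfg$populations, .data$dataset == .env$dataset)
  out <- vapply(seq_len(nrow(pops)), function(i) {
    own <- f[, pops$region[i]]
    if (is.na(pops$source[i]) || pops$admixture[i] == 0) {
      own
    } else {
      (1 - pops$admixture[i]) * own +
        pops$admixture[i] * f[, pops$source[i]]
    }
  }, numeric(nrow(f)))
  matrix(out, nrow = nrow(f),
         dimnames = list(rownames(f), pops$population))
}

#' Generate synthetic three-cohort VCFs with a truth table
#'
#' Materialises a [synth_config()] into three VCF v4.2 files (GT-only
#' FORMAT, ancestral allele as `AA=` in INFO), a sample manifest TSV and
#' a machine-readable truth table TSV. Each haplotype originates from its
#' own population with probability `1 - admixture` and from the donor
#' region otherwise, then carries the site's alternative allele with the
#' origin region's nominal frequency, independently across sites
#' (Hardy-Weinberg; no linkage disequilibrium unless `ld_twins` copies
#' genotype columns). The large validation cohort is written phased
#' (`|`), the others unphased (`/`); in the second validation cohort
#' every seventh site has its REF/ALT roles swapped, as happens between
#' real call sets, so downstream allele matching must go by base.
#' Deterministic under the config seed.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `vcf` (named paths per dataset), `manifest_path`,
#'   `manifest` (tibble), and — when the roster contains the standard
#'   `discovery`/`validation1`/`validation2` triple — `truth` (tibble
#'   from [truth_table()]) and `truth_path` (`NULL`/`NA` otherwise).
#' @export
generate_cohorts <- function(cfg, dir = tempfile("cohorts_")) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  datasets <- unique(cfg$populations$dataset)

  manifest <- cfg$populations |>
    mutate(idx = purrr::map(.data$n, seq_len)) |>
    tidyr::unnest("idx") |>
    mutate(sample = paste0(.data$population, "_",
                           sprintf("%03d", .data$idx))) |>
    select("sample", "population", "region", "dataset", "admixture")

  paths <- withr::with_seed(cfg$seed, {
    setNames(purrr::map_chr(datasets, function(ds) {
      write_cohort_vcf(cfg, ds, file.path(dir, paste0(ds, ".vcf")))
    }), datasets)
  })

  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  # truth labels are defined for the full three-cohort design only
  standard <- all(c("discovery", "validation1", "validation2") %in% datasets)
  truth <- if (standard) truth_table(cfg) else NULL
  truth_path <- if (standard) file.path(dir, "truth.tsv") else NA_character_
  if (standard) readr::write_tsv(truth, truth_path, progress = FALSE)

  list(
    vcf = paths, manifest_path = manifest_path, truth_path = truth_path,
    manifest = manifest, truth = truth
  )
}

write_cohort_vcf <- function(cfg, dataset, path) {
  s <- cfg$sites
  pops <- filter(cfg$populations, .data$dataset == .env$dataset)
  pf <- population_freqs(cfg, dataset)
  sep <- if (dataset == "validation1") "|" else "/"
  swap <- if (dataset == "validation2") s$swap else rep(FALSE, nrow(s))

  hap <- function(p, n_ind) {
    matrix(rbinom(length(p) * n_ind, 1L, rep(p, n_ind)), nrow = length(p))
  }
  gt_blocks <- purrr::map(seq_len(nrow(pops)), function(i) {
    p <- pf[, pops$population[i]]
    p_file <- ifelse(swap, 1 - p, p)
    h1 <- hap(p_file, pops$n[i])
    h2 <- hap(p_file, pops$n[i])
    matrix(paste0(h1, sep, h2), nrow = nrow(s))
  })
  gt <- do.call(cbind, gt_blocks)
  copies <- which(!is.na(s$copy_of))
  if (length(copies) > 0) {
    gt[copies, ] <- gt[match(s$copy_of[copies], s$site_id), ]
  }
  samples <- unlist(purrr::map(seq_len(nrow(pops)), function(i) {
    paste0(pops$population[i], "_", sprintf("%03d", seq_len(pops$n[i])))
  }))

  file_ref <- if_else(swap, s$alt, s$ref)
  file_alt <- if_else(swap, s$ref, s$alt)
  aa_base <- dplyr::case_when(
    s$ancestral_choice == "ref" ~ s$ref,
    s$ancestral_choice == "alt" ~ s$alt,
    TRUE ~ "."
  )
  body <- paste(
    s$chrom, s$pos, s$site_id, file_ref, file_alt, ".", "PASS",
    paste0("AA=", aa_base), "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  if (cfg$n_invalid > 0) {
    inv_pos <- max(s$pos) + c(10000L, 20000L)
    filler <- paste(rep("0/0", length(samples)), collapse = "\t")
    inv <- c(
      paste("1", inv_pos[1], "inv_multi", "A", "C,T", ".", "PASS",
            "AA=A", "GT", filler, sep = "\t"),
      paste("1", inv_pos[2], "inv_indel", "AT", "A", ".", "PASS",
            "AA=.", "GT", filler, sep = "\t")
    )
    body <- c(body, inv[seq_len(cfg$n_invalid)])
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=1,length=", format(cfg$chrom_length,
                                            scientific = FALSE), ">"),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}
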