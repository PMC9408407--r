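#' Parse ancestral-allele annotations from VCF INFO strings
#'
#' The ancestral allele is carried in the INFO column as `AA=n`. The
#' 1000-Genomes dialect appends pipe-delimited extra fields
#' (`AA=g|||`); only the first token is used. Case encodes annotation
#' confidence: uppercase = high, lowercase = low. `"."`, `"-"`, `"N"`,
#' or a missing AA subfield mean the ancestral state is unknown. Total on
#' strings: never errors.
#'
#' @param info_field Character vector of raw VCF INFO strings.
#' @return A tibble with columns `ancestral` (uppercase base or `NA`) and
#'   `confidence` (`"high"`, `"low"`, or `"unknown"`).
#' @examples
#' parse_ancestral(c("AC=12;AA=T;DP=99", "AA=.", "AA=g|||", "DP=3"))
#' @export
parse_ancestral <- function(info_field) {
  info_field <- as.character(info_field)
  m <- stringr::str_match(info_field, "(?:^|;)AA=([^;]*)")[, 2]
  tok <- stringr::str_split_i(m, stringr::fixed("|"), 1)
  tok <- stringr::str_trim(tok)
  known <- !is.na(tok) & tok %in% c("A", "C", "G", "T", "a", "c", "g", "t")
  tibble(
    ancestral = if_else(known, toupper(tok), NA_character_),
    confidence = dplyr::case_when(
      known & tok %in% c("A", "C", "G", "T") ~ "high",
      known ~ "low",
      TRUE ~ "unknown"
    )
  )
}

#' Per-group allele counts from a VCF
#'
#' Reads a VCF (plain or bgzipped), restricts to the manifest samples of
#' one dataset, and tallies reference/alternative/missing allele copies
#' per population or per region for every biallelic SNV. Multi-allelic
#' records, non-SNVs, records on excluded chromosomes, and records with
#' malformed genotypes are skipped and itemised in a skip log (see
#' [skip_log()]). Missing genotypes (`./.`) count as missing copies only,
#' so frequencies downstream use called chromosomes as denominator;
#' half-calls (`0/.`) contribute one called and one missing copy. Phased
#' (`|`) and unphased (`/`) separators are treated identically.
#'
#' @param vcf_path Path to a VCF v4.x file.
#' @param manifest Sample manifest tibble (see [read_manifest()]).
#' @param dataset Dataset id selecting the manifest rows; all of that
#'   dataset's samples must be present in the VCF header.
#' @param grouping `"region"` (default) or `"population"`: granularity of
#'   the `group` column.
#' @param exclude_chroms Chromosomes dropped before counting. Defaults to
#'   sex chromosomes and mitochondria, since the diploid 2N count
#'   arithmetic of the thresholds presumes autosomes.
#' @return A long tibble, one row per site x group:
#'   `chrom`, `pos`, `site_id`, `ref`, `alt`, `ancestral`,
#'   `ancestral_conf`, `group`, `ref_count`, `alt_count`,
#'   `missing_count`. For every group
#'   `ref_count + alt_count + missing_count == 2 * group size`.
#'   The skip log is attached as attribute `"skip_log"`.
#' @export
scan_sites <- function(vcf_path, manifest, dataset,
                       grouping = c("region", "population"),
                       exclude_chroms = c("X", "Y", "MT", "M",
                                          "chrX", "chrY", "chrM")) {
  grouping <- match.arg(grouping)
  man <- filter(validate_manifest(manifest), .data$dataset == .env$dataset)
  if (nrow(man) == 0) {
    abort(paste0("No samples for dataset '", dataset, "' in manifest."))
  }

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcf@fix
  vcf_samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(man$sample, vcf_samples)
  if (length(absent) > 0) {
    abort(paste0(
      "Manifest sample(s) absent from VCF header: ",
      paste(utils::head(absent, 10), collapse = ", "),
      if (length(absent) > 10) ", ..." else "", "."
    ))
  }

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")

  skip_reason <- rep(NA_character_, nrow(fix))
  skip_reason[chrom %in% exclude_chroms] <- "excluded_chrom"
  multi <- is.na(skip_reason) & grepl(",", alt, fixed = TRUE)
  skip_reason[multi] <- "multiallelic"
  nonsnv <- is.na(skip_reason) &
    (!(ref %in% bases) | !(alt %in% bases) | ref == alt)
  skip_reason[nonsnv] <- "non_snv"

  gt <- vcfR::extract.gt(vcf, element = "GT", convertNA = FALSE)
  gt <- gt[, man$sample, drop = FALSE]
  gt[is.na(gt)] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  # first and second allele token of each diploid call; haploid calls
  # contribute one called plus one missing copy (conservative)
  a1 <- sub("/.*$", "", gt)
  a2 <- ifelse(grepl("/", gt, fixed = TRUE), sub("^[^/]*/", "", gt), ".")
  ok_tok <- c("0", "1", ".")
  bad_gt <- matrix(!(a1 %in% ok_tok) | !(a2 %in% ok_tok), nrow = nrow(gt))
  malformed <- is.na(skip_reason) & rowSums(bad_gt) > 0
  if (any(malformed)) {
    warn(paste0(
      sum(malformed), " record(s) skipped due to malformed GT fields."
    ))
    skip_reason[malformed] <- "malformed_gt"
  }

  keep <- is.na(skip_reason)
  skips <- tibble(
    chrom = chrom[!keep], pos = pos[!keep], reason = skip_reason[!keep]
  )
  if (!any(keep)) {
    out <- tibble(
      chrom = character(), pos = integer(), site_id = character(),
      ref = character(), alt = character(), ancestral = character(),
      ancestral_conf = character(), group = character(),
      ref_count = integer(), alt_count = integer(), missing_count = integer()
    )
    attr(out, "skip_log") <- skips
    return(out)
  }

  a1 <- matrix(a1, nrow = nrow(gt))[keep, , drop = FALSE]
  a2 <- matrix(a2, nrow = nrow(gt))[keep, , drop = FALSE]
  grp <- factor(if (grouping == "region") man$region else man$population)

  count_by_group <- function(token) {
    contrib <- (a1 == token) + (a2 == token) # sites x samples
    t(rowsum(t(contrib), grp)) # sites x groups
  }
  refc <- count_by_group("0")
  altc <- count_by_group("1")
  misc <- count_by_group(".")

  aa <- parse_ancestral(fix[keep, "INFO"])
  id <- fix[keep, "ID"]
  site_id <- if_else(
    is.na(id) | id == ".",
    paste(chrom[keep], pos[keep], ref[keep], alt[keep], sep = ":"),
    id
  )
  site <- tibble(
    chrom = chrom[keep], pos = pos[keep], site_id = site_id,
    ref = ref[keep], alt = alt[keep],
    ancestral = aa$ancestral, ancestral_conf = aa$confidence
  )

  groups <- levels(grp)
  out <- purrr::map(seq_along(groups), function(i) {
    mutate(site,
      group = groups[i],
      ref_count = as.integer(refc[, i]),
      alt_count = as.integer(altc[, i]),
      missing_count = as.integer(misc[, i])
    )
  }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$pos, .data$group)

  attr(out, "skip_log") <- skips
  out
}

#' Skip log of a site scan
#'
#' Records skipped by [scan_sites()], one row per record with columns
#' `chrom`, `pos`, `reason` (`"multiallelic"`, `"non_snv"`,
#' `"excluded_chrom"`, `"malformed_gt"`).
#'
#' @param counts A tibble returned by [scan_sites()].
#' @return The skip-log tibble (empty if nothing was skipped).
#' @export
skip_log <- function(counts) {
  log <- attr(counts, "skip_log")
  if (is.null(log)) {
    tibble(chrom = character(), pos = integer(), reason = character())
  } else {
    log
  }
}
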