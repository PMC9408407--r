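#' Group called SNPs into proximity clusters
#'
#' Neighbouring region-specific SNPs are frequently in linkage
#' disequilibrium; as a proxy for independent signals, calls are chained
#' into clusters per chromosome by single linkage: after sorting by
#' position, consecutive calls strictly less than `gap_bp` apart join the
#' same cluster (distance is the difference of 1-based positions). The
#' clusters partition the call set; chaining never crosses chromosomes.
#'
#' @param calls A tibble with at least `chrom`, `pos`, `site_id` (e.g.
#'   [tidy()] of an ARSA result, or RACA calls).
#' @param gap_bp Joining distance in base pairs (default 5000).
#' @return A tibble, one row per cluster: `chrom`, `cluster_id`, `start`,
#'   `end` (1-based inclusive span), `n_snps`, `site_ids` (list column,
#'   ordered by position).
#' @examples
#' calls <- tibble::tibble(
#'   chrom = "1", pos = c(100, 4000, 12000),
#'   site_id = c("a", "b", "c")
#' )
#' cluster_by_gap(calls) # {100,4000} and {12000}
#' @export
cluster_by_gap <- function(calls, gap_bp = 5000L) {
  stopifnot(gap_bp > 0)
  if (nrow(calls) == 0) {
    return(tibble(
      chrom = character(), cluster_id = integer(), start = integer(),
      end = integer(), n_snps = integer(), site_ids = list()
    ))
  }
  calls |>
    distinct(.data$chrom, .data$pos, .data$site_id) |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(
      new_cluster = is.na(lag(.data$pos)) |
        (.data$pos - lag(.data$pos)) >= .env$gap_bp,
      within_chrom = cumsum(.data$new_cluster)
    ) |>
    ungroup() |>
    mutate(key = paste(.data$chrom, .data$within_chrom)) |>
    mutate(cluster_id = match(.data$key, unique(.data$key))) |>
    group_by(.data$chrom, .data$cluster_id) |>
    summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_snps = dplyr::n(), site_ids = list(.data$site_id),
      .groups = "drop"
    ) |>
    arrange(.data$cluster_id)
}

#' Ancestral vs derived composition of a call set
#'
#' Classifies each called allele against the site's ancestral base (from
#' the VCF `AA` annotation, see [parse_ancestral()]): "ancestral" when
#' the called region-specific/absent allele equals the ancestral base,
#' "derived" when the ancestral base is the site's other allele, and
#' "unknown" when the ancestral state is missing or matches neither
#' allele. Percentages are over known calls only and rounded to integers
#' (half-up, the convention of the published summary tables);
#' `pct_derived` is reported as the complement so the two always sum to
#' 100.
#'
#' @param calls A tibble with columns `allele`, `ref`, `alt`, `ancestral`
#'   (uppercase base or `NA`).
#' @return One-row tibble: `n_ancestral`, `n_derived`, `n_unknown`,
#'   `pct_ancestral`, `pct_derived` (both `NA` when no call has a known
#'   ancestral state).
#' @export
polarity_summary <- function(calls) {
  status <- dplyr::case_when(
    is.na(calls$ancestral) ~ "unknown",
    !(calls$ancestral == calls$ref | calls$ancestral == calls$alt) ~ "unknown",
    calls$allele == calls$ancestral ~ "ancestral",
    TRUE ~ "derived"
  )
  n_anc <- sum(status == "ancestral")
  n_der <- sum(status == "derived")
  n_unk <- sum(status == "unknown")
  known <- n_anc + n_der
  pct_anc <- if (known > 0) floor(100 * n_anc / known + 0.5) else NA_real_
  tibble(
    n_ancestral = n_anc, n_derived = n_der, n_unknown = n_unk,
    pct_ancestral = pct_anc,
    pct_derived = if (known > 0) 100 - pct_anc else NA_real_
  )
}

#' Read gene intervals from BED or GFF3
#'
#' Thin wrapper over `rtracklayer::import()` returning a tibble in
#' 1-based inclusive coordinates (BED's 0-based half-open intervals are
#' converted on import: `[start, end)` zero-based becomes
#' `[start + 1, end]` one-based). For GFF3, only `type == "gene"`
#' records are kept (all records if none are typed "gene"); the gene
#' identifier is taken from `gene_name`, `Name`, `gene_id` or `ID`,
#' whichever exists first.
#'
#' @param path File path; format inferred from the extension unless
#'   given.
#' @param format `"bed"` or `"gff3"`.
#' @return Tibble with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
      "bed"
    } else {
      "gff3"
    }
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  meta <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(meta) &&
      any(meta$type == "gene")) {
    keep <- meta$type == "gene"
    gr <- gr[keep]
    meta <- meta[keep, , drop = FALSE]
  }
  id_col <- intersect(c("gene_name", "Name", "gene_id", "ID", "name"),
                      names(meta))
  gene_id <- if (length(id_col) > 0) {
    as.character(meta[[id_col[1]]])
  } else {
    paste0("gene_", seq_along(gr))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene_id = gene_id
  )
}

#' Assign called SNPs to overlapping gene intervals
#'
#' Plain genomic interval overlap of call positions against gene bodies
#' (1-based inclusive on both sides). A site overlapping k gene intervals
#' maps to k genes; sites overlapping none are absent from the result.
#' This is a deliberate simplification of transcript-aware annotation:
#' boundary cases (promoters, UTR-only overlaps) differ from what an
#' effect predictor would report.
#'
#' @param calls Tibble with `chrom`, `pos`, `site_id`.
#' @param genes Tibble with `chrom`, `start`, `end`, `gene_id` in 1-based
#'   inclusive coordinates (see [read_gene_intervals()]).
#' @return Tibble of overlapping pairs: `site_id`, `gene_id`.
#' @export
assign_genes <- function(calls, genes) {
  sites <- distinct(calls, .data$chrom, .data$pos, .data$site_id)
  if (nrow(sites) == 0 || nrow(genes) == 0) {
    return(tibble(site_id = character(), gene_id = character()))
  }
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos, sites$pos)
  )
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  tibble(
    site_id = sites$site_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)]
  ) |>
    distinct() |>
    arrange(.data$gene_id, .data$site_id)
}

#' Distribution of called SNPs per gene
#'
#' Tallies the inverse of a gene assignment: how many genes carry exactly
#' n assigned SNPs. Genes with zero assigned SNPs are excluded, so the
#' histogram mass equals the number of assigned genes.
#'
#' @param assignment Tibble of `site_id`, `gene_id` pairs from
#'   [assign_genes()].
#' @return Tibble with columns `n_snps`, `n_genes`, ascending in
#'   `n_snps`.
#' @export
snps_per_gene <- function(assignment) {
  if (nrow(assignment) == 0) {
    return(tibble(n_snps = integer(), n_genes = integer()))
  }
  assignment |>
    distinct(.data$site_id, .data$gene_id) |>
    dplyr::count(.data$gene_id, name = "n_snps") |>
    dplyr::count(.data$n_snps, name = "n_genes") |>
    arrange(.data$n_snps)
}

#' Bar chart of the SNPs-per-gene distribution
#'
#' @param histogram Tibble from [snps_per_gene()].
#' @return A ggplot object.
#' @export
plot_snps_per_gene <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$n_snps), y = .data$n_genes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "SNPs assigned to gene", y = "Number of genes") +
    ggplot2::theme_minimal()
}
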