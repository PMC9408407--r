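# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# O(n^2) union-find clustering: join any two sites on the same chromosome
# strictly closer than gap_bp, then count connected components.
oracle_cluster_count <- function(chrom, pos, gap_bp) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && chrom[i] == chrom[j] &&
          abs(pos[i] - pos[j]) < gap_bp) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Naive per-genotype allele tally: loop over samples and split every GT
# string by hand.
oracle_tally <- function(gt_strings) {
  ref <- 0L
  alt <- 0L
  mis <- 0L
  for (g in gt_strings) {
    toks <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (length(toks) == 1) toks <- c(toks, ".")
    for (t in toks) {
      if (t == "0") ref <- ref + 1L
      else if (t == "1") alt <- alt + 1L
      else mis <- mis + 1L
    }
  }
  c(ref = ref, alt = alt, missing = mis)
}

# All-pairs interval overlap for point queries (1-based inclusive).
oracle_overlap <- function(sites, genes) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(genes))) {
      if (sites$chrom[i] == genes$chrom[j] &&
          sites$pos[i] >= genes$start[j] &&
          sites$pos[i] <= genes$end[j]) {
        out[[length(out) + 1]] <- c(sites$site_id[i], genes$gene_id[j])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(site_id = character(), gene_id = character()))
  }
  m <- do.call(rbind, out)
  unique(tibble::tibble(site_id = m[, 1], gene_id = m[, 2]))
}

# Per-gene membership-mask tally for exclusive combination counts.
oracle_combinations <- function(gene_lists) {
  genes <- unique(unlist(gene_lists))
  combos <- vapply(genes, function(g) {
    paste(names(gene_lists)[vapply(gene_lists, function(l) g %in% l,
                                   logical(1))], collapse = "&")
  }, character(1))
  table(combos)
}

# Minimal hand-rolled VCF writer for handcrafted fixtures.
write_test_vcf <- function(path, samples, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts, info = ".") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")
}

test_manifest <- function(samples, population, region,
                          dataset = "d1", admixture = 0) {
  tibble::tibble(
    sample = samples, population = population, region = region,
    dataset = dataset, admixture = admixture
  )
}

# One site x group count row for handcrafted pipeline fixtures.
count_row <- function(group, ref_count, alt_count, missing_count = 0L,
                      chrom = "1", pos = 100L, site_id = "s1",
                      ref = "A", alt = "G", ancestral = NA_character_,
                      ancestral_conf = "unknown") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), site_id = site_id,
    ref = ref, alt = alt, ancestral = ancestral,
    ancestral_conf = ancestral_conf, group = group,
    ref_count = as.integer(ref_count), alt_count = as.integer(alt_count),
    missing_count = as.integer(missing_count)
  )
}

panel_row <- function(region, n_individuals, mean_admixture = 0) {
  tibble::tibble(region = region, n_individuals = n_individuals,
                 mean_admixture = mean_admixture)
}

# Expand a comma-separated truth label into "site region" pairs.
truth_pairs <- function(site_id, label) {
  ok <- !is.na(label)
  if (!any(ok)) return(character())
  unlist(mapply(function(s, l) paste(s, strsplit(l, ",")[[1]]),
                site_id[ok], label[ok], SIMPLIFY = FALSE),
         use.names = FALSE)
}
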