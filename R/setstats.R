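#' Exclusive gene-list combination counts
#'
#' UpSet-style decomposition of several gene lists: every gene in the
#' union is counted in exactly one combination, the set of all lists that
#' contain it, so the counts over all combinations sum to the size of the
#' union.
#'
#' @param gene_lists Named list (length >= 2) of character vectors of
#'   gene identifiers.
#' @return Tibble with columns `combination` (list names joined by
#'   `"&"`), `sets` (list column of member list names), `degree`, and
#'   `observed`, sorted by decreasing count.
#' @examples
#' combination_counts(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
combination_counts <- function(gene_lists) {
  if (length(gene_lists) < 2) {
    abort("`gene_lists` must contain at least two lists.")
  }
  if (is.null(names(gene_lists)) || any(names(gene_lists) == "")) {
    abort("`gene_lists` must be a fully named list.")
  }
  gene_lists <- purrr::map(gene_lists, unique)
  universe <- unique(unlist(gene_lists, use.names = FALSE))
  mask <- vapply(gene_lists, function(g) universe %in% g,
                 logical(length(universe)))
  mask <- matrix(mask, nrow = length(universe),
                 dimnames = list(NULL, names(gene_lists)))
  combo <- apply(mask, 1, function(row) {
    paste(names(gene_lists)[row], collapse = "&")
  })
  tibble(combination = combo) |>
    dplyr::count(.data$combination, name = "observed") |>
    mutate(
      sets = stringr::str_split(.data$combination, stringr::fixed("&")),
      degree = lengths(.data$sets)
    ) |>
    select("combination", "sets", "degree", "observed") |>
    arrange(dplyr::desc(.data$observed), .data$combination)
}

#' Expected overlap of random gene sets
#'
#' Mean overlap between a random sample of `sample_size` genes and a
#' fixed set of `set_size` genes drawn from a universe of `universe`
#' genes: `sample_size * set_size / universe` (the hypergeometric mean).
#' With a 25,000-gene universe, 100 random genes are expected to hit an
#' African-scale set of 6400 genes about 25.6 times.
#'
#' @param sample_size,set_size Sizes of the two sets.
#' @param universe Total number of genes to draw from.
#' @return Expected overlap (numeric).
#' @examples
#' expected_overlap(100, 6400, 25000) # 25.6
#' @export
expected_overlap <- function(sample_size, set_size, universe) {
  if (sample_size < 0 || set_size < 0 || universe < 1 ||
      sample_size > universe || set_size > universe) {
    abort("Require 0 <= sample_size, set_size <= universe.")
  }
  sample_size * set_size / universe
}

#' Monte-Carlo p-value for a multi-list gene overlap
#'
#' Null model: each list is replaced by a uniform random gene set of the
#' same size, drawn without replacement from the universe, independently
#' across lists. Each permutation records the size of the intersection of
#' all drawn sets; the p-value uses the add-one estimator
#' `p = (1 + #(perm >= observed)) / (n_perm + 1)`, which is never zero
#' and has resolution `1/(n_perm + 1)`. Deterministic under a fixed
#' `seed`.
#'
#' @param observed Observed overlap count of the real lists.
#' @param list_sizes Integer vector (length >= 2) of the list sizes.
#' @param universe Number of genes in the sampling universe (25,000 is a
#'   conventional human gene total).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed; drawn randomly if `NULL`.
#' @param combination Optional label for the tested combination.
#' @return One-row tibble: `combination`, `observed`, `expected`
#'   (product-form expectation `U * prod(size_i / U)`), `null_mean`
#'   (mean permuted overlap), `p_value`, `n_perm`, `seed`.
#' @examples
#' mc_intersection_pvalue(3, c(3, 3), universe = 6, n_perm = 2000, seed = 1)
#' @export
mc_intersection_pvalue <- function(observed, list_sizes, universe,
                                   n_perm = 10000L, seed = NULL,
                                   combination = NA_character_) {
  if (length(list_sizes) < 2) {
    abort("`list_sizes` must have at least two entries.")
  }
  if (any(list_sizes < 0) || any(list_sizes > universe)) {
    abort("All list sizes must lie in [0, universe].")
  }
  if (n_perm < 1) {
    abort("`n_perm` must be at least 1.")
  }
  if (observed > min(list_sizes)) {
    abort("`observed` cannot exceed the smallest list size.")
  }
  if (observed < 0) {
    abort("`observed` must be non-negative.")
  }
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
  }
  sizes <- sort(as.integer(list_sizes), decreasing = TRUE)
  perm_overlap <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      inter <- sample.int(universe, sizes[1])
      for (s in sizes[-1]) {
        inter <- inter[inter %in% sample.int(universe, s)]
        if (length(inter) == 0) break
      }
      length(inter)
    }, integer(1))
  })
  tibble(
    combination = combination,
    observed = as.integer(observed),
    expected = universe * prod(list_sizes / universe),
    null_mean = mean(perm_overlap),
    p_value = (1 + sum(perm_overlap >= observed)) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  )
}

#' Test an observed gene-list intersection against the random expectation
#'
#' Convenience wrapper: computes the plain intersection of the named
#' lists (every gene present in all of them, regardless of other lists)
#' and its Monte-Carlo p-value via [mc_intersection_pvalue()].
#'
#' @param gene_lists Named list of character vectors.
#' @param combination Names of the lists whose joint intersection is
#'   tested (default: all).
#' @inheritParams mc_intersection_pvalue
#' @return One-row tibble as in [mc_intersection_pvalue()].
#' @export
intersection_test <- function(gene_lists, combination = names(gene_lists),
                              universe = 25000L, n_perm = 10000L,
                              seed = NULL) {
  missing_lists <- setdiff(combination, names(gene_lists))
  if (length(missing_lists) > 0) {
    abort(paste0("Unknown list(s): ", paste(missing_lists, collapse = ", ")))
  }
  lists <- purrr::map(gene_lists[combination], unique)
  observed <- length(purrr::reduce(lists, intersect))
  mc_intersection_pvalue(
    observed, lengths(lists), universe,
    n_perm = n_perm, seed = seed,
    combination = paste(combination, collapse = "&")
  )
}

#' Exact upper binomial tail
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, used as the exact sign test for
#' ancestral-vs-derived polarity on small call sets: with 8 informative
#' calls of which 7 are ancestral, the one-sided tail at p = 1/2 is
#' 9/256 = 0.0352.
#'
#' @param n Number of trials.
#' @param k Threshold count (`0 <= k <= n`).
#' @param p Success probability.
#' @return `P(X >= k)` as a numeric scalar.
#' @examples
#' exact_binomial_tail(8, 7, 0.5) # 9/256
#' @export
exact_binomial_tail <- function(n, k, p) {
  if (length(n) != 1 || length(k) != 1 || length(p) != 1 ||
      n < 0 || k < 0 || k > n || p < 0 || p > 1 ||
      n != round(n) || k != round(k)) {
    abort("Require integers 0 <= k <= n and p in [0, 1].")
  }
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Bar chart of exclusive combination counts
#'
#' A compact textual substitute for an UpSet diagram: one bar per
#' combination, labelled by the member lists.
#'
#' @param combos Tibble from [combination_counts()].
#' @return A ggplot object.
#' @export
plot_combination_counts <- function(combos) {
  ggplot2::ggplot(combos,
                  ggplot2::aes(x = stats::reorder(.data$combination,
                                                  -.data$observed),
                               y = .data$observed)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Combination", y = "Genes (exclusive)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
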