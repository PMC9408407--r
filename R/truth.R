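#' Expected call labels for a synthetic configuration
#'
#' Derives, for every synthetic site, whether it should be recovered as a
#' region-specific (ARSA) or regionally absent (RACA) allele, from the
#' nominal planted frequencies and the threshold arithmetic alone —
#' sampling noise is ignored. Every filter rule of the pipeline is
#' re-expressed as an expected-allele-copy margin (admixture leakage into
#' panels is accounted for exactly); a site whose smallest margin lies
#' within `buffer` copies of a threshold is flagged borderline, so tests
#' can exclude it from hard assertions. Both alleles of every site are
#' evaluated against every target region, so accidental passers
#' (e.g. the reference allele of a planted site) are labelled too.
#'
#' The regional-absence labels are evaluated against the large validation
#' cohort (`validation1`), where the scan runs.
#'
#' @param cfg A [synth_config()].
#' @param thresholds A [threshold_config()].
#' @param policy ARSA exclusion policy (default
#'   [default_exclusion_policy()]).
#' @param raca_policy RACA exclusion policy (default
#'   [default_raca_policy()]).
#' @param buffer Borderline margin in allele copies (default 2).
#' @return A tibble, one row per site: `site_id`, `kind`,
#'   `target_region`, `pos`, `should_pass_arsa` (region id or `NA`;
#'   comma-separated if a site qualifies in several regions),
#'   `arsa_allele`, `arsa_borderline`, `should_pass_raca`,
#'   `raca_allele`, `raca_borderline`.
#' @export
truth_table <- function(cfg, thresholds = threshold_config(),
                        policy = default_exclusion_policy(),
                        raca_policy = default_raca_policy(),
                        buffer = 2) {
  stopifnot(inherits(cfg, "synth_config"))
  datasets <- c("discovery", "validation1", "validation2")
  panels <- purrr::map(datasets, function(ds) {
    filter(cfg$populations, .data$dataset == .env$ds) |>
      group_by(region = .data$region) |>
      summarise(
        n_individuals = sum(.data$n),
        mean_admixture = sum(.data$n * .data$admixture) / sum(.data$n),
        .groups = "drop"
      )
  })
  names(panels) <- datasets

  # panel-level expected alt frequency: sites x regions, per dataset
  eff <- purrr::map(datasets, function(ds) {
    pf <- population_freqs(cfg, ds)
    pops <- filter(cfg$populations, .data$dataset == .env$ds)
    w <- vapply(panels[[ds]]$region, function(R) {
      idx <- pops$region == R
      as.numeric(pf[, idx, drop = FALSE] %*% pops$n[idx]) /
        sum(pops$n[idx])
    }, numeric(nrow(cfg$sites)))
    matrix(w, nrow = nrow(cfg$sites),
           dimnames = list(cfg$sites$site_id, panels[[ds]]$region))
  })
  names(eff) <- datasets

  n_sites <- nrow(cfg$sites)
  arsa_targets <- intersect(panels$discovery$region,
                            c("AFR", "AMR", "EAS", "EUR", "OCE"))
  raca_targets <- intersect(c("AFR", "EUR", "EAS"),
                            panels$validation1$region)

  chroms2n <- function(panel) setNames(2 * panel$n_individuals, panel$region)

  # Ceiling-type rules: a structurally zero expected count (every
  # contributing frequency exactly 0) is deterministic, not borderline,
  # so its margin is +Inf rather than the small cutoff value.
  ceiling_margin <- function(cutoff, expected) {
    if_else(expected == 0, Inf, cutoff - expected)
  }

  eval_arsa <- function(Fa, R) {
    n1 <- chroms2n(panels$discovery)
    k1 <- min_count_threshold(panels$discovery$n_individuals[
      panels$discovery$region == R], thresholds$base_fraction)
    excl <- excluded_regions_for(policy, R)
    m <- list()
    m$disc_region <- Fa$discovery[, R] * n1[R] - k1
    others <- setdiff(names(n1), c(R, excl))
    m$disc_world <- ceiling_margin(
      thresholds$step1_world_max_count,
      as.numeric(Fa$discovery[, others, drop = FALSE] %*% n1[others])
    )
    for (ds in c("validation1", "validation2")) {
      nv <- chroms2n(panels[[ds]])
      lbl <- if (ds == "validation1") "v1" else "v2"
      if (R %in% names(nv)) {
        adm <- panels[[ds]]$mean_admixture[panels[[ds]]$region == R]
        thr <- adjusted_threshold(thresholds$base_fraction, adm)
        m[[paste0(lbl, "_freq")]] <- (Fa[[ds]][, R] - thr) * nv[R]
        pool <- setdiff(names(nv), c(R, excl))
        w <- as.numeric(Fa[[ds]][, pool, drop = FALSE] %*% nv[pool])
        wan <- sum(nv[pool])
        m[[paste0(lbl, "_ratio")]] <- if_else(
          w == 0, Inf,
          Fa[[ds]][, R] * wan / thresholds$world_ratio - w
        )
      } else if (identical(R, thresholds$oceania_region)) {
        tot <- as.numeric(Fa[[ds]] %*% nv)
        m[[paste0(lbl, "_ceiling")]] <-
          ceiling_margin(thresholds$oceania_world_max_count, tot)
      }
    }
    do.call(cbind, m)
  }

  eval_raca <- function(Fa2, R) {
    nv <- chroms2n(panels$validation1)
    excl <- excluded_regions_for(raca_policy, R)
    pool <- setdiff(names(nv), c(R, excl))
    w <- as.numeric(Fa2[, pool, drop = FALSE] %*% nv[pool])
    cbind(
      in_region = ceiling_margin(thresholds$raca_in_region_max_count,
                                 Fa2[, R] * nv[R]),
      world = w - thresholds$raca_world_min_count
    )
  }

  classify <- function(margins) {
    lo <- apply(margins, 1, min)
    tibble(
      pass = lo > buffer,
      fail = apply(margins, 1, function(x) any(x < -buffer)),
      borderline = !(lo > buffer) & !apply(margins, 1,
                                           function(x) any(x < -buffer))
    )
  }

  arsa_region <- rep(NA_character_, n_sites)
  arsa_allele <- rep(NA_character_, n_sites)
  arsa_border <- rep(FALSE, n_sites)
  raca_region <- rep(NA_character_, n_sites)
  raca_allele <- rep(NA_character_, n_sites)
  raca_border <- rep(FALSE, n_sites)

  add_label <- function(current, hit, R) {
    if_else(hit & !is.na(current) & current != R,
            paste(current, R, sep = ","),
            if_else(hit, R, current))
  }
  for (al in c("alt", "ref")) {
    Fa <- purrr::map(eff, function(m) if (al == "alt") m else 1 - m)
    base <- if (al == "alt") cfg$sites$alt else cfg$sites$ref
    for (R in arsa_targets) {
      cl <- classify(eval_arsa(Fa, R))
      arsa_region <- add_label(arsa_region, cl$pass, R)
      arsa_allele[cl$pass] <- base[cl$pass]
      arsa_border <- arsa_border | cl$borderline
    }
    for (R in raca_targets) {
      cl <- classify(eval_raca(Fa$validation1, R))
      raca_region <- add_label(raca_region, cl$pass, R)
      raca_allele[cl$pass] <- base[cl$pass]
      raca_border <- raca_border | cl$borderline
    }
  }

  tibble(
    site_id = cfg$sites$site_id,
    kind = cfg$sites$kind,
    target_region = cfg$sites$target_region,
    pos = cfg$sites$pos,
    should_pass_arsa = arsa_region,
    arsa_allele = arsa_allele,
    arsa_borderline = arsa_border,
    should_pass_raca = raca_region,
    raca_allele = raca_allele,
    raca_borderline = raca_border
  )
}
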