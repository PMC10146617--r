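#' Cohen's d effect size
#'
#' Independent arms: `(mean_a - mean_b) / s_pooled` with the pooled sample
#' standard deviation (n-1 denominators). Paired arms: mean of the
#' differences over their standard deviation. The sign is reported; summaries
#' use the magnitude.
#'
#' @param arm_a,arm_b numeric vectors (>= 2 values each; equal length when
#'   paired).
#' @param paired treat the arms as matched pairs.
#' @return Cohen's d (may be `Inf` when the variance is zero; flagged
#'   degenerate by callers).
#' @export
cohens_d <- function(arm_a, arm_b, paired = FALSE) {
  if (length(arm_a) < 2 || length(arm_b) < 2) stop("need >= 2 values per arm", call. = FALSE)
  if (paired) {
    if (length(arm_a) != length(arm_b)) stop("paired arms must have equal length", call. = FALSE)
    d <- arm_a - arm_b
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 0 else Inf * sign(mean(d)))
    mean(d) / stats::sd(d)
  } else {
    na <- length(arm_a); nb <- length(arm_b)
    sp2 <- ((na - 1) * stats::var(arm_a) + (nb - 1) * stats::var(arm_b)) / (na + nb - 2)
    if (sp2 == 0) return(if (mean(arm_a) == mean(arm_b)) 0 else Inf * sign(mean(arm_a) - mean(arm_b)))
    (mean(arm_a) - mean(arm_b)) / sqrt(sp2)
  }
}

comparison_kinds <- c("controls_pre_vs_post", "patients_pre_vs_post",
                      "pre_controls_vs_patients", "post_controls_vs_patients")

# one test; returns list(p, d, n_a, n_b, untestable)
run_one_comparison <- function(df, kind) {
  if (kind %in% c("controls_pre_vs_post", "patients_pre_vs_post")) {
    grp <- if (kind == "controls_pre_vs_post") "control" else "patient"
    sub <- df[df$group == grp, ]
    pre <- sub[sub$condition == "pre", c("subject", "energy")]
    post <- sub[sub$condition == "post", c("subject", "energy")]
    common <- intersect(pre$subject, post$subject)
    a <- post$energy[match(common, post$subject)]
    b <- pre$energy[match(common, pre$subject)]
    if (length(common) < 2) return(list(p = NA_real_, d = NA_real_,
                                        n_a = length(common), n_b = length(common),
                                        untestable = TRUE))
    diffs <- a - b
    if (stats::sd(diffs) == 0) {
      return(list(p = 1, d = cohens_d(a, b, paired = TRUE),
                  n_a = length(a), n_b = length(b), untestable = mean(diffs) != 0))
    }
    p <- stats::t.test(a, b, paired = TRUE)$p.value
    list(p = p, d = cohens_d(a, b, paired = TRUE),
         n_a = length(a), n_b = length(b), untestable = FALSE)
  } else {
    cond <- if (kind == "pre_controls_vs_patients") "pre" else "post"
    sub <- df[df$condition == cond, ]
    a <- sub$energy[sub$group == "control"]
    b <- sub$energy[sub$group == "patient"]
    if (length(a) < 2 || length(b) < 2) {
      return(list(p = NA_real_, d = NA_real_, n_a = length(a), n_b = length(b),
                  untestable = TRUE))
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(list(p = if (mean(a) == mean(b)) 1 else NA_real_,
                  d = cohens_d(a, b), n_a = length(a), n_b = length(b),
                  untestable = mean(a) != mean(b)))
    }
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value  # Welch, two-sided
    list(p = p, d = cohens_d(a, b), n_a = length(a), n_b = length(b),
         untestable = FALSE)
  }
}

#' Run the four group/condition comparisons on pattern energies
#'
#' For every (site, network, pattern) cell of the subject-energy table, runs
#' paired two-sided t-tests for the within-group pre/post comparisons and
#' Welch two-sample t-tests for the between-group comparisons, with Cohen's d
#' for each. Cells with too few observations are flagged untestable rather
#' than dropped.
#'
#' @param energies tidy data.frame from [subject_energies()] (columns
#'   subject, group, site, condition, network, pattern_code, pattern_string,
#'   energy).
#' @param kinds comparison kinds to run (default all four).
#' @return data.frame of signature records: site, network, pattern_code,
#'   pattern_string, comparison, n_a, n_b, p_value, cohens_d, untestable.
#' @export
run_comparisons <- function(energies, kinds = comparison_kinds) {
  cells <- unique(energies[, c("site", "network", "pattern_code", "pattern_string")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    df <- energies[energies$site == cell$site & energies$network == cell$network &
                     energies$pattern_code == cell$pattern_code, ]
    for (kind in kinds) {
      r <- run_one_comparison(df, kind)
      rows[[length(rows) + 1L]] <- data.frame(
        site = cell$site, network = cell$network,
        pattern_code = cell$pattern_code, pattern_string = cell$pattern_string,
        comparison = kind, n_a = r$n_a, n_b = r$n_b, p_value = r$p,
        cohens_d = r$d, untestable = r$untestable, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Apply the per-network Bonferroni gate and the relevance gate
#'
#' For each network the significance threshold is `alpha / n`, where `n` is
#' the number of stable patterns selected for that network's landscape
#' (counted per stimulation site by default, or pooled across sites with
#' `pool_sites = TRUE`). A record passes the Bonferroni gate when
#' `p < alpha/n`, and additionally passes the relevance gate when
#' `p <= relevance` (default 5e-5), the stricter cut used to short-select the
#' most reliable signatures.
#'
#' @param records data.frame from [run_comparisons()].
#' @param alpha family-wise significance level.
#' @param relevance relevance threshold on p.
#' @param pool_sites count patterns per network pooled over sites.
#' @return `records` with added columns `n_patterns`, `bonferroni_threshold`,
#'   `passes_bonferroni`, `passes_relevance`.
#' @export
bonferroni_gate <- function(records, alpha = 0.05, relevance = 5e-5,
                            pool_sites = FALSE) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no selected patterns for a network (n = 0)", call. = FALSE)
  }
  key <- if (pool_sites) records$network else paste(records$site, records$network)
  n_by_key <- tapply(records$pattern_code, key, function(x) length(unique(x)))
  n <- as.integer(n_by_key[key])
  if (any(is.na(n)) || any(n == 0)) stop("no selected patterns for a network (n = 0)", call. = FALSE)
  records$n_patterns <- n
  records$bonferroni_threshold <- alpha / n
  records$passes_bonferroni <- !records$untestable & !is.na(records$p_value) &
    records$p_value < records$bonferroni_threshold
  records$passes_relevance <- records$passes_bonferroni & records$p_value <= relevance
  records
}

#' Render gated records as a signature table
#'
#' Expands each passing record into one row per constituent region with its
#' active status (+1/-1), mirroring the region/status layout of the study's
#' network-state summary tables, alongside the comparison, p-value,
#' threshold and effect size.
#'
#' @param records gated records from [bonferroni_gate()].
#' @param networks named list of `network_definition`s.
#' @param passing_only keep only records passing the Bonferroni gate.
#' @return data.frame with columns region, status, network, site, comparison,
#'   p_value, bonferroni_threshold, cohens_d, passes_relevance (empty, with
#'   headers, when nothing passes).
#' @export
build_signature_table <- function(records, networks, passing_only = TRUE) {
  empty <- data.frame(region = character(0), status = numeric(0),
                      network = character(0), site = character(0),
                      comparison = character(0), p_value = numeric(0),
                      bonferroni_threshold = numeric(0), cohens_d = numeric(0),
                      passes_relevance = logical(0), stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0) return(empty)
  if (passing_only) records <- records[records$passes_bonferroni, , drop = FALSE]
  if (nrow(records) == 0) return(empty)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    nw <- networks[[rec$network]]
    status <- drop(pattern_decode(rec$pattern_code, length(nw$regions)))
    data.frame(region = nw$regions, status = status, network = rec$network,
               site = rec$site, comparison = rec$comparison,
               p_value = rec$p_value,
               bonferroni_threshold = rec$bonferroni_threshold,
               cohens_d = rec$cohens_d, passes_relevance = rec$passes_relevance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference table of the study's six reported signatures
#'
#' The six relevance-gated connectivity signatures (site, network, state,
#' comparison) with their published p-values and Cohen's d effect sizes,
#' shipped as package data for comparison and summary.
#'
#' @return data.frame with columns signature, site, network, state,
#'   comparison, p_value, cohens_d.
#' @export
reported_signatures <- function() {
  utils::read.csv(system.file("extdata", "reported_signatures.csv",
                              package = "tmslandscape"),
                  stringsAsFactors = FALSE)
}
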