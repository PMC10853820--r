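#' Two-sided Welch two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (unequal variances) returning a
#' one-row tibble.  The degenerate case — zero variance in both samples
#' with equal means — returns t = 0, p = 1 instead of an error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1,
                            mean_a = mean(a), mean_b = mean(b)))
    return(tibble::tibble(statistic = sign(mean(a) - mean(b)) * Inf,
                          df = NA_real_, p_value = 0,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b))
}

#' Per-group sample size from a power analysis
#'
#' Smallest per-group n for a two-sided two-sample t-test to reach the
#' requested power at effect size d (Cohen's d, standardised mean
#' difference).
#'
#' @param effect_size Cohen's d, > 0.
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.8).
#' @return integer per-group sample size.
#' @export
required_n <- function(effect_size, alpha = 0.05, power = 0.8) {
  if (!is.numeric(effect_size) || effect_size <= 0)
    stop("effect_size must be > 0", call. = FALSE)
  pt <- stats::power.t.test(delta = effect_size, sd = 1,
                            sig.level = alpha, power = power,
                            type = "two.sample",
                            alternative = "two.sided")
  max(2L, as.integer(ceiling(pt$n)))
}

#' Earliest significant recovery timepoint after washout
#'
#' Compares each post-zero timepoint group of enrichment values against the
#' 0-hour group with a two-sided Welch t-test.  The onset is the earliest
#' timepoint whose p-value falls below `alpha` *and* whose mean exceeds the
#' 0-hour mean (recovery is directional even though the test is
#' two-sided).  If `baseline_mean` is given (the untreated enrichment
#' level), the result also reports whether the final timepoint's mean is
#' still below that baseline.
#'
#' @param quant tidy tibble with columns `timepoint` and the value column;
#'   typically the output of [quantify_timecourse()] filtered to one
#'   channel, or any per-record table.
#' @param channel if `quant` has a `channel` column, which channel to
#'   analyse (default `"rna"`).
#' @param value name of the value column (default `"enrichment"`).
#' @param alpha significance level (default 0.05).
#' @param baseline_mean optional untreated-baseline mean enrichment.
#' @param p_adjust `"none"` (default; each timepoint tested at `alpha`) or
#'   `"holm"` to correct across timepoints.
#' @return object of class `recovery_result`: per-timepoint summary table
#'   (mean, sd, n, statistic, p_value, significant), `onset` (hours, or
#'   `NA` if no significant recovery), and the baseline comparison.
#'   See [tidy.recovery_result()] and [glance.recovery_result()].
#' @export
recovery_onset <- function(quant, channel = "rna", value = "enrichment",
                           alpha = 0.05, baseline_mean = NULL,
                           p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if ("channel" %in% names(quant))
    quant <- quant[quant$channel == channel, ]
  if (!value %in% names(quant))
    stop("no '", value, "' column in quant", call. = FALSE)
  if (!0 %in% quant$timepoint)
    stop("time-course must contain a 0-hour group", call. = FALSE)
  groups <- split(quant[[value]], quant$timepoint)
  tps <- sort(as.numeric(names(groups)))
  if (any(vapply(groups, length, 1L) < 2))
    stop("every timepoint needs at least 2 records", call. = FALSE)
  ref <- groups[["0"]]
  tab <- purrr::map_dfr(tps, function(t) {
    g <- groups[[as.character(t)]]
    row <- tibble::tibble(timepoint = t, mean = mean(g),
                          sd = stats::sd(g), n = length(g),
                          statistic = NA_real_, p_value = NA_real_)
    if (t > 0) {
      tt <- two_sample_t(g, ref)
      row$statistic <- tt$statistic
      row$p_value <- tt$p_value
    }
    row
  })
  post <- tab$timepoint > 0
  padj <- tab$p_value
  if (p_adjust == "holm")
    padj[post] <- stats::p.adjust(tab$p_value[post], method = "holm")
  tab$p_adjusted <- padj
  tab$significant <- post & !is.na(padj) & padj < alpha &
    tab$mean > tab$mean[tab$timepoint == 0]
  onset <- if (any(tab$significant)) min(tab$timepoint[tab$significant])
           else NA_real_
  final_mean <- tab$mean[which.max(tab$timepoint)]
  structure(list(table = tab, onset = onset, alpha = alpha,
                 channel = channel, p_adjust = p_adjust,
                 baseline_mean = baseline_mean,
                 below_baseline = if (is.null(baseline_mean)) NA
                                  else final_mean < baseline_mean),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> channel '%s', alpha %.3g (%s)\n",
              x$channel, x$alpha, x$p_adjust))
  if (is.na(x$onset)) cat("  onset: none (no significant recovery)\n")
  else cat(sprintf("  onset: %g h\n", x$onset))
  if (!is.null(x$baseline_mean))
    cat(sprintf("  final mean %s baseline (%.4g)\n",
                if (isTRUE(x$below_baseline)) "below" else "at/above",
                x$baseline_mean))
  print(x$table)
  invisible(x)
}

#' Tidy a recovery result
#'
#' @param x a `recovery_result`.
#' @param ... unused.
#' @return the per-timepoint summary tibble.
#' @method tidy recovery_result
#' @export
tidy.recovery_result <- function(x, ...) x$table

#' One-row summary of a recovery result
#'
#' @param x a `recovery_result`.
#' @param ... unused.
#' @return one-row tibble: `onset`, `alpha`, `channel`, `n_timepoints`,
#'   `below_baseline`.
#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  tibble::tibble(onset = x$onset, alpha = x$alpha, channel = x$channel,
                 n_timepoints = nrow(x$table),
                 below_baseline = x$below_baseline)
}

#' Time to translate an open reading frame
#'
#' Elapsed time to translate `orf_codons` codons at `rate` amino acids per
#' second (default 6 aa/s, a standard mammalian elongation rate), in
#' minutes, with a convenience rounding to the nearest 5 minutes.
#'
#' @param orf_codons number of codons (>= 1).  The packaged constant
#'   [aspm_orf_codons] gives the ASPM open reading frame.
#' @param rate elongation rate, amino acids per second (> 0).
#' @return one-row tibble: `minutes`, `minutes_rounded` (nearest 5 min).
#' @export
#' @examples
#' translation_time(aspm_orf_codons)
translation_time <- function(orf_codons, rate = 6) {
  if (orf_codons < 1) stop("orf_codons must be >= 1", call. = FALSE)
  if (!is.numeric(rate) || rate <= 0)
    stop("rate must be > 0", call. = FALSE)
  minutes <- orf_codons / rate / 60
  tibble::tibble(minutes = minutes,
                 minutes_rounded = 5 * round(minutes / 5))
}

#' Codon count of the human ASPM open reading frame
#'
#' The ASPM protein (abnormal spindle-like microcephaly-associated) is
#' 3477 amino acids, so its ORF spans 3477 codons; at 6 aa/s complete
#' translation takes about 10 minutes.
#' @export
aspm_orf_codons <- 3477L
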