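# Densitometry quantification of co-immunoprecipitation signals:
# input-control normalization, scaling relative to the wild-type condition,
# and exact rank-based testing at triplicate scale.

#' Normalize an IP band to its input control
#'
#' Divides the immunoprecipitated band intensity by the input-control
#' intensity (the total amount of protein produced in the cells), making
#' pulldown efficiency comparable across transfections.
#'
#' @param ip_intensity numeric, IP band intensity (>= 0).
#' @param input_intensity numeric, input-control intensity (> 0).
#' @return `ip_intensity / input_intensity`, vectorized.
#' @export
normalize_to_input <- function(ip_intensity, input_intensity) {
  if (anyNA(input_intensity) || any(input_intensity <= 0)) {
    stop("input_intensity must be positive (zero input would divide by zero)")
  }
  if (anyNA(ip_intensity) || any(ip_intensity < 0)) {
    stop("ip_intensity must be non-negative")
  }
  ip_intensity / input_intensity
}

#' Scale normalized values relative to the wild-type condition
#'
#' Divides every value by the mean of the wild-type condition, so WT levels
#' are indicated by 1: ratios above 1 mean more protein pulled down than WT,
#' below 1 less. Scale-invariant: multiplying all raw intensities by a
#' constant leaves every ratio unchanged.
#'
#' @param values numeric vector of input-normalized intensities.
#' @param condition character vector of condition labels, same length.
#' @param wt_label label of the wild-type condition; default `"WT"`.
#' @return numeric vector of ratios (same order as `values`).
#' @export
relative_to_wt <- function(values, condition, wt_label = "WT") {
  stopifnot(length(values) == length(condition))
  wt <- values[condition == wt_label]
  if (!length(wt)) stop("no measurements for WT condition '", wt_label, "'")
  wt_mean <- mean(wt)
  if (!is.finite(wt_mean) || wt_mean <= 0) {
    stop("WT mean must be positive to scale against")
  }
  values / wt_mean
}

#' Exact two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum p-value. For small samples
#' (`length(x) + length(y) <= exact_max_n`) the permutation distribution of
#' the rank-sum statistic is enumerated in full — ties are handled by
#' midranks, which the enumeration respects — and the smaller tail
#' (including the observed value) is doubled, capped at 1. Larger samples
#' fall back to the normal approximation with the usual tie correction.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_max_n largest combined sample size for exact enumeration;
#'   default 12 (triplicate-scale experiments are always exact).
#' @return two-sided p-value. When every value in both samples is identical,
#'   returns 1 with attribute `flag = "all_tied"`.
#' @export
wilcoxon_rank_sum_exact <- function(x, y, exact_max_n = 12L) {
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stop("both samples must be non-empty")
  v <- c(x, y)
  if (length(unique(v)) == 1L) return(structure(1, flag = "all_tied"))
  r <- rank(v)
  w <- sum(r[seq_len(n)])
  total <- n + m

  if (total <= exact_max_n) {
    sums <- utils::combn(total, n, FUN = function(idx) sum(r[idx]))
    eps <- 1e-9
    lower <- mean(sums <= w + eps)
    upper <- mean(sums >= w - eps)
    return(min(1, 2 * min(lower, upper)))
  }

  mu <- n * (total + 1) / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 * ((total + 1) -
    sum(tie_tab^3 - tie_tab) / (total * (total - 1)))
  if (sigma2 <= 0) return(structure(1, flag = "all_tied"))
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Exact Wilcoxon signed-rank test for paired measurements
#'
#' Thin wrapper over [stats::wilcox.test()] with `paired = TRUE`, exposed for
#' designs where replicates are paired across conditions (the rank-sum test
#' in [wilcoxon_rank_sum_exact()] is the default for independent
#' transfections).
#'
#' @param x,y paired numeric samples of equal length.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}

#' Quantify a co-IP experiment table
#'
#' Takes long-format band measurements, normalizes each to its input control,
#' scales relative to the WT condition per target subunit, and tests each
#' non-WT condition against WT with the exact rank-sum test.
#'
#' @param measurements data.frame with columns `condition`, `target`,
#'   `replicate`, `ip_intensity`, `input_intensity`.
#' @param wt_label wild-type condition label; default `"WT"`.
#' @return list with `ratios` (the input data.frame plus `normalized` and
#'   `ratio` columns) and `tests` (data.frame `target`, `condition`,
#'   `n_wt`, `n_condition`, `p_value`).
#' @export
ip_quantify <- function(measurements, wt_label = "WT") {
  req <- c("condition", "target", "replicate", "ip_intensity", "input_intensity")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols)) {
    stop("measurements missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- duplicated(measurements[c("condition", "target", "replicate")])
  if (any(dup)) stop("replicate ids must be unique within (condition, target)")

  measurements$normalized <- normalize_to_input(
    measurements$ip_intensity, measurements$input_intensity
  )
  measurements$ratio <- NA_real_
  tests <- list()
  for (tgt in unique(measurements$target)) {
    sel <- measurements$target == tgt
    measurements$ratio[sel] <- relative_to_wt(
      measurements$normalized[sel], measurements$condition[sel], wt_label
    )
    wt_vals <- measurements$normalized[sel & measurements$condition == wt_label]
    for (cond in setdiff(unique(measurements$condition[sel]), wt_label)) {
      cv <- measurements$normalized[sel & measurements$condition == cond]
      tests[[length(tests) + 1L]] <- data.frame(
        target = tgt, condition = cond,
        n_wt = length(wt_vals), n_condition = length(cv),
        p_value = as.numeric(wilcoxon_rank_sum_exact(wt_vals, cv)),
        stringsAsFactors = FALSE
      )
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(target = character(0), condition = character(0),
               n_wt = integer(0), n_condition = integer(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  list(ratios = measurements, tests = tests)
}
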