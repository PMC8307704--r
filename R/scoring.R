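#' Aggregate visual-analog-scale histology scores across raters
#'
#' Semi-quantitative histological scoring (modified Abramov rubric on a
#' continuous 0-3 VAS with 0.1 increments) is performed by several blinded
#' raters; this aggregates their scores per sample and parameter.
#'
#' @param scores data.frame with columns `sample`, `parameter`, `rater`,
#'   `value` (as produced by [generate_rater_scores()]).
#' @param scale_range admissible score range, default `c(0, 3)`; values
#'   outside it or off the 0.1 grid are rejected.
#' @return data.frame with columns `sample`, `parameter`, `mean`, `sd`
#'   (`NA` for a single rater), `n_raters`.
#' @examples
#' sc <- data.frame(sample = "s1", parameter = "granulation",
#'                  rater = c("r1", "r2", "r3"), value = c(1.0, 1.2, 1.4))
#' aggregate_scores(sc)
#' @export
aggregate_scores <- function(scores, scale_range = c(0, 3)) {
  if (is.null(scores) || nrow(scores) == 0) stop("no scores")
  v <- scores$value
  if (any(v < scale_range[1] | v > scale_range[2]))
    stop("score outside the scale range")
  if (any(abs(v * 10 - round(v * 10)) > 1e-8))
    stop("scores must be quantized to 0.1")
  a <- stats::aggregate(value ~ sample + parameter, data = scores,
                        FUN = function(x) c(mean = mean(x),
                                            sd = stats::sd(x),
                                            n = length(x)))
  out <- data.frame(a[c("sample", "parameter")], mean = a$value[, "mean"],
                    sd = a$value[, "sd"], n_raters = a$value[, "n"])
  out[order(out$sample, out$parameter), ]
}

#' Wound closure rate per group from binary rater calls
#'
#' Each sample's closure status is decided by majority vote across raters;
#' exact ties are unresolved and excluded from the rate with a warning. The
#' rate is the fraction of resolved samples called closed, per group.
#'
#' @param calls data.frame with columns `sample`, `group`, `rater`,
#'   `closed` (logical).
#' @return data.frame with columns `group`, `rate`, `n_closed`, `n_resolved`,
#'   `n_unresolved`.
#' @export
closure_rate <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) stop("no closure calls")
  stopifnot(is.logical(calls$closed))
  per_sample <- do.call(rbind, lapply(split(calls, calls$sample), function(s) {
    yes <- sum(s$closed); no <- sum(!s$closed)
    data.frame(sample = s$sample[1], group = s$group[1],
               closed = if (yes > no) TRUE else if (no > yes) FALSE else NA)
  }))
  if (anyNA(per_sample$closed))
    warning(sum(is.na(per_sample$closed)),
            " sample(s) with tied rater votes excluded from the closure rate")
  out <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                               function(g) {
    res <- g$closed[!is.na(g$closed)]
    if (length(res) == 0) stop("group ", g$group[1], " has no resolved calls")
    data.frame(group = g$group[1], rate = mean(res), n_closed = sum(res),
               n_resolved = length(res), n_unresolved = sum(is.na(g$closed)))
  }))
  rownames(out) <- NULL
  out
}
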