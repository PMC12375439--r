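#' Equal-weight macro-average
#'
#' Arithmetic mean of per-class (or per-study) metric values, reported at
#' 3 decimals with half-up rounding — the convention used when summarising
#' per-study classifier scores into a macro-average row.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param digits Reporting precision. Default 3.
#' @return The rounded mean.
#' @examples
#' macro_average(c(0.940, 0.921, 0.904, 0.916, 0.901, 0.897)) # 0.913
#' @export
macro_average <- function(values, digits = 3) {
  if (length(values) == 0L || any(!is.finite(values)))
    stop("macro_average: need a non-empty list of finite values",
         call. = FALSE)
  round_half_up(mean(values), digits)
}

#' Relative improvement between two percentages
#'
#' Percent reduction of a degradation metric:
#' `(reference - improved) / reference * 100`, reported at 1 decimal with
#' half-up rounding. E.g. an accuracy drop falling from 18.3% to 4.1% is a
#' 77.6% improvement.
#'
#' @param reference Baseline percentage, > 0.
#' @param improved Improved percentage.
#' @param digits Reporting precision. Default 1.
#' @return The rounded percent reduction.
#' @examples
#' relative_improvement(18.3, 4.1) # 77.6
#' @export
relative_improvement <- function(reference, improved, digits = 1) {
  if (!is.finite(reference) || reference <= 0)
    stop("relative_improvement: reference must be > 0", call. = FALSE)
  round_half_up((reference - improved) / reference * 100, digits)
}

# round half away from zero at `digits` decimals (printed-table convention;
# base round() rounds half to even)
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Literature-flow counts for a PRISMA-style systematic search
#'
#' @param identified Records identified by the search.
#' @param after_dedup Records after duplicate removal.
#' @param title_abstract_excluded Excluded at title/abstract screening.
#' @param fulltext_assessed Full texts assessed for eligibility.
#' @param fulltext_excluded_by_reason Named counts of full-text exclusions.
#' @param included Studies included.
#' @param quality_counts Named counts by quality grade (should sum to
#'   `included`).
#' @return An object of class `prisma_counts`.
#' @export
prisma_counts <- function(identified, after_dedup, title_abstract_excluded,
                          fulltext_assessed, fulltext_excluded_by_reason,
                          included, quality_counts) {
  cnt <- c(identified, after_dedup, title_abstract_excluded,
           fulltext_assessed, unlist(fulltext_excluded_by_reason),
           included, unlist(quality_counts))
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stop("prisma_counts: all counts must be non-negative integers",
         call. = FALSE)
  structure(list(identified = identified, after_dedup = after_dedup,
                 title_abstract_excluded = title_abstract_excluded,
                 fulltext_assessed = fulltext_assessed,
                 fulltext_excluded_by_reason =
                   as.list(fulltext_excluded_by_reason),
                 included = included,
                 quality_counts = as.list(quality_counts)),
            class = "prisma_counts")
}

#' PRISMA flow accounting
#'
#' Checks the arithmetic consistency of a literature flow and derives its
#' reported proportions. Three identities are verified:
#' `after_dedup - title_abstract_excluded = fulltext_assessed`;
#' `fulltext_assessed - sum(exclusion reasons) = included`;
#' `sum(quality counts) = included`. Inconsistencies are reported as failed
#' checks, never raised as errors.
#'
#' @param counts A [prisma_counts()] object.
#' @return List with `checks` (named logicals), `all_consistent`,
#'   `fulltext_excluded_total`, and `quality_percent` (each grade as
#'   `count / included * 100`, half-up rounded to 1 decimal; `NA` when
#'   `included` is 0).
#' @export
prisma_accounting <- function(counts) {
  stopifnot(inherits(counts, "prisma_counts"))
  excl_total <- sum(unlist(counts$fulltext_excluded_by_reason))
  checks <- c(
    screening_flow = counts$after_dedup - counts$title_abstract_excluded ==
      counts$fulltext_assessed,
    fulltext_flow = counts$fulltext_assessed - excl_total ==
      counts$included,
    quality_sum = sum(unlist(counts$quality_counts)) == counts$included)
  qp <- if (counts$included > 0) {
    vapply(counts$quality_counts,
           function(k) round_half_up(k / counts$included * 100, 1),
           numeric(1))
  } else {
    vapply(counts$quality_counts, function(k) NA_real_, numeric(1))
  }
  list(checks = as.list(checks), all_consistent = all(checks),
       fulltext_excluded_total = excl_total, quality_percent = as.list(qp))
}
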