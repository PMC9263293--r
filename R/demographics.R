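#' Demographics of the study cohort
#'
#' The published per-subject demographic table of the two groups (25 Tai Chi
#' practitioners, 25 controls): age in years, sex, field of study, and months
#' of practice. These are the inputs for the demographic checks
#' (two-sample t-test on age, chi-square test on sex balance) and for giving
#' synthetic cohorts realistic covariate marginals.
#'
#' @return data.frame with columns \code{subject_id}, \code{group}
#'   (\code{"TC"}/\code{"control"}), \code{age}, \code{sex} (\code{"M"}/\code{"F"}),
#'   \code{field}, \code{tc_months}.
#' @examples
#' d <- demographics_table()
#' tapply(d$age, d$group, mean)
#' @export
demographics_table <- function() {
  path <- system.file("extdata", "demographics.tsv", package = "plvnet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Demographic group comparison
#'
#' Recomputes the standard demographic comparisons from a cohort table:
#' pooled-variance two-sample t-test on age and a 1-df Pearson chi-square test
#' (no continuity correction) on the sex-by-group table.
#'
#' @param demo data.frame as returned by [demographics_table()] (needs
#'   \code{group}, \code{age}, \code{sex}).
#' @return list with per-group age mean/sd, sex counts, \code{age_t},
#'   \code{age_p}, \code{sex_chi2}, \code{sex_p}.
#' @export
demographic_tests <- function(demo = demographics_table()) {
  stopifnot(all(c("group", "age", "sex") %in% names(demo)))
  groups <- unique(demo$group)
  if (length(groups) != 2L) stop("expected exactly two groups")
  a <- demo$age[demo$group == groups[1]]
  b <- demo$age[demo$group == groups[2]]
  tt <- two_sample_t(a, b)
  counts <- table(factor(demo$group, levels = groups),
                  factor(demo$sex, levels = c("M", "F")))
  ch <- chi_square_2x2(unclass(counts))
  list(
    groups = groups,
    age_mean = c(mean(a), mean(b)),
    age_sd = c(stats::sd(a), stats::sd(b)),
    sex_counts = counts,
    age_t = tt$t, age_p = tt$p,
    sex_chi2 = ch$chi2, sex_p = ch$p
  )
}
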