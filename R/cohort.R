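#' APOE genotype counts
#'
#' @param e2e2,e2e3,e2e4,e3e3,e3e4,e4e4 Non-negative integer subject
#'   counts per genotype.
#' @return A named integer vector of class `genotype_counts`.
#' @examples
#' # the study cohort before restricting to e3/e3 and e3/e4 carriers
#' genotype_counts(e2e2 = 2, e2e3 = 33, e2e4 = 5,
#'                 e3e3 = 202, e3e4 = 65, e4e4 = 5)
#' @export
genotype_counts <- function(e2e2 = 0, e2e3 = 0, e2e4 = 0,
                            e3e3 = 0, e3e4 = 0, e4e4 = 0) {
  g <- c("e2/e2" = e2e2, "e2/e3" = e2e3, "e2/e4" = e2e4,
         "e3/e3" = e3e3, "e3/e4" = e3e4, "e4/e4" = e4e4)
  if (any(g < 0) || any(g != round(g))) {
    stop("genotype counts must be non-negative integers")
  }
  structure(as.integer(g), names = names(g), class = "genotype_counts")
}

#' Allele frequencies and genotype prevalences
#'
#' Allele counts follow Mendelian arithmetic (two alleles per subject:
#' homozygotes contribute two copies, heterozygote carriers one), so
#' allele frequencies are standardized by `N_allele = 2 * N_genotype`.
#' Genotype prevalences are standardized by the number of subjects.
#'
#' @param g A [genotype_counts()] vector.
#' @return A list with `n_genotype`, `n_allele`, `allele_freq` (named
#'   percentages for e2, e3, e4) and `genotype_prev` (named percentages).
#' @examples
#' g <- genotype_counts(e2e2 = 2, e2e3 = 33, e2e4 = 5,
#'                      e3e3 = 202, e3e4 = 65, e4e4 = 5)
#' allele_and_genotype_frequencies(g)$allele_freq # e4 = 12.82%
#' @export
allele_and_genotype_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_counts"))
  n_genotype <- sum(g)
  if (n_genotype == 0) stop("all genotype counts are zero")
  n_allele <- 2L * n_genotype
  allele <- c(
    e2 = 2 * g["e2/e2"] + g["e2/e3"] + g["e2/e4"],
    e3 = 2 * g["e3/e3"] + g["e2/e3"] + g["e3/e4"],
    e4 = 2 * g["e4/e4"] + g["e2/e4"] + g["e3/e4"]
  )
  names(allele) <- c("e2", "e3", "e4")
  list(
    n_genotype = n_genotype,
    n_allele = n_allele,
    allele_freq = 100 * allele / n_allele,
    genotype_prev = stats::setNames(100 * as.numeric(g) / n_genotype,
                                    names(g))
  )
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with 1 degree of
#' freedom (no Yates continuity correction -- the convention used for the
#' genotype-by-age-group comparisons).
#'
#' @param tab A 2 x 2 matrix of non-negative counts.
#' @return A list with `statistic`, `df`, `p_value`.
#' @examples
#' pearson_chi_square(matrix(c(35, 30, 128, 74), 2))$statistic # ~1.87
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (sum(tab) == 0) stop("empty contingency table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal: expected counts undefined")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Exclusion accounting
#'
#' @param recruited Number of recruited participants.
#' @param exclusion_counts Named numeric vector of exclusion counts.
#' @return A list with `final_n` and an `audit` data frame (one row per
#'   exclusion rule plus the recruited and final totals).
#' @examples
#' apply_exclusions(318, c(genotype = 46, familiarity = 1, technical = 4))
#' @export
apply_exclusions <- function(recruited, exclusion_counts = numeric()) {
  stopifnot(recruited >= 0)
  total <- sum(exclusion_counts)
  final_n <- recruited - total
  if (final_n < 0) {
    stop("accounting error: exclusions (", total,
         ") exceed recruited (", recruited, ")")
  }
  audit <- data.frame(
    rule = c("recruited", names(exclusion_counts) %||% character(), "final"),
    n = c(recruited, -as.numeric(exclusion_counts), final_n)
  )
  list(final_n = final_n, audit = audit)
}

#' Data-driven age split via k-means
#'
#' One-dimensional k-means with k = 2 and multiple seeded restarts,
#' mirroring the data-driven young/old split of the cohort. The cutoff is
#' the minimum age of the older cluster, so "older" means
#' `age >= cutoff`.
#'
#' @param ages Numeric vector of ages in years (at least 2 distinct).
#' @param seed Integer seed.
#' @param nstart Number of k-means restarts.
#' @return A list with `cutoff`, `group` (factor `"younger"`/`"older"`)
#'   and the cluster `centers`.
#' @examples
#' kmeans_age_split(c(rep(20, 50), rep(60, 50)), seed = 1)$cutoff # 60
#' @export
kmeans_age_split <- function(ages, seed = 1, nstart = 10) {
  ages <- as.numeric(ages)
  if (length(unique(ages)) < 2L) {
    stop("degenerate clustering: need at least 2 distinct ages")
  }
  if (length(unique(ages)) == 2L) {
    # two distinct values: the optimal 2-means split is by value
    km <- list(cluster = as.integer(factor(ages)),
               centers = matrix(sort(unique(ages))))
  } else {
    km <- with_seed(seed, stats::kmeans(ages, centers = 2, nstart = nstart))
  }
  older_cl <- which.max(km$centers)
  cutoff <- min(ages[km$cluster == older_cl])
  list(
    cutoff = cutoff,
    group = factor(ifelse(ages >= cutoff, "older", "younger"),
                   levels = c("younger", "older")),
    centers = sort(as.numeric(km$centers))
  )
}
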