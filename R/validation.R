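# Validation statistics: efficiency-corrected relative expression
# (Pfaffl ratio) with a REST-style fixed-reallocation randomization test
# and leave-one-out jackknife SD, plus the plain equal-variance two-sample
# t-test used for ELISA group comparisons.

#' Efficiency-corrected relative expression ratio (Pfaffl)
#'
#' `ratio = e_target^dct_target / e_ref^dct_ref`, where each delta-Ct is
#' `mean Ct(control) - mean Ct(treated)` for that assay. With this sign
#' convention ratios above 1 mean up-regulation in the treated group.
#'
#' @param e_target,e_ref Amplification efficiencies in (1, 2]
#'   (2 = perfect doubling per cycle).
#' @param dct_target,dct_ref Delta-Ct values (control minus treated), in
#'   cycles.
#' @return The positive expression ratio.
#' @examples
#' pfaffl_ratio(2, 0, 2, 0)   # 1
#' pfaffl_ratio(2, 1, 2, 0)   # 2
#' pfaffl_ratio(2, -2, 2, 0)  # 0.25
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  check_efficiency(e_target)
  check_efficiency(e_ref)
  e_target^dct_target / e_ref^dct_ref
}

# Wide per-sample view of a qPCR table; validates pairing and grouping.
qpcr_wide <- function(qpcr) {
  required <- c("sample_id", "sample_group", "gene_role", "ct", "efficiency")
  missing <- setdiff(required, names(qpcr))
  if (length(missing) > 0L) {
    stop("qPCR table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(qpcr$sample_group %in% c("treated", "control")),
            all(qpcr$gene_role %in% c("target", "reference")),
            all(qpcr$ct > 0))
  for (role in c("target", "reference")) {
    if (length(unique(qpcr$efficiency[qpcr$gene_role == role])) != 1L) {
      stop("efficiency must be constant across wells of the ", role,
           " assay", call. = FALSE)
    }
  }
  wide <- qpcr |>
    dplyr::select("sample_id", "sample_group", "gene_role", "ct") |>
    tidyr::pivot_wider(names_from = "gene_role", values_from = "ct")
  if (any(is.na(wide$target)) || any(is.na(wide$reference))) {
    stop("every sample needs one target and one reference Ct", call. = FALSE)
  }
  if (min(table(wide$sample_group)) < 2L) {
    stop("need >= 2 samples per group", call. = FALSE)
  }
  wide
}

ratio_from_groups <- function(wide, groups, e_target, e_ref) {
  ctrl <- groups == "control"
  dct_t <- mean(wide$target[ctrl]) - mean(wide$target[!ctrl])
  dct_r <- mean(wide$reference[ctrl]) - mean(wide$reference[!ctrl])
  e_target^dct_t / e_ref^dct_r
}

#' REST-style randomization test for a relative expression ratio
#'
#' Point estimate via [pfaffl_ratio()] on group-mean delta-Cts. The
#' significance test is a fixed-reallocation randomization: treated/control
#' labels are shuffled jointly across samples (each sample keeps its
#' target and reference Cts together), and the two-sided p-value is the
#' fraction of reallocations whose ratio is at least as extreme, relative
#' to 1, as the observed one, with the (k + 1)/(n + 1) small-sample
#' correction. The reported SD is the spread of leave-one-out jackknife
#' ratios.
#'
#' @param qpcr A qPCR tibble as from [simulate_qpcr()]: columns
#'   `sample_id`, `sample_group` (treated/control), `gene_role`
#'   (target/reference), `ct`, `efficiency`.
#' @param n_iterations Number of random reallocations (default 2000).
#' @param seed Integer seed for the reallocation draw.
#' @return An object of class `expression_ratio`: a list with `ratio`,
#'   `sd`, `p_value`, `n_iterations`, `seed`.
#' @export
rest_randomization <- function(qpcr, n_iterations = 2000L, seed = 1L) {
  stopifnot(n_iterations >= 1L)
  wide <- qpcr_wide(qpcr)
  e_target <- qpcr$efficiency[qpcr$gene_role == "target"][1]
  e_ref <- qpcr$efficiency[qpcr$gene_role == "reference"][1]
  check_efficiency(e_target)
  check_efficiency(e_ref)

  obs <- ratio_from_groups(wide, wide$sample_group, e_target, e_ref)

  set.seed(seed %% 2147483647L)
  n_extreme <- 0L
  for (i in seq_len(n_iterations)) {
    perm <- sample(wide$sample_group)
    r <- ratio_from_groups(wide, perm, e_target, e_ref)
    if (abs(log(r)) >= abs(log(obs))) n_extreme <- n_extreme + 1L
  }
  p_value <- (n_extreme + 1L) / (n_iterations + 1L)

  jack <- vapply(seq_len(nrow(wide)), function(i) {
    ratio_from_groups(wide[-i, ], wide$sample_group[-i], e_target, e_ref)
  }, numeric(1))

  structure(
    list(ratio = obs, sd = stats::sd(jack), p_value = p_value,
         n_iterations = as.integer(n_iterations), seed = as.integer(seed)),
    class = "expression_ratio"
  )
}

#' @export
print.expression_ratio <- function(x, ...) {
  cat(sprintf("Relative expression ratio: %.4g (jackknife SD %.3g)\n",
              x$ratio, x$sd))
  cat(sprintf("Randomization p-value: %.4g (%d reallocations, seed %d)\n",
              x$p_value, x$n_iterations, x$seed))
  invisible(x)
}

#' Equal-variance (pooled) two-sample t-test
#'
#' The unpaired, equal-variance ("type 2") Student's t-test, two-sided.
#' Degenerate zero-variance inputs follow the conventions: equal means
#' give `t = 0, p = 1`; unequal means with zero pooled variance give
#' `p = 0` with an infinite statistic and `degenerate = TRUE`.
#'
#' @param group_a,group_b Numeric vectors with at least two values each.
#' @return An object of class `ttest_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `group_means`, `degenerate`.
#' @export
t_test_equal_var <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L,
            all(is.finite(group_a)), all(is.finite(group_b)))
  na <- length(group_a)
  nb <- length(group_b)
  df <- na + nb - 2L
  means <- c(mean(group_a), mean(group_b))
  pooled_var <- (sum((group_a - means[1])^2) + sum((group_b - means[2])^2)) / df
  if (pooled_var == 0) {
    degenerate_equal <- means[1] == means[2]
    res <- list(
      t_statistic = if (degenerate_equal) 0 else sign(means[1] - means[2]) * Inf,
      degrees_of_freedom = df,
      p_value = if (degenerate_equal) 1 else 0,
      group_means = means,
      degenerate = TRUE
    )
    if (!degenerate_equal) {
      warning("zero pooled variance with unequal means: p = 0 by convention",
              call. = FALSE)
    }
    return(structure(res, class = "ttest_result"))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  structure(
    list(
      t_statistic = unname(ht$statistic),
      degrees_of_freedom = as.integer(unname(ht$parameter)),
      p_value = ht$p.value,
      group_means = means,
      degenerate = FALSE
    ),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Equal-variance t-test: t = %.4g, df = %d, p = %.4g\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("Group means: %.4g vs %.4g\n",
              x$group_means[1], x$group_means[2]))
  invisible(x)
}

#' Signed fractional change of a treated mean versus control
#'
#' `(treated_mean - control_mean) / control_mean`; -0.25 is a 25%
#' reduction.
#'
#' @param treated_mean Treated-group mean.
#' @param control_mean Control-group mean (> 0).
#' @return Signed fraction.
#' @export
percent_change <- function(treated_mean, control_mean) {
  if (!is.numeric(control_mean) || any(control_mean <= 0)) {
    stop("control_mean must be positive", call. = FALSE)
  }
  (treated_mean - control_mean) / control_mean
}
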