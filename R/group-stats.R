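# Normality-gated group comparisons against a control, reproducing the
# study's test-selection logic:
#   two groups                    -> unpaired Student's t-test
#   > 2 groups, all Shapiro-Wilk  -> one-way ANOVA + Dunnett many-to-one
#   > 2 groups, any non-normal    -> Kruskal-Wallis + Dunn vs control
# Stars: * p < 0.05, ** p < 0.01, *** p < 0.001 (strict inequalities).

#' Significance stars for an adjusted p-value
#'
#' Maps p-values to the conventional annotation with strict thresholds:
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for
#' p < 0.05, otherwise \code{ns} (so p = 0.05 exactly is \code{ns}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return character vector of \code{"ns"}, \code{"*"}, \code{"**"},
#'   \code{"***"}.
#' @export
significance_stars <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    abort_domain("'p' must be in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

# --- Dunnett many-to-one distribution -------------------------------------
#
# P(max_i |T_i| <= q) for the many-to-one comparison statistics
# T_i = (xbar_i - xbar_0) / (S sqrt(1/n_i + 1/n_0)), which share the
# control mean and the pooled SD S (df nu).  Their correlation has the
# product form lambda_i lambda_j with
#   lambda_i = sqrt((1/n_0) / (1/n_i + 1/n_0)),
# so conditioning on the control deviate Z0 = z and on U = S/sigma = u
# factorises the joint probability into a product of normal CDFs.  Both
# conditioning variables are integrated out with fixed Gaussian
# quadrature (Hermite in z, Legendre in the chi probability scale for
# u), giving a deterministic result -- no Monte Carlo.

dunnett_pmax <- function(q, lambda, df, n_nodes = 64L) {
  if (q <= 0) return(0)
  s <- sqrt(1 - lambda^2)
  gh <- statmod::gauss.quad(n_nodes, kind = "hermite")
  z <- sqrt(2) * gh$nodes
  wz <- gh$weights / sqrt(pi)
  gl <- statmod::gauss.quad(n_nodes, kind = "legendre")
  pu <- (gl$nodes + 1) / 2           # chi probability scale on (0, 1)
  wu <- gl$weights / 2
  u <- sqrt(stats::qchisq(pu, df) / df)
  total <- 0
  for (k in seq_along(u)) {
    c_k <- q * u[k]
    inner <- rep(1, length(z))
    for (i in seq_along(lambda)) {
      inner <- inner * (stats::pnorm((c_k + lambda[i] * z) / s[i]) -
                        stats::pnorm((-c_k + lambda[i] * z) / s[i]))
    }
    total <- total + wu[k] * sum(wz * inner)
  }
  min(max(total, 0), 1)
}

#' Dunnett's many-to-one post-hoc test
#'
#' Compares every treatment group with the designated control using the
#' pooled-variance t statistics of a one-way layout, with single-step
#' adjustment over the family: each adjusted p-value is
#' \eqn{1 - P(\max_j |T_j| \le |t_i|)} under the joint null
#' distribution of the correlated statistics.  The joint probability is
#' evaluated by deterministic Gaussian quadrature, so repeated calls are
#' bit-identical.
#'
#' @param groups named list of numeric vectors (replicate values per
#'   group).
#' @param control name of the control group in \code{groups}.
#' @return \code{data.frame} with one row per non-control group:
#'   \code{group}, \code{estimate} (mean difference vs control),
#'   \code{t}, \code{df}, \code{p_adjusted}.
#' @export
dunnett_test <- function(groups, control) {
  groups <- validate_grouped(groups, control, min_n = 2L)
  labs <- setdiff(names(groups), control)
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  N <- sum(n); k <- length(groups)
  df <- N - k
  if (df < 1L) abort_validation("no residual degrees of freedom")
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (sse <= 0)
    abort("degenerate data: zero within-group variance everywhere",
          "npcquant_degenerate_error")
  s2 <- sse / df
  n0 <- n[[control]]
  tstat <- (means[labs] - means[[control]]) /
    sqrt(s2 * (1 / n[labs] + 1 / n0))
  lambda <- sqrt((1 / n0) / (1 / n[labs] + 1 / n0))
  p_adj <- vapply(abs(tstat), function(q)
    1 - dunnett_pmax(q, lambda, df), numeric(1))
  data.frame(group = labs, estimate = means[labs] - means[[control]],
             t = as.numeric(tstat), df = df,
             p_adjusted = pmin(pmax(p_adj, 0), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dunn's post-hoc test versus a control
#'
#' Rank-based many-to-one comparisons following a Kruskal-Wallis
#' omnibus: z statistics on tie-corrected mean ranks, with Bonferroni
#' adjustment over the k - 1 treatment-vs-control comparisons.
#'
#' @inheritParams dunnett_test
#' @return \code{data.frame} with \code{group}, \code{z},
#'   \code{p_unadjusted}, \code{p_adjusted}.
#' @export
dunn_test <- function(groups, control) {
  groups <- validate_grouped(groups, control, min_n = 2L)
  labs <- setdiff(names(groups), control)
  values <- unlist(groups, use.names = FALSE)
  gidx <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, gidx, mean)
  n <- tapply(rk, gidx, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  z <- (mean_rank[labs] - mean_rank[[control]]) /
    sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[labs] + 1 / n[[control]]))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group = labs, z = as.numeric(z),
             p_unadjusted = as.numeric(p),
             p_adjusted = pmin(as.numeric(p) * length(labs), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

validate_grouped <- function(groups, control, min_n = 3L) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups)))
      abort_validation("data.frame input needs columns 'group' and 'value'")
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    abort_validation("'groups' must be a named list of numeric vectors")
  if (length(groups) < 2L)
    abort_validation("need at least 2 groups")
  if (!control %in% names(groups))
    abort_validation(sprintf("control group '%s' not found", control))
  bad <- names(groups)[vapply(groups, function(g)
    !is.numeric(g) || anyNA(g) || length(g) < min_n, logical(1))]
  if (length(bad))
    abort_validation(paste0("groups with fewer than ", min_n,
                            " numeric replicates: ",
                            paste(bad, collapse = ", ")))
  groups
}

#' Normality-gated group comparison against a control
#'
#' Reproduces the study's statistical decision logic.  With exactly two
#' groups an unpaired two-sided Student's t-test (equal variances) is
#' used.  With more than two groups each group is screened with the
#' Shapiro-Wilk test at \code{alpha_normality}; if every group passes,
#' a one-way ANOVA with Dunnett's many-to-one post hoc follows,
#' otherwise Kruskal-Wallis with Dunn's post hoc (Bonferroni over the
#' treatment-vs-control family).  Adjusted p-values are annotated with
#' significance stars (strict thresholds 0.05 / 0.01 / 0.001).  A group
#' with zero variance cannot pass the normality screen and routes to
#' the rank-based path.
#'
#' @param groups named list of numeric replicate vectors, or a
#'   \code{data.frame} with columns \code{group} and \code{value}.
#' @param control control group label.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return object of class \code{comparison_result}: list with
#'   \code{test_used} (\code{"t_test"}, \code{"anova_dunnett"} or
#'   \code{"kruskal_dunn"}), \code{control}, \code{normality_pass}
#'   (named logical, > 2 groups only), \code{omnibus_p}, and
#'   \code{comparisons} (per-group \code{p_adjusted} and \code{stars}).
#' @export
choose_and_run_test <- function(groups, control, alpha_normality = 0.05) {
  groups <- validate_grouped(groups, control, min_n = 3L)
  if (all(vapply(groups, function(g) stats::var(g) == 0, logical(1))) &&
      length(unique(unlist(groups))) == 1L)
    abort("degenerate data: all groups constant and identical",
          "npcquant_degenerate_error")
  labs <- setdiff(names(groups), control)

  if (length(groups) == 2L) {
    tt <- stats::t.test(groups[[labs]], groups[[control]],
                        var.equal = TRUE)
    comparisons <- data.frame(group = labs, p_adjusted = tt$p.value,
                              stars = significance_stars(tt$p.value),
                              stringsAsFactors = FALSE)
    res <- list(test_used = "t_test", control = control,
                normality_pass = NULL, omnibus_p = tt$p.value,
                comparisons = comparisons)
    class(res) <- "comparison_result"
    return(res)
  }

  normality_pass <- vapply(groups, function(g) {
    if (stats::var(g) == 0) return(FALSE)  # Shapiro-Wilk undefined
    stats::shapiro.test(g)$p.value > alpha_normality
  }, logical(1))

  if (all(normality_pass)) {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), vapply(groups, length, integer(1))))
    omnibus <- stats::oneway.test(values ~ fac, var.equal = TRUE)$p.value
    post <- dunnett_test(groups, control)
    comparisons <- data.frame(group = post$group,
                              p_adjusted = post$p_adjusted,
                              stars = significance_stars(post$p_adjusted),
                              stringsAsFactors = FALSE)
    test_used <- "anova_dunnett"
  } else {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), vapply(groups, length, integer(1))))
    omnibus <- stats::kruskal.test(values, fac)$p.value
    post <- dunn_test(groups, control)
    comparisons <- data.frame(group = post$group,
                              p_adjusted = post$p_adjusted,
                              stars = significance_stars(post$p_adjusted),
                              stringsAsFactors = FALSE)
    test_used <- "kruskal_dunn"
  }
  res <- list(test_used = test_used, control = control,
              normality_pass = normality_pass, omnibus_p = omnibus,
              comparisons = comparisons)
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Group comparison vs '%s' via %s (omnibus p = %.4g)\n",
              x$control, x$test_used, x$omnibus_p))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
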