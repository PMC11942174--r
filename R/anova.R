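#' One-way ANOVA with Dunnett or Tukey post hoc comparisons
#'
#' Standard comparison of treatment groups of normalized efflux fractions
#' against a control (Dunnett) or all pairs (Tukey), as used when testing
#' whether chaperone-rescued channels differ from vehicle-treated cells.
#'
#' Degenerate input in which every observation is the same constant has no
#' variance to partition: the F statistic is undefined and all adjusted
#' p-values are reported as 1 by convention, with `degenerate = TRUE`.
#'
#' @param values numeric observations.
#' @param group group labels, same length; at least 2 groups with at least
#'   2 observations each.
#' @param control control group label (Dunnett only).
#' @param method `"dunnett"` (vs control) or `"tukey"` (all pairs).
#' @return list of class `group_comparison`: `f_statistic`, `p_anova`,
#'   `comparisons` (data.frame: comparison, estimate, p_adjusted),
#'   `method`, `degenerate`.
#' @export
compare_to_control <- function(values, group, control = NULL,
                               method = c("dunnett", "tukey")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(group))
  group <- as.character(group)
  sizes <- table(group)
  if (length(sizes) < 2)
    stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (method == "dunnett") {
    if (is.null(control)) stop("control label required for Dunnett")
    if (!control %in% names(sizes))
      stop("control group '", control, "' not present")
  }

  if (stats::var(values) < .Machine$double.eps) {
    labs <- if (method == "dunnett")
      paste(setdiff(names(sizes), control), "-", control)
    else
      utils::combn(names(sizes), 2, FUN = function(p) paste(p[2], "-", p[1]))
    return(structure(list(
      f_statistic = NA_real_, p_anova = NA_real_,
      comparisons = data.frame(comparison = labs, estimate = 0,
                               p_adjusted = 1, stringsAsFactors = FALSE),
      method = method, degenerate = TRUE), class = "group_comparison"))
  }

  g <- factor(group)
  if (method == "dunnett")
    g <- stats::relevel(g, ref = control)
  d <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  mcp_spec <- if (method == "dunnett") multcomp::mcp(g = "Dunnett")
              else multcomp::mcp(g = "Tukey")
  gl <- summary(multcomp::glht(fit, linfct = mcp_spec))
  structure(list(
    f_statistic = an[["F value"]][1],
    p_anova = an[["Pr(>F)"]][1],
    comparisons = data.frame(
      comparison = rownames(gl$linfct),
      estimate = as.numeric(gl$test$coefficients),
      p_adjusted = as.numeric(gl$test$pvalues),
      stringsAsFactors = FALSE),
    method = method, degenerate = FALSE),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g (%s post hoc)\n",
              x$f_statistic, x$p_anova, x$method))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
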