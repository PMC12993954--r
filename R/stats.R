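# Statistical layer: mixed-effects comparisons over the animal/slice
# hierarchy, Sholl AUC summarization, cross-method z-score harmonization.

#' Fit a linear mixed-effects model over the animal hierarchy
#'
#' Fits `value ~ group` with a random intercept per animal — accounting for
#' the nonindependence of cells nested within animals — and, when
#' `slice_component = TRUE`, an additional variance component for slice
#' nested within animal (appropriate when treatments are applied to
#' individual brain slices rather than animals). Estimation is by REML via
#' \pkg{lme4}; this function owns the model specification, convergence
#' checking and the reporting contract.
#'
#' The group coefficient is the treated-minus-control fixed effect. The
#' default p-value is a Wald z test on that coefficient; `test = "lrt"`
#' refits by ML with and without the group term and reports the
#' likelihood-ratio p-value instead. Singular fits and convergence warnings
#' are flagged in the result, not raised: boundary variance estimates of
#' zero are legitimate outcomes.
#'
#' @param table data.frame with columns `animal`, `slice`, `cell`, `group`,
#'   `metric`, `value` (a `method` column is carried but not modeled).
#' @param metric optional metric name to filter on.
#' @param slice_component include the slice-within-animal variance
#'   component?
#' @param test `"wald"` (default) or `"lrt"`.
#' @return An object of class `lmem_result`: `estimate`, `se`, `p_value`,
#'   `var_animal`, `var_slice` (`NA` when not modeled), `var_residual`,
#'   `n_animals`, `n_cells`, `converged`, `singular`, `messages`,
#'   `formula`.
#' @examples
#' tab <- simulate_hierarchical_table(hier_sim_config(beta1 = 2, seed = 3))
#' fit_lmem(tab)
#' @export
fit_lmem <- function(table, metric = NULL, slice_component = FALSE,
                     test = c("wald", "lrt")) {
  test <- match.arg(test)
  d <- table
  if (!is.null(metric)) d <- d[d$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for metric ", metric)
  for (col in c("animal", "group", "value"))
    if (is.null(d[[col]])) stop("table lacks column '", col, "'")
  if (any(is.na(d$group)) || any(is.na(d$animal)))
    stop("missing group or animal labels")
  glev <- unique(d$group)
  if (length(glev) != 2L) stop("exactly two groups required; found ",
                               length(glev))
  if ("control" %in% glev) glev <- c("control", setdiff(glev, "control"))
  d$group <- factor(d$group, levels = glev)
  per_group <- tapply(d$animal, d$group, function(a) length(unique(a)))
  if (any(per_group < 2L))
    stop("at least 2 animals per group required (inference undefined ",
         "with a single animal)")
  form <- if (slice_component)
    value ~ group + (1 | animal) + (1 | animal:slice)
  else
    value ~ group + (1 | animal)
  msgs <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(form, data = d, REML = TRUE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  singular <- lme4::isSingular(fit)
  fe <- lme4::fixef(fit)
  est <- unname(fe[2])
  se <- tryCatch(
    suppressWarnings(unname(coef(summary(fit))[2, "Std. Error"])),
    error = function(e) NA_real_)
  p <- if (test == "wald") {
    if (is.finite(se) && se > 0) 2 * pnorm(-abs(est / se)) else NA_real_
  } else {
    m1 <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = FALSE)))
    form0 <- stats::update.formula(form, . ~ . - group)
    m0 <- suppressMessages(suppressWarnings(
      lme4::lmer(form0, data = d, REML = FALSE)))
    anova(m0, m1)[2, "Pr(>Chisq)"]
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1] else NA_real_
  }
  structure(
    list(estimate = est, se = se, p_value = p,
         var_animal = getv("animal"),
         var_slice = if (slice_component) getv("animal:slice") else NA_real_,
         var_residual = getv("Residual"),
         n_animals = length(unique(d$animal)),
         n_cells = nrow(d),
         converged = converged, singular = singular, messages = msgs,
         formula = deparse(form), test = test),
    class = "lmem_result")
}

#' @export
print.lmem_result <- function(x, ...) {
  cat(sprintf("<lmem_result> %s\n", x$formula))
  cat(sprintf(
    "  group effect %.4f (SE %.4f), p = %.4g [%s]\n",
    x$estimate, x$se, x$p_value, x$test))
  cat(sprintf(
    "  var: animal %.4g%s, residual %.4g | %d animals, %d cells%s%s\n",
    x$var_animal,
    if (!is.na(x$var_slice)) sprintf(", slice %.4g", x$var_slice) else "",
    x$var_residual, x$n_animals, x$n_cells,
    if (!x$converged) " [non-convergence flagged]" else "",
    if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Summarize Sholl curves as per-cell AUC rows
#'
#' Repeated measures across radii are reduced to one area-under-the-curve
#' value per cell before mixed-effects modeling. Curves are joined to cell
#' metadata positionally: `metadata` must have one row per curve.
#'
#' @param curves list of `sholl_curve` objects (see [sholl()]).
#' @param metadata data.frame with columns `animal`, `slice`, `cell`,
#'   `group` and optionally `method` (one row per curve).
#' @return A measurement-table data.frame (columns `animal`, `slice`,
#'   `cell`, `group`, `method`, `metric = "sholl_auc"`, `value`, `flag`;
#'   empty curves get value 0 and flag `"empty_curve"`).
#' @export
sholl_auc_summary <- function(curves, metadata) {
  if (length(curves) != nrow(metadata))
    stop("one metadata row per curve required")
  if (is.null(metadata$method)) metadata$method <- "m1"
  if (is.null(metadata$slice)) metadata$slice <- "s1"
  auc <- vapply(curves, function(cv) {
    stopifnot(inherits(cv, "sholl_curve"))
    cv$auc
  }, numeric(1))
  empty <- vapply(curves, function(cv) length(cv$radii) == 0L, logical(1))
  data.frame(animal = metadata$animal, slice = metadata$slice,
             cell = metadata$cell, group = metadata$group,
             method = metadata$method, metric = "sholl_auc",
             value = auc,
             flag = ifelse(empty, "empty_curve", NA_character_))
}

#' Z-score harmonization across labeling methods
#'
#' Morphology acquired with different labeling methods lives on different
#' scales; to compare genotypes across methods, raw values are transformed
#' within each method label to z-scores, `z = (x - mu) / sigma`, where `mu`
#' and `sigma` are the mean and SD of all cells of that method pooled
#' across both genotypes (denominator `n - 1`). Pooling preserves the
#' between-genotype separation — standardizing within genotype would erase
#' the effect being tested — while removing method-specific offset and
#' scale.
#'
#' @param table measurement-table data.frame with a `method` column.
#' @param metric optional metric name to filter on.
#' @return The table with `value` replaced by its within-method z-score;
#'   the per-method `mu` and `sigma` are attached as
#'   `attr(, "scaling")`.
#' @export
zscore_by_method <- function(table, metric = NULL) {
  d <- table
  if (!is.null(metric)) d <- d[d$metric == metric, , drop = FALSE]
  if (is.null(d$method)) stop("table lacks a 'method' column")
  if (nrow(d) == 0L) stop("no rows to transform")
  scaling <- list()
  for (m in unique(d$method)) {
    i <- d$method == m
    if (sum(i) < 2L)
      stop("method '", m, "' has fewer than 2 cells")
    mu <- mean(d$value[i])
    sigma <- sd(d$value[i])
    if (sigma == 0)
      stop("method '", m, "' has zero SD; z-scores undefined")
    d$value[i] <- (d$value[i] - mu) / sigma
    scaling[[m]] <- c(mu = mu, sigma = sigma)
  }
  attr(d, "scaling") <- do.call(rbind, scaling)
  d
}

#' One-way ANOVA with Bonferroni-corrected pairwise tests
#'
#' Convenience wrapper for cell-culture designs without animal nesting
#' (classical parametric analysis): one-way `aov` across groups plus
#' Bonferroni-adjusted pairwise t tests.
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels.
#' @return A list with `anova_p`, `pairwise` (matrix of adjusted p-values)
#'   and the fitted `aov` object.
#' @export
compare_groups_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  fit <- stats::aov(values ~ groups)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  pw <- stats::pairwise.t.test(values, groups, p.adjust.method = "bonferroni")
  list(anova_p = p, pairwise = pw$p.value, fit = fit)
}
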