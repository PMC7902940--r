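# Two-way sex x genotype factorial analysis, the uniform group-comparison
# method for every measurement table (IHC percent areas, object counts,
# structure volumes). Type II sums of squares are used; on the nominally
# balanced designs here they coincide with Type I and Type III, and they
# degrade gracefully when an exclusion unbalances a cell.

#' Two-way ANOVA with sex and genotype as factors
#'
#' Fits `response ~ sex * genotype` and reports the F statistic, degrees of
#' freedom and p value for the sex, genotype and interaction terms (Type II
#' sums of squares), with a significance flag at `alpha`.
#'
#' @param table Data.frame with columns `sex`, `genotype` and the response.
#' @param response Name of the response column.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of class `anova_result` with one row per term:
#'   `term`, `F`, `df1`, `df2`, `p`, `significant`.
#' @examples
#' d <- cohort_design(3)
#' d$y <- stats::rnorm(nrow(d)) + (d$genotype == "KO")
#' two_way_anova(d, "y")
#' @export
two_way_anova <- function(table, response, alpha = 0.05) {
  for (col in c("sex", "genotype", response)) {
    if (!col %in% names(table)) {
      stop(sprintf("column '%s' missing from table", col), call. = FALSE)
    }
  }
  y <- table[[response]]
  if (anyNA(y)) stop("response contains NA", call. = FALSE)
  cells <- table(factor(table$sex), factor(table$genotype))
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)
    stop(sprintf("cell %s:%s has fewer than 2 observations",
                 rownames(cells)[bad[1, 1]], colnames(cells)[bad[1, 2]]),
         call. = FALSE)
  }
  df <- data.frame(
    y = y,
    sex = factor(table$sex),
    genotype = factor(table$genotype)
  )
  fit <- stats::lm(y ~ sex * genotype, data = df)
  if (stats::deviance(fit) <= sum(df$y^2) * 1e-24 + 1e-300) {
    stop("zero residual variance: ANOVA undefined", call. = FALSE)
  }
  aov2 <- car::Anova(fit, type = 2)
  terms <- c("sex", "genotype", "sex:genotype")
  ridx <- match(terms, rownames(aov2))
  res_df <- aov2[["Df"]][rownames(aov2) == "Residuals"]
  out <- data.frame(
    term = terms,
    F = aov2[["F value"]][ridx],
    df1 = aov2[["Df"]][ridx],
    df2 = res_df,
    p = aov2[["Pr(>F)"]][ridx],
    stringsAsFactors = FALSE
  )
  out$significant <- out$p < alpha
  class(out) <- c("anova_result", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Two-way ANOVA per group of a tidy table
#'
#' Runs [two_way_anova()] within each level of a grouping column (region,
#' antibody, structure, ...). Groups that fail the preconditions (empty or
#' underfilled cells, zero residual variance) are skipped with a warning and
#' recorded in the `skipped` attribute. No multiplicity correction is applied
#' across groups; per-group p values are reported as-is.
#'
#' @param table Tidy data.frame.
#' @param response Response column name.
#' @param group_by Grouping column name (or character vector of several, in
#'   which case their interaction defines the groups).
#' @param alpha Significance level.
#' @return Long data.frame: one row per group x term, with attribute
#'   `skipped` naming groups that could not be analyzed.
#' @export
batch_anova <- function(table, response, group_by, alpha = 0.05) {
  key <- if (length(group_by) == 1L) {
    as.character(table[[group_by]])
  } else {
    do.call(paste, c(lapply(group_by, function(g) table[[g]]), sep = ":"))
  }
  groups <- unique(key)
  skipped <- character(0)
  rows <- list()
  for (g in groups) {
    sub <- table[key == g, , drop = FALSE]
    res <- tryCatch(two_way_anova(sub, response, alpha), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("group '%s' skipped: %s", g, conditionMessage(res)),
              call. = FALSE)
      skipped <- c(skipped, g)
      next
    }
    res <- cbind(group = g, as.data.frame(res), stringsAsFactors = FALSE)
    rows[[g]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), term = character(0), F = numeric(0),
               df1 = integer(0), df2 = integer(0), p = numeric(0),
               significant = logical(0))
  rownames(out) <- NULL
  names(out)[1] <- paste(group_by, collapse = ":")
  attr(out, "skipped") <- skipped
  out
}

#' Within-sex genotype contrasts (Welch t)
#'
#' Post hoc pairwise comparison restricted to the two within-sex genotype
#' contrasts, using Welch's t test.
#'
#' @param table Data.frame with `sex`, `genotype` and the response.
#' @param response Response column name.
#' @return Data.frame with one row per sex: mean difference (KO - WT), t,
#'   df, p.
#' @export
pairwise_genotype_welch <- function(table, response) {
  out <- lapply(unique(table$sex), function(sx) {
    sub <- table[table$sex == sx, ]
    ko <- sub[[response]][sub$genotype == "KO"]
    wt <- sub[[response]][sub$genotype == "WT"]
    tt <- stats::t.test(ko, wt)
    data.frame(sex = sx, estimate = mean(ko) - mean(wt),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
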