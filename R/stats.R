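#' Unpaired two-sample t-test
#'
#' Equal-variance by default (Welch by flag). When both groups have zero
#' variance and equal means the test is degenerate and returns `t = 0`,
#' `p = 1` by convention.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (default `TRUE`).
#' @return list with `t`, `df`, `p`, `mean_diff` (mean of `x` minus mean of
#'   `y`).
#' @export
two_sample_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop_invalid("each group needs n >= 2")
  if (sd(x) == 0 && sd(y) == 0) {
    d <- mean(x) - mean(y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(x) + length(y) - 2,
                p = if (d == 0) 1 else 0, mean_diff = d))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(x) - mean(y))
}

rm_check_complete <- function(tab) {
  counts <- table(tab$animal_id, tab$factor2)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    cells <- apply(bad, 1, function(i) {
      paste0(rownames(counts)[i[1]], " x ", colnames(counts)[i[2]])
    })
    stop("repeated-measures design incomplete in cell(s): ",
         paste(cells, collapse = "; "))
  }
}

#' Two-way ANOVA (strain x within-group factor), with or without repeated
#' measures
#'
#' Fits `value ~ strain * factor2`. With `repeated = TRUE` the within-animal
#' variance is partitioned over `factor2` via `aov` error strata
#' (`Error(animal_id / factor2)`), so the strain main effect is tested
#' against between-animal variance and `factor2` and the interaction against
#' within-animal variance. No sphericity correction is applied. If `factor2`
#' has a single level the model collapses to a one-factor ANOVA whose F
#' equals the squared equal-variance t statistic.
#'
#' @param table tidy cohort table with `animal_id`, `strain`, `factor2`,
#'   `value` (and optionally `measure`).
#' @param measure if `table` holds several measures, which one to analyse.
#' @param repeated treat `factor2` as a within-animal (repeated) factor.
#' @return an `anova_result` list: `effects` data frame (`effect`, `F`,
#'   `df_num`, `df_den`, `p`), `repeated`, `alpha`, and the analysed data.
#' @export
two_way_anova <- function(table, measure = NULL, repeated = FALSE) {
  if (!is.null(measure)) table <- table[table$measure == measure, , drop = FALSE]
  stopifnot(all(c("strain", "factor2", "value") %in% names(table)))
  tab <- data.frame(animal_id = factor(table$animal_id),
                    strain = factor(table$strain),
                    factor2 = factor(table$factor2),
                    value = table$value)
  if (any(table(tab$strain) < 2)) stop_invalid("need n >= 2 per strain")

  if (nlevels(tab$factor2) == 1L) {
    fit <- aov(value ~ strain, data = tab)
    sm <- summary(fit)[[1]]
    eff <- data.frame(effect = "strain", F = sm$`F value`[1],
                      df_num = sm$Df[1], df_den = sm$Df[2],
                      p = sm$`Pr(>F)`[1])
  } else if (repeated) {
    rm_check_complete(tab)
    fit <- aov(value ~ strain * factor2 + Error(animal_id / factor2), data = tab)
    sm <- summary(fit)
    between <- sm[["Error: animal_id"]][[1]]
    within <- sm[["Error: animal_id:factor2"]][[1]]
    rn <- trimws(rownames(within))
    eff <- data.frame(
      effect = c("strain", "factor2", "interaction"),
      F = c(between$`F value`[1],
            within$`F value`[match(c("factor2", "strain:factor2"), rn)]),
      df_num = c(between$Df[1],
                 within$Df[match(c("factor2", "strain:factor2"), rn)]),
      df_den = c(between$Df[nrow(between)],
                 rep(within$Df[nrow(within)], 2)),
      p = c(between$`Pr(>F)`[1],
            within$`Pr(>F)`[match(c("factor2", "strain:factor2"), rn)]))
  } else {
    fit <- aov(value ~ strain * factor2, data = tab)
    sm <- summary(fit)[[1]]
    rn <- trimws(rownames(sm))
    i <- match(c("strain", "factor2", "strain:factor2"), rn)
    eff <- data.frame(effect = c("strain", "factor2", "interaction"),
                      F = sm$`F value`[i], df_num = sm$Df[i],
                      df_den = sm$Df[match("Residuals", rn)],
                      p = sm$`Pr(>F)`[i])
  }
  rownames(eff) <- NULL
  structure(list(effects = eff, repeated = repeated, alpha = 0.05, data = tab),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA%s (alpha = %g)\n",
              if (x$repeated) " with repeated measures" else "", x$alpha))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected planned comparisons
#'
#' One unpaired two-sample strain comparison per requested level of the
#' within-group factor; adjusted p-values are `min(1, p * m)` for `m`
#' comparisons in the family.
#'
#' @param anova an `anova_result` from [two_way_anova()].
#' @param comparisons factor levels to compare (default: all levels in the
#'   data).
#' @param var_equal passed to [two_sample_test()].
#' @return data frame `level`, `mean_diff`, `t`, `df`, `p`, `p_adjusted`
#'   (empty for an empty comparison list).
#' @export
bonferroni_posthoc <- function(anova, comparisons = NULL, var_equal = TRUE) {
  stopifnot(inherits(anova, "anova_result"))
  tab <- anova$data
  if (is.null(comparisons)) comparisons <- levels(tab$factor2)
  if (length(comparisons) == 0) {
    return(data.frame(level = character(0), mean_diff = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      p_adjusted = numeric(0)))
  }
  strains <- levels(tab$strain)
  stopifnot(length(strains) == 2)
  m <- length(comparisons)
  out <- do.call(rbind, lapply(comparisons, function(lv) {
    d <- tab[tab$factor2 == lv, , drop = FALSE]
    ts <- two_sample_test(d$value[d$strain == strains[1]],
                          d$value[d$strain == strains[2]],
                          var_equal = var_equal)
    data.frame(level = lv, mean_diff = ts$mean_diff, t = ts$t, df = ts$df,
               p = ts$p, p_adjusted = min(1, ts$p * m))
  }))
  rownames(out) <- NULL
  out
}

#' Figure-style statistical report for one measure
#'
#' Runs the two-way (optionally repeated-measures) ANOVA and the
#' Bonferroni-corrected per-level planned comparisons, returning both.
#'
#' @inheritParams two_way_anova
#' @param posthoc run the per-level comparisons (default `TRUE`).
#' @return list with `anova` (effects data frame) and `post_hoc`.
#' @export
stats_report <- function(table, measure = NULL, repeated = FALSE,
                         posthoc = TRUE) {
  an <- two_way_anova(table, measure = measure, repeated = repeated)
  list(measure = measure %||% NA_character_,
       repeated = repeated,
       anova = an$effects,
       post_hoc = if (posthoc) bonferroni_posthoc(an) else NULL)
}

#' Write a statistics report to JSON
#'
#' @param report output of [stats_report()] (or a list of them).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
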