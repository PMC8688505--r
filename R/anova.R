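#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject factorial ANOVA on a long-format table. The
#' multivariate linear model is analysed with `car::Anova` (type III);
#' for every within-subject term with more than one numerator degree of
#' freedom, Mauchly's sphericity test is run and, when it rejects at
#' `alpha`, the Greenhouse-Geisser epsilon corrects the degrees of
#' freedom and p-value. Partial eta-squared is reported from the
#' univariate sums of squares.
#'
#' @param data long tibble with one row per (subject, cell).
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor columns.
#' @param subject name of the subject identifier column.
#' @param alpha significance level of Mauchly's test.
#' @return An `rm_anova` object; `tidy()` gives the effect table.
#' @export
rm_anova <- function(data, dv, within, subject = "participant",
                     alpha = 0.05) {
  data <- as.data.frame(data)
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])
  cells <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  wide <- tapply(data[[dv]], list(data[[subject]], cells), mean)
  if (anyNA(wide)) stop_microdyn("design is unbalanced: missing cells")
  n_sub <- nrow(wide)
  if (n_sub < 3L) stop_microdyn("need at least 3 subjects")
  # columns of `wide` follow lex.order = TRUE on `within`, i.e. the first
  # factor varies slowest; build idata to match
  idata <- do.call(expand.grid,
                   c(rev(lapply(within, function(w) levels(data[[w]]))),
                     KEEP.OUT.ATTRS = FALSE))
  names(idata) <- rev(within)
  idata <- idata[, within, drop = FALSE]
  if (stats::var(as.vector(wide)) < .Machine$double.eps) {
    # no variance anywhere: every effect is null by construction
    terms <- attr(stats::terms(
      stats::as.formula(paste("~", paste(within, collapse = "*")))),
      "term.labels")
    tab <- tibble::tibble(
      term = gsub(":", " x ", terms), df = NA_real_, df_error = NA_real_,
      statistic = 0, p.value = 1, pes = 0, gg_epsilon = NA_real_,
      gg_applied = FALSE, mauchly_p = NA_real_)
    return(structure(list(table = tab, n_subjects = n_sub, dv = dv,
                          within = within, alpha = alpha),
                     class = "rm_anova"))
  }
  mlm <- stats::lm(wide ~ 1)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- summary(av, multivariate = FALSE)
  uni <- s$univariate.tests
  terms <- setdiff(rownames(uni), "(Intercept)")
  sph <- s$sphericity.tests
  pva <- s$pval.adjustments
  rows <- lapply(terms, function(tm) {
    ss <- uni[tm, "Sum Sq"]
    sse <- uni[tm, "Error SS"]
    df1 <- uni[tm, "num Df"]
    df2 <- uni[tm, "den Df"]
    fval <- uni[tm, "F value"]
    pval <- uni[tm, "Pr(>F)"]
    eps <- NA_real_
    mauchly_p <- NA_real_
    gg_applied <- FALSE
    if (!is.null(sph) && tm %in% rownames(sph)) {
      mauchly_p <- sph[tm, "p-value"]
      eps <- pva[tm, "GG eps"]
      if (is.finite(mauchly_p) && mauchly_p < alpha) {
        gg_applied <- TRUE
        df1 <- df1 * eps
        df2 <- df2 * eps
        pval <- pva[tm, "Pr(>F[GG])"]
      }
    }
    tibble::tibble(
      term = gsub(":", " x ", tm),
      df = df1, df_error = df2, statistic = fval, p.value = pval,
      pes = ss / (ss + sse), gg_epsilon = eps, gg_applied = gg_applied,
      mauchly_p = mauchly_p
    )
  })
  structure(
    list(table = dplyr::bind_rows(rows), n_subjects = n_sub,
         dv = dv, within = within, alpha = alpha),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> %s over %s (n = %d)\n", x$dv,
              paste(x$within, collapse = " x "), x$n_subjects))
  print(x$table)
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_terms = nrow(x$table),
                 n_significant = sum(x$table$p.value < 0.05))
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Paired t-tests between all (or the given) pairs of condition levels,
#' optionally within the levels of a stratifying factor (e.g. cortical
#' region), with p-values multiplied by the number of comparisons in each
#' stratum and clipped at 1.
#'
#' @param data long tibble.
#' @param dv dependent-variable column name.
#' @param condition factor column of the compared levels.
#' @param subject subject identifier column.
#' @param within optional stratifying column; comparisons and the
#'   correction are carried out per stratum.
#' @param pairs optional list of 2-vectors of levels; default all pairs.
#' @return tibble `group`, `level1`, `level2`, `estimate`, `statistic`,
#'   `p.value`, `p.adjusted`, `direction`.
#' @export
bonferroni_posthoc <- function(data, dv, condition, subject = "participant",
                               within = NULL, pairs = NULL) {
  data <- as.data.frame(data)
  strata <- if (is.null(within)) list(all = data) else
    split(data, data[[within]])
  out <- lapply(names(strata), function(gname) {
    d <- strata[[gname]]
    agg <- stats::aggregate(d[[dv]],
                            list(subject = d[[subject]],
                                 condition = d[[condition]]), mean)
    lv <- unique(as.character(agg$condition))
    prs <- pairs %||% utils::combn(lv, 2L, simplify = FALSE)
    m <- length(prs)
    rows <- lapply(prs, function(pr) {
      a <- agg[agg$condition == pr[1L], ]
      b <- agg[agg$condition == pr[2L], ]
      common <- intersect(a$subject, b$subject)
      if (length(common) < 2L) stop_microdyn("need >= 2 paired subjects")
      xa <- a$x[match(common, a$subject)]
      xb <- b$x[match(common, b$subject)]
      diffs <- xa - xb
      if (stats::sd(diffs) == 0) {
        tt <- list(statistic = c(t = 0), p.value = 1,
                   estimate = mean(diffs))
      } else {
        tt <- stats::t.test(xa, xb, paired = TRUE)
      }
      tibble::tibble(
        group = gname, level1 = pr[1L], level2 = pr[2L],
        estimate = mean(diffs), statistic = unname(tt$statistic),
        p.value = tt$p.value,
        p.adjusted = min(1, tt$p.value * m),
        direction = ifelse(mean(diffs) >= 0, "increase", "decrease")
      )
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' One-way repeated-measures ANOVA on sequence statistics
#'
#' Condition effect on a per-(participant, condition) statistic (entropy
#' rate, Hurst exponent, ...): one-way within-subject ANOVA with
#' Greenhouse-Geisser correction, followed by Bonferroni-corrected paired
#' post-hoc tests over all condition pairs. Participants with missing
#' cells are excluded listwise with a message.
#'
#' @param data tibble with columns for subject, condition and the value.
#' @param dv value column name.
#' @param condition condition column name.
#' @param subject subject column name.
#' @return list with `anova` (an [rm_anova]) and `posthoc` (tibble).
#' @export
condition_anova_seqstats <- function(data, dv = "value",
                                     condition = "condition",
                                     subject = "participant") {
  data <- as.data.frame(data)
  counts <- table(data[[subject]], data[[condition]]) > 0
  complete <- rownames(counts)[rowSums(counts) == ncol(counts)]
  dropped <- setdiff(unique(as.character(data[[subject]])), complete)
  if (length(dropped)) {
    message(sprintf("excluding %d participant(s) with missing cells: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    data <- data[data[[subject]] %in% complete, ]
  }
  av <- rm_anova(data, dv = dv, within = condition, subject = subject)
  ph <- bonferroni_posthoc(data, dv = dv, condition = condition,
                           subject = subject)
  list(anova = av, posthoc = ph)
}
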