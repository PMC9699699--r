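#' Stage (DIV) temporal profile of a metric
#'
#' Aggregates per-view (or per-cell) metric values into per-stage mean,
#' SEM (SD/sqrt(n)) and n, ordered by DIV.
#'
#' @param records data.frame with a DIV column and a value column.
#' @param value_col name of the value column (default \code{"value"}).
#' @param div_col name of the DIV column (default \code{"div"}).
#' @param metric_name label stored with the profile.
#' @return a \code{stage_profile} data.frame with columns \code{div},
#'   \code{mean}, \code{sem}, \code{n}. Stages with a single value get
#'   \code{NA} SEM; empty stages are dropped with a warning.
#' @export
stage_profiles <- function(records, value_col = "value", div_col = "div",
                           metric_name = value_col) {
  stopifnot(is.data.frame(records),
            value_col %in% names(records), div_col %in% names(records))
  v <- records[[value_col]]; d <- records[[div_col]]
  keep <- !is.na(v)
  if (!all(keep)) {
    records <- records[keep, ]; v <- v[keep]; d <- d[keep]
  }
  divs <- sort(unique(d))
  out <- data.frame(
    div = divs,
    mean = vapply(divs, function(dd) mean(v[d == dd]), numeric(1)),
    sem = vapply(divs, function(dd) {
      vv <- v[d == dd]
      if (length(vv) < 2) NA_real_ else stats::sd(vv) / sqrt(length(vv))
    }, numeric(1)),
    n = vapply(divs, function(dd) sum(d == dd), integer(1))
  )
  if (any(out$n == 0)) {
    warning("empty stage(s) dropped")
    out <- out[out$n > 0, ]
  }
  structure(out, class = c("stage_profile", "data.frame"),
            metric_name = metric_name)
}

#' Growth rates (first derivative of a stage profile)
#'
#' Finite-difference derivative of the per-stage means on the irregular
#' DIV grid: \code{(mean[i+1] - mean[i]) / (div[i+1] - div[i])}, assigned
#' to interval midpoints.
#'
#' @param profile a \code{\link{stage_profiles}} result.
#' @return data.frame with columns \code{div_mid} and \code{rate}
#'   (metric units per day).
#' @export
growth_rates <- function(profile) {
  if (nrow(profile) < 2) stop("need at least 2 stages")
  if (anyDuplicated(profile$div)) stop("duplicate stage days")
  dd <- diff(profile$div)
  data.frame(div_mid = profile$div[-nrow(profile)] + dd / 2,
             rate = diff(profile$mean) / dd)
}

#' Correlation between two stage profiles
#'
#' Ordinary least-squares fit of the y-profile means on the x-profile
#' means over a matching stage grid.
#'
#' @param x,y \code{stage_profile}s on identical DIV grids (>= 3 stages).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared} and
#'   \code{degenerate} (TRUE when y has zero variance, in which case
#'   \code{r_squared} is 0 by convention).
#' @export
profile_correlation <- function(x, y) {
  if (!identical(x$div, y$div)) stop("stage grids differ")
  if (nrow(x) < 3) stop("need at least 3 stages")
  if (stats::var(x$mean) == 0) stop("zero variance in x profile")
  if (stats::var(y$mean) == 0) {
    return(list(slope = 0, intercept = mean(y$mean), r_squared = 0,
                degenerate = TRUE))
  }
  fit <- stats::lm(y$mean ~ x$mean)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y$mean - mean(y$mean))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot,
       degenerate = FALSE)
}

#' Significance stars
#'
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for
#' p < 0.05, otherwise \code{"n.s."}.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "n.s.")))
}

#' Group comparison (t-test or one-way ANOVA with Bonferroni post hoc)
#'
#' Two groups: two-tailed unpaired Student's t-test (pooled variance).
#' Three or more groups: one-way ANOVA, followed by all-pairs pooled
#' t-tests with Bonferroni adjustment (raw p times the number of pairs,
#' capped at 1).
#'
#' @param groups named list of numeric vectors (each n >= 2), or a
#'   data.frame with \code{value} and \code{group} columns.
#' @param test \code{"auto"} (default: t-test for 2 groups, ANOVA
#'   otherwise), \code{"t_test_two_tailed_unpaired"} or
#'   \code{"anova_bonferroni"}.
#' @return object of class \code{group_comparison}: list with \code{test},
#'   \code{statistic}, \code{p_value}, \code{stars}, and for ANOVA a
#'   \code{pairwise} data.frame (group1, group2, t, p_raw, p_adj, stars).
#' @export
group_compare <- function(groups,
                          test = c("auto", "t_test_two_tailed_unpaired",
                                   "anova_bonferroni")) {
  test <- match.arg(test)
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  g <- length(groups)
  if (g < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs n >= 2")
  }
  if (test == "auto") {
    test <- if (g == 2) "t_test_two_tailed_unpaired" else "anova_bonferroni"
  }
  if (test == "t_test_two_tailed_unpaired") {
    if (g != 2) stop("t-test needs exactly 2 groups")
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE,
                        alternative = "two.sided")
    return(structure(list(test = test,
                          statistic = unname(tt$statistic),
                          df = unname(tt$parameter),
                          p_value = tt$p.value,
                          stars = p_stars(tt$p.value),
                          groups = names(groups)),
                     class = "group_comparison"))
  }
  val <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  fit <- stats::aov(val ~ lab)
  an <- summary(fit)[[1]]
  m <- g * (g - 1) / 2
  pairs <- utils::combn(names(groups), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   t = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                   stars = NA_character_)
  for (i in seq_len(ncol(pairs))) {
    tt <- stats::t.test(groups[[pairs[1, i]]], groups[[pairs[2, i]]],
                        var.equal = TRUE)
    pw$t[i] <- unname(tt$statistic)
    pw$p_raw[i] <- tt$p.value
    pw$p_adj[i] <- min(1, tt$p.value * m)
  }
  pw$stars <- p_stars(pw$p_adj)
  structure(list(test = test,
                 statistic = an$`F value`[1],
                 df = c(an$Df[1], an$Df[2]),
                 p_value = an$`Pr(>F)`[1],
                 stars = p_stars(an$`Pr(>F)`[1]),
                 pairwise = pw,
                 groups = names(groups)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$test == "t_test_two_tailed_unpaired") {
    cat(sprintf("<group_comparison>  t(%g) = %.3f, p = %.4g %s\n",
                x$df, x$statistic, x$p_value, x$stars))
  } else {
    cat(sprintf("<group_comparison>  F(%d,%d) = %.3f, p = %.4g %s; %d Bonferroni pairs\n",
                x$df[1], x$df[2], x$statistic, x$p_value, x$stars,
                nrow(x$pairwise)))
  }
  invisible(x)
}
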