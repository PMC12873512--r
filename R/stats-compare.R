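#' Group summaries (mean, SD, n, SE, 95% CI)
#'
#' @param data a data frame.
#' @param value name of the numeric response column.
#' @param ... grouping column names (character or bare, via `dplyr::across`).
#' @return a tibble with one row per group: `mean`, `sd`, `n`, `se`,
#'   `ci_lower`, `ci_upper` (t-based 95% interval).
#' @export
group_summary <- function(data, value, ...) {
  groups <- c(...)
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      mean = mean(.data[[value]], na.rm = TRUE),
      sd = sd(.data[[value]], na.rm = TRUE),
      n = sum(!is.na(.data[[value]])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n),
      ci_lower = .data$mean - qt(0.975, .data$n - 1) * .data$se,
      ci_upper = .data$mean + qt(0.975, .data$n - 1) * .data$se
    )
  out
}

#' Two-way factorial ANOVA with Tukey HSD and assumption checks
#'
#' Fits `value ~ a * b` (main effects plus interaction), reports Type-II F
#' tests (equivalent to the classical decomposition in balanced designs),
#' Tukey honest significant difference pairwise comparisons for both factors
#' and the interaction cells, and the usual assumption checks: Levene's test
#' for homogeneity of variances across cells and Shapiro-Wilk on the
#' residuals.
#'
#' @param data a data frame in long format.
#' @param value numeric response column name.
#' @param a,b factor column names.
#' @return an object of class `factorial_comparison`: list with `anova`
#'   (tibble: term, df, sumsq, statistic, p_value), `tukey` (tibble:
#'   term, contrast, estimate, conf_low, conf_high, adj_p_value),
#'   `levene`, `shapiro` (one-row tibbles), `groups` (cell summaries via
#'   [group_summary()]) and the fitted `aov` object.
#' @export
two_way_anova_tukey <- function(data, value, a, b) {
  df <- tibble(
    value = data[[value]],
    a = factor(data[[a]]),
    b = factor(data[[b]])
  )
  df <- df[complete.cases(df), ]
  cells <- table(df$a, df$b)
  if (any(cells == 0L)) abort("empty factorial cell.")
  if (any(cells < 2L)) abort("need >= 2 observations per cell.")

  fit <- aov(value ~ a * b, data = df)

  tot_ss <- sum((df$value - mean(df$value))^2)
  if (tot_ss <= 1e-12 * max(abs(df$value), 1)^2) {
    # perfectly constant response: every effect is exactly null
    terms_out <- c(a, b, paste0(a, ":", b))
    cell_summary <- df |>
      dplyr::rename(!!a := "a", !!b := "b") |>
      group_summary("value", a, b)
    return(structure(
      list(
        anova = tibble(term = terms_out,
                       df = c(nlevels(df$a) - 1L, nlevels(df$b) - 1L,
                              (nlevels(df$a) - 1L) * (nlevels(df$b) - 1L)),
                       sumsq = 0, statistic = 0, p_value = 1),
        tukey = tibble(term = character(), contrast = character(),
                       estimate = numeric(), conf_low = numeric(),
                       conf_high = numeric(), adj_p_value = numeric()),
        levene = tibble(statistic = NA_real_, df1 = NA_integer_,
                        df2 = NA_integer_, p_value = NA_real_),
        shapiro = tibble(statistic = NA_real_, p_value = NA_real_),
        groups = cell_summary, fit = fit
      ),
      class = "factorial_comparison"
    ))
  }

  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  keep <- terms != "Residuals"
  anova_tbl <- tibble(
    term = sub("^a$", a, sub("^b$", b, sub("^a:b$", paste0(a, ":", b), terms[keep]))),
    df = a2$Df[keep],
    sumsq = a2$`Sum Sq`[keep],
    statistic = a2$`F value`[keep],
    p_value = a2$`Pr(>F)`[keep]
  )

  tk <- TukeyHSD(fit)
  tukey_tbl <- purrr::map_dfr(names(tk), function(tn) {
    mm <- tk[[tn]]
    tibble(
      term = sub("^a$", a, sub("^b$", b, sub("^a:b$", paste0(a, ":", b), tn))),
      contrast = rownames(mm),
      estimate = unname(mm[, "diff"]),
      conf_low = unname(mm[, "lwr"]),
      conf_high = unname(mm[, "upr"]),
      adj_p_value = unname(mm[, "p adj"])
    )
  })

  lev <- car::leveneTest(value ~ a:b, data = df)
  levene_tbl <- tibble(
    statistic = lev$`F value`[1],
    df1 = lev$Df[1], df2 = lev$Df[2],
    p_value = lev$`Pr(>F)`[1]
  )
  sw <- shapiro.test(stats::residuals(fit))
  shapiro_tbl <- tibble(statistic = unname(sw$statistic), p_value = sw$p.value)

  cell_summary <- df |>
    dplyr::rename(!!a := "a", !!b := "b") |>
    group_summary("value", a, b)

  structure(
    list(
      anova = anova_tbl, tukey = tukey_tbl, levene = levene_tbl,
      shapiro = shapiro_tbl, groups = cell_summary, fit = fit
    ),
    class = "factorial_comparison"
  )
}

#' @export
#' @method print factorial_comparison
print.factorial_comparison <- function(x, ...) {
  cat("<factorial_comparison>\n")
  print(x$anova)
  invisible(x)
}

#' @export
tidy.factorial_comparison <- function(x, ...) x$anova

#' @export
glance.factorial_comparison <- function(x, ...) {
  tibble(
    levene_p = x$levene$p_value,
    shapiro_p = x$shapiro$p_value,
    n = sum(x$groups$n)
  )
}

#' Compare two groups with a normality-gated test
#'
#' Checks each group for normality with the Kolmogorov-Smirnov test (against
#' a normal with the group's own moments); if both pass at `alpha`, an
#' (unpaired, Welch) t-test is used, otherwise the Mann-Whitney U test.
#' Zero-variance groups are routed to the rank test.
#'
#' @param data a data frame in long format.
#' @param value numeric response column name.
#' @param group grouping column with exactly two levels.
#' @param alpha significance level of the normality gate (default 0.05).
#' @return a one-row tibble: `test` (`"t"` or `"mann-whitney"`), `statistic`,
#'   `p_value`, `normal_a`, `normal_b` (gate p-values), plus the group
#'   summaries in `attr(, "groups")`.
#' @export
compare_two_groups <- function(data, value, group, alpha = 0.05) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) abort("`group` must have exactly two levels.")
  x <- data[[value]][g == levels(g)[1]]
  y <- data[[value]][g == levels(g)[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) abort("need n >= 3 per group.")

  ks_p <- function(v) {
    if (sd(v) == 0) return(0) # degenerate: clearly not normal
    suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
  }
  pa <- ks_p(x); pb <- ks_p(y)
  if (pa > alpha && pb > alpha) {
    ht <- t.test(x, y)
    test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
    test <- "mann-whitney"
  }
  out <- tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    normal_a = pa,
    normal_b = pb
  )
  attr(out, "groups") <- group_summary(data, value, group)
  out
}

#' Kruskal-Wallis test with Dunn post hoc and compact letters
#'
#' Rank-based comparison of three or more groups: the Kruskal-Wallis H
#' statistic (tie-corrected, via [stats::kruskal.test()]), Dunn's z tests for
#' all pairs with Holm adjustment, and a compact letter display at `alpha`
#' (groups sharing no letter differ significantly).
#'
#' @param data a data frame in long format.
#' @param value numeric response column name.
#' @param group grouping column (>= 2 levels, each n >= 2).
#' @param alpha significance level for the letters (default 0.05).
#' @return an object of class `rank_comparison`: list with `test` (one-row
#'   tibble: statistic, df, p_value), `pairwise` (tibble: contrast, z,
#'   p_value, adj_p_value), `letters` (tibble: group, letters) and `groups`
#'   (summaries).
#' @export
kruskal_wallis <- function(data, value, group, alpha = 0.05) {
  g <- factor(data[[group]])
  v <- data[[value]]
  keep <- !is.na(v) & !is.na(g)
  g <- droplevels(g[keep]); v <- v[keep]
  if (nlevels(g) < 2L) abort("need at least 2 groups.")
  if (any(table(g) < 2L)) abort("each group needs n >= 2.")
  if (sd(v) == 0) abort("all observations tied across all groups.")

  kt <- kruskal.test(v, g)

  # Dunn's test: pairwise z on mean ranks with tie correction
  n <- length(v)
  rk <- rank(v)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    tibble(contrast = paste(i, j, sep = "-"), z = z,
           p_value = 2 * pnorm(-abs(z)))
  })
  pw$adj_p_value <- p.adjust(pw$p_value, method = "holm")

  med <- tapply(v, g, median)
  letters_tbl <- compact_letters(levs[order(-med)], pw$contrast, pw$adj_p_value, alpha)

  structure(
    list(
      test = tibble(statistic = unname(kt$statistic),
                    df = unname(kt$parameter), p_value = kt$p.value),
      pairwise = pw,
      letters = letters_tbl,
      groups = group_summary(data[keep, , drop = FALSE], value, group)
    ),
    class = "rank_comparison"
  )
}

#' @export
#' @method print rank_comparison
print.rank_comparison <- function(x, ...) {
  cat(sprintf(
    "<rank_comparison> Kruskal-Wallis H = %.3f (df = %d), p = %.3g\n",
    x$test$statistic, x$test$df, x$test$p_value
  ))
  print(x$letters)
  invisible(x)
}

#' @export
tidy.rank_comparison <- function(x, ...) x$pairwise

#' @export
glance.rank_comparison <- function(x, ...) x$test

# Compact letter display from an adjusted p matrix: maximal cliques of the
# "not significantly different" graph get a letter each (groups ordered as
# given; absorbed cliques dropped). Group counts here are small, so subsets
# are enumerated directly.
compact_letters <- function(groups, contrasts, adj_p, alpha = 0.05) {
  k <- length(groups)
  ns <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_along(contrasts)) {
    pr <- strsplit(contrasts[i], "-", fixed = TRUE)[[1]]
    if (adj_p[i] < alpha) {
      ns[pr[1], pr[2]] <- FALSE
      ns[pr[2], pr[1]] <- FALSE
    }
  }
  # all subsets that are cliques of the NS graph
  cliques <- list()
  for (bits in seq_len(2^k - 1)) {
    members <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    sub <- ns[members, members, drop = FALSE]
    if (all(sub)) cliques[[length(cliques) + 1L]] <- members
  }
  # keep maximal cliques only
  maximal <- cliques[vapply(cliques, function(ci) {
    !any(vapply(cliques, function(cj) {
      length(cj) > length(ci) && all(ci %in% cj)
    }, logical(1)))
  }, logical(1))]
  maximal <- maximal[order(vapply(maximal, min, integer(1)))]
  lett <- rep("", k)
  for (m in seq_along(maximal)) {
    lett[maximal[[m]]] <- paste0(lett[maximal[[m]]], letters[m])
  }
  tibble(group = groups, letters = lett)
}
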