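#' Median transcript count per group
#'
#' Standard median (midpoint of the central order statistics for even n) of
#' per-cell spot counts, for one group or all groups at once.
#'
#' @param cells Per-cell tibble with `group` and `spot_count` columns.
#' @param group Optional single group label; if omitted, a per-group table
#'   is returned.
#' @return A number (one group) or a tibble `group`, `n`, `median_count`.
#' @export
median_counts <- function(cells, group = NULL) {
  stopifnot(all(c("group", "spot_count") %in% names(cells)))
  if (!is.null(group)) {
    x <- cells$spot_count[cells$group == group]
    if (length(x) == 0L) stop("no cells in group '", group, "'", call. = FALSE)
    return(median(x))
  }
  cells |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), median_count = median(.data$spot_count),
                     .groups = "drop")
}

#' Pearson correlation between cell volume and transcript count
#'
#' Pearson's r with the two-sided p-value from the t transform, as given by
#' `cor.test()`; `r2` is reported because count-volume scaling is judged on
#' the fraction of count variance explained by cell size.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), e.g. volumes and
#'   counts; both must have nonzero variance.
#' @return An object of class `fish_cor` with fields `r`, `r2`, `p_value`,
#'   `n`; has [tidy()] and [glance()] methods.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
         p_value = ct$p.value, n = length(x), conf_int = ct$conf.int),
    class = "fish_cor"
  )
}

#' @export
print.fish_cor <- function(x, ...) {
  cat(sprintf("<fish_cor> r = %.3f, R^2 = %.3f, p = %.3g, n = %d\n",
              x$r, x$r2, x$p_value, x$n))
  invisible(x)
}

#' @rdname pearson
#' @param x A `fish_cor` object.
#' @param ... Unused.
#' @export
tidy.fish_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, r.squared = x$r2, p.value = x$p_value,
                 conf.low = x$conf_int[1], conf.high = x$conf_int[2])
}

#' @rdname pearson
#' @export
glance.fish_cor <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, p.value = x$p_value, nobs = x$n)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fits `aov(value ~ group)` and runs `TukeyHSD()` -- the Tukey-Kramer
#' studentized-range procedure, valid for unequal group sizes -- exactly as
#' used for probe-set TCCF comparisons. Groups with zero variance and n = 2
#' are tolerated with a warning.
#'
#' @param data Tibble with the response and grouping columns.
#' @param value,group Column names (strings) of response and group.
#' @return An object of class `fish_tukey`: fields `f_statistic`, `p_value`,
#'   `df`, `comparisons` (tibble of pairwise contrasts with mean difference,
#'   confidence bounds and adjusted p). Has [tidy()]/[glance()] methods.
#' @export
anova_tukey <- function(data, value = "tccf", group = "group") {
  stopifnot(all(c(value, group) %in% names(data)))
  df <- data.frame(value = data[[value]], group = factor(data[[group]]))
  tab <- table(df$group)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs n >= 2", call. = FALSE)
  degenerate <- vapply(split(df$value, df$group),
                       function(v) sd(v) == 0 && length(v) == 2L, logical(1))
  if (any(degenerate)) {
    warning("group(s) with n = 2 and zero variance: ",
            paste(names(degenerate)[degenerate], collapse = ", "), call. = FALSE)
  }
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit)$group
  cmp <- tibble::tibble(
    contrast = rownames(hsd),
    diff = hsd[, "diff"], conf.low = hsd[, "lwr"], conf.high = hsd[, "upr"],
    adj.p.value = hsd[, "p adj"]
  )
  structure(
    list(f_statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
         df = unname(an$Df), comparisons = cmp, fit = fit),
    class = "fish_tukey"
  )
}

#' @export
print.fish_tukey <- function(x, ...) {
  cat(sprintf("<fish_tukey> F(%d, %d) = %.3f, p = %.3g; %d pairwise contrasts\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value, nrow(x$comparisons)))
  invisible(x)
}

#' @rdname anova_tukey
#' @param x A `fish_tukey` object.
#' @param ... Unused.
#' @export
tidy.fish_tukey <- function(x, ...) x$comparisons

#' @rdname anova_tukey
#' @export
glance.fish_tukey <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, p.value = x$p_value,
                 df = x$df[1], df.residual = x$df[2])
}

#' Relative label intensity per probe set
#'
#' Expresses each group's mean corrected fluorescence as a percentage of a
#' reference group. By default the reference is the group with the highest
#' mean, so the brightest probe set reads 100% and all others <= 100%.
#'
#' @param spots Spot-level tibble with `group` and a value column.
#' @param value Column to average (default `"tccf"`).
#' @param reference Reference group label; default `NULL` picks the group
#'   with the highest mean.
#' @return Tibble with `group`, `n`, `mean_value`, `relative_pct`.
#' @export
relative_intensity <- function(spots, value = "tccf", reference = NULL) {
  means <- spots |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_value = mean(.data[[value]]),
                     .groups = "drop")
  if (is.null(reference)) {
    reference <- means$group[which.max(means$mean_value)]
  }
  ref <- means$mean_value[means$group == reference]
  if (length(ref) != 1L || ref <= 0) {
    stop("reference group mean must be positive", call. = FALSE)
  }
  dplyr::mutate(means, relative_pct = 100 * .data$mean_value / ref)
}

# greedy one-to-one matching by ascending pairwise distance
match_spots_greedy <- function(ay, ax, by, bx, max_dist) {
  na <- length(ay); nb <- length(by)
  if (na == 0L || nb == 0L) return(integer(0))
  d <- outer(ay, by, "-")^2 + outer(ax, bx, "-")^2
  ok <- which(d <= max_dist^2)
  if (length(ok) == 0L) return(integer(0))
  ord <- ok[order(d[ok], ok)]  # ties broken by (a, b) index order
  used_a <- logical(na); used_b <- logical(nb)
  match_of_a <- rep(NA_integer_, na)
  for (idx in ord) {
    a <- (idx - 1L) %% na + 1L
    b <- (idx - 1L) %/% na + 1L
    if (!used_a[a] && !used_b[b]) {
      used_a[a] <- TRUE; used_b[b] <- TRUE
      match_of_a[a] <- b
    }
  }
  match_of_a
}

#' Dual-dye spot co-localization
#'
#' Fraction of channel-a spots with a one-to-one channel-b partner within
#' `max_dist_px`, using greedy nearest-pair-first matching (closest pairs
#' claimed first, each spot used at most once, which prevents double
#' counting in dense fields). When a `cell` column is present in both
#' tables the fraction is computed per cell and averaged, matching how
#' odd/even probe-set co-localization is reported.
#'
#' @param spots_a,spots_b Tibbles with `y`, `x` (and optionally `cell_id`)
#'   columns; both non-empty.
#' @param max_dist_px Matching radius in pixels (default 2, about one
#'   diffraction-limited spot diameter at 100 nm pixels).
#' @return A list: `fraction` (mean per-cell or pooled fraction of a-spots
#'   matched), `per_cell` tibble when cell ids were available, `n_a`, `n_b`.
#' @export
colocalization <- function(spots_a, spots_b, max_dist_px = 2) {
  if (nrow(spots_a) == 0L || nrow(spots_b) == 0L) {
    stop("both spot lists must be non-empty", call. = FALSE)
  }
  stopifnot(max_dist_px >= 0)
  per_cell_possible <- "cell_id" %in% names(spots_a) &&
    "cell_id" %in% names(spots_b)
  frac_of <- function(a, b) {
    m <- match_spots_greedy(a$y, a$x, b$y, b$x, max_dist_px)
    if (length(m) == 0L) 0 else mean(!is.na(m))
  }
  if (per_cell_possible) {
    cells <- unique(spots_a$cell_id)
    per_cell <- tibble::tibble(
      cell_id = cells,
      fraction = purrr::map_dbl(cells, function(cc) {
        frac_of(spots_a[spots_a$cell_id == cc, ],
                spots_b[spots_b$cell_id == cc, ])
      })
    )
    list(fraction = mean(per_cell$fraction), per_cell = per_cell,
         n_a = nrow(spots_a), n_b = nrow(spots_b))
  } else {
    list(fraction = frac_of(spots_a, spots_b), per_cell = NULL,
         n_a = nrow(spots_a), n_b = nrow(spots_b))
  }
}

#' False detection rate from no-probe controls
#'
#' Spots per cell in probe-omission controls, plus its reciprocal ("one
#' spurious mRNA per k cells"), the form in which non-specific detection is
#' usually quoted.
#'
#' @param cells Per-cell tibble with `spot_count` (no-probe group rows).
#' @return Tibble with `n_cells`, `n_spots`, `spots_per_cell`,
#'   `cells_per_spot` (Inf when no spots at all).
#' @export
false_detection_rate <- function(cells) {
  stopifnot("spot_count" %in% names(cells), nrow(cells) >= 1L)
  total <- sum(cells$spot_count)
  rate <- total / nrow(cells)
  tibble::tibble(n_cells = nrow(cells), n_spots = total,
                 spots_per_cell = rate,
                 cells_per_spot = if (total == 0) Inf else 1 / rate)
}
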