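# Condition-level statistics: Mann-Whitney U comparisons, the gliding-assay
# track filter, and per-condition summary tables.

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from the rank definition, U = R1 - n1(n1+1)/2, the number of
#' (x, y) pairs with x > y (ties counted 1/2). The two-sided p-value uses the
#' exact null distribution whenever n1 + n2 <= 20 and there are no ties
#' (tail doubling, capped at 1), and otherwise the normal approximation with
#' tie correction and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return Object of class `mw_test`: `u_statistic` (U for `x`),
#'   `p_two_sided`, `method` (`"exact"` or `"normal-approximation"`),
#'   `n1`, `n2`, `ties`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && n1 + n2 <= 20L) {
    # exact null distribution of U; symmetric about n1*n2/2
    lo <- stats::pwilcox(u, n1, n2)
    hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    if (ties)
      message("mann_whitney: ties present, using the tie-corrected ",
              "normal approximation")
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0)
      stop("degenerate samples: all pooled values tie", call. = FALSE)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
    method <- "normal-approximation"
  }
  structure(list(u_statistic = u, p_two_sided = p, method = method,
                 n1 = n1, n2 = n2, ties = ties),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g (n1 = %d, n2 = %d), p = %.4g [%s] %s\n",
              x$u_statistic, x$n1, x$n2, x$p_two_sided, x$method,
              significance_stars(x$p_two_sided)))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 1e-4,
#' `"n.s."` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "n.s."), right = FALSE) |>
    as.character()
}

#' Filter motility tracks on velocity dispersion
#'
#' Tracks whose velocity SD / mean velocity exceeds 0.33 are excluded
#' (strictly greater: a ratio of exactly 0.33 is retained). Tracks with
#' non-positive mean velocity are flagged invalid and fall in neither bin.
#'
#' @param tracks List of per-track velocity vectors (nm/s, one value per
#'   frame interval; >= 2 values each), or a `data.frame` with columns
#'   `mean_v` and `sd_v`.
#' @param max_cv Exclusion threshold on sd/mean (default 0.33).
#' @return List with data frames `retained`, `excluded`, `invalid`, each
#'   having track_id, mean_v, sd_v, cv columns.
#' @export
filter_motility_tracks <- function(tracks, max_cv = 0.33) {
  if (is.data.frame(tracks)) {
    df <- data.frame(track_id = if (!is.null(tracks$track_id))
                       as.character(tracks$track_id)
                     else as.character(seq_len(nrow(tracks))),
                     mean_v = tracks$mean_v, sd_v = tracks$sd_v,
                     stringsAsFactors = FALSE)
  } else {
    bad <- vapply(tracks, length, integer(1)) < 2L
    if (any(bad))
      stop("each track needs at least 2 velocity samples", call. = FALSE)
    df <- data.frame(
      track_id = if (!is.null(names(tracks))) names(tracks)
                 else as.character(seq_along(tracks)),
      mean_v = vapply(tracks, mean, numeric(1)),
      sd_v = vapply(tracks, stats::sd, numeric(1)),
      stringsAsFactors = FALSE)
  }
  df$cv <- df$sd_v / df$mean_v
  invalid <- df$mean_v <= 0 | !is.finite(df$cv)
  excluded <- !invalid & df$cv > max_cv
  retained <- !invalid & !excluded
  if (any(invalid))
    message(sprintf("filter_motility_tracks: %d invalid track(s) ",
                    sum(invalid)), "(non-positive mean velocity)")
  message(sprintf("filter_motility_tracks: retained %d, excluded %d of %d",
                  sum(retained), sum(excluded), nrow(df)))
  list(retained = df[retained, , drop = FALSE],
       excluded = df[excluded, , drop = FALSE],
       invalid = df[invalid, , drop = FALSE])
}

#' Per-condition summary of a metric
#'
#' Groups records by `group_keys` and reports n, mean, median and SEM of
#' `metric`. Records that are non-converged (`converged == FALSE`) or carry a
#' missing metric value are counted as excluded, not averaged — mirroring the
#' exclusion of unanalyzable ROIs/traces from condition summaries. Groups
#' with no usable records are omitted with a warning.
#'
#' @param records `data.frame` of per-ROI or per-trace rows.
#' @param group_keys Character vector of grouping column names.
#' @param metric Name of the numeric column to summarize.
#' @return `data.frame`: group key columns, metric, n, mean, median, sem,
#'   excluded_n. Row order follows the sorted group keys, so summaries are
#'   invariant to input row order.
#' @export
summarize_condition <- function(records, group_keys, metric) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  missing_cols <- setdiff(c(group_keys, metric), names(records))
  if (length(missing_cols) > 0L)
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  usable <- if ("converged" %in% names(records))
    records$converged & !is.na(records[[metric]])
  else !is.na(records[[metric]])

  key <- interaction(records[group_keys], drop = FALSE, sep = "\r")
  out <- lapply(sort(unique(as.character(key))), function(k) {
    in_grp <- as.character(key) == k
    vals <- records[[metric]][in_grp & usable]
    excl <- sum(in_grp & !usable)
    if (length(vals) == 0L) {
      warning(sprintf("group '%s' has no usable records; omitted",
                      gsub("\r", "/", k)), call. = FALSE)
      return(NULL)
    }
    grp <- records[which(in_grp)[1], group_keys, drop = FALSE]
    cbind(grp,
          data.frame(metric = metric, n = length(vals), mean = mean(vals),
                     median = stats::median(vals),
                     sem = if (length(vals) > 1L)
                       stats::sd(vals) / sqrt(length(vals)) else 0,
                     excluded_n = excl, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise Mann-Whitney comparisons of a metric across conditions
#'
#' Runs [mann_whitney()] on every unordered pair of groups, with optional
#' Holm adjustment (off by default: per-comparison p-values are reported, as
#' is conventional for star annotations).
#'
#' @inheritParams summarize_condition
#' @param group Single grouping column name.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return `data.frame`: group_a, group_b, n1, n2, U, p, method, stars.
#' @export
compare_conditions <- function(records, group, metric, adjust = "none") {
  adjust <- match.arg(adjust, c("none", "holm"))
  usable <- if ("converged" %in% names(records))
    records$converged & !is.na(records[[metric]])
  else !is.na(records[[metric]])
  records <- records[usable, , drop = FALSE]
  groups <- sort(unique(records[[group]]))
  if (length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    xa <- records[[metric]][records[[group]] == pr[1]]
    xb <- records[[metric]][records[[group]] == pr[2]]
    tst <- mann_whitney(xa, xb)
    data.frame(group_a = pr[1], group_b = pr[2], n1 = tst$n1, n2 = tst$n2,
               U = tst$u_statistic, p = tst$p_two_sided,
               method = tst$method, stringsAsFactors = FALSE)
  }))
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  out$stars <- significance_stars(out$p)
  out
}
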