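# Paired comfort-vs-fatigue inference. The test-selection rule: Shapiro-Wilk
# on the paired differences at alpha = 0.05; normal -> paired t-test,
# otherwise Wilcoxon signed-rank (Pratt zero handling, normal approximation
# with tie correction at the usual n = 18 scale, exact null distribution for
# fewer than 10 nonzero-inclusive pairs without ties). Edge-wise maps use a
# plain paired t-test regardless of normality, with Benjamini-Hochberg FDR
# over the 276 pairs.

#' Paired two-condition comparison with a normality gate
#'
#' @param comfort,fatigue participant-aligned numeric vectors, length >= 3.
#' @param alpha_normality Shapiro-Wilk significance level for the gate.
#' @param tail `"two"` or `"one"`; one-tailed tests the direction
#'   fatigue > comfort.
#' @param gate `TRUE` (default) applies the Shapiro-Wilk gate; `FALSE`
#'   forces the paired t-test.
#' @return object of class `comparison_result`: `test_used` (`"paired_t"` or
#'   `"wilcoxon"`), `normality_p`, `statistic` (t or z), `p_value`, `tail`,
#'   `n`, and `descriptives` (per condition: mean/SD when normal,
#'   median/Q1/Q3 otherwise, plus a formatted string).
#' @export
paired_compare <- function(comfort, fatigue, alpha_normality = 0.05,
                           tail = c("two", "one"), gate = TRUE) {
  tail <- match.arg(tail)
  if (length(comfort) != length(fatigue)) {
    stop("paired_compare: conditions must be participant-aligned")
  }
  n <- length(comfort)
  if (n < 3) stop("paired_compare: needs n >= 3")
  if (anyNA(comfort) || anyNA(fatigue)) stop("paired_compare: NA values")
  d <- fatigue - comfort
  if (all(d == 0)) {
    res <- list(test_used = "degenerate", normality_p = NA_real_,
                statistic = 0, p_value = 1, tail = tail, n = n,
                descriptives = describe_pair(comfort, fatigue, TRUE))
    return(structure(res, class = "comparison_result"))
  }
  # Shapiro-Wilk needs non-constant data; constant nonzero differences are
  # maximally non-normal for the gate's purposes
  normality_p <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
  normal <- normality_p >= alpha_normality
  use_t <- !gate || normal

  if (use_t) {
    tt <- tryCatch(
      stats::t.test(fatigue, comfort, paired = TRUE,
                    alternative = switch(tail, two = "two.sided",
                                         one = "greater")),
      error = function(e) NULL)   # (near-)constant nonzero shift
    if (is.null(tt)) {
      statistic <- sign(mean(d)) * Inf
      p <- if (tail == "two" || mean(d) > 0) 0 else 1
    } else {
      statistic <- unname(tt$statistic)
      p <- tt$p.value
    }
    test_used <- "paired_t"
  } else {
    w <- wilcoxon_signed_rank(d, tail = tail)
    statistic <- w$z
    p <- w$p_value
    test_used <- "wilcoxon"
  }
  structure(list(test_used = test_used, normality_p = normality_p,
                 statistic = statistic, p_value = p, tail = tail, n = n,
                 descriptives = describe_pair(comfort, fatigue, use_t)),
            class = "comparison_result")
}

describe_pair <- function(comfort, fatigue, normal) {
  fmt <- function(x) {
    if (normal) {
      sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
    } else {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.2f (%.2f~%.2f)", q[2], q[1], q[3])
    }
  }
  list(format = if (normal) "mean_sd" else "median_q1q3",
       comfort_mean = mean(comfort), comfort_sd = stats::sd(comfort),
       fatigue_mean = mean(fatigue), fatigue_sd = stats::sd(fatigue),
       comfort_label = fmt(comfort), fatigue_label = fmt(fatigue))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "%s (n=%d, %s-tailed): statistic %.3f, p %.4g | comfort %s, fatigue %s\n",
    x$test_used, x$n, x$tail, x$statistic, x$p_value,
    x$descriptives$comfort_label, x$descriptives$fatigue_label))
  invisible(x)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Pratt handling of zero differences (zeros are ranked, then dropped from
#' the signed sum). Uses the exact signed-rank null distribution when there
#' are fewer than 10 differences and no ties or zeros; otherwise the normal
#' approximation with tie/zero variance correction.
#'
#' @param d vector of paired differences.
#' @param tail `"two"` or `"one"` (one-tailed: positive shift).
#' @return list with `statistic` (V, signed-rank sum of positive
#'   differences), `z`, `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(d, tail = c("two", "one")) {
  tail <- match.arg(tail)
  n_all <- length(d)
  r <- rank(abs(d))
  nonzero <- d != 0
  n <- sum(nonzero)
  if (n == 0) stop("wilcoxon_signed_rank: all differences zero")
  has_ties <- anyDuplicated(abs(d[nonzero])) > 0 || any(!nonzero)

  if (n_all < 10 && !has_ties) {
    v <- sum(r[d > 0])
    p_ge <- stats::psignrank(v - 1, n_all, lower.tail = FALSE)
    p_le <- stats::psignrank(v, n_all)
    p <- switch(tail, one = p_ge, two = min(1, 2 * min(p_ge, p_le)))
    mu <- n_all * (n_all + 1) / 4
    sg <- sqrt(n_all * (n_all + 1) * (2 * n_all + 1) / 24)
    return(list(statistic = v, z = (v - mu) / sg, p_value = p,
                method = "exact"))
  }

  # Pratt: rank all |d| including zeros, drop zeros from the sum; the null
  # mean/variance sums run over the nonzero ranks only
  rp <- r[nonzero]
  v <- sum(rp[d[nonzero] > 0])
  mu <- sum(rp) / 2
  sg2 <- sum(rp^2) / 4
  # tie correction is implicit: midranks enter rp directly
  z <- (v - mu) / sqrt(sg2)
  p <- switch(tail,
              one = stats::pnorm(z, lower.tail = FALSE),
              two = 2 * stats::pnorm(-abs(z)))
  list(statistic = v, z = z, p_value = min(1, p), method = "normal")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, order-invariant) plus rejection
#' flags at level `q`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` and logical `reject`.
#' @export
fdr_adjust <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("fdr_adjust: empty p-value vector")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("fdr_adjust: p-values outside [0, 1]")
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted < q)
}

star_code <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Edge-wise paired comparison with FDR control
#'
#' One paired test per electrode pair across participants, Benjamini-
#' Hochberg adjusted over all pairs. By default the edge test is a paired
#' t-test irrespective of normality (the convention for edge-wise maps);
#' set `gate = TRUE` for the Shapiro-Wilk-gated rule.
#'
#' @param plvs_comfort,plvs_fatigue participant-aligned lists of
#'   [plv_matrix()] objects.
#' @param q FDR level.
#' @param gate apply the normality gate per edge (default FALSE).
#' @param tail `"two"` or `"one"`.
#' @return object of class `edge_comparison_map`: `edges` data.frame
#'   (`chan_a, chan_b, region_a, region_b, comfort_mean, fatigue_mean,
#'   statistic, p, p_adj, significant`), and `summary` with the grand
#'   mean (SD) PLV per condition over all pairs and participants, the same
#'   restricted to significant pairs, and mean (SD) adjusted p over
#'   significant pairs.
#' @export
compare_edges <- function(plvs_comfort, plvs_fatigue, q = 0.05,
                          gate = FALSE, tail = "two") {
  n <- length(plvs_comfort)
  if (n != length(plvs_fatigue) || n < 3) {
    stop("compare_edges: need >= 3 aligned participants per condition")
  }
  ref <- plvs_comfort[[1]]
  labels <- ref$channel_labels
  for (m in c(plvs_comfort, plvs_fatigue)) {
    if (!identical(m$channel_labels, labels)) {
      stop("compare_edges: channel labels differ across participants")
    }
  }
  pc <- vapply(plvs_comfort, function(m) m$values[upper.tri(m$values)],
               numeric(sum(upper.tri(ref$values))))
  pf <- vapply(plvs_fatigue, function(m) m$values[upper.tri(m$values)],
               numeric(nrow(pc)))
  idx <- which(upper.tri(ref$values), arr.ind = TRUE)
  regions <- if (all(labels %in% default_montage()$label)) {
    channel_regions(labels)
  } else {
    rep(NA_character_, length(labels))
  }

  res <- lapply(seq_len(nrow(pc)), function(i) {
    paired_compare(pc[i, ], pf[i, ], tail = tail, gate = gate)
  })
  p <- vapply(res, function(r) r$p_value, numeric(1))
  adj <- fdr_adjust(p, q)
  edges <- data.frame(
    chan_a = labels[idx[, 1]], chan_b = labels[idx[, 2]],
    region_a = regions[idx[, 1]], region_b = regions[idx[, 2]],
    comfort_mean = rowMeans(pc), fatigue_mean = rowMeans(pf),
    test = vapply(res, function(r) r$test_used, character(1)),
    statistic = vapply(res, function(r) r$statistic, numeric(1)),
    p = p, p_adj = adj$adjusted, significant = adj$reject,
    stringsAsFactors = FALSE)
  sig <- edges$significant
  summary <- data.frame(
    comfort_mean = mean(pc), comfort_sd = stats::sd(as.vector(pc)),
    fatigue_mean = mean(pf), fatigue_sd = stats::sd(as.vector(pf)),
    comfort_mean_sig = if (any(sig)) mean(pc[sig, ]) else NA_real_,
    fatigue_mean_sig = if (any(sig)) mean(pf[sig, ]) else NA_real_,
    n_significant = sum(sig),
    p_adj_sig_mean = if (any(sig)) mean(edges$p_adj[sig]) else NA_real_,
    p_adj_sig_sd = if (sum(sig) > 1) stats::sd(edges$p_adj[sig]) else
      NA_real_)
  structure(list(edges = edges, summary = summary, q = q, n = n),
            class = "edge_comparison_map")
}

#' @export
print.edge_comparison_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "edge map (n=%d): %d/%d pairs significant at q=%.2g | PLV comfort %.3f (%.3f), fatigue %.3f (%.3f)\n",
    x$n, s$n_significant, nrow(x$edges), x$q,
    s$comfort_mean, s$comfort_sd, s$fatigue_mean, s$fatigue_sd))
  invisible(x)
}

# per-participant graph-level value of one metric
graph_level_value <- function(mt, metric) {
  switch(metric,
         bc = mean(mt$nodes$bc),
         ne = mean(mt$nodes$ne),
         cc = mt$cc_global,
         cpl = mt$cpl,
         stop("unknown metric: ", metric))
}

#' Graph-level metric comparison across a threshold grid
#'
#' For every band x metric x threshold: node metrics are averaged over nodes
#' per participant, then compared comfort vs fatigue with the gated paired
#' rule. Rows carry significance stars (0.05 / 0.01 / 0.001).
#'
#' @param metric_tables list of [metrics_for_graph()] results covering every
#'   participant, condition, band and grid threshold.
#' @param grid numeric thresholds (default [threshold_grid()]).
#' @param tail `"two"` (default) or `"one"`.
#' @param gate apply the Shapiro-Wilk gate (default TRUE).
#' @return data.frame with one row per band x metric x threshold: test used,
#'   statistic, p, stars, and per-condition descriptive labels.
#' @export
compare_global_across_thresholds <- function(metric_tables,
                                             grid = threshold_grid(),
                                             tail = "two", gate = TRUE) {
  meta <- data.frame(
    participant = vapply(metric_tables, `[[`, "", "participant"),
    condition = vapply(metric_tables, `[[`, "", "condition"),
    band = vapply(metric_tables, `[[`, "", "band"),
    threshold = vapply(metric_tables, `[[`, 0, "threshold"),
    stringsAsFactors = FALSE)
  bands <- unique(meta$band)
  participants <- sort(unique(meta$participant))
  rows <- list()
  for (band in bands) {
    for (metric in c("bc", "ne", "cc", "cpl")) {
      for (Ti in grid) {
        pick <- function(cond) {
          vapply(participants, function(p) {
            k <- which(meta$band == band & meta$condition == cond &
                         abs(meta$threshold - Ti) < 1e-9 &
                         meta$participant == p)
            if (length(k) != 1) {
              stop(sprintf(
                "missing metric table: %s/%s/%s at T=%.2f", p, cond, band,
                Ti))
            }
            graph_level_value(metric_tables[[k]], metric)
          }, numeric(1))
        }
        comfort <- pick("comfort"); fatigue <- pick("fatigue")
        if (anyNA(comfort) || anyNA(fatigue)) {
          stop("compare_global_across_thresholds: undefined metric value ",
               sprintf("(%s, %s, T=%.2f)", band, metric, Ti))
        }
        r <- paired_compare(comfort, fatigue, tail = tail, gate = gate)
        rows[[length(rows) + 1]] <- data.frame(
          band = band, metric = metric, threshold = Ti,
          comfort = r$descriptives$comfort_label,
          fatigue = r$descriptives$fatigue_label,
          comfort_mean = mean(comfort), fatigue_mean = mean(fatigue),
          test = r$test_used, statistic = r$statistic, p = r$p_value,
          stars = star_code(r$p_value), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Per-channel node-metric difference map
#'
#' Mean fatigue-minus-comfort difference of one node metric per channel at
#' one band and threshold, with a gated paired test per channel and a
#' region roll-up of significant channels.
#'
#' @param metric_tables as in [compare_global_across_thresholds()].
#' @param metric `"bc"`, `"ne"` or `"cc"` (local clustering).
#' @param band band name.
#' @param threshold grid threshold at which to compare.
#' @param tail,gate test options, see [paired_compare()].
#' @return object of class `node_difference_map`: `channels` data.frame
#'   (`node, region, comfort_mean, fatigue_mean, diff, test, statistic, p,
#'   stars`) and `regions` roll-up (`region, n_channels, n_significant`).
#' @export
node_difference_map <- function(metric_tables, metric = c("bc", "ne", "cc"),
                                band, threshold, tail = "two", gate = TRUE) {
  metric <- match.arg(metric)
  col <- if (metric == "cc") "cc_local" else metric
  sel <- Filter(function(mt) {
    mt$band == band && abs(mt$threshold - threshold) < 1e-9
  }, metric_tables)
  if (!length(sel)) stop("node_difference_map: no tables at that band/T")
  participants <- sort(unique(vapply(sel, `[[`, "", "participant")))
  nodes <- sel[[1]]$nodes$node
  regions <- sel[[1]]$nodes$region
  get <- function(cond) {
    sapply(participants, function(p) {
      k <- which(vapply(sel, function(mt) {
        mt$participant == p && mt$condition == cond
      }, logical(1)))
      if (length(k) != 1) stop("node_difference_map: missing ", p, " ", cond)
      sel[[k]]$nodes[[col]]
    })  # nodes x participants
  }
  comfort <- get("comfort"); fatigue <- get("fatigue")
  rows <- lapply(seq_along(nodes), function(i) {
    r <- paired_compare(comfort[i, ], fatigue[i, ], tail = tail,
                        gate = gate)
    data.frame(node = nodes[i], region = regions[i],
               comfort_mean = mean(comfort[i, ]),
               fatigue_mean = mean(fatigue[i, ]),
               diff = mean(fatigue[i, ] - comfort[i, ]),
               test = r$test_used, statistic = r$statistic, p = r$p_value,
               stars = star_code(r$p_value), stringsAsFactors = FALSE)
  })
  channels <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(n_channels = p) ~ region, channels, length)
  sigagg <- stats::aggregate(cbind(n_significant = p < 0.05) ~ region,
                             channels, sum)
  structure(list(channels = channels,
                 regions = merge(agg, sigagg, by = "region"),
                 metric = metric, band = band, threshold = threshold),
            class = "node_difference_map")
}

#' @export
print.node_difference_map <- function(x, ...) {
  cat(sprintf("node differences (%s, %s band, T=%.2f): %d/%d significant\n",
              x$metric, x$band, x$threshold,
              sum(x$channels$p < 0.05), nrow(x$channels)))
  print(x$regions, row.names = FALSE)
  invisible(x)
}
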