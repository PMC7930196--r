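#' Period binning and modern matching
#'
#' Ancient samples are grouped into dated periods, each paired with
#' phylogenetically equivalent modern samples; the modern-ancient pairwise
#' differences per period feed the rate estimator.
#'
#' @name periods
NULL

#' Bin ancient samples into dated periods
#'
#' Either explicit age boundaries (`edges`, half-open intervals
#' `[low, high)`) or equal-count quantile binning into `target_bins`
#' periods. Bins are ordered youngest to oldest and indexed from 1.
#'
#' @param ancients named list of `mito_profile`, all with `age_bp > 0`.
#' @param edges numeric vector of increasing age boundaries covering all
#'   samples, or `NULL`.
#' @param target_bins number of equal-count bins, used when `edges` is
#'   `NULL`.
#' @return list of `period_bin` objects (fields `index`, `ancients` (ids),
#'   `pairs`, `mean_age`, `age_sd`, `n_pairs`); pair fields are filled by
#'   [build_pairs()].
#' @export
assign_periods <- function(ancients, edges = NULL, target_bins = NULL) {
  ages <- vapply(ancients, `[[`, 0, "age_bp")
  if (any(ages <= 0)) {
    stop("all ancients must have age_bp > 0; offending: ",
         paste(names(ancients)[ages <= 0], collapse = ", "))
  }
  ids <- vapply(ancients, `[[`, "", "id")
  if (!is.null(edges)) {
    edges <- sort(as.numeric(edges))
    if (length(edges) < 2) {
      stop("need at least two edges")
    }
    idx <- findInterval(ages, edges, rightmost.closed = FALSE)
    outside <- idx == 0L | idx == length(edges)
    if (any(outside)) {
      stop("ages outside the half-open edge range [",
           edges[1], ", ", edges[length(edges)], "): ",
           paste(ids[outside], collapse = ", "))
    }
    groups <- split(ids, idx)
    empty <- setdiff(seq_len(length(edges) - 1L), as.integer(names(groups)))
    if (length(empty)) {
      stop("empty period bin(s) for interval(s): ",
           paste(sprintf("[%g, %g)", edges[empty], edges[empty + 1L]),
                 collapse = ", "))
    }
  } else {
    if (is.null(target_bins) || target_bins < 1) {
      stop("supply edges or a positive target_bins")
    }
    target_bins <- as.integer(target_bins)
    if (target_bins > length(ages)) {
      stop("target_bins exceeds the number of ancient samples")
    }
    ord <- order(ages)
    sizes <- diff(floor(seq(0, length(ages), length.out = target_bins + 1L)))
    idx <- integer(length(ages))
    idx[ord] <- rep(seq_len(target_bins), sizes)
    groups <- split(ids, idx)
  }
  bins <- lapply(seq_along(groups), function(k) {
    members <- groups[[k]]
    a <- ages[match(members, ids)]
    structure(list(index = k, ancients = members, pairs = NULL,
                   mean_age = mean(a), age_sd = stats::sd(a),
                   n_pairs = NA_integer_),
              class = "period_bin")
  })
  bins
}

#' @export
print.period_bin <- function(x, ...) {
  cat("<period_bin> #", x$index, ": ", length(x$ancients), " ancients, ",
      ifelse(is.na(x$n_pairs), "unpaired", paste0(x$n_pairs, " pairs")),
      ", mean age ", round(x$mean_age), " BP\n", sep = "")
  invisible(x)
}

#' Match phylogenetically equivalent modern samples
#'
#' Moderns whose haplogroup label shares the longest prefix with the
#' ancient's label; all tied moderns are returned. If no modern shares
#' even one leading character (not even the macrohaplogroup lineage), an
#' empty list is returned with a warning.
#'
#' @param ancient a `mito_profile`.
#' @param modern_pool non-empty list of modern `mito_profile`.
#' @return list of matched moderns (possibly empty).
#' @export
match_modern <- function(ancient, modern_pool) {
  if (!length(modern_pool)) {
    stop("modern pool is empty")
  }
  labs <- vapply(modern_pool, `[[`, "", "haplogroup")
  plen <- vapply(labs, common_prefix_length, 0L, b = ancient$haplogroup)
  best <- max(plen)
  if (best == 0L) {
    warning("no modern matches ancient ", ancient$id, " (",
            ancient$haplogroup, "), not even at the macrohaplogroup level")
    return(list())
  }
  modern_pool[plen == best]
}

common_prefix_length <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- min(length(a), length(b))
  if (n == 0L) {
    return(0L)
  }
  same <- a[seq_len(n)] == b[seq_len(n)]
  if (all(same)) n else which.min(same) - 1L
}

#' Pair ancients in a bin with matched moderns
#'
#' `mode = "best"` pairs each ancient with one best-matched modern (ties
#' broken by sample id, deterministically); `mode = "cross"` pairs each
#' ancient with every tied best match. Also fills the bin's weighted mean
#' age (see [weighted_mean_age()]) and `n_pairs`.
#'
#' @param bin a `period_bin` from [assign_periods()].
#' @param ancients,moderns named lists of `mito_profile`.
#' @param mode pairing mode.
#' @param weighting age weighting, passed to [weighted_mean_age()].
#' @return the bin with `pairs` (data.frame `ancient`, `modern`,
#'   `macrohaplogroup`), `n_pairs`, `mean_age`, `age_sd` filled.
#' @export
build_pairs <- function(bin, ancients, moderns, mode = c("best", "cross"),
                        weighting = c("pairs", "plain")) {
  mode <- match.arg(mode)
  rows <- list()
  for (aid in bin$ancients) {
    anc <- ancients[[aid]]
    matches <- match_modern(anc, moderns)
    if (!length(matches)) {
      next
    }
    mids <- sort(vapply(matches, `[[`, "", "id"))
    if (mode == "best") {
      mids <- mids[1]
    }
    rows[[aid]] <- data.frame(ancient = aid, modern = mids,
                              macrohaplogroup = anc$macrohaplogroup,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no pairs could be formed in period ", bin$index)
  }
  bin$pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  bin$n_pairs <- nrow(bin$pairs)
  wa <- weighted_mean_age(bin, ancients, weighting = weighting)
  bin$mean_age <- wa[["mean_age"]]
  bin$age_sd <- wa[["age_sd"]]
  bin
}

#' Weighted mean age of a period
#'
#' The period age is the average of its ancient sample ages, weighted by
#' the number of pairs each ancient participates in (`"pairs"`, the
#' default) or unweighted (`"plain"`). The spread is the same-weighted
#' (population) standard deviation.
#'
#' @param bin a paired `period_bin`.
#' @param ancients named list of ancient profiles.
#' @param weighting `"pairs"` or `"plain"`.
#' @return named numeric vector `c(mean_age, age_sd)`.
#' @export
weighted_mean_age <- function(bin, ancients, weighting = c("pairs", "plain")) {
  weighting <- match.arg(weighting)
  if (!length(bin$ancients)) {
    stop("empty period bin")
  }
  ages <- vapply(bin$ancients, function(i) ancients[[i]]$age_bp, 0)
  w <- if (weighting == "pairs" && !is.null(bin$pairs)) {
    counts <- table(bin$pairs$ancient)
    as.numeric(counts[bin$ancients])
  } else {
    rep(1, length(ages))
  }
  w[is.na(w)] <- 0
  if (sum(w) == 0) {
    stop("no pair weights available in period ", bin$index)
  }
  m <- sum(w * ages) / sum(w)
  s <- sqrt(sum(w * (ages - m)^2) / sum(w))
  c(mean_age = m, age_sd = s)
}

#' Per-pair differences of a period
#'
#' @param bin a paired `period_bin`.
#' @param profiles named list of all profiles (ancients and moderns).
#' @param policy an [exclusion_policy()].
#' @return the bin's `pairs` data.frame with a column `d` of pairwise
#'   mutational differences appended.
#' @export
pair_differences <- function(bin, profiles, policy = exclusion_policy()) {
  if (is.null(bin$pairs)) {
    stop("bin has no pairs; call build_pairs() first")
  }
  missing <- setdiff(unique(c(bin$pairs$ancient, bin$pairs$modern)),
                     names(profiles))
  if (length(missing)) {
    stop("pair ids not found among profiles: ",
         paste(missing, collapse = ", "))
  }
  d <- mapply(function(a, m) pair_difference(profiles[[a]], profiles[[m]],
                                             policy),
              bin$pairs$ancient, bin$pairs$modern)
  out <- bin$pairs
  out$d <- as.numeric(d)
  out
}

#' Summarize modern-ancient differences by macrohaplogroup
#'
#' Per-macrohaplogroup mean and sd of the pairwise difference over the
#' bin's pairs, plus the pair-count-weighted pooled mean,
#' `sum(n_g * mean_g) / sum(n_g)`.
#'
#' @inheritParams pair_differences
#' @return a `diff_summary`: list with `per_group` (data.frame
#'   `macrohaplogroup, mean_d, sd_d, n`), `pooled_mean`, `pooled_sd`
#'   (pair-weighted sd of the per-pair differences), `n_pairs`,
#'   `expected` (`NA` until [expected_differences()] fills it).
#' @export
summarize_differences <- function(bin, profiles,
                                  policy = exclusion_policy()) {
  pd <- pair_differences(bin, profiles, policy)
  groups <- split(pd$d, pd$macrohaplogroup)
  per_group <- data.frame(
    macrohaplogroup = names(groups),
    mean_d = vapply(groups, mean, 0),
    sd_d = vapply(groups, function(x) if (length(x) > 1) stats::sd(x) else 0,
                  0),
    n = vapply(groups, length, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_group = per_group,
                 pooled_mean = pooled_mean(per_group$mean_d, per_group$n),
                 pooled_sd = stats::sd(pd$d),
                 n_pairs = nrow(pd),
                 expected = NA_real_),
            class = "diff_summary")
}

#' Pair-count-weighted pooled mean
#'
#' @param means per-group mean differences.
#' @param ns per-group pair counts.
#' @return `sum(means * ns) / sum(ns)`.
#' @export
pooled_mean <- function(means, ns) {
  stopifnot(length(means) == length(ns), sum(ns) > 0)
  sum(means * ns) / sum(ns)
}

#' Expected differences under a linear clock anchored on one period
#'
#' Extrapolates the anchor period's per-year difference rate linearly:
#' `expected = (anchor_mean / anchor_age) * age`.
#'
#' @param bin a `period_bin` (or anything with `mean_age`).
#' @param anchor the anchor period; needs `pooled_mean` and `mean_age`.
#' @return expected mean difference count for `bin`.
#' @seealso [expected_from_anchor()] for the vectorized raw form.
#' @export
expected_differences <- function(bin, anchor) {
  expected_from_anchor(anchor$pooled_mean, anchor$mean_age, bin$mean_age)
}

#' @rdname expected_differences
#' @param anchor_mean,anchor_age the anchor's observed mean difference
#'   count and mean age (years BP).
#' @param ages ages (years BP) to extrapolate to.
#' @export
expected_from_anchor <- function(anchor_mean, anchor_age, ages) {
  if (is.na(anchor_age) || anchor_age == 0) {
    stop("anchor mean age must be non-zero")
  }
  (anchor_mean / anchor_age) * ages
}

#' Rate homogeneity across macrohaplogroups within a period
#'
#' Welch's unpaired t-test between the two groups whose mean pairwise
#' differences diverge most. A high p-value supports pooling the groups.
#'
#' @param x a named list of per-pair difference vectors (one per
#'   macrohaplogroup), or a paired `period_bin`.
#' @param ... for the `period_bin` method: `profiles` and optionally
#'   `policy`, as in [pair_differences()].
#' @return list with `statistic`, `p_value`, and `groups` (the two labels
#'   compared).
#' @export
homogeneity_test <- function(x, ...) {
  UseMethod("homogeneity_test")
}

#' @export
homogeneity_test.period_bin <- function(x, profiles,
                                        policy = exclusion_policy(), ...) {
  pd <- pair_differences(x, profiles, policy)
  homogeneity_test(split(pd$d, pd$macrohaplogroup))
}

#' @export
homogeneity_test.list <- function(x, ...) {
  x <- x[vapply(x, length, 0L) >= 2L]
  if (length(x) < 2L) {
    stop("need at least two macrohaplogroup groups with n >= 2")
  }
  means <- vapply(x, mean, 0)
  pick <- order(means)[c(1L, length(means))]
  a <- x[[pick[2]]]
  b <- x[[pick[1]]]
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # Welch's statistic is undefined for two constant samples: identical
    # constants are indistinguishable, different constants are disjoint
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                groups = names(x)[pick]))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       groups = names(x)[pick])
}

#' Build the full observed/expected period table
#'
#' Runs [summarize_differences()] on every bin, fills the expected column
#' anchored on `anchor_period`, and returns one row per period in the
#' layout of the published comparison table.
#'
#' @param bins list of paired `period_bin`.
#' @param profiles named list of all profiles.
#' @param policy an [exclusion_policy()].
#' @param anchor_period index of the anchor bin (default 1, the
#'   youngest).
#' @return data.frame with columns `period, mean_age, age_sd, n_pairs,
#'   observed, observed_sd, expected` plus one `mean (sd, n)` text column
#'   per macrohaplogroup.
#' @export
period_table <- function(bins, profiles, policy = exclusion_policy(),
                         anchor_period = 1L) {
  summaries <- lapply(bins, summarize_differences, profiles = profiles,
                      policy = policy)
  anchor <- list(pooled_mean = summaries[[anchor_period]]$pooled_mean,
                 mean_age = bins[[anchor_period]]$mean_age)
  macro_cols <- sort(unique(unlist(lapply(summaries, function(s) {
    s$per_group$macrohaplogroup
  }))))
  rows <- lapply(seq_along(bins), function(k) {
    b <- bins[[k]]
    s <- summaries[[k]]
    row <- data.frame(period = b$index, mean_age = b$mean_age,
                      age_sd = b$age_sd, n_pairs = s$n_pairs,
                      observed = s$pooled_mean, observed_sd = s$pooled_sd,
                      expected = expected_differences(b, anchor),
                      stringsAsFactors = FALSE)
    for (m in macro_cols) {
      g <- s$per_group[s$per_group$macrohaplogroup == m, ]
      row[[paste0("hg_", m)]] <- if (nrow(g)) {
        sprintf("%.2f (%.2f, %d)", g$mean_d, g$sd_d, g$n)
      } else {
        "NA"
      }
    }
    row
  })
  do.call(rbind, rows)
}
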