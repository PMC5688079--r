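#' Significance stars
#'
#' `**` for p < 0.001, `*` for p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", ""))
}

#' Per-channel permutation test of a condition contrast
#'
#' For each channel the summary value is its mean connectivity to all
#' other channels within each 5-s window (see
#' [channel_strength_windows()]). The test statistic is the difference of
#' condition means; the null distribution is built by shuffling condition
#' labels across windows (two-sided, `p = (1 + #{|null| >= |obs|}) /
#' (1 + n_perm)`), assuming windows are exchangeable under the null. With
#' a layout, channels are additionally aggregated by implant region code
#' and the same test applied to each region's mean series.
#'
#' @param ec,eo windows x channels matrices of per-window channel
#'   connectivity values (same channels; >= 5 windows per condition).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param layout optional `electrode_layout` supplying region codes.
#' @return A data.frame (class `channel_test_result`): channel, region,
#'   statistic (EC - EO mean difference), p, stars. When a layout is
#'   given, the per-region table is attached as attribute `regions`.
#' @export
channel_condition_test <- function(ec, eo, n_perm = 10000, seed = 1,
                                   layout = NULL) {
  ec <- as.matrix(ec); eo <- as.matrix(eo)
  if (ncol(ec) != ncol(eo)) stop("conditions must share channels")
  if (nrow(ec) < 5L || nrow(eo) < 5L)
    stop("need at least 5 windows per condition")
  chan <- colnames(ec)
  if (is.null(chan)) chan <- sprintf("CH%02d", seq_len(ncol(ec)))
  res <- perm_mean_diff(ec, eo, n_perm, seed)
  region <- rep(NA_character_, length(chan))
  regions_tab <- NULL
  if (!is.null(layout)) {
    idx <- match(chan, layout$label)
    if (anyNA(idx)) stop("channels missing from layout: ",
                         paste(chan[is.na(idx)], collapse = ", "))
    region <- layout$region[idx]
    reg_ec <- group_means(ec, region)
    reg_eo <- group_means(eo, region)
    rres <- perm_mean_diff(reg_ec, reg_eo, n_perm, seed)
    regions_tab <- data.frame(region = colnames(reg_ec),
                              statistic = rres$stat, p = rres$p,
                              stars = significance_stars(rres$p),
                              stringsAsFactors = FALSE)
  }
  out <- data.frame(channel = chan, region = region, statistic = res$stat,
                    p = res$p, stars = significance_stars(res$p),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "regions") <- regions_tab
  class(out) <- c("channel_test_result", "data.frame")
  out
}

group_means <- function(m, groups) {
  gs <- sort(unique(groups))
  out <- vapply(gs, function(g)
    rowMeans(m[, groups == g, drop = FALSE]), numeric(nrow(m)))
  colnames(out) <- gs
  out
}

# two-sided permutation test of the difference in column means between
# two window blocks; all columns share the permutations
perm_mean_diff <- function(ec, eo, n_perm, seed) {
  n1 <- nrow(ec); n2 <- nrow(eo)
  pooled <- rbind(ec, eo)
  obs <- colMeans(ec) - colMeans(eo)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  W <- matrix(-1 / n2, n1 + n2, n_perm)
  for (b in seq_len(n_perm)) {
    sel <- sample.int(n1 + n2, n1)
    W[sel, b] <- 1 / n1
  }
  null <- crossprod(pooled, W)              # channels x n_perm
  exceed <- rowSums(abs(null) >= abs(obs) - 1e-15)
  list(stat = obs, p = (1 + exceed) / (1 + n_perm))
}

#' Permutation test of condition differences in filtration curves
#'
#' Contrasts the EC and EO metric-versus-threshold curves. The observed
#' statistic per metric is the area between the two step-function curves
#' over a fixed threshold grid (sum of |EC - EO| times grid spacing).
#' Condition mean matrices are rebuilt from window-level connectivity
#' matrices; the null shuffles condition labels over windows and
#' recomputes matrices, filtration curves and areas. The grid is a
#' quantile grid of the pooled (label-invariant) mean matrix values, so
#' the statistic is computed identically for observed and permuted data.
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param wins_ec,wins_eo lists of per-window connectivity matrices (see
#'   [connectivity_windows()]).
#' @param D distance matrix (mm) matching the matrices.
#' @param on filtrate the `"wiring"` cost matrix `D * F` (default) or the
#'   `"connectivity"` matrix `F`.
#' @param rule filtration rule, `"sublevel"` (default) or `"superlevel"`.
#' @param grid_size number of grid thresholds (quantiles of the pooled
#'   matrix values; default 100).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return A data.frame (class `curve_test_result`): metric, statistic
#'   (area), p, n_perm, seed.
#' @export
curve_condition_test <- function(wins_ec, wins_eo, D,
                                 on = c("wiring", "connectivity"),
                                 rule = c("sublevel", "superlevel"),
                                 grid_size = 100, n_perm = 999, seed = 1) {
  on <- match.arg(on)
  rule <- match.arg(rule)
  n <- nrow(wins_ec[[1L]])
  D <- unclass(D)
  n1 <- length(wins_ec); n2 <- length(wins_eo)
  flat <- vapply(c(wins_ec, wins_eo), as.numeric, numeric(n * n))
  up <- as.vector(upper.tri(matrix(0, n, n)))

  to_filt_mats <- function(is_ec) {
    Fm <- matrix(rowMeans(flat[, is_ec, drop = FALSE]), n, n)
    cost <- D * Fm
    m <- if (on == "wiring") cost else Fm
    list(m = m, cost = cost)
  }
  pooled_mean <- matrix(rowMeans(flat), n, n)
  pooled_vals <- (if (on == "wiring") D * pooled_mean else pooled_mean)[
    as.logical(up)]
  grid <- unique(quantile(pooled_vals, probs = seq(0, 1, length.out = grid_size),
                          names = FALSE, type = 7))
  dt <- diff(grid)
  sub <- rule == "sublevel"

  areas <- function(is_ec) {
    a <- to_filt_mats(is_ec)
    b <- to_filt_mats(!is_ec)
    ca <- filtration_curves_cpp(a$m, a$cost, grid, sub)
    cb <- filtration_curves_cpp(b$m, b$cost, grid, sub)
    d <- abs(ca - cb)
    # step functions: rectangle rule with the left value on each interval
    colSums(d[-nrow(d), , drop = FALSE] * dt)
  }

  is_ec_obs <- c(rep(TRUE, n1), rep(FALSE, n2))
  obs <- areas(is_ec_obs)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  exceed <- numeric(4)
  for (b in seq_len(n_perm)) {
    lab <- rep(FALSE, n1 + n2)
    lab[sample.int(n1 + n2, n1)] <- TRUE
    exceed <- exceed + (areas(lab) >= obs - 1e-15)
  }
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(metric = c("clustering", "density", "path_length",
                               "wiring_cost"),
                    statistic = as.numeric(obs), p = p,
                    stars = significance_stars(p),
                    n_perm = n_perm, seed = seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("curve_test_result", "data.frame")
  out
}

#' Cohort significance counts
#'
#' Tallies, per metric (or region), how many subjects reached p < alpha,
#' formatted as "k/n".
#'
#' @param results data.frame with columns `subject`, `p`, and a grouping
#'   column (`metric` or `region`).
#' @param by name of the grouping column (default `"metric"`).
#' @param alpha significance level (default 0.05).
#' @return data.frame with the group, `k`, `n`, and `label` ("k/n").
#' @export
cohort_summary <- function(results, by = "metric", alpha = 0.05) {
  if (nrow(results) == 0L) stop("need at least one subject")
  if (!all(c("subject", "p", by) %in% names(results)))
    stop("results must have columns subject, p, ", by)
  groups <- sort(unique(results[[by]]))
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- results[results[[by]] == g, ]
    sig <- tapply(r$p < alpha, r$subject, any)
    data.frame(group = g, k = sum(sig), n = length(sig),
               label = sprintf("%d/%d", sum(sig), length(sig)),
               stringsAsFactors = FALSE)
  }))
  names(out)[1L] <- by
  out
}
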