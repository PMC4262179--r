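#' Percentage range extension of hybrids beyond the parental range
#'
#' Transgressive segregation is measured per shape axis as the extent to
#' which hybrid values fall outside the pooled parental range, summing the
#' exceedance beyond the parental maximum and below the parental minimum,
#' expressed as a percentage of the parental range:
#' \deqn{100 \times \frac{\max(0, \max H - \max P) + \max(0, \min P - \min H)}
#'   {\max P - \min P}}
#' Zero when all hybrid values lie within the parental range.
#'
#' @param hybrid_values numeric vector of hybrid scores (>= 1 value).
#' @param parent_values numeric vector of pooled parental scores spanning a
#'   nonzero range (>= 2 values).
#' @return non-negative percentage.
#' @export
range_extension <- function(hybrid_values, parent_values) {
  h <- as.numeric(hybrid_values)
  p <- as.numeric(parent_values)
  if (length(h) < 1L) stop("need at least one hybrid value")
  if (length(p) < 2L) stop("need at least two parental values")
  if (anyNA(h) || anyNA(p)) stop("missing values not allowed")
  rng <- max(p) - min(p)
  if (rng <= 0) stop("parental range is zero: extension undefined")
  100 * (max(0, max(h) - max(p)) + max(0, min(p) - min(h))) / rng
}

.cell_seed <- function(seed, axis_index, group_index) {
  ## deterministic substream per table cell, kept well below 2^31
  (abs(as.integer(seed)) %% 100000L) * 10000L +
    (axis_index %% 100L) * 100L + group_index %% 100L
}

#' Bootstrap test of transgressive segregation on one axis
#'
#' Draws `B` bootstrap samples of `n` individuals (with replacement) from
#' the hybrid group and computes the percentage range extension of each
#' sample beyond the fixed pooled parental sample, equalising sample sizes
#' between hybrid and parental lines. Reported are the median extension
#' across replicates, the support (proportion of replicates with strictly
#' positive extension) and `p_value = 1 - support`. Setting
#' `resample = "parents"` instead holds the hybrid sample fixed and
#' bootstraps the parental sample (an alternative reading of the
#' equal-sample-size design, not the default).
#'
#' @param hybrid_values,parent_values numeric score vectors.
#' @param B number of bootstrap replicates (default 500).
#' @param n bootstrap sample size (default 50, the pooled parental sample
#'   size of the common-garden design).
#' @param seed optional integer seed for reproducibility.
#' @param resample which sample is bootstrapped: `"hybrids"` (default) or
#'   `"parents"`.
#' @return object of class `transgression`: `median_pct`, `support`,
#'   `p_value`, `n_boot`, `n_resample`, `seed`, `extensions` (the B
#'   per-replicate percentages).
#' @export
bootstrap_transgression <- function(hybrid_values, parent_values, B = 500L,
                                    n = 50L, seed = NULL,
                                    resample = c("hybrids", "parents")) {
  resample <- match.arg(resample)
  h <- as.numeric(hybrid_values)
  p <- as.numeric(parent_values)
  if (B < 1L || n < 1L) stop("B and n must be positive")
  range_extension(h, p)  # validates inputs, errors on zero parental range
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (resample == "hybrids") {
    draw <- matrix(h[sample.int(length(h), B * n, replace = TRUE)], n, B)
    hmax <- draw[cbind(max.col(t(draw)), seq_len(B))]
    hmin <- draw[cbind(max.col(-t(draw)), seq_len(B))]
    ext <- 100 * (pmax(0, hmax - max(p)) + pmax(0, min(p) - hmin)) /
      (max(p) - min(p))
  } else {
    draw <- matrix(p[sample.int(length(p), B * n, replace = TRUE)], n, B)
    pmax_ <- draw[cbind(max.col(t(draw)), seq_len(B))]
    pmin_ <- draw[cbind(max.col(-t(draw)), seq_len(B))]
    rng <- pmax_ - pmin_
    ok <- rng > 0
    ext <- rep(NA_real_, B)
    ext[ok] <- 100 * (pmax(0, max(h) - pmax_[ok]) +
                        pmax(0, pmin_[ok] - min(h))) / rng[ok]
    ext <- ext[!is.na(ext)]
  }
  support <- mean(ext > 0)
  structure(
    list(median_pct = stats::median(ext), support = support,
         p_value = 1 - support, n_boot = as.integer(B),
         n_resample = as.integer(n),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         extensions = ext),
    class = "transgression")
}

#' @export
print.transgression <- function(x, ...) {
  cat(sprintf(
    "Bootstrap transgression: median %.1f%% (support %.3f, p = %.3f; B = %d, n = %d)\n",
    x$median_pct, x$support, x$p_value, x$n_boot, x$n_resample))
  invisible(x)
}

.stars <- function(support) {
  ifelse(support >= 0.999, "***",
         ifelse(support >= 0.99, "**",
                ifelse(support >= 0.95, "*", "")))
}

#' Per-axis, per-hybrid-group transgression table
#'
#' Runs [bootstrap_transgression()] for every combination of shape axis and
#' hybrid cross, pooling the parental groups into a single fixed parental
#' sample. A single integer `seed` controls the whole table; each cell uses
#' a substream derived deterministically from (seed, axis, group) so the
#' table is reproducible cell-by-cell. Significance stars follow support
#' thresholds 0.95 (*), 0.99 (**) and 0.999 (***), i.e. p < 0.05 / 0.01 /
#' 0.001 under `p = 1 - support`.
#'
#' @param scores a `size_corrected` object, a `shape_space`, or a numeric
#'   matrix of per-specimen axis scores (rows named by specimen).
#' @param groups character vector of group labels, one per specimen (or a
#'   named vector matched to rownames).
#' @param hybrid_groups labels of the hybrid crosses to test.
#' @param parent_groups labels of the parental lines to pool.
#' @param axes axis indices or names to test (default first six).
#' @param B,n,seed bootstrap parameters as in [bootstrap_transgression()].
#' @param resample see [bootstrap_transgression()].
#' @return data.frame of class `transgression_table` with one row per
#'   (axis, hybrid group): `axis`, `hybrid_group`, `median_pct`, `support`,
#'   `p_value`, `stars`, `n_boot`, `n_resample`.
#' @export
transgression_table <- function(scores, groups, hybrid_groups,
                                parent_groups, axes = 1:6, B = 500L,
                                n = 50L, seed = 1L,
                                resample = c("hybrids", "parents")) {
  resample <- match.arg(resample)
  mat <- if (inherits(scores, "size_corrected")) scores$residuals
         else if (inherits(scores, "shape_space")) scores$scores
         else as.matrix(scores)
  groups <- as.character(groups)
  if (length(groups) != nrow(mat))
    stop("need one group label per specimen")
  missing_g <- setdiff(c(hybrid_groups, parent_groups), groups)
  if (length(missing_g))
    stop("group labels absent from the data: ",
         paste(missing_g, collapse = ", "))
  if (is.character(axes)) axes <- match(axes, colnames(mat))
  if (anyNA(axes) || any(axes > ncol(mat)))
    stop("requested axes not present in the score matrix")
  axis_names <- if (!is.null(colnames(mat))) colnames(mat)[axes]
                else paste0("RW", axes)
  parent_idx <- groups %in% parent_groups
  rows <- vector("list", length(axes) * length(hybrid_groups))
  r <- 0L
  for (ai in seq_along(axes)) {
    p <- mat[parent_idx, axes[ai]]
    for (gi in seq_along(hybrid_groups)) {
      h <- mat[groups == hybrid_groups[gi], axes[ai]]
      bt <- bootstrap_transgression(h, p, B = B, n = n,
                                    seed = .cell_seed(seed, ai, gi),
                                    resample = resample)
      r <- r + 1L
      rows[[r]] <- data.frame(
        axis = axis_names[ai], hybrid_group = hybrid_groups[gi],
        median_pct = bt$median_pct, support = bt$support,
        p_value = bt$p_value, stars = .stars(bt$support),
        n_boot = bt$n_boot, n_resample = bt$n_resample)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("transgression_table", "data.frame")
  out
}

#' Format a transgression table in wide (axes x crosses) layout
#'
#' Mirrors the customary presentation: rows are relative warp axes, columns
#' are hybrid crosses, cells are median percentage extensions with
#' significance stars.
#'
#' @param tab a `transgression_table`.
#' @param digits digits for the percentages.
#' @return character matrix.
#' @export
format_transgression_table <- function(tab, digits = 1L) {
  stopifnot(inherits(tab, "transgression_table"))
  axes <- unique(tab$axis)
  grps <- unique(tab$hybrid_group)
  out <- matrix("", length(axes), length(grps),
                dimnames = list(axes, grps))
  for (i in seq_len(nrow(tab)))
    out[tab$axis[i], tab$hybrid_group[i]] <-
      paste0(formatC(tab$median_pct[i], digits = digits, format = "f"),
             tab$stars[i])
  out
}
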