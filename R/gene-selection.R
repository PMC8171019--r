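# Gene selection from the fitted weight matrix, in two stages:
#   S1 "weight-based" — iteratively histogram the per-gene maximum weight
#       into a Sturges number of equal-width bins and drop the lowest
#       non-empty bin until fewer than `target` genes remain;
#   S2 "weight-deviation" — regress log(CV^2) of each gene's weights across
#       clusters on log10(mean weight), standardise the residuals, and keep
#       genes whose upper-tail normal p-value is at most `p_threshold`
#       (marker-like genes whose weights vary more across clusters than the
#       mean-CV trend predicts).

#' Sturges-style group count
#'
#' `N = round(3.322 * log10(n) - 1)`, rounded half away from zero and floored
#' at 2.
#'
#' @param n_features number of features being grouped, at least 2.
#' @return Integer number of groups.
#' @export
sturges_group_count <- function(n_features) {
  if (n_features < 2) stop_selection("Need at least 2 features to group.")
  max(2L, as.integer(round_half_away(3.322 * log10(n_features) - 1)))
}

#' Weight-based screening (stage S1)
#'
#' Scores each gene by its maximum weight over clusters and repeatedly
#' removes the lowest-scoring non-empty equal-width bin (bin count from
#' [sturges_group_count()] on the current gene count) until fewer than
#' `target` genes remain. The loop never removes the final surviving bin,
#' and an all-equal score vector stops immediately with a warning.
#'
#' @param W K x n weight matrix with gene ids as column names.
#' @param gene_ids gene identifiers (default: column names of `W`).
#' @param target stop once the surviving gene count is strictly below this.
#' @return List with `survivors` (character), `scores` (named max weights)
#'   and `history` (tibble: `iteration`, `n_before`, `n_bins`, `bin_lower`,
#'   `bin_upper`, `n_removed`).
#' @export
weight_based_screen <- function(W, gene_ids = colnames(W), target = 10000) {
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(W)))
  scores <- setNames(apply(W, 2, max), gene_ids)
  surv <- gene_ids
  history <- list()
  it <- 0L
  while (length(surv) >= target) {
    s <- scores[surv]
    if (max(s) == min(s)) {
      warn("All maximum weights are equal; weight-based screen keeps every gene.")
      break
    }
    it <- it + 1L
    nb <- sturges_group_count(length(surv))
    breaks <- seq(min(s), max(s), length.out = nb + 1L)
    bin <- findInterval(s, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    lowest <- min(bin)
    drop <- surv[bin == lowest]
    if (length(drop) == length(surv)) {
      warn("Weight-based screen would remove every remaining gene; stopping.")
      break
    }
    history[[it]] <- tibble::tibble(
      iteration = it, n_before = length(surv), n_bins = nb,
      bin_lower = breaks[lowest], bin_upper = breaks[lowest + 1L],
      n_removed = length(drop)
    )
    surv <- setdiff(surv, drop)
  }
  list(
    survivors = surv,
    scores = scores,
    history = if (length(history)) dplyr::bind_rows(history) else
      tibble::tibble(iteration = integer(), n_before = integer(), n_bins = integer(),
                     bin_lower = double(), bin_upper = double(), n_removed = integer())
  )
}

#' Fit the CV-versus-mean trend of weight rows (stage S2, part 1)
#'
#' For each gene computes the mean and the coefficient of variation
#' (population standard deviation over mean) of its weights across the K
#' clusters, then fits `log(CV^2) = a * log10(mean) + b` by ordinary least
#' squares over genes with positive mean and positive CV. Genes excluded
#' from the fit carry `NA` residuals and are assigned p = 1 downstream.
#'
#' @inheritParams weight_based_screen
#' @return List with `slope`, `intercept`, and a tibble `genes` holding
#'   `gene_id`, `mean_weight`, `cv`, `residual` (NA when excluded).
#' @export
fit_cv_mean_trend <- function(W, gene_ids = colnames(W)) {
  if (nrow(W) < 2) stop_selection("CV across clusters needs K >= 2 weight rows.")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(W)))
  mw <- colMeans(W)
  sdw <- col_sd_pop(W)
  cv <- ifelse(mw > 0, sdw / mw, NA_real_)
  eligible <- is.finite(cv) & cv > 0 & mw > 0
  if (sum(eligible) < 3) {
    stop_selection("Fewer than 3 genes with positive mean and CV; cannot fit the trend line.")
  }
  y <- log(cv[eligible]^2)
  u <- log10(mw[eligible])
  fit <- lm(y ~ u)
  res <- rep(NA_real_, length(mw))
  res[eligible] <- unname(stats::residuals(fit))
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    genes = tibble::tibble(
      gene_id = gene_ids,
      mean_weight = unname(mw),
      cv = unname(cv),
      residual = res
    )
  )
}

#' Deviation-based screening (stage S2, part 2)
#'
#' Standardises the trend residuals to z-scores, converts them to one-sided
#' upper-tail normal p-values (a large positive residual means the gene's
#' weights vary across clusters more than its mean predicts) and keeps genes
#' with `p <= p_threshold`. Genes with `NA` residuals get p = 1.
#'
#' @param residuals named numeric vector (or the `genes` tibble from
#'   [fit_cv_mean_trend()]); `NA` entries mark genes excluded from the fit.
#' @param p_threshold selection cutoff on the p-value, default 0.05.
#' @return Tibble with `gene_id`, `residual`, `z`, `p`, `selected`.
#' @export
deviation_based_screen <- function(residuals, p_threshold = 0.05) {
  if (is.data.frame(residuals)) {
    residuals <- setNames(residuals$residual, residuals$gene_id)
  }
  if (is.null(names(residuals))) {
    names(residuals) <- paste0("gene_", seq_along(residuals))
  }
  d <- residuals[!is.na(residuals)]
  z <- rep(NA_real_, length(residuals))
  names(z) <- names(residuals)
  if (length(d) > 0) {
    s <- sd(d)
    if (!is.finite(s) || s == 0) {
      warn("Residuals have zero spread; no gene passes the deviation screen.")
      z[names(d)] <- 0
    } else {
      z[names(d)] <- (d - mean(d)) / s
    }
  }
  p <- ifelse(is.na(z), 1, pnorm(z, lower.tail = FALSE))
  tibble::tibble(
    gene_id = names(residuals),
    residual = unname(residuals),
    z = unname(z),
    p = unname(p),
    selected = unname(p <= p_threshold & !is.na(residuals) & !all(z[!is.na(z)] == 0))
  )
}

#' Select genes by cluster-aware feature weighting
#'
#' Composes the full selection path: fit the weighted k-medians model once on
#' the supplied (preprocessed) matrix, screen the weight matrix by maximum
#' weight (S1), then screen the S1 survivors by CV-trend deviation (S2). The
#' weight matrix is fitted once; screening only subsets its columns.
#'
#' @inheritParams weighted_kmedians
#' @param s1_target gene-count target of the weight-based screen.
#' @param p_threshold p-value cutoff of the deviation screen.
#' @return List with `matrix` (the input restricted to the selected genes),
#'   `report` (a `screening_report`) and `fit` (the `cafw_fit`).
#' @examples
#' ds <- simulate_expression(K = 3, cells_per_cluster = 30, n_informative = 10,
#'                           n_noise = 90, seed = 7)
#' sel <- select_genes(ds$matrix, K = 3, seed = 7)
#' glance(sel$report)
#' @export
select_genes <- function(x, K, c_delta = 1, max_iter = 100, tol = 1e-6,
                         seed = 1L, s1_target = 10000, p_threshold = 0.05) {
  x <- as_expr_matrix(x)
  fit <- weighted_kmedians(x, K, c_delta = c_delta, max_iter = max_iter,
                           tol = tol, seed = seed)
  s1 <- weight_based_screen(fit$W, gene_ids = gene_ids(x), target = s1_target)
  W1 <- fit$W[, match(s1$survivors, gene_ids(x)), drop = FALSE]
  trend <- fit_cv_mean_trend(W1, gene_ids = s1$survivors)
  s2 <- deviation_based_screen(trend$genes, p_threshold = p_threshold)
  survivors_s2 <- s2$gene_id[s2$selected]

  gene_table <- tibble::tibble(
    gene_id = gene_ids(x),
    max_weight = unname(s1$scores[gene_ids(x)]),
    survived_s1 = gene_ids(x) %in% s1$survivors
  ) |>
    dplyr::left_join(trend$genes, by = "gene_id") |>
    dplyr::left_join(s2[, c("gene_id", "z", "p", "selected")], by = "gene_id") |>
    dplyr::mutate(
      p = dplyr::if_else(.data$survived_s1, .data$p, NA_real_),
      selected = dplyr::coalesce(.data$selected, FALSE)
    )

  report <- structure(
    list(
      gene_table = gene_table,
      group_history = s1$history,
      trend = list(slope = trend$slope, intercept = trend$intercept),
      survivors_s1 = s1$survivors,
      survivors_s2 = survivors_s2,
      s1_target = s1_target,
      p_threshold = p_threshold,
      n_input = n_genes(x)
    ),
    class = "screening_report"
  )

  reduced <- if (length(survivors_s2) >= 2) subset_genes(x, survivors_s2) else NULL
  if (is.null(reduced)) {
    warn(sprintf("Only %d gene(s) pass the deviation screen; no reduced matrix returned.",
                 length(survivors_s2)))
  }
  list(matrix = reduced, report = report, fit = fit)
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> #Genes %d | #Genes-S1 %d (%.1f%%) | #Genes-S2 %d (%.1f%%)\n",
              x$n_input,
              length(x$survivors_s1), 100 * length(x$survivors_s1) / x$n_input,
              length(x$survivors_s2), 100 * length(x$survivors_s2) / x$n_input))
  invisible(x)
}

#' @export
tidy.screening_report <- function(x, ...) x$gene_table

#' @export
glance.screening_report <- function(x, ...) {
  tibble::tibble(
    n_genes = x$n_input,
    n_genes_s1 = length(x$survivors_s1),
    n_genes_s2 = length(x$survivors_s2),
    pct_s1 = 100 * length(x$survivors_s1) / x$n_input,
    pct_s2 = 100 * length(x$survivors_s2) / x$n_input,
    trend_slope = x$trend$slope,
    trend_intercept = x$trend$intercept,
    p_threshold = x$p_threshold
  )
}

#' Serialise a screening report to JSON
#'
#' @param report a `screening_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path) {
  out <- list(
    n_input = report$n_input,
    survivors_s1 = report$survivors_s1,
    survivors_s2 = report$survivors_s2,
    s1_target = report$s1_target,
    p_threshold = report$p_threshold,
    trend = report$trend,
    group_history = report$group_history,
    genes = report$gene_table
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
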