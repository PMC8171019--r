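# Two-stage gene screening on the fitted weight matrix.

test_that("Sturges-style group counts match direct formula evaluation", {
  expect_equal(sturges_group_count(10000), 12)  # 3.322*4 - 1 = 12.288
  expect_equal(sturges_group_count(25737), 14)  # 13.65 rounds up
  expect_equal(sturges_group_count(2), 2)       # floored at 2
  expect_error(sturges_group_count(1), class = "cafw_selection_error")
})

test_that("weight-based screen is a no-op below target and guards degeneracy", {
  W <- rand_simplex_rows(3, 500)
  colnames(W) <- paste0("g", 1:500)
  res <- weight_based_screen(W, target = 10000)
  expect_identical(res$survivors, paste0("g", 1:500))
  expect_equal(nrow(res$history), 0)

  flat <- matrix(1 / 50, 4, 50, dimnames = list(NULL, paste0("g", 1:50)))
  expect_warning(res2 <- weight_based_screen(flat, target = 10),
                 "keeps every gene")
  expect_length(res2$survivors, 50)
})

test_that("bin-removal loop reproduces a scripted oracle on 20000 uniform scores", {
  set.seed(33)
  n <- 20000
  scores <- runif(n)
  # one-row weight matrix makes max-weight equal the score itself
  W <- matrix(scores, 1, n, dimnames = list(NULL, paste0("g", 1:n)))
  W <- rbind(W, W) # K >= 2 genes, same max
  res <- weight_based_screen(W, target = 10000)
  expect_equal(length(res$survivors), screen_count_oracle(scores, 10000))
  expect_lt(length(res$survivors), 10000)
  # first iteration used 13 bins (Sturges on 20000) and removed ~1/13 of range
  expect_equal(res$history$n_bins[1], sturges_group_count(20000))
})

test_that("no removed gene outscores a survivor at its removal iteration", {
  set.seed(14)
  W <- rand_simplex_rows(4, 3000)
  colnames(W) <- paste0("g", 1:3000)
  res <- weight_based_screen(W, target = 1000)
  expect_gt(nrow(res$history), 0)
  scores <- res$scores
  surviving <- colnames(W)
  for (i in seq_len(nrow(res$history))) {
    # the lowest non-empty equal-width bin always holds the smallest scores
    ord <- surviving[order(scores[surviving])]
    removed <- ord[seq_len(res$history$n_removed[i])]
    remaining <- setdiff(surviving, removed)
    expect_lte(max(scores[removed]), min(scores[remaining]))
    expect_lte(max(scores[removed]), res$history$bin_upper[i])
    surviving <- remaining
  }
  expect_setequal(res$survivors, surviving)
})

test_that("CV trend fit excludes flat genes and recovers exact linear relations", {
  # a gene with identical weights across clusters has CV = 0 -> excluded, p = 1
  W <- rbind(c(0.2, 0.5, 0.3), c(0.2, 0.1, 0.7))
  colnames(W) <- c("flat", "g2", "g3")
  W <- cbind(W, g4 = c(0.25, 0.33)) # ensure >= 3 eligible genes
  trend <- fit_cv_mean_trend(W)
  expect_true(is.na(trend$genes$residual[trend$genes$gene_id == "flat"]))
  scr <- deviation_based_screen(trend$genes)
  expect_equal(scr$p[scr$gene_id == "flat"], 1)

  # construct K = 2 weights with exactly log(CV^2) = a*log10(mean) + b
  a <- -1.4; b <- -3
  mu <- seq(0.01, 0.2, length.out = 40)
  sigma <- mu * sqrt(exp(a * log10(mu) + b))
  Wex <- rbind(mu + sigma, mu - sigma)
  colnames(Wex) <- paste0("g", seq_along(mu))
  tr <- fit_cv_mean_trend(Wex)
  expect_equal(tr$slope, a, tolerance = 1e-9)
  expect_equal(tr$intercept, b, tolerance = 1e-9)
  expect_lt(max(abs(tr$genes$residual)), 1e-9)
})

test_that("trend coefficients and residuals match a normal-equations oracle", {
  set.seed(41)
  W <- rand_simplex_rows(5, 100)
  colnames(W) <- paste0("g", 1:100)
  tr <- fit_cv_mean_trend(W)
  mu <- colMeans(W)
  cv <- sqrt(colMeans(W^2) - mu^2) / mu # population sd over mean
  o <- ols_oracle(log10(mu), log(cv^2))
  expect_equal(tr$slope, o$slope, tolerance = 1e-9)
  expect_equal(tr$intercept, o$intercept, tolerance = 1e-9)
  expect_equal(tr$genes$residual, unname(o$residuals), tolerance = 1e-9)
})

test_that("deviation screen standardises residuals and applies the normal tail", {
  set.seed(52)
  d <- rnorm(200, 3, 2)
  names(d) <- paste0("g", 1:200)
  scr <- deviation_based_screen(d, p_threshold = 0.05)
  expect_equal(mean(scr$z), 0, tolerance = 1e-9)
  expect_equal(sd(scr$z), 1, tolerance = 1e-9)
  expect_equal(scr$p, pnorm((d - mean(d)) / sd(d), lower.tail = FALSE),
               ignore_attr = TRUE)
  expect_equal(scr$p[abs(scr$z) < 1e-12], rep(0.5, sum(abs(scr$z) < 1e-12)))
  # selection boundary sits at z = qnorm(0.95) = 1.6449
  expect_identical(scr$selected, scr$z >= qnorm(0.95))
  # affine rescaling of all residuals leaves the selection unchanged
  scr2 <- deviation_based_screen(3.7 * d + 11, p_threshold = 0.05)
  expect_identical(scr2$selected, scr$selected)
  # zero-spread residuals select nothing
  expect_warning(flat <- deviation_based_screen(setNames(rep(2, 10), paste0("g", 1:10))),
                 "zero spread")
  expect_false(any(flat$selected))
  expect_equal(flat$p, rep(0.5, 10))
})

test_that("planted outlier residuals are exactly the genes recovered", {
  set.seed(63)
  d <- c(rnorm(990), rnorm(10, mean = 5, sd = 0.1))
  names(d) <- c(paste0("bg", 1:990), paste0("hit", 1:10))
  scr <- deviation_based_screen(d)
  hits <- scr$gene_id[scr$selected]
  expect_true(all(paste0("hit", 1:10) %in% hits))
  # false positives bounded well above the binomial tail at the nominal rate
  expect_lt(length(hits) - 10, qbinom(0.9999, 990, 0.05) + 1)
  expect_setequal(head(scr$gene_id[order(scr$p)], 10), paste0("hit", 1:10))
})

test_that("fed exactly-normal residuals the screen selects the nominal 5%", {
  set.seed(74)
  rates <- vapply(1:30, function(i) {
    d <- setNames(rnorm(1000), paste0("g", 1:1000))
    mean(deviation_based_screen(d)$selected)
  }, numeric(1))
  n_tot <- 30 * 1000
  expect_lt(abs(mean(rates) - 0.05), 3 * sqrt(0.05 * 0.95 / n_tot))
})

test_that("a single informative gene among uninformative genes ranks first", {
  # The deviation screen is relative: a gene is picked for sitting above the
  # CV-mean trend of its peers, so the informative gene should dominate the
  # ranking. (With K = 2 and few genes the CV estimates are noisy enough
  # that the absolute p <= 0.05 cut can be empty, so the ranking, not the
  # cut, is the stable property of the extreme-contrast design.)
  set.seed(85)
  m <- matrix(rpois(60 * 30, 5), 60, 30,
              dimnames = list(sprintf("c%02d", 1:60), sprintf("g%02d", 1:30)))
  m[, 1] <- c(rep(0, 30), rpois(30, 40)) # silent in group 1, high in group 2
  sel <- suppressWarnings(select_genes(expr_matrix(m), K = 2, seed = 1))
  tt <- tidy(sel$report)
  expect_equal(adjusted_rand_index(rep(1:2, each = 30), sel$fit$assignments), 1)
  expect_equal(tt$gene_id[which.min(tt$p)], "g01")
  expect_true("g01" %in% sel$report$survivors_s1)
})

test_that("select_genes composes the stages without re-fitting weights", {
  ds <- simulate_expression(K = 3, cells_per_cluster = 30, n_informative = 10,
                            n_noise = 190, seed = 3)
  sel <- select_genes(ds$matrix, K = 3, seed = 3)
  rep <- sel$report
  expect_true(all(rep$survivors_s2 %in% rep$survivors_s1))
  expect_true(all(rep$survivors_s1 %in% gene_ids(ds$matrix)))
  # columns of the fitted W were subset, not re-fitted: max weights agree
  expect_equal(rep$gene_table$max_weight,
               unname(apply(sel$fit$W, 2, max)[rep$gene_table$gene_id]))
  g <- glance(rep)
  expect_equal(g$n_genes_s2, length(rep$survivors_s2))
  expect_true(all(tidy(rep)$p >= 0 & tidy(rep)$p <= 1, na.rm = TRUE))
  if (!is.null(sel$matrix)) {
    expect_identical(gene_ids(sel$matrix), rep$survivors_s2)
  }
})
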