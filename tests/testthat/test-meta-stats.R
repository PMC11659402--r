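mat_from <- function(...) build_matrix(list(...))

test_that("heterogeneity statistic matches hand arithmetic and exclusions", {
  m <- mat_from(c1 = c(g1 = 1, g2 = 5, g3 = 2),
                c2 = c(g1 = 2, g2 = 5, g3 = 4),
                c3 = c(g1 = 3, g2 = 5, g3 = 6))
  h <- heterogeneity_cv(m)
  expect_equal(h$stat[["g1"]], log10(0.25), tolerance = 1e-12) # sd 1, mean 2
  expect_true("g2" %in% h$excluded)                            # zero variance
  # CV is scale invariant
  h2 <- heterogeneity_cv(m * 7)
  expect_equal(h2$stat, h$stat, tolerance = 1e-12)
  expect_error(heterogeneity_cv(m, scope = c("c1", "c2")), "3")
})

test_that("heterogeneity scopes are comparable via Mann-Whitney", {
  set.seed(31)
  noisy <- lapply(1:6, function(i)
    setNames(rnorm(60, 10, 20), sprintf("g%d", 1:60)))
  tight <- lapply(1:6, function(i)
    setNames(rnorm(60, 10, 1), sprintf("g%d", 1:60)))
  names(noisy) <- paste0("tam", 1:6); names(tight) <- paste0("fulv", 1:6)
  m <- build_matrix(c(noisy, tight))
  ht <- heterogeneity_test(m, paste0("tam", 1:6), paste0("fulv", 1:6))
  expect_gt(ht$median_a, ht$median_b)
  expect_lt(ht$p, 0.01)
})

test_that("pairwise correlation has unit diagonal and honors negation", {
  set.seed(32)
  v <- setNames(rnorm(100), sprintf("g%d", 1:100))
  m <- build_matrix(list(a = v, b = -v, c = v + rnorm(100, 0, 0.2)))
  pc <- pairwise_correlation(m)
  expect_equal(unname(diag(pc$r)), c(1, 1, 1))
  expect_equal(pc$r["a", "b"], -1, tolerance = 1e-12)
  expect_equal(pc$r, t(pc$r))
  expect_setequal(pc$order, c("a", "b", "c"))
})

test_that("pairwise correlation recovers the designed class correlation", {
  sim <- generate_shared_effect_classes(n_genes = 2000, n_per_class = 10,
                                        share = 0.5, seed = 41)
  m <- simulated_percentile_matrix(sim)
  ids_a <- sim$metas$comparison_id[sim$metas$compound == "classA"]
  ids_b <- sim$metas$comparison_id[sim$metas$compound == "classB"]
  pc <- pairwise_correlation(m, list(A = ids_a, B = ids_b))
  expect_lt(abs(pc$r["A", "B"] - sim$truth$design_correlation), 0.1)
})

test_that("concordance quadrants use boundary-inclusive +/-25 cuts", {
  x <- c(g1 = 30, g2 = -40, g3 = 25, g4 = 10, g5 = -30)
  y <- c(g1 = 40, g2 = -25, g3 = -25, g4 = -90, g5 = 30)
  q <- concordance_quadrants(x, y, cut = 25)
  expect_equal(q$up_up$genes, "g1")
  expect_equal(q$down_down$genes, "g2")
  expect_equal(q$x_up_y_down$genes, "g3")   # boundary +25 / -25 inclusive
  expect_equal(q$x_down_y_up$genes, "g5")
  expect_false("g4" %in% unlist(lapply(q, `[[`, "genes")))
})

test_that("discordance calls are strict and label-symmetric", {
  a <- c(g1 = 80, g2 = 50, g3 = 0, g4 = -60)
  b <- c(g1 = -20, g2 = 20, g3 = -70, g4 = 40)
  d <- discordance_genes(a, b, delta_cut = 70)
  expect_setequal(d$a_pref$genes, "g1")       # delta 100
  expect_false("g2" %in% d$a_pref$genes)      # delta 30
  expect_false("g3" %in% d$a_pref$genes)      # delta exactly 70: excluded
  expect_equal(d$b_pref$genes, "g4")          # delta -100
  rev_d <- discordance_genes(b, a, delta_cut = 70)
  expect_equal(rev_d$a_pref$genes, d$b_pref$genes)
  expect_equal(rev_d$b_pref$genes, d$a_pref$genes)
  expect_error(discordance_genes(a, b, 0), "positive")
})

test_that("bidirectional calls apply both inclusive fraction thresholds", {
  n <- 20
  mk <- function(up, dn) {
    v <- rep(0, n)
    if (up > 0) v[seq_len(up)] <- 95
    if (dn > 0) v[up + seq_len(dn)] <- -95
    v
  }
  vals <- rbind(called = mk(4, 3),        # 20% up, 15% down: called
                up_only = mk(8, 0),
                short_down = mk(3, 2))    # 10% down < 15%
  cols <- lapply(seq_len(n), function(j) setNames(vals[, j], rownames(vals)))
  names(cols) <- sprintf("c%02d", seq_len(n))
  m <- build_matrix(cols)
  bid <- bidirectional_genes(m)
  expect_equal(bid$genes, "called")
  # invariant to a comparison where every gene is missing from a new gene's
  # perspective: add a column holding only an unrelated gene
  cols$extra <- c(other = 50)
  m2 <- build_matrix(cols)
  expect_equal(bidirectional_genes(m2)$genes, "called")
  expect_error(bidirectional_genes(m[, 1:4]), "5")
})

test_that("consensus targets respect the consistency boundary", {
  n <- 46
  mk <- function(k) c(rep(95, k), rep(0, n - k))
  vals <- rbind(in50 = mk(23), out50 = mk(22), always = mk(46))
  cols <- lapply(seq_len(n), function(j) setNames(vals[, j], rownames(vals)))
  names(cols) <- sprintf("c%02d", seq_len(n))
  m <- build_matrix(cols)
  ct <- consensus_targets(m, direction = "up", min_frac = 0.5)
  expect_setequal(ct$gene_id, c("in50", "always"))
  expect_equal(ct$consistency[ct$gene_id == "in50"], 0.5)
  expect_equal(ct$gene_id[1], "always")   # ranked by consistency
  all_ranked <- consensus_targets(m, direction = "up", min_frac = 0)
  expect_equal(nrow(all_ranked), 3)
})

test_that("ligand-dependence gate separates shared, de novo and neither", {
  model <- c(g1 = 60, g2 = 60, g3 = 60, g4 = -70, g5 = 20)
  e2 <- c(g1 = 55, g2 = 5, g3 = 30, g4 = -80, g5 = 80)
  gate <- ligand_dependence_gate(model, e2, high_cut = 50, null_band = 15)
  expect_equal(gate$ligand_up$genes, "g1")
  expect_equal(gate$de_novo$genes, "g2")
  expect_false("g3" %in% c(gate$ligand_up$genes, gate$de_novo$genes))
  expect_equal(gate$ligand_down$genes, "g4")
  expect_error(ligand_dependence_gate(model, e2, 15, 15), "exceed")
})

test_that("mixed model recovers a planted drug effect with correct sign", {
  sim <- generate_comparisons(n_genes = 300, n_comparisons = 40, seed = 51)
  resp <- simulate_percentile_response(sim$metas, n_genes = 6,
                                       n_affected = 6, drug_effect = 30,
                                       noise_sd = 10, seed = 52)
  lvl <- resp$truth$effect_term_level
  for (g in rownames(resp$y)[1:3]) {
    fit <- fit_gene_mixed_model(resp$y[g, ], sim$metas)
    expect_false(fit$degenerate)
    expect_gt(fit$coef[[paste0("drug", lvl)]], 0)
    expect_lt(fit$p[[paste0("drug", lvl)]], 0.01)
  }
})

test_that("mixed model flags degenerate input and ignores observation order", {
  sim <- generate_comparisons(n_genes = 300, n_comparisons = 30, seed = 53)
  y <- setNames(rep(12, 30), sim$metas$comparison_id)
  fit <- fit_gene_mixed_model(y, sim$metas)
  expect_true(fit$degenerate)
  expect_equal(unname(fit$coef[1]), 12)

  resp <- simulate_percentile_response(sim$metas, n_genes = 1,
                                       n_affected = 1, drug_effect = 20,
                                       noise_sd = 8, seed = 54)
  y1 <- resp$y[1, ]
  f1 <- fit_gene_mixed_model(y1, sim$metas)
  f2 <- fit_gene_mixed_model(y1[sample(length(y1))], sim$metas)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  expect_error(fit_gene_mixed_model(y1[1:5], sim$metas), "10")
})

test_that("single-level terms are dropped with a warning, not an error", {
  sim <- generate_comparisons(n_genes = 300, n_comparisons = 30,
                              n_cell_lines = 1, seed = 55)
  resp <- simulate_percentile_response(sim$metas, n_genes = 1,
                                       n_affected = 1, drug_effect = 25,
                                       noise_sd = 8, seed = 56)
  expect_warning(fit <- fit_gene_mixed_model(resp$y[1, ], sim$metas),
                 "cell_line")
  expect_false(fit$degenerate)
})

test_that("similarity search ranks duplicates first and negations last", {
  set.seed(33)
  base <- setNames(rnorm(20, 0, 40), sprintf("c%02d", 1:20))
  cols <- lapply(seq_along(base), function(j)
    c(query = base[[j]], twin = base[[j]], anti = -base[[j]],
      noise = rnorm(1, 0, 40)))
  names(cols) <- names(base)
  m <- build_matrix(cols)
  res <- similar_genes(m, "query")
  expect_equal(res$gene_id[1], "twin")
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_equal(res$gene_id[nrow(res)], "anti")
  expect_equal(res$r[nrow(res)], -1, tolerance = 1e-12)
  expect_true(all(res$padj >= res$p - 1e-15))
  expect_error(similar_genes(m, "absent"), "absent")
})

test_that("a planted co-regulated pair is recovered above r = 0.5", {
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    latent <- rnorm(30)
    y <- rbind(query = 25 * (0.9 * latent + sqrt(1 - 0.81) * rnorm(30)),
               partner = 25 * (0.9 * latent + sqrt(1 - 0.81) * rnorm(30)))
    y <- rbind(y, matrix(rnorm(28 * 30, 0, 25), 28, 30,
                         dimnames = list(sprintf("n%02d", 1:28), NULL)))
    y <- pmax(pmin(y, 100), -100)
    colnames(y) <- sprintf("c%02d", 1:30)
    m <- build_matrix(lapply(seq_len(30), function(j)
      setNames(y[, j], rownames(y))) |> setNames(colnames(y)))
    res <- similar_genes(m, "query", r_cut = 0.5)
    if ("partner" %in% res$gene_id) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("set intersections match the power-set enumeration oracle", {
  two <- intersect_sets(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(two$regions$count[two$regions$pattern == "A&B"], 1L)
  expect_equal(sum(two$regions$count), 3L)

  disjoint <- intersect_sets(list(A = "a", B = "b"))
  expect_false("A&B" %in% disjoint$regions$pattern)

  set.seed(34)
  sets <- list(X = sample(letters, 10), Y = sample(letters, 12),
               Z = sample(letters, 8))
  got <- intersect_sets(sets)$regions
  ref <- oracle_regions(sets)
  expect_equal(got$pattern, ref$pattern)
  expect_equal(got$count, ref$count)
  expect_error(intersect_sets(list(A = "a")), "2")
})
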