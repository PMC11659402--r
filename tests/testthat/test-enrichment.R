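test_that("GMT round trip preserves sets; defective files are rejected", {
  coll <- list(sets = list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5")),
               category = "Hallmark")
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, category = "Hallmark")
  expect_equal(back$sets, coll$sets)

  writeLines(c("a\tna\tg1", "a\tna\tg2"), path)
  expect_error(read_gmt(path), "duplicate")
  writeLines(c("a\tna\t"), path)
  expect_error(read_gmt(path), "empty")
})

test_that("Fisher ORA equals the hypergeometric tail on the worked table", {
  universe <- sprintf("u%03d", 1:100)
  query <- universe[1:10]
  term <- universe[6:25]          # overlap 5, term 20
  res <- fisher_ora(query, list(t1 = term), universe)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, oracle_hyper_tail(5, 10, 20, 100), tolerance = 1e-12)
})

test_that("Fisher ORA edge cases behave as counted", {
  universe <- sprintf("u%02d", 1:30)
  res0 <- fisher_ora(universe[1:5], list(t = universe[10:20]), universe)
  expect_equal(res0$odds_ratio, 0)
  expect_equal(res0$p, 1)

  degen <- fisher_ora(universe, list(t = universe), universe)
  expect_equal(degen$overlap, 30)
  expect_equal(degen$p, 1)

  expect_warning(fisher_ora(c(universe[1:3], "zzz"),
                            list(t = universe[1:4]), universe), "dropped")
  expect_error(fisher_ora("a", list(t = "a"), character(0)), "universe")
})

test_that("Fisher ORA matches choose-summation tails over small margins", {
  for (N in c(8, 15)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (q in seq_len(N - 1)) {
      query <- universe[seq_len(q)]
      terms <- list(); want <- c()
      for (t_ in seq_len(N - 1)) for (k in 0:min(q, t_)) {
        if (t_ - k > N - q) next
        nm <- sprintf("t%d_k%d", t_, k)
        terms[[nm]] <- c(if (k > 0) query[seq_len(k)],
                         if (t_ > k) setdiff(universe, query)[seq_len(t_ - k)])
        want[nm] <- oracle_hyper_tail(k, q, t_, N)
      }
      res <- fisher_ora(query, terms, universe)
      expect_equal(setNames(res$p, res$term)[names(want)], want,
                   tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment never drops below the raw p and sorts the output", {
  universe <- sprintf("u%03d", 1:60)
  set.seed(42)
  coll <- lapply(1:8, function(i) sample(universe, 12))
  names(coll) <- paste0("s", 1:8)
  res <- fisher_ora(universe[1:15], coll, universe)
  expect_true(all(res$padj >= res$p - 1e-15))
  expect_false(is.unsorted(res$padj))
  expect_equal(nrow(fisher_ora(universe[1:15], coll, universe, top_k = 3)), 3)
})

test_that("GSEA ES equals the exhaustive running-sum oracle on subsets", {
  set.seed(43)
  for (n in c(6, 10)) {
    ranking <- setNames(rnorm(n), letters[seq_len(n)])
    subsets <- unlist(lapply(seq_len(min(5, n - 1)), function(s)
      combn(letters[seq_len(n)], s, simplify = FALSE)), recursive = FALSE)
    names(subsets) <- sprintf("set%04d", seq_along(subsets))
    res <- preranked_gsea(ranking, subsets, min_size = 1, max_size = n,
                          n_perm = 5, seed = 6)
    want <- vapply(subsets, function(s) oracle_gsea_es(ranking, s),
                   numeric(1))
    expect_equal(setNames(res$es, res$term), want[res$term],
                 tolerance = 1e-12)
  }
})

test_that("GSEA weight 0 reduces to the classic unweighted KS statistic", {
  set.seed(44)
  ranking <- setNames(rnorm(40), sprintf("g%02d", 1:40))
  set_ <- list(s = sample(names(ranking), 8))
  res <- preranked_gsea(ranking, set_, min_size = 1, n_perm = 5, seed = 6,
                        weight = 0)
  expect_equal(res$es, oracle_gsea_es(ranking, set_$s, weight = 0),
               tolerance = 1e-12)
})

test_that("GSEA degenerate and antisymmetric cases hold", {
  set.seed(45)
  ranking <- setNames(rnorm(20), sprintf("g%02d", 1:20))
  whole <- preranked_gsea(ranking, list(all = names(ranking)),
                          min_size = 1, max_size = 20, n_perm = 5, seed = 6)
  expect_equal(whole$es, 0)

  set_ <- list(s = sample(names(ranking), 6))
  fwd <- preranked_gsea(ranking, set_, min_size = 1, n_perm = 5, seed = 6)
  rev_ <- preranked_gsea(-ranking, set_, min_size = 1, n_perm = 5, seed = 6)
  expect_equal(rev_$es, -fwd$es, tolerance = 1e-12)

  expect_error(preranked_gsea(setNames(rep(1, 10), letters[1:10]), set_),
               "degenerate")
  expect_error(preranked_gsea(setNames(c(1, NA), c("a", "b")), set_),
               "missing")
})

test_that("GSEA matches an established implementation's enrichment score", {
  skip_if_not_installed("fgsea")
  set.seed(46)
  ranking <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  coll <- list(a = sprintf("g%03d", 1:20), b = sprintf("g%03d", 150:190),
               c = sample(names(ranking), 30))
  mine <- preranked_gsea(ranking, coll, n_perm = 50, seed = 6)
  ref <- suppressWarnings(fgsea::fgsea(coll, ranking, nproc = 1, eps = 0))
  expect_equal(setNames(mine$es, mine$term)[ref$pathway], setNames(ref$ES, ref$pathway),
               tolerance = 1e-10)
})

test_that("NES shares the ES sign and fixed seeds reproduce bit-exactly", {
  set.seed(47)
  ranking <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  coll <- list(up = sprintf("g%03d", 1:15), dn = sprintf("g%03d", 180:195),
               rand = sample(names(ranking), 25))
  r1 <- preranked_gsea(ranking, coll, n_perm = 200, seed = 6)
  r2 <- preranked_gsea(ranking, coll, n_perm = 200, seed = 6)
  expect_identical(r1, r2)
  expect_true(all(sign(r1$nes) == sign(r1$es) | r1$es == 0))
  expect_true(all(r1$fdr >= 0 & r1$fdr <= 1))
})

test_that("signature fold change follows the geometric-mean definition", {
  expr <- rbind(gA = c(4, 4, 8, 8), gB = c(16, 16, 32, 32))
  colnames(expr) <- paste0("s", 1:4)
  groups <- c("control", "control", "treated", "treated")
  # per-sample signature values: sqrt(4*16)=8 control, sqrt(8*32)=16 treated
  res <- signature_fold_change(expr, groups, c("gA", "gB"))
  expect_equal(res$fold_change, 2)

  one <- signature_fold_change(expr, groups, "gA")
  expect_equal(one$fold_change, 2)   # single gene: that gene's fold change

  null_expr <- rbind(gA = c(4, 8, 8, 4), gB = c(16, 32, 32, 16))
  colnames(null_expr) <- paste0("s", 1:4)
  res0 <- signature_fold_change(null_expr, groups, c("gA", "gB"))
  expect_equal(res0$fold_change, 1)
  expect_equal(res0$p, 1)

  expect_error(signature_fold_change(expr, groups, "gZ"), "no signature")
})

test_that("single-sample scores are rank-based, bounded and monotone", {
  set.seed(48)
  expr <- matrix(rnorm(100 * 6, 8, 2), 100, 6,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  top_set <- rownames(expr)[order(expr[, 1], decreasing = TRUE)[1:10]]
  sc <- single_sample_score(expr, top_set)
  expect_equal(which.max(sc), c(s1 = 1))

  expr_const <- expr; expr_const[, 2] <- 5
  expect_equal(single_sample_score(expr_const, top_set)[["s2"]], 0)

  # monotonicity: raising all set genes in one sample cannot lower its score
  expr_up <- expr
  expr_up[top_set, 3] <- expr_up[top_set, 3] + 10
  expect_gte(single_sample_score(expr_up, top_set)[["s3"]], sc[["s3"]])

  expect_error(single_sample_score(expr, rownames(expr)[1:3]), "5")
})

test_that("planted cohort shifts separate case and control set scores", {
  seps <- vapply(1:5, function(s) {
    coh <- generate_cohort(n_samples = 60, case_frac = 0.4, effect = 1,
                           seed = s)
    sc <- single_sample_score(coh$expr, coh$up_set)
    mean(sc[coh$labels]) > mean(sc[!coh$labels])
  }, logical(1))
  expect_true(all(seps))
})

test_that("Oncotype weighted impact reproduces the printed coefficients", {
  zero <- c(HER2 = 0, ER = 0, Proliferation = 0, Invasion = 0,
            CD68 = 0, GSTM1 = 0, BAG1 = 0)
  expect_equal(oncotype_weighted_impact(zero), 0)

  prolif <- zero; prolif["Proliferation"] <- 100
  expect_equal(oncotype_weighted_impact(prolif), 104)

  her2_er <- zero; her2_er[c("HER2", "ER")] <- 50
  expect_equal(oncotype_weighted_impact(her2_er), 0.47 * 50 - 0.34 * 50)

  # linearity
  set.seed(49)
  x <- setNames(runif(7, -100, 100), names(zero))
  expect_equal(oncotype_weighted_impact(3 * x),
               3 * oncotype_weighted_impact(x), tolerance = 1e-12)
})

test_that("Oncotype gene-level input averages within groups", {
  pct <- c(GRB7 = 40, ERBB2 = 60, ESR1 = 0, PGR = 0, BCL2 = 0, SCUBE2 = 0,
           MKI67 = 10, AURKA = 10, BIRC5 = 10, CCNB1 = 10, MYBL2 = 10,
           MMP11 = 0, CD68 = 0, GSTM1 = 0, BAG1 = 0)
  expect_equal(oncotype_weighted_impact(pct), 0.47 * 50 + 1.04 * 10)
  expect_error(oncotype_weighted_impact(pct[!(names(pct) %in%
                                                c("CD68"))]), "CD68")
})
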