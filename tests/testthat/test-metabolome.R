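# QC, dynamic-range filter, row normalization, clustering, PCA and the
# killed-control significance model.

test_that("qc_filter removes flagged samples and errors on empty results", {
  tbl <- manual_peak_tbl(rep(5, 10), "m1", stages = "A",
                         times = c(1, 2, 3, 4, 5), replicates = 2)
  expect_identical(qc_filter(tbl), tbl)

  # flag one cell's samples: those columns disappear
  flagged <- tbl %>% dplyr::mutate(qc_pass = !(time == 2))
  expect_message(out <- qc_filter(flagged), "removing 2 sample")
  expect_false(any(out$time == 2))

  expect_error(qc_filter(tbl[0, ]), "empty")
  none <- tbl %>% dplyr::mutate(qc_pass = FALSE)
  expect_error(suppressMessages(qc_filter(none)), "every sample")
})

test_that("fold_range_filter applies the two-fold rule on cell means", {
  times <- c(1, 2, 3)
  mk <- function(vals, id) manual_peak_tbl(vals, id, stages = "A", times = times)
  tbl <- dplyr::bind_rows(
    mk(c(5, 5, 5), "m_const"),        # ratio 1 -> excluded
    mk(c(1, 2.1, 1), "m_modest"),     # ratio 2.1 -> retained
    mk(c(NA, 4, 2), "m_partial")      # positive means (4, 2) -> ratio 2 -> retained
  )
  out <- fold_range_filter(tbl, threshold = 2)
  verdict <- function(id) out$retained[out$metabolite_id == id]
  expect_false(verdict("m_const"))
  expect_true(verdict("m_modest"))
  expect_true(verdict("m_partial"))
  expect_equal(out$fold_range[out$metabolite_id == "m_partial"], 2)

  # a metabolite with < 2 non-missing cells is flagged unevaluable
  sparse <- dplyr::bind_rows(mk(c(NA, NA, 3), "m_sparse"), mk(c(1, 2, 4), "m_ok"))
  expect_message(out2 <- fold_range_filter(sparse), "unevaluable")
  expect_false(out2$evaluable[out2$metabolite_id == "m_sparse"])
  expect_false(out2$retained[out2$metabolite_id == "m_sparse"])
})

test_that("fold_range_filter is scale-invariant per metabolite", {
  times <- c(1, 2, 3, 4)
  set.seed(42)
  for (i in 1:10) {
    vals <- runif(4, 0.5, 4)
    base <- manual_peak_tbl(vals, "m", stages = "A", times = times)
    scaled <- base %>% dplyr::mutate(area = area * 7.3)
    expect_identical(
      fold_range_filter(base)$retained,
      fold_range_filter(scaled)$retained
    )
  }
})

test_that("row_normalize scales each profile to [0, 1] with max 1 and is idempotent", {
  tbl <- manual_peak_tbl(c(2, 4, 8), "m1", stages = "A", times = c(1, 2, 3))
  out <- row_normalize(tbl)
  expect_equal(out$value, c(0.25, 0.5, 1.0))

  single <- manual_peak_tbl(7, "m_single", stages = "A", times = 1)
  expect_equal(row_normalize(single)$value, 1.0)

  # idempotence: normalizing an already-normalized profile changes nothing
  renorm <- out %>%
    dplyr::mutate(area = value, replicate = 1L, condition = "active",
                  qc_pass = TRUE,
                  sample_id = paste0("s", dplyr::row_number()))
  expect_equal(row_normalize(renorm)$value, out$value)

  # property: bounds and a 1 in every row, over random tables
  set.seed(11)
  for (i in 1:5) {
    vals <- runif(12, 0, 10)
    tb <- manual_peak_tbl(vals, c("a", "b", "c"), stages = "A",
                          times = c(1, 2, 3, 4))
    nn <- row_normalize(tb)
    by_row <- split(nn$value, nn$metabolite_id)
    for (v in by_row) {
      expect_true(all(v >= 0 & v <= 1))
      expect_equal(max(v), 1)
    }
  }

  all_missing <- manual_peak_tbl(c(NA_real_, NA_real_), "m_gone",
                                 stages = "A", times = c(1, 2))
  expect_error(row_normalize(all_missing), "no positive values")
})

test_that("cluster_metabolites recovers archetypes and honours k contracts", {
  times <- c(0.05, 9, 18, 42, 49.5)
  early <- c(1, 0.5, 0.3, 0.1, 0.05)
  mid <- c(0.1, 0.8, 1, 0.6, 0.3)
  late <- c(0.05, 0.1, 0.3, 0.8, 1)
  prof <- function(shape, id) {
    tibble::tibble(metabolite_id = id, stage = "A", time = times, value = shape)
  }
  # 3 archetypes x 5 copies, noise off: exact recovery
  norm <- purrr::map_dfr(1:5, function(i) dplyr::bind_rows(
    prof(early, sprintf("early_%d", i)),
    prof(mid, sprintf("mid_%d", i)),
    prof(late, sprintf("late_%d", i))
  ))
  cl <- cluster_metabolites(norm, k = 3)
  lab <- function(prefix) unique(cl$cluster[startsWith(cl$metabolite_id, prefix)])
  expect_length(lab("early"), 1)
  expect_length(lab("mid"), 1)
  expect_length(lab("late"), 1)
  expect_length(unique(c(lab("early"), lab("mid"), lab("late"))), 3)

  # identical profiles share a label
  two <- dplyr::bind_rows(prof(early, "x1"), prof(early, "x2"), prof(late, "y"))
  cl2 <- cluster_metabolites(two, k = 2)
  expect_equal(cl2$cluster[cl2$metabolite_id == "x1"],
               cl2$cluster[cl2$metabolite_id == "x2"])

  # k = rows: singletons; k > rows: error
  cl3 <- cluster_metabolites(two, k = 3)
  expect_length(unique(cl3$cluster), 3)
  expect_error(cluster_metabolites(two, k = 4), "exceeds")
})

test_that("pca_ordinate centers log-areas and orders explained variance", {
  scen <- tiny_scenario(noise_sigma = 0.2)
  d <- simulate_wetup(scen)
  pca <- pca_ordinate(d$peak_areas)
  ev <- pca$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-9)

  # duplicate samples get identical scores
  tbl <- manual_peak_tbl(rep(c(1, 5, 2, 8, 3, 3), 2), c("a", "b", "c"),
                         stages = "A", times = c(1, 2), replicates = 2) %>%
    dplyr::group_by(metabolite_id, time) %>%
    dplyr::mutate(area = area[1]) %>%  # replicate 2 duplicates replicate 1
    dplyr::ungroup()
  p2 <- pca_ordinate(tbl)
  sc <- p2$scores
  s1 <- sc %>% dplyr::filter(time == 1)
  expect_equal(s1$PC1[1], s1$PC1[2], tolerance = 1e-10)

  # 2-metabolite toy: PC1 fraction equals the closed-form eigenvalue ratio
  x <- c(0, 1, 2, 3)
  y <- c(0, 0.5, 1, 1.5)
  toy <- manual_peak_tbl(c(expm1(x), expm1(y)), c("mx", "my"),
                         stages = "A", times = c(1, 2, 3, 4))
  p3 <- pca_ordinate(toy)
  S <- cov(cbind(x, y))
  eig <- eigen(S, symmetric = TRUE)$values
  expect_equal(p3$explained_variance[1], eig[1] / sum(eig), tolerance = 1e-10)

  expect_error(pca_ordinate(toy %>% dplyr::filter(time == 1)), "two samples")
})

test_that("killed_control_test verdicts follow the detection and F-test rules", {
  scen <- tiny_scenario(noise_sigma = 0.05)
  pools <- simulate_metabolites(scen)

  # identical active and killed trajectories (same pools, near-zero noise):
  # condition indistinguishable -> not significant
  act <- observe_peak_areas(pools, scen, condition = "active")
  fake_killed <- observe_peak_areas(pools, scen, condition = "killed",
                                    stages = scen$stages)
  both <- dplyr::bind_rows(act, fake_killed) %>%
    dplyr::filter(metabolite_id == "met_inert")
  v0 <- killed_control_test(both, compare_all = TRUE)
  expect_false(v0$biologically_controlled[v0$metabolite_id == "met_inert"])

  # metabolite absent from the killed controls is biologically controlled
  scen_n <- tiny_scenario(noise_sigma = 0.2)
  d <- simulate_wetup(scen_n)
  peaks <- d$peak_areas %>%
    dplyr::filter(!(condition == "killed" & metabolite_id == "met_released"))
  v1 <- killed_control_test(peaks)
  row <- v1[v1$metabolite_id == "met_released", ]
  expect_false(row$detected_in_killed)
  expect_true(row$biologically_controlled)
  expect_true(is.na(row$p_condition))

  # a strongly consumed metabolite is significantly different from killed
  d7 <- simulate_wetup(default_wetup_scenario(seed = 7))
  v7 <- killed_control_test(d7$peak_areas)
  expect_true(v7$biologically_controlled[v7$metabolite_id == "m_fattyacid_1"])

  # cross-check p-values against a from-scratch sequential OLS F-test
  m <- "m_fattyacid_1"
  sub <- d7$peak_areas %>%
    dplyr::filter(metabolite_id == m, !is.na(area),
                  condition == "killed" | (condition == "active" & stage == "D"))
  oracle <- ols_f_oracle(log1p(sub$area), sub$condition, sub$time)
  expect_equal(v7$p_condition[v7$metabolite_id == m],
               unname(oracle["p_condition"]), tolerance = 1e-8)
  expect_equal(v7$p_interaction[v7$metabolite_id == m],
               unname(oracle["p_interaction"]), tolerance = 1e-8)

  # Tukey HSD supplementary table is attached
  expect_s3_class(attr(v7, "tukey"), "data.frame")
  expect_true(nrow(attr(v7, "tukey")) > 0)
})

test_that("killed-control F-tests reject at about alpha under label permutation", {
  # null data: flat pools, pure lognormal noise; permute condition labels
  scen <- null_wetup_scenario(seed = 5, n_metabolites = 6)
  scen$replicates_active <- 8L
  pools <- simulate_metabolites(scen)
  base <- observe_peak_areas(pools, scen, condition = "active",
                             stages = "D") %>%
    dplyr::filter(metabolite_id %in% sprintf("m_null_%02d", 1:6))
  n_perm <- 200
  alpha <- 0.05
  set.seed(99)
  rates <- vapply(seq_len(n_perm), function(i) {
    relab <- base %>%
      dplyr::group_by(time) %>%
      dplyr::mutate(condition = sample(rep(c("active", "killed"), c(5, 3)))[replicate]) %>%
      dplyr::ungroup()
    v <- killed_control_test(relab, alpha = alpha, compare_all = TRUE)
    mean(c(v$p_condition, v$p_interaction) < alpha, na.rm = TRUE)
  }, numeric(1))
  rate <- mean(rates)
  se <- sd(rates) / sqrt(n_perm)
  expect_lt(abs(rate - alpha), 2 * se + 1e-12)
})
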