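# AAFC score, permutation null, z / empirical p, Fisher's method, and
# the joint significance classification.

test_that("the AAFC score sums absolute fold changes with set semantics", {
  tab <- toy_fc_table(c(1.0, -0.5, 0.25))
  expect_equal(aafc_score(tab, c("g001", "g002", "g003")), 1.75)
  expect_equal(aafc_score(tab, c("g003", "g002", "g001")), 1.75)
  expect_equal(aafc_score(toy_fc_table(c(0, 0)), c("g001", "g002")), 0)
  # duplicates count once
  expect_equal(aafc_score(tab, c("g001", "g001")), 1.0)
  # unmeasured genes are ignored; an all-unmeasured set errors by name
  expect_equal(aafc_score(tab, c("g001", "nope")), 1.0)
  expect_error(aafc_score(tab, "nope", set_name = "Fibrogenesis"),
               "Fibrogenesis")
  expect_equal(aafc_score(tab, c("g001", "g002"), summarise = "mean"),
               0.75)
})

test_that("the exhaustive permutation null matches full enumeration", {
  tab <- toy_fc_table(c(1, -2, 3, -4))
  nl <- permutation_null(tab, 2, exhaustive = TRUE)
  oracle <- exhaustive_null_oracle(abs(tab$fc), 2)
  expect_equal(sort(nl$draws), sort(oracle$draws))
  expect_equal(sort(nl$draws), c(3, 4, 5, 5, 6, 7))
  expect_equal(nl$mean, 5.0)
  expect_equal(nl$sd, oracle$sd, tolerance = 1e-12)
  expect_equal(nl$sd, sqrt(10 / 6), tolerance = 1e-12)
})

test_that("the sampled null converges to the exhaustive null", {
  tab <- toy_fc_table(c(1, -2, 3, -4))
  nl <- permutation_null(tab, 2, B = 10000, seed = 1)
  se <- sqrt(10 / 6) / sqrt(10000)
  expect_lt(abs(nl$mean - 5.0), 3 * se)
  # and more generally on a larger random universe
  set.seed(99)
  tab <- toy_fc_table(rnorm(12))
  oracle <- exhaustive_null_oracle(abs(tab$fc), 4)
  nl <- permutation_null(tab, 4, B = 10000, seed = 2)
  expect_lt(abs(nl$mean - oracle$mean), 3 * oracle$sd / sqrt(10000))
})

test_that("degenerate and invalid null requests are handled", {
  tab <- toy_fc_table(c(1, -2, 3))
  full <- permutation_null(tab, 3, B = 50, seed = 1)
  expect_equal(full$sd, 0)
  expect_true(all(full$draws == 6))
  zp <- module_z_and_p(6, full)
  expect_true(is.na(zp$z))              # undefined z, flagged as NA
  expect_equal(zp$p_perm, 1 / 51)       # p still computed
  expect_error(permutation_null(tab, 4), "exceeds")
  expect_error(permutation_null(tab, 0), "positive")
})

test_that("z and the smoothed empirical p follow their definitions", {
  tab <- toy_fc_table(c(1, -2, 3, -4))
  nl <- permutation_null(tab, 2, exhaustive = TRUE)
  expect_equal(module_z_and_p(nl$mean, nl)$z, 0)
  zp <- module_z_and_p(7, nl)
  expect_equal(zp$z, 2 / sqrt(10 / 6), tolerance = 1e-12)
  expect_equal(round(zp$z, 2), 1.55)
  # observed above every draw at B = 10,000 hits the smoothing floor
  big <- permutation_null(toy_fc_table(rnorm(100)), 10, B = 10000,
                          seed = 3)
  expect_equal(module_z_and_p(1e6, big)$p_perm, 1 / 10001)
})

test_that("Fisher's method matches its chi-square closed form", {
  expect_equal(as.numeric(fisher_combined(c(1, 1, 1))), 1)
  expect_equal(as.numeric(fisher_combined(0.05)), 0.05)  # k = 1 identity
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(x, 11.98293, tolerance = 1e-5)
  # df = 4 survival function is exp(-X/2) * (1 + X/2)
  expect_equal(as.numeric(fisher_combined(c(0.05, 0.05))),
               exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(round(as.numeric(fisher_combined(c(0.05, 0.05))), 4),
               0.0175)
  # missing values are dropped with a count; all-missing errors
  res <- fisher_combined(c(0.05, NA))
  expect_equal(as.numeric(res), 0.05)
  expect_equal(attr(res, "n_dropped"), 1L)
  expect_error(fisher_combined(c(NA_real_, NA_real_)), "no usable")
  expect_warning(fisher_combined(c(0, 0.5)), "clamped")
})

test_that("the joint significance rule reproduces the published convention", {
  # bolding fixtures: activation p < 0.05 AND Fisher < 0.01
  expect_true(classify_module(2.1, 2.3e-20))
  expect_false(classify_module(2.8, 0.74))
  expect_false(classify_module(1.6, 6.6e-29))
  # explicit empirical p takes precedence over the normal tail of z
  expect_true(classify_module(1.6, 6.6e-29, p_perm = 0.03))
  expect_false(classify_module(2.1, 2.3e-20, p_perm = 0.2))
  # activation is one-sided: negative z never significant
  expect_false(classify_module(-2.9, 1e-30))
  expect_false(classify_module(-2.9, 1e-30, p_perm = 0.01))
})

test_that("score_all_modules is order-independent and sign/scale stable", {
  sim <- generate_experiment(simulation_config(400, modules = list(
    module_spec("Fibrogenesis", 25, effect = 0.8, class = "inflammation"),
    module_spec("Hypertrophy", 25, effect = 0, class = "proliferation"),
    module_spec("Necrosis", 25, effect = 0.3, class = "degeneration")),
    seed = 21))
  fc <- compute_fc(sim$experiment)
  coll <- collection_from_truth(sim$truth)
  res <- score_all_modules(fc, coll, B = 500, seed = 5)

  # permuting the collection leaves per-module results identical
  perm <- module_collection(unclass(coll)[c(3, 1, 2)])
  res_perm <- score_all_modules(fc, perm, B = 500, seed = 5)
  expect_equal(res[order(res$module), ],
               res_perm[order(res_perm$module), ], ignore_attr = TRUE)

  # negating all fold changes changes nothing (sign invariance)
  neg <- fc_table(fc$gene_id, -fc$fc, fc$t_p, q = fc$q)
  res_neg <- score_all_modules(neg, coll, B = 500, seed = 5)
  expect_equal(res_neg$aafc, res$aafc)
  expect_equal(res_neg$z, res$z)
  expect_equal(res_neg$p_perm, res$p_perm)

  # positive rescaling multiplies scores by c, leaves z and p unchanged
  sc <- fc_table(fc$gene_id, 3 * fc$fc, fc$t_p, q = fc$q)
  res_sc <- score_all_modules(sc, coll, B = 500, seed = 5)
  expect_equal(res_sc$aafc, 3 * res$aafc, tolerance = 1e-9)
  expect_equal(res_sc$z, res$z, tolerance = 1e-9)
  expect_equal(res_sc$p_perm, res$p_perm)

  # ranked by decreasing z, and the implanted module leads
  expect_true(all(diff(res$z) <= 0))
  expect_identical(res$module[1], "Fibrogenesis")
})

test_that("boosting one member gene's |fc| never lowers the module z", {
  set.seed(77)
  fc_vals <- rnorm(60)
  tab <- toy_fc_table(fc_vals)
  genes <- tab$gene_id[1:8]
  base_null <- permutation_null(tab, 8, B = 4000, seed = 9)
  z0 <- module_z_and_p(aafc_score(tab, genes), base_null)$z
  for (boost in c(0.5, 1, 2)) {
    fc2 <- fc_vals
    fc2[1] <- fc2[1] + sign(fc2[1]) * boost
    tab2 <- toy_fc_table(fc2)
    null2 <- permutation_null(tab2, 8, B = 4000, seed = 9)
    z1 <- module_z_and_p(aafc_score(tab2, genes), null2)$z
    expect_gte(z1, z0)
    z0 <- z1
  }
})

test_that("coverage accounting flags thin modules and skips empty ones", {
  tab <- toy_fc_table(rnorm(30))
  coll <- module_collection(list(
    list(name = "thin", genes = c(tab$gene_id[1:2],
                                  sprintf("x%02d", 1:8))),
    list(name = "gone", genes = sprintf("y%02d", 1:5)),
    list(name = "full", genes = tab$gene_id[3:12])))
  expect_warning(res <- score_all_modules(tab, coll, B = 200, seed = 1),
                 "gone")
  thin <- res[res$module == "thin", ]
  expect_equal(thin$coverage, 0.2)
  expect_true(thin$low_coverage)
  expect_false(res$low_coverage[res$module == "full"])
  expect_true(is.na(res$z[res$module == "gone"]))
})
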