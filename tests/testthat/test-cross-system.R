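# Ortholog mapping, overlap vs chance, activation correlation, PCA and
# hypergeometric enrichment.

test_that("ortholog mapping honours its resolution policy", {
  idmap <- data.frame(source_gene = letters[1:5],
                      target_gene = letters[1:5])
  res <- map_orthologs(c("a", "b", "c"), idmap)
  expect_equal(res$mapped, c("a", "b", "c"))
  expect_equal(res$n_unmapped, 0L)

  res <- map_orthologs(c("a", "b"),
                       data.frame(source_gene = "a", target_gene = "x"))
  expect_equal(res$mapped, "x")
  expect_equal(res$n_unmapped, 1L)

  many <- data.frame(source_gene = c("a", "b"),
                     target_gene = c("x", "x"))
  res <- map_orthologs(c("a", "b"), many, policy = "one_to_one")
  expect_equal(res$mapped, "x")
  expect_equal(res$n_collapsed, 1L)
  res <- map_orthologs(c("a", "b"), many, policy = "any")
  expect_equal(res$mapped, "x")

  # one-to-one tie-break is lexicographic on the target
  ties <- data.frame(source_gene = c("a", "a"),
                     target_gene = c("z", "y"))
  expect_equal(map_orthologs("a", ties)$mapped, "y")
  expect_equal(map_orthologs(character(0), idmap)$mapped, character(0))
  expect_error(map_orthologs("a", idmap[0, ]), "empty")
})

test_that("overlap reports exact regions and the independence expectation", {
  A <- sprintf("g%03d", 1:20)
  B <- sprintf("g%03d", 11:40)
  rep2 <- overlap_with_expectation(list(A = A, B = B),
                                   universe_size = 100)
  expect_equal(rep2$observed[["A&B"]], 10)
  expect_equal(rep2$expected[["A&B"]], 20 * 30 / 100)  # 6 by chance
  expect_equal(sum(rep2$regions), length(union(A, B)))

  same <- overlap_with_expectation(list(A = A, B = A), 50)
  expect_equal(same$observed[["A&B"]], length(A))

  tri <- overlap_with_expectation(
    list(h = sprintf("g%03d", 1:10), r = sprintf("g%03d", 5:14),
         v = sprintf("g%03d", 8:17)), universe_size = 60)
  expect_equal(tri$observed[["h&r&v"]], length(8:10))
  expect_equal(tri$expected[["h&r&v"]], 10 * 10 * 10 / 60^2)
  expect_equal(sum(tri$regions),
               length(unique(c(1:10, 5:14, 8:17))))
  expect_error(overlap_with_expectation(list(A = A, B = B), 10),
               "universe")
})

test_that("random subsets overlap at the hypergeometric mean", {
  set.seed(4)
  universe <- sprintf("g%04d", 1:200)
  obs <- vapply(1:1000, function(i) {
    a <- sample(universe, 40)
    b <- sample(universe, 60)
    length(intersect(a, b))
  }, numeric(1))
  mu <- 40 * 60 / 200
  # hypergeometric sd for the Monte-Carlo band
  sdev <- sqrt(40 * (60 / 200) * (140 / 200) * (160 / 199))
  expect_lt(abs(mean(obs) - mu), 3 * sdev / sqrt(1000))
})

test_that("activation correlation matches hand computation and is one-sided", {
  av <- function(z, sys = "s") activation_vector(sys, "c",
                                                 paste0("m", seq_along(z)),
                                                 z)
  self <- correlate_activation(av(c(1, 2, 3, 4)), av(c(1, 2, 3, 4), "t"))
  expect_equal(self$r, 1)

  hand <- correlate_activation(av(c(1, 2, 3, 4)), av(c(1, 3, 2, 4), "t"))
  expect_equal(hand$r, 0.8)   # cov 4/3 over variances 5/3
  ref <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4), alternative = "greater")
  expect_equal(hand$p, ref$p.value)

  flip <- correlate_activation(av(c(1, 2, 3, 4)), av(c(4, 3, 2, 1), "t"))
  expect_equal(flip$r, -1)
  expect_gt(flip$p, 0.95)     # negative correlation is never "activation"

  expect_error(correlate_activation(av(1:4), av(rep(2, 4), "flat")),
               "flat")
  expect_error(correlate_activation(av(1:2), av(2:1, "t")), "3 modules")
  b <- av(1:4, "t"); b$modules <- rev(b$modules)
  expect_error(correlate_activation(av(1:4), b), "ordering")
})

test_that("activation correlation is symmetric and scale invariant", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    a <- activation_vector("a", "c", paste0("m", 1:8), x)
    b <- activation_vector("b", "c", paste0("m", 1:8), y)
    ab <- correlate_activation(a, b)
    ba <- correlate_activation(b, a)
    expect_equal(ab$r, ba$r, tolerance = 1e-12)
    b2 <- activation_vector("b", "c", paste0("m", 1:8), 2.5 * y + 1)
    expect_equal(correlate_activation(a, b2)$r, ab$r, tolerance = 1e-12)
  }
})

test_that("condition PCA conserves variance and finds linear structure", {
  set.seed(6)
  m <- matrix(rnorm(66), nrow = 6, ncol = 11,
              dimnames = list(paste0("c", 1:6), NULL))
  pca <- pca_conditions(m)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$explained) <= 1e-12))

  # points on the line y = 2x: one component carries all variance
  line <- cbind(x = 1:5, y = 2 * (1:5))
  rownames(line) <- paste0("c", 1:5)
  pl <- pca_conditions(line)
  expect_equal(pl$explained[1], 1, tolerance = 1e-12)
  expect_equal(pl$explained[2], 0, tolerance = 1e-12)

  # two identical conditions: zero total variance, equal coordinates
  flat <- matrix(1, 2, 3, dimnames = list(c("a", "b"), NULL))
  pf <- pca_conditions(flat)
  expect_equal(pf$coordinates["a", ], pf$coordinates["b", ])
  expect_equal(sum(pf$sdev^2), 0)
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  universe <- sprintf("g%02d", 1:10)
  coll <- module_collection(list(
    list(name = "hit", genes = universe[1:4]),
    list(name = "miss", genes = universe[7:10])))
  deg <- universe[1:4]   # exactly the first set
  res <- enrich_genesets(deg, universe, coll)
  hit <- res[res$set == "hit", ]
  expect_equal(hit$overlap, 4)
  expect_equal(hit$p, hyper_tail_oracle(4, 4, 10, 4), tolerance = 1e-12)
  expect_equal(hit$p, 1 / choose(10, 4), tolerance = 1e-12)
  # disjoint set: overlap 0, upper tail from k >= 0 is 1
  miss <- res[res$set == "miss", ]
  expect_equal(miss$overlap, 0)
  expect_equal(miss$p, 1)
  # degenerate: universe = set = deg set
  all_in <- enrich_genesets(universe, universe, module_collection(
    list(list(name = "all", genes = universe))))
  expect_equal(all_in$overlap, 10)
  expect_equal(all_in$p, 1)
  expect_error(enrich_genesets("x", character(0), coll), "universe")
  expect_error(enrich_genesets("zz", universe, coll), "outside")
})

test_that("concordant synthetic systems show the activation contrast", {
  score_pair <- function(rho, seed) {
    base <- simulation_config(1000, modules = lapply(1:11, function(i)
      module_spec(paste0("M", i), 20, effect = 1)), seed = seed,
      noise_sd = 0.5)
    ms <- generate_multi_system(
      multi_system_config(c("HS", "RN"), rho, 1, base))
    zs <- lapply(c("HS", "RN"), function(sys) {
      fc <- compute_fc(ms$experiments[[sys]]$experiment)
      sc <- score_all_modules(fc, ms$collections[[sys]], B = 400,
                              seed = seed)
      as_activation_vector(sc, system = sys)
    })
    correlate_activation(zs[[1]], zs[[2]])$r
  }
  r_conc <- vapply(1:25, function(s) score_pair(1, s), numeric(1))
  expect_gte(mean(r_conc >= 0.9), 0.9)
  r_disc <- vapply(1:25, function(s) score_pair(0, 100 + s), numeric(1))
  expect_lt(abs(mean(r_disc)), 0.2)
})
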