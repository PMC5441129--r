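test_that("Gaussian CMI follows the closed form and is monotone in |rho|", {
  # construct data with known sample correlation via exact rotation
  set.seed(81)
  n <- 500
  x <- rnorm(n); e <- residuals(lm(rnorm(n) ~ x))
  mk_y <- function(rho) rho * scale(x)[, 1] + sqrt(1 - rho^2) * scale(e)[, 1]
  d <- data.frame(x = scale(x)[, 1], y = mk_y(0.5))
  out <- gaussian_cmi(d, "x", "y")
  expect_equal(out$rho, 0.5, tolerance = 1e-10)
  expect_equal(out$cmi, -0.5 * log(0.75), tolerance = 1e-10)
  expect_equal(-0.5 * log(0.75), 0.1438, tolerance = 1e-3)
  # rho = 0 -> CMI = 0
  d0 <- data.frame(x = scale(x)[, 1], y = mk_y(0))
  expect_equal(gaussian_cmi(d0, "x", "y")$cmi, 0, tolerance = 1e-10)
  # strictly increasing in |rho|
  cmis <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                 function(r) gaussian_cmi(data.frame(x = scale(x)[, 1],
                                                    y = mk_y(r)),
                                          "x", "y")$cmi, numeric(1))
  expect_true(all(diff(cmis) > 0))
})

test_that("conditioning on a collinear set is rejected", {
  set.seed(82)
  d <- data.frame(x = rnorm(50), y = rnorm(50), a = rnorm(50))
  d$b <- 2 * d$a
  expect_error(gaussian_cmi(d, "x", "y", c("a", "b")), "collinear")
})

test_that("edge determination coefficient is the squared Pearson correlation", {
  set.seed(83)
  x <- rnorm(200)
  expect_equal(edge_r2(x, x), 1)
  expect_lt(edge_r2(x, rnorm(200)), 0.05)
  y <- 0.56 * scale(x)[, 1] + sqrt(1 - 0.56^2) * scale(residuals(lm(rnorm(200) ~ x)))[, 1]
  expect_equal(edge_r2(scale(x)[, 1], y), 0.3136, tolerance = 1e-6)
  expect_error(edge_r2(x, rep(1, 200)), "zero variance")
})

test_that("independent variables yield an (almost always) empty graph", {
  empty <- 0L
  for (s in 1:10) {
    set.seed(900 + s)
    d <- as.data.frame(matrix(rnorm(2000 * 4), 2000, 4))
    names(d) <- letters[1:4]
    g <- tpda_learn(d)
    if (nrow(g$edges) == 0L) empty <- empty + 1L
  }
  expect_gte(empty, 8L)
})

test_that("a linear-Gaussian chain yields the chain skeleton without shortcut", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(910 + s)
    n <- 2000
    a <- rnorm(n); b <- 0.8 * a + rnorm(n); c_ <- 0.8 * b + rnorm(n)
    g <- tpda_learn(data.frame(a = a, b = b, c = c_))
    sk <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
    if (setequal(sk, c("a b", "b c"))) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("colliders are oriented into the common effect", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(920 + s)
    n <- 2000
    a <- rnorm(n); b <- rnorm(n); c_ <- 0.8 * a + 0.8 * b + rnorm(n)
    g <- tpda_learn(data.frame(a = a, b = b, c = c_))
    ed <- g$edges
    ok <- nrow(ed) == 2 && all(ed$direction == "forward") &&
      all(ed$to == "c") && setequal(ed$from, c("a", "b"))
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("skeleton recovery on random 6-node DAGs is precise and sensitive", {
  tp <- fp <- fn <- 0
  for (s in 1:25) {
    dag <- random_dag_data(p = 6, n = 2000, seed = 930 + s)
    g <- tpda_learn(dag$data)
    m <- skeleton_metrics(g, dag$amat)
    tp <- tp + m["tp"]; fp <- fp + m["fp"]; fn <- fn + m["fn"]
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("the learned skeleton does not depend on column order", {
  set.seed(84)
  n <- 2000
  a <- rnorm(n); b <- 0.7 * a + rnorm(n); c_ <- 0.7 * b + rnorm(n)
  d1 <- data.frame(a = a, b = b, c = c_)
  g1 <- tpda_learn(d1)
  g2 <- tpda_learn(d1[, c(3, 1, 2)])
  key <- function(g) paste(pmin(g$edges$from, g$edges$to),
                           pmax(g$edges$from, g$edges$to))
  expect_setequal(key(g1), key(g2))
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- data.frame(a = rnorm(50), b = rnorm(50), c = rep(1, 50))
  expect_error(tpda_learn(d), "constant variable")
  expect_error(tpda_learn(d[, 1:2]), "at least 3")
  expect_error(tpda_learn(data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))),
               "n >= 30")
})

test_that("graph export writes DOT and TSV edge lists", {
  set.seed(85)
  n <- 1000
  a <- rnorm(n); b <- 0.8 * a + rnorm(n); c_ <- 0.8 * b + rnorm(n)
  g <- tpda_learn(data.frame(a = a, b = b, c = c_))
  dot <- withr::local_tempfile(fileext = ".dot")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_bn_graph(g, dot, tsv)
  expect_true(any(grepl("digraph", readLines(dot))))
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(g$edges))
  expect_true(all(back$r2 >= 0 & back$r2 <= 1))
  td <- tidy(g)
  expect_named(td, c("from", "to", "direction", "r2", "p_marginal"))
  expect_equal(glance(g)$n_edges, nrow(g$edges))
})
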