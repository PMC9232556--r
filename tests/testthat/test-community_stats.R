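test_that("log density transform evaluates ln(1+x)", {
  expect_equal(log_density_transform(0), 0)
  expect_equal(log_density_transform(exp(1) - 1), 1)
  expect_equal(log_density_transform(7), log(8))
  expect_error(log_density_transform(-0.1), "non-negative")
})

test_that("Bray-Curtis matches the hand formula and vegan", {
  m <- rbind(a = c(6, 2), b = c(2, 2))
  d <- bray_curtis(m)
  expect_equal(as.numeric(d), 1 / 3)  # (4+0)/(8+4)
  ident <- rbind(a = c(3, 1), b = c(3, 1))
  expect_equal(as.numeric(bray_curtis(ident)), 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 4))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  expect_error(bray_curtis(m[1, , drop = FALSE]), "2 samples")
  set.seed(9)
  big <- matrix(rpois(60, 4), nrow = 6)
  expect_equal(as.numeric(bray_curtis(big)),
               as.numeric(vegan::vegdist(big, "bray")))
})

test_that("a pair of all-zero samples is defined as 0 with a warning", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 2))
  expect_warning(d <- bray_curtis(m), "all-zero")
  dm <- as.matrix(d)
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm["a", "c"], 1)
})

test_that("ANOSIM reproduces constructed extremes", {
  # every between-group dissimilarity exceeds every within-group one
  set.seed(2)
  n <- 6; g <- rep(c("x", "y"), each = 3)
  dm <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    dm[i, j] <- if (g[i] == g[j]) runif(1, 0, 0.3) else runif(1, 0.7, 1)
    dm[j, i] <- dm[i, j]
  }
  dm[lower.tri(dm)] <- t(dm)[lower.tri(dm)]
  res <- anosim_test(dm, g, permutations = 99, seed = 1)
  expect_equal(res$statistic, 1)
  # constant dissimilarities: all ranks tied, R = 0
  dc <- matrix(1, n, n); diag(dc) <- 0
  expect_warning(res0 <- anosim_test(dc, g, permutations = 99, seed = 1),
                 "constant")
  expect_equal(res0$statistic, 0)
})

test_that("ANOSIM validates its grouping", {
  dm <- as.matrix(dist(matrix(rnorm(10), 5)))
  expect_error(anosim_test(dm, c("a", "a", "a", "a", "b")), ">= 2 members")
  expect_error(anosim_test(dm, rep("a", 5)), "2 groups")
  expect_error(anosim_test(dm, c("a", "b")), "does not match")
})

test_that("ANOSIM R agrees with vegan and is seed-reproducible", {
  set.seed(21)
  comm <- matrix(rpois(10 * 8, 5), nrow = 10)
  g <- rep(c("c1", "c2"), each = 5)
  d <- bray_curtis(comm)
  ours <- anosim_test(d, g, permutations = 199, seed = 7)
  ref <- vegan::anosim(d, g, permutations = 199)
  expect_equal(ours$statistic, unname(ref$statistic))
  again <- anosim_test(d, g, permutations = 199, seed = 7)
  expect_equal(ours$p, again$p)
})

test_that("exact ANOSIM matches the enumeration oracle on small n", {
  for (n in 4:6) {
    set.seed(n)
    dm <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    g <- c(rep("a", 2), rep("b", n - 2))
    res <- anosim_test(dm, g, exact = TRUE)
    orc <- oracle_anosim_exact(dm, g)
    expect_equal(res$statistic, orc$R)
    expect_equal(res$p, orc$p)
    expect_equal(res$permutations, orc$n_assign)
  }
})

test_that("Shannon index matches direct evaluation and is scale invariant", {
  expect_equal(shannon_index(c(5)), 0)
  expect_equal(shannon_index(c(2, 2, 2, 2)), log(4))
  expect_equal(shannon_index(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_error(shannon_index(c(0, 0)), "positive")
  set.seed(3)
  cts <- rpois(12, 6) + 1
  expect_equal(shannon_index(cts), oracle_shannon(cts))
  expect_equal(shannon_index(cts * 10), shannon_index(cts))
})

test_that("EPT counting filters by insect order", {
  traits <- mini_traits()
  expect_equal(ept_count(c("Baetis sp." = 4, "Chironomidae" = 50), traits), 4)
  expect_equal(ept_count(c("Chironomidae" = 50, "Erpobdella sp." = 2),
                         traits), 0)
  expect_equal(ept_count(c("Limnephilus sp." = 2, "Baetis sp." = 3), traits),
               5)
  expect_error(ept_count(c("Nobody" = 1), traits), "missing")
})
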