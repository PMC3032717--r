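# brute-force enumeration oracle for the exact two-tailed Mann-Whitney p:
# every way of assigning the pooled values to the two groups
mwu_exact_p <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  U_of <- function(ix) {
    a <- pool[ix]; b <- pool[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- U_of(seq_len(n))
  all_ix <- utils::combn(length(pool), n)
  us <- apply(all_ix, 2, U_of)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

test_that("the Mann-Whitney U test matches exact enumeration", {
  cmp <- mann_whitney_bonferroni(c(1, 2, 3), c(4, 5, 6), m = 1)
  expect_equal(unname(cmp$U), 0)
  expect_equal(cmp$p, 0.1)
  expect_equal(cmp$p, mwu_exact_p(c(1, 2, 3), c(4, 5, 6)))
  # a second configuration, partially overlapping groups
  x <- c(1, 4, 7); y <- c(2, 3, 9, 11)
  expect_equal(mann_whitney_bonferroni(x, y)$p, mwu_exact_p(x, y))
})

test_that("identical samples are maximally non-significant", {
  cmp <- mann_whitney_bonferroni(c(2, 2, 2), c(2, 2, 2), m = 4)
  expect_equal(cmp$p, 1)
  expect_false(cmp$significant)
})

test_that("Bonferroni adjustment scales the significance level", {
  cmp <- mann_whitney_bonferroni(c(1, 2, 3), c(4, 5, 6), m = 8)
  expect_equal(cmp$alpha_adj, 0.00625)
  expect_false(cmp$significant)  # p = 0.1 > 0.00625
  expect_error(mann_whitney_bonferroni(numeric(0), 1:3), "empty")
})

test_that("the normal approximation tracks the exact test within 0.02", {
  set.seed(7)
  for (i in 1:10) {
    a <- sample(1000, 10); b <- sample(2000, 10) + 0.5  # tie-free
    pe <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    pn <- mann_whitney_bonferroni(a, b)$p  # n = 20 -> approximation path
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("degree histograms and their Spearman statistics are correct", {
  tab <- data.frame(tick = 400L, agent_id = 1:5, agent_type = "TCell",
                    alive = TRUE, partner_type = "Dendritic", zone = 2L,
                    count = c(1L, 1L, 1L, 2L, 3L))
  f <- degree_distribution(tab, "TCell")
  expect_equal(f$points$links, c(1, 2, 3))
  expect_equal(f$points$nodes, c(3, 1, 1))
  # node counts (3, 1, 1) contain a tie, so r is -sqrt(3)/2, not -1
  expect_equal(f$spearman_r, stats::cor(c(3, 1, 1), c(1, 2, 3),
                                        method = "spearman"))
  expect_equal(f$spearman_r, -sqrt(3) / 2, tolerance = 1e-12)
})

test_that("strictly decreasing node counts give Spearman r of exactly -1", {
  tab <- data.frame(tick = 400L, agent_id = 1:6, agent_type = "TCell",
                    alive = TRUE, partner_type = "Dendritic", zone = 2L,
                    count = c(1L, 1L, 1L, 2L, 2L, 3L))
  f <- degree_distribution(tab, "TCell")
  expect_equal(f$points$nodes, c(3, 2, 1))
  expect_equal(f$spearman_r, -1)
})

test_that("fewer than three distinct degrees is an undetermined fit", {
  tab <- data.frame(tick = 400L, agent_id = 1:4, agent_type = "Granulocyte",
                    alive = TRUE, partner_type = "Parenchymal", zone = 1L,
                    count = c(1L, 1L, 2L, 2L))
  f <- degree_distribution(tab, "Granulocyte")
  expect_false(f$determined)
  expect_true(is.na(f$spearman_r))
  same <- tab; same$count <- 2L
  expect_false(degree_distribution(same, "Granulocyte")$determined)
})

test_that("log-log regression recovers a known power-law exponent", {
  set.seed(42)
  deg <- rpowerlaw_degrees(2e5, alpha = 2, kmin = 1, kmax = 60)
  tab <- data.frame(tick = 400L, agent_id = seq_along(deg),
                    agent_type = "Dendritic", alive = TRUE,
                    partner_type = "Dendritic", zone = 2L, count = deg)
  f <- degree_distribution(tab, "Dendritic")
  expect_true(f$determined)
  expect_equal(f$slope, -2, tolerance = 0.1)
  expect_lt(f$spearman_r, -0.9)
  expect_lt(f$spearman_p, 1e-6)
})

test_that("engagement time courses start at zero and compare outcomes", {
  b <- small_batch()
  tc <- engagement_timecourse(b, types = c("Dendritic", "Macrophage"))
  t0 <- tc[tc$tick == 0, ]
  expect_true(all(t0$median == 0))
  expect_true(all(t0$q25 == 0 & t0$q75 == 0))
  expect_true(all(tc$median >= 0 & tc$median <= 100))
  # identical runs would give zero-width IQR; here just check coherence
  expect_true(all(tc$q25 <= tc$median & tc$median <= tc$q75))
})

test_that("hubs are identified from median links per node", {
  tab <- data.frame(tick = rep(c(100L, 200L), each = 4),
                    agent_id = rep(1:4, 2),
                    agent_type = rep(c("Dendritic", "Dendritic",
                                       "TCell", "TCell"), 2),
                    alive = TRUE, partner_type = "BCell", zone = 2L,
                    count = c(5L, 7L, 2L, 2L, 50L, 70L, 3L, 3L))
  ht <- hub_table(tab, types = c("Dendritic", "TCell"))
  expect_equal(unname(ht$hub), c("Dendritic", "Dendritic"))
  expect_equal(ht$medians["Dendritic", "200"], 60)
  # a single-type world trivially makes that type the hub
  solo <- tab[tab$agent_type == "TCell", ]
  expect_equal(unname(hub_table(solo, types = "TCell")$hub), c("TCell", "TCell"))
})
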