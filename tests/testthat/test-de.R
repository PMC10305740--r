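test_that("exact rank-sum p equals exhaustive enumeration on small groups", {
  withr::with_seed(17, {
    for (n1 in 2:5) {
      for (n2 in 2:5) {
        x <- runif(n1)
        y <- runif(n2)
        expect_equal(agenoise:::rank_sum_p(c(x, y), n1),
                     enum_ranksum_p(x, y), tolerance = 1e-12)
      }
    }
  })
  # fully separated groups of 3: the doubled extreme tail is 2/20
  expect_equal(agenoise:::rank_sum_p(c(1, 2, 3, 4, 5, 6), 3), 0.1,
               tolerance = 1e-12)
})

test_that("the tied/normal path agrees with the reference implementation", {
  withr::with_seed(18, {
    for (i in 1:20) {
      x <- rpois(40, 1)
      y <- rpois(35, 1.4)
      expect_equal(agenoise:::rank_sum_p(c(x, y), 40),
                   stats::wilcox.test(x, y, exact = FALSE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment matches the brute-force step-up and p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  withr::with_seed(19, {
    for (i in 1:50) {
      p <- round(runif(sample(2:80, 1)), sample(1:3, 1)) # duplicates likely
      adj <- benjamini_hochberg(p)
      expect_equal(adj, brute_bh(p), tolerance = 1e-12)
      expect_equal(adj, stats::p.adjust(p, "BH"), tolerance = 1e-12)
      expect_true(all(adj >= p))
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-15))
    }
  })
})

test_that("identical group expression gives p = 1 and zero fold change", {
  # two groups with the same per-cell expression profile, constant per group
  m <- matrix(rep(c(4L, 2L, 1L), 12), nrow = 3)
  colnames(m) <- sprintf("c%02d", 1:12)
  cells <- tibble::tibble(cell = colnames(m),
                          sample = rep(c("y1", "y2", "o1", "o2"), each = 3),
                          age = rep(c("young", "old"), each = 6),
                          cell_type = "A")
  ds <- normalize_counts(toy_dataset(m, gene_names = paste0("g", 1:3),
                                     cells = cells))
  degs <- wilcoxon_deg(ds, "A")
  expect_true(all(degs$p_value == 1))
  expect_true(all(degs$log_fc == 0))
  expect_true(all(!degs$significant))
})

test_that("DEG table satisfies its invariants on simulated data", {
  ds <- null_normalized(seed = 23L, cells_per_sample = 25L, n_genes = 300L)
  degs <- run_deg(ds)
  expect_equal(degs$significant,
               abs(degs$log_fc) > 0.25 & degs$adj_p < 0.05)
  expect_true(all(degs$adj_p >= degs$p_value))
  expect_identical(degs$direction[degs$log_fc > 0] == "up",
                   rep(TRUE, sum(degs$log_fc > 0)))
  expect_identical(degs$direction[degs$log_fc < 0] == "down",
                   rep(TRUE, sum(degs$log_fc < 0)))
  expect_error(wilcoxon_deg(ds, "Nonexistent"), "empty|at least")
})

test_that("a strong but small-fold-change gene is not called significant", {
  # gene 1: old is a deterministic upward shift of young, but the fold
  # change in natural-log units stays below 0.25
  ny <- no <- 30L
  m <- matrix(0L, nrow = 2, ncol = ny + no)
  m[1, ] <- c(rep(c(100L, 101L), ny / 2), rep(c(110L, 111L), no / 2))
  m[2, ] <- 50L # keeps library sizes comparable
  colnames(m) <- sprintf("c%02d", seq_len(ny + no))
  cells <- tibble::tibble(cell = colnames(m),
                          sample = rep(c("y1", "o1"), c(ny, no)),
                          age = rep(c("young", "old"), c(ny, no)),
                          cell_type = "A")
  ds <- normalize_counts(toy_dataset(m, gene_names = c("g1", "g2"),
                                     cells = cells))
  degs <- wilcoxon_deg(ds, "A")
  g1 <- degs[degs$gene == "g1", ]
  expect_lt(g1$adj_p, 0.01)
  expect_lt(abs(g1$log_fc), 0.25)
  expect_false(g1$significant)
})

test_that("Welch marker statistics match the scalar formula and t.test", {
  withr::with_seed(29, {
    m <- matrix(rpois(4 * 20, 5) + 1L, nrow = 4)
  })
  colnames(m) <- sprintf("c%02d", 1:20)
  cells <- tibble::tibble(cell = colnames(m),
                          sample = "s1",
                          age = "young",
                          cell_type = rep(c("A", "B"), each = 10))
  ds <- normalize_counts(toy_dataset(m, gene_names = paste0("g", 1:4),
                                     cells = cells))
  mk <- ttest_markers(ds)
  M <- as.matrix(ds$lognorm)
  for (g in paste0("g", 1:4)) {
    a <- M[g, 1:10]
    b <- M[g, 11:20]
    tt <- stats::t.test(a, b)
    row <- mk[mk$gene == g & mk$cell_type == "A", ]
    # hand-applied Welch formula
    t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 10 + var(b) / 10)
    expect_equal(row$t_statistic, t_hand, tolerance = 1e-9)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("an exclusive gene is the top-ranked marker of its cell type", {
  withr::with_seed(30, {
    m <- matrix(rpois(6 * 24, 2), nrow = 6)
  })
  m[1, ] <- 0L
  m[1, 1:12] <- 20L # gene 1 only in cell type A
  colnames(m) <- sprintf("c%02d", 1:24)
  cells <- tibble::tibble(cell = colnames(m), sample = "s1", age = "young",
                          cell_type = rep(c("A", "B"), each = 12))
  ds <- normalize_counts(toy_dataset(m, gene_names = paste0("g", 1:6),
                                     cells = cells))
  mk <- ttest_markers(ds)
  a <- mk[mk$cell_type == "A", ]
  expect_equal(a$gene[which.max(a$log_fc)], "g1")
  expect_true(a$significant[a$gene == "g1"])
})

test_that("shared-DEG aggregation equals an exhaustive scan", {
  for (seed in 1:5) {
    tab <- random_deg_table(seed = seed)
    got <- shared_degs(tab, min_celltypes = 3L)
    # brute-force scan over genes
    for (g in unique(tab$gene)) {
      rows <- tab[tab$gene == g & tab$significant, ]
      n_ct <- length(unique(rows$cell_type))
      if (n_ct >= 3) {
        hit <- got[got$gene == g, ]
        expect_equal(nrow(hit), 1)
        expect_equal(hit$n_celltypes_de, n_ct)
        cls <- if (all(rows$direction == "up")) "consistently_up"
          else if (all(rows$direction == "down")) "consistently_down"
          else "mixed"
        expect_equal(hit$direction_class, cls)
      } else {
        expect_false(g %in% got$gene)
      }
    }
    # invariance to row order
    shuf <- withr::with_seed(seed, tab[sample(nrow(tab)), ])
    class(shuf) <- class(tab)
    expect_equal(shared_degs(shuf, 3L), got)
  }
})

test_that("shared-DEG direction classes cover the boundary cases", {
  tab <- tibble::tibble(
    gene = c(rep("up5", 5), rep("solo", 1), rep("mix", 5)),
    cell_type = c(paste0("ct", 1:5), "ct1", paste0("ct", 1:5)),
    log_fc = c(rep(1, 5), 1, c(1, 1, 1, -1, -1)),
    p_value = 0.001, adj_p = 0.001,
    direction = c(rep("up", 5), "up", c("up", "up", "up", "down", "down")),
    significant = TRUE
  )
  class(tab) <- c("deg_table", class(tab))
  got <- shared_degs(tab, min_celltypes = 5L)
  expect_setequal(got$gene, c("up5", "mix"))
  expect_equal(got$direction_class[got$gene == "up5"], "consistently_up")
  expect_equal(got$direction_class[got$gene == "mix"], "mixed")
})

test_that("hub-gene scores equal brute-force counting with stable ordering", {
  tab <- random_deg_table(seed = 11L)
  got <- gene_hub_scores(tab)
  for (g in unique(tab$gene)) {
    expect_equal(got$score[got$gene == g],
                 length(unique(tab$cell_type[tab$gene == g & tab$significant])))
  }
  expect_true(all(diff(got$score) <= 0))
  ties <- split(got$gene, got$score)
  expect_true(all(vapply(ties, function(v) !is.unsorted(v), logical(1))))
})

test_that("the rank-sum test holds its size on null genes", {
  # 10,000 genes with no age effect, ~300 cells in one cell type: the raw
  # p < 0.05 rate should sit near the nominal level (discreteness of sparse
  # counts makes it mildly conservative)
  cfg <- simulation_config(n_genes = 10000L, cell_types = c(A = 1),
                           cells_per_sample = 75L, seed = 42L)
  sim <- simulate_dataset(cfg)
  ds <- normalize_counts(filter_cells(sim$dataset, qc_thresholds(0L, 1),
                                      verbose = FALSE))
  degs <- wilcoxon_deg(ds, "A")
  rate <- mean(degs$p_value < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})
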