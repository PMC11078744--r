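make_pairs <- function(df) {
  df$length_cM <- df$end_cM - df$start_cM
  if (!"state" %in% names(df)) df$state <- "IBD1"
  ibd_pairs_from_segments(df)
}

seg_row <- function(id_a, id_b, len, n_snps = NULL, chrom = "chr1") {
  if (is.null(n_snps)) n_snps <- round(len * 250)
  data.frame(id_a = id_a, id_b = id_b, chrom = chrom, start_cM = 0,
             end_cM = len, n_snps = n_snps, stringsAsFactors = FALSE)
}

test_that("the three segment filters implement the published rules", {
  # a single 14-cM segment is not enough (one segment below 16 cM)
  p <- make_pairs(seg_row("A", "B", 14))
  expect_equal(nrow(filter_edges(p)), 0)
  # two 13-cM segments qualify, weight 13
  p <- make_pairs(rbind(seg_row("A", "B", 13),
                        seg_row("A", "B", 13, chrom = "chr2")))
  e <- filter_edges(p)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 13)
  # one 20-cM segment qualifies, weight 20
  e <- filter_edges(make_pairs(seg_row("A", "B", 20)))
  expect_equal(e$weight, 20)
  # density filter: 20 cM with only 150 SNPs/cM is discarded
  e <- filter_edges(make_pairs(seg_row("A", "B", 20, n_snps = 3000)))
  expect_equal(nrow(e), 0)
  # low-coverage individuals are dropped entirely
  meta <- data.frame(id = c("A", "B"), snp_count = c(7e5, 4e5))
  e <- filter_edges(make_pairs(seg_row("A", "B", 20)), meta)
  expect_equal(nrow(e), 0)
})

test_that("filter rules agree with rule-by-rule brute force on random segment sets", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    segs <- do.call(rbind, lapply(seq_len(n), function(i) {
      seg_row(sample(c("A", "B", "C"), 1), sample(c("D", "E"), 1),
              runif(1, 4, 30), n_snps = round(runif(1, 100, 300) * 10),
              chrom = sample(paste0("chr", 1:5), 1))
    }))
    segs$n_snps <- round((segs$end_cM - segs$start_cM) *
                           runif(nrow(segs), 150, 300))
    p <- make_pairs(segs)
    got <- filter_edges(p)
    # brute force: apply the three rules independently
    s <- p$segments
    s <- s[s$length_cM > 8 & s$n_snps / s$length_cM > 220, , drop = FALSE]
    s <- s[s$length_cM > 12, , drop = FALSE]
    want <- do.call(rbind, lapply(
      split(s, paste(s$id_a, s$id_b)), function(d) {
        if (max(d$length_cM) >= 16 || nrow(d) >= 2) {
          data.frame(id_a = d$id_a[1], id_b = d$id_b[1],
                     weight = max(d$length_cM))
        }
      }))
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$id_a, want$id_b), ]
      expect_equal(got$weight, want$weight)
      expect_equal(got$id_a, want$id_a)
    }
  }
})

test_that("edge filtering is idempotent", {
  set.seed(32)
  segs <- do.call(rbind, lapply(1:8, function(i) {
    seg_row("A", "B", runif(1, 6, 25), chrom = paste0("chr", i))
  }))
  p <- make_pairs(segs)
  e1 <- filter_edges(p)
  # re-feed the surviving segments through the filter
  kept <- p$segments[p$segments$length_cM > 12 &
                       p$segments$n_snps / p$segments$length_cM > 220, ]
  e2 <- filter_edges(ibd_pairs_from_segments(kept))
  expect_equal(e1, e2)
})

test_that("network statistics match hand calculations on a two-site fixture", {
  fx <- hand_network_fixture()
  net <- build_network(fx$edges, fx$individuals)
  expect_equal(nrow(net$nodes), 5)  # b3 has no edge
  stats <- node_stats(net)
  rownames(stats) <- stats$id
  # hand enumeration: a1-a2 (20), a1-a3 (30), a2-a3 (25) within A;
  # a3-b1 (15) across; b1-b2 (40) within B
  expect_equal(stats["a1", "k"], 2)
  expect_equal(stats["a3", "k"], 3)
  expect_equal(stats["a3", "w"], 70)
  expect_equal(stats["a3", "k_B"], 1)
  expect_equal(stats["a3", "kB_over_k"], 1 / 3)
  expect_equal(stats["b1", "kB_over_k"], 1 / 2)
  expect_equal(stats["a1", "kB_over_k"], 0)
  # identities on every node set
  expect_equal(sum(stats$k), 2 * nrow(net$edges))
  expect_equal(sum(stats$w), 2 * sum(net$edges$weight))
  expect_true(all(stats$k == stats$k_W + stats$k_B))
})

test_that("triangle within one site and a single cross-site edge behave as expected", {
  meta <- data.frame(id = c("x", "y", "z"), site = "A", sex = "male",
                     age_class = "adult", stringsAsFactors = FALSE)
  tri <- data.frame(id_a = c("x", "x", "y"), id_b = c("y", "z", "z"),
                    weight = 10, stringsAsFactors = FALSE)
  st <- node_stats(build_network(tri, meta))
  expect_true(all(st$k == 2))
  expect_true(all(st$k_B == 0))
  expect_true(all(st$kB_over_k == 0))
  meta2 <- data.frame(id = c("p", "q"), site = c("A", "B"), sex = "male",
                      age_class = "adult", stringsAsFactors = FALSE)
  st2 <- node_stats(build_network(
    data.frame(id_a = "p", id_b = "q", weight = 12), meta2))
  expect_true(all(st2$kB_over_k == 1))
})

test_that("the adults-only restriction removes subadult endpoints", {
  meta <- data.frame(id = c("a", "b", "c"), site = "A", sex = "male",
                     age_class = c("adult", "subadult", "adult"),
                     stringsAsFactors = FALSE)
  edges <- data.frame(id_a = c("a", "a"), id_b = c("b", "c"),
                      weight = c(20, 25), stringsAsFactors = FALSE)
  net <- build_network(edges, meta, adults_only = TRUE)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(net$nodes$id), c("a", "c"))
  empty <- build_network(edges[0, ], meta)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("KS permutation test handles analytic edge cases", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_permutation_test(x, x, n_perm = 200, seed = 1)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disj <- ks_permutation_test(1:6, 7:12, n_perm = 200, seed = 2)
  expect_equal(disj$D, 1)
  expect_gte(disj$p, 1 / 201)
  expect_lt(disj$p, 0.05)
  expect_error(ks_permutation_test(numeric(0), x), "nonempty")
  # D agrees with the reference implementation
  set.seed(3)
  a <- rnorm(40); b <- rnorm(35, 0.5)
  expect_equal(ks_permutation_test(a, b, n_perm = 10, seed = 4)$D,
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
})

test_that("KS permutation p-values are calibrated under the null", {
  set.seed(33)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    a <- rnorm(25)
    b <- rnorm(25)
    ks_permutation_test(a, b, n_perm = 199)$p <= 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.01)
})

test_that("Welch test matches the reference implementation and is calibrated", {
  set.seed(34)
  a <- rnorm(20, 0, 1)
  b <- rnorm(15, 0.8, 2)
  got <- welch_t_test(a, b)
  want <- stats::t.test(a, b)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$df, unname(want$parameter))
  expect_equal(got$p, want$p.value)
  expect_equal(welch_t_test(a, a)$t, 0)
  expect_equal(welch_t_test(a, a)$p, 1)
  expect_error(welch_t_test(1, b), "size")
  # type-I error under the null
  n_rep <- 2000
  rej <- vapply(seq_len(n_rep), function(i) {
    welch_t_test(rnorm(15), rnorm(20))$p <= 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("multi-site simulations show the female between-site excess", {
  diffs <- vapply(1:8, function(s) {
    b <- generate_scenario(scenario_spec(
      "multi_site", seed = 40 + s,
      overrides = list(n_generations = 4, n_founder_males = 2,
                       mean_sons_per_union = 1.3,
                       mean_daughters_per_union = 1.3,
                       max_reproducing_males = 8)))
    edges <- filter_edges(b$pairs, b$individuals)
    if (nrow(edges) == 0) return(NA_real_)
    st <- node_stats(build_network(edges, b$individuals))
    mean(st$kB_over_k[st$sex == "female"], na.rm = TRUE) -
      mean(st$kB_over_k[st$sex == "male"], na.rm = TRUE)
  }, 1)
  diffs <- diffs[!is.na(diffs)]
  expect_gt(mean(diffs), 0)
  # and at least one between-site edge with a female endpoint exists
  b <- generate_scenario(scenario_spec(
    "multi_site", seed = 49,
    overrides = list(n_generations = 4, n_founder_males = 2,
                     mean_sons_per_union = 1.3,
                     mean_daughters_per_union = 1.3,
                     max_reproducing_males = 8)))
  edges <- filter_edges(b$pairs, b$individuals)
  site <- setNames(b$individuals$site, b$individuals$id)
  sex <- setNames(b$individuals$sex, b$individuals$id)
  cross <- edges[site[edges$id_a] != site[edges$id_b], ]
  expect_gt(nrow(cross), 0)
  expect_true(any(sex[cross$id_a] == "female" |
                    sex[cross$id_b] == "female"))
})
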