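test_that("pair summaries follow the kinship arithmetic", {
  m <- default_genetic_map()
  expect_equal(pair_summary(NULL, m)$kinship, 0)
  # full-genome IBD1 -> kinship 1/4 (parent-child)
  full <- data.frame(chrom = m$chrom, start_cM = 0, end_cM = m$length_cM,
                     length_cM = m$length_cM, state = "IBD1",
                     stringsAsFactors = FALSE)
  s <- pair_summary(full, m)
  expect_equal(s$kinship, 0.25)
  expect_equal(classify_degree(s), "parent_child")
  # no segments -> unrelated
  expect_equal(classify_degree(pair_summary(full[0, ], m)), "unrelated")
})

test_that("degree bins sit at the log2 midpoints and are monotone in kinship", {
  mk <- function(phi) list(kinship = phi, p1 = 4 * phi, p2 = 0)
  closeness <- c(unrelated = 0, third = 1, second = 2, parent_child = 3,
                 first_ambiguous = 3, sibling = 3, identical = 4)
  phis <- seq(0, 0.5, by = 0.002)
  classes <- vapply(phis, function(p) classify_degree(mk(p)), character(1))
  ranks <- closeness[classes]
  expect_true(all(diff(ranks) >= 0))
  expect_equal(unname(classes[phis == 0.06]), "third")
  expect_equal(unname(classes[phis == 0.12]), "second")
  expect_equal(unname(classes[phis == 0.25]), "parent_child")
  # sibling subtype needs substantial IBD2
  expect_equal(classify_degree(list(kinship = 0.25, p1 = 0.5, p2 = 0.25)),
               "sibling")
  expect_equal(classify_degree(list(kinship = 0.25, p1 = 0.6, p2 = 0.05)),
               "first_ambiguous")
})

test_that("perfect observation separates first/second degree nearly perfectly", {
  ped <- patrikin:::second_degree_pedigree()
  m <- default_genetic_map()
  set.seed(20)
  n_rep <- 120
  got <- replicate(n_rep, {
    g <- drop_genomes(ped, m)
    c(pc = classify_degree(pair_summary(pairwise_ibd(g[["F"]], g[["C"]], m), m)),
      sib = classify_degree(pair_summary(pairwise_ibd(g[["F"]], g[["U"]], m), m)),
      av = classify_degree(pair_summary(pairwise_ibd(g[["U"]], g[["C"]], m), m)),
      gp = classify_degree(pair_summary(pairwise_ibd(g[["GF"]], g[["C"]], m), m)))
  })
  expect_equal(mean(got["pc", ] == "parent_child"), 1)  # zero confusion
  expect_gte(mean(got["sib", ] == "sibling"), 0.95)
  expect_gte(mean(got["av", ] == "second"), 0.95)
  expect_gte(mean(got["gp", ] == "second"), 0.95)
})

test_that("reference distributions reproduce the avuncular/grandparent contrast", {
  refs <- build_reference_distributions(n_pedigrees = 60, seed = 21)
  av <- refs$classes$avuncular
  gp <- refs$classes$grandparent
  hs <- refs$classes$half_sibling
  expect_gt(mean(av$n_segments), mean(gp$n_segments))
  expect_gt(mean(gp$mean_length_cM), mean(av$mean_length_cM))
  # half siblings overlap both other classes: completely on total IBD
  # (all three classes share a quarter of the genome in expectation) and
  # on segment count they straddle the avuncular side while their mean
  # length lies between the two class means
  overlaps <- function(rng, iqr) rng[1] <= iqr[2] && rng[2] >= iqr[1]
  expect_true(overlaps(range(hs$total_cM),
                       quantile(av$total_cM, c(0.25, 0.75))))
  expect_true(overlaps(range(hs$total_cM),
                       quantile(gp$total_cM, c(0.25, 0.75))))
  expect_true(overlaps(range(hs$n_segments),
                       quantile(av$n_segments, c(0.25, 0.75))))
  expect_true(mean(hs$mean_length_cM) > mean(av$mean_length_cM) &&
                mean(hs$mean_length_cM) < mean(gp$mean_length_cM))
  expect_error(build_reference_distributions(n_pedigrees = 1), "n_pedigrees")
})

test_that("second-degree subtype calls follow the kernel likelihood", {
  refs <- build_reference_distributions(n_pedigrees = 40, seed = 22)
  gp <- refs$classes$grandparent
  centroid <- list(n_segments = round(mean(gp$n_segments)),
                   mean_length_cM = mean(gp$mean_length_cM))
  expect_equal(classify_second_degree(centroid, refs)$subtype, "grandparent")
  # exact tie -> ambiguous: all classes share the same sample
  tied <- refs
  tied$classes <- list(avuncular = gp, grandparent = gp, half_sibling = gp)
  expect_equal(classify_second_degree(centroid, tied)$subtype, "ambiguous")
  bad <- refs
  bad$classes <- list()
  expect_error(classify_second_degree(centroid, bad), "empty")
})

test_that("held-out subtype accuracy beats the majority baseline, half-sibs confuse", {
  refs <- build_reference_distributions(n_pedigrees = 60, seed = 23)
  ped <- patrikin:::second_degree_pedigree()
  m <- default_genetic_map()
  model <- observation_model()
  set.seed(24)
  n_rep <- 80
  calls <- sapply(seq_len(n_rep), function(i) {
    g <- drop_genomes(ped, m)
    one <- function(a, b) {
      segs <- degrade_segments(pairwise_ibd(g[[a]], g[[b]], m), model, m)
      classify_second_degree(
        list(n_segments = nrow(segs),
             mean_length_cM = if (nrow(segs)) mean(segs$length_cM) else 0),
        refs)$subtype
    }
    c(av = one("U", "C"), gp = one("GF", "C"), hs = one("C", "H"))
  })
  av_acc <- mean(calls["av", ] == "avuncular")
  gp_acc <- mean(calls["gp", ] == "grandparent")
  hs_acc <- mean(calls["hs", ] == "half_sibling")
  expect_gt(av_acc, 1 / 3)
  expect_gt(gp_acc, 1 / 3)
  # the overlap shows as mutual avuncular/half-sib confusion dwarfing
  # either class's confusion with grandparent-grandchild
  av_as_hs <- mean(calls["av", ] == "half_sibling")
  hs_as_av <- mean(calls["hs", ] == "avuncular")
  av_as_gp <- mean(calls["av", ] == "grandparent")
  hs_as_gp <- mean(calls["hs", ] == "grandparent")
  expect_gt(av_as_hs + hs_as_av, av_as_gp + hs_as_gp)
  # grandparent-grandchild is the cleanly separable class
  expect_gt(gp_acc, max(av_acc, hs_acc) - 0.15)
})

test_that("consanguinity flagging meets its calibration targets", {
  m <- default_genetic_map()
  # empty ROH -> clean call
  none <- detect_consanguinity(
    data.frame(chrom = character(), start_cM = numeric(),
               end_cM = numeric(), length_cM = numeric()), m)
  expect_equal(none$sum_roh_gt4_cM, 0)
  expect_false(none$flagged)
  # outbred individuals essentially never flag
  set.seed(25)
  ob <- outbred_pedigree()
  fp <- replicate(200, {
    detect_consanguinity(roh_segments(drop_genomes(ob)[["K"]]), m)$flagged
  })
  expect_lte(mean(fp), 0.05)
  # offspring of first cousins flag nearly always
  fc <- first_cousin_pedigree()
  tp <- replicate(200, {
    detect_consanguinity(roh_segments(drop_genomes(fc)[["K"]]), m)$flagged
  })
  expect_gte(mean(tp), 0.95)
  # offspring of second cousins (F = 1/64) are caught at >= 80%
  sc <- second_cousin_pedigree()
  tp2 <- replicate(200, {
    detect_consanguinity(roh_segments(drop_genomes(sc)[["K"]]), m)$flagged
  })
  expect_gte(mean(tp2), 0.8)
})

test_that("classify_pairs attaches subtypes to second-degree pairs", {
  ped <- patrikin:::second_degree_pedigree()
  m <- default_genetic_map()
  set.seed(26)
  g <- drop_genomes(ped, m)
  pairs <- compute_pairwise_ibd(g, ids = c("GF", "F", "U", "C"), map = m)
  refs <- build_reference_distributions(n_pedigrees = 30, seed = 27)
  calls <- classify_pairs(pairs, m, refs = refs)
  second <- calls[calls$degree == "second", ]
  expect_true(all(!is.na(second$subtype)))
  first <- calls[calls$degree %in% patrikin:::first_degree_labels, ]
  expect_true(all(is.na(first$subtype)))
  # writer emits the KIN-style dialect
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relatedness_calls(calls, path)
  expect_true(all(c("degree", "kinship", "max_ibd_cM") %in%
                    names(utils::read.delim(path))))
})
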