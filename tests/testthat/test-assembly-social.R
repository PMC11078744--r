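test_that("a forced parent-child orientation produces a father-son edge", {
  calls <- data.frame(id_a = "A", id_b = "B", degree = "parent_child",
                      stringsAsFactors = FALSE)
  meta <- data.frame(id = c("A", "B"), sex = c("male", "male"),
                     site = "S", age_class = c("adult", "subadult"),
                     birth_year = c(NA, NA), phase = c("early", "early"),
                     y_haplogroup = c("J1a", "J1a"),
                     mt_haplogroup = c("H1", "U5"), stringsAsFactors = FALSE)
  peds <- assemble_pedigrees(calls, meta)
  expect_length(peds, 1)
  ind <- peds[[1]]$individuals
  expect_equal(ind$father[ind$id == "B"], "A")
  expect_equal(nrow(attr(peds[[1]], "conflicts")), 0)
})

test_that("haplogroup mismatches yield conflict reports, not guesses", {
  calls <- data.frame(id_a = "M", id_b = "C", degree = "parent_child",
                      stringsAsFactors = FALSE)
  meta <- data.frame(id = c("M", "C"), sex = c("female", "male"), site = "S",
                     age_class = c("adult", "subadult"),
                     birth_year = c(500, 530), phase = "early",
                     y_haplogroup = c(NA, "J1a"),
                     mt_haplogroup = c("H1", "K2"), stringsAsFactors = FALSE)
  peds <- assemble_pedigrees(calls, meta)
  conf <- attr(peds[[1]], "conflicts")
  expect_equal(nrow(conf), 1)
  expect_match(conf$reason, "mtDNA")
  expect_true(all(is.na(peds[[1]]$individuals$mother)))
  # with enforcement off the edge is accepted
  peds2 <- assemble_pedigrees(calls, meta,
                              assembly_constraints(
                                enforce_mt_mother_child = FALSE))
  expect_equal(peds2[[1]]$individuals$mother[
    peds2[[1]]$individuals$id == "C"], "M")
})

test_that("equal ages leave parent-child orientation unresolved", {
  calls <- data.frame(id_a = "A", id_b = "B", degree = "parent_child",
                      stringsAsFactors = FALSE)
  meta <- data.frame(id = c("A", "B"), sex = "male", site = "S",
                     age_class = "adult", birth_year = c(500, 500),
                     phase = "early", stringsAsFactors = FALSE)
  peds <- assemble_pedigrees(calls, meta)
  expect_match(attr(peds[[1]], "conflicts")$reason, "orientation")
})

test_that("sibling sets with no observed parent get one inferred parent", {
  calls <- data.frame(id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
                      degree = "sibling", stringsAsFactors = FALSE)
  meta <- data.frame(id = c("A", "B", "C"), sex = "male", site = "S",
                     age_class = "adult", birth_year = c(500, 502, 504),
                     phase = "early", mt_haplogroup = "H1",
                     stringsAsFactors = FALSE)
  peds <- assemble_pedigrees(calls, meta)
  ind <- peds[[1]]$individuals
  ghosts <- ind$id[grepl("^inferred_", ind$id)]
  expect_length(ghosts, 2)  # one father, one mother
  expect_equal(length(unique(ind$father[match(c("A", "B", "C"), ind$id)])), 1)
})

test_that("assembly recovers the simulated truth under perfect observation", {
  cfg <- sim_config(n_generations = 4, n_founder_males = 2,
                    polygyny_prob = 0.2, levirate_prob = 0.2, seed = 42)
  ped <- apply_burial_sampling(simulate_community(cfg), cfg, seed = 43)
  obs <- observed_individuals(ped)
  genomes <- drop_genomes(ped, seed = 44)
  pairs <- compute_pairwise_ibd(genomes, ids = obs$id, model = NULL)
  calls <- classify_pairs(pairs)
  peds <- assemble_pedigrees(calls, obs)
  edge_key <- function(child, parent) sort(paste(child, parent))
  truth <- ped$individuals
  tr <- rbind(data.frame(child = truth$id, parent = truth$father),
              data.frame(child = truth$id, parent = truth$mother))
  tr <- tr[!is.na(tr$parent) & tr$child %in% obs$id &
             tr$parent %in% obs$id, ]
  asm <- do.call(rbind, lapply(peds, function(p) {
    ii <- p$individuals
    rbind(data.frame(child = ii$id, parent = ii$father),
          data.frame(child = ii$id, parent = ii$mother))
  }))
  asm <- asm[!is.na(asm$parent) & !grepl("^inferred_", asm$parent), ]
  expect_identical(edge_key(asm$child, asm$parent),
                   edge_key(tr$child, tr$parent))
})

test_that("patriliny metrics match a hand-enumerated toy pedigree", {
  # founder M with two sons and a daughter by his two exogamous wives
  ind <- ped_df(c("M", "W1", "W2", "S1", "S2", "D1"),
                c("male", "female", "female", "male", "male", "female"),
                c(NA, NA, NA, "M", "M", "M"),
                c(NA, NA, NA, "W1", "W1", "W2"))
  ind$founder <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ped <- new_pedigree_graph(
    ind, data.frame(male_id = c("M", "M"), female_id = c("W1", "W2")))
  sm <- patriliny_metrics(ped)
  expect_equal(sm$n_sons, 2)
  expect_equal(sm$n_daughters, 1)
  expect_equal(sm$n_exogamous_mothers, 2)
  expect_equal(sm$n_lineage_mothers, 0)
  expect_equal(sm$patriline_purity, 1.0)
})

test_that("a father breaking the Y line lowers patriline purity", {
  ind <- ped_df(c("M", "W", "S", "WS", "G", "M2", "W2", "S2"),
                c("male", "female", "male", "female", "male",
                  "male", "female", "male"),
                c(NA, NA, "M", NA, "S", NA, NA, "M2"),
                c(NA, NA, "W", NA, "WS", NA, NA, "W2"))
  ind$founder <- is.na(ind$father)
  ind$y_haplogroup <- c("Y1", NA, "Y1", NA, "Y9", "Y2", NA, "Y2")
  ped <- new_pedigree_graph(ind, no_unions())
  sm <- patriliny_metrics(ped)
  # fathers: M (pure), S (child G carries a different Y -> impure chain
  # seen from G's father S? S itself is pure), M2 (pure); purity checked
  # along each father's own chain: G is not a father, so all three are
  # pure; make G a father to expose the break
  expect_equal(sm$patriline_purity, 1.0)
  row <- ped_df("GG", "male", "G", "WS")
  row$founder <- FALSE
  row$y_haplogroup <- "Y9"
  ind2 <- rbind(ind, row)
  sm2 <- patriliny_metrics(new_pedigree_graph(ind2, no_unions()))
  expect_lt(sm2$patriline_purity, 1.0)
})

test_that("exogamy-rate recovery is unbiased across seeds", {
  rate <- 0.8
  n_seeds <- 60
  est <- vapply(seq_len(n_seeds), function(s) {
    cfg <- sim_config(n_generations = 4, n_founder_males = 5,
                      exogamy_rate = rate, mean_daughters_per_union = 2,
                      seed = 500 + s)
    patriliny_metrics(simulate_community(cfg))$exogamy_rate_postfounding
  }, 1)
  est <- est[!is.na(est)]
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - rate), 3 * se)
})

test_that("shared-partner detection matches the simulator's levirate log", {
  hits <- vapply(1:40, function(s) {
    cfg <- sim_config(n_generations = 3, n_founder_males = 3,
                      levirate_prob = 0.5, mean_sons_per_union = 1.5,
                      seed = 900 + s)
    ped <- simulate_community(cfg)
    shared <- detect_shared_partner_unions(ped)
    ev <- ped$levirate_events
    rel_map <- c(full_brother = "full_brothers",
                 paternal_half_brother = "paternal_half_brothers",
                 paternal_uncle_son = "other_agnate",
                 son_by_other_partner = "father_son")
    if (nrow(shared) != nrow(ev)) return(FALSE)
    if (nrow(ev) == 0) return(TRUE)
    key_obs <- sort(paste(shared$female, shared$relation))
    key_exp <- sort(paste(ev$widow, unname(rel_map[ev$relation])))
    identical(key_obs, key_exp)
  }, logical(1))
  expect_true(all(hits))
})

test_that("partner counts match the truncated-geometric union model", {
  p <- 0.3
  cnt <- unlist(lapply(1:40, function(s) {
    cfg <- sim_config(n_generations = 3, n_founder_males = 3,
                      polygyny_prob = p, levirate_prob = 0,
                      exogamy_rate = 1, seed = 1300 + s)
    pc <- partner_counts(simulate_community(cfg))
    pc$n_partners[pc$sex == "male"]
  }))
  # males take 1 + min(Geometric(p), 3) partners: E = 1 + p + p^2 + p^3
  expected <- 1 + p + p^2 + p^3
  se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - expected), 3 * se)
  # monogamous toy pedigree: all counts 1
  ped <- nuclear_pedigree(2)
  expect_true(all(partner_counts(ped)$n_partners == 1))
})

test_that("unrelated-individual sex counts use same-site close calls only", {
  calls <- data.frame(id_a = c("A", "C"), id_b = c("B", "D"),
                      degree = c("parent_child", "third"),
                      stringsAsFactors = FALSE)
  meta <- data.frame(id = c("A", "B", "C", "D", "E", "F"),
                     site = c("S1", "S1", "S1", "S2", "S1", "S1"),
                     sex = c("male", "male", "male", "female", "female",
                             "female"), stringsAsFactors = FALSE)
  # C-D is cross-site, so C, D count as unrelated at their own sites
  tab <- unrelated_sex_counts(calls, meta)
  get <- function(site, sex) tab$n[tab$site == site & tab$sex == sex]
  expect_equal(get("S1", "male"), 1)    # C
  expect_equal(get("S1", "female"), 2)  # E, F
  expect_equal(get("S2", "female"), 1)  # D
})
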