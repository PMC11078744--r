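# pedigree fixtures built in code; all parent links child -> (father, mother)

ped_df <- function(id, sex, father, mother) {
  data.frame(id = id, sex = sex, father = father, mother = mother,
             stringsAsFactors = FALSE)
}

no_unions <- function() {
  data.frame(male_id = character(), female_id = character(),
             stringsAsFactors = FALSE)
}

# founder couple with n children
nuclear_pedigree <- function(n_children = 2) {
  kids <- sprintf("K%d", seq_len(n_children))
  new_pedigree_graph(
    ped_df(c("F", "M", kids),
           c("male", "female", rep("male", n_children)),
           c(NA, NA, rep("F", n_children)),
           c(NA, NA, rep("M", n_children))),
    data.frame(male_id = "F", female_id = "M", stringsAsFactors = FALSE))
}

# offspring K of two full siblings (F = 1/4)
sibling_union_pedigree <- function() {
  new_pedigree_graph(
    ped_df(c("GF", "GM", "S1", "S2", "K"),
           c("male", "female", "male", "female", "male"),
           c(NA, NA, "GF", "GF", "S1"),
           c(NA, NA, "GM", "GM", "S2")),
    no_unions())
}

# offspring K of first cousins (F = 1/16)
first_cousin_pedigree <- function() {
  new_pedigree_graph(
    ped_df(c("GF", "GM", "P1", "P2", "W1", "W2", "C1", "C2", "K"),
           c("male", "female", "male", "male", "female", "female",
             "male", "female", "male"),
           c(NA, NA, "GF", "GF", NA, NA, "P1", "P2", "C1"),
           c(NA, NA, "GM", "GM", NA, NA, "W1", "W2", "C2")),
    no_unions())
}

# offspring K of second cousins (F = 1/64)
second_cousin_pedigree <- function() {
  new_pedigree_graph(
    ped_df(c("G1", "G2", "A", "B", "SA", "SB", "C1", "C2", "S1", "S2",
             "D1", "D2", "K"),
           c("male", "female", "male", "male", "female", "female",
             "male", "male", "female", "female", "male", "female", "male"),
           c(NA, NA, "G1", "G1", NA, NA, "A", "B", NA, NA, "C1", "C2",
             "D1"),
           c(NA, NA, "G2", "G2", NA, NA, "SA", "SB", NA, NA, "S1", "S2",
             "D2")),
    no_unions())
}

# child of two unrelated founders (outbred)
outbred_pedigree <- function() {
  new_pedigree_graph(
    ped_df(c("F", "M", "K"), c("male", "female", "male"),
           c(NA, NA, "F"), c(NA, NA, "M")),
    no_unions())
}

# six-node, two-site network fixture with hand-computable statistics
hand_network_fixture <- function() {
  individuals <- data.frame(
    id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    site = c("A", "A", "A", "B", "B", "B"),
    sex = c("male", "male", "female", "male", "female", "female"),
    age_class = "adult", snp_count = 7e5, stringsAsFactors = FALSE)
  edges <- data.frame(
    id_a = c("a1", "a1", "a2", "a3", "b1"),
    id_b = c("a2", "a3", "a3", "b1", "b2"),
    weight = c(20, 30, 25, 15, 40), n_segments = 1L,
    stringsAsFactors = FALSE)
  list(individuals = individuals, edges = edges)
}

# metadata table for io tests
write_individuals_fixture <- function(path) {
  writeLines(c(
    "id\tsite\tsex\tage_class\tage_min\tage_max\tphase\ty_haplogroup\tmt_haplogroup\tsnp_count",
    "RKF001\tRK\tmale\tadult\t25\t35\tearly\tJ1a\tH5\t700000",
    "RKF002\tRK\tfemale\tsubadult\t5\t9\tearly\t\tU4\t650000"),
    path)
  path
}

map1 <- function(L = 100) genetic_map("chr1", L)
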