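#' @title Pairwise relatedness classification from IBD summaries
#' @description Degrees of relatedness are inferred from segment summaries
#'   (total IBD1/IBD2, segment count, maximum and mean segment length)
#'   rather than from genotype likelihoods: the upstream HMM callers that
#'   this module stands in for emit exactly these summaries.
#' @name relatedness
NULL

# kinship-coefficient bin edges: standard log2 midpoints between the
# expected values 1/2, 1/4, 1/8, 1/16, 1/32 for degrees 0..4
KINSHIP_CUTS <- c(identical = 2^-1.5, first = 2^-2.5, second = 2^-3.5,
                  third = 2^-4.5)

# sum of >4 cM ROH as a fraction of the map above which an individual is
# flagged consanguineous; calibrated on simulations so that offspring of
# second cousins (F = 1/64) are detected at >= 80% sensitivity while
# outbred individuals stay below 5% false positives
CONSANGUINITY_F_THRESHOLD <- 0.004
ROH_MIN_CM <- 4

#' Summarise the IBD sharing of one pair
#'
#' @param segs segment data.frame for a single pair (columns chrom,
#'   start_cM, end_cM, length_cM, state; may be empty).
#' @param map genetic map.
#' @return list with total_ibd1_cM, total_ibd2_cM, n_segments, max_ibd_cM,
#'   p1, p2 (genome fractions in IBD1/IBD2) and kinship = p1/4 + p2/2.
#' @export
pair_summary <- function(segs, map = default_genetic_map()) {
  total <- map_total_cM(map)
  if (is.null(segs) || nrow(segs) == 0) {
    return(list(total_ibd1_cM = 0, total_ibd2_cM = 0, n_segments = 0L,
                max_ibd_cM = 0, p1 = 0, p2 = 0, kinship = 0))
  }
  t1 <- sum(segs$length_cM[segs$state == "IBD1"])
  t2 <- sum(segs$length_cM[segs$state == "IBD2"])
  p1 <- t1 / total
  p2 <- t2 / total
  list(total_ibd1_cM = t1, total_ibd2_cM = t2, n_segments = nrow(segs),
       max_ibd_cM = max(segs$length_cM), p1 = p1, p2 = p2,
       kinship = p1 / 4 + p2 / 2)
}

#' Classify the degree of a pair from its summary
#'
#' Kinship bins use standard log2 midpoints: identical above 0.354, first
#' degree 0.177-0.354, second 0.088-0.177, third 0.044-0.088, otherwise
#' unrelated. Within the first degree, parent-child requires essentially
#' no IBD2 (p2 < 0.02) and near-complete IBD1 coverage (p1 > 0.9);
#' siblings require p2 >= 0.1; anything else is first-degree ambiguous.
#'
#' @param summary list from [pair_summary()] (fields kinship, p1, p2).
#' @return one of "identical", "parent_child", "sibling",
#'   "first_ambiguous", "second", "third", "unrelated".
#' @export
classify_degree <- function(summary) {
  phi <- summary$kinship
  if (phi > KINSHIP_CUTS[["identical"]]) return("identical")
  if (phi > KINSHIP_CUTS[["first"]]) {
    if (summary$p2 < 0.02 && summary$p1 > 0.9) return("parent_child")
    if (summary$p2 >= 0.1) return("sibling")
    return("first_ambiguous")
  }
  if (phi > KINSHIP_CUTS[["second"]]) return("second")
  if (phi > KINSHIP_CUTS[["third"]]) return("third")
  "unrelated"
}

first_degree_labels <- c("parent_child", "sibling", "first_ambiguous")

#' Classify every pair in an \code{ibd_pairs} object
#'
#' @param pairs an \code{ibd_pairs} object with segments.
#' @param map genetic map.
#' @param refs optional [build_reference_distributions()] output; when
#'   given, second-degree pairs receive a subtype call.
#' @return data.frame with per-pair summaries, kinship, degree and
#'   (optionally) subtype + likelihood-ratio score.
#' @export
classify_pairs <- function(pairs, map = default_genetic_map(), refs = NULL) {
  stopifnot(inherits(pairs, "ibd_pairs"))
  segs <- pairs$segments
  key <- paste(segs$id_a, segs$id_b, sep = "\r")
  groups <- split(seq_len(nrow(segs)), key)
  rows <- lapply(names(groups), function(k) {
    s <- pair_summary(segs[groups[[k]], , drop = FALSE], map)
    ids <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(id_a = ids[1], id_b = ids[2],
               total_ibd1_cM = s$total_ibd1_cM,
               total_ibd2_cM = s$total_ibd2_cM,
               n_segments = s$n_segments, max_ibd_cM = s$max_ibd_cM,
               p1 = s$p1, p2 = s$p2, kinship = s$kinship,
               degree = classify_degree(s), stringsAsFactors = FALSE)
  })
  calls <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id_a = character(), id_b = character(),
               total_ibd1_cM = numeric(), total_ibd2_cM = numeric(),
               n_segments = integer(), max_ibd_cM = numeric(),
               p1 = numeric(), p2 = numeric(), kinship = numeric(),
               degree = character(), stringsAsFactors = FALSE)
  }
  calls$subtype <- NA_character_
  calls$subtype_score <- NA_real_
  if (!is.null(refs) && nrow(calls)) {
    second <- which(calls$degree == "second")
    for (i in second) {
      sub <- classify_second_degree(
        list(n_segments = calls$n_segments[i],
             total_ibd1_cM = calls$total_ibd1_cM[i] +
               calls$total_ibd2_cM[i]), refs)
      calls$subtype[i] <- sub$subtype
      calls$subtype_score[i] <- sub$score
    }
  }
  calls
}

# the three-class second-degree benchmark pedigree: grandfather/grandmother
# -> father + uncle; father with two wives -> child and paternal half-sib.
# avuncular pair: uncle-child; grandparent pair: grandfather-child;
# half-sibling pair: child-halfsib.
second_degree_pedigree <- function() {
  ind <- data.frame(
    id = c("GF", "GM", "F", "U", "M1", "M2", "C", "H"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "male"),
    father = c(NA, NA, "GF", "GF", NA, NA, "F", "F"),
    mother = c(NA, NA, "GM", "GM", NA, NA, "M1", "M2"),
    stringsAsFactors = FALSE)
  unions <- data.frame(male_id = c("GF", "F", "F"),
                       female_id = c("GM", "M1", "M2"),
                       stringsAsFactors = FALSE)
  new_pedigree_graph(ind, unions)
}

#' Simulation-derived reference distributions for second-degree subtypes
#'
#' Simulates \code{n_pedigrees} eight-member pedigrees containing an
#' avuncular, a grandparent-grandchild and a paternal half-sibling pair,
#' transmits genomes, applies the observation model, and records the
#' summary triple (segment count, mean segment length, total IBD) per
#' relationship class. Segment count and mean length separate avuncular
#' from grandparent-grandchild pairs (more, shorter segments for
#' avuncular); half siblings overlap both.
#'
#' @param n_pedigrees number of simulated pedigrees (>= 2; 60 is the
#'   conventional choice).
#' @param seed integer seed.
#' @param model an [observation_model()] (its own seed field is ignored;
#'   this function's seed governs).
#' @param map genetic map.
#' @return object of class \code{reference_distributions}: list of
#'   data.frames (n_segments, mean_length_cM, total_cM) per class, with
#'   the simulation settings recorded.
#' @export
build_reference_distributions <- function(n_pedigrees = 60, seed = 1,
                                          model = observation_model(),
                                          map = default_genetic_map()) {
  if (n_pedigrees < 2) stop("n_pedigrees must be >= 2")
  set.seed(seed)
  model$seed <- NULL
  ped <- second_degree_pedigree()
  pairs <- list(avuncular = c("U", "C"), grandparent = c("GF", "C"),
                half_sibling = c("C", "H"))
  acc <- lapply(pairs, function(p) vector("list", n_pedigrees))
  for (r in seq_len(n_pedigrees)) {
    genomes <- drop_genomes(ped, map)
    for (cls in names(pairs)) {
      segs <- pairwise_ibd(genomes[[pairs[[cls]][1]]],
                           genomes[[pairs[[cls]][2]]], map)
      segs <- degrade_segments(segs, model, map)
      acc[[cls]][[r]] <- data.frame(
        n_segments = nrow(segs),
        mean_length_cM = if (nrow(segs)) mean(segs$length_cM) else 0,
        total_cM = sum(segs$length_cM))
    }
  }
  refs <- lapply(acc, function(x) do.call(rbind, x))
  structure(list(classes = refs, n_pedigrees = n_pedigrees, seed = seed,
                 model = model), class = "reference_distributions")
}

# product-Gaussian kernel density of x (2-vector) under a reference sample
kde2_likelihood <- function(x, ref) {
  bw1 <- max(stats::bw.nrd0(ref$n_segments), 0.5)
  bw2 <- max(stats::bw.nrd0(ref$mean_length_cM), 0.5)
  mean(stats::dnorm(x[1], ref$n_segments, bw1) *
         stats::dnorm(x[2], ref$mean_length_cM, bw2))
}

#' Second-degree subtype classification
#'
#' Chooses the relationship class (avuncular, grandparent, half_sibling)
#' maximizing a kernel-density likelihood of the observed (segment count,
#' mean segment length) under the simulation-derived reference
#' distributions; the score is the likelihood ratio of the best to the
#' second-best class, and calls with ratio below 2 are "ambiguous".
#'
#' @param summary list with fields \code{n_segments} and either
#'   \code{mean_length_cM} or \code{total_ibd1_cM} (mean length is then
#'   total/count).
#' @param refs a \code{reference_distributions} object.
#' @return list with \code{subtype} ("avuncular", "grandparent",
#'   "half_sibling" or "ambiguous"), \code{score} (likelihood ratio) and
#'   per-class likelihoods.
#' @export
classify_second_degree <- function(summary, refs) {
  stopifnot(inherits(refs, "reference_distributions"))
  if (!length(refs$classes) || !all(vapply(refs$classes, nrow, 1L) > 0)) {
    stop("empty reference distributions")
  }
  mean_len <- if (!is.null(summary$mean_length_cM)) {
    summary$mean_length_cM
  } else if (summary$n_segments > 0) {
    summary$total_ibd1_cM / summary$n_segments
  } else 0
  x <- c(summary$n_segments, mean_len)
  lik <- vapply(refs$classes, function(ref) kde2_likelihood(x, ref), 1)
  ord <- order(lik, decreasing = TRUE)
  best <- lik[ord[1]]
  second <- lik[ord[2]]
  score <- if (second > 0) best / second else Inf
  subtype <- if (is.finite(score) && score < 2) "ambiguous" else
    names(lik)[ord[1]]
  list(subtype = subtype, score = score, likelihoods = lik)
}

#' Consanguinity call from runs of homozygosity
#'
#' Sums ROH longer than 4 cM; the inbreeding estimate is that sum divided
#' by the total map length. An individual is flagged when the estimate
#' exceeds a fixed threshold (see package constants) calibrated so that
#' offspring of second cousins (F = 1/64) are detected at >= 80%
#' sensitivity with <= 5% false positives on outbred simulations.
#'
#' @param roh ROH data.frame from [roh_segments()].
#' @param map genetic map.
#' @param individual_id optional id carried through.
#' @return list with individual_id, sum_roh_gt4_cM, n_roh_gt4, f_estimate,
#'   flagged.
#' @export
detect_consanguinity <- function(roh, map = default_genetic_map(),
                                 individual_id = NA_character_) {
  long <- roh[roh$length_cM > ROH_MIN_CM, , drop = FALSE]
  s <- sum(long$length_cM)
  f <- s / map_total_cM(map)
  list(individual_id = individual_id, sum_roh_gt4_cM = s,
       n_roh_gt4 = nrow(long), f_estimate = f,
       flagged = f > CONSANGUINITY_F_THRESHOLD)
}
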