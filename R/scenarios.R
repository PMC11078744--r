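#' Scenario specification for end-to-end fixture generation
#'
#' Presets resolve to full simulation configurations:
#' \describe{
#'   \item{rk_like}{one large site, nine generations, strong patriliny,
#'     levirate on, and a community-replacement event: a new founder
#'     cohort with distinct Y lineages enters mid-sequence and takes over
#'     reproduction.}
#'   \item{multi_site}{three sites with female exchange between them.}
#'   \item{null}{unrelated individuals only, no kinship structure.}
#' }
#' Presets are structural, not calibrated to any real site's counts.
#'
#' @param preset one of "rk_like", "multi_site", "null".
#' @param seed integer seed.
#' @param overrides named list of [sim_config()] fields to override.
#' @return object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(preset = c("rk_like", "multi_site", "null"),
                          seed = 1, overrides = list()) {
  preset <- match.arg(preset)
  base <- switch(preset,
    rk_like = list(n_generations = 9, n_founder_males = 4,
                   mean_sons_per_union = 1.15,
                   mean_daughters_per_union = 1.15,
                   polygyny_prob = 0.2, levirate_prob = 0.2,
                   exogamy_rate = 0.98, daughter_emigration_prob = 0.75,
                   consanguinity_min_degree = 6, n_sites = 1,
                   max_reproducing_males = 12,
                   replacement_generation = 5, replacement_founder_males = 3,
                   replacement_continuity = 0.15),
    multi_site = list(n_generations = 5, n_founder_males = 3,
                      mean_sons_per_union = 1.2,
                      mean_daughters_per_union = 1.2,
                      polygyny_prob = 0.15, levirate_prob = 0.15,
                      exogamy_rate = 0.98, daughter_emigration_prob = 0.6,
                      consanguinity_min_degree = 6, n_sites = 3,
                      female_exchange_rate = 0.4),
    null = list(n_generations = 1, n_founder_males = 40,
                unrelated_partner_frac = 0.6, levirate_prob = 0,
                polygyny_prob = 0))
  base$seed <- seed
  for (f in names(overrides)) base[[f]] <- overrides[[f]]
  cfg <- do.call(sim_config, base)
  structure(list(preset = preset, config = cfg, seed = seed),
            class = "scenario_spec")
}

#' Generate a complete synthetic cemetery bundle
#'
#' Orchestrates community simulation, burial sampling, genome
#' transmission, pairwise IBD with the observation model, and radiocarbon
#' dates on a synthetic calibration curve, so that every pipeline stage is
#' testable without downloads. Truth files (true pedigree, levirate event
#' log, replacement generation) are included for oracle tests.
#' Deterministic given the spec seed.
#'
#' @param spec a [scenario_spec()].
#' @param out_dir optional directory; when given, all tables are written
#'   (individuals.tsv, pedigree.fam, unions.tsv, ibd_segments.tsv,
#'   dates.tsv, curve.14c, levirate_events.tsv).
#' @param model [observation_model()] for segment degradation; the
#'   default uses a 250 SNPs-per-cM density (comfortably above the 220
#'   filter floor) with the standard jitter and length-decaying dropout.
#' @param map genetic map.
#' @param c14_sigma measurement error (years) of simulated dates.
#' @param anchor_year_AD calendar year AD of the founder generation.
#' @return list (class \code{scenario_bundle}) with pedigree, genomes,
#'   observed ibd pairs, observed-individual metadata, dates, curve,
#'   config and preset.
#' @export
generate_scenario <- function(spec, out_dir = NULL,
                              model = observation_model(snps_per_cM = 250),
                              map = default_genetic_map(),
                              c14_sigma = 25, anchor_year_AD = 580) {
  stopifnot(inherits(spec, "scenario_spec"))
  ped <- simulate_community(spec$config)
  ped <- apply_burial_sampling(ped, spec$config)
  genomes <- drop_genomes(ped, map)
  obs <- observed_individuals(ped)
  pairs <- compute_pairwise_ibd(genomes, ids = obs$id, map = map,
                                model = model)
  curve <- synthetic_calibration_curve()
  true_year_AD <- anchor_year_AD + obs$death_year
  cal_BP <- 1950 - true_year_AD
  cv <- curve_at(curve, pmin(pmax(cal_BP, min(curve$cal_BP)),
                             max(curve$cal_BP)))
  dates <- data.frame(individual_id = obs$id,
                      c14_age_BP = stats::rnorm(nrow(obs), cv$c14_age_BP,
                                                c14_sigma),
                      sigma = c14_sigma, stringsAsFactors = FALSE)
  individuals <- obs[, c("id", "site", "sex", "age_class", "age_min",
                         "age_max", "phase", "y_haplogroup",
                         "mt_haplogroup", "snp_count", "birth_year",
                         "generation")]
  bundle <- structure(list(pedigree = ped, genomes = genomes, pairs = pairs,
                           individuals = individuals, dates = dates,
                           curve = curve, config = spec$config,
                           preset = spec$preset), class = "scenario_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_individuals(individuals, file.path(out_dir, "individuals.tsv"))
    write_pedigree(ped, file.path(out_dir, "pedigree.fam"),
                   file.path(out_dir, "unions.tsv"))
    write_ibd_pairs(pairs, file.path(out_dir, "ibd_segments.tsv"))
    write_c14_dates(dates, file.path(out_dir, "dates.tsv"))
    write_calibration_curve(curve, file.path(out_dir, "curve.14c"),
                            comment = "synthetic wiggly curve")
    write_tsv_base(ped$levirate_events,
                   file.path(out_dir, "levirate_events.tsv"))
  }
  bundle
}
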