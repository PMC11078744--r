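#' Simulation configuration for a patrilineal community
#'
#' Parameters of the generative model for steppe-style kinship: patrilineal
#' descent with patrilocal residence, exogamous in-marrying wives, optional
#' polygyny and levirate re-partnering, and strict consanguinity avoidance.
#'
#' @param n_generations number of generations simulated (>= 1).
#' @param n_founder_males founder males per site (>= 1).
#' @param mean_sons_per_union,mean_daughters_per_union Poisson means of
#'   offspring counts drawn per union.
#' @param polygyny_prob per-partner probability that a male takes a further
#'   reproductive partner (capped at four partners).
#' @param levirate_prob probability that a union's male dies and his widow
#'   is re-partnered to a male agnate.
#' @param exogamy_rate probability that a wife is an unrelated immigrant
#'   founder female rather than an in-community female.
#' @param daughter_emigration_prob probability that an adult lineage
#'   daughter married away and is absent from the burial record.
#' @param consanguinity_min_degree unions between relatives closer than
#'   this genetic degree never occur (6 forbids second cousins and closer).
#' @param n_sites number of cemeteries simulated.
#' @param female_exchange_rate probability that an exogamous wife is a
#'   daughter of another simulated site's patriline (multi-site only).
#' @param generation_gap_mean,generation_gap_sd mean and sd in years of the
#'   parent-to-child birth interval (default mean 29 years).
#' @param subadult_frac fraction of individuals dying before age 18.
#' @param unrelated_partner_frac fraction of last-generation adult males
#'   whose (childless) partner is included in the burial sample.
#' @param max_reproducing_males per-generation cap on the number of males
#'   who form unions (a carrying-capacity knob keeping community size
#'   bounded over many generations); excess males remain childless.
#' @param replacement_generation generation at which a new founder cohort
#'   with distinct Y lineages takes over reproduction, or \code{NA}.
#' @param replacement_founder_males size of the incoming founder cohort.
#' @param replacement_continuity probability that an old-cohort male still
#'   reproduces after the replacement generation.
#' @param seed integer RNG seed or \code{NULL}.
#' @return object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_generations = 4,
                       n_founder_males = 3,
                       mean_sons_per_union = 1.1,
                       mean_daughters_per_union = 1.1,
                       polygyny_prob = 0.15,
                       levirate_prob = 0.15,
                       exogamy_rate = 0.98,
                       daughter_emigration_prob = 0.7,
                       consanguinity_min_degree = 6,
                       n_sites = 1,
                       female_exchange_rate = 0,
                       generation_gap_mean = 29,
                       generation_gap_sd = 4,
                       subadult_frac = 0.2,
                       unrelated_partner_frac = 0.5,
                       max_reproducing_males = Inf,
                       replacement_generation = NA_integer_,
                       replacement_founder_males = 0,
                       replacement_continuity = 0.15,
                       seed = NULL) {
  cfg <- list(n_generations = as.integer(n_generations),
              n_founder_males = as.integer(n_founder_males),
              mean_sons_per_union = mean_sons_per_union,
              mean_daughters_per_union = mean_daughters_per_union,
              polygyny_prob = polygyny_prob,
              levirate_prob = levirate_prob,
              exogamy_rate = exogamy_rate,
              daughter_emigration_prob = daughter_emigration_prob,
              consanguinity_min_degree = consanguinity_min_degree,
              n_sites = as.integer(n_sites),
              female_exchange_rate = female_exchange_rate,
              generation_gap_mean = generation_gap_mean,
              generation_gap_sd = generation_gap_sd,
              subadult_frac = subadult_frac,
              unrelated_partner_frac = unrelated_partner_frac,
              max_reproducing_males = max_reproducing_males,
              replacement_generation = as.integer(replacement_generation),
              replacement_founder_males = as.integer(replacement_founder_males),
              replacement_continuity = replacement_continuity,
              seed = seed)
  probs <- c("polygyny_prob", "levirate_prob", "exogamy_rate",
             "daughter_emigration_prob", "female_exchange_rate",
             "subadult_frac", "unrelated_partner_frac",
             "replacement_continuity")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$n_generations < 1) stop("n_generations must be >= 1")
  if (cfg$n_founder_males < 1) stop("n_founder_males must be >= 1")
  if (cfg$consanguinity_min_degree < 0) {
    stop("consanguinity_min_degree must be >= 0")
  }
  if (cfg$mean_sons_per_union <= 0 || cfg$mean_daughters_per_union <= 0) {
    stop("offspring means must be positive")
  }
  if (cfg$generation_gap_mean <= 0) stop("generation_gap_mean must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# mutable simulation state held in an environment
new_sim_state <- function() {
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$unions <- list()
  st$levirate <- list()
  st$n_ind <- 0L
  st$n_y <- 0L
  st$n_mt <- 0L
  st
}

add_individual <- function(st, site, sex, generation, father = NA_character_,
                           mother = NA_character_, founder = FALSE,
                           cohort = NA_character_, y_hap = NA_character_,
                           mt_hap = NA_character_, birth_year = NA_real_,
                           exogamous = FALSE) {
  st$n_ind <- st$n_ind + 1L
  id <- sprintf("%s_I%04d", site, st$n_ind)
  if (is.na(y_hap) && sex == "male") {
    st$n_y <- st$n_y + 1L
    y_hap <- sprintf("Y%03d", st$n_y)
  }
  if (is.na(mt_hap)) {
    st$n_mt <- st$n_mt + 1L
    mt_hap <- sprintf("M%03d", st$n_mt)
  }
  if (sex == "female") y_hap <- NA_character_
  st$rows[[id]] <- list(id = id, site = site, sex = sex,
                        generation = as.integer(generation),
                        father = father, mother = mother, founder = founder,
                        cohort = cohort, y_haplogroup = y_hap,
                        mt_haplogroup = mt_hap, birth_year = birth_year,
                        exogamous = exogamous)
  id
}

sim_rows_df <- function(st) {
  rows <- st$rows
  grab <- function(field, mode) {
    v <- vapply(rows, function(r) {
      x <- r[[field]]
      if (is.null(x)) NA else x
    }, vector(mode, 1))
    unname(v)
  }
  data.frame(id = grab("id", "character"), site = grab("site", "character"),
             sex = grab("sex", "character"),
             generation = grab("generation", "integer"),
             father = grab("father", "character"),
             mother = grab("mother", "character"),
             founder = grab("founder", "logical"),
             cohort = grab("cohort", "character"),
             y_haplogroup = grab("y_haplogroup", "character"),
             mt_haplogroup = grab("mt_haplogroup", "character"),
             birth_year = grab("birth_year", "numeric"),
             exogamous = grab("exogamous", "logical"),
             stringsAsFactors = FALSE)
}

# interim pedigree view of the state (for kinship checks during simulation)
state_pedigree <- function(st) {
  ind <- sim_rows_df(st)
  unions <- if (length(st$unions)) {
    do.call(rbind, lapply(st$unions, as.data.frame))
  } else {
    data.frame(male_id = character(), female_id = character(),
               stringsAsFactors = FALSE)
  }
  new_pedigree_graph(ind, unions)
}

#' Simulate a multi-generation patrilineal community
#'
#' Generates one or more sites generation by generation. Every non-founder
#' father is a patrilineal descendant of a founder male; wives are
#' unrelated immigrant founder females with probability
#' \code{exogamy_rate}, otherwise in-community females at genealogical
#' degree at least \code{consanguinity_min_degree}; unions violating the
#' consanguinity rule never occur. With \code{polygyny_prob} males take
#' additional partners (up to four); with \code{levirate_prob} a union's
#' male dies and his widow is re-partnered to a male agnate chosen in the
#' priority order full brother, paternal half-brother, father's brother's
#' son, son of the deceased by another partner. Y-haplogroup labels are
#' copied father to son and mtDNA labels mother to child; founders receive
#' distinct labels. Birth years advance by Normal(gap mean, gap sd) per
#' generation. Deterministic given \code{config$seed}.
#'
#' If \code{replacement_generation} is set, a new founder-male cohort with
#' fresh Y lineages enters at that generation and takes over reproduction;
#' old-cohort males born afterwards reproduce only with probability
#' \code{replacement_continuity}.
#'
#' @param config a [sim_config()].
#' @return a \code{pedigree_graph} with full per-individual metadata
#'   (site, haplogroups, birth year, age at death, phase, snp_count,
#'   cohort), union records and a levirate event log.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- new_sim_state()
  sites <- sprintf("S%d", seq_len(config$n_sites))
  for (site in sites) simulate_site(st, site, config)
  if (config$n_sites > 1 && config$female_exchange_rate > 0) {
    rewire_female_exchange(st, config)
  }
  ind <- sim_rows_df(st)
  ind <- assign_death_metadata(ind, config)
  unions <- if (length(st$unions)) {
    do.call(rbind, lapply(st$unions, as.data.frame))
  } else {
    data.frame(male_id = character(), female_id = character(),
               stringsAsFactors = FALSE)
  }
  lev <- if (length(st$levirate)) {
    do.call(rbind, lapply(st$levirate, as.data.frame))
  } else NULL
  ped <- new_pedigree_graph(ind, unions, levirate_events = lev,
                            replacement_generation =
                              config$replacement_generation)
  attr(ped, "config") <- config
  ped
}

simulate_site <- function(st, site, config) {
  gap <- function(n) stats::rnorm(n, config$generation_gap_mean,
                                  config$generation_gap_sd)
  founders <- character(config$n_founder_males)
  for (i in seq_len(config$n_founder_males)) {
    founders[i] <- add_individual(st, site, "male", 1L, founder = TRUE,
                                  cohort = "old",
                                  birth_year = stats::rnorm(1, 0, 5))
  }
  males_by_gen <- list(founders)
  if (config$n_generations == 1) return(invisible(NULL))
  cache <- NULL  # kinship cache invalidated whenever individuals are added
  for (g in seq_len(config$n_generations - 1)) {
    males <- males_by_gen[[g]]
    if (!is.na(config$replacement_generation) &&
        g == config$replacement_generation &&
        config$replacement_founder_males > 0) {
      mean_by <- if (length(males)) {
        mean(vapply(st$rows[males], function(r) r$birth_year, 1))
      } else {
        # patriline extinct before the newcomers arrive: anchor their
        # birth cohort on the expected generation clock
        (g - 1) * config$generation_gap_mean
      }
      newcomers <- vapply(seq_len(config$replacement_founder_males),
                          function(i) {
        add_individual(st, site, "male", as.integer(g), founder = TRUE,
                       cohort = "new",
                       birth_year = mean_by + stats::rnorm(1, 0, 5))
      }, character(1))
      males <- c(males, newcomers)
      males_by_gen[[g]] <- males
    }
    next_gen <- character(0)
    breeding <- males[vapply(males, function(m) reproduces(st, m, g, config),
                             logical(1))]
    if (length(breeding) > config$max_reproducing_males) {
      breeding <- sort(breeding[sample.int(length(breeding),
                                           config$max_reproducing_males)])
    }
    for (m in breeding) {
      n_partners <- 1L
      while (stats::runif(1) < config$polygyny_prob && n_partners < 4L) {
        n_partners <- n_partners + 1L
      }
      for (p in seq_len(n_partners)) {
        wife <- choose_wife(st, site, m, g, config)
        union_children <- make_union(st, site, m, wife, g, config, gap)
        next_gen <- c(next_gen, union_children$sons)
        # levirate: the union's male may die, his widow re-partnered
        if (stats::runif(1) < config$levirate_prob) {
          succ <- find_levirate_successor(st, m, wife, config)
          if (!is.null(succ)) {
            lev_children <- make_union(st, site, succ$id, wife, g, config,
                                       gap)
            next_gen <- c(next_gen, lev_children$sons)
            st$levirate[[length(st$levirate) + 1L]] <-
              list(widow = wife, deceased = m, successor = succ$id,
                   relation = succ$relation, generation = as.integer(g),
                   site = site)
          }
        }
      }
    }
    males_by_gen[[g + 1L]] <- next_gen
  }
  invisible(NULL)
}

reproduces <- function(st, male, g, config) {
  if (is.na(config$replacement_generation)) return(TRUE)
  if (g < config$replacement_generation) return(TRUE)
  cohort <- st$rows[[male]]$cohort
  if (identical(cohort, "new")) return(TRUE)
  stats::runif(1) < config$replacement_continuity
}

choose_wife <- function(st, site, male, g, config) {
  husband <- st$rows[[male]]
  if (stats::runif(1) >= config$exogamy_rate) {
    ped <- state_pedigree(st)
    cache <- new.env(parent = emptyenv())
    partnered <- unique(vapply(st$unions, function(u) u$female_id,
                               character(1)))
    cand <- vapply(st$rows, function(r) {
      r$sex == "female" && r$site == site && !r$exogamous &&
        abs(r$generation - g) <= 1 && !(r$id %in% partnered)
    }, logical(1))
    cand_ids <- names(cand)[cand]
    ok <- cand_ids[vapply(cand_ids, function(f) {
      relationship_degree(ped, male, f, cache) >=
        config$consanguinity_min_degree
    }, logical(1))]
    if (length(ok)) {
      return(ok[sample.int(length(ok), 1)])
    }
    if (config$exogamy_rate == 0) {
      stop("simulation error: no union partner satisfies ",
           "consanguinity_min_degree = ", config$consanguinity_min_degree,
           " for male ", male)
    }
    # fall through to an exogamous wife
  }
  add_individual(st, site, "female", as.integer(g), founder = TRUE,
                 birth_year = husband$birth_year + stats::rnorm(1, 0, 5),
                 exogamous = TRUE)
}

make_union <- function(st, site, male, wife, g, config, gap) {
  st$unions[[length(st$unions) + 1L]] <-
    list(male_id = male, female_id = wife, generation = as.integer(g),
         site = site)
  father_by <- st$rows[[male]]$birth_year
  y <- st$rows[[male]]$y_haplogroup
  mt <- st$rows[[wife]]$mt_haplogroup
  n_sons <- stats::rpois(1, config$mean_sons_per_union)
  n_daughters <- stats::rpois(1, config$mean_daughters_per_union)
  sons <- character(0)
  cohort <- st$rows[[male]]$cohort
  for (i in seq_len(n_sons)) {
    sons <- c(sons, add_individual(st, site, "male", as.integer(g + 1),
                                   father = male, mother = wife,
                                   cohort = cohort, y_hap = y, mt_hap = mt,
                                   birth_year = father_by + gap(1)))
  }
  for (i in seq_len(n_daughters)) {
    add_individual(st, site, "female", as.integer(g + 1), father = male,
                   mother = wife, cohort = cohort, mt_hap = mt,
                   birth_year = father_by + gap(1))
  }
  list(sons = sons)
}

find_levirate_successor <- function(st, deceased, widow, config) {
  rows <- st$rows
  d <- rows[[deceased]]
  fa <- d$father
  all_ids <- names(rows)
  males <- all_ids[vapply(rows, function(r) r$sex == "male", logical(1))]
  father_of <- function(id) rows[[id]]$father
  mother_of <- function(id) rows[[id]]$mother
  full_brothers <- males[vapply(males, function(m) {
    m != deceased && !is.na(fa) && identical(father_of(m), fa) &&
      identical(mother_of(m), d$mother)
  }, logical(1))]
  half_brothers <- males[vapply(males, function(m) {
    m != deceased && !is.na(fa) && identical(father_of(m), fa) &&
      !identical(mother_of(m), d$mother)
  }, logical(1))]
  fbs <- if (!is.na(fa) && !is.na(rows[[fa]]$father)) {
    gf <- rows[[fa]]$father
    uncles <- males[vapply(males, function(m) {
      m != fa && identical(father_of(m), gf)
    }, logical(1))]
    males[vapply(males, function(m) {
      !is.na(father_of(m)) && father_of(m) %in% uncles
    }, logical(1))]
  } else character(0)
  sons_other <- males[vapply(males, function(m) {
    identical(father_of(m), deceased) && !identical(mother_of(m), widow)
  }, logical(1))]
  priority <- list(full_brother = full_brothers,
                   paternal_half_brother = half_brothers,
                   paternal_uncle_son = fbs,
                   son_by_other_partner = sons_other)
  ped <- NULL
  cache <- NULL
  for (rel in names(priority)) {
    cand <- setdiff(priority[[rel]], deceased)
    if (!length(cand)) next
    if (is.null(ped)) {
      ped <- state_pedigree(st)
      cache <- new.env(parent = emptyenv())
    }
    ok <- cand[vapply(cand, function(m) {
      relationship_degree(ped, m, widow, cache) >=
        config$consanguinity_min_degree
    }, logical(1))]
    if (length(ok)) {
      pick <- ok[sample.int(length(ok), 1)]
      return(list(id = pick, relation = rel))
    }
  }
  NULL
}

rewire_female_exchange <- function(st, config) {
  rows <- st$rows
  unions <- st$unions
  # wives married somewhere: exogamous founder females in a union
  wives <- names(rows)[vapply(rows, function(r) {
    r$sex == "female" && isTRUE(r$exogamous) && is.na(r$father)
  }, logical(1))]
  union_df <- do.call(rbind, lapply(unions, as.data.frame))
  for (w in wives) {
    if (stats::runif(1) >= config$female_exchange_rate) next
    r <- rows[[w]]
    other <- union_df[union_df$site != r$site &
                        union_df$generation == r$generation - 1L, ,
                      drop = FALSE]
    if (!nrow(other)) next
    pick <- other[sample.int(nrow(other), 1), ]
    st$rows[[w]]$father <- pick$male_id
    st$rows[[w]]$mother <- pick$female_id
    st$rows[[w]]$founder <- FALSE
    st$rows[[w]]$mt_haplogroup <- rows[[pick$female_id]]$mt_haplogroup
    st$rows[[w]]$natal_site <- pick$site
  }
  invisible(NULL)
}

assign_death_metadata <- function(ind, config) {
  n <- nrow(ind)
  subadult <- stats::runif(n) < config$subadult_frac
  # parents must have survived to reproduce: anyone recorded as a parent
  # or union partner is an adult
  is_parent <- ind$id %in% c(ind$father, ind$mother)
  subadult[is_parent] <- FALSE
  age <- ifelse(subadult, stats::runif(n, 0, 17.5),
                pmin(18 + stats::rgamma(n, shape = 2, scale = 12), 85))
  ind$age_death <- age
  ind$age_class <- ifelse(subadult, "subadult", "adult")
  ind$age_min <- ifelse(subadult, pmax(0, floor(age) - 2),
                        pmax(18, floor(age) - 3))
  ind$age_max <- ifelse(subadult, pmin(17, ceiling(age) + 2),
                        ceiling(age) + 3)
  ind$death_year <- ind$birth_year + ind$age_death
  by <- ind$birth_year
  qs <- stats::quantile(by, c(1 / 3, 2 / 3), na.rm = TRUE)
  ind$phase <- ifelse(by <= qs[1], "early",
                      ifelse(by <= qs[2], "middle", "late"))
  # SNP-coverage counts emulate 1240k capture yields
  ind$snp_count <- round(stats::rlnorm(n, meanlog = log(7e5), sdlog = 0.35))
  ind
}

#' Apply burial sampling to a simulated community
#'
#' Produces the observed cemetery: adult lineage daughters (married away as
#' brides) are removed with probability \code{daughter_emigration_prob};
#' exogamous mothers' parents are never present at the site by
#' construction; a configurable fraction of last-generation adult males
#' gain a childless, unrelated female partner in the burial sample.
#' Removal only toggles an \code{observed} flag, so segment data of
#' retained pairs are untouched. Deterministic given \code{seed}.
#'
#' @param ped a simulated \code{pedigree_graph}.
#' @param config the [sim_config()] used for the simulation.
#' @param seed optional integer seed.
#' @return the pedigree with an \code{observed} column and any added
#'   childless partners.
#' @export
apply_burial_sampling <- function(ped, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- ped$individuals
  ind$observed <- TRUE
  locally_partnered <- ind$id %in% ped$unions$female_id
  daughter <- ind$sex == "female" & ind$age_class == "adult" &
    (!is.na(ind$father) | !is.na(ind$mother)) & !locally_partnered
  emigrated <- daughter & stats::runif(nrow(ind)) <
    config$daughter_emigration_prob
  ind$observed[emigrated] <- FALSE
  # childless partners of last-generation adult males
  last_gen <- max(ind$generation)
  lg_males <- ind$id[ind$sex == "male" & ind$generation == last_gen &
                       ind$age_class == "adult" & ind$observed]
  add <- lg_males[stats::runif(length(lg_males)) <
                    config$unrelated_partner_frac]
  if (length(add)) {
    st <- new_sim_state()
    st$n_ind <- nrow(ind)
    st$n_mt <- sum(grepl("^M", ind$mt_haplogroup))
    new_rows <- list()
    new_unions <- list()
    for (m in add) {
      site <- ind$site[ind$id == m]
      by <- ind$birth_year[ind$id == m]
      st$n_ind <- st$n_ind + 1L
      st$n_mt <- st$n_mt + 1L
      id <- sprintf("%s_U%04d", site, st$n_ind)
      age <- stats::runif(1, 18, 35)  # unrelated wives skew young adult
      new_rows[[id]] <- data.frame(
        id = id, site = site, sex = "female",
        generation = last_gen, father = NA_character_,
        mother = NA_character_, founder = TRUE, cohort = NA_character_,
        y_haplogroup = NA_character_,
        mt_haplogroup = sprintf("M%03d", st$n_mt),
        birth_year = by + stats::rnorm(1, 0, 5), exogamous = TRUE,
        age_death = age, age_class = "adult",
        age_min = max(18, floor(age) - 3), age_max = ceiling(age) + 3,
        death_year = by + age, phase = ind$phase[ind$id == m],
        snp_count = round(stats::rlnorm(1, log(7e5), 0.35)),
        observed = TRUE, stringsAsFactors = FALSE)
      new_unions[[id]] <- data.frame(male_id = m, female_id = id,
                                     generation = last_gen,
                                     site = site, stringsAsFactors = FALSE)
    }
    extra <- do.call(rbind, new_rows)
    missing_cols <- setdiff(names(ind), names(extra))
    for (col in missing_cols) extra[[col]] <- NA
    ind <- rbind(ind, extra[, names(ind)])
    ped$unions <- rbind(ped$unions, do.call(rbind, new_unions))
  }
  ped$individuals <- ind
  ped
}
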