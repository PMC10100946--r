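#' Configure a synthetic two-compartment fermentation experiment
#'
#' Builds the full parameterization of a simulated colon-fermenter run: a
#' donor community split into gut-only, oral-only and shared species; a
#' luminal compartment modelled as a logistic chemostat (24-h mean retention
#' time, i.e. dilution 1/day, after a 1-day batch amplification without
#' washout); a mucosal compartment of mucin beads fed by linear adhesion
#' from the lumen, drained by detachment, and reset to a retained fraction
#' at every bead replacement; a 9-h saliva enrichment step with per-species
#' Bernoulli dropout; and twice-daily spike-ins of enriched saliva on the
#' injection days. Sequencing is emulated downstream by multinomial
#' read-to-gene sampling at a fixed depth with an unassigned (host/unknown)
#' read fraction.
#'
#' All defaults are the study conditions the simulator emulates: 11-day
#' horizon, injections on days 9 and 10 (twice a day, 0.33 days apart),
#' mucin beads replaced every 2 days, 100 marker genes per MSP, enrichment
#' retaining on average 70% of saliva richness, sequencing depth 1e5 with a
#' 5% unassigned fraction for fecal-origin samples and 50% for salivary
#' ones.
#'
#' @param n_gut_only,n_oral_only,n_shared Number of species present only in
#'   baseline stool, only in baseline saliva, or in both (the latter end up
#'   niche "ND").
#' @param markers_per_msp,genes_per_msp Marker genes and total genes per MSP
#'   (markers first; `genes_per_msp >= markers_per_msp`).
#' @param dilution_rate Luminal washout rate per day (1/retention time).
#' @param growth_median,growth_sdlog Log-normal distribution of per-species
#'   growth rates (per day).
#' @param carrying_capacity Shared logistic carrying capacity of the lumen.
#' @param adhesion,detachment Lumen-to-mucosa transfer and mucosa-to-lumen
#'   loss rates (per day).
#' @param oral_mucosal_affinity Multiplier (>= 1) on `adhesion` for
#'   oral-niche species, the simulator's handle on mucosal tropism of oral
#'   bacteria.
#' @param oral_luminal_clearance Additional per-day decay of oral-niche
#'   species in the free luminal medium (default 2/day). Oral taxa are
#'   maladapted to colonic conditions and are cleared from the lumen much
#'   faster than dilution alone, while the mucin beads act as a protective
#'   adhesive niche; this is the asymmetry that lets spiked oral species
#'   persist on mucus but not in the lumen.
#' @param bead_replacement_period Days between mucin-bead replacements.
#' @param bead_retention_fraction Fraction of mucosal biomass surviving a
#'   bead swap.
#' @param enrichment_hours Duration of the saliva enrichment culture.
#' @param enrichment_dropout Per-species probability of surviving
#'   enrichment.
#' @param saliva_dose Injected biomass as a fraction of current total
#'   luminal biomass (default mirrors the 10 mL : 300 mL volume ratio).
#' @param injection_days,injections_per_day Spike-in schedule.
#' @param sequencing_depth Reads per sample.
#' @param unassigned_fraction_fecal,unassigned_fraction_saliva Fraction of
#'   reads assigned to no catalogue gene, by sample origin.
#' @param dirichlet_alpha Concentration of the Dirichlet draw for baseline
#'   stool and saliva compositions (< 1 gives the long-tailed rank-abundance
#'   curves typical of real communities).
#' @param shared_min_abundance Minimum relative abundance planted for shared
#'   species in each baseline. Shared species are shared *by definition* —
#'   present in both stool and saliva — so the generator keeps them above
#'   the detection scale of the simulated sequencing depth instead of
#'   letting the Dirichlet tail make them effectively absent from one
#'   habitat.
#' @param init_biomass_fraction Initial luminal biomass as a fraction of the
#'   carrying capacity.
#' @param dt Euler time step (days).
#' @param horizon_days Length of the fermentation (days).
#' @param donor Donor label used in sample ids.
#' @param seed Root seed; every random stage derives a named substream from
#'   it via [stream_seed()].
#' @return A list of class `oralgut_sim_config`.
#' @seealso [run_simulation()], [simulate_experiment()]
#' @export
sim_config <- function(n_gut_only = 200,
                       n_oral_only = 100,
                       n_shared = 30,
                       markers_per_msp = 100,
                       genes_per_msp = 200,
                       dilution_rate = 1.0,
                       growth_median = 0.8,
                       growth_sdlog = 0.5,
                       carrying_capacity = 1.0,
                       adhesion = 0.05,
                       detachment = 0.2,
                       oral_mucosal_affinity = 5,
                       oral_luminal_clearance = 2,
                       bead_replacement_period = 2,
                       bead_retention_fraction = 0.2,
                       enrichment_hours = 9,
                       enrichment_dropout = 0.7,
                       saliva_dose = 0.033,
                       injection_days = c(9, 10),
                       injections_per_day = 2,
                       sequencing_depth = 1e5,
                       unassigned_fraction_fecal = 0.05,
                       unassigned_fraction_saliva = 0.5,
                       dirichlet_alpha = 0.5,
                       shared_min_abundance = 3e-3,
                       init_biomass_fraction = 0.1,
                       dt = 0.01,
                       horizon_days = 11,
                       donor = "S1",
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "oralgut_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A config to validate; called for its side effect of
#'   raising a classed `oralgut_config_error` on the first violation.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "oralgut_sim_config") || is.list(config))
  chk <- function(ok, msg) if (!isTRUE(ok)) abort_config(msg)
  with(config, {
    chk(n_gut_only >= 0 && n_oral_only >= 0 && n_shared >= 0,
        "Species counts must be non-negative.")
    chk(n_gut_only + n_oral_only + n_shared >= 1,
        "At least one species is required.")
    chk(markers_per_msp >= 10, "`markers_per_msp` must be >= 10.")
    chk(genes_per_msp >= markers_per_msp,
        "`genes_per_msp` must be >= `markers_per_msp`.")
    chk(dilution_rate >= 0, "`dilution_rate` must be >= 0.")
    chk(growth_median > 0 && growth_sdlog >= 0,
        "Growth-rate distribution parameters out of range.")
    chk(carrying_capacity > 0, "`carrying_capacity` must be > 0.")
    chk(adhesion >= 0 && detachment >= 0,
        "`adhesion` and `detachment` must be >= 0.")
    chk(oral_mucosal_affinity >= 1, "`oral_mucosal_affinity` must be >= 1.")
    chk(oral_luminal_clearance >= 0, "`oral_luminal_clearance` must be >= 0.")
    chk(bead_replacement_period > 0, "`bead_replacement_period` must be > 0.")
    chk(bead_retention_fraction >= 0 && bead_retention_fraction <= 1,
        "`bead_retention_fraction` must lie in [0, 1].")
    chk(enrichment_hours >= 0, "`enrichment_hours` must be >= 0.")
    chk(enrichment_dropout >= 0 && enrichment_dropout <= 1,
        "`enrichment_dropout` must lie in [0, 1].")
    chk(saliva_dose >= 0 && saliva_dose <= 1,
        "`saliva_dose` must lie in [0, 1].")
    chk(injections_per_day >= 1, "`injections_per_day` must be >= 1.")
    chk(sequencing_depth >= 1, "`sequencing_depth` must be >= 1.")
    chk(unassigned_fraction_fecal >= 0 && unassigned_fraction_fecal <= 1 &&
          unassigned_fraction_saliva >= 0 && unassigned_fraction_saliva <= 1,
        "Unassigned fractions must lie in [0, 1].")
    chk(dirichlet_alpha > 0, "`dirichlet_alpha` must be > 0.")
    chk(shared_min_abundance >= 0 && shared_min_abundance < 1,
        "`shared_min_abundance` must lie in [0, 1).")
    chk(init_biomass_fraction > 0 && init_biomass_fraction <= 1,
        "`init_biomass_fraction` must lie in (0, 1].")
    chk(dt > 0 && dt <= 0.5, "`dt` must lie in (0, 0.5].")
    chk(horizon_days >= 1, "`horizon_days` must be >= 1.")
    if (length(injection_days) > 0) {
      last <- max(injection_days) + 0.33 * (injections_per_day - 1)
      chk(all(injection_days >= 1) && last <= horizon_days,
          "Injection day outside the simulated horizon.")
    }
  })
  invisible(config)
}

#' Build the miniature paired gut/oral gene catalogues of a simulation
#'
#' Every gut-only and shared species gets an MSP in the gut catalogue; every
#' oral-only and shared species one in the oral catalogue; shared species
#' therefore appear twice, linked by an overlap pair. Each MSP carries
#' `genes_per_msp` genes of which the first `markers_per_msp` are markers,
#' with length weights drawn uniformly from `[0.5, 1.5]` under the
#' `"catalogue"` seed substream.
#'
#' @param config An [sim_config()].
#' @return An [gene_catalogue()] carrying a `species_map` attribute
#'   (tibble `species_id, truth_niche, gut_msp_id, oral_msp_id,
#'   merged_msp_id`) that links simulated species to their catalogue MSPs.
#' @export
build_catalogue_pair <- function(config) {
  validate_sim_config(config)
  species_map <- with(config, tibble(
    species_id = c(
      sprintf("sp_gut_%04d", seq_len(n_gut_only)),
      sprintf("sp_oral_%04d", seq_len(n_oral_only)),
      sprintf("sp_shared_%04d", seq_len(n_shared))
    ),
    truth_niche = rep(c("gut", "oral", "ND"),
                      times = c(n_gut_only, n_oral_only, n_shared)),
    gut_msp_id = c(
      sprintf("msp_g%04d", seq_len(n_gut_only)),
      rep(NA_character_, n_oral_only),
      sprintf("msp_gs%04d", seq_len(n_shared))
    ),
    oral_msp_id = c(
      rep(NA_character_, n_gut_only),
      sprintf("msp_o%04d", seq_len(n_oral_only)),
      sprintf("msp_os%04d", seq_len(n_shared))
    )
  ))
  # the merged table keeps the gut id of an overlap pair
  species_map$merged_msp_id <- ifelse(
    is.na(species_map$gut_msp_id),
    species_map$oral_msp_id, species_map$gut_msp_id
  )

  one_catalogue <- function(msp_ids, which_cat) {
    g <- config$genes_per_msp
    tibble(
      gene_id = paste0(rep(msp_ids, each = g), "_gene", sprintf("%04d", seq_len(g))),
      msp_id = rep(msp_ids, each = g),
      is_marker = rep(seq_len(g) <= config$markers_per_msp, times = length(msp_ids)),
      catalogue = which_cat
    )
  }
  gut_ids <- species_map$gut_msp_id[!is.na(species_map$gut_msp_id)]
  oral_ids <- species_map$oral_msp_id[!is.na(species_map$oral_msp_id)]
  genes <- bind_rows(
    one_catalogue(gut_ids, "gut"),
    one_catalogue(oral_ids, "oral")
  )
  genes$length_weight <- with_seed(
    stream_seed(config$seed, "catalogue"),
    runif(nrow(genes), 0.5, 1.5)
  )
  shared <- species_map[!is.na(species_map$gut_msp_id) &
                          !is.na(species_map$oral_msp_id), ]
  overlaps <- tibble(gut_msp_id = shared$gut_msp_id,
                     oral_msp_id = shared$oral_msp_id)
  cat <- gene_catalogue(genes, overlaps,
                        markers_per_msp = config$markers_per_msp)
  attr(cat, "species_map") <- species_map
  cat
}

# Dirichlet draw (gamma normalization); returns a named composition vector.
rdirichlet1 <- function(names, alpha) {
  w <- rgamma(length(names), shape = alpha, rate = 1)
  if (sum(w) <= 0) w <- rep(1, length(names))
  setNames(w / sum(w), names)
}

#' Simulate the 9-h saliva enrichment culture
#'
#' Each species survives the enrichment independently with probability
#' `dropout` (the retained-richness handle; the study conditions retain
#' about 70%); survivors grow exponentially for `hours` at their own rate,
#' and the result is renormalized to a composition. Species lost to dropout
#' are exactly zero.
#'
#' @param raw Named composition vector of the raw saliva (sums to 1).
#' @param growth_rates Named per-species growth rates (per day), covering
#'   `names(raw)`.
#' @param hours Enrichment duration in hours.
#' @param dropout Per-species survival probability.
#' @param seed Integer seed for the dropout draw.
#' @return A named composition vector summing to 1.
#' @export
enrich_saliva <- function(raw, growth_rates, hours, dropout, seed) {
  stopifnot(abs(sum(raw) - 1) < 1e-6, hours >= 0)
  g <- growth_rates[names(raw)]
  survive <- with_seed(seed, rbinom(length(raw), 1, dropout))
  w <- raw * survive * exp(g * hours / 24)
  if (sum(w) <= 0) {
    abort_runtime("Enrichment extinguished the community.")
  }
  w / sum(w)
}

#' One Euler step of the luminal and mucosal compartments
#'
#' The lumen is a logistic chemostat with a shared carrying capacity:
#' `x_i <- x_i * exp((g_i * (1 - X/K) - D) * dt)` with `X` the total
#' luminal biomass before the step. The mucosa gains biomass by linear
#' adhesion from the lumen and loses it by detachment:
#' `m_i <- m_i + dt * (a_i * x_i - delta_i * m_i)`, clipped at zero; when
#' `bead_swap` is set the mucin beads are replaced after the update and only
#' `retention` of the mucosal biomass survives.
#'
#' @param state A list with numeric vectors `lumen` and `mucosa` (same
#'   species order) and a `time` in days.
#' @param growth,adhesion,detachment Per-species rate vectors (per day).
#' @param dilution Washout rate `D` (per day).
#' @param capacity Carrying capacity `K` (> 0).
#' @param dt Step length in days.
#' @param bead_swap Replace the beads after this mucosal step?
#' @param retention Fraction of mucosal biomass surviving a bead swap.
#' @return The updated state (time advanced by `dt` in `step_lumen`).
#' @name stepping
NULL

#' @rdname stepping
#' @param clearance Optional per-species extra luminal decay rate (per
#'   day), e.g. active clearance of maladapted oral taxa; defaults to 0 for
#'   every species.
#' @export
step_lumen <- function(state, growth, dilution, capacity, dt, clearance = 0) {
  if (capacity <= 0) abort_config("`capacity` must be > 0.")
  stopifnot(dt > 0)
  x_tot <- sum(state$lumen)
  state$lumen <- state$lumen *
    exp((growth * (1 - x_tot / capacity) - dilution - clearance) * dt)
  state$time <- state$time + dt
  state
}

#' @rdname stepping
#' @export
step_mucosa <- function(state, adhesion, detachment, dt,
                        bead_swap = FALSE, retention = 0.2) {
  stopifnot(dt > 0)
  m <- state$mucosa + dt * (adhesion * state$lumen - detachment * state$mucosa)
  m <- pmax(m, 0)
  if (isTRUE(bead_swap)) {
    m <- m * retention
  }
  state$mucosa <- m
  state
}

#' Run the full fermentation scenario and return the planted ground truth
#'
#' Inoculates the lumen with a Dirichlet-drawn stool community (gut-only and
#' shared species), runs the coupled lumen/mucosa dynamics with a 1-day
#' batch phase (no washout) followed by continuous dilution, replaces the
#' mucin beads on schedule (sampling reads the pre-swap state), enriches the
#' donor's saliva on each injection day, and spikes it into the lumen
#' `injections_per_day` times (0.33 days apart, the first injection ordered
#' before that day's luminal sample). Compositions are recorded on the full
#' sampling grid: daily luminal samples, mucosal samples on bead-swap days,
#' the two baselines, and the enriched saliva of each injection day.
#'
#' @param config An [sim_config()].
#' @param catalogue Optionally a pre-built [build_catalogue_pair()] result
#'   for this config (rebuilt when `NULL`).
#' @return A list of class `oralgut_simulation` with elements
#'   `truth` (niche labels, baseline/enriched compositions, trajectory at
#'   sample times, planted invader table), `compositions` (named list of
#'   per-species composition vectors, one per sample), `meta` (sample
#'   metadata tibble) and `catalogue`. Identical configs (including seed)
#'   give identical output.
#' @export
run_simulation <- function(config, catalogue = NULL) {
  validate_sim_config(config)
  if (is.null(catalogue)) {
    catalogue <- build_catalogue_pair(config)
  }
  smap <- attr(catalogue, "species_map")
  sp <- smap$species_id
  n <- length(sp)
  niche <- setNames(smap$truth_niche, sp)

  growth <- with_seed(
    stream_seed(config$seed, "growth"),
    setNames(rlnorm(n, meanlog = log(config$growth_median),
                    sdlog = config$growth_sdlog), sp)
  )
  adhesion <- setNames(rep(config$adhesion, n), sp)
  adhesion[niche == "oral"] <- adhesion[niche == "oral"] * config$oral_mucosal_affinity
  detachment <- setNames(rep(config$detachment, n), sp)
  clearance <- setNames(rep(0, n), sp)
  clearance[niche == "oral"] <- config$oral_luminal_clearance

  in_stool <- niche %in% c("gut", "ND")
  in_saliva <- niche %in% c("oral", "ND")
  shared <- niche == "ND"
  plant_baseline <- function(present, stream) {
    comp <- setNames(numeric(n), sp)
    comp[present] <- with_seed(
      stream_seed(config$seed, stream),
      rdirichlet1(sp[present], config$dirichlet_alpha)
    )
    # shared species are present in *both* habitats by construction: keep
    # them above the detection scale of the simulated depth
    comp[shared] <- pmax(comp[shared], config$shared_min_abundance)
    comp / sum(comp)
  }
  stool <- plant_baseline(in_stool, "stool")
  saliva <- plant_baseline(in_saliva, "saliva")

  enriched <- list()
  for (d in config$injection_days) {
    enriched[[as.character(d)]] <- enrich_saliva(
      saliva[in_saliva], growth[in_saliva],
      hours = config$enrichment_hours,
      dropout = config$enrichment_dropout,
      seed = stream_seed(config$seed, paste0("dropout_day", d))
    )
  }

  dt <- config$dt
  n_steps <- as.integer(round(config$horizon_days / dt))
  step_of <- function(t) as.integer(round(t / dt))
  lum_days <- seq_len(config$horizon_days)
  muc_days <- seq(config$bead_replacement_period, config$horizon_days,
                  by = config$bead_replacement_period)
  swap_steps <- step_of(muc_days)
  sample_steps <- list(luminal = step_of(lum_days), mucosal = step_of(muc_days))
  inj <- expand_injections(config)
  inj_steps <- step_of(inj$time)

  state <- list(
    time = 0,
    lumen = stool * config$init_biomass_fraction * config$carrying_capacity,
    mucosa = setNames(numeric(n), sp)
  )

  traj <- list()
  record <- function(compartment, day, st) {
    biomass <- unname(if (compartment == "luminal") st$lumen else st$mucosa)
    traj[[length(traj) + 1]] <<- tibble(
      compartment = compartment, day = day, species_id = sp, biomass = biomass
    )
  }
  compositions <- list()
  sid <- function(type, day = NULL) {
    if (is.null(day)) paste0(config$donor, "_", type)
    else sprintf("%s_%s_d%02d", config$donor, type, day)
  }
  compositions[[sid("stool")]] <- stool
  compositions[[sid("raw_saliva")]] <- saliva
  for (d in config$injection_days) {
    full <- setNames(numeric(n), sp)
    full[names(enriched[[as.character(d)]])] <- enriched[[as.character(d)]]
    compositions[[sid("enriched_saliva", d)]] <- full
  }

  for (k in seq_len(n_steps + 1)) {
    step <- k - 1L # events at time step*dt, then dynamics to (step+1)*dt
    # event order at an instant: sample, replace beads, inject -- so a
    # day-d sample reads the pre-swap mucosa and the pre-injection lumen
    day_here <- step * dt
    if (step %in% sample_steps$luminal) {
      d <- as.integer(round(day_here))
      compositions[[sid("luminal", d)]] <- normalize_comp(state$lumen)
      record("luminal", d, state)
    }
    if (step %in% sample_steps$mucosal) {
      d <- as.integer(round(day_here))
      compositions[[sid("mucosal", d)]] <- normalize_comp(state$mucosa)
      record("mucosal", d, state)
    }
    if (step %in% swap_steps && step > 0) {
      state$mucosa <- state$mucosa * config$bead_retention_fraction
    }
    for (j in which(inj_steps == step)) {
      e <- enriched[[as.character(inj$day[j])]]
      dose <- config$saliva_dose * sum(state$lumen)
      state$lumen[names(e)] <- state$lumen[names(e)] + dose * e
    }
    if (k > n_steps) break
    dil <- if (day_here < 1) 0 else config$dilution_rate # batch amplification
    state <- step_lumen(state, growth, dil, config$carrying_capacity, dt,
                        clearance = clearance)
    state <- step_mucosa(state, adhesion, detachment, dt)
  }

  traj <- bind_rows(traj)
  meta <- sim_sample_meta(config)
  first_inj <- min(config$injection_days)

  post <- traj[traj$day >= first_inj, ]
  rel <- post |>
    group_by(.data$compartment, .data$day) |>
    mutate(rel = if (sum(.data$biomass) > 0) .data$biomass / sum(.data$biomass)
           else .data$biomass * 0) |>
    ungroup()
  oral_sp <- sp[niche == "oral"]
  planted <- rel |>
    filter(.data$species_id %in% oral_sp) |>
    group_by(.data$species_id) |>
    summarise(
      max_luminal_rel = max(.data$rel[.data$compartment == "luminal"], 0),
      max_mucosal_rel = max(.data$rel[.data$compartment == "mucosal"], 0),
      any_biomass = any(.data$biomass > 0),
      .groups = "drop"
    )
  planted_invaders <- planted$species_id[planted$any_biomass]

  truth <- list(
    niche = tibble(
      species_id = sp,
      msp_id = smap$merged_msp_id,
      niche = unname(niche)
    ),
    stool = stool,
    saliva = saliva,
    enriched = enriched,
    trajectory = traj,
    planted_oral = planted,
    planted_invaders = planted_invaders
  )

  structure(
    list(truth = truth, compositions = compositions, meta = meta,
         catalogue = catalogue, config = config),
    class = "oralgut_simulation"
  )
}

# injection schedule as (day, time) rows; spaced 0.33 d within a day
expand_injections <- function(config) {
  if (length(config$injection_days) == 0) {
    return(tibble(day = integer(), time = numeric()))
  }
  offs <- 0.33 * (seq_len(config$injections_per_day) - 1)
  tibble(
    day = rep(as.integer(config$injection_days), each = length(offs)),
    time = rep(config$injection_days, each = length(offs)) + offs
  )
}

normalize_comp <- function(x) {
  s <- sum(x)
  if (s > 0) x / s else x
}

# The Fig-1-style sampling grid as a sample metadata tibble.
sim_sample_meta <- function(config) {
  sid <- function(type, day = NULL) {
    if (is.null(day)) paste0(config$donor, "_", type)
    else sprintf("%s_%s_d%02d", config$donor, type, day)
  }
  lum_days <- seq_len(config$horizon_days)
  muc_days <- seq(config$bead_replacement_period, config$horizon_days,
                  by = config$bead_replacement_period)
  bind_rows(
    tibble(sample_id = sid("stool"), sample_type = "stool",
           day = NA_integer_, is_baseline = TRUE),
    tibble(sample_id = sid("raw_saliva"), sample_type = "raw_saliva",
           day = NA_integer_, is_baseline = TRUE),
    tibble(sample_id = vapply(config$injection_days,
                              function(d) sid("enriched_saliva", d), character(1)),
           sample_type = "enriched_saliva",
           day = as.integer(config$injection_days), is_baseline = FALSE),
    tibble(sample_id = vapply(lum_days, function(d) sid("luminal", d), character(1)),
           sample_type = "luminal", day = as.integer(lum_days),
           is_baseline = FALSE),
    tibble(sample_id = vapply(muc_days, function(d) sid("mucosal", d), character(1)),
           sample_type = "mucosal", day = as.integer(muc_days),
           is_baseline = FALSE)
  ) |>
    mutate(donor = config$donor, .after = "sample_id")
}

#' Emulate shotgun sequencing of one sample as gene counts
#'
#' Draws `depth` reads for one sample: an unassigned count from
#' `Binomial(depth, unassigned_fraction)` (host or unmapped reads), the rest
#' from a multinomial over the catalogue's genes with probability
#' proportional to the owning MSP's weight times the gene's length weight
#' (renormalized within each MSP). Assigned plus unassigned reads always sum
#' to `depth` exactly.
#'
#' @param composition Named non-negative weight vector keyed by `msp_id`
#'   (any MSP absent from the names gets weight zero).
#' @param catalogue An [gene_catalogue()].
#' @param depth Total reads for the sample (>= 1).
#' @param unassigned_fraction Fraction of reads assigned to no gene.
#' @param seed Integer seed.
#' @param sample_id Column name for the emitted sample.
#' @return A one-sample [gene_table()] over all catalogue genes.
#' @export
emit_gene_counts <- function(composition, catalogue, depth,
                             unassigned_fraction, seed,
                             sample_id = "sample") {
  stopifnot(inherits(catalogue, "oralgut_catalogue"))
  if (any(composition < 0) || sum(composition) <= 0) {
    abort_input("`composition` must be non-negative with a positive sum.")
  }
  if (depth < 1) abort_input("`depth` must be >= 1.")
  genes <- catalogue$genes
  w_msp <- setNames(rep(0, length(unique(genes$msp_id))), unique(genes$msp_id))
  keep <- intersect(names(composition), names(w_msp))
  w_msp[keep] <- composition[keep]
  lw_sum <- tapply(genes$length_weight, genes$msp_id, sum)
  p <- unname(w_msp[genes$msp_id]) * genes$length_weight /
    unname(lw_sum[genes$msp_id])
  counts <- with_seed(seed, {
    n_ua <- rbinom(1, size = as.integer(depth), prob = unassigned_fraction)
    assigned <- as.integer(depth) - n_ua
    cts <- if (assigned > 0 && any(p > 0)) {
      as.numeric(rmultinom(1, assigned, p))
    } else {
      rep(0, length(p))
    }
    list(ua = n_ua, cts = cts)
  })
  tbl <- tibble(gene_id = genes$gene_id, !!sample_id := counts$cts)
  gene_table(tbl, unassigned = setNames(counts$ua, sample_id))
}

# Convert per-species weights to per-MSP weights: a shared species' weight is
# split between its gut and oral catalogue copies in proportion to each
# copy's total gene length weight (reads from one organism hit both
# catalogues).
species_to_msp_weights <- function(composition, catalogue) {
  smap <- attr(catalogue, "species_map")
  lw_sum <- tapply(catalogue$genes$length_weight, catalogue$genes$msp_id, sum)
  w <- c()
  comp <- composition[smap$species_id]
  comp[is.na(comp)] <- 0
  gut_lw <- ifelse(is.na(smap$gut_msp_id), 0, unname(lw_sum[smap$gut_msp_id]))
  oral_lw <- ifelse(is.na(smap$oral_msp_id), 0, unname(lw_sum[smap$oral_msp_id]))
  tot <- gut_lw + oral_lw
  gut_w <- setNames(comp * gut_lw / tot, smap$gut_msp_id)
  oral_w <- setNames(comp * oral_lw / tot, smap$oral_msp_id)
  w <- c(gut_w[!is.na(names(gut_w))], oral_w[!is.na(names(oral_w))])
  w
}

#' Simulate a complete sequenced experiment
#'
#' Runs [run_simulation()] and sequences every sample on the grid with
#' [emit_gene_counts()] (fecal-origin samples use the fecal unassigned
#' fraction; salivary samples the salivary one), returning everything the
#' quantification pipeline needs plus the planted truth to score against.
#'
#' @param config An [sim_config()].
#' @return A list of class `oralgut_experiment` with elements `genes`
#'   (an [gene_table()] across all samples), `catalogue`, `meta`, `truth`,
#'   `compositions` and `config`.
#' @export
simulate_experiment <- function(config) {
  sim <- run_simulation(config)
  meta <- sim$meta
  cols <- vector("list", nrow(meta))
  ua <- numeric(nrow(meta))
  gene_ids <- sim$catalogue$genes$gene_id
  for (i in seq_len(nrow(meta))) {
    s <- meta$sample_id[i]
    uf <- if (meta$sample_type[i] %in% c("raw_saliva", "enriched_saliva")) {
      config$unassigned_fraction_saliva
    } else {
      config$unassigned_fraction_fecal
    }
    w <- species_to_msp_weights(sim$compositions[[s]], sim$catalogue)
    one <- emit_gene_counts(
      w, sim$catalogue, depth = config$sequencing_depth,
      unassigned_fraction = uf,
      seed = stream_seed(config$seed, paste0("seq_", s)),
      sample_id = s
    )
    cols[[i]] <- one[[s]]
    ua[i] <- unassigned_counts(one)[[s]]
  }
  counts <- bind_cols(tibble(gene_id = gene_ids), setNames(cols, meta$sample_id))
  genes <- gene_table(counts, unassigned = setNames(ua, meta$sample_id))
  structure(
    list(genes = genes, catalogue = sim$catalogue, meta = meta,
         truth = sim$truth, compositions = sim$compositions, config = config),
    class = "oralgut_experiment"
  )
}
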