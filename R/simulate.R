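#' Configuration for the synthetic diploid-triploid complex generator
#'
#' The generator emulates the statistical structure a mixed-ploidy
#' microsatellite survey of a clonal yeast population assumes: K ancestral
#' pools with locus-specific allele frequencies, diploid genotypes (two
#' draws per locus), allotriploid genotypes (a core diploid from one pool
#' plus one extra haploid allele set from a donor pool), clonal expansion
#' with stepwise mutation, missing calls, country/substrate metadata, and
#' logistic growth curves whose rate/plateau/lag degrade with sulfite dose
#' in group-dependent fashion.
#'
#' All core pools draw alleles from one shared window of
#' `n_allele_states` repeat counts: each pool's frequencies mix a common
#' species-wide Dirichlet draw (weight `core_shared_weight`) with a
#' pool-specific draw, so groups share a core genome yet favour different
#' alleles -- exactly the structure that lets a chi-square screen strip
#' polyploid-specific alleles while leaving most diploid calls intact.
#' Donor pools (the extra haploid set of allotriploids) sit `donor_shift`
#' repeats away in their own windows (staggered by `pool_shift`), so the
#' third allele is identifiably foreign, mirroring hybridisation with a
#' divergent lineage. Default group sizes follow the observed 6-group
#' complex at roughly one-eighth scale.
#'
#' @param seed integer seed.
#' @param n_loci number of microsatellite loci.
#' @param groups data.frame defining the groups: `name`, `ploidy`
#'   (`"2n"`/`"3n"`), `core_pool`, `extra_pool` (`NA` for diploids),
#'   `n_genotypes`, `n_isolates`, `substrate`, `archetype`
#'   (`"tolerant"`/`"sensitive"`).
#' @param countries named list (per group) of named country-probability
#'   vectors.
#' @param pool_alpha Dirichlet concentration per allele state.
#' @param n_allele_states allele window width per pool (repeat counts).
#' @param pool_shift window shift between successive core pools.
#' @param donor_shift extra shift applied to donor pools.
#' @param base_repeat smallest repeat count of pool 1's window.
#' @param smm_rate per-allele, per-clonal-copy probability of a +-1
#'   stepwise mutation.
#' @param missing_rate per-call probability of a missing locus.
#' @param clone_country_fidelity probability that a clonal copy is
#'   isolated from its genotype's home country (local clonal dispersal);
#'   otherwise the country is redrawn from the group distribution.
#' @param country_tilt Dirichlet concentration used to perturb each
#'   group's country profile around its substrate base distribution
#'   (smaller = stronger regional differentiation between lineages,
#'   `Inf` = none); together with clonal fidelity this creates the
#'   isolation-by-distance signal a Mantel test detects.
#' @param repeat_unit_bp motif lengths recycled across loci.
#' @param doses sulfite doses (mg/L molecular SO2).
#' @param od_noise_sd Gaussian OD noise.
#' @param archetypes growth archetype parameters; see Details in the
#'   package vignette.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 12L,
                       groups = NULL,
                       countries = NULL,
                       pool_alpha = 0.15,
                       core_shared_weight = 0.2,
                       n_allele_states = 10L,
                       pool_shift = 6L,
                       donor_shift = 40L,
                       base_repeat = 8L,
                       smm_rate = 0.002,
                       missing_rate = 0.03,
                       clone_country_fidelity = 0.9,
                       country_tilt = 8,
                       repeat_unit_bp = c(3L, 4L),
                       doses = c(0, 0.2, 0.4, 0.6),
                       od_noise_sd = 0.02,
                       archetypes = NULL) {
  if (is.null(groups)) {
    groups <- data.frame(
      name = c("wine-3n-A", "beer-3n", "wine-2n", "wine-3n-B",
               "ethanol-3n", "kombucha-2n"),
      ploidy = c("3n", "3n", "2n", "3n", "3n", "2n"),
      core_pool = c("P1", "P2", "P3", "P4", "P5", "P6"),
      extra_pool = c("D1", "D2", NA, "D3", "D4", NA),
      n_genotypes = c(25L, 16L, 26L, 4L, 2L, 8L),
      n_isolates = c(68L, 26L, 72L, 5L, 3L, 14L),
      substrate = c("wine", "beer", "wine", "wine", "bioethanol",
                    "kombucha"),
      archetype = c("tolerant", "sensitive", "sensitive", "tolerant",
                    "sensitive", "sensitive"),
      stringsAsFactors = FALSE)
  }
  if (is.null(countries)) {
    # wine lineages are globally traded and share one broad distribution;
    # niche substrates are regionally concentrated. Fine-scale geographic
    # signal comes from clonal fidelity (clones share their genotype's
    # country), not from group-level tilts.
    wine <- c(France = 0.25, Italy = 0.15, Spain = 0.10, Portugal = 0.08,
              Australia = 0.12, USA = 0.10, Chile = 0.08, Argentina = 0.07,
              `South Africa` = 0.05)
    by_substrate <- list(
      wine = wine,
      beer = c(Belgium = 0.5, USA = 0.3, UK = 0.2),
      bioethanol = c(Brazil = 0.6, Mexico = 0.4),
      tequila = c(Mexico = 1.0),
      kombucha = c(France = 0.4, USA = 0.3, Germany = 0.3))
    countries <- lapply(seq_len(nrow(groups)), function(g) {
      cn <- by_substrate[[groups$substrate[g]]]
      if (is.null(cn)) wine else cn
    })
    names(countries) <- groups$name
    # the small wine triploid subgroup is geographically concentrated
    if ("wine-3n-B" %in% groups$name) {
      countries[["wine-3n-B"]] <- c(France = 0.7, Italy = 0.3)
    }
  }
  if (is.null(archetypes)) {
    archetypes <- list(
      tolerant = list(r = 0.08, plateau = 2.0, lag = 60,
                      rate_mult = c(1, 1, 1, 1),
                      plateau_mult = c(1, 1, 1, 1),
                      lag_add = c(0, 10, 30, 60)),
      sensitive = list(r = 0.10, plateau = 2.0, lag = 20,
                       rate_mult = c(1, 0.7, 0.35, 0),
                       plateau_mult = c(1, 0.95, 0.5, 0),
                       lag_add = c(0, 20, 80, 0)))
  }
  stopifnot(all(groups$n_genotypes >= 1L),
            all(groups$n_isolates >= groups$n_genotypes),
            smm_rate >= 0, smm_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(seed = seed, n_loci = n_loci, groups = groups,
                 countries = countries, pool_alpha = pool_alpha,
                 core_shared_weight = core_shared_weight,
                 n_allele_states = n_allele_states,
                 pool_shift = pool_shift, donor_shift = donor_shift,
                 base_repeat = base_repeat, smm_rate = smm_rate,
                 missing_rate = missing_rate,
                 clone_country_fidelity = clone_country_fidelity,
                 country_tilt = country_tilt,
                 repeat_unit_bp = repeat_unit_bp,
                 doses = doses, od_noise_sd = od_noise_sd,
                 archetypes = archetypes),
            class = "sim_config")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha)
  g / sum(g)
}

# clone multiplicities: 1 + geometric draws with mean n_iso/n_gen,
# adjusted to sum exactly to n_iso
.clone_sizes <- function(n_gen, n_iso) {
  if (n_gen == n_iso) return(rep(1L, n_gen))
  p <- n_gen / n_iso
  sizes <- 1L + stats::rgeom(n_gen, p)
  while (sum(sizes) > n_iso) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] - 1L
  }
  while (sum(sizes) < n_iso) {
    i <- sample.int(n_gen, 1L)
    sizes[i] <- sizes[i] + 1L
  }
  sizes
}

#' Simulate a diploid-triploid microsatellite complex with known truth
#'
#' See [sim_config()] for the generative model. Fully reproducible from
#' the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list: `dataset` (an [msat_dataset()]), `truth` (data.frame per
#'   isolate: group, pools, true ploidy, genotype id, extra alleles),
#'   `extra_alleles` (data.frame of donor-contributed (locus, allele)
#'   pairs), `pools` (allele-frequency list, pool x locus).
#' @export
simulate_complex <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gr <- cfg$groups
  pool_names <- unique(c(gr$core_pool, stats::na.omit(gr$extra_pool)))
  core_names <- unique(gr$core_pool)
  donor_names <- setdiff(pool_names, core_names)
  # one shared window for all core pools; each donor pool far away
  core_window <- seq.int(cfg$base_repeat,
                         cfg$base_repeat + cfg$n_allele_states - 1L)
  windows <- stats::setNames(rep(list(core_window), length(core_names)),
                             core_names)
  for (d in seq_along(donor_names)) {
    start <- cfg$base_repeat + cfg$donor_shift + (d - 1L) * cfg$pool_shift
    windows[[donor_names[d]]] <- seq.int(start,
                                         start + cfg$n_allele_states - 1L)
  }
  shared <- lapply(seq_len(cfg$n_loci), function(j)
    .rdirichlet1(rep(cfg$pool_alpha, cfg$n_allele_states)))
  w <- cfg$core_shared_weight
  pools <- lapply(pool_names, function(p) {
    lapply(seq_len(cfg$n_loci), function(j) {
      own <- .rdirichlet1(rep(cfg$pool_alpha, cfg$n_allele_states))
      f <- if (p %in% core_names) w * shared[[j]] + (1 - w) * own else own
      stats::setNames(f / sum(f), windows[[p]])
    })
  })
  names(pools) <- pool_names
  draw <- function(pool, j, k) {
    f <- pools[[pool]][[j]]
    as.integer(sample(names(f), k, replace = TRUE, prob = f))
  }
  loci <- data.frame(
    name = sprintf("L%02d", seq_len(cfg$n_loci)),
    repeat_unit_bp = rep_len(cfg$repeat_unit_bp, cfg$n_loci),
    offset_bp = rep_len(c(90L, 120L), cfg$n_loci),
    stringsAsFactors = FALSE)

  calls_rows <- list(); truth_rows <- list(); meta_rows <- list()
  extra_pairs <- list()
  iso_counter <- 0L
  for (g in seq_len(nrow(gr))) {
    gname <- gr$name[g]
    triploid <- gr$ploidy[g] == "3n"
    sizes <- .clone_sizes(gr$n_genotypes[g], gr$n_isolates[g])
    cn <- cfg$countries[[gname]]
    if (is.finite(cfg$country_tilt)) {
      cn <- stats::setNames(.rdirichlet1(cfg$country_tilt * cn / sum(cn)),
                            names(cn))
    }
    for (t in seq_len(gr$n_genotypes[g])) {
      core <- lapply(seq_len(cfg$n_loci), function(j)
        draw(gr$core_pool[g], j, 2L))
      extra <- if (triploid) {
        vapply(seq_len(cfg$n_loci), function(j)
          draw(gr$extra_pool[g], j, 1L), integer(1))
      } else NULL
      gid <- sprintf("%s-g%02d", gname, t)
      home_country <- sample(names(cn), 1L, prob = cn)
      if (triploid) {
        for (j in seq_len(cfg$n_loci)) {
          extra_pairs[[length(extra_pairs) + 1L]] <- data.frame(
            locus = loci$name[j], allele = extra[j], group = gname,
            stringsAsFactors = FALSE)
        }
      }
      for (copy in seq_len(sizes[t])) {
        iso_counter <- iso_counter + 1L
        iso_id <- sprintf("iso%04d", iso_counter)
        row <- vector("list", cfg$n_loci)
        for (j in seq_len(cfg$n_loci)) {
          alleles <- c(core[[j]], if (triploid) extra[j])
          mut <- stats::runif(length(alleles)) < cfg$smm_rate
          if (any(mut)) {
            alleles[mut] <- alleles[mut] +
              sample(c(-1L, 1L), sum(mut), replace = TRUE)
            alleles <- pmax(alleles, 1L)
          }
          if (stats::runif(1) < cfg$missing_rate) {
            row[j] <- list(NULL)
          } else {
            row[[j]] <- sort(unique(alleles))
          }
        }
        calls_rows[[iso_counter]] <- row
        country <- if (stats::runif(1) < cfg$clone_country_fidelity) {
          home_country
        } else {
          sample(names(cn), 1L, prob = cn)
        }
        meta_rows[[iso_counter]] <- data.frame(
          isolate_id = iso_id, country = country,
          substrate = gr$substrate[g], group = gname,
          stringsAsFactors = FALSE)
        truth_rows[[iso_counter]] <- data.frame(
          isolate_id = iso_id, group = gname,
          core_pool = gr$core_pool[g],
          extra_pool = if (triploid) gr$extra_pool[g] else NA_character_,
          ploidy = gr$ploidy[g], genotype_id = gid,
          extra_alleles = if (triploid)
            paste(loci$name, extra, sep = ":", collapse = ";") else "",
          archetype = gr$archetype[g],
          stringsAsFactors = FALSE)
      }
    }
  }
  n <- iso_counter
  calls <- matrix(vector("list", n * cfg$n_loci), n, cfg$n_loci)
  for (i in seq_len(n)) {
    for (j in seq_len(cfg$n_loci)) calls[i, j] <- calls_rows[[i]][j]
  }
  meta <- do.call(rbind, meta_rows)
  cents <- country_centroids()
  hit <- match(meta$country, cents$country)
  meta$lat <- cents$lat[hit]
  meta$lon <- cents$lon[hit]
  truth <- do.call(rbind, truth_rows)
  extra_df <- unique(do.call(rbind, extra_pairs))
  list(dataset = msat_dataset(calls, loci, meta),
       truth = truth,
       extra_alleles = extra_df,
       pools = pools)
}

# noiseless logistic OD trajectory; rate r in divisions/h, lag L in h
.logistic_od <- function(times, r, plateau, lag, od0 = 0.1) {
  if (r <= 0 || plateau <= od0) return(rep(od0, length(times)))
  te <- pmax(times - lag, 0)
  rl <- r * log(2)
  plateau * od0 * exp(rl * te) / (plateau - od0 + od0 * exp(rl * te))
}

#' Simulate dose-response growth curves for a strain panel
#'
#' Three replicates per strain and dose, sampled every 24 h to 300 h.
#' Tolerant archetypes keep their rate and plateau across doses (lag may
#' lengthen); sensitive archetypes lose rate and plateau with dose,
#' including total growth failure where the rate multiplier is 0. Strain
#' level lognormal jitter (sd 5%) individualises curves; Gaussian OD noise
#' is added per reading.
#'
#' @param cfg a [sim_config()].
#' @param strains data.frame with `strain` and `archetype`
#'   (`"tolerant"`/`"sensitive"`).
#' @param seed integer seed (defaults to the config seed).
#' @return list: `curves` (long-format data.frame `strain`, `dose`,
#'   `replicate`, `time_h`, `od600`), `truth` (per strain x dose: true
#'   rate, plateau, lag, grows).
#' @export
simulate_growth <- function(cfg, strains, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"),
            all(c("strain", "archetype") %in% names(strains)))
  set.seed(seed)
  times <- seq(0, 300, by = 24)
  rows <- list(); truth <- list()
  for (s in seq_len(nrow(strains))) {
    at <- cfg$archetypes[[strains$archetype[s]]]
    jit <- exp(stats::rnorm(3, 0, 0.05))    # strain-level r, plateau, lag
    r_s <- at$r * jit[1]; K_s <- at$plateau * jit[2]; L_s <- at$lag * jit[3]
    for (d in seq_along(cfg$doses)) {
      r_d <- r_s * at$rate_mult[d]
      K_d <- 0.1 + (K_s - 0.1) * at$plateau_mult[d]
      L_d <- L_s + at$lag_add[d]
      grows <- r_d > 0 && at$plateau_mult[d] > 0
      truth[[length(truth) + 1L]] <- data.frame(
        strain = strains$strain[s], dose = cfg$doses[d],
        r = if (grows) r_d else 0, plateau = if (grows) K_d else 0.1,
        lag = if (grows) L_d else NA_real_, grows = grows,
        stringsAsFactors = FALSE)
      for (rep_i in 1:3) {
        od <- if (grows) .logistic_od(times, r_d, K_d, L_d) else
          rep(0.1, length(times))
        od <- pmax(od + stats::rnorm(length(od), 0, cfg$od_noise_sd), 0.01)
        rows[[length(rows) + 1L]] <- data.frame(
          strain = strains$strain[s], dose = cfg$doses[d],
          replicate = rep_i, time_h = times, od600 = od,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(curves = do.call(rbind, rows), truth = do.call(rbind, truth))
}
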