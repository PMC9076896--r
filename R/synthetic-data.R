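# Synthetic transplant-experiment generator: species pools with known
# vital-rate parameter surfaces, individual-level demographic records, and
# ground-truth population growth rates.

.DEFAULT_ELEVATIONS <- c(890, 1400, 1900)
.TRUE_MESH_RANGE <- c(-3, 5)  # log-biomass bounds used for true-parameter IPMs

#' Generate a pool of species with known vital-rate parameter surfaces
#'
#' Each species carries the true coefficients of its size-dependent vital
#' rates (survival, growth, flowering, fecundity), size-independent
#' recruitment probabilities (germination, establishment), an offspring size
#' distribution, and competition parameters: the competitive effect it exerts
#' as a background monoculture and its response to competition. Species
#' belong to one of two origin groups (lowland or highland) whose vital rates
#' may decline away from their home elevation.
#'
#' Scenarios:
#' \describe{
#'   \item{neutral}{all elevation slopes are exactly zero; true growth rates
#'     are identical at every site.}
#'   \item{range_limited}{lowland vital rates decline with increasing
#'     elevation and highland vital rates decline with decreasing elevation,
#'     emulating performance declines beyond elevational range edges.}
#'   \item{facilitation_mix}{as range_limited, but a fraction of
#'     interspecific interactions is facilitative (negative competition
#'     penalty), to exercise the handling of negative sensitivities.}
#' }
#'
#' @param n_lowland,n_highland Number of species per origin group (>= 1).
#' @param scenario One of `"neutral"`, `"range_limited"`,
#'   `"facilitation_mix"`.
#' @param seed Integer seed; pools are reproducible given the seed.
#' @param facilitation_prob Probability that an interspecific interaction is
#'   facilitative under `facilitation_mix` (default 0.15).
#' @return List of `species_spec` objects (class `species_pool`).
#' @export
species_pool <- function(n_lowland, n_highland,
                         scenario = c("neutral", "range_limited",
                                      "facilitation_mix"),
                         seed = 1L, facilitation_prob = 0.15) {
  scenario <- match.arg(scenario)
  stopifnot(n_lowland >= 1, n_highland >= 1)
  set.seed(as.integer(seed))
  n <- n_lowland + n_highland
  origin <- rep(c("lowland", "highland"), c(n_lowland, n_highland))
  ids <- sprintf("%s_%02d", ifelse(origin == "lowland", "low", "high"),
                 c(seq_len(n_lowland), seq_len(n_highland)))

  elev_on <- scenario != "neutral"
  pool <- vector("list", n)
  for (i in seq_len(n)) {
    # species-level heterogeneity around the group-level surfaces
    surv <- c(intercept = 1.3 + stats::rnorm(1, 0, 0.20), size = 0.8,
              elev = if (elev_on) -0.9 else 0)
    grow <- c(intercept = 0.8 + stats::rnorm(1, 0, 0.10), size = 0.7,
              elev = if (elev_on) -0.35 else 0)
    flow <- c(intercept = -0.3 + stats::rnorm(1, 0, 0.15), size = 1.2)
    fec  <- c(intercept = 3.0 + stats::rnorm(1, 0, 0.20), size = 0.7,
              elev = if (elev_on) -0.8 else 0)
    pool[[i]] <- structure(list(
      species_id = ids[i],
      origin = origin[i],
      surv = surv, grow = grow, flow = flow, fec = fec,
      grow_sd = 0.6,
      comp_effect = exp(stats::rnorm(1, 0, 0.15)),
      comp_resp = c(surv = 0.6, grow = 0.26, fec = 0.68) *
        exp(stats::rnorm(1, 0, 0.15)),
      intra_mult = 1.4,
      pair_modifier = stats::setNames(rep(1, n), ids),
      germ = 0.15, estab = 0.30,
      rec_mean = -0.8, rec_sd = 0.5,
      elev_anchor = if (origin[i] == "lowland") 890 else 1900,
      elev_sign = if (origin[i] == "lowland") 1 else -1
    ), class = "species_spec")
  }
  if (scenario == "facilitation_mix") {
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      fac <- others[stats::runif(length(others)) < facilitation_prob]
      pool[[i]]$pair_modifier[ids[fac]] <- -0.3
    }
  }
  names(pool) <- ids
  structure(pool, class = "species_pool", scenario = scenario)
}

# scaled elevation displacement from the species' home elevation
.elev_u <- function(spec, elevation) {
  spec$elev_sign * (elevation - spec$elev_anchor) / 1000
}

# competition penalty exerted on focal `spec` by background `bg` (NULL = none)
.comp_penalty <- function(spec, bg) {
  if (is.null(bg)) return(0)
  mod <- spec$pair_modifier[[bg$species_id]]
  if (is.null(mod) || is.na(mod)) mod <- 1
  bg$comp_effect * mod *
    if (identical(bg$species_id, spec$species_id)) spec$intra_mult else 1
}

#' True vital-rate functions of a species in a given context
#'
#' Evaluates the generator's parameter surfaces at an elevation and
#' (optionally) in the presence of a background competitor, returning the
#' same [vital_rate_set()] container used by estimated rates, so true and
#' estimated kernels are built by identical code.
#'
#' @param spec A `species_spec`.
#' @param elevation Site elevation in metres.
#' @param background A `species_spec` for the background monoculture, or
#'   `NULL` for no competition.
#' @return A `vital_rate_set`.
#' @export
true_vital_rates <- function(spec, elevation, background = NULL) {
  u <- .elev_u(spec, elevation)
  cp <- .comp_penalty(spec, background)
  s_lp <- function(z) spec$surv["intercept"] + spec$surv["size"] * z +
    spec$surv["elev"] * u - spec$comp_resp["surv"] * cp
  g_mu <- function(z) unname(spec$grow["intercept"] + spec$grow["size"] * z +
    spec$grow["elev"] * u - spec$comp_resp["grow"] * cp)
  f_lp <- function(z) spec$flow["intercept"] + spec$flow["size"] * z
  fec_mu <- function(z) unname(exp(spec$fec["intercept"] + spec$fec["size"] * z +
    spec$fec["elev"] * u - spec$comp_resp["fec"] * cp))
  vital_rate_set(
    surv = function(z) unname(stats::plogis(s_lp(z))),
    grow_mean = g_mu, grow_sd = spec$grow_sd,
    flower = function(z) unname(stats::plogis(f_lp(z))),
    fec = fec_mu,
    germ = spec$germ, estab = spec$estab,
    rec_mean = spec$rec_mean, rec_sd = spec$rec_sd
  )
}

#' Ground-truth population growth rate from the generator's parameters
#'
#' Builds an IPM kernel directly from the true parameter surfaces (bypassing
#' any estimation) and returns its dominant eigenvalue. Serves as the oracle
#' against which estimated growth rates are validated.
#'
#' @inheritParams true_vital_rates
#' @param n_bins Mesh resolution (default 100).
#' @return Positive scalar lambda.
#' @export
true_lambda <- function(spec, elevation, background = NULL, n_bins = 100L) {
  mesh <- make_mesh(.TRUE_MESH_RANGE, n_bins = n_bins, extension = 0)
  vr <- true_vital_rates(spec, elevation, background)
  lambda_of(build_kernel(vr, mesh))$lambda
}

#' Table of true growth rates for every context of a design
#'
#' @param pool A `species_pool`.
#' @param design An [experiment_design()]; its `pair_list` and
#'   `site_elevations` define the contexts.
#' @param n_bins Mesh resolution.
#' @return Data frame: species, background ("none" or species id),
#'   site_elevation_m, lambda, ln_lambda.
#' @export
true_lambda_table <- function(pool, design, n_bins = 100L) {
  pl <- design$pair_list
  out <- expand.grid(row = seq_len(nrow(pl)),
                     site_elevation_m = design$site_elevations)
  res <- lapply(seq_len(nrow(out)), function(k) {
    foc <- pl$focal[out$row[k]]
    bgl <- pl$background[out$row[k]]
    bg <- if (bgl == "none") NULL else pool[[bgl]]
    lam <- true_lambda(pool[[foc]], out$site_elevation_m[k], bg,
                       n_bins = n_bins)
    data.frame(species = foc, background = bgl,
               site_elevation_m = out$site_elevation_m[k],
               lambda = lam, ln_lambda = log(lam))
  })
  do.call(rbind, res)
}

#' Define a transplant-experiment design
#'
#' @param site_elevations Strictly increasing site elevations in metres
#'   (default 890, 1400, 1900).
#' @param n_individuals Focal individuals per species x background x site
#'   (default 9).
#' @param n_transitions Number of annual census transitions (default 3).
#' @param pair_list Data frame with columns `focal` and `background`
#'   (species ids; `background = "none"` for no-competition plots). Default:
#'   every focal with no competition, every intraspecific monoculture, and
#'   every interspecific combination, built from `species_ids`.
#' @param species_ids Character vector of species ids used to build the
#'   default `pair_list`.
#' @param drop_combinations Optional data frame (`background`,
#'   `site_elevation_m`) of monocultures that failed to establish; matching
#'   focal x background x site combinations are not simulated.
#' @param seed Integer seed used by [simulate_individuals()].
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(site_elevations = .DEFAULT_ELEVATIONS,
                              n_individuals = 9L, n_transitions = 3L,
                              pair_list = NULL, species_ids = NULL,
                              drop_combinations = NULL, seed = 1L) {
  stopifnot(length(site_elevations) >= 1,
            !is.unsorted(site_elevations, strictly = TRUE),
            n_individuals >= 1, n_transitions >= 1)
  if (is.null(pair_list)) {
    if (is.null(species_ids)) stop("supply pair_list or species_ids")
    pair_list <- rbind(
      data.frame(focal = species_ids, background = "none"),
      expand.grid(focal = species_ids, background = species_ids,
                  stringsAsFactors = FALSE)
    )
  }
  stopifnot(all(c("focal", "background") %in% names(pair_list)))
  structure(list(site_elevations = site_elevations,
                 n_individuals = as.integer(n_individuals),
                 n_transitions = as.integer(n_transitions),
                 pair_list = pair_list,
                 drop_combinations = drop_combinations,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate individual-level demographic records under a design
#'
#' For each focal x background x site combination, `n_individuals` transplants
#' are followed over `n_transitions` annual censuses. At each census,
#' flowering is Bernoulli in the flowering probability at current size, seed
#' counts are Poisson in the expected fecundity for flowering individuals,
#' survival to the next census is Bernoulli in the survival probability, and
#' surviving individuals draw a new size from the Gaussian growth
#' distribution. Individuals that die are replaced at the next census by new
#' transplants (flagged `is_replacement = 1`), mimicking replanting in the
#' field. Recruitment trials (sown/germinated/established counts) and observed
#' seedling sizes are generated per species x site.
#'
#' @param pool A `species_pool`.
#' @param design An `experiment_design`; every species referenced by its
#'   `pair_list` must exist in `pool`.
#' @param n_sown Seeds sown per recruitment trial (default 100).
#' @param n_seedlings Observed seedling sizes per species x site (default 25).
#' @return Object of class `synthetic_dataset`: list with `records`,
#'   `recruitment`, `seedling_sizes`, `truth` (the pool and the true lambda
#'   table) and `design`.
#' @export
simulate_individuals <- function(pool, design, n_sown = 100L,
                                 n_seedlings = 25L) {
  stopifnot(inherits(design, "experiment_design"))
  ids <- vapply(pool, function(s) s$species_id, character(1))
  used <- unique(c(design$pair_list$focal,
                   setdiff(design$pair_list$background, "none")))
  unknown <- setdiff(used, ids)
  if (length(unknown) > 0)
    stop("design references unknown species: ", paste(unknown, collapse = ", "))

  set.seed(design$seed)
  recs <- list()
  counter <- 0L
  for (si in seq_along(design$site_elevations)) {
    E <- design$site_elevations[si]
    for (r in seq_len(nrow(design$pair_list))) {
      foc <- design$pair_list$focal[r]
      bgl <- design$pair_list$background[r]
      if (!is.null(design$drop_combinations)) {
        dc <- design$drop_combinations
        if (any(dc$background == bgl & dc$site_elevation_m == E)) next
      }
      spec <- pool[[foc]]
      bg <- if (bgl == "none") NULL else pool[[bgl]]
      vr <- true_vital_rates(spec, E, bg)
      n <- design$n_individuals

      id_new <- function(k) {
        ids_out <- sprintf("%s_%s_%d_i%06d", foc, bgl, E,
                           counter + seq_len(k))
        counter <<- counter + k
        ids_out
      }
      cur_id <- id_new(n)
      cur_z <- stats::rnorm(n, 0, 0.7)      # transplant size distribution
      cur_rep <- rep(0L, n)
      for (t in seq_len(design$n_transitions)) {
        pfl <- vr$flower(cur_z)
        flowered <- stats::rbinom(n, 1L, pfl)
        seeds <- integer(n)
        if (any(flowered == 1L))
          seeds[flowered == 1L] <-
            stats::rpois(sum(flowered), vr$fec(cur_z[flowered == 1L]))
        ps <- vr$surv(cur_z)
        survived <- stats::rbinom(n, 1L, ps)
        z1 <- rep(NA_real_, n)
        if (any(survived == 1L))
          z1[survived == 1L] <- stats::rnorm(sum(survived),
                                             vr$grow_mean(cur_z[survived == 1L]),
                                             vr$grow_sd)
        recs[[length(recs) + 1L]] <- data.frame(
          individual_id = cur_id, species = foc, origin = spec$origin,
          site_elevation_m = E, background = bgl, year = t,
          size_t = cur_z, survived = survived, size_t1 = z1,
          flowered = flowered, seeds = seeds, is_replacement = cur_rep,
          stringsAsFactors = FALSE)
        # next census: survivors keep their new size, dead are replaced
        dead <- survived == 0L
        cur_z[!dead] <- z1[!dead]
        if (any(dead)) {
          cur_id[dead] <- id_new(sum(dead))
          cur_z[dead] <- stats::rnorm(sum(dead), 0, 0.7)
          cur_rep[dead] <- 1L
        }
        cur_rep[!dead] <- cur_rep[!dead]  # replacement flag persists
      }
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  # recruitment trials and seedling sizes per species x site
  rec_rows <- list(); sdl_rows <- list()
  for (sp in used) {
    spec <- pool[[sp]]
    for (E in design$site_elevations) {
      g <- stats::rbinom(1L, n_sown, spec$germ)
      e <- if (g > 0) stats::rbinom(1L, g, spec$estab) else 0L
      rec_rows[[length(rec_rows) + 1L]] <- data.frame(
        species = sp, site_elevation_m = E, n_sown = n_sown,
        n_germinated = g, n_established = e, stringsAsFactors = FALSE)
      sdl_rows[[length(sdl_rows) + 1L]] <- data.frame(
        species = sp, site_elevation_m = E,
        size = stats::rnorm(n_seedlings, spec$rec_mean, spec$rec_sd),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(records = records,
                 recruitment = do.call(rbind, rec_rows),
                 seedling_sizes = do.call(rbind, sdl_rows),
                 truth = list(pool = pool,
                              lambda = true_lambda_table(pool, design)),
                 design = design),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `records.csv`, `recruitment.csv`, `seedling_sizes.csv` and the
#' ground-truth tables `truth_lambda.csv` into `dir`.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("records.csv", "recruitment.csv",
                            "seedling_sizes.csv", "truth_lambda.csv"))
  utils::write.csv(dataset$records, paths[1], row.names = FALSE)
  utils::write.csv(dataset$recruitment, paths[2], row.names = FALSE)
  utils::write.csv(dataset$seedling_sizes, paths[3], row.names = FALSE)
  utils::write.csv(dataset$truth$lambda, paths[4], row.names = FALSE)
  invisible(paths)
}
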