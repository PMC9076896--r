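# End-to-end convenience wrappers tying the modules together.

#' Fit vital rates for every species in a dataset
#'
#' @param dataset A `synthetic_dataset`, or a list with elements `records`,
#'   `recruitment`, `seedling_sizes`.
#' @param ... Passed to [fit_species_vital_rates()].
#' @return Named list of `species_fits`.
#' @export
fit_all_species <- function(dataset, ...) {
  sp <- unique(dataset$records$species)
  out <- lapply(sp, function(s)
    fit_species_vital_rates(dataset$records, dataset$recruitment,
                            dataset$seedling_sizes, s, ...))
  stats::setNames(out, sp)
}

#' Contexts (species x background x site) implied by a design
#'
#' @param design An [experiment_design()].
#' @return Data frame with columns `species`, `background`,
#'   `site_elevation_m`, one row per kernel to build.
#' @export
contexts_from_design <- function(design) {
  pl <- design$pair_list
  out <- do.call(rbind, lapply(design$site_elevations, function(E)
    data.frame(species = pl$focal, background = pl$background,
               site_elevation_m = E, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Origin lookup for a species pool
#'
#' @param pool A `species_pool`.
#' @return Named character vector, species id -> origin.
#' @export
pool_origins <- function(pool) {
  vapply(pool, function(s) s$origin, character(1))
}
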