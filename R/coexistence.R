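# Sensitivities to competition, niche and relative fitness differences,
# coexistence metric, and classification of pairwise competitive outcomes.

#' Sensitivity to competition
#'
#' The proportional reduction of a focal species' log growth rate when
#' invading a competitor's resident monoculture:
#' S = 1 - ln(lambda_invasion) / ln(lambda_intrinsic). Positive values
#' indicate competition (larger = stronger); negative values indicate
#' facilitation. A zero intrinsic log growth rate leaves the sensitivity
#' undefined (NA).
#'
#' @param ln_lambda_invasion,ln_lambda_intrinsic Log population growth rates
#'   (vectorized).
#' @return Numeric vector of sensitivities; NA where undefined.
#' @export
sensitivity <- function(ln_lambda_invasion, ln_lambda_intrinsic) {
  out <- 1 - ln_lambda_invasion / ln_lambda_intrinsic
  out[ln_lambda_intrinsic == 0] <- NA_real_
  out
}

#' Niche difference, relative fitness difference, and coexistence metric
#'
#' For a pair with positive sensitivities S_ij (species i invading j's
#' monoculture) and S_ji: the niche difference is one minus the geometric
#' mean of the sensitivities, ND = 1 - sqrt(S_ij S_ji); the relative fitness
#' difference is their geometric standard deviation, RFD = sqrt(S_ji / S_ij),
#' under the caller's ordering convention; and the coexistence metric is
#' 1 / (RFD' (1 - ND)) with RFD' the fitness difference oriented to be >= 1,
#' so that the metric is invariant to exchanging i and j (algebraically equal
#' to 1 / max(S_ij, S_ji)). Values above 1 indicate stable coexistence, with
#' larger values indicating stronger stabilization.
#'
#' Facilitative pairs (either sensitivity <= 0) are incompatible with these
#' definitions and yield NA for all three quantities.
#'
#' @param S_ij,S_ji Sensitivities (vectorized).
#' @return Data frame with columns `ND`, `niche_overlap` (1 - ND), `RFD`,
#'   `ln_RFD`, `metric`, `facilitative` (logical).
#' @examples
#' niche_fitness(0.5, 0.8)  # ND ~ 0.3675, RFD ~ 1.2649, metric = 1.25
#' @export
niche_fitness <- function(S_ij, S_ji) {
  fac <- !(S_ij > 0 & S_ji > 0)
  ok <- which(!fac & !is.na(fac))
  nd <- rfd <- metric <- rep(NA_real_, length(fac))
  nd[ok] <- 1 - sqrt(S_ij[ok] * S_ji[ok])
  rfd[ok] <- sqrt(S_ji[ok] / S_ij[ok])
  rfd_or <- pmax(rfd, 1 / rfd)
  metric[ok] <- 1 / (rfd_or[ok] * (1 - nd[ok]))
  data.frame(ND = nd, niche_overlap = 1 - nd, RFD = rfd, ln_RFD = log(rfd),
             metric = metric, facilitative = fac | is.na(fac))
}

#' Classify the outcome of pairwise competition by mutual invasibility
#'
#' A species invades its competitor's resident monoculture when its
#' sensitivity is below 1 (equivalently, when its invasion growth rate is
#' positive, given a positive intrinsic growth rate). Both invade: stable
#' coexistence. Neither: priority effect (the initially established species
#' excludes the other). Exactly one: competitive exclusion by the invader.
#'
#' @param S_ij,S_ji Sensitivities (vectorized); may be negative
#'   (facilitation).
#' @return Character vector: `"stable_coexistence"`, `"priority_effect"`, or
#'   `"competitive_exclusion"`; NA where a sensitivity is NA.
#' @export
classify_outcome <- function(S_ij, S_ji) {
  inv_i <- S_ij < 1
  inv_j <- S_ji < 1
  out <- ifelse(inv_i & inv_j, "stable_coexistence",
                ifelse(!inv_i & !inv_j, "priority_effect",
                       "competitive_exclusion"))
  out[is.na(S_ij) | is.na(S_ji)] <- NA_character_
  out
}

# ordering convention: for mixed-origin pairs i = highland, j = lowland
# (so ln RFD < 0 means the lowland species is competitively dominant);
# same-origin pairs are ordered alphabetically.
.order_pair <- function(a, b, origins) {
  oa <- origins[[a]]; ob <- origins[[b]]
  if (oa != ob) {
    if (oa == "highland") c(a, b) else c(b, a)
  } else {
    sort(c(a, b))
  }
}

#' Pairwise coexistence table from a table of growth rates
#'
#' Joins intrinsic and invasion growth rates for every species pair present
#' in both directions at each site (and bootstrap replicate, when a
#' `replicate` column is present), and computes sensitivities, niche and
#' relative fitness differences, the coexistence metric, and the competitive
#' outcome.
#'
#' Pairs with a facilitative direction (sensitivity <= 0) are flagged and
#' excluded from ND/RFD/metric but retain their growth rates and outcome.
#' Pairs where a species cannot persist alone (ln lambda_intrinsic < 0) are
#' flagged `intrinsic_nonpersistent`; their ND/RFD are retained (sensitivity
#' is a proportional impact, independent of the growth-rate level) and their
#' outcome is classified from the invasion growth-rate signs directly.
#'
#' @param lambda_table Data frame with columns `species`, `background`
#'   (`"none"` for intrinsic contexts), `site_elevation_m`, `ln_lambda`, and
#'   optionally `replicate`.
#' @param origins Named character vector mapping species id to `"lowland"` or
#'   `"highland"`.
#' @return Data frame with one row per pair x site (x replicate): species_i,
#'   species_j, pair_type, site_elevation_m, replicate, sensitivities, ND,
#'   niche_overlap, RFD, ln_RFD, metric, outcome and flags.
#' @export
pair_table <- function(lambda_table, origins) {
  lt <- lambda_table
  if (!"replicate" %in% names(lt)) lt$replicate <- 0L
  key <- function(sp, bg, site, rep)
    paste(sp, bg, site, rep, sep = "\r")
  lam <- stats::setNames(lt$ln_lambda,
                         key(lt$species, lt$background,
                             lt$site_elevation_m, lt$replicate))
  sp_ids <- unique(lt$species)
  cand <- unique(lt[lt$background != "none" &
                      lt$background != lt$species,
                    c("species", "background")])
  pairs <- unique(t(apply(cand, 1, function(r)
    .order_pair(r[[1]], r[[2]], origins))))
  dimnames(pairs) <- NULL
  sites <- unique(lt$site_elevation_m)
  reps <- unique(lt$replicate)

  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    ptype <- paste(sort(c(origins[[i]], origins[[j]]), decreasing = TRUE),
                   collapse = "-")  # lowland-lowland, lowland-highland, ...
    for (s in sites) {
      k_i <- key(i, "none", s, reps);  k_j <- key(j, "none", s, reps)
      k_ij <- key(i, j, s, reps);      k_ji <- key(j, i, s, reps)
      have <- k_i %in% names(lam) & k_j %in% names(lam) &
        k_ij %in% names(lam) & k_ji %in% names(lam)
      if (!any(have)) next
      ll_i <- unname(lam[k_i[have]]); ll_j <- unname(lam[k_j[have]])
      ll_ij <- unname(lam[k_ij[have]]); ll_ji <- unname(lam[k_ji[have]])
      S_ij <- sensitivity(ll_ij, ll_i)
      S_ji <- sensitivity(ll_ji, ll_j)
      nf <- niche_fitness(S_ij, S_ji)
      nonpers <- ll_i < 0 | ll_j < 0
      undef <- is.na(S_ij) | is.na(S_ji)
      # invasion criterion: S < 1 when the species persists alone; the sign
      # of the invasion growth rate directly otherwise
      inv_i <- ifelse(ll_i > 0, S_ij < 1, ll_ij > 0)
      inv_j <- ifelse(ll_j > 0, S_ji < 1, ll_ji > 0)
      outcome <- ifelse(inv_i & inv_j, "stable_coexistence",
                        ifelse(!inv_i & !inv_j, "priority_effect",
                               "competitive_exclusion"))
      outcome[undef] <- NA_character_
      flags <- paste0(ifelse(nf$facilitative & !undef, "facilitative_excluded;", ""),
                      ifelse(nonpers, "intrinsic_nonpersistent;", ""),
                      ifelse(undef, "sensitivity_undefined;", ""))
      rows[[length(rows) + 1L]] <- data.frame(
        species_i = i, species_j = j, pair_type = ptype,
        site_elevation_m = s, replicate = reps[have],
        ln_lambda_i = ll_i, ln_lambda_j = ll_j,
        ln_lambda_ij = ll_ij, ln_lambda_ji = ll_ji,
        S_ij = S_ij, S_ji = S_ji,
        ND = nf$ND, niche_overlap = nf$niche_overlap,
        RFD = nf$RFD, ln_RFD = nf$ln_RFD, metric = nf$metric,
        outcome = outcome, flags = sub(";$", "", flags),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop("no species pair has growth rates in both directions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
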