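# Care-seeking: preference weights over the four institution types, the
# community first-visit promotion effect, the categorical type choice, and
# nearest-facility assignment by great-circle distance.

#' Baseline care-seeking preference weights for one patient
#'
#' Looks up the configured preference weights keyed on the patient's disease
#' severity class, age band and income band, and boosts the specialized-
#' hospital weight when the disease is specialized-eligible. Deterministic:
#' the same patient always gets the same weights. Severe-disease patients
#' always have zero weight on community centers.
#'
#' @param patient One row of a [generate_patients()] data frame.
#' @param config A validated `hospexp_config`.
#' @return Named numeric vector of non-negative weights over
#'   [institution_types()], normalized to sum to 1.
#' @export
base_preference <- function(patient, config) {
  W <- preference_matrix(as.data.frame(patient), config)
  w <- W[1, ]
  names(w) <- institution_types()
  w
}

# Vectorized preference lookup: one weight row per patient.
preference_matrix <- function(patients, config) {
  pref <- config$preference
  key <- paste(pref$severity_class, pref$age_band, pref$income_band)
  idx <- match(paste(patients$severity_class, patients$age_band,
                     patients$income_band), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("no preference entry for (%s, %s, %s)",
                 patients$severity_class[bad], patients$age_band[bad],
                 patients$income_band[bad]))
  }
  W <- as.matrix(pref[idx, institution_types(), drop = FALSE])
  elig <- config$diseases$specialized_eligible[
    match(patients$disease_id, config$diseases$id)]
  W[, "specialized"] <- W[, "specialized"] *
    ifelse(elig, config$policy$specialized_boost, 1)
  W <- W / rowSums(W)
  dimnames(W) <- list(NULL, institution_types())
  W
}

#' Apply community first-visit promotion to preference weights
#'
#' Government promotion of the community first-visit system multiplies the
#' community-center weight of minor- and common-severity patients by the
#' promotion degree, then renormalizes. Severe patients are unaffected, and a
#' degree of 1 is the identity.
#'
#' @param weights Named non-negative weight vector over [institution_types()].
#' @param promotion_degree Non-negative scalar (baseline 1).
#' @param severity `"minor"`, `"common"` or `"severe"`.
#' @return Renormalized weight vector.
#' @export
apply_first_visit_promotion <- function(weights, promotion_degree, severity) {
  if (promotion_degree < 0) stop("promotion_degree must be >= 0")
  if (severity != "severe")
    weights["community_center"] <- weights["community_center"] * promotion_degree
  weights / sum(weights)
}

# Vectorized policy action on a weight matrix: promotion multiplier on the
# community column for non-severe rows and, when preferences are
# "rationalized", the tertiary-comprehensive column of the same rows divided
# by the promotion degree (minor cases steered away from topmost hospitals).
apply_policy_weights <- function(W, severity, policy) {
  ns <- severity != "severe"
  deg <- policy$promotion_degree
  W[ns, "community_center"] <- W[ns, "community_center"] * deg
  if (isTRUE(policy$rationalized) && deg > 0)
    W[ns, "tertiary_comprehensive"] <- W[ns, "tertiary_comprehensive"] / deg
  W / rowSums(W)
}

#' Sample an institution type from preference weights
#'
#' @param weights Named non-negative weight vector over [institution_types()];
#'   must have a positive sum.
#' @return One institution type name.
#' @export
choose_institution_type <- function(weights) {
  if (sum(weights) <= 0) stop("all-zero preference weights")
  w <- weights[institution_types()] / sum(weights)
  choose_type_from_uniform(matrix(w, nrow = 1), stats::runif(1))
}

# Inverse-CDF categorical draw in the fixed type order (community last), so
# that under common random numbers a larger community share can only recruit
# patients, never lose them, and a smaller tertiary share only loses them.
choose_type_from_uniform <- function(W, u) {
  c1 <- W[, 1]
  c2 <- c1 + W[, 2]
  c3 <- c2 + W[, 3]
  idx <- 1L + (u > c1) + (u > c2) + (u > c3)
  institution_types()[idx]
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, vectorized over
#' coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 360))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Assign the nearest institution of a chosen type
#'
#' Among institutions of `chosen_type`, returns the one minimizing the
#' great-circle distance to the patient; exact ties are broken by the lowest
#' institution id.
#'
#' @param patient One patient row (fields `lat`, `lon`).
#' @param institutions Institution roster data frame.
#' @param chosen_type Institution type name.
#' @return The chosen institution as a one-row data frame.
#' @export
nearest_institution <- function(patient, institutions, chosen_type) {
  cand <- institutions[institutions$type == chosen_type, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no institution of type ", chosen_type, " available for assignment")
  cand <- cand[order(cand$id), , drop = FALSE]
  d <- haversine_km(patient$lat, patient$lon, cand$lat, cand$lon)
  cand[which.min(d), , drop = FALSE]
}

# Vectorized nearest-facility assignment: returns the institution roster row
# index for each patient, given each patient's chosen type.
assign_institutions <- function(lat, lon, chosen_type, institutions) {
  out <- integer(length(lat))
  for (t in unique(chosen_type)) {
    rows <- which(institutions$type == t)
    if (!length(rows)) stop("no institution of type ", t, " available for assignment")
    rows <- rows[order(institutions$id[rows])]
    p <- which(chosen_type == t)
    m <- length(rows)
    d <- haversine_km(rep(lat[p], each = m), rep(lon[p], each = m),
                      rep.int(institutions$lat[rows], length(p)),
                      rep.int(institutions$lon[rows], length(p)))
    dmat <- matrix(d, ncol = m, byrow = TRUE)
    out[p] <- rows[max.col(-dmat, ties.method = "first")]
  }
  out
}
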