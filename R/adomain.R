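# Applicability-domain gating in structural and physicochemical space.

#' Applicability-domain configuration
#'
#' A prediction is inside the structural domain when the query is similar to
#' at least one training compound with Tanimoto > 0.6 (i.e. minimum Jaccard
#' distance < 0.4) AND the predicted class probability exceeds 0.6. The
#' physicochemical domain replaces the similarity condition with a minimum
#' Euclidean distance below 2.0 in the scaled nine-descriptor space. All four
#' thresholds use strict inequalities.
#'
#' @param max_jaccard_dist,structural_min_prob Structural-domain thresholds.
#' @param max_euclidean,physchem_min_prob Physicochemical-domain thresholds.
#' @return `ad_config` object.
#' @export
ad_config <- function(max_jaccard_dist = 0.4, structural_min_prob = 0.6,
                      max_euclidean = 2.0, physchem_min_prob = 0.6) {
  stopifnot(max_jaccard_dist > 0, max_euclidean > 0,
            structural_min_prob > 0, structural_min_prob < 1,
            physchem_min_prob > 0, physchem_min_prob < 1)
  structure(list(
    structural = list(max_jaccard_dist = max_jaccard_dist,
                      min_class_prob = structural_min_prob),
    physchem = list(max_euclidean = max_euclidean,
                    min_class_prob = physchem_min_prob)
  ), class = "ad_config")
}

ad_verdict <- function(distance, max_prob, max_dist, min_prob,
                       dist_name) {
  fail_sim <- !(distance < max_dist)
  fail_prob <- !(max_prob > min_prob)
  data.frame(
    in_domain = !fail_sim & !fail_prob,
    distance = distance, max_prob = max_prob,
    failed_similarity = fail_sim, failed_probability = fail_prob,
    stringsAsFactors = FALSE
  )
}

#' Structural applicability-domain check
#'
#' In-domain iff minimum Jaccard distance to the training fingerprints is
#' strictly below the threshold (default 0.4, i.e. Tanimoto > 0.6 to at least
#' one training compound) and the predicted class probability is strictly
#' above its threshold (default 0.6).
#'
#' @param min_jaccard Minimum Jaccard distance(s) to training compounds.
#' @param max_prob Predicted class probability(ies).
#' @param cfg An [ad_config()].
#' @return Data frame verdict: `in_domain`, `distance`, `max_prob`,
#'   `failed_similarity`, `failed_probability`.
#' @export
#' @examples
#' structural_ad_check(0.3, 0.7)$in_domain  # TRUE
structural_ad_check <- function(min_jaccard, max_prob, cfg = ad_config()) {
  stopifnot(all(min_jaccard >= 0), all(min_jaccard <= 1),
            all(max_prob >= 0), all(max_prob <= 1))
  ad_verdict(min_jaccard, max_prob,
             cfg$structural$max_jaccard_dist, cfg$structural$min_class_prob)
}

#' Physicochemical applicability-domain check
#'
#' In-domain iff the minimum Euclidean distance to the training compounds in
#' the scaled descriptor space is strictly below the threshold (default 2.0)
#' and the predicted class probability is strictly above its threshold
#' (default 0.6).
#'
#' @param min_euclid Minimum Euclidean distance(s), computed on descriptors
#'   scaled with the training statistics.
#' @param max_prob Predicted class probability(ies).
#' @param cfg An [ad_config()].
#' @return Data frame verdict as in [structural_ad_check()].
#' @export
#' @examples
#' physchem_ad_check(1.5, 0.8)$in_domain  # TRUE
physchem_ad_check <- function(min_euclid, max_prob, cfg = ad_config()) {
  stopifnot(all(min_euclid >= 0), all(max_prob >= 0), all(max_prob <= 1))
  ad_verdict(min_euclid, max_prob,
             cfg$physchem$max_euclidean, cfg$physchem$min_class_prob)
}
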