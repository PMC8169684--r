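# Herbicide-likeness rule filter and the stepwise screening cascade.

#' Herbicide-likeness rule set
#'
#' Six criterion families over raw-unit descriptors: HBD (OH/NH) <= 2;
#' HBA (O/N) <= 6 (strict) or <= 7 (lenient); 0.5 < clogP <= 3.5 (strict) or
#' <= 4.5 (lenient); 20 < TPSA <= 120 A^2; 0.1 < RelPSA <= 0.5;
#' net charge <= 0. A compound passes the filter when it satisfies at least
#' `min_criteria` families (default 4). The lenient variant is the default;
#' both variants are first-class so screens can report both counts.
#'
#' @param variant "lenient" (HBA <= 7, clogP <= 4.5) or "strict"
#'   (HBA <= 6, clogP <= 3.5).
#' @param min_criteria Minimum satisfied families to pass (0..6).
#' @return `likeness_rules` object with the per-family bounds.
#' @export
likeness_rules <- function(variant = c("lenient", "strict"), min_criteria = 4) {
  variant <- match.arg(variant)
  stopifnot(min_criteria >= 0, min_criteria <= 6)
  structure(list(
    variant = variant,
    hbd_max = 2,
    hba_max = if (variant == "strict") 6 else 7,
    clogp_range = c(0.5, if (variant == "strict") 3.5 else 4.5),
    tpsa_range = c(20, 120),
    relpsa_range = c(0.1, 0.5),
    net_charge_max = 0,
    min_criteria = min_criteria
  ), class = "likeness_rules")
}

#' Evaluate the herbicide-likeness criteria
#'
#' @param descriptors A `descriptor_table` (raw units, not scaled) or data
#'   frame with columns HBD, HBA, clogP, TPSA, RelPSA, net_charge.
#' @param rules A [likeness_rules()] object.
#' @return Data frame: one logical flag per criterion family
#'   (`ok_hbd`, `ok_hba`, `ok_clogp`, `ok_tpsa`, `ok_relpsa`, `ok_charge`),
#'   the satisfied-criterion `count`, and `pass` (count >= min_criteria).
#' @export
#' @examples
#' d <- data.frame(HBD = 1, HBA = 5, clogP = 2, TPSA = 60, RelPSA = 0.3,
#'                 net_charge = 0)
#' likeness_evaluate(d)$count  # 6
likeness_evaluate <- function(descriptors, rules = likeness_rules()) {
  d <- as.data.frame(descriptors)
  if (isTRUE(attr(descriptors, "scaled"))) {
    validation_error("likeness evaluation needs raw-unit descriptors")
  }
  need <- c("HBD", "HBA", "clogP", "TPSA", "RelPSA", "net_charge")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    validation_error(paste0("missing descriptor(s): ",
                            paste(miss, collapse = ", ")))
  }
  in_range <- function(x, r) x > r[1] & x <= r[2]  # (lo, hi] bounds
  flags <- data.frame(
    ok_hbd = d$HBD <= rules$hbd_max,
    ok_hba = d$HBA <= rules$hba_max,
    ok_clogp = in_range(d$clogP, rules$clogp_range),
    ok_tpsa = in_range(d$TPSA, rules$tpsa_range),
    ok_relpsa = in_range(d$RelPSA, rules$relpsa_range),
    ok_charge = d$net_charge <= rules$net_charge_max
  )
  flags$count <- rowSums(flags)
  flags$pass <- flags$count >= rules$min_criteria
  if ("id" %in% names(d)) flags <- cbind(id = d$id, flags)
  flags
}

#' Stepwise virtual screening cascade
#'
#' Stage 1 applies the herbicide-likeness filter; stage 2 predicts weed
#' selectivity, gated by the physicochemical applicability domain; stage 3
#' predicts mode of action, gated by the structural applicability domain.
#' Each compound's report row records the furthest stage reached and every
#' quantity computed on the way. In audit mode all stages are computed for
#' every compound regardless of gates (gate verdicts are still reported).
#'
#' @param compounds A `compound_set` with `smiles_clean` (optionally with
#'   pass-through descriptor columns used as overrides).
#' @param selectivity_bundle `classifier_bundle` trained on the scaled
#'   nine-descriptor matrix, with `scaling_stats` attached (see
#'   [train_selectivity_model()]).
#' @param moa_bundle `classifier_bundle` trained on retained MACCS keys, with
#'   `retained_keys` attached (see [train_moa_model()]).
#' @param rules A [likeness_rules()] object.
#' @param ad_cfg An [ad_config()].
#' @param audit Compute all stages for every compound (default FALSE).
#' @return `screening_report` data frame: one row per compound with likeness
#'   flags and count, stage reached (`rejected_likeness`,
#'   `selectivity_predicted`, `moa_predicted`), selectivity and MoA
#'   predictions with probabilities and domain verdicts.
#' @export
screen_cascade <- function(compounds, selectivity_bundle, moa_bundle,
                           rules = likeness_rules(), ad_cfg = ad_config(),
                           audit = FALSE) {
  df <- as.data.frame(compounds)
  if (!("smiles_clean" %in% names(df))) {
    validation_error("compounds need a smiles_clean column")
  }
  keys <- attr(moa_bundle, "retained_keys")
  stats <- attr(selectivity_bundle, "scaling_stats")
  if (is.null(keys) || is.null(stats)) {
    validation_error(paste("bundles must carry retained_keys /",
                           "scaling_stats from their training pipelines"))
  }
  n <- nrow(df)
  overrides <- df[, intersect(names(df), c("clogP", "logD74", "logSw",
                                           "ShapeIndex")), drop = FALSE]
  desc <- physchem_profile(df$smiles_clean, ids = df$id,
                           overrides = if (ncol(overrides)) overrides else NULL)
  like <- likeness_evaluate(desc, rules)

  # stage 2: physicochemical space
  nine <- as.matrix(desc[, selectivity_descriptors()])
  nine_sc <- scale_columns(nine, stats)$scaled
  sel_prob <- class_probabilities(selectivity_bundle, nine_sc)
  sel_dist <- min_euclidean_distance(nine_sc, selectivity_bundle$x_train)
  sel_ad <- physchem_ad_check(sel_dist, sel_prob$max_prob, ad_cfg)

  # stage 3: structural space
  fp <- maccs_fingerprint(df$smiles_clean, ids = df$id)
  fp_sel <- apply_key_selection(fp, keys)
  moa_prob <- class_probabilities(moa_bundle, unclass(fp_sel))
  moa_dist <- min_jaccard_distance(fp_sel, moa_bundle$x_train)
  moa_ad <- structural_ad_check(moa_dist, moa_prob$max_prob, ad_cfg)

  stage <- ifelse(!like$pass, "rejected_likeness",
                  ifelse(sel_ad$in_domain, "moa_predicted",
                         "selectivity_predicted"))
  # gate MoA outputs behind stage progression unless auditing
  blank <- if (audit) rep(FALSE, n) else !like$pass
  report <- data.frame(
    id = df$id,
    like[, setdiff(names(like), "id")],
    stage = stage,
    selectivity_pred = ifelse(blank, NA, sel_prob$label),
    selectivity_prob = ifelse(blank, NA, sel_prob$max_prob),
    selectivity_in_domain = sel_ad$in_domain,
    physchem_distance = sel_dist,
    moa_pred = ifelse(blank, NA, moa_prob$label),
    moa_prob = ifelse(blank, NA, moa_prob$max_prob),
    moa_in_domain = moa_ad$in_domain,
    structural_distance = moa_dist,
    unclassified = !moa_ad$in_domain,
    stringsAsFactors = FALSE
  )
  structure(report, class = c("screening_report", "data.frame"),
            audit = audit, rules_variant = rules$variant)
}

#' Train a mode-of-action model from a compound set
#'
#' Convenience wrapper wiring the fingerprint pipeline into
#' [tune_and_train()]: computes MACCS keys on the training compounds, keeps
#' keys present in more than `min_count` compounds, fits the classifier and
#' attaches the retained-key list the cascade needs.
#'
#' @param set Labelled `compound_set` (uses `moa_label` by default).
#' @param ids Ids of the training compounds (e.g. from [stratified_split()]).
#' @param label_field Label column.
#' @param min_count Key-frequency threshold (see [select_frequent_keys()]).
#' @param ... Passed to [tune_and_train()].
#' @return `classifier_bundle` with attribute `retained_keys`.
#' @export
train_moa_model <- function(set, ids = NULL, label_field = "moa_label",
                            min_count = 5, ...) {
  df <- as.data.frame(set)
  if (!is.null(ids)) df <- df[df$id %in% ids, , drop = FALSE]
  fp <- maccs_fingerprint(df$smiles_clean, ids = df$id)
  keys <- select_frequent_keys(fp, min_count)
  fp_sel <- apply_key_selection(fp, keys)
  bundle <- tune_and_train(unclass(fp_sel), df[[label_field]], ...)
  attr(bundle, "retained_keys") <- keys
  bundle
}

#' Train a weed-selectivity model from a compound set
#'
#' Computes the nine-descriptor profile on the training compounds, scales it
#' (statistics learned on the training set only), fits the classifier and
#' attaches the scaling statistics the cascade needs.
#'
#' @param set Labelled `compound_set` (uses `selectivity_label` by default).
#' @param ids Ids of the training compounds.
#' @param label_field Label column.
#' @param ... Passed to [tune_and_train()].
#' @return `classifier_bundle` with attribute `scaling_stats`.
#' @export
train_selectivity_model <- function(set, ids = NULL,
                                    label_field = "selectivity_label", ...) {
  df <- as.data.frame(set)
  if (!is.null(ids)) df <- df[df$id %in% ids, , drop = FALSE]
  desc <- physchem_profile(df$smiles_clean, ids = df$id)
  nine <- as.matrix(desc[, selectivity_descriptors()])
  sc <- scale_columns(nine)
  bundle <- tune_and_train(sc$scaled, df[[label_field]], ...)
  attr(bundle, "scaling_stats") <- sc$stats
  bundle
}
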