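# Structural fingerprints, physicochemical descriptors, scaling.

#' MACCS structural key fingerprints
#'
#' Computes the 166-key MACCS substructure fingerprint for each cleaned
#' structure. Keys are numbered 1..166; the toolkit's padding bits beyond 166
#' are discarded.
#'
#' @param smiles Character vector of cleaned SMILES.
#' @param ids Compound ids (default: names of `smiles` or seq).
#' @return A `fingerprint_matrix`: binary integer matrix (compounds x 166)
#'   with `rownames = ids`, `colnames = "K1".."K166"`, and attribute
#'   `retained_keys` (initially all 166).
#' @export
#' @examples
#' fp <- maccs_fingerprint(c(benzene = "c1ccccc1"))
#' which(fp[1, ] == 1)  # aromatic, six-ring and ring keys
maccs_fingerprint <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  mols <- ob_mols(smiles)
  raw <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  bits <- raw[, 1:166, drop = FALSE]
  storage.mode(bits) <- "integer"
  fingerprint_matrix(bits, ids = ids)
}

#' Construct a fingerprint matrix object
#'
#' @param bits Binary matrix, one row per compound, one column per key.
#' @param ids Row ids.
#' @param retained_keys Sorted integer vector of retained key indices.
#' @return `fingerprint_matrix` object.
#' @export
fingerprint_matrix <- function(bits, ids = rownames(bits),
                               retained_keys = seq_len(ncol(bits))) {
  bits <- as.matrix(bits)
  if (!all(bits %in% c(0L, 1L))) validation_error("fingerprint bits must be 0/1")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(bits)))
  rownames(bits) <- as.character(ids)
  if (is.null(colnames(bits))) colnames(bits) <- paste0("K", seq_len(ncol(bits)))
  retained_keys <- as.integer(retained_keys)
  if (is.unsorted(retained_keys, strictly = TRUE)) {
    validation_error("retained_keys must be strictly ascending")
  }
  structure(bits, class = c("fingerprint_matrix", class(bits)),
            retained_keys = retained_keys)
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d compounds x %d keys (%d retained)\n",
              nrow(x), ncol(x), length(attr(x, "retained_keys"))))
  invisible(x)
}

#' Select keys present in more than `min_count` compounds
#'
#' A key is retained iff its column sum is strictly greater than `min_count`
#' (the default 5 keeps keys present in more than five compounds).
#'
#' @param fp A `fingerprint_matrix`.
#' @param min_count Non-negative integer threshold.
#' @return Sorted integer vector of retained key indices.
#' @export
select_frequent_keys <- function(fp, min_count = 5) {
  if (nrow(fp) == 0) validation_error("empty fingerprint matrix")
  if (min_count < 0) validation_error("min_count must be >= 0")
  which(colSums(fp) > min_count)
}

#' Restrict a fingerprint matrix to a key subset
#'
#' @param fp A `fingerprint_matrix`.
#' @param keys Integer key indices (e.g. from [select_frequent_keys()]).
#' @return `fingerprint_matrix` with only those columns, `retained_keys` set.
#' @export
apply_key_selection <- function(fp, keys) {
  keys <- sort(unique(as.integer(keys)))
  if (length(keys) == 0) validation_error("no keys retained")
  fingerprint_matrix(unclass(fp)[, keys, drop = FALSE],
                     ids = rownames(fp), retained_keys = keys)
}

# SMARTS rule lists for the net-charge heuristic: the estimate is
# (# basic nitrogens, pKa conceptually above 7) minus (# acidic oxygens,
# pKa conceptually below 7), each identified by substructure rules.
default_basic_n_smarts <- function() c(
  primary_aliphatic_amine   = "[NX3;H2;!$(NC=[O,S,N]);!$(Nc);!$(NS(=O)=O);!$(N[#7,#8])]",
  secondary_aliphatic_amine = "[NX3;H1;!$(NC=[O,S,N]);!$(Nc);!$(NS(=O)=O);!$(N[#7,#8])]",
  tertiary_aliphatic_amine  = "[NX3;H0;!$(NC=[O,S,N]);!$(Nc);!$(NS(=O)=O);!$(N[#7,#8]);!$(N=*);!$(N#*)]",
  amidine_guanidine         = "[NX2;$(N=C[NX3])]",
  quaternary_ammonium       = "[NX4+]"
)

default_acidic_o_smarts <- function() c(
  carboxylic = "[OX2H1,OX1-;$([OX2H1,OX1-][CX3]=O)]",
  sulfonic   = "[OX2H1,OX1-;$([OX2H1,OX1-][SX4](=O)=O)]",
  phosphonic = "[OX2H1,OX1-;$([OX2H1,OX1-][PX4]=O)]",
  n_hydroxy  = "[OX2H1;$([OX2H1][#7])]"
)

#' Net-charge estimate from substructure rules
#'
#' The net ionization state at physiological pH is estimated as the number of
#' basic nitrogen atoms minus the number of acidic oxygen atoms, each matched
#' by a configurable SMARTS rule list (proprietary pKa engines are not used).
#'
#' @param smiles Cleaned SMILES vector.
#' @param basic_smarts,acidic_smarts Named SMARTS vectors; defaults cover
#'   aliphatic amines, amidines/guanidines and quaternary N (basic) and
#'   carboxylic, sulfonic, phosphonic and N-hydroxy oxygens (acidic).
#' @return Integer vector: (# basic N) - (# acidic O) per compound.
#' @export
#' @examples
#' net_charge_estimate(c("CC(=O)O", "CCN", "c1ccccc1"))  # -1, +1, 0
net_charge_estimate <- function(smiles,
                                basic_smarts = default_basic_n_smarts(),
                                acidic_smarts = default_acidic_o_smarts()) {
  mols <- ob_mols(smiles)
  basic <- rowSums(vapply(basic_smarts, function(s) smarts_count(mols, s),
                          numeric(length(smiles))) |> matrix(nrow = length(smiles)))
  acidic <- rowSums(vapply(acidic_smarts, function(s) smarts_count(mols, s),
                           numeric(length(smiles))) |> matrix(nrow = length(smiles)))
  as.integer(round(basic - acidic))
}

# LeBas additive atomic volume increments (cm^3/mol) with a flat per-ring
# deduction; a coarse but standard estimate of molar volume at boiling point.
.lebas_increments <- c(C = 14.8, H = 3.7, O = 7.4, N = 15.6, S = 25.6,
                       P = 27.0, F = 8.7, Cl = 24.6, Br = 27.0, I = 37.0,
                       B = 13.0, Si = 32.0)
.lebas_ring_correction <- -15.0

#' LeBas additive molar volume estimate
#'
#' @param smiles Cleaned SMILES vector.
#' @return Molar volumes in cm^3/mol.
#' @export
#' @examples
#' lebas_molar_volume("c1ccccc1")  # benzene: 6C + 6H - ring = 96
lebas_molar_volume <- function(smiles) {
  props <- ob_properties(smiles)
  gs <- mol_graph_stats(smiles)
  vapply(seq_along(smiles), function(i) {
    counts <- parse_formula(props$formula[i])
    inc <- .lebas_increments[names(counts)]
    if (anyNA(inc)) {
      unknown <- names(counts)[is.na(inc)]
      inc[is.na(inc)] <- 20.0  # generic heavy-atom fallback
      warning(sprintf("no LeBas increment for %s; using 20 cm^3/mol",
                      paste(unknown, collapse = ",")))
    }
    sum(inc * counts) + .lebas_ring_correction * gs$n_rings[i]
  }, numeric(1))
}

#' Hayduk-Laudie aqueous diffusion coefficient (log scale)
#'
#' D = 13.26e-5 / (viscosity^1.14 * molar_volume^0.589) cm^2/s, returned as
#' log10 of D expressed in units of 1e-5 cm^2/s.
#'
#' @param molar_volume Solute molar volume, cm^3/mol.
#' @param viscosity Solvent viscosity in centipoise (default: water at 25 C).
#' @return log10(D / 1e-5 cm^2 s^-1).
#' @export
#' @examples
#' hayduk_laudie_log_diffusion(100)  # ~0.00
hayduk_laudie_log_diffusion <- function(molar_volume, viscosity = 0.8904) {
  if (any(!is.finite(molar_volume)) || any(molar_volume <= 0)) {
    hs_error("molar_volume must be positive", "herbiscreen_domain_error")
  }
  if (any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    hs_error("viscosity must be positive", "herbiscreen_domain_error")
  }
  log10(13.26 / (viscosity^1.14 * molar_volume^0.589))
}

# van der Waals radii (Angstrom) for the additive total-surface approximation.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
                Br = 1.85, I = 1.98, S = 1.80, P = 1.80, B = 1.92, Si = 2.10)
# Sum of free-sphere areas overestimates the molecular surface because bonded
# spheres overlap; a flat 1/3 scale reproduces benzene's ~110 A^2 vdW surface.
.surface_overlap_scale <- 1 / 3

approx_total_surface <- function(formula) {
  counts <- parse_formula(formula)
  r <- .vdw_radii[names(counts)]
  r[is.na(r)] <- 1.8
  sum(4 * pi * r^2 * counts) * .surface_overlap_scale
}

#' Physicochemical descriptor profile
#'
#' Computes the descriptor set used by the weed-selectivity models and the
#' herbicide-likeness filter: HBD, HBA (O/N count), clogP, TPSA, RelPSA,
#' net charge, MW, carbon count (Cat), sp3-atom count (sp3At), ShapeIndex,
#' logSw, logDiff, and a pass-through logD74 column. Any descriptor can be
#' overridden with externally computed values (used verbatim and flagged).
#'
#' Open fallbacks stand in where the original calculators are closed tools:
#' clogP is the toolkit's additive atom-contribution logP, logSw is the ESOL
#' estimate, ShapeIndex is topological diameter / heavy-atom count (spherical
#' < 0.5 < linear), logDiff is Hayduk-Laudie on a LeBas molar volume.
#'
#' @param smiles Cleaned SMILES vector.
#' @param ids Optional compound ids.
#' @param overrides Optional data frame (or named list for a single value per
#'   column) of externally supplied descriptor columns; unknown names are a
#'   configuration error.
#' @return Data frame of class `descriptor_table`, one row per compound, with
#'   attributes `scaled = FALSE` and `external` (overridden column names).
#' @export
#' @examples
#' physchem_profile("CCO")[, c("HBD", "HBA", "Cat", "TPSA")]
physchem_profile <- function(smiles, ids = NULL, overrides = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  props <- ob_properties(smiles)
  mols <- ob_mols(smiles)
  gs <- mol_graph_stats(smiles)

  hbd <- smarts_count(mols, "[$([#7;!H0]),$([#8;!H0])]")
  hba <- smarts_count(mols, "[#7,#8]")
  cat_n <- smarts_count(mols, "[#6]")
  sp3 <- smarts_count(mols, "[^3]")
  arom <- smarts_count(mols, "[a]")
  rotb <- smarts_count(mols, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")

  tpsa <- props$TPSA
  tsa <- vapply(props$formula, approx_total_surface, numeric(1))
  relpsa <- pmin(1, ifelse(tsa > 0, tpsa / tsa, 0))
  clogp <- props$logP
  mw <- props$MW
  shape <- ifelse(gs$n_heavy > 0, gs$diameter / gs$n_heavy, 0)
  # ESOL (Delaney) aqueous solubility estimate, log10 mol/L
  ap <- ifelse(gs$n_heavy > 0, arom / gs$n_heavy, 0)
  logsw <- 0.16 - 0.63 * clogp - 0.0062 * mw + 0.066 * rotb - 0.74 * ap
  vol <- lebas_molar_volume(smiles)
  logdiff <- hayduk_laudie_log_diffusion(vol)

  out <- data.frame(
    id = ids,
    HBD = as.integer(hbd), HBA = as.integer(hba), clogP = clogp,
    logD74 = NA_real_, TPSA = tpsa, RelPSA = relpsa,
    net_charge = net_charge_estimate(smiles), MW = mw,
    Cat = as.integer(cat_n), sp3At = as.integer(sp3),
    ShapeIndex = shape, logSw = logsw, logDiff = logdiff,
    stringsAsFactors = FALSE
  )
  external <- character()
  if (!is.null(overrides)) {
    ov <- as.data.frame(overrides, stringsAsFactors = FALSE)
    unknown <- setdiff(names(ov), setdiff(names(out), "id"))
    if (length(unknown)) {
      config_error(paste0("unknown descriptor override(s): ",
                          paste(unknown, collapse = ", ")))
    }
    for (col in names(ov)) {
      v <- rep_len(as.numeric(ov[[col]]), nrow(out))
      out[[col]][!is.na(v)] <- v[!is.na(v)]
    }
    external <- names(ov)
  }
  structure(out, class = c("descriptor_table", "data.frame"),
            scaled = FALSE, external = external)
}

#' The nine descriptors driving the weed-selectivity models
#' @return Character vector of column names.
#' @export
selectivity_descriptors <- function() {
  c("logDiff", "logSw", "ShapeIndex", "Cat", "sp3At", "TPSA", "HBA", "HBD",
    "clogP")
}

#' Column scaling to zero mean and unit sample standard deviation
#'
#' Transforms each column as (x - mean) / sd using the sample sd (n - 1
#' denominator). When `stats` is supplied (learned from a reference/training
#' set), those statistics are applied instead of refitting, so external
#' compounds are placed in the training frame.
#'
#' @param x Numeric matrix or data frame (no fingerprint columns).
#' @param stats Optional `scaling_stats` from a previous call.
#' @return List with `scaled` (matrix) and `stats` (`scaling_stats`: named
#'   means and sds).
#' @export
#' @examples
#' scale_columns(matrix(c(1, 2, 3), ncol = 1))$scaled
scale_columns <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) validation_error("scale_columns needs a numeric matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(stats)) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    zero <- !is.finite(sdv) | sdv == 0
    if (any(zero)) {
      validation_error(paste0("constant column(s): ",
                              paste(colnames(x)[zero], collapse = ", ")))
    }
    stats <- structure(list(mean = mu, sd = sdv), class = "scaling_stats")
  } else {
    if (!inherits(stats, "scaling_stats")) validation_error("bad scaling stats")
    miss <- setdiff(colnames(x), names(stats$mean))
    if (length(miss)) {
      validation_error(paste0("no scaling stats for: ",
                              paste(miss, collapse = ", ")))
    }
  }
  sc <- sweep(sweep(x, 2, stats$mean[colnames(x)], "-"),
              2, stats$sd[colnames(x)], "/")
  list(scaled = sc, stats = stats)
}
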