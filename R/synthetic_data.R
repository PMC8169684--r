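# Synthetic labelled compound sets: scaffold-based classes for structural
# models and physicochemically shifted classes for selectivity models.
# Decoration is a Poisson number of substituents placed uniformly over the
# scaffold's open ring positions; descriptor shifts are realized by weighting
# the substituent pool, never by editing descriptor values after the fact.

#' Built-in scaffold template library
#'
#' Templates are SMILES with `{n}` markers at open substitution slots; during
#' generation a chosen slot becomes a parenthesised substituent branch and
#' unused slots are deleted. The first nine templates are synthetic-herbicide
#' core motifs; the last three are natural-product-like cores (sugar,
#' terpenoid, polyketide fragment) that are structurally remote from them,
#' useful as "unseen family" probes for the structural applicability domain.
#'
#' @return Named character vector of scaffold templates.
#' @export
default_scaffolds <- function() c(
  benzene          = "c1c{1}c{2}c{3}c{4}c1{5}",
  pyridine         = "c1c{1}c{2}nc{3}c1{4}",
  pyrimidine       = "c1{1}nc{2}nc{3}c1{4}",
  triazine         = "c1nc{1}nc{2}n1",
  naphthalene      = "c1cc{1}c2cc{2}c{3}cc2c1",
  thiophene        = "c1c{1}c{2}sc1{3}",
  diphenylurea     = "O=C(Nc1ccc{1}cc1)Nc1ccc{2}cc1{3}",
  phenoxyacetic    = "OC(=O)COc1cc{1}ccc1{2}",
  cyclohexanedione = "O=C1CC(=O)C{1}C{2}C1{3}",
  # natural-product-like cores (sugar, terpenoid, polyketide fragment):
  # structurally remote from the synthetic-herbicide templates above
  pyranose         = "OC1OC(CO)C{1}C(O)C1O",
  decalin          = "C1CC{1}C2CC{2}CCC2C1",
  polyketide       = "CCC(C)C(=O)OCC(O)C{1}CC(=O)C{2}C"
)

# Substituent pool, grouped by physicochemical character.
.sub_pool <- list(
  lipophilic = c("Cl", "Br", "C", "CC", "CCCC", "C(C)(C)C", "C(F)(F)F",
                 "c9ccccc9"),
  polar      = c("C#N", "C(C)=O", "OC(C)=O", "C(OC)=O", "S(C)(=O)=O", "OC"),
  donor      = c("O", "N", "C(N)=O", "S(N)(=O)=O", "NC(C)=O"),
  acidic     = c("C(O)=O")
)

#' Synthetic compound-set specification
#'
#' @param n_classes Number of classes (<= number of scaffolds for the
#'   scaffold-class generator).
#' @param n_per_class Compounds per class.
#' @param scaffold_library Named character vector of scaffold templates with
#'   `{n}` substitution slots (default [default_scaffolds()]).
#' @param decoration_rate Expected substituent count per molecule (Poisson).
#' @param descriptor_shifts Per-class target means for clogP/TPSA/HBD used by
#'   the selectivity generator (see [default_selectivity_shifts()]); an empty
#'   list makes the classes physicochemically indistinguishable.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_classes = 3, n_per_class = 30,
                           scaffold_library = default_scaffolds(),
                           decoration_rate = 2,
                           descriptor_shifts = default_selectivity_shifts(),
                           seed = 1) {
  if (decoration_rate < 0) config_error("decoration_rate must be >= 0")
  bad <- is.na(vapply(scaffold_library,
                      function(s) ob_canonical_one(strip_slots(s)),
                      character(1)))
  if (any(bad)) {
    config_error(paste0("unparseable scaffold(s): ",
                        paste(names(scaffold_library)[bad], collapse = ", ")))
  }
  structure(list(n_classes = n_classes, n_per_class = n_per_class,
                 scaffold_library = scaffold_library,
                 decoration_rate = decoration_rate,
                 descriptor_shifts = descriptor_shifts,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

strip_slots <- function(template) gsub("\\{[0-9]+\\}", "", template)

n_slots <- function(template) {
  length(regmatches(template, gregexpr("\\{[0-9]+\\}", template))[[1]])
}

decorate_scaffold <- function(template, substituents, slots) {
  s <- template
  all_slots <- seq_len(n_slots(template))
  for (i in seq_along(all_slots)) {
    token <- sprintf("{%d}", all_slots[i])
    repl <- if (all_slots[i] %in% slots) {
      sprintf("(%s)", substituents[match(all_slots[i], slots)])
    } else ""
    s <- sub(token, repl, s, fixed = TRUE)
  }
  s
}

# Draw one decorated, parseable molecule from a template.
draw_molecule <- function(template, pool, weights, rate, max_tries = 25) {
  ns <- n_slots(template)
  for (. in seq_len(max_tries)) {
    k <- min(ns, stats::rpois(1, rate))
    if (k == 0) {
      smi <- ob_canonical_one(strip_slots(template))
      if (!is.na(smi)) return(smi)
      next
    }
    slots <- sample(ns, k)
    subs <- sample(pool, k, replace = TRUE, prob = weights)
    smi <- ob_canonical_one(decorate_scaffold(template, subs, slots))
    if (!is.na(smi)) return(smi)
  }
  structure_error(sprintf("could not build a valid molecule from '%s'",
                          template))
}

#' Default physicochemical shift targets for the selectivity classes
#'
#' Encodes the contrasts the selectivity models exploit: non-selective (NS)
#' compounds are polar and hydrophilic (low clogP, high TPSA, ~2 donors);
#' grass-selective (G) compounds are lipophilic with few donors; broadleaf-
#' selective (BL) compounds sit in between with a single donor.
#'
#' @return Named list of per-class targets (clogP, TPSA, HBD).
#' @export
default_selectivity_shifts <- function() {
  list(
    BL = list(clogP = 2.5, TPSA = 60, HBD = 1),
    G  = list(clogP = 3.5, TPSA = 40, HBD = 0),
    NS = list(clogP = 1.0, TPSA = 110, HBD = 2)
  )
}

#' Generate scaffold-separated classes with MoA-style labels
#'
#' Each class is built from one scaffold of the library, decorated with
#' random substituents, so classes are structurally separable (high
#' within-class, low between-class Tanimoto similarity) -- the regime in
#' which structural-fingerprint classifiers are expected to work.
#'
#' @param spec A [synthetic_spec()].
#' @return A `compound_set` with `moa_label` set to the first
#'   `n_classes` mode-of-action codes and `origin = "synthetic"`.
#' @export
generate_scaffold_classes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_classes > length(spec$scaffold_library)) {
    config_error("n_classes exceeds the scaffold library size")
  }
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)
  classes <- label_vocabularies()$moa[seq_len(spec$n_classes)]
  pool <- unlist(.sub_pool, use.names = FALSE)
  weights <- rep(1, length(pool))
  rows <- list()
  for (ci in seq_along(classes)) {
    template <- spec$scaffold_library[[ci]]
    for (j in seq_len(spec$n_per_class)) {
      raw <- draw_molecule(template, pool, weights, spec$decoration_rate)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("SYN-%s-%03d", classes[ci], j),
        smiles_raw = raw, smiles_clean = clean_structure_one(raw),
        moa_label = classes[ci], origin = "synthetic",
        stringsAsFactors = FALSE)
    }
  }
  compound_set(do.call(rbind, rows),
               provenance = sprintf("synthetic scaffold classes (seed %d)",
                                    spec$seed))
}

# Map a (clogP, TPSA, HBD) target to expected substituent counts per group.
# Donor substituents carry one OH/NH each, so the donor mean is the HBD
# target itself; lipophilic and polar means are rough inversions of the
# per-substituent clogP (~ +0.8) and TPSA (~ +35 A^2) increments.
shift_to_group_means <- function(shift, rate_scale = 1) {
  # donor substituents already carry ~30 A^2 of polar surface each, so the
  # polar-group mean covers only the remainder of the TPSA target
  c(lipophilic = max((shift$clogP - 1) / 1.0, 0.05),
    polar = max((shift$TPSA - 20 - 30 * shift$HBD) / 30, 0.05),
    donor = max(shift$HBD, 0.02),
    acidic = if (shift$TPSA >= 100) 0.5 else 0) * rate_scale
}

# Draw one molecule whose substituents are composed per-group: counts per
# substituent group are Poisson with the given means, truncated to the
# scaffold's open slots.
draw_shifted_molecule <- function(template, group_means, max_tries = 25) {
  ns <- n_slots(template)
  # under-dispersed count draw: integer base plus Bernoulli fraction plus
  # sparse two-sided jitter, so a class sits tightly around its target
  count_near <- function(m, jitter = 0.06) {
    b <- floor(m)
    as.integer(max(0, b + stats::rbinom(1, 1, m - b) +
                     stats::rpois(1, jitter) - stats::rpois(1, min(jitter, m))))
  }
  for (. in seq_len(max_tries)) {
    counts <- vapply(group_means, count_near, integer(1))
    # the donor count is the class signature; keep it at the target with only
    # rare jitter, and let an acidic OH (itself a donor) count toward it
    counts["donor"] <- max(0L, count_near(group_means[["donor"]],
                                          jitter = 0.03) - counts["acidic"])
    drawn <- mapply(function(grp, k) {
      if (k > 0) sample(.sub_pool[[grp]], k, replace = TRUE) else character()
    }, names(group_means), counts, SIMPLIFY = FALSE)
    # when draws exceed open slots, keep donor substituents preferentially so
    # the class's H-bond-donor signature survives truncation
    donors <- drawn[["donor"]] %||% character()
    others <- unlist(drawn[setdiff(names(drawn), "donor")], use.names = FALSE)
    subs <- c(donors[seq_len(min(length(donors), ns))],
              if (length(others)) sample(others) else character())
    subs <- subs[seq_len(min(length(subs), ns))]
    if (length(subs) == 0) {
      smi <- ob_canonical_one(strip_slots(template))
    } else {
      slots <- sample(ns, length(subs))
      smi <- ob_canonical_one(decorate_scaffold(template, subs, slots))
    }
    if (!is.na(smi)) return(smi)
  }
  structure_error(sprintf("could not build a valid molecule from '%s'",
                          template))
}

#' Generate selectivity classes with shifted physicochemical distributions
#'
#' All classes share the same small-aromatic scaffold pool, so separation
#' comes only from the physicochemical character of the substituents: the
#' per-class descriptor_shifts weight the substituent groups (polar,
#' lipophilic, H-bond donor, acidic) and modulate the decoration intensity.
#' With empty `descriptor_shifts` every class samples identically, giving a
#' null set on which classifiers should perform at chance.
#'
#' @param spec A [synthetic_spec()]; `descriptor_shifts` must be either empty
#'   or contain entries BL, G, NS.
#' @return A `compound_set` with `selectivity_label` in {BL, G, NS}.
#' @export
generate_selectivity_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  shifts <- spec$descriptor_shifts
  null_case <- length(shifts) == 0
  if (!null_case && !all(c("BL", "G", "NS") %in% names(shifts))) {
    config_error("descriptor_shifts must name BL, G and NS")
  }
  if (!null_case) {
    ok <- vapply(shifts, function(s) s$TPSA >= 0 && s$HBD >= 0, logical(1))
    if (!all(ok)) config_error("unreachable descriptor shift (negative TPSA/HBD)")
  }
  rng <- local_rng(spec$seed)
  on.exit(rng(), add = TRUE)
  # shared slot-rich aromatic scaffolds: separation must come from the
  # substituents, not the ring systems
  scaffolds <- default_scaffolds()[c("benzene", "pyridine", "pyrimidine")]
  classes <- c("BL", "G", "NS")
  rate_scale <- spec$decoration_rate / 2  # default rate 2 leaves means as-is
  rows <- list()
  for (cls in classes) {
    means <- if (null_case) {
      c(lipophilic = 0.7, polar = 0.7, donor = 0.5, acidic = 0.1) * rate_scale
    } else {
      shift_to_group_means(shifts[[cls]], rate_scale)
    }
    for (j in seq_len(spec$n_per_class)) {
      template <- sample(scaffolds, 1)[[1]]
      raw <- draw_shifted_molecule(template, means)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("SEL-%s-%03d", cls, j),
        smiles_raw = raw, smiles_clean = clean_structure_one(raw),
        selectivity_label = cls, origin = "synthetic",
        stringsAsFactors = FALSE)
    }
  }
  compound_set(do.call(rbind, rows),
               provenance = sprintf("synthetic selectivity set (seed %d)",
                                    spec$seed))
}
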