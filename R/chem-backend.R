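# Internal Open Babel backend. All SMILES parsing, canonicalization, SMARTS
# counting and property calculation in the package funnels through here so the
# toolkit is swappable in one place.

#' Error condition helpers
#' @noRd
hs_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "herbiscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

structure_error <- function(msg, smiles = NULL) {
  hs_error(msg, "herbiscreen_structure_error", smiles = smiles)
}
validation_error <- function(msg) hs_error(msg, "herbiscreen_validation_error")
config_error <- function(msg) hs_error(msg, "herbiscreen_config_error")

#' Syntactic pre-check for a SMILES string.
#'
#' Open Babel silently truncates some malformed inputs (e.g. "C(" parses as
#' methane), so unbalanced parentheses, brackets or ring-bond digits are
#' rejected before the toolkit sees them.
#' @noRd
smiles_presanity <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  # every ring-bond digit must appear an even number of times (outside brackets)
  bare <- gsub("\\[[^]]*\\]", "", s)
  bare <- gsub("%[0-9]{2}", "", bare)
  digs <- regmatches(bare, gregexpr("[0-9]", bare))[[1]]
  if (length(digs) && any(table(digs) %% 2 != 0)) return(FALSE)
  TRUE
}

#' Canonicalize one SMILES via Open Babel; NA on failure.
#' @noRd
ob_canonical_one <- function(s) {
  if (!smiles_presanity(s)) return(NA_character_)
  out <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", s),
    error = function(e) ""
  ))
  out <- trimws(strsplit(out, "\t|\n")[[1]][1])
  if (is.na(out) || !nzchar(out)) return(NA_character_)
  out
}

#' Parse a vector of known-good SMILES into OBMol references (batch).
#' @noRd
ob_mols <- function(smiles) {
  stopifnot(length(smiles) >= 1)
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
  if (length(mols) != length(smiles)) {
    structure_error("one or more SMILES failed to parse in batch conversion")
  }
  mols
}

#' Vectorized SMARTS match count over a molecule list.
#' @noRd
smarts_count <- function(mols, smarts) {
  as.numeric(ChemmineOB::smartsSearch_OB(mols, smarts))
}

#' Open Babel bulk properties for a vector of SMILES.
#' @noRd
ob_properties <- function(smiles) {
  ChemmineOB::prop_OB(ob_mols(smiles))
}

#' Parse a molecular formula string ("C8H11ClN2O") into named element counts.
#' Trailing charge annotations ("+", "-", "2-") are dropped.
#' @noRd
parse_formula <- function(formula) {
  f <- gsub("[0-9]*[+-]+$", "", formula)
  m <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  m <- m[nzchar(m)]
  el <- gsub("[0-9]", "", m)
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", m)))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

#' Molecular-graph statistics (heavy atoms, bonds, rings, topological diameter)
#' for a vector of cleaned SMILES. Bonds come from an Open Babel V2000 SDF
#' parsed by ChemmineR; the diameter is computed with igraph.
#' @noRd
mol_graph_stats <- function(smiles) {
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste(smiles, collapse = "\n"))
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdf_txt, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  if (length(sdfs) != length(smiles)) {
    structure_error("SDF round trip lost molecules; unparseable input?")
  }
  out <- data.frame(n_heavy = integer(length(smiles)),
                    n_bonds = integer(length(smiles)),
                    n_rings = integer(length(smiles)),
                    diameter = numeric(length(smiles)))
  for (i in seq_along(smiles)) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    bb <- ChemmineR::bondblock(sdfs[[i]])
    na <- nrow(ab)
    nb <- if (is.null(nrow(bb))) 0L else nrow(bb)
    out$n_heavy[i] <- na
    out$n_bonds[i] <- nb
    if (na <= 1L || nb == 0L) {
      out$n_rings[i] <- 0L
      out$diameter[i] <- 0
      next
    }
    g <- igraph::graph_from_edgelist(
      cbind(as.integer(bb[, 1]), as.integer(bb[, 2])), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, na - igraph::vcount(g)))
    comp <- igraph::components(g)$no
    out$n_rings[i] <- nb - na + comp
    d <- igraph::distances(g)
    out$diameter[i] <- max(d[is.finite(d)])
  }
  out
}
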