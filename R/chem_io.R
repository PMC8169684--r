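# Compound table I/O, structure cleaning, label vocabularies.

#' Label vocabularies used throughout the package
#'
#' Mode-of-action labels follow the legacy HRAC letter codes plus the catch-all
#' "Z" class for compounds with unassigned mode of action. Weed-selectivity
#' labels are BL (broadleaf-selective), G (grass-selective) and NS
#' (non-selective); application-stage labels are PRE, POST and BOTH.
#'
#' @return Named list of character vectors: `moa`, `selectivity`, `stage`,
#'   `origin`.
#' @export
#' @examples
#' label_vocabularies()$selectivity
label_vocabularies <- function() {
  list(
    moa = c("A", "B", "C1", "C2", "C3", "D", "E", "F1", "F2", "F3", "F4",
            "G", "H", "I", "K1", "K2", "K3", "L", "M", "N", "O", "P", "Z"),
    selectivity = c("BL", "G", "NS"),
    stage = c("PRE", "POST", "BOTH"),
    origin = c("synthetic", "bacterial", "fungal", "plant", "other")
  )
}

# Charged-group motifs that must never be neutralized because the charge is
# internally balanced (nitro, N-oxide, azide) -- protected during cleaning.
.protected_motifs <- c(
  "[N+](=O)[O-]", "[N+]([O-])=O", "[O-][N+](=O)", "[O-][N+]",
  "[n+][O-]", "[O-][n+]", "[N+]=[N-]", "[N-]=[N+]", "[N+][O-]"
)

# Simple charged-atom neutralization map applied outside protected motifs.
.neutralize_map <- c(
  "[O-]"   = "O",  "[S-]"  = "S",  "[N-]" = "N", "[NH-]" = "N",
  "[NH3+]" = "N",  "[NH2+]" = "N", "[NH+]" = "N",
  "[nH+]"  = "[nH]", "[OH2+]" = "O", "[OH+]" = "O", "[SH+]" = "S"
)

neutralize_smiles <- function(s) {
  prot <- .protected_motifs
  keys <- vapply(seq_along(prot), function(i) sprintf("\x01%02d\x02", i), "")
  for (i in seq_along(prot)) s <- gsub(prot[i], keys[i], s, fixed = TRUE)
  for (pat in names(.neutralize_map)) {
    s <- gsub(pat, .neutralize_map[[pat]], s, fixed = TRUE)
  }
  for (i in seq_along(prot)) s <- gsub(keys[i], prot[i], s, fixed = TRUE)
  s
}

#' Clean and canonicalize a structure string
#'
#' Applies the standardization used ahead of all descriptor and model work:
#' the largest organic fragment is kept (counter-ions stripped), formal charges
#' are neutralized where a neutral form exists (permanently charged species
#' such as quaternary ammonium, and internally balanced groups such as nitro,
#' are kept as-is), and the canonical SMILES is returned. Deterministic and
#' idempotent.
#'
#' @param smiles Character vector of raw SMILES.
#' @return Character vector of cleaned canonical SMILES.
#' @export
#' @examples
#' clean_structure("CC(=O)[O-].[Na+]")  # acetic acid, neutralized
clean_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  vapply(smiles, clean_structure_one, character(1), USE.NAMES = FALSE)
}

clean_structure_one <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) {
    structure_error("empty structure string", smiles = s)
  }
  can <- ob_canonical_one(s)
  if (is.na(can)) {
    structure_error(sprintf("unparseable SMILES: '%s'", s), smiles = s)
  }
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  if (length(frags) > 1) {
    fm <- ob_mols(frags)
    nheavy <- smarts_count(fm, "[!#1]")
    ncarbon <- smarts_count(fm, "[#6]")
    organic <- ncarbon > 0
    cand <- if (any(organic)) frags[organic] else frags
    nh <- nheavy[match(cand, frags)]
    cand <- cand[nh == max(nh)]
    frag <- sort(cand)[1]  # tie -> lexicographically first canonical string
  } else {
    frag <- frags
  }
  neut <- neutralize_smiles(frag)
  out <- ob_canonical_one(neut)
  if (is.na(out)) out <- ob_canonical_one(frag)  # neutralization produced junk
  out
}

#' Construct a compound set
#'
#' A compound set is a data frame with at least columns `id` and `smiles_raw`,
#' optionally `smiles_clean`, label columns (`moa_label`, `selectivity_label`,
#' `stage_label`, `origin`) and any number of pass-through descriptor columns.
#'
#' @param data Data frame of compound records.
#' @param provenance Free-text source note.
#' @return Object of class `compound_set` (a data frame).
#' @export
compound_set <- function(data, provenance = "") {
  stopifnot(is.data.frame(data))
  if (!all(c("id", "smiles_raw") %in% names(data))) {
    validation_error("compound set needs 'id' and 'smiles_raw' columns")
  }
  data$id <- as.character(data$id)
  if (any(!nzchar(data$id)) || anyNA(data$id)) {
    validation_error("compound ids must be non-empty")
  }
  dup <- unique(data$id[duplicated(data$id)])
  if (length(dup)) {
    validation_error(paste0("duplicate compound ids: ",
                            paste(dup, collapse = ", ")))
  }
  vocab <- label_vocabularies()
  if ("moa_label" %in% names(data)) {
    bad <- !is.na(data$moa_label) & !(data$moa_label %in% vocab$moa)
    if (any(bad)) {
      warning(sprintf("%d unknown MoA label(s) mapped to class 'Z'", sum(bad)))
      data$moa_label[bad] <- "Z"
    }
  }
  for (col in c("selectivity_label", "stage_label", "origin")) {
    voc <- vocab[[sub("_label$", "", sub("origin", "origin", col))]]
    voc <- switch(col, selectivity_label = vocab$selectivity,
                  stage_label = vocab$stage, origin = vocab$origin)
    if (col %in% names(data)) {
      bad <- !is.na(data[[col]]) & !(data[[col]] %in% voc)
      if (any(bad)) {
        warning(sprintf("%d unknown value(s) in %s set to NA", sum(bad), col))
        data[[col]][bad] <- NA
      }
    }
  }
  structure(data, class = c("compound_set", "data.frame"),
            provenance = provenance)
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compounds", nrow(x)))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat(" | ", prov, sep = "")
  cat("\n")
  labs <- intersect(c("moa_label", "selectivity_label", "stage_label", "origin"),
                    names(x))
  if (length(labs)) cat("labels:", paste(labs, collapse = ", "), "\n")
  rej <- attr(x, "rejections")
  if (!is.null(rej) && nrow(rej)) cat(nrow(rej), "rejected row(s)\n")
  invisible(x)
}

#' Rejected rows of a loaded compound table
#'
#' @param set A `compound_set` returned by [load_compound_table()].
#' @return Data frame with columns `id`, `smiles_raw`, `reason` (possibly
#'   zero rows).
#' @export
rejections <- function(set) {
  rej <- attr(set, "rejections")
  if (is.null(rej)) {
    rej <- data.frame(id = character(), smiles_raw = character(),
                      reason = character())
  }
  rej
}

#' Load a compound table from CSV
#'
#' Reads a UTF-8 comma-separated table with a header row, cleans every
#' structure, and collects rows whose SMILES cannot be parsed into a rejection
#' report (available via [rejections()]) instead of silently dropping them.
#'
#' @param path CSV file path.
#' @param id_col,smiles_col Names of the mandatory id and SMILES columns.
#' @param moa_col,selectivity_col,stage_col,origin_col Optional label columns.
#' @param extra_cols Optional character vector of pass-through descriptor
#'   columns to carry along (numeric).
#' @param provenance Free-text source note.
#' @return A [compound_set()] with `smiles_clean` filled in and a
#'   `rejections` attribute.
#' @export
load_compound_table <- function(path, id_col = "id", smiles_col = "smiles",
                                moa_col = NULL, selectivity_col = NULL,
                                stage_col = NULL, origin_col = NULL,
                                extra_cols = NULL, provenance = path) {
  if (!file.exists(path)) config_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) validation_error("empty compound table")
  for (col in c(id_col, smiles_col)) {
    if (!(col %in% names(raw))) {
      config_error(sprintf("mandatory column '%s' missing", col))
    }
  }
  ids <- as.character(raw[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    validation_error(paste0("duplicate compound ids: ",
                            paste(dup, collapse = ", ")))
  }
  smi <- as.character(raw[[smiles_col]])
  clean <- rep(NA_character_, nrow(raw))
  reason <- rep(NA_character_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    clean[i] <- tryCatch(clean_structure_one(smi[i]),
                         herbiscreen_structure_error = function(e) {
                           reason[i] <<- conditionMessage(e)
                           NA_character_
                         })
  }
  keep <- !is.na(clean)
  df <- data.frame(id = ids[keep], smiles_raw = smi[keep],
                   smiles_clean = clean[keep], stringsAsFactors = FALSE)
  grab <- function(col) if (!is.null(col) && col %in% names(raw)) {
    v <- raw[[col]][keep]
    v[!nzchar(trimws(as.character(v)))] <- NA
    as.character(v)
  } else NULL
  if (!is.null(moa_col)) df$moa_label <- grab(moa_col)
  if (!is.null(selectivity_col)) df$selectivity_label <- grab(selectivity_col)
  if (!is.null(stage_col)) df$stage_label <- grab(stage_col)
  if (!is.null(origin_col)) df$origin <- grab(origin_col)
  for (col in extra_cols %||% character()) {
    if (!(col %in% names(raw))) config_error(sprintf("extra column '%s' missing", col))
    df[[col]] <- as.numeric(raw[[col]][keep])
  }
  set <- compound_set(df, provenance = provenance)
  attr(set, "rejections") <- data.frame(
    id = ids[!keep], smiles_raw = smi[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  set
}

#' Save a compound set to CSV
#'
#' Plain data columns only (attributes are not serialized); a save/load round
#' trip through [load_compound_table()] reproduces ids, labels and cleaned
#' SMILES exactly.
#'
#' @param set A `compound_set`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
save_compound_table <- function(set, path) {
  utils::write.csv(as.data.frame(set), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
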