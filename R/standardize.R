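#' Standardize raw structures
#'
#' Applies the structure curation pipeline to raw SMILES: keep the largest
#' organic fragment (salt/solvent stripping), neutralize formal charges where
#' chemically possible, canonicalize the tautomer, and strip stereochemistry
#' so that compound identity is constitutional. Standardization is
#' idempotent: re-standardizing an output SMILES returns the same string.
#'
#' @param smiles character vector of input SMILES.
#' @param ids identifiers; defaults to `names(smiles)` or `"S1"..."Sn"`.
#' @return data.frame with columns `id`, `smiles`, `ok` (logical),
#'   `smiles_std`, `mw` (average molecular weight, Da) and a list-column
#'   `elements` of element symbols (including implicit H). Records that fail
#'   to parse have `ok = FALSE` and should be routed to a rejection report
#'   with rule `"unparseable"`.
#' @export
standardize_compounds <- function(smiles, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(smiles))) names(smiles) else
      paste0("S", seq_along(smiles))
  }
  stopifnot(!anyDuplicated(ids))
  out <- run_chemtool("standardize", ids, smiles)
  data.frame(
    id = out$id,
    smiles = as.character(smiles),
    ok = out$ok == "1",
    smiles_std = out$smiles_std,
    mw = suppressWarnings(as.numeric(out$mw)),
    elements = I(lapply(out$elements, function(e)
      if (is.na(e) || !nzchar(e)) character() else strsplit(e, " ")[[1]])),
    stringsAsFactors = FALSE
  )
}

#' Eligibility check: molecular weight and element whitelist
#'
#' The two structure-level eligibility rules applied right after
#' standardization: molecular weight within \[`mw_min`, `mw_max`\] Da and
#' elemental composition restricted to a whitelist (C, H, O, N, P, S, F, Cl,
#' Br, I by default).
#'
#' @param records data.frame from [standardize_compounds()] (columns `id`,
#'   `mw`, `elements`).
#' @param config filter configuration, see [default_filter_config()].
#' @return verdict data.frame: `id`, `passed`, list-column `violated_rules`.
#' @export
eligibility_check <- function(records, config = default_filter_config()) {
  rules <- lapply(seq_len(nrow(records)), function(i) {
    v <- character()
    mw <- records$mw[i]
    if (is.na(mw) || mw < config$mw_min || mw > config$mw_max) {
      v <- c(v, "mw_range")
    }
    if (length(setdiff(records$elements[[i]], config$elements)) > 0) {
      v <- c(v, "element_whitelist")
    }
    v
  })
  filter_verdict(records$id, rules)
}

#' Merge SSSR rings into fused ring systems
#'
#' Two rings belong to the same system when they share at least one atom
#' (this covers both classical fusion and spiro junctions). The number of
#' rings in the largest system drives the fused-ring property filter.
#'
#' @param x either a single SMILES string (resolved through the chemistry
#'   backend) or a list of integer vectors of ring atom indices (one vector
#'   per SSSR ring).
#' @return integer vector of ring counts per system, sorted decreasingly;
#'   `integer(0)` for acyclic molecules. The sum over systems always equals
#'   the SSSR ring count.
#' @export
ring_systems <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    out <- run_chemtool("profile", "q", x)
    if (out$ok != "1") stop("unparseable SMILES: ", x)
    x <- parse_ring_atoms(out$ring_atoms)
  }
  stopifnot(is.list(x))
  n <- length(x)
  if (n == 0L) return(integer())
  # union-find over rings keyed on shared atoms
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (length(intersect(x[[i]], x[[j]])) > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

#' @keywords internal
parse_ring_atoms <- function(ring_atoms) {
  if (is.na(ring_atoms) || !nzchar(ring_atoms)) return(list())
  lapply(strsplit(ring_atoms, "|", fixed = TRUE)[[1]],
         function(r) as.integer(strsplit(r, ",", fixed = TRUE)[[1]]))
}

#' Compute the full property profile of standardized structures
#'
#' Populates every descriptor consulted by the property filters plus the
#' reporting descriptors (logP, QED): heavy-atom count, SSSR ring count,
#' ring count of the largest fused system, rotatable bonds, hydrogen-bond
#' donors and acceptors, charged-carbon and N/O flags, and the names of all
#' matching exclusion SMARTS (user-supplied structural alerts plus the
#' built-in tosyl pattern `S(=O)(=O)O`).
#'
#' @param records data.frame with columns `id` and `smiles_std` (from
#'   [standardize_compounds()]), or a character vector of SMILES.
#' @param patterns optional data.frame of structural alerts with columns
#'   `name` and `smarts` (e.g. the "remove"/"extreme caution" alert lists).
#' @param bits,radius Morgan fingerprint parameters (fingerprints are
#'   computed in the same pass and attached as attribute `"fingerprints"`).
#' @return data.frame with one row per record: `id`, `heavy_atoms`, `rings`,
#'   `max_fused_system_rings`, `rotatable_bonds`, `hbd`, `hba`, `logp`,
#'   `qed`, `mw`, `has_charged_carbon`, `has_N_or_O`, list-columns
#'   `matched_exclusion_patterns` and `ring_atom_sets`, and `murcko`.
#' @export
property_profile <- function(records, patterns = NULL,
                             bits = 2048L, radius = 2L) {
  if (is.character(records)) {
    records <- data.frame(id = if (!is.null(names(records))) names(records)
                          else paste0("S", seq_along(records)),
                          smiles_std = as.character(records),
                          stringsAsFactors = FALSE)
  }
  args <- c("--bits", bits, "--radius", radius)
  if (!is.null(patterns)) {
    check_columns(patterns, c("name", "smarts"), "exclusion patterns")
    smarts_file <- tempfile("smarts-", fileext = ".tsv")
    on.exit(unlink(smarts_file), add = TRUE)
    writeLines(paste(patterns$name, patterns$smarts, sep = "\t"), smarts_file)
    args <- c(args, "--smarts", smarts_file)
  }
  out <- run_chemtool("profile", records$id, records$smiles_std, args)
  bad <- out$ok != "1"
  ring_sets <- lapply(out$ring_atoms, parse_ring_atoms)
  profile <- data.frame(
    id = out$id,
    ok = !bad,
    heavy_atoms = suppressWarnings(as.integer(out$heavy_atoms)),
    rings = suppressWarnings(as.integer(out$rings)),
    max_fused_system_rings = vapply(ring_sets, function(r) {
      s <- ring_systems(r); if (length(s)) max(s) else 0L
    }, integer(1)),
    rotatable_bonds = suppressWarnings(as.integer(out$rotatable_bonds)),
    hbd = suppressWarnings(as.integer(out$hbd)),
    hba = suppressWarnings(as.integer(out$hba)),
    logp = suppressWarnings(as.numeric(out$logp)),
    qed = suppressWarnings(as.numeric(out$qed)),
    mw = suppressWarnings(as.numeric(out$mw)),
    has_charged_carbon = out$has_charged_carbon == "1",
    has_N_or_O = out$has_N_or_O == "1",
    matched_exclusion_patterns = I(lapply(out$matched_patterns, function(p)
      if (is.na(p) || !nzchar(p)) character() else strsplit(p, ";")[[1]])),
    ring_atom_sets = I(ring_sets),
    murcko = ifelse(is.na(out$murcko), "", out$murcko),
    stringsAsFactors = FALSE
  )
  fps <- fp_from_bitstrings(ifelse(bad, "", out$fp_bits), bits = bits,
                            ids = out$id)
  attr(profile, "fingerprints") <- fps
  profile
}

#' Merge duplicate standardized structures
#'
#' After stereo-stripping standardization, distinct input records can share
#' one constitution. One record is kept per unique standardized SMILES; the
#' kept identifier is the lexicographically smallest of the merged ids, so
#' the result is independent of input order.
#'
#' @param records data.frame with columns `id` and `smiles_std`.
#' @return the deduplicated records, ordered by kept id.
#' @export
dedupe_compounds <- function(records) {
  check_columns(records, c("id", "smiles_std"), "standardized records")
  keep_id <- vapply(split(records$id, records$smiles_std),
                    function(ids) sort(ids)[1], character(1))
  out <- records[match(keep_id, records$id), , drop = FALSE]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
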