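#' Curate bioactivity records for the prediction reference set
#'
#' Applies the record-level selection criteria to a raw bioactivity table:
#' assay confidence score in \{6, 7, 8, 9\} (single protein or protein
#' complex); data-validity comment missing or `"manually validated"`; not a
#' potential duplicate; measurement type one of Kd, Potency, AC50, IC50,
#' Ki, EC50; activity comment not Inconclusive/inconclusive/unspecified;
#' and not (relation missing while the activity comment is not
#' Active/active). Records in unsupported units are also rejected.
#'
#' Criteria are evaluated in a fixed order and each rejected record is
#' attributed to the first criterion it fails, so every exclusion has
#' exactly one named reason.
#'
#' @param records data.frame with columns `compound_id`, `smiles`,
#'   `target_id`, `confidence`, `validity_comment`, `potential_duplicate`,
#'   `standard_type`, `activity_comment`, `standard_relation`, `value`,
#'   `units`, `year`.
#' @return list with `records` (the retained subset) and `rejected` (the
#'   excluded subset with a `reason` column).
#' @export
filter_bioactivities <- function(records) {
  check_columns(records,
                c("target_id", "confidence", "validity_comment",
                  "potential_duplicate", "standard_type", "activity_comment",
                  "standard_relation", "value", "units"),
                "bioactivity table")
  blank_na <- function(x) ifelse(is.na(x) | !nzchar(as.character(x)),
                                 NA_character_, as.character(x))
  validity <- blank_na(records$validity_comment)
  comment <- blank_na(records$activity_comment)
  relation <- blank_na(records$standard_relation)

  reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, name) {
    reason[is.na(reason) & cond] <<- name
  }
  flag(!(records$confidence %in% 6:9), "confidence")
  flag(!(is.na(validity) | validity == "manually validated"), "validity")
  flag(records$potential_duplicate != 0, "potential_duplicate")
  flag(!(records$standard_type %in%
           c("Kd", "Potency", "AC50", "IC50", "Ki", "EC50")), "standard_type")
  flag(comment %in% c("Inconclusive", "inconclusive", "unspecified"),
       "activity_comment")
  flag(is.na(relation) &
         !(comment %in% c("Active", "active")), "relation")
  flag(!(records$units %in% c("nM", "ug.mL^-1")), "units")

  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(rejected) <- NULL
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept, rejected = rejected)
}

#' Convert a mass concentration to a molar concentration
#'
#' `ugml_to_nM(v, mw) = v * 1e6 / mw`: one microgram per millilitre of a
#' compound of molecular weight `mw` Da corresponds to `1e6 / mw` nmol/L.
#'
#' @param value concentration in ug/mL.
#' @param mw molecular weight in Da; must be positive.
#' @return concentration in nM.
#' @export
ugml_to_nM <- function(value, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  value * 1e6 / mw
}

#' @rdname ugml_to_nM
#' @export
nM_to_ugml <- function(value, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  value * mw / 1e6
}

#' Express all activity values in nM
#'
#' Records reported in ug/mL are converted with [ugml_to_nM()] using the
#' compound's molecular weight; records already in nM are unchanged.
#'
#' @param records curated bioactivity records with columns `value`, `units`
#'   and either an `mw` column or a `smiles_std` column resolvable through
#'   `mw_lookup`.
#' @param mw_lookup optional named numeric vector mapping `smiles_std` to
#'   molecular weight (Da).
#' @return records with `value` in nM and `units` set to `"nM"`.
#' @export
normalize_units <- function(records, mw_lookup = NULL) {
  conv <- which(records$units == "ug.mL^-1")
  if (length(conv) > 0) {
    mw <- if ("mw" %in% names(records)) records$mw[conv]
          else mw_lookup[records$smiles_std[conv]]
    if (any(is.na(mw))) stop("missing molecular weight for unit conversion")
    records$value[conv] <- ugml_to_nM(records$value[conv], mw)
    records$units[conv] <- "nM"
  }
  records
}

#' Merge duplicate compound-target activity records
#'
#' After standardization, several records can describe the same
#' (standardized compound, target) pair. They are merged into one record
#' whose activity is the median of the merged values (arithmetic mean of
#' the two middle values for even counts). The merged record keeps the
#' earliest non-missing publication year, and `n_merged` counts the source
#' records.
#'
#' @param records data.frame with columns `smiles_std`, `target_id`,
#'   `value` (nM) and optionally `year`.
#' @return one record per (smiles_std, target_id), ordered by compound then
#'   target.
#' @export
merge_activity_pairs <- function(records) {
  check_columns(records, c("smiles_std", "target_id", "value"),
                "activity records")
  if (!"year" %in% names(records)) records$year <- NA_integer_
  key <- paste(records$smiles_std, records$target_id, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  out <- lapply(groups, function(idx) {
    years <- records$year[idx]
    years <- years[!is.na(years)]
    data.frame(
      smiles_std = records$smiles_std[idx[1]],
      target_id = records$target_id[idx[1]],
      value = stats::median(records$value[idx]),
      year = if (length(years)) min(years) else NA_integer_,
      n_merged = length(idx),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$smiles_std, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the active compound-target reference set
#'
#' Merged records with activity at or below the threshold (10 uM by
#' default) are labeled active; compounds with at least one active target
#' become reference entries carrying their set of active targets.
#'
#' @param merged data.frame from [merge_activity_pairs()].
#' @param active_threshold activity cutoff in nM (default 10000).
#' @return list with `entries` (data.frame `smiles_std`, list-column
#'   `active_targets`), and `active_records` (the active merged records,
#'   used downstream for novelty dating).
#' @export
build_reference <- function(merged, active_threshold = 10000) {
  active <- merged[merged$value <= active_threshold, , drop = FALSE]
  targets <- lapply(split(active$target_id, active$smiles_std),
                    function(t) sort(unique(t)))
  entries <- data.frame(smiles_std = names(targets),
                        active_targets = I(unname(targets)),
                        stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  rownames(active) <- NULL
  list(entries = entries, active_records = active)
}
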