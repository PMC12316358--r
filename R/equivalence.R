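#' Prednisolone-equivalence table for systemic glucocorticoids
#'
#' Oral systemic glucocorticoids (ATC H02AB) with their WHO defined daily
#' dose (DDD, mg) and anti-inflammatory potency relative to prednisolone.
#' Cumulative dose from a dispensation is `n_ddd * ddd_mg * factor`
#' prednisolone-equivalent mg, so different substances accumulate on one
#' scale.  The factors are the standard clinical conversion ratios
#' (prednisolone 5 mg equivalent to methylprednisolone 4 mg, dexamethasone
#' 0.75 mg, betamethasone 0.6 mg, hydrocortisone 20 mg, cortisone 25 mg);
#' both columns are plain data and can be replaced by the caller.
#'
#' @return a `data.table` with columns `atc_code`, `substance`, `ddd_mg`
#'   and `factor` (prednisolone-equivalence, dimensionless).
#' @export
gc_equivalence_table <- function() {
  data.table(
    atc_code  = c("H02AB01", "H02AB02", "H02AB04", "H02AB06",
                  "H02AB07", "H02AB08", "H02AB09", "H02AB10"),
    substance = c("betamethasone", "dexamethasone", "methylprednisolone",
                  "prednisolone", "prednisone", "triamcinolone",
                  "hydrocortisone", "cortisone"),
    ddd_mg    = c(1.5, 1.5, 7.5, 10, 10, 7.5, 30, 37.5),
    factor    = c(25 / 3, 20 / 3, 1.25, 1, 1, 1.25, 0.25, 0.2)
  )
}

#' ATC to analysis drug-class map
#'
#' Maps ATC code prefixes to the drug classes of the analysis: oral
#' systemic glucocorticoids (`GC`, ATC H02AB), hydroxychloroquine (`HCQ`)
#' and the seven immunosuppressant classes (`IS:*`).  Any dispensation
#' whose ATC code matches no prefix is outside the analysis.
#'
#' @return a `data.table` with columns `atc_prefix` and `drug_class`.
#' @export
atc_class_map <- function() {
  data.table(
    atc_prefix = c("H02AB", "P01BA02",
                   "L04AX01", "L04AX03", "L01BA01", "L04AA06", "L01AA01",
                   "L04AA13", "L04AD02", "L04AD01"),
    drug_class = c("GC", "HCQ",
                   "IS:AZA", "IS:MTX", "IS:MTX", "IS:MMF", "IS:CYC",
                   "IS:LEF", "IS:TAC", "IS:CSA")
  )
}

#' Classify ATC codes into analysis drug classes
#'
#' @param atc_code character vector of ATC codes.
#' @param map class map as from [atc_class_map()].
#' @return character vector of drug classes (`NA` where unclassified).
#' @export
classify_atc <- function(atc_code, map = atc_class_map()) {
  out <- rep(NA_character_, length(atc_code))
  # longest prefixes first so e.g. a full code wins over a class prefix
  ord <- order(-nchar(map$atc_prefix))
  for (i in ord) {
    hit <- is.na(out) & startsWith(atc_code, map$atc_prefix[i])
    out[hit] <- map$drug_class[i]
  }
  out
}

is_is_class <- function(drug_class) {
  !is.na(drug_class) & startsWith(drug_class, "IS:")
}
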