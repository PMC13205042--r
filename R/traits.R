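#' Recode Child-form AQ item scores to the 0-50 total
#'
#' The child form is rated 0-3 per item; for comparability with the
#' adolescent and adult forms, item scores of 0 or 1 count 0 and scores of 2
#' or 3 count 1, giving a total from 0 to 50.  Monotone: raising any raw
#' item never lowers the total.
#'
#' @param itemScores Integer vector of exactly 50 item scores, each in
#'   \{0, 1, 2, 3\}.
#' @return Integer AQ total in [0, 50].
#' @examples
#' recodeChildAq(rep(3, 50))  # 50
#' @export
recodeChildAq <- function(itemScores) {
  if (length(itemScores) != 50L)
    stop("exactly 50 item scores required, got ", length(itemScores))
  if (any(is.na(itemScores)) || any(!itemScores %in% 0:3))
    stop("item scores must be integers in {0, 1, 2, 3}")
  sum(itemScores >= 2L)
}

.aqSubscaleCols <- paste0("aq_", c("attention_switching",
                                   "attention_to_detail", "communication",
                                   "social_skills", "imagination"))

#' Validate and screen a trait/covariate table
#'
#' Applies the inclusion rule for the trait analyses: a participant is
#' retained if they have at least one stability record and a complete AQ
#' total or SRS-2 T-score.  Missing values are preserved (no imputation, no
#' listwise deletion across components); per-trait availability flags
#' (\code{has_aq}, \code{has_srs2}) record which models each participant can
#' enter.  Duplicate participant ids and non-numeric scores are hard errors.
#'
#' @param traits \code{data.frame} with \code{participant_id},
#'   \code{aq_total}, optionally the five \code{aq_*} subscale columns,
#'   \code{srs2_t}, \code{age}, \code{vci}, \code{group}; missing values as
#'   \code{NA} (empty cells in delimited files).
#' @param stability Stability record table with \code{participant_id} (one
#'   row per participant x component).
#' @return A list: \code{clean} (retained rows, with \code{has_aq} /
#'   \code{has_srs2} flags) and \code{report} (dropped ids and reasons, and
#'   any subscale-sum inconsistencies).  Idempotent: validating the clean
#'   table again changes nothing.
#' @export
validateTraits <- function(traits, stability) {
  stopifnot(is.data.frame(traits), "participant_id" %in% names(traits))
  if (anyDuplicated(traits$participant_id))
    stop("duplicate participant ids: ",
         paste(unique(traits$participant_id[
           duplicated(traits$participant_id)]), collapse = ", "))
  for (col in intersect(c("aq_total", "srs2_t", "age", "vci",
                          .aqSubscaleCols), names(traits)))
    if (!is.numeric(traits[[col]]))
      stop("non-numeric scores in column ", col)
  if (!"aq_total" %in% names(traits)) traits$aq_total <- NA_real_
  if (!"srs2_t" %in% names(traits)) traits$srs2_t <- NA_real_
  if (any(traits$aq_total < 0 | traits$aq_total > 50, na.rm = TRUE))
    stop("aq_total outside [0, 50]")
  if (any(traits$srs2_t < 0, na.rm = TRUE))
    stop("srs2_t must be nonnegative")

  issues <- character(0)
  if (all(.aqSubscaleCols %in% names(traits))) {
    subSum <- rowSums(traits[.aqSubscaleCols])
    bad <- which(!is.na(subSum) & !is.na(traits$aq_total) &
                   subSum != traits$aq_total)
    if (length(bad))
      issues <- c(issues, sprintf(
        "subscales do not sum to aq_total for: %s",
        paste(traits$participant_id[bad], collapse = ", ")))
  }

  hasNeural <- traits$participant_id %in% stability$participant_id
  hasAq <- !is.na(traits$aq_total)
  hasSrs <- !is.na(traits$srs2_t)
  keep <- hasNeural & (hasAq | hasSrs)

  dropped <- data.frame(
    participant_id = traits$participant_id[!keep],
    reason = ifelse(!hasNeural[!keep], "no stability records",
                    "no complete AQ or SRS-2 score"),
    stringsAsFactors = FALSE)

  clean <- traits[keep, , drop = FALSE]
  clean$has_aq <- hasAq[keep]
  clean$has_srs2 <- hasSrs[keep]
  rownames(clean) <- NULL
  list(clean = clean, report = list(n_in = nrow(traits),
                                    n_kept = nrow(clean),
                                    dropped = dropped, issues = issues))
}
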