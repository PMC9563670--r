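receptor_stratum <- function(ER, PR, HER2) {
  ifelse(ER == "+" & PR == "+" & HER2 == "+", "ER+PR+HER2+",
  ifelse(ER == "-" & PR == "-" & HER2 == "-", "ER-PR-HER2-",
  ifelse(HER2 == "+", "ER+PR-/ER-PR+/ER-PR-HER2+",
         "ER+PR-/ER-PR+/ER-PR-HER2-")))
}

cohort_strata <- function() {
  expand.grid(
    age_group = c("Age < 55", "Age > 55"),
    race = c("white", "non-white"),
    receptor = c("ER+PR+HER2+", "ER+PR-/ER-PR+/ER-PR-HER2-",
                 "ER+PR-/ER-PR+/ER-PR-HER2+", "ER-PR-HER2-"),
    stringsAsFactors = FALSE
  )[, c("age_group", "race", "receptor")]
}

#' Demographic and clinical stratification of a two-condition cohort
#'
#' Summarizes sample metadata into the 16 matching strata used for an
#' unpaired pre/post comparison: age group (below vs at-or-above 55), race
#' (white vs non-white) and four receptor strata (triple positive;
#' hormone-receptor discordant or negative with HER2 negative; the same with
#' HER2 positive; triple negative). Counts and column percentages (two
#' decimals, half-up rounding) are reported per condition.
#'
#' @param metadata Data frame with columns `condition` (`"pre"`/`"post"`),
#'   `age` (numeric), `race`, `ER`, `PR`, `HER2` (`"+"`/`"-"`).
#' @return Data frame with one row per stratum: `age_group`, `race`,
#'   `receptor`, `pre_n`, `pre_pct`, `post_n`, `post_pct`.
#' @export
cohort_summary <- function(metadata) {
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  need <- c("condition", "age", "race", "ER", "PR", "HER2")
  missing <- setdiff(need, names(metadata))
  if (length(missing)) {
    stop("metadata lacks stratification fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  strata <- cohort_strata()
  out <- cbind(strata,
               pre_n = 0L, pre_pct = 0, post_n = 0L, post_pct = 0)
  if (nrow(metadata)) {
    ag <- ifelse(metadata$age < 55, "Age < 55", "Age > 55")
    rc <- ifelse(metadata$race == "white", "white", "non-white")
    rec <- receptor_stratum(metadata$ER, metadata$PR, metadata$HER2)
    key <- paste(ag, rc, rec, sep = "|")
    skey <- paste(strata$age_group, strata$race, strata$receptor, sep = "|")
    for (cond in c("pre", "post")) {
      n <- table(factor(key[metadata$condition == cond], levels = skey))
      total <- sum(n)
      out[[paste0(cond, "_n")]] <- as.integer(n)
      out[[paste0(cond, "_pct")]] <-
        if (total > 0) round_half_up(100 * as.integer(n) / total, 2) else 0
    }
  }
  rownames(out) <- NULL
  out
}

#' Synthetic metadata for a matched unpaired cohort
#'
#' Builds a sample metadata table realizing a given per-stratum count scheme
#' for an unpaired pre/post cohort (default: a published-style matching scheme
#' with 690 pre-treatment and 45 post-treatment samples across the 16 strata
#' of [cohort_summary()]). Ages and receptor statuses are representative
#' values that land each sample unambiguously in its stratum.
#'
#' @param pre_counts,post_counts Integer vectors of length 16, ordered as the
#'   rows of `cohort_summary()` output.
#' @return Data frame with columns `sample_id`, `condition`, `age`, `race`,
#'   `ER`, `PR`, `HER2`.
#' @export
matched_cohort_metadata <- function(
    pre_counts = c(15L, 31L, 22L, 51L, 89L, 94L, 52L, 30L,
                   21L, 30L, 35L, 25L, 46L, 55L, 48L, 46L),
    post_counts = c(1L, 0L, 1L, 0L, 5L, 6L, 6L, 0L,
                    2L, 3L, 4L, 0L, 7L, 6L, 4L, 0L)) {
  strata <- cohort_strata()
  stopifnot(length(pre_counts) == nrow(strata),
            length(post_counts) == nrow(strata))
  receptor_rep <- c(
    "ER+PR+HER2+" = "+++",
    "ER+PR-/ER-PR+/ER-PR-HER2-" = "+--",
    "ER+PR-/ER-PR+/ER-PR-HER2+" = "+-+",
    "ER-PR-HER2-" = "---"
  )
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    rep3 <- strsplit(receptor_rep[[strata$receptor[i]]], "")[[1]]
    for (cond in c("pre", "post")) {
      n <- if (cond == "pre") pre_counts[i] else post_counts[i]
      if (n == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond,
        age = if (strata$age_group[i] == "Age < 55") 45 else 65,
        race = strata$race[i],
        ER = rep3[1], PR = rep3[2], HER2 = rep3[3],
        stringsAsFactors = FALSE
      )[rep(1L, n), , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(sample_id = sprintf("M%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
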