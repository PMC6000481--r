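#' System Usability Scale (SUS) score
#'
#' Standard SUS scoring of a 10-item response (items 1-5): odd items
#' contribute `score - 1`, even items `5 - score`; the sum is scaled by 2.5
#' to a 0-100 range, so every score is a multiple of 2.5.
#'
#' @param r Numeric vector of 10 item scores in 1..5, or a matrix/data.frame
#'   with one respondent per row and 10 columns.
#' @return Numeric score(s) in `[0, 100]`.
#' @export
#' @examples
#' susScore(rep(c(5, 1), 5))  # best possible answers -> 100
susScore <- function(r) {
  if (is.data.frame(r)) r <- as.matrix(r)
  if (is.matrix(r)) return(apply(r, 1L, susScore))
  if (length(r) != 10L) stop("a SUS response has exactly 10 items")
  if (anyNA(r) || any(r < 1 | r > 5) || any(r != round(r)))
    stop("SUS items must be integers in 1..5")
  odd <- r[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - r[c(2, 4, 6, 8, 10)]
  2.5 * sum(odd, even)
}

#' Default AttrakDiff 2 item map
#'
#' Maps the 28 bipolar items to the four subscales (7 items each) with a
#' polarity flag per item (+1 when the positive pole is the high anchor,
#' -1 for reversed presentation). Shipped as an editable CSV under
#' `extdata`; deployments using a randomised item order or reversed poles
#' supply their own file in the same layout.
#'
#' @param file Path to an alternative item-map CSV.
#' @return Data.frame with columns `item`, `subscale`, `anchor_low`,
#'   `anchor_high`, `polarity`.
#' @export
attrakdiffItemMap <- function(file = system.file("extdata",
                                                 "attrakdiff_items.csv",
                                                 package = "bodymapr")) {
  map <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("item", "subscale", "polarity")
  if (!all(need %in% names(map)))
    stop("item map needs columns: ", paste(need, collapse = ", "))
  if (!setequal(map$item, 1:28))
    stop("item map must cover items 1..28 exactly once")
  map
}

#' AttrakDiff 2 subscale scores
#'
#' Mean of the polarity-adjusted items of each subscale: pragmatic quality,
#' hedonic quality (identity), hedonic quality (stimulation), and
#' attractiveness; each mean lies in `[-3, 3]`.
#'
#' @param r Numeric vector of 28 item scores in -3..3, or a matrix with one
#'   respondent per row.
#' @param itemMap Item-to-subscale map; see [attrakdiffItemMap()].
#' @return Named numeric vector of the four subscale means (or a matrix,
#'   respondents in rows).
#' @export
attrakdiffScores <- function(r, itemMap = attrakdiffItemMap()) {
  if (is.data.frame(r)) r <- as.matrix(r)
  if (is.matrix(r))
    return(t(apply(r, 1L, attrakdiffScores, itemMap = itemMap)))
  if (length(r) != 28L) stop("an AttrakDiff 2 response has exactly 28 items")
  if (anyNA(r) || any(r < -3 | r > 3))
    stop("AttrakDiff items must lie in -3..3")
  itemMap <- itemMap[order(itemMap$item), ]
  adj <- r * itemMap$polarity
  out <- tapply(adj, itemMap$subscale, mean)
  order <- c("pragmatic_quality", "hedonic_identity", "hedonic_stimulation",
             "attractiveness")
  order <- order[order %in% names(out)]
  stats::setNames(as.numeric(out[order]), order)
}

#' ISONORM 9241/10 category scores
#'
#' Mean of the five items in each of the seven dialogue-principle
#' categories (suitability for the task, self-descriptiveness,
#' controllability, conformity with user expectations, error tolerance,
#' suitability for individualization, suitability for learning), each in
#' `[-3, 3]`.
#'
#' @param r Numeric vector of 35 item scores in -3..3 (category-major: items
#'   1-5 category 1, 6-10 category 2, ...), or a matrix with one respondent
#'   per row.
#' @return Named numeric vector of the seven category means (or a matrix).
#' @export
isonormScores <- function(r) {
  cats <- c("suitability_task", "self_descriptiveness", "controllability",
            "conformity_expectations", "error_tolerance",
            "suitability_individualization", "suitability_learning")
  if (is.data.frame(r)) r <- as.matrix(r)
  if (is.matrix(r)) return(t(apply(r, 1L, isonormScores)))
  if (length(r) != 35L)
    stop("an ISONORM 9241/10 response has exactly 35 items (7 x 5)")
  if (anyNA(r) || any(r < -3 | r > 3))
    stop("ISONORM items must lie in -3..3")
  out <- colMeans(matrix(r, nrow = 5L))
  names(out) <- cats
  out
}

#' Compare Likert item tables of two study arms
#'
#' Runs a two-sample t test from summary statistics per item across two
#' tables of (n, mean, sd) rows, as used to compare usability ratings of two
#' app versions. Items with p < .05 are flagged. Missing items are handled
#' through the per-item n; nothing is imputed.
#'
#' @param study1,study2 Data.frames with columns `item`, `n`, `mean`, `sd`;
#'   item sets must match.
#' @param variant Passed to [tTestFromSummary()].
#' @return Data.frame with one row per item: group summaries, `t`, `df`,
#'   `p`, `pFormatted`, `significant`.
#' @export
compareLikertTables <- function(study1, study2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  need <- c("item", "n", "mean", "sd")
  stopifnot(all(need %in% names(study1)), all(need %in% names(study2)))
  if (!identical(as.character(study1$item), as.character(study2$item)))
    stop("item lists of the two studies do not match")
  rows <- lapply(seq_len(nrow(study1)), function(i) {
    tt <- tTestFromSummary(study1$mean[i], study1$sd[i], study1$n[i],
                           study2$mean[i], study2$sd[i], study2$n[i],
                           variant = variant)
    data.frame(item = study1$item[i],
               n1 = study1$n[i], mean1 = study1$mean[i], sd1 = study1$sd[i],
               n2 = study2$n[i], mean2 = study2$mean[i], sd2 = study2$sd[i],
               t = tt$t, df = tt$df, p = tt$p, pFormatted = formatP(tt$p),
               significant = tt$p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score usability response files
#'
#' Reads respondent-per-row CSVs of instrument responses and writes scored
#' output: one row per respondent plus a `mean (SD)` group block, matching
#' the layout of a usability-assessment table.
#'
#' @param file Input CSV (one respondent per row, one column per item).
#' @param instrument `"sus"`, `"attrakdiff"` or `"isonorm"`.
#' @param out Optional output CSV path.
#' @return Data.frame of per-respondent scores with group mean and SD rows
#'   appended.
#' @export
scoreResponsesCSV <- function(file, instrument = c("sus", "attrakdiff",
                                                   "isonorm"),
                              out = NULL) {
  instrument <- match.arg(instrument)
  resp <- utils::read.csv(file, stringsAsFactors = FALSE)
  scores <- switch(instrument,
    sus = data.frame(sus = susScore(resp)),
    attrakdiff = as.data.frame(attrakdiffScores(as.matrix(resp))),
    isonorm = as.data.frame(isonormScores(as.matrix(resp))))
  res <- cbind(data.frame(respondent = as.character(seq_len(nrow(scores)))),
               scores)
  summary <- rbind(
    cbind(data.frame(respondent = "mean"), as.data.frame(t(colMeans(scores)))),
    cbind(data.frame(respondent = "sd"),
          as.data.frame(t(apply(scores, 2L, stats::sd)))))
  res <- rbind(res, summary)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
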