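## Benchmarking: precision/sensitivity of predicted classifications against
## truth labels, per category, at a chosen lineage level.

#' Score classifications against truth labels
#'
#' For each category (a lineage path truncated at `level`, e.g.
#' `"LTR/Copia"`): `tp` = elements predicted and truly in the category;
#' `fp` = predicted in but truly outside it; `fn` = truly in but predicted
#' outside it or not classified to that level.  Unclassified predictions
#' (and predictions shallower than `level`) therefore count against
#' sensitivity only, never against precision — the usual treatment of
#' classifier abstentions.  Elements whose truth label does not reach
#' `level` (or is `"unknown"`) are excluded from scoring.
#'
#' @param predicted data.frame with `element_id` and `order`/`superfamily`/
#'   `clade` columns (e.g. from [classification_table()]).  `"unknown"`
#'   entries are treated as unclassified at that level.
#' @param truth data.frame with the same columns giving the true lineage.
#' @param level `"order"`, `"superfamily"` or `"clade"`.
#' @return data.frame with one row per category: `category`, `tp`, `fp`,
#'   `fn`, `precision`, `sensitivity` (`NaN` where the denominator is 0),
#'   ordered by category.
#' @export
score_classifications <- function(predicted, truth,
                                  level = c("superfamily", "order",
                                            "clade")) {
  level <- match.arg(level)
  depth <- match(level, c("order", "superfamily", "clade"))
  path_at <- function(df) {
    cols <- c("order", "superfamily", "clade")[seq_len(depth)]
    missing <- setdiff(cols, colnames(df))
    if (length(missing)) {
      stop("input lacks level column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    vals <- df[cols]
    vals[] <- lapply(vals, function(v) {
      v <- as.character(v)
      v[!is.na(v) & v == "unknown"] <- NA_character_
      v
    })
    out <- do.call(paste, c(vals, sep = "/"))
    incomplete <- Reduce(`|`, lapply(vals, is.na))
    out[incomplete] <- NA_character_
    out
  }
  truth_path <- stats::setNames(path_at(truth), truth$element_id)
  truth_path <- truth_path[!is.na(truth_path)]
  if (length(truth_path) == 0L) {
    stop("no truth labels reach level '", level, "'", call. = FALSE)
  }
  pred_path <- stats::setNames(path_at(predicted), predicted$element_id)
  pred <- pred_path[names(truth_path)]  # NA when absent or unclassified
  cats <- sort(unique(c(truth_path, stats::na.omit(unname(pred)))))
  rows <- lapply(cats, function(cat) {
    tp <- sum(!is.na(pred) & pred == cat & truth_path == cat)
    fp <- sum(!is.na(pred) & pred == cat & truth_path != cat)
    fn <- sum(truth_path == cat & (is.na(pred) | pred != cat))
    data.frame(category = cat, tp = tp, fp = fp, fn = fn,
               precision = tp / (tp + fp), sensitivity = tp / (tp + fn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pooled (micro-averaged) precision and sensitivity
#'
#' @param scores Output of [score_classifications()].
#' @return Named numeric vector `c(precision =, sensitivity =)` pooling
#'   counts over categories.
#' @export
pooled_scores <- function(scores) {
  c(precision = sum(scores$tp) / sum(scores$tp + scores$fp),
    sensitivity = sum(scores$tp) / sum(scores$tp + scores$fn))
}
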