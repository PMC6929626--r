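#' Glucose-stimulated insulin secretion enhancement index
#'
#' Ratio of the insulin content at the stimulating glucose concentration
#' (15 mM) to the content at the basal concentration (3 mM), each summarized
#' over the triplicate batches of five islets. The other concentrations of
#' the series (6, 8, 10, 30 mM) are carried for dose-response plots but do
#' not enter the index.
#'
#' @param records data.frame rows for one mouse and time point, with columns
#'   `glucose_mM`, `rep1`, `rep2`, `rep3`.
#' @param aggregate `"mean"` (default) or `"median"` across replicates.
#' @return The enhancement index (unitless).
#' @export
enhancement_index <- function(records, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  cond <- function(g) {
    row <- records[records$glucose_mM == g, , drop = FALSE]
    if (nrow(row) == 0L)
      stop(sprintf("missing condition: no %g mM records", g))
    agg(unlist(row[1, c("rep1", "rep2", "rep3")], use.names = FALSE))
  }
  basal <- cond(3)
  if (!is.finite(basal) || basal <= 0)
    stop("zero basal mean: cannot form the enhancement index")
  cond(15) / basal
}

#' Per-mouse enhancement indexes of a secretion table
#'
#' @param table Secretion table as produced by [simulate_secretion()] (or
#'   read with [read_secretion()]): one row per mouse/time point/glucose
#'   concentration.
#' @inheritParams enhancement_index
#' @return data.frame with `mouse_id`, `group`, `timepoint`, `index`.
#' @export
secretion_indexes <- function(table, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  keys <- unique(table[, c("mouse_id", "group", "timepoint")])
  keys$index <- vapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$mouse_id == keys$mouse_id[i] &
                   table$timepoint == keys$timepoint[i], , drop = FALSE]
    enhancement_index(sub, aggregate)
  }, numeric(1))
  rownames(keys) <- NULL
  keys
}

#' Summarize enhancement indexes by group
#'
#' Per-group mean, SD and n, plus a Welch two-sample comparison between the
#' first two groups when both have at least two mice (otherwise the test is
#' skipped with a message).
#'
#' @param indexes data.frame from [secretion_indexes()] (columns `group`,
#'   `index`).
#' @return List with `summary` (data.frame) and `test` (a `test_result` or
#'   `NULL`).
#' @export
summarize_secretion <- function(indexes) {
  grs <- split(indexes$index, indexes$group)
  summ <- data.frame(group = names(grs),
                     mean = vapply(grs, mean, numeric(1)),
                     sd = vapply(grs, stats::sd, numeric(1)),
                     n = vapply(grs, length, integer(1)),
                     row.names = NULL)
  test <- NULL
  if (length(grs) >= 2L && all(lengths(grs[1:2]) >= 2L)) {
    test <- welch_t(grs[[1]], grs[[2]])
  } else {
    message("group comparison skipped: fewer than 2 mice in a group")
  }
  list(summary = summ, test = test)
}

#' Read / write a secretion table as CSV
#'
#' Columns: `mouse_id`, `group`, `timepoint`, `glucose_mM`, `rep1`, `rep2`,
#' `rep3`.
#'
#' @param table Secretion data.frame.
#' @param path CSV path.
#' @export
write_secretion <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_secretion
#' @export
read_secretion <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "timepoint", "glucose_mM",
            "rep1", "rep2", "rep3")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("secretion table missing columns: ", paste(miss, collapse = ", "))
  tab
}
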