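# Data model and I/O for report corpora, case sequences and dataset splits.
#
# A report corpus is a data.frame with columns report_id, tumor_id, date, text
# and one column per classification task (class ids, NA = missing label). The
# six registry tasks are site, subsite, laterality, histology, behavior and
# grade. A case is the date-ordered sequence of all reports sharing one tumor
# ID; cases with a single report carry no case-level context and are filtered
# out.

#' The six registry classification tasks
#' @export
CTX_TASKS <- c("site", "subsite", "laterality", "histology", "behavior", "grade")

parse_report_date <- function(x, report_id = NULL) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ym <- grepl("^\\d{4}-\\d{2}$", x)
  yr <- grepl("^\\d{4}$", x)
  if (any(full)) out[full] <- as.Date(x[full])
  if (any(ym)) out[ym] <- as.Date(paste0(x[ym], "-01"))
  if (any(yr)) out[yr] <- as.Date(paste0(x[yr], "-01-01"))
  bad <- is.na(out)
  if (any(bad)) {
    offender <- if (!is.null(report_id)) report_id[bad][1L] else "<unknown>"
    stop("unparseable date '", x[bad][1L], "' for report_id ", offender)
  }
  out
}

#' Read a report corpus from JSON Lines
#'
#' One JSON object per line with keys `report_id`, `tumor_id`, `date`, `text`
#' and `labels` (a map from task name to class id; absent tasks become NA).
#' Dates are ISO-8601; year or year-month granularity is accepted.
#'
#' @param path path to a JSON-Lines file
#' @param tasks task names to extract from `labels`
#' @return a `report_corpus` data.frame
#' @export
read_report_corpus <- function(path, tasks = CTX_TASKS) {
  recs <- jsonlite::stream_in(file(path), verbose = FALSE, simplifyVector = TRUE)
  df <- data.frame(
    report_id = as.character(recs$report_id),
    tumor_id = as.character(recs$tumor_id),
    date = as.character(recs$date),
    text = as.character(recs$text),
    stringsAsFactors = FALSE
  )
  for (task in tasks) {
    v <- if (!is.null(recs$labels) && task %in% names(recs$labels))
      recs$labels[[task]] else rep(NA, nrow(df))
    df[[task]] <- as.integer(v)
  }
  as_report_corpus(df, tasks)
}

#' Coerce a data.frame to a report corpus
#' @param df data.frame with the corpus columns
#' @param tasks task column names present
#' @return `report_corpus` data.frame
#' @export
as_report_corpus <- function(df, tasks = CTX_TASKS) {
  need <- c("report_id", "tumor_id", "date", "text")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing corpus columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$report_id))
    stop("report_id values must be unique within a corpus")
  structure(df, class = c("report_corpus", "data.frame"),
            tasks = intersect(tasks, names(df)))
}

#' Write a report corpus as JSON Lines
#' @param reports a `report_corpus` data.frame
#' @param path output path
#' @export
write_report_corpus <- function(reports, path) {
  tasks <- intersect(CTX_TASKS, names(reports))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    labels <- as.list(reports[i, tasks, drop = FALSE])
    labels <- labels[!vapply(labels, is.na, logical(1L))]
    rec <- list(report_id = reports$report_id[i],
                tumor_id = reports$tumor_id[i],
                date = as.character(reports$date[i]),
                text = reports$text[i],
                labels = labels)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Group reports into case sequences
#'
#' Reports are grouped by tumor ID and sorted ascending by date (stable, with
#' report_id as lexicographic secondary key for date ties). Cases with exactly
#' one report have no case-level context and are removed.
#'
#' @param reports a `report_corpus` data.frame
#' @return a `case_set`: list of per-case data.frames plus counts
#' @export
build_cases <- function(reports) {
  if (!all(c("tumor_id", "date") %in% names(reports)))
    stop("reports need tumor_id and date columns")
  dates <- parse_report_date(reports$date, reports$report_id)
  ord <- order(reports$tumor_id, dates, reports$report_id, method = "radix")
  df <- reports[ord, , drop = FALSE]
  df$.date <- dates[ord]
  groups <- split(seq_len(nrow(df)), df$tumor_id)
  groups <- groups[lengths(groups) >= 2L]
  cases <- lapply(groups, function(ix) {
    cs <- df[ix, , drop = FALSE]
    rownames(cs) <- NULL
    cs
  })
  structure(
    list(cases = cases,
         n_cases = length(cases),
         n_reports = sum(lengths(groups)),
         n_input_reports = nrow(reports),
         tasks = attr(reports, "tasks") %||% intersect(CTX_TASKS, names(reports))),
    class = "case_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.case_set <- function(x, ...) {
  cat("<case_set> ", x$n_cases, " cases, ", x$n_reports, " reports (mean ",
      format(round(x$n_reports / max(x$n_cases, 1L), 1), nsmall = 1),
      " reports/case)\n", sep = "")
  invisible(x)
}

#' Summary statistics of a case set
#'
#' @param cases a `case_set`
#' @return list with `n_reports`, `n_cases`, `mean_reports_per_case` (exact),
#'   `mean_reports_per_case_1dp` (presentation rounding to one decimal) and a
#'   case-length histogram
#' @export
case_stats <- function(cases) {
  if (cases$n_cases == 0L) stop("case set is empty")
  lens <- vapply(cases$cases, nrow, integer(1L))
  mean_rpc <- cases$n_reports / cases$n_cases
  list(
    n_reports = cases$n_reports,
    n_cases = cases$n_cases,
    mean_reports_per_case = mean_rpc,
    mean_reports_per_case_1dp = round(mean_rpc, 1L),
    length_histogram = table(lens)
  )
}

#' Date-based train/validation/test split of cases
#'
#' Any case containing at least one report dated in or after `cutoff_year` is
#' placed entirely in the test set, simulating prediction on future data. The
#' remaining cases are randomly split at the case level into train and
#' validation (default 80:20), so no case is divided between the two.
#'
#' @param cases a `case_set`
#' @param cutoff_year first test-set year (default 2016)
#' @param train_frac fraction of pre-cutoff cases assigned to train
#' @param seed integer seed making the random assignment reproducible
#' @return a `dataset_split`: list of disjoint tumor-id vectors `train`, `val`,
#'   `test`, plus `cutoff_year`
#' @export
split_by_date <- function(cases, cutoff_year = 2016L, train_frac = 0.8,
                          seed = 1L) {
  if (cases$n_cases == 0L) stop("case set is empty")
  years <- lapply(cases$cases, function(cs) as.integer(format(cs$.date, "%Y")))
  is_test <- vapply(years, function(y) any(y >= cutoff_year), logical(1L))
  ids <- names(cases$cases)
  test <- ids[is_test]
  rest <- ids[!is_test]
  if (length(rest) == 0L) {
    warning("all cases fall at or after the cutoff year; train set is empty")
    train <- character(0)
    val <- character(0)
  } else {
    rng <- with_seed(seed, sample.int(length(rest)))
    n_train <- floor(train_frac * length(rest))
    train <- rest[rng[seq_len(n_train)]]
    val <- rest[rng[-seq_len(n_train)]]
  }
  structure(list(train = sort(train), val = sort(val), test = sort(test),
                 cutoff_year = as.integer(cutoff_year)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train ", length(x$train), " / val ", length(x$val),
      " / test ", length(x$test), " cases (cutoff ", x$cutoff_year, ")\n",
      sep = "")
  invisible(x)
}

#' Write / read a split manifest (CSV with columns tumor_id, split)
#' @param split a `dataset_split`
#' @param path file path
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    tumor_id = c(split$train, split$val, split$test),
    split = rep(c("train", "val", "test"),
                c(length(split$train), length(split$val), length(split$test)))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(train = df$tumor_id[df$split == "train"],
                 val = df$tumor_id[df$split == "val"],
                 test = df$tumor_id[df$split == "test"],
                 cutoff_year = NA_integer_),
            class = "dataset_split")
}

# subset of a case_set by tumor ids
subset_cases <- function(cases, ids) {
  keep <- cases$cases[intersect(names(cases$cases), ids)]
  structure(list(cases = keep, n_cases = length(keep),
                 n_reports = sum(vapply(keep, nrow, integer(1L))),
                 n_input_reports = NA_integer_, tasks = cases$tasks),
            class = "case_set")
}
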