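#' Column schema for long-format longitudinal survival data
#'
#' Describes how the columns of a long-format visit file map onto the fields
#' the package needs: one row per subject-visit, with the day of the visit,
#' the subject's total follow-up time, a terminal status code (constant
#' within subject), and any number of covariate columns.
#'
#' The visit day is the day the covariates were measured; consecutive visit
#' days bound the discrete hazard intervals, and the final interval ends at
#' the subject's last follow-up day (`futime`). The midpoint of each interval
#' is the time value entering the model.
#'
#' @param id,day,futime,status column names for subject identifier, visit
#'   day, total follow-up day, and terminal status code.
#' @param covariates character vector of covariate column names. If `NULL`,
#'   every column not otherwise mapped is treated as a covariate.
#' @param status_codes named numeric vector mapping terminal states to the
#'   codes used in the `status` column. Must name `censored`, `transplanted`
#'   and `dead`.
#' @return An object of class `visit_schema`.
#' @examples
#' visit_schema(covariates = c("age", "pro", "bili"))
#' @export
visit_schema <- function(id = "id", day = "day", futime = "futime",
                         status = "status", covariates = NULL,
                         status_codes = c(censored = 0, transplanted = 1, dead = 2)) {
  stopifnot(is.character(id), is.character(day), is.character(futime),
            is.character(status))
  need <- c("censored", "transplanted", "dead")
  if (!all(need %in% names(status_codes)))
    stop("status_codes must name 'censored', 'transplanted' and 'dead'")
  structure(list(id = id, day = day, futime = futime, status = status,
                 covariates = covariates, status_codes = status_codes),
            class = "visit_schema")
}

#' Read long-format longitudinal survival data
#'
#' Reads a delimited text file with one row per subject-visit and groups it
#' into per-subject visit histories. Visits are sorted by day within subject;
#' the terminal status (died / censored / transplanted) is taken from the
#' subject's status code, which must be constant across the subject's rows.
#'
#' @param path path to a CSV/TSV file.
#' @param schema a [visit_schema()] describing the columns.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @return An object of class `subject_histories`: a list with one element
#'   per subject (see [as_subject_histories()]).
#' @seealso [expand_person_period()], [write_cohort()]
#' @export
read_longitudinal <- function(path, schema = visit_schema(), sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_subject_histories(df, schema)
}

#' Build subject histories from a long-format data frame
#'
#' @param df data frame with one row per subject-visit.
#' @param schema a [visit_schema()].
#' @return A `subject_histories` object: a list of per-subject records, each
#'   holding `subject_id`, a `visits` data frame (columns `interval`,
#'   `t_start`, `t_end`, `midpoint`, the covariates, and the event indicator
#'   `y`), `terminal_status` and `n_visits`. The covariate names are stored
#'   in the `"covariates"` attribute.
#' @export
as_subject_histories <- function(df, schema = visit_schema()) {
  if (nrow(df) == 0L) {
    covs <- schema$covariates
    if (is.null(covs))
      covs <- setdiff(names(df), c(schema$id, schema$day, schema$futime, schema$status))
    return(structure(list(), covariates = covs, class = "subject_histories"))
  }
  required <- c(schema$id, schema$day, schema$futime, schema$status)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  covs <- schema$covariates
  if (is.null(covs)) covs <- setdiff(names(df), required)
  missing <- setdiff(covs, names(df))
  if (length(missing))
    stop("missing covariate column(s): ", paste(missing, collapse = ", "))

  codes <- schema$status_codes
  out <- lapply(split(df, factor(df[[schema$id]], levels = unique(df[[schema$id]]))),
                function(rows) {
    rows <- rows[order(rows[[schema$day]]), , drop = FALSE]
    day <- rows[[schema$day]]
    if (anyDuplicated(day))
      stop("duplicate visit days for subject ", rows[[schema$id]][1])
    futime <- unique(rows[[schema$futime]])
    status <- unique(rows[[schema$status]])
    if (length(futime) != 1L || length(status) != 1L)
      stop("futime/status not constant within subject ", rows[[schema$id]][1])
    if (futime <= day[length(day)])
      stop("follow-up ends on or before the last visit day for subject ",
           rows[[schema$id]][1])
    term <- names(codes)[match(status, codes)]
    if (is.na(term))
      stop("unknown status code ", status, " for subject ", rows[[schema$id]][1])
    l <- length(day)
    t_start <- day
    t_end <- c(day[-1L], futime)
    y <- c(rep(0, l - 1L), as.numeric(term == "dead"))
    visits <- data.frame(interval = seq_len(l), t_start = t_start,
                         t_end = t_end, midpoint = (t_start + t_end) / 2)
    for (v in covs) visits[[v]] <- rows[[v]]
    visits$y <- y
    list(subject_id = rows[[schema$id]][1], visits = visits,
         terminal_status = term, n_visits = l)
  })
  names(out) <- vapply(out, function(s) as.character(s$subject_id), "")
  structure(out, covariates = covs, class = "subject_histories")
}

#' @export
print.subject_histories <- function(x, ...) {
  status <- vapply(x, function(s) s$terminal_status, "")
  cat("Subject histories: ", length(x), " subjects, ",
      sum(vapply(x, function(s) s$n_visits, 0L)), " visit intervals\n", sep = "")
  if (length(x)) print(table(terminal_status = status))
  cat("Covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  invisible(x)
}

#' Midpoint of a visit interval
#'
#' The time value entering the hazard model for an interval is the midpoint
#' of the interval's two bounding days.
#'
#' @param t_start,t_end interval boundaries (days); `t_start < t_end`.
#' @return `(t_start + t_end) / 2`, vectorized.
#' @examples
#' compute_midpoint(0, 184) # 92
#' @export
compute_midpoint <- function(t_start, t_end) {
  if (any(t_end - t_start <= 0))
    stop("interval length must be positive")
  (t_start + t_end) / 2
}

#' Expand subject histories into a person-period table
#'
#' Rewrites each subject's follow-up as one Bernoulli trial per visit
#' interval: the response `y` is 1 only on the final interval of a subject
#' who died, and 0 on every other row (including all rows of censored and
#' transplanted subjects). The resulting table is the likelihood's input:
#' its total row count is the sum of the subjects' visit counts.
#'
#' @param subjects a `subject_histories` object.
#' @return A data frame of class `person_period` with columns `subject_id`,
#'   `interval`, `t_start`, `t_end`, `midpoint`, the covariates, and `y`.
#'   Attribute `"covariates"` carries the covariate names and
#'   `"terminal_status"` a named character vector per subject.
#' @examples
#' path <- system.file("extdata", "patient9.csv", package = "dtsgam")
#' pp <- expand_person_period(read_longitudinal(path))
#' nrow(pp)  # 7 intervals, event on the last
#' @export
expand_person_period <- function(subjects) {
  stopifnot(inherits(subjects, "subject_histories"))
  covs <- attr(subjects, "covariates")
  if (length(subjects) == 0L) {
    pp <- data.frame(subject_id = character(), interval = integer(),
                     t_start = numeric(), t_end = numeric(),
                     midpoint = numeric(), y = numeric())
    for (v in covs) pp[[v]] <- numeric()
    pp <- pp[c("subject_id", "interval", "t_start", "t_end", "midpoint", covs, "y")]
  } else {
    pieces <- lapply(subjects, function(s) {
      cbind(data.frame(subject_id = rep(s$subject_id, s$n_visits)), s$visits)
    })
    pp <- do.call(rbind, pieces)
    rownames(pp) <- NULL
  }
  attr(pp, "covariates") <- covs
  attr(pp, "terminal_status") <-
    vapply(subjects, function(s) s$terminal_status, "")
  class(pp) <- c("person_period", "data.frame")
  pp
}

#' Add a time-dependent competing-event covariate
#'
#' Codes a competing terminal event (canonically liver transplantation) as a
#' binary time-dependent covariate: 0 on every interval before the event and
#' 1 at the event interval. Subjects who died or were censored get an
#' all-zero column; transplanted subjects get 0 on all but their final
#' interval and 1 there, and contribute `y = 0` on every row (the competing
#' event is not the modeled event).
#'
#' @param subjects a `subject_histories` object.
#' @param column name of the covariate column to create.
#' @return The `subject_histories` with the new covariate added.
#' @export
encode_transplant <- function(subjects, column = "transplant") {
  stopifnot(inherits(subjects, "subject_histories"))
  covs <- attr(subjects, "covariates")
  out <- lapply(subjects, function(s) {
    flag <- rep(0, s$n_visits)
    if (s$terminal_status == "transplanted") flag[s$n_visits] <- 1
    s$visits[[column]] <- flag
    # keep the event column last
    s$visits <- s$visits[c(setdiff(names(s$visits), "y"), "y")]
    s
  })
  structure(out, covariates = union(covs, column), class = "subject_histories")
}

#' Write subject histories back to long-format CSV
#'
#' Inverse of [read_longitudinal()] under the default schema: writes one row
#' per subject-visit with columns `id`, `day`, `futime`, `status` and the
#' covariates, such that reading the file back reproduces the histories.
#'
#' @param subjects a `subject_histories` object.
#' @param path output file path.
#' @param schema a [visit_schema()] naming the output columns.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(subjects, path, schema = visit_schema()) {
  stopifnot(inherits(subjects, "subject_histories"))
  covs <- attr(subjects, "covariates")
  codes <- schema$status_codes
  if (length(subjects) == 0L) {
    df <- data.frame(id = character(), day = numeric(), futime = numeric(),
                     status = numeric())
    names(df) <- c(schema$id, schema$day, schema$futime, schema$status)
    for (v in covs) df[[v]] <- numeric()
  } else {
    pieces <- lapply(subjects, function(s) {
      df <- data.frame(id = rep(s$subject_id, s$n_visits),
                       day = s$visits$t_start,
                       futime = rep(s$visits$t_end[s$n_visits], s$n_visits),
                       status = rep(unname(codes[s$terminal_status]), s$n_visits))
      names(df) <- c(schema$id, schema$day, schema$futime, schema$status)
      for (v in covs) df[[v]] <- s$visits[[v]]
      df
    })
    df <- do.call(rbind, pieces)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
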