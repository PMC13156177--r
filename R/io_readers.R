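# Tabular IO: interbeat-interval files, per-second code streams, dyad
# manifests. All formats are delimited text with declared (not sniffed)
# dialects; seconds are 0-based half-open epochs [t, t+1).

#' Affect and ERSB code alphabets
#'
#' Per-second behavior streams use closed alphabets. Affect codes follow a
#' mutually exclusive scheme (one code per 1-second epoch); emotion-related
#' socialization behavior (ERSB) codes mark parent responses to child
#' emotion, with three unsupportive forms.
#'
#' @format Character vectors.
#' @name code_alphabets
#' @export
affect_codes <- c("positive_warm", "dysphoric", "angry_aggressive",
                  "neutral", "uncodable")

#' @rdname code_alphabets
#' @export
ersb_codes <- c("supportive", "dismissing", "mild_rejection",
                "firm_rejection", "none", "uncodable")

#' @rdname code_alphabets
#' @export
unsupportive_codes <- c("dismissing", "mild_rejection", "firm_rejection")

code_alphabet <- function(stream_kind) {
  switch(stream_kind,
         affect = affect_codes,
         ersb   = ersb_codes,
         stop("unknown stream_kind: ", stream_kind))
}

#' Construct an interbeat-interval series
#'
#' An `ibi_series` anchors beat-by-beat interbeat intervals to task time.
#' Interval i spans beat i-1 to beat i; the interval of the first recorded
#' beat spans task start (time 0) to that beat. If only one of
#' `beat_times`/`intervals` is supplied the other is reconstructed
#' (cumulative sum from 0, or first differences against 0).
#'
#' @param person_id Opaque identifier.
#' @param beat_times Beat times in seconds from task start, strictly
#'   increasing, or `NULL`.
#' @param intervals Interbeat intervals in milliseconds, one per beat, or
#'   `NULL`.
#' @param tol_ms Consistency tolerance (ms) between successive beat-time
#'   differences and intervals when both are supplied.
#' @return An object of class `ibi_series` with fields `person_id`,
#'   `beat_times`, `intervals`.
#' @export
ibi_series <- function(person_id, beat_times = NULL, intervals = NULL,
                       tol_ms = 1) {
  if (is.null(beat_times) && is.null(intervals))
    stop("need beat_times and/or intervals")
  if (is.null(beat_times)) {
    intervals <- as.numeric(intervals)
    if (any(!is.na(intervals) & intervals <= 0))
      stop("non-positive interval at index ",
           which(intervals <= 0)[1])
    beat_times <- cumsum(intervals) / 1000
  } else if (is.null(intervals)) {
    beat_times <- as.numeric(beat_times)
    intervals <- diff(c(0, beat_times)) * 1000
  } else {
    beat_times <- as.numeric(beat_times)
    intervals <- as.numeric(intervals)
  }
  if (length(beat_times) != length(intervals))
    stop("beat_times and intervals must have equal length")
  if (any(!is.finite(beat_times)) || any(!is.finite(intervals)))
    stop("non-finite values in IBI series")
  dt <- diff(beat_times)
  if (any(dt <= 0))
    stop("beat_times not strictly increasing at index ",
         which(dt <= 0)[1] + 1)
  if (any(intervals <= 0))
    stop("non-positive interval at index ",
         which(intervals <= 0)[1])
  gap <- abs(dt * 1000 - intervals[-1])
  if (any(gap >= tol_ms))
    stop("beat_times and intervals disagree by >= ", tol_ms,
         " ms at index ", which(gap >= tol_ms)[1] + 1)
  structure(list(person_id = person_id,
                 beat_times = beat_times,
                 intervals = intervals),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series %s: %d beats over %.1f s, mean IBI %.0f ms>\n",
              x$person_id, length(x$intervals),
              max(x$beat_times) - min(0, x$beat_times[1]),
              mean(x$intervals)))
  invisible(x)
}

#' IBI file dialect
#'
#' Column names and delimiter for interbeat-interval files. Dialects are
#' declared, never sniffed, so a run is reproducible from its config alone.
#'
#' @param time_col Name of the beat-time column (seconds), or `NA` if absent.
#' @param interval_col Name of the interval column (ms), or `NA` if absent.
#' @param delim Field delimiter.
#' @return A list with class `ibi_dialect`.
#' @export
ibi_dialect <- function(time_col = "beat_time_s", interval_col = "ibi_ms",
                        delim = ",") {
  if (is.na(time_col) && is.na(interval_col))
    stop("dialect must declare a time and/or interval column")
  structure(list(time_col = time_col, interval_col = interval_col,
                 delim = delim), class = "ibi_dialect")
}

#' Read an interbeat-interval file
#'
#' Reads delimited text holding an interval column (ms) and/or a beat-time
#' column (s), per the declared dialect. Rows with non-positive intervals
#' are rejected with a warning naming their line numbers; non-monotone beat
#' times are a hard error naming the first offending index.
#'
#' @param path File path.
#' @param person_id Identifier stored on the result (defaults to file stem).
#' @param dialect An [ibi_dialect()].
#' @return An [ibi_series()].
#' @export
read_ibi <- function(path, person_id = NULL, dialect = ibi_dialect()) {
  if (is.null(person_id))
    person_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = dialect$delim,
                          stringsAsFactors = FALSE)
  has_t <- !is.na(dialect$time_col) && dialect$time_col %in% names(df)
  has_i <- !is.na(dialect$interval_col) && dialect$interval_col %in% names(df)
  if (!has_t && !has_i)
    stop("file ", path, " has neither declared column (",
         dialect$time_col, ", ", dialect$interval_col, ")")
  tms <- if (has_t) as.numeric(df[[dialect$time_col]]) else NULL
  if (!is.null(tms) && any(diff(tms) <= 0))
    stop("non-monotone beat times in ", path, " at index ",
         which(diff(tms) <= 0)[1] + 1)
  ivl <- if (has_i) as.numeric(df[[dialect$interval_col]]) else NULL
  if (is.null(ivl)) ivl <- diff(c(0, tms)) * 1000
  bad <- which(!is.finite(ivl) | ivl <= 0)
  if (length(bad)) {
    # +1: header line occupies line 1 of the file
    warning("rejected ", length(bad), " beat(s) with non-positive interval",
            " at line(s) ", paste(bad + 1, collapse = ", "),
            " of ", basename(path))
    ivl <- ivl[-bad]
    if (!is.null(tms)) tms <- tms[-bad]
  }
  if (!is.null(tms) && has_i) {
    # both columns present: recompute intervals from times after rejection
    # so dropped beats merge into their successor's interval
    if (length(bad)) ivl <- diff(c(0, tms)) * 1000
    ibi_series(person_id, beat_times = tms, intervals = ivl)
  } else if (!is.null(tms)) {
    ibi_series(person_id, beat_times = tms)
  } else {
    ibi_series(person_id, intervals = ivl)
  }
}

#' Write an interbeat-interval file
#'
#' Inverse of [read_ibi()] under the same dialect: writes both beat time and
#' interval columns.
#'
#' @param ibi An [ibi_series()].
#' @inheritParams read_ibi
#' @return `path`, invisibly.
#' @export
write_ibi <- function(ibi, path, dialect = ibi_dialect()) {
  stopifnot(inherits(ibi, "ibi_series"))
  df <- data.frame(a = ibi$beat_times, b = ibi$intervals)
  names(df) <- c(dialect$time_col, dialect$interval_col)
  utils::write.table(df, path, sep = dialect$delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a per-second coded behavior stream
#'
#' One code per 1-second epoch over a closed alphabet (see
#' [code_alphabets]); `uncodable` marks epochs where the behavior could not
#' be observed.
#'
#' @param person_id Opaque identifier.
#' @param role `"parent"` or `"child"`.
#' @param stream_kind `"affect"` or `"ersb"`.
#' @param codes Character vector of per-second codes.
#' @return An object of class `coded_stream`.
#' @export
coded_stream <- function(person_id, role = c("parent", "child"),
                         stream_kind = c("affect", "ersb"), codes) {
  role <- match.arg(role)
  stream_kind <- match.arg(stream_kind)
  codes <- as.character(codes)
  alpha <- code_alphabet(stream_kind)
  bad <- setdiff(unique(codes), alpha)
  if (length(bad))
    stop("unknown ", stream_kind, " code(s): ", paste(bad, collapse = ", "))
  structure(list(person_id = person_id, role = role,
                 stream_kind = stream_kind, codes = codes,
                 task_length_s = length(codes)),
            class = "coded_stream")
}

#' @export
print.coded_stream <- function(x, ...) {
  cat(sprintf("<coded_stream %s %s/%s: %d s, %.0f%% uncodable>\n",
              x$person_id, x$role, x$stream_kind, x$task_length_s,
              100 * mean(x$codes == "uncodable")))
  invisible(x)
}

#' Read a per-second code stream
#'
#' Reads tall delimited text with columns `second` (0-based index) and
#' `code`. Seconds missing from the file are filled with `uncodable`;
#' duplicate second indices are a hard error; code tokens outside the
#' alphabet are an error listing the offenders. This tall-CSV convention
#' stands in for annotation-tool exports.
#'
#' @param path File path.
#' @param stream_kind `"affect"` or `"ersb"`.
#' @param role `"parent"` or `"child"`.
#' @param person_id Identifier (defaults to file stem).
#' @param task_length_s Total epochs; defaults to `max(second) + 1`.
#' @param delim Field delimiter.
#' @return A [coded_stream()].
#' @export
read_coded_stream <- function(path, stream_kind, role = "parent",
                              person_id = NULL, task_length_s = NULL,
                              delim = ",") {
  if (is.null(person_id))
    person_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE)
  if (!all(c("second", "code") %in% names(df)))
    stop("expected columns 'second' and 'code' in ", path)
  sec <- as.integer(df$second)
  if (anyNA(sec) || any(sec < 0)) stop("invalid second index in ", path)
  if (anyDuplicated(sec))
    stop("duplicate second index ", sec[duplicated(sec)][1], " in ", path)
  if (is.null(task_length_s)) task_length_s <- max(sec) + 1L
  if (any(sec >= task_length_s))
    stop("second index beyond task_length_s in ", path)
  codes <- rep("uncodable", task_length_s)
  codes[sec + 1L] <- as.character(df$code)
  coded_stream(person_id, role = role, stream_kind = stream_kind,
               codes = codes)
}

#' Write a per-second code stream
#'
#' Writes the tall (second, code) format read by [read_coded_stream()].
#' All seconds are written explicitly, including `uncodable` ones, so the
#' round trip is the identity.
#'
#' @param stream A [coded_stream()].
#' @inheritParams read_coded_stream
#' @return `path`, invisibly.
#' @export
write_coded_stream <- function(stream, path, delim = ",") {
  stopifnot(inherits(stream, "coded_stream"))
  df <- data.frame(second = seq_along(stream$codes) - 1L,
                   code = stream$codes)
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a dyad record
#'
#' One dyad's physiological series, behavior streams, covariates and
#' outcome T-scores. Any component may be missing: missingness is data, not
#' an error, and is carried through to the analysis stage.
#'
#' @param dyad_id Identifier.
#' @param parent_ibi,child_ibi [ibi_series()] or `NULL`.
#' @param parent_affect,child_affect,parent_ersb [coded_stream()] or `NULL`.
#' @param covariates Named list/vector with elements `child_medication`,
#'   `pubertal_status`, `pandemic_cohort`, each 0/1 or `NA`.
#' @param parent_dep_T,child_dep_T Symptom T-scores (>= 0) or `NA`.
#' @param child_internalizing_T,child_total_T Optional additional outcomes.
#' @return An object of class `dyad_record`.
#' @export
dyad_record <- function(dyad_id, parent_ibi = NULL, child_ibi = NULL,
                        parent_affect = NULL, child_affect = NULL,
                        parent_ersb = NULL,
                        covariates = list(child_medication = NA,
                                          pubertal_status = NA,
                                          pandemic_cohort = NA),
                        parent_dep_T = NA, child_dep_T = NA,
                        child_internalizing_T = NA, child_total_T = NA) {
  for (nm in c("child_medication", "pubertal_status", "pandemic_cohort")) {
    v <- covariates[[nm]]
    if (!is.null(v) && !is.na(v) && !v %in% c(0, 1))
      stop(nm, " must be 0, 1 or missing")
  }
  parent_dep_T <- as.numeric(parent_dep_T)
  child_dep_T <- as.numeric(child_dep_T)
  child_internalizing_T <- as.numeric(child_internalizing_T)
  child_total_T <- as.numeric(child_total_T)
  for (v in c(parent_dep_T, child_dep_T, child_internalizing_T,
              child_total_T))
    if (!is.na(v) && v < 0) stop("T-scores must be >= 0")
  structure(list(dyad_id = dyad_id,
                 parent_ibi = parent_ibi, child_ibi = child_ibi,
                 parent_affect = parent_affect, child_affect = child_affect,
                 parent_ersb = parent_ersb,
                 covariates = covariates,
                 parent_dep_T = parent_dep_T, child_dep_T = child_dep_T,
                 child_internalizing_T = child_internalizing_T,
                 child_total_T = child_total_T),
            class = "dyad_record")
}

#' Assemble dyad records from a manifest and covariate table
#'
#' The manifest links each dyad to its data files (columns `dyad_id`,
#' `parent_ibi`, `child_ibi`, `parent_affect`, `child_affect`,
#' `parent_ersb`; empty/`NA` entries mean the component is missing). The
#' covariate table carries per-dyad covariates and outcome T-scores.
#'
#' @param manifest data.frame as above; file paths are resolved against
#'   `data_dir`.
#' @param covariates data.frame with column `dyad_id` plus covariate and
#'   outcome columns (missing columns become `NA`).
#' @param data_dir Directory against which manifest paths are resolved.
#' @param ibi_dialect An [ibi_dialect()] for the IBI files.
#' @return List of [dyad_record()]s, one per manifest row.
#' @export
assemble_dyads <- function(manifest, covariates = NULL, data_dir = ".",
                           ibi_dialect = dyadsync::ibi_dialect()) {
  if (nrow(manifest) == 0) return(list())
  if (anyDuplicated(manifest$dyad_id))
    stop("dyad_id collision in manifest: ",
         manifest$dyad_id[duplicated(manifest$dyad_id)][1])
  getpath <- function(row, col) {
    if (!col %in% names(manifest)) return(NULL)
    p <- manifest[[col]][row]
    if (is.na(p) || !nzchar(p)) return(NULL)
    file.path(data_dir, p)
  }
  covrow <- function(id, col) {
    if (is.null(covariates) || !col %in% names(covariates)) return(NA)
    i <- match(id, covariates$dyad_id)
    if (is.na(i)) NA else covariates[[col]][i]
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$dyad_id[i]
    rd <- function(col, f) {
      p <- getpath(i, col)
      if (is.null(p)) NULL else f(p)
    }
    dyad_record(
      dyad_id = id,
      parent_ibi = rd("parent_ibi", function(p)
        read_ibi(p, person_id = paste0(id, "_parent"),
                 dialect = ibi_dialect)),
      child_ibi = rd("child_ibi", function(p)
        read_ibi(p, person_id = paste0(id, "_child"),
                 dialect = ibi_dialect)),
      parent_affect = rd("parent_affect", function(p)
        read_coded_stream(p, "affect", role = "parent",
                          person_id = paste0(id, "_parent"))),
      child_affect = rd("child_affect", function(p)
        read_coded_stream(p, "affect", role = "child",
                          person_id = paste0(id, "_child"))),
      parent_ersb = rd("parent_ersb", function(p)
        read_coded_stream(p, "ersb", role = "parent",
                          person_id = paste0(id, "_parent"))),
      covariates = list(
        child_medication = covrow(id, "child_medication"),
        pubertal_status = covrow(id, "pubertal_status"),
        pandemic_cohort = covrow(id, "pandemic_cohort")),
      parent_dep_T = covrow(id, "parent_dep_T"),
      child_dep_T = covrow(id, "child_dep_T"),
      child_internalizing_T = covrow(id, "child_internalizing_T"),
      child_total_T = covrow(id, "child_total_T"))
  })
}
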