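#' Read a PPG signal from a generic CSV file
#'
#' Accepts either a two-column `time,value` layout (sampling rate inferred
#' from the time column) or a value-only file with the sampling rate given
#' through `fs`. A header row is detected automatically. Unparseable or
#' empty cells become missing samples; no row is ever dropped, so the
#' record length equals the number of data rows.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling frequency in Hz. Required when the file has no time
#'   column; when both are available the time column wins.
#' @param column Name of the value column to read (matched
#'   case-insensitively). Defaults to the last column.
#' @param subject_id Optional label attached to the record.
#' @return A [ppg_record()].
#' @details The sampling rate inferred from a time column is
#'   `1 / median(diff(time))`; time steps must be uniform to within 1%
#'   of the median step, and the time column must be strictly increasing.
#' @export
read_ppg_csv <- function(path, fs = NULL, column = NULL, subject_id = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, header = .has_header(path),
                        stringsAsFactors = FALSE, check.names = FALSE,
                        blank.lines.skip = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty file: ", path, call. = FALSE)

  time_col <- .match_column(names(df), c("time", "t", "time_s", "time [s]"))
  if (!is.null(column)) {
    val_col <- .match_column(names(df), column)
    if (is.null(val_col)) {
      stop("column '", column, "' not found; file has: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    }
  } else if (ncol(df) == 1) {
    val_col <- names(df)[1]
  } else if (!is.null(time_col)) {
    val_col <- setdiff(names(df), time_col)[1]
  } else {
    val_col <- names(df)[ncol(df)]
  }

  samples <- suppressWarnings(as.double(df[[val_col]]))

  if (is.null(time_col) && ncol(df) >= 2 && is.null(column)) {
    # headerless two-column file: treat the first column as time
    tc <- suppressWarnings(as.double(df[[1]]))
    if (!anyNA(tc) && all(diff(tc) > 0)) {
      time_col <- names(df)[1]
      val_col <- names(df)[2]
      samples <- suppressWarnings(as.double(df[[val_col]]))
    }
  }

  if (!is.null(time_col)) {
    tv <- suppressWarnings(as.double(df[[time_col]]))
    if (anyNA(tv) || any(diff(tv) <= 0)) {
      stop("time column is not strictly increasing", call. = FALSE)
    }
    dt <- stats::median(diff(tv))
    if (any(abs(diff(tv) - dt) > 0.01 * dt)) {
      stop("time column is not uniformly sampled (>1% step deviation)",
           call. = FALSE)
    }
    fs <- 1 / dt
  } else if (is.null(fs)) {
    stop("no time column found; supply `fs`", call. = FALSE)
  }

  ppg_record(samples, fs = fs, subject_id = subject_id)
}

#' Read a paired signals/numerics recording
#'
#' Reads the paired-CSV layout used by bedside-monitor exports: a
#' "Signals" file with one row per sample at 125 Hz whose header names the
#' channels (the PPG channel is usually called `PLETH`), and a "Numerics"
#' file with one row per second containing, among others, a reference
#' respiratory-rate column (`RESP`).
#'
#' @param signals_path Path to the signals CSV.
#' @param numerics_path Path to the numerics CSV, or `NULL` to load the
#'   signal without reference rates.
#' @param ppg_candidates Channel names accepted for the PPG column,
#'   matched case-insensitively and in order.
#' @param resp_candidates Column names accepted for the reference
#'   respiratory rate.
#' @param fs Sampling frequency assumed when the signals file has no time
#'   column (default 125 Hz).
#' @return A [ppg_record()] with `ref_resp` populated at 1 s spacing when
#'   a numerics file is given.
#' @export
read_bidmc_pair <- function(signals_path, numerics_path = NULL,
                            ppg_candidates = c("PLETH", "PPG", "PULSE"),
                            resp_candidates = c("RESP", "RESP RATE", "RR"),
                            fs = 125) {
  if (!file.exists(signals_path)) {
    stop("file not found: ", signals_path, call. = FALSE)
  }
  sig <- utils::read.csv(signals_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  names(sig) <- trimws(names(sig))
  ppg_col <- .match_column(names(sig), ppg_candidates)
  if (is.null(ppg_col)) {
    stop("no PPG column (tried: ", paste(ppg_candidates, collapse = ", "),
         "); file has: ", paste(names(sig), collapse = ", "), call. = FALSE)
  }
  time_col <- .match_column(names(sig), c("time [s]", "time", "t"))
  if (!is.null(time_col)) {
    tv <- suppressWarnings(as.double(sig[[time_col]]))
    if (!anyNA(tv) && length(tv) > 1 && all(diff(tv) > 0)) {
      fs <- 1 / stats::median(diff(tv))
    }
  }
  samples <- suppressWarnings(as.double(sig[[ppg_col]]))

  ref_resp <- NULL
  if (!is.null(numerics_path)) {
    if (!file.exists(numerics_path)) {
      stop("file not found: ", numerics_path, call. = FALSE)
    }
    num <- utils::read.csv(numerics_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    names(num) <- trimws(names(num))
    resp_col <- .match_column(names(num), resp_candidates)
    if (is.null(resp_col)) {
      stop("no respiratory-rate column (tried: ",
           paste(resp_candidates, collapse = ", "), "); file has: ",
           paste(names(num), collapse = ", "), call. = FALSE)
    }
    ntime <- .match_column(names(num), c("time [s]", "time", "t"))
    tvals <- if (!is.null(ntime)) {
      suppressWarnings(as.double(num[[ntime]]))
    } else {
      seq_len(nrow(num)) - 1
    }
    ref_resp <- tibble::tibble(
      time_s = tvals,
      resp_brpm = suppressWarnings(as.double(num[[resp_col]]))
    )
    ref_resp <- ref_resp[!is.na(ref_resp$resp_brpm), ]
  }

  ppg_record(samples, fs = fs, ref_resp = ref_resp,
             subject_id = sub("_Signals.*$", "", basename(signals_path)))
}

#' Write per-window respiratory-rate estimates to CSV
#'
#' One row per analysis window with a deterministic column order:
#' `start_s, window_s, respr, esqi, hr_bpm, skipped, skip_reason,
#' clamped, scale`. Skipped windows get an empty `respr` cell. The file
#' round-trips through [read_estimates_csv()] with numeric fields
#' preserved to better than 1e-6.
#'
#' @param estimates A tibble of estimates as returned by
#'   [estimate_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (nrow(estimates) == 0) stop("`estimates` is empty", call. = FALSE)
  cols <- c("start_s", "window_s", "respr", "esqi", "hr_bpm",
            "skipped", "skip_reason", "clamped", "scale")
  out <- estimates[, intersect(cols, names(estimates))]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.9g", v))
  })
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read back an estimates CSV written by [write_estimates_csv()]
#' @param path File path.
#' @return A tibble with the same columns.
#' @export
read_estimates_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in intersect(c("start_s", "window_s", "respr", "esqi",
                          "hr_bpm", "scale"), names(df))) {
    df[[col]] <- as.double(df[[col]])
  }
  for (col in intersect(c("skipped", "clamped"), names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  if ("skip_reason" %in% names(df)) {
    df$skip_reason <- as.character(df$skip_reason)
  }
  tibble::as_tibble(df)
}

# first header cell failing numeric parse => header row present
.has_header <- function(path) {
  first <- readLines(path, n = 1)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  any(is.na(suppressWarnings(as.double(cells[cells != ""]))))
}

.match_column <- function(names, candidates) {
  lower <- tolower(trimws(names))
  for (cand in tolower(candidates)) {
    hit <- which(lower == cand)
    if (length(hit)) return(names[hit[1]])
  }
  NULL
}
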