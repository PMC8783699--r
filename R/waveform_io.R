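#' Construct a synchronized ECG/PPG/ABP waveform record
#'
#' A `waveform_record` holds three channels sampled simultaneously at a
#' common rate: an ECG lead (arbitrary amplitude units), a PPG intensity
#' channel (arbitrary units, positive by convention) and an invasively
#' measured arterial blood pressure (ABP) channel in mmHg. All downstream
#' feature extraction assumes the channels are beat-synchronized, i.e.
#' sample `i` of each channel was acquired at the same instant.
#'
#' @param record_id character label for the record.
#' @param sampling_rate_hz sampling rate in samples/second (> 0).
#' @param ecg,ppg,abp numeric sample vectors of identical length >= 2.
#' @param dropped_rows count of input rows discarded while loading
#'   (non-numeric or missing entries); informational.
#' @return an object of class `waveform_record`.
#' @export
#' @examples
#' r <- waveform_record("demo", 125, ecg = sin(1:300), ppg = 1 + cos(1:300) / 2,
#'                      abp = 100 + 20 * sin(1:300 / 10))
#' r
waveform_record <- function(record_id, sampling_rate_hz, ecg, ppg, abp,
                            dropped_rows = 0L) {
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  if (!is.character(record_id) || length(record_id) != 1L) {
    stop("`record_id` must be a single character label", call. = FALSE)
  }
  ecg <- as.double(ecg); ppg <- as.double(ppg); abp <- as.double(abp)
  n <- length(ecg)
  if (length(ppg) != n || length(abp) != n) {
    stop("ECG, PPG and ABP channels must have identical length", call. = FALSE)
  }
  if (n < 2L) {
    stop("empty record: fewer than 2 valid samples per channel", call. = FALSE)
  }
  if (anyNA(ecg) || anyNA(ppg) || anyNA(abp) || any(!is.finite(abp))) {
    stop("channels must be free of missing/non-finite values after loading",
         call. = FALSE)
  }
  structure(
    list(record_id = record_id,
         sampling_rate_hz = as.double(sampling_rate_hz),
         ecg = ecg, ppg = ppg, abp = abp,
         dropped_rows = as.integer(dropped_rows)),
    class = "waveform_record"
  )
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record '%s': %d samples @ %g Hz (%.1f s), %d row(s) dropped on load>\n",
              x$record_id, length(x$ecg), x$sampling_rate_hz,
              length(x$ecg) / x$sampling_rate_hz, x$dropped_rows))
  invisible(x)
}

#' @export
length.waveform_record <- function(x) length(x$ecg)

#' Column-mapping layout for multi-channel signal files
#'
#' Public waveform dumps store channels under inconsistent column names
#' and may or may not carry the sampling rate in the file, so the reader
#' is driven by an explicit layout: which column is ECG / PPG / ABP and
#' what the sampling rate is.
#'
#' @param ecg,ppg,abp column names (or 1-based indices) of the three
#'   channels in the file.
#' @param sampling_rate_hz sampling rate in Hz; `NA` means "read it from
#'   a `# sampling_rate_hz:` header comment in the file".
#' @return a `waveform_layout` list.
#' @export
waveform_layout <- function(ecg = "ecg", ppg = "ppg", abp = "abp",
                            sampling_rate_hz = NA_real_) {
  structure(list(ecg = ecg, ppg = ppg, abp = abp,
                 sampling_rate_hz = sampling_rate_hz),
            class = "waveform_layout")
}

#' Read a synchronized multi-channel waveform record from CSV
#'
#' Reads a comma-separated file with one header line and one row per
#' sample. Rows containing non-numeric or missing entries in any mapped
#' channel are dropped and counted (`dropped_rows` on the returned
#' record); sample order is preserved. Lines starting with `#` are
#' treated as metadata comments; `# sampling_rate_hz: <value>` supplies
#' the rate when the layout does not.
#'
#' @param path path to the CSV file.
#' @param layout a [waveform_layout()] naming the channel columns.
#' @param record_id label for the record; default is the file name.
#' @return a [waveform_record()].
#' @export
read_waveform_record <- function(path, layout = waveform_layout(),
                                 record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header_fs <- NA_real_
  first <- readLines(path, n = 50L)
  meta <- grep("^#", first, value = TRUE)
  m <- regmatches(meta, regexpr("sampling_rate_hz:\\s*[0-9.eE+-]+", meta))
  if (length(m)) {
    header_fs <- as.numeric(sub("sampling_rate_hz:\\s*", "", m[[1L]]))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  pick <- function(col, what) {
    if (is.numeric(col)) {
      if (col < 1 || col > ncol(df)) {
        stop(sprintf("input-format error: no column %s for %s channel", col, what),
             call. = FALSE)
      }
      return(df[[col]])
    }
    if (!col %in% names(df)) {
      stop(sprintf("input-format error: missing %s channel column '%s'", what, col),
           call. = FALSE)
    }
    df[[col]]
  }
  chans <- list(ecg = pick(layout$ecg, "ECG"),
                ppg = pick(layout$ppg, "PPG"),
                abp = pick(layout$abp, "ABP"))
  chans <- lapply(chans, function(v) suppressWarnings(as.numeric(v)))
  ok <- Reduce(`&`, lapply(chans, function(v) is.finite(v)))
  dropped <- sum(!ok)
  if (dropped > 0L) {
    message(sprintf("read_waveform_record: dropped %d row(s) with missing/non-numeric entries",
                    dropped))
  }
  fs <- if (is.finite(layout$sampling_rate_hz)) layout$sampling_rate_hz else header_fs
  if (!is.finite(fs)) {
    stop("sampling rate not supplied in layout nor in file header", call. = FALSE)
  }
  if (sum(ok) < 2L) {
    stop("empty record: fewer than 2 valid samples in ", path, call. = FALSE)
  }
  waveform_record(record_id = record_id %||% basename(path),
                  sampling_rate_hz = fs,
                  ecg = chans$ecg[ok], ppg = chans$ppg[ok], abp = chans$abp[ok],
                  dropped_rows = dropped)
}

#' Write a waveform record to CSV
#'
#' Writes one header line (`ecg,ppg,abp`), a `# sampling_rate_hz:` comment
#' carrying the rate, and one row per sample at full double precision, so
#' that [read_waveform_record()] reproduces the samples exactly.
#'
#' @param record a [waveform_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# record_id: %s", record$record_id),
               sprintf("# sampling_rate_hz: %.17g", record$sampling_rate_hz),
               "ecg,ppg,abp"), con)
  lines <- paste(sprintf("%.17g", record$ecg),
                 sprintf("%.17g", record$ppg),
                 sprintf("%.17g", record$abp), sep = ",")
  writeLines(lines, con)
  invisible(path)
}

feature_table_columns <- c("record_id", "cycle_index", "ptt_s", "pir_ratio",
                           "hr_bpm", "sbp_mmHg", "dbp_mmHg")

#' Validate a per-cycle feature table
#'
#' A feature table has one row per retained cardiac cycle with the fixed
#' column set `record_id, cycle_index, ptt_s, pir_ratio, hr_bpm, sbp_mmHg,
#' dbp_mmHg`. Invariants: PTT and PIR positive, SBP >= DBP, and no
#' duplicated (record_id, cycle_index) pair. Extra columns (e.g. a
#' `regime_id` ground-truth column from the simulator) are allowed and
#' preserved.
#'
#' @param table a data.frame.
#' @return the validated data.frame (invisibly usable in pipelines).
#' @export
validate_feature_table <- function(table) {
  missing <- setdiff(feature_table_columns, names(table))
  if (length(missing)) {
    stop("schema error: feature table lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(table)) {
    if (any(table$sbp_mmHg < table$dbp_mmHg)) {
      bad <- which(table$sbp_mmHg < table$dbp_mmHg)
      stop("invariant violation: sbp_mmHg < dbp_mmHg at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    if (any(table$ptt_s <= 0) || any(table$pir_ratio <= 0)) {
      stop("invariant violation: ptt_s and pir_ratio must be positive",
           call. = FALSE)
    }
    key <- paste(table$record_id, table$cycle_index)
    if (anyDuplicated(key)) {
      stop("invariant violation: duplicated (record_id, cycle_index) pair",
           call. = FALSE)
    }
  }
  table
}

#' Read a per-cycle feature table from CSV
#'
#' Rows violating the SBP >= DBP invariant are rejected (dropped) and
#' reported through the `rejected_rows` attribute, a data.frame with the
#' offending 1-based data-row indices and the reason.
#'
#' @param path path to the CSV file.
#' @return a validated feature table data.frame with attribute
#'   `rejected_rows`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_table_columns, names(df))
  if (length(missing)) {
    stop("schema error: feature table lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$sbp_mmHg < df$dbp_mmHg)
  rejected <- data.frame(row = bad,
                         reason = rep("sbp_mmHg < dbp_mmHg", length(bad)))
  if (length(bad)) {
    message(sprintf("read_feature_table: rejected %d row(s) violating SBP >= DBP",
                    length(bad)))
    df <- df[-bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  out <- validate_feature_table(df)
  attr(out, "rejected_rows") <- rejected
  out
}

#' Write a per-cycle feature table to CSV
#'
#' @param table a feature table (validated on the way out).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  # full precision so write -> read is the identity on finite values
  num <- vapply(table, is.double, logical(1L))
  out <- table
  out[num] <- lapply(table[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
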