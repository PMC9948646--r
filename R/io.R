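#' Default analysis configuration
#'
#' The screen's fixed constants and thresholds in one place: Stern-Volmer
#' coefficient 60 1/M, extravesicular Tl+ 25 mM, fit window 2 ms to 1 s,
#' temperature 298.15 K, lipid/aqueous volume ratio 3.6e-5, NormRate
#' category edges 1.25/1.5, CC20 bands 10/50 uM with 80 uM truncation,
#' ALogP/PSA quadrant cuts 3 and 75, QED cut 0.5, pScore bands 100/300, and
#' the r^2 QC flag level 0.95.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(...) {
  cfg <- list(
    ksv = 60, tl_ext = 0.025,
    window = c(0.002, 1),
    temperature = 298.15,
    vlip_over_vaq = 3.6e-5,
    normrate_edges = c(1.25, 1.5),
    cc20_edges = c(10, 50),
    cc20_truncation = 80,
    alogp_cut = 3, psa_cut = 75,
    qed_cut = 0.5,
    pscore_edges = c(100, 300),
    r2_flag = 0.95,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "screen_config")
}

mandatory_drug_cols <- c("id", "normrate")

#' Read a drug-library table
#'
#' Reads a comma-separated drug table (header row, "." decimal, UTF-8) into
#' typed records. Mandatory columns are `id` and `normrate`; recognised
#' numeric columns (`alogp`, `psa`, `qed`, `pscore`, `cc20`, `fu_mouse`,
#' `fu_mic`, `normrate`, `normrate_disp`, `true_normrate`) are validated,
#' unknown columns are preserved as read. Blank CC20 entries become missing;
#' CC20 values above the truncation limit are clamped to it with a warning
#' (the database truncates at 80 uM).
#'
#' @param path File path.
#' @param cc20_truncation Truncation limit (uM). Default 80.
#' @return A data.frame of class `drug_library`.
#' @export
read_drug_table <- function(path, cc20_truncation = 80) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"), check.names = FALSE)
  miss <- setdiff(mandatory_drug_cols, names(df))
  if (length(miss)) {
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  num_cols <- intersect(c("alogp", "psa", "qed", "pscore", "cc20", "fu_mouse",
                          "fu_mic", "normrate", "normrate_disp",
                          "true_normrate"), names(df))
  for (col in num_cols) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & trimws(as.character(raw)) != "" & is.na(v))
    if (length(bad)) {
      stop(sprintf("schema error: malformed number in column '%s', row %d (line %d)",
                   col, bad[1], bad[1] + 1L))
    }
    df[[col]] <- v
  }
  if (any(!is.na(df$normrate) & df$normrate <= 0)) {
    stop("schema error: `normrate` must be > 0")
  }
  if ("cc20" %in% names(df) && any(df$cc20 > cc20_truncation, na.rm = TRUE)) {
    warning(sprintf("CC20 values above %g uM clamped to the truncation limit",
                    cc20_truncation), call. = FALSE)
    df$cc20 <- pmin(df$cc20, cc20_truncation)
  }
  class(df) <- c("drug_library", "data.frame")
  df
}

#' Write a drug-library table
#'
#' Comma-separated, header row, "." decimal; byte-identical across runs for
#' identical input.
#'
#' @param records Drug table (data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a stopped-flow session to a directory
#'
#' One two-column (time_s, fluorescence) comma-separated file per trace plus
#' a `manifest.csv` (file, mix_type, replicate_id) distinguishing buffer
#' from quencher mixes.
#'
#' @param traces List of [fluorescence_trace()] objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace_session <- function(traces, dir) {
  stopifnot(is.list(traces), length(traces) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "fluorescence_trace"))
    file <- sprintf("trace_%03d.csv", i)
    utils::write.csv(data.frame(time_s = tr$time, fluorescence = tr$signal),
                     file.path(dir, file), row.names = FALSE)
    data.frame(file = file, mix_type = attr(tr, "mix_type"),
               replicate_id = attr(tr, "replicate_id"))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a stopped-flow session directory
#'
#' Reads every trace listed in the session `manifest.csv`, validating that
#' each file exists, has the two expected columns, and a strictly
#' increasing time column.
#'
#' @param dir Session directory written by [write_trace_session()] (or any
#'   directory with the same layout).
#' @return List of [fluorescence_trace()] objects, with attribute
#'   `session_info` (counts of buffer and quencher mixes).
#' @export
read_trace_session <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("empty session: no manifest.csv in ", dir)
  mf <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  if (nrow(mf) == 0) stop("empty session: manifest lists no traces")
  traces <- lapply(seq_len(nrow(mf)), function(i) {
    p <- file.path(dir, mf$file[i])
    if (!file.exists(p)) stop("manifest names a missing file: ", mf$file[i])
    df <- utils::read.csv(p)
    if (!all(c("time_s", "fluorescence") %in% names(df)) || nrow(df) < 2) {
      stop("truncated or malformed trace file: ", mf$file[i])
    }
    if (any(diff(df$time_s) <= 0)) {
      stop("non-monotone time column in ", mf$file[i])
    }
    fluorescence_trace(df$time_s, df$fluorescence,
                       mix_type = mf$mix_type[i],
                       replicate_id = mf$replicate_id[i])
  })
  attr(traces, "session_info") <- c(
    n_buffer = sum(mf$mix_type == "buffer"),
    n_quencher = sum(mf$mix_type == "quencher"))
  traces
}
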