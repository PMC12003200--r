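#' @keywords internal
"_PACKAGE"

# Column order of the localization-table dialect. Units: t in seconds,
# x/y/z in nm, efo/efc in kHz, cfr and dcr dimensionless.
.loc_columns <- c("trace_id", "t", "x", "y", "z",
                  "efo", "efc", "cfr", "dcr", "channel")
.loc_required <- c("trace_id", "t", "x", "y", "z", "channel")

.loc_channels <- c("scaffold", "cargo")

#' Construct a localization table
#'
#' Builds a validated data frame of 3D MINFLUX localizations, one row per
#' localization. Photometric columns (`efo`, `efc`, `cfr`, `dcr`) may be
#' `NA` where the acquisition did not report them; they are never silently
#' zero-filled, so downstream filters see genuine absence.
#'
#' @param trace_id integer emitter/track label.
#' @param t time in seconds, strictly increasing within a `trace_id`.
#' @param x,y,z coordinates in nm.
#' @param efo effective frequency at offset, kHz (`NA` allowed).
#' @param efc effective frequency at centre, kHz (`NA` allowed).
#' @param cfr centre frequency ratio EFC/EFO (`NA` allowed).
#' @param dcr detector channel ratio in \[0, 1\] (`NA` allowed).
#' @param channel `"scaffold"` or `"cargo"`.
#' @param validate run [validate_localizations()] (default `TRUE`).
#' @return data frame with the dialect's ten columns.
#' @export
localizations <- function(trace_id, t, x, y, z,
                          efo = NA_real_, efc = NA_real_,
                          cfr = NA_real_, dcr = NA_real_,
                          channel = "scaffold", validate = TRUE) {
  df <- data.frame(trace_id = as.integer(trace_id), t = as.numeric(t),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   efo = as.numeric(efo), efc = as.numeric(efc),
                   cfr = as.numeric(cfr), dcr = as.numeric(dcr),
                   channel = as.character(channel),
                   stringsAsFactors = FALSE)
  if (validate) validate_localizations(df)
  df
}

#' Validate a localization table
#'
#' Checks the dialect invariants: required columns present, time strictly
#' increasing within each trace, `efo > 0` where finite, `dcr` in \[0, 1\],
#' and `cfr = efc/efo` (relative tolerance 1e-6) wherever both frequencies
#' are present.
#'
#' @param records localization data frame.
#' @param strict error on violation (default); if `FALSE`, return a character
#'   vector of problems instead.
#' @return invisibly `records` (strict mode) or character vector of problems.
#' @export
validate_localizations <- function(records, strict = TRUE) {
  probs <- character(0)
  missing_cols <- setdiff(.loc_required, names(records))
  if (length(missing_cols)) {
    probs <- c(probs, paste0("missing required column(s): ",
                             paste(missing_cols, collapse = ", ")))
  } else {
    if (nrow(records)) {
      bad_chan <- !records$channel %in% .loc_channels
      if (any(bad_chan))
        probs <- c(probs, paste0("unknown channel at row(s): ",
                                 paste(utils::head(which(bad_chan), 5), collapse = ", ")))
      ord <- order(records$trace_id, seq_len(nrow(records)))
      by_trace <- split(records$t[ord], records$trace_id[ord])
      nonmono <- names(by_trace)[vapply(by_trace, function(tt)
        any(diff(tt) <= 0), logical(1))]
      if (length(nonmono))
        probs <- c(probs, paste0("t not strictly increasing within trace_id(s): ",
                                 paste(utils::head(nonmono, 5), collapse = ", ")))
      if ("efo" %in% names(records)) {
        bad <- is.finite(records$efo) & records$efo <= 0
        if (any(bad))
          probs <- c(probs, paste0("non-positive efo at row(s): ",
                                   paste(utils::head(which(bad), 5), collapse = ", ")))
      }
      if ("dcr" %in% names(records)) {
        bad <- is.finite(records$dcr) & (records$dcr < 0 | records$dcr > 1)
        if (any(bad))
          probs <- c(probs, paste0("dcr outside [0, 1] at row(s): ",
                                   paste(utils::head(which(bad), 5), collapse = ", ")))
      }
      if (all(c("efo", "efc", "cfr") %in% names(records))) {
        have <- is.finite(records$efo) & is.finite(records$efc) &
          is.finite(records$cfr) & records$efo > 0
        if (any(have)) {
          rel <- abs(records$cfr[have] - records$efc[have] / records$efo[have]) /
            pmax(abs(records$cfr[have]), 1e-12)
          if (any(rel > 1e-6))
            probs <- c(probs, paste0("cfr != efc/efo at row(s): ",
                                     paste(utils::head(which(have)[rel > 1e-6], 5),
                                           collapse = ", ")))
        }
      }
    }
  }
  if (strict && length(probs))
    stop("invalid localization table: ", paste(probs, collapse = "; "),
         call. = FALSE)
  if (strict) invisible(records) else probs
}

#' Read a localization table
#'
#' Reads the package's plain-CSV localization dialect (header
#' `trace_id,t,x,y,z,efo,efc,cfr,dcr,channel`). A `.gz` extension is
#' transparently decompressed. Missing optional photometric fields are
#' empty in the file and become `NA`, never zeros.
#'
#' @param path file path (`.csv` or `.csv.gz`).
#' @param channel optional channel restriction (`"scaffold"` or `"cargo"`);
#'   rows from other channels are dropped.
#' @param validate validate invariants after reading (default `TRUE`).
#' @return localization data frame in file order.
#' @export
read_localizations <- function(path, channel = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  df <- tryCatch(
    utils::read.csv(con, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("malformed localization file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  missing_cols <- setdiff(.loc_required, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in '", path, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in setdiff(.loc_columns, names(df))) df[[cc]] <- ""
  df <- df[, .loc_columns]
  to_num <- function(cc, allow_empty) {
    v <- trimws(df[[cc]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which((v != "" & is.na(out)) | (!allow_empty & v == ""))
    if (length(bad))
      stop("malformed value in column '", cc, "' of '", path,
           "' at data line(s): ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    out
  }
  df$trace_id <- as.integer(to_num("trace_id", allow_empty = FALSE))
  for (cc in c("t", "x", "y", "z")) df[[cc]] <- to_num(cc, allow_empty = FALSE)
  for (cc in c("efo", "efc", "cfr", "dcr")) df[[cc]] <- to_num(cc, allow_empty = TRUE)
  if (!is.null(channel)) {
    channel <- match.arg(channel, .loc_channels)
    df <- df[df$channel == channel, , drop = FALSE]
    rownames(df) <- NULL
  }
  if (validate) validate_localizations(df)
  df
}

#' Write a localization table
#'
#' Serialises records in the plain-CSV dialect; `NA` photometric fields are
#' written as empty strings so they round-trip to `NA`. Re-reading a written
#' file reproduces the input (bit-exact integers, 1e-9 relative on floats).
#'
#' @param records localization data frame.
#' @param path output path; `.gz` extension triggers gzip compression.
#' @param validate validate before writing (default `TRUE`).
#' @return invisibly `path`.
#' @export
write_localizations <- function(records, path, validate = TRUE) {
  if (validate) validate_localizations(records)
  for (cc in setdiff(.loc_columns, names(records))) records[[cc]] <- NA_real_
  records <- records[, .loc_columns]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  # 15 significant digits keeps doubles well inside the 1e-9 round-trip bound
  out <- records
  for (cc in c("t", "x", "y", "z", "efo", "efc", "cfr", "dcr"))
    out[[cc]] <- ifelse(is.na(records[[cc]]), "",
                        formatC(records[[cc]], digits = 15, format = "g"))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a fiducial (gold-bead) coordinate file
#'
#' CSV with columns `bead_id,channel,t,x,y,z` (nm, seconds). Beads are
#' measured repeatedly in both channels; [fit_rigid_transform()] collapses
#' repeats to per-bead medians.
#'
#' @param path CSV path.
#' @return data frame with the six fiducial columns.
#' @export
read_fiducials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bead_id", "channel", "t", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in '", path, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df[, need]
}

#' Acquisition metadata for the two imaging profiles
#'
#' The two acquisition settings differ in their EFO gates: profile
#' `"dataset1"` uses a 25 kHz lower / 60 kHz upper EFO limit, `"dataset2"`
#' 50 kHz / 100 kHz. `z_flip = TRUE` records that raw data were stored with
#' the cytoplasm at negative z and are flipped for presentation.
#'
#' @param profile `"dataset1"` or `"dataset2"`.
#' @param dataset_id free-text identifier.
#' @param z_flip logical, see above.
#' @return list of class `acquisition_meta`.
#' @export
acquisition_profile <- function(profile = c("dataset1", "dataset2"),
                                dataset_id = profile, z_flip = TRUE) {
  profile <- match.arg(profile)
  lim <- switch(profile,
                dataset1 = c(lower = 25, upper = 60),
                dataset2 = c(lower = 50, upper = 100))
  meta <- list(dataset_id = dataset_id[1],
               efo_lower_kHz = unname(lim["lower"]),
               efo_upper_kHz = unname(lim["upper"]),
               min_photons = if (profile == "dataset1") 20L else 25L,
               base_cycle_ms = 3.3,
               z_flip = isTRUE(z_flip))
  stopifnot(meta$efo_lower_kHz < meta$efo_upper_kHz, meta$min_photons > 0)
  class(meta) <- "acquisition_meta"
  meta
}

#' Split localizations into emitter bursts
#'
#' A burst is a maximal run of localizations of one `trace_id` whose
#' consecutive time gaps do not exceed `max_gap` (default 3 ms — the dye is
#' considered switched off beyond that). A new burst also starts at every
#' `trace_id` change. Concatenating the bursts in order reproduces the
#' input exactly.
#'
#' @param records localization data frame sorted by (`trace_id`, `t`).
#' @param max_gap maximum intra-burst gap in seconds (default 0.003;
#'   `Inf` yields one burst per trace).
#' @return list of data frames, each with attributes `trace_id` and
#'   `channel`.
#' @export
split_bursts <- function(records, max_gap = 0.003) {
  if (!nrow(records)) return(list())
  ord_ok <- !is.unsorted(records$trace_id) &&
    all(tapply(records$t, records$trace_id, function(tt)
      !is.unsorted(tt, strictly = FALSE)))
  if (!ord_ok)
    stop("records must be sorted by (trace_id, t); refusing to sort silently",
         call. = FALSE)
  new_trace <- c(TRUE, diff(records$trace_id) != 0)
  gap <- c(0, diff(records$t))
  burst_id <- cumsum(new_trace | (!new_trace & gap > max_gap))
  idx <- split(seq_len(nrow(records)), burst_id)
  lapply(idx, function(i) {
    b <- records[i, , drop = FALSE]
    rownames(b) <- NULL
    attr(b, "trace_id") <- b$trace_id[1]
    attr(b, "channel") <- b$channel[1]
    b
  })
}
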