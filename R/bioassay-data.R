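# Canonical column set of the interchange CSV. Concentrations are stored in
# ug active ingredient per bottle, never log-transformed on disk; 0 denotes
# the solvent/surfactant control.
BIOASSAY_COLUMNS <- c(
  "institution", "country", "species", "strain", "insecticide",
  "endpoint_type", "bioassay_id", "replicate_id",
  "concentration_ug_per_bottle", "n_exposed", "n_responded",
  "n_chambered", "recording_time_h"
)

# Keys whose combination identifies one bioassay (one concentration series
# run on one occasion in one laboratory).
BIOASSAY_KEYS <- c("institution", "species", "insecticide", "bioassay_id")

#' Construct a bioassay dataset
#'
#' Bundles a validated table of exposure records with free-text provenance.
#' One record is one exposure unit (one cup/bottle replicate at one
#' concentration): for mortality endpoints \code{n_responded} is the number
#' dead at the recording time out of \code{n_exposed}; for oviposition
#' endpoints it is the number of chambered survivors (\code{n_chambered})
#' that did \emph{not} lay eggs.
#'
#' @param records data frame with the canonical columns (see
#'   \code{\link{read_bioassay_csv}}).
#' @param provenance free-text description of origin.
#' @return object of class \code{bioassay_dataset}.
#' @export
bioassay_dataset <- function(records, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(BIOASSAY_COLUMNS, names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- records[, BIOASSAY_COLUMNS]
  validate_bioassay_records(records)
  structure(list(records = records, provenance = provenance),
            class = "bioassay_dataset")
}

#' @export
print.bioassay_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("bioassay_dataset: %d records, %d bioassays, %d institution(s)\n",
              nrow(r), nrow(unique(r[BIOASSAY_KEYS])),
              length(unique(r$institution))))
  cat(sprintf("  species: %s\n", paste(unique(r$species), collapse = ", ")))
  cat(sprintf("  insecticides: %s\n", paste(unique(r$insecticide), collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

validate_bioassay_records <- function(records) {
  fail <- function(rows, what) {
    stop(sprintf("invalid bioassay record(s) at row(s) %s: %s",
                 paste(utils::head(rows, 5L), collapse = ", "), what),
         call. = FALSE)
  }
  num <- c("concentration_ug_per_bottle", "n_exposed", "n_responded",
           "recording_time_h")
  for (col in num) {
    if (!is.numeric(records[[col]]) || anyNA(records[[col]]))
      stop(sprintf("column '%s' must be numeric and complete", col), call. = FALSE)
  }
  if (!is.numeric(records$n_chambered))
    records$n_chambered <- as.numeric(records$n_chambered)
  bad <- which(records$concentration_ug_per_bottle < 0)
  if (length(bad)) fail(bad, "negative concentration")
  bad <- which(records$n_exposed <= 0 | records$n_exposed != round(records$n_exposed))
  if (length(bad)) fail(bad, "n_exposed must be a positive integer")
  bad <- which(records$n_responded < 0 | records$n_responded != round(records$n_responded))
  if (length(bad)) fail(bad, "n_responded must be a non-negative integer")
  bad <- which(records$n_responded > records$n_exposed &
                 records$endpoint_type == "mortality")
  if (length(bad)) fail(bad, "n_responded exceeds n_exposed")
  bad <- which(!records$endpoint_type %in% c("mortality", "oviposition"))
  if (length(bad)) fail(bad, "endpoint_type must be 'mortality' or 'oviposition'")
  ovi <- records$endpoint_type == "oviposition"
  bad <- which(ovi & is.na(records$n_chambered))
  if (length(bad)) fail(bad, "oviposition rows require n_chambered")
  bad <- which(ovi & !is.na(records$n_chambered) &
                 records$n_chambered > records$n_exposed)
  if (length(bad)) fail(bad, "n_chambered exceeds n_exposed")
  bad <- which(ovi & !is.na(records$n_chambered) &
                 records$n_responded > records$n_chambered)
  if (length(bad)) fail(bad, "n_responded exceeds n_chambered")
  # endpoint type must be constant within one bioassay
  key <- interaction(records[BIOASSAY_KEYS], drop = TRUE)
  mixed <- tapply(records$endpoint_type, key, function(e) length(unique(e)) > 1L)
  if (any(mixed))
    stop("bioassay(s) mixing endpoint types: ",
         paste(names(mixed)[mixed], collapse = ", "), call. = FALSE)
  invisible(records)
}

#' Read bioassay records from the canonical CSV
#'
#' Reads a UTF-8, comma-separated file with a header row naming exactly the
#' canonical columns: \code{institution, country, species, strain,
#' insecticide, endpoint_type, bioassay_id, replicate_id,
#' concentration_ug_per_bottle, n_exposed, n_responded, n_chambered,
#' recording_time_h}. \code{n_chambered} is empty for mortality rows.
#' Numbers are parsed with a decimal point regardless of locale.
#'
#' @param path path to the CSV file.
#' @param provenance optional provenance string recorded on the dataset;
#'   defaults to the file path.
#' @return a \code{\link{bioassay_dataset}} with row order preserved.
#' @export
read_bioassay_csv <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(BIOASSAY_COLUMNS, names(records))
  if (length(missing_cols))
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) stop("empty bioassay dataset: ", path, call. = FALSE)
  label_cols <- c("institution", "country", "species", "strain", "insecticide",
                  "endpoint_type", "bioassay_id", "replicate_id")
  records[label_cols] <- lapply(records[label_cols], as.character)
  bioassay_dataset(records, provenance = provenance)
}

#' Write a bioassay dataset to the canonical CSV
#'
#' Counts are written exactly; concentrations with 15 significant digits, so
#' a write/read round trip preserves them to at least 12 significant digits.
#'
#' @param ds a \code{\link{bioassay_dataset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bioassay_csv <- function(ds, path) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  rec <- ds$records
  rec$concentration_ug_per_bottle <-
    formatC(rec$concentration_ug_per_bottle, digits = 15, format = "g")
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Pool replicate counts at one concentration
#'
#' Pooled response for one bioassay at one concentration: the sum of
#' responders across replicate cups/bottles over the sum tested. For
#' oviposition endpoints the denominator is the number of chambered
#' survivors, not the number exposed.
#'
#' @param records data frame of records sharing one bioassay, concentration
#'   and endpoint type.
#' @return list with \code{n_total} (denominator) and \code{y_total}
#'   (summed responders).
#' @export
pool_replicates <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (length(unique(records$endpoint_type)) > 1L)
    stop("cannot pool mixed endpoint types", call. = FALSE)
  if (length(unique(records$concentration_ug_per_bottle)) > 1L)
    stop("cannot pool records at different concentrations", call. = FALSE)
  if ("bioassay_id" %in% names(records) &&
      length(unique(records$bioassay_id)) > 1L)
    stop("cannot pool records from different bioassays", call. = FALSE)
  denom <- if (records$endpoint_type[1L] == "oviposition")
    records$n_chambered else records$n_exposed
  list(n_total = sum(denom), y_total = sum(records$n_responded))
}

#' Abbott correction for control response
#'
#' Corrects an observed response proportion for background (control)
#' response: \code{(p_obs - p_control) / (1 - p_control)}, clamped to
#' \code{[0, 1]} so the result stays a valid probability. In model-based
#' analyses the same correction is carried by the background parameter
#' \code{Z} inside the fit; this explicit form is for descriptive reporting.
#'
#' @param p_obs observed response proportion(s) in \code{[0, 1]}.
#' @param p_control control response proportion in \code{[0, 1)}.
#' @return corrected proportion(s) in \code{[0, 1]}.
#' @examples
#' abbott_correct(0.6, 0.2)  # 0.5
#' @export
abbott_correct <- function(p_obs, p_control) {
  if (any(p_obs < 0) || any(p_obs > 1) || any(p_control < 0) || any(p_control > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (any(p_control == 1))
    stop("correction undefined at 100% control response", call. = FALSE)
  pmin(1, pmax(0, (p_obs - p_control) / (1 - p_control)))
}

#' Oviposition inhibition percentage
#'
#' OI\% compares the proportion of egg-laying females in the treatment
#' against the proportion laying in the control:
#' \code{100 * (1 - treated/control)}, clamped to \code{[0, 100]}.
#'
#' @param treated_laying_prop proportion of chambered treated females laying.
#' @param control_laying_prop proportion of chambered control females laying;
#'   must be \code{> 0}.
#' @return OI as a percentage in \code{[0, 100]}.
#' @examples
#' compute_oi(0.2, 0.8)  # 75
#' @export
compute_oi <- function(treated_laying_prop, control_laying_prop) {
  if (any(control_laying_prop <= 0))
    stop("OI undefined when no control females lay eggs", call. = FALSE)
  if (any(treated_laying_prop < 0) || any(treated_laying_prop > 1) ||
      any(control_laying_prop > 1))
    stop("laying proportions must lie in [0, 1]", call. = FALSE)
  pmin(100, pmax(0, 100 * (1 - treated_laying_prop / control_laying_prop)))
}

#' Quality-control filtering of bioassays
#'
#' Applies the control-based acceptance rules bioassay by bioassay, on
#' counts pooled across the control replicates of each bioassay:
#' \itemize{
#'   \item mortality endpoint: control mortality \code{>= mortality_discard}
#'     (default 20\%) discards the bioassay; strictly between
#'     \code{correction_floor} (default 5\%) and the discard threshold, the
#'     bioassay is accepted with Abbott-style correction (applied through the
#'     background parameter \code{Z} during model fitting); at or below the
#'     floor it is accepted as is.
#'   \item oviposition endpoint: a control laying rate below
#'     \code{oviposition_floor} (default 30\%) discards the bioassay. The
#'     rule is on the \emph{laying} rate, i.e. one minus the control
#'     non-laying proportion.
#' }
#' A bioassay with no control records cannot be evaluated and is excluded
#' from the accepted set with status \code{"unevaluable"}. A control rate of
#' exactly 5\% is left uncorrected (the band is open at both ends); this
#' boundary convention is flagged in the report's reason text.
#'
#' @param ds a \code{\link{bioassay_dataset}}.
#' @param mortality_discard control-mortality discard threshold.
#' @param correction_floor control mortality above which correction applies.
#' @param oviposition_floor minimum acceptable control laying rate.
#' @return list with \code{accepted} (a \code{bioassay_dataset} restricted to
#'   non-discarded, evaluable bioassays) and \code{report} (data frame with
#'   one row per bioassay: keys, \code{status} in \code{accepted},
#'   \code{accepted_with_correction}, \code{discarded}, \code{unevaluable};
#'   \code{control_response_rate}; \code{reason}).
#' @export
apply_qc <- function(ds, mortality_discard = 0.20, correction_floor = 0.05,
                     oviposition_floor = 0.30) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  rec <- ds$records
  key <- interaction(rec[BIOASSAY_KEYS], drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  report <- do.call(rbind, lapply(groups, function(idx) {
    g <- rec[idx, , drop = FALSE]
    out <- g[1L, BIOASSAY_KEYS]
    out$endpoint_type <- g$endpoint_type[1L]
    ctrl <- g[g$concentration_ug_per_bottle == 0, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      out$status <- "unevaluable"
      out$control_response_rate <- NA_real_
      out$reason <- "no control records"
      return(out)
    }
    pooled <- pool_replicates(ctrl)
    rate <- pooled$y_total / pooled$n_total
    out$control_response_rate <- rate
    if (out$endpoint_type == "mortality") {
      if (rate >= mortality_discard) {
        out$status <- "discarded"
        out$reason <- sprintf("control mortality %.1f%% >= %.0f%%",
                              100 * rate, 100 * mortality_discard)
      } else if (rate > correction_floor) {
        out$status <- "accepted_with_correction"
        out$reason <- sprintf(
          "control mortality %.1f%% in (%.0f%%, %.0f%%); Abbott-style correction via Z",
          100 * rate, 100 * correction_floor, 100 * mortality_discard)
      } else {
        out$status <- "accepted"
        out$reason <- sprintf(
          "control mortality %.1f%% <= %.0f%% (boundary convention: exactly %.0f%% is uncorrected)",
          100 * rate, 100 * correction_floor, 100 * correction_floor)
      }
    } else {
      laying <- 1 - rate
      if (laying < oviposition_floor) {
        out$status <- "discarded"
        out$reason <- sprintf("control laying rate %.1f%% < %.0f%%",
                              100 * laying, 100 * oviposition_floor)
      } else {
        out$status <- "accepted"
        out$reason <- sprintf("control laying rate %.1f%% >= %.0f%%",
                              100 * laying, 100 * oviposition_floor)
      }
    }
    out
  }))
  rownames(report) <- NULL
  keep <- report[report$status %in% c("accepted", "accepted_with_correction"), ,
                 drop = FALSE]
  keep_key <- interaction(keep[BIOASSAY_KEYS], drop = TRUE, sep = "\r")
  accepted <- rec[key %in% keep_key, , drop = FALSE]
  rownames(accepted) <- NULL
  acc_ds <- if (nrow(accepted))
    bioassay_dataset(accepted, provenance = ds$provenance)
  else
    structure(list(records = accepted, provenance = ds$provenance),
              class = "bioassay_dataset")
  list(accepted = acc_ds, report = report)
}

# Model-ready (x, n, y) triples: one triple per exposure record, controls at
# x = 0 included. Oviposition denominators use chambered survivors.
fit_data <- function(ds) {
  rec <- if (inherits(ds, "bioassay_dataset")) ds$records else ds
  n <- ifelse(rec$endpoint_type == "oviposition", rec$n_chambered, rec$n_exposed)
  data.frame(x = rec$concentration_ug_per_bottle, n = n, y = rec$n_responded)
}
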