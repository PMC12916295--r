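# ERP dataset container and its plain-text exchange format:
# one TSV matrix per condition (rows = time, columns = modes) plus a JSON
# sidecar holding the time axis, units and subject/session metadata.

#' Evoked-response dataset for one subject and session
#'
#' @param subject subject identifier
#' @param session session label (e.g. "placebo", "drug", "baseline")
#' @param time time axis in ms (uniform step, covering 0-300 ms)
#' @param deviant,standard time x mode response matrices sharing the time
#'   axis
#' @param dt sampling step (ms)
#' @param meta optional named list of provenance metadata
#' @return object of class `erp_dataset`
#' @export
erp_dataset <- function(subject, session, time, deviant, standard,
                        dt = diff(time[1:2]), meta = list()) {
  deviant <- as.matrix(deviant); standard <- as.matrix(standard)
  if (nrow(deviant) != length(time) || nrow(standard) != length(time))
    stop("condition matrices must match the time axis length", call. = FALSE)
  if (ncol(deviant) != ncol(standard))
    stop("conditions must have the same number of modes", call. = FALSE)
  steps <- diff(time)
  if (length(steps) && max(abs(steps - steps[1])) > 1e-9)
    stop("time axis must have a uniform step", call. = FALSE)
  structure(list(subject = as.character(subject),
                 session = as.character(session),
                 time = as.numeric(time), dt = as.numeric(dt),
                 n_modes = ncol(deviant),
                 deviant = deviant, standard = standard, meta = meta),
            class = "erp_dataset")
}

#' @export
print.erp_dataset <- function(x, ...) {
  cat(sprintf("erp_dataset: subject %s, session %s; %d samples x %d modes (%g-%g ms, dt = %g ms)\n",
              x$subject, x$session, length(x$time), x$n_modes,
              min(x$time), max(x$time), x$dt))
  invisible(x)
}

#' Write / read an ERP dataset
#'
#' `write_erp()` writes `<stem>_deviant.tsv`, `<stem>_standard.tsv` and
#' `<stem>.json` where `<stem> = <dir>/<subject>_<session>`; `read_erp()`
#' restores the dataset losslessly (to numeric text precision, ~1e-15
#' relative).
#'
#' @param x an `erp_dataset`
#' @param dir output directory (created if needed)
#' @return the sidecar path (`write_erp`), an `erp_dataset` (`read_erp`)
#' @export
write_erp <- function(x, dir) {
  stopifnot(inherits(x, "erp_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, paste0(x$subject, "_", x$session))
  for (cond in c("deviant", "standard")) {
    write.table(format(x[[cond]], digits = 17, trim = TRUE, scientific = TRUE),
                paste0(stem, "_", cond, ".tsv"),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  sidecar <- list(subject = x$subject, session = x$session,
                  dt = x$dt, t0 = x$time[1], n_samples = length(x$time),
                  n_modes = x$n_modes, units = list(time = "ms"),
                  meta = x$meta)
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_erp
#' @param sidecar path to the `<subject>_<session>.json` sidecar
#' @export
read_erp <- function(sidecar) {
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar, call. = FALSE)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("subject", "session", "dt", "t0", "n_samples", "n_modes")
  miss <- need[!need %in% names(sc) | vapply(sc[need], is.null, TRUE)[match(need, names(sc), nomatch = NA)] %in% TRUE]
  miss <- setdiff(need, names(sc))
  if (length(miss))
    stop("malformed sidecar ", sidecar, ": missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  stem <- sub("\\.json$", "", sidecar)
  mats <- lapply(c("deviant", "standard"), function(cond) {
    f <- paste0(stem, "_", cond, ".tsv")
    if (!file.exists(f)) stop("missing condition file: ", f, call. = FALSE)
    as.matrix(read.table(f, sep = "\t", header = FALSE))
  })
  if (nrow(mats[[1]]) != nrow(mats[[2]]))
    stop("condition matrices have unequal length in ", stem, call. = FALSE)
  if (nrow(mats[[1]]) != sc$n_samples)
    stop("sidecar/time-axis mismatch in ", stem, ": sidecar says ",
         sc$n_samples, " samples, file has ", nrow(mats[[1]]), call. = FALSE)
  time <- sc$t0 + sc$dt * (seq_len(sc$n_samples) - 1)
  erp_dataset(sc$subject, sc$session, time,
              deviant = unname(mats[[1]]), standard = unname(mats[[2]]),
              dt = sc$dt, meta = if (is.null(sc$meta)) list() else sc$meta)
}
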