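#' Drug-screen plate data for one sample
#'
#' Raw viability readouts (luminescence units) for one screened sample.
#' Each well is a `condition` (a drug label, or a vehicle label equal to its
#' `vehicle_class`), a `vehicle_class` (`"DMSO"` or `"H2O"`) naming the
#' solvent control it is normalized against, a `replicate` index and a
#' non-negative `readout`. Wells whose `condition` equals their
#' `vehicle_class` are the vehicle (solvent-only) control wells.
#'
#' Platinum-based conditions (cisplatin, gemcitabine and their combination)
#' are conventionally referenced to the H2O vehicle; all other drugs to
#' DMSO.
#'
#' @param sample_id Sample identifier.
#' @param wells Data.frame with columns `condition`, `vehicle_class`,
#'   `replicate`, `readout`.
#' @return An object of class `plate_data`.
#' @export
plate_data <- function(sample_id, wells) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  req <- c("condition", "vehicle_class", "replicate", "readout")
  miss <- setdiff(req, names(wells))
  if (length(miss) > 0)
    stop("plate wells are missing column(s): ", paste(miss, collapse = ", "))
  wells <- as.data.frame(wells)[req]
  wells$condition <- as.character(wells$condition)
  wells$vehicle_class <- as.character(wells$vehicle_class)
  bad <- setdiff(unique(wells$vehicle_class), c("DMSO", "H2O"))
  if (length(bad) > 0)
    stop("unknown vehicle_class value(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(wells$readout) | wells$readout < 0))
    stop("readouts must be finite and non-negative")
  # every drug condition needs vehicle wells of its class on the same plate
  is_vehicle <- wells$condition == wells$vehicle_class
  for (vc in unique(wells$vehicle_class[!is_vehicle])) {
    if (sum(is_vehicle & wells$vehicle_class == vc) == 0)
      stop("sample ", sample_id, ": no ", vc,
           " vehicle wells for conditions referencing ", vc)
  }
  reps <- table(wells$condition)
  if (any(reps < 2))
    warning("sample ", sample_id, ": condition(s) with a single replicate: ",
            paste(names(reps)[reps < 2], collapse = ", "),
            " (variance-based statistics need >= 2)")
  rownames(wells) <- NULL
  structure(list(sample_id = sample_id, wells = wells), class = "plate_data")
}

#' @export
print.plate_data <- function(x, ...) {
  cat("plate_data:", x$sample_id, "-", nrow(x$wells), "wells,",
      length(setdiff(unique(x$wells$condition),
                     unique(x$wells$vehicle_class))), "drug conditions\n")
  invisible(x)
}

#' Read drug-screen plate tables from CSV
#'
#' CSV columns: `sample_id`, `condition`, `vehicle_class`, `replicate`,
#' `readout`. Returns one [plate_data()] per sample.
#'
#' @param path Path to the CSV file.
#' @return A named list of `plate_data` objects, one per sample.
#' @export
read_plates <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "vehicle_class", "replicate", "readout")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("plate file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  plates <- lapply(split(tab, tab$sample_id), function(sub)
    plate_data(sub$sample_id[1], sub[setdiff(req, "sample_id")]))
  plates[unique(tab$sample_id)]
}

#' Write plate data to CSV
#'
#' @param plates A `plate_data` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plates <- function(plates, path) {
  if (inherits(plates, "plate_data")) plates <- list(plates)
  tab <- do.call(rbind, lapply(plates, function(p)
    cbind(sample_id = p$sample_id, p$wells)))
  write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
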